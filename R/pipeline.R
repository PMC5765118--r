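#' Run the complete synthetic-study pipeline
#'
#' Simulates a study (genome, annotation, per-sample SAM alignments, protein
#' and peptide tables with planted ground truth), then runs every analysis
#' stage through the on-disk files: IR quantification, retention filtering,
#' differential intron retention and protein calling per stimulus, junction
#' database construction from CTRL-retained introns, peptide matching and
#' junction-peptide quantification, transcript expression, and the
#' integrative outputs (stimulus partition, protein-mRNA table, validation
#' table). All outputs are TSV/FASTA files under `out_dir` plus an md5
#' manifest; a rerun with the same configuration reproduces identical files.
#'
#' @param config A [sim_config()]; its seed drives every stage.
#' @param out_dir Output directory.
#' @param filter An [ir_filter_params()].
#' @param diff A [diff_config()]; defaults to `diff_config(seed = config$seed)`.
#' @param flank Junction window half-width in exonic nt (default 75).
#' @param strandedness SAM library protocol (default `"reverse"`).
#' @param il_equivalent Peptide matching I/L equivalence (default `FALSE`).
#' @param quiet Suppress progress messages.
#' @return A list with all intermediate and final objects (see Details) and
#'   `paths`/`manifest` describing the files written.
#' @export
run_all <- function(config = sim_config(), out_dir,
                    filter = ir_filter_params(),
                    diff = diff_config(seed = config$seed),
                    flank = 75L,
                    strandedness = "reverse",
                    il_equivalent = FALSE,
                    quiet = FALSE) {
  say <- function(...) if (!quiet) message("[run_all] ", ...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  say("simulating study (seed ", config$seed, ")")
  study <- simulate_study(config, out_dir)
  samples <- study$samples
  stimuli <- config$stimuli

  say("reading inputs back from disk")
  genome <- read_genome(study$paths$genome)
  annotation <- read_annotation(study$paths$gtf)
  introns <- derive_introns(annotation)
  alignments <- lapply(study$paths$sam, read_alignments,
                       strandedness = strandedness)

  say("quantifying intron retention (", length(introns), " introns, ",
      length(alignments), " samples)")
  irm <- quantify_ir(alignments, introns, annotation, samples,
                     params = filter)
  paths <- list(ir_matrix = file.path(out_dir, "ir_matrix.tsv"))
  write_tsv(as.data.frame(irm), paths$ir_matrix)

  say("applying retention filter")
  retained <- lapply(c("CTRL", stimuli), function(g) {
    filter_retained(irm, filter, g)
  })
  names(retained) <- c("CTRL", stimuli)

  say("building junction database from CTRL-retained introns")
  db <- build_junction_db(genome, annotation,
                          introns[introns$intron_id %in% retained$CTRL],
                          flank = flank)
  paths$junctions <- file.path(out_dir, "junctions.fasta")
  write_junction_fasta(db, paths$junctions)

  say("matching peptides")
  peptide_table <- read_tsv(study$paths$peptides)
  matches <- match_peptides(peptide_table$peptide_seq,
                            read_junction_fasta(paths$junctions),
                            il_equivalent = il_equivalent)
  paths$matches <- file.path(out_dir, "peptide_matches.tsv")
  write_tsv(matches, paths$matches)

  protein_table <- read_tsv(study$paths$proteins)
  prot_mat <- as.matrix(protein_table[, names(samples)])
  rownames(prot_mat) <- protein_table$protein_id
  gene_of_protein <- stats::setNames(protein_table$gene_id,
                                     protein_table$protein_id)
  intron_genes <- stats::setNames(introns$gene_id, introns$intron_id)
  junction_genes <- stats::setNames(db$gene_id[db$frame == 0L],
                                    db$junction_id[db$frame == 0L])

  tx_lengths <- vapply(transcript_exons(annotation), function(ex) {
    sum(GenomicRanges::width(ex))
  }, numeric(1L))
  counts <- vapply(alignments, count_reads_per_transcript,
                   FUN.VALUE = numeric(length(tx_lengths)),
                   annotation = annotation)

  ir_diff <- list(); protein_diff <- list(); junction_pep <- list()
  expression <- list(); scatter <- list(); validation <- list()
  for (stim in stimuli) {
    say("differential analysis: ", stim, " vs CTRL")
    tested <- union(retained$CTRL, retained[[stim]])
    ir_diff[[stim]] <- call_differential_introns(irm, stim, diff,
                                                 introns = tested)
    pd <- call_differential_proteins(prot_mat, samples, stim, diff)
    pd$gene_id <- unname(gene_of_protein[pd$feature_id])
    protein_diff[[stim]] <- pd
    junction_pep[[stim]] <- quantify_junction_peptides(
      matches, peptide_table, samples, stim, diff,
      junction_ids = unique(db$junction_id))
    expression[[stim]] <- transcript_expression(counts, tx_lengths, samples,
                                                stim, diff)
    scatter[[stim]] <- protein_mrna_scatter(pd, expression[[stim]], diff)
    validation[[stim]] <- build_validation_table(
      ir_diff[[stim]], pd, junction_pep[[stim]],
      intron_genes, junction_genes, stim)
    for (what in c("ir_diff", "protein_diff", "junction_peptides",
                   "expression", "scatter")) {
      obj <- switch(what, ir_diff = ir_diff[[stim]],
                    protein_diff = protein_diff[[stim]],
                    junction_peptides = junction_pep[[stim]],
                    expression = expression[[stim]],
                    scatter = scatter[[stim]])
      p <- file.path(out_dir, sprintf("%s_%s.tsv", what, stim))
      paths[[sprintf("%s_%s", what, stim)]] <- p
      write_tsv(obj, p)
    }
  }

  say("integrating across stimuli")
  partition <- partition_stimulus_sets(protein_diff[[stimuli[1L]]],
                                       protein_diff[[stimuli[2L]]],
                                       names_ab = stimuli[1:2])
  paths$partition <- file.path(out_dir, "partition.tsv")
  write_tsv(data.frame(
    feature_id = c(partition$only_a, partition$only_b, partition$common),
    set = rep(c(paste0("only_", stimuli[1L]), paste0("only_", stimuli[2L]),
                "common"),
              c(length(partition$only_a), length(partition$only_b),
                length(partition$common)))
  ), paths$partition)
  validation_all <- do.call(rbind, validation)
  paths$validation <- file.path(out_dir, "validation.tsv")
  write_tsv(validation_all, paths$validation)

  all_files <- c(unlist(study$paths, use.names = FALSE),
                 unlist(paths, use.names = FALSE))
  manifest <- data.frame(file = basename(all_files),
                         md5 = unname(tools::md5sum(all_files)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), ]
  write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  say("done: ", nrow(manifest), " files")

  invisible(list(
    config = config, paths = c(study$paths, paths), samples = samples,
    study = study, ir = irm, retained = retained, junction_db = db,
    matches = matches, ir_diff = ir_diff, protein_diff = protein_diff,
    junction_peptides = junction_pep, expression = expression,
    partition = partition, scatter = scatter, validation = validation_all,
    manifest = manifest
  ))
}
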