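#' Partition significant features between two stimuli
#'
#' Set algebra on the significant features of two differential analyses:
#' features responding only to the first stimulus, only to the second, or to
#' both; common features are split by effect-sign concordance.
#'
#' @param res_a,res_b data.frames with `feature_id`, `effect`,
#'   `significant` columns (e.g. from [call_differential_proteins()]).
#' @param names_ab Labels of the two stimuli (for printing).
#' @return A list of class `stimulus_partition`: `only_a`, `only_b`,
#'   `common` (feature-id vectors) and `common_direction` (counts: both_down,
#'   both_up, discordant). The three sets are disjoint and their union is
#'   the set of all significant features.
#' @export
partition_stimulus_sets <- function(res_a, res_b,
                                    names_ab = c("COLL", "TRAP")) {
  sig_a <- res_a$feature_id[res_a$significant]
  sig_b <- res_b$feature_id[res_b$significant]
  common <- intersect(sig_a, sig_b)
  ea <- stats::setNames(res_a$effect, res_a$feature_id)[common]
  eb <- stats::setNames(res_b$effect, res_b$feature_id)[common]
  out <- list(
    only_a = setdiff(sig_a, sig_b),
    only_b = setdiff(sig_b, sig_a),
    common = common,
    common_direction = c(both_down = sum(ea < 0 & eb < 0),
                         both_up = sum(ea > 0 & eb > 0),
                         discordant = sum(sign(ea) != sign(eb))),
    names_ab = names_ab
  )
  stopifnot(length(intersect(out$only_a, out$only_b)) == 0L,
            length(intersect(out$only_a, out$common)) == 0L,
            length(intersect(out$only_b, out$common)) == 0L,
            setequal(c(out$only_a, out$only_b, out$common),
                     union(sig_a, sig_b)))
  class(out) <- "stimulus_partition"
  out
}

#' @export
print.stimulus_partition <- function(x, ...) {
  cat(sprintf("<stimulus_partition> %s only: %d; %s only: %d; common: %d (down %d, up %d, discordant %d)\n",
              x$names_ab[1L], length(x$only_a), x$names_ab[2L],
              length(x$only_b), length(x$common),
              x$common_direction[["both_down"]],
              x$common_direction[["both_up"]],
              x$common_direction[["discordant"]]))
  invisible(x)
}

#' Count reads per transcript
#'
#' A read is assigned to a transcript when any of its aligned blocks
#' overlaps any exon of the transcript on a compatible fragment strand;
#' reads are counted once per transcript.
#'
#' @param aln A `platelet_alignments` object.
#' @param annotation Annotation `GRanges`.
#' @param stranded Require fragment-strand agreement (default `TRUE`).
#' @return Named integer vector of read counts, one per transcript.
#' @export
count_reads_per_transcript <- function(aln, annotation, stranded = TRUE) {
  byt <- transcript_exons(annotation)
  blocks <- unlist(aln$blocks, use.names = FALSE)
  ridx <- rep(seq_along(aln$blocks), lengths(aln$blocks))
  counts <- stats::setNames(integer(length(byt)), names(byt))
  for (tx in names(byt)) {
    ex <- byt[[tx]]
    contig <- as.character(GenomicRanges::seqnames(ex))[1L]
    strand <- as.character(GenomicRanges::strand(ex))[1L]
    on_contig <- aln$reads$contig[ridx] == contig
    if (stranded) {
      fs <- aln$reads$fragment_strand[ridx]
      on_contig <- on_contig & (fs == strand | fs == "*")
    }
    ov <- IRanges::overlapsAny(blocks, IRanges::ranges(ex)) & on_contig
    counts[[tx]] <- length(unique(ridx[ov]))
  }
  counts
}

#' Transcript expression records
#'
#' Read counts, FPKM, the expressed flag (median count in the group >= the
#' read threshold) and a simple differential call: effect is the log2 ratio
#' of mean FPKM (treated vs CTRL), significance from the permutation
#' machinery on log2(FPKM + 1) at BH-FDR `config$fdr_rna` combined with the
#' linear fold-change cutoff `config$fc_cutoff_rna`.
#'
#' @param counts Matrix of transcript read counts (transcripts x samples).
#' @param lengths_nt Named exonic lengths per transcript.
#' @param groups Named group labels for the columns.
#' @param stimulus Treated group.
#' @param config A [diff_config()].
#' @param min_reads Expression threshold in reads (default 10).
#' @return data.frame: transcript_id, gene_id (parsed from the
#'   `gene.t` naming if possible), mean FPKM per compared group, expressed
#'   flags per group, effect (log2FC), p_perm, p_adj, significant.
#' @export
transcript_expression <- function(counts, lengths_nt, groups, stimulus,
                                  config = diff_config(), min_reads = 10) {
  samples <- colnames(counts)
  totals <- colSums(counts)
  fpkm <- vapply(seq_along(samples), function(j) {
    compute_fpkm(counts[, j], lengths_nt[rownames(counts)], totals[j])
  }, numeric(nrow(counts)))
  dimnames(fpkm) <- dimnames(counts)
  cols_ctrl <- samples[groups[samples] == "CTRL"]
  cols_trt <- samples[groups[samples] == stimulus]
  med_count <- function(cols) apply(counts[, cols, drop = FALSE], 1L,
                                    stats::median)
  mean_fpkm_ctrl <- rowMeans(fpkm[, cols_ctrl, drop = FALSE])
  mean_fpkm_trt <- rowMeans(fpkm[, cols_trt, drop = FALSE])
  effect <- ifelse(mean_fpkm_ctrl > 0 & mean_fpkm_trt > 0,
                   log2(mean_fpkm_trt / mean_fpkm_ctrl), NA_real_)
  labels <- factor(rep(c("CTRL", stimulus),
                       c(length(cols_ctrl), length(cols_trt))),
                   levels = c("CTRL", stimulus))
  res <- permutation_test(log2(fpkm[, c(cols_ctrl, cols_trt),
                                    drop = FALSE] + 1),
                          labels, config)
  p_adj <- adjust_p(res$p_perm, "bh_fdr")
  data.frame(
    transcript_id = rownames(counts),
    gene_id = sub("\\.t[0-9]+$", "", rownames(counts)),
    fpkm_ctrl = mean_fpkm_ctrl, fpkm_trt = mean_fpkm_trt,
    expressed_ctrl = med_count(cols_ctrl) >= min_reads,
    expressed_trt = med_count(cols_trt) >= min_reads,
    effect = effect, p_perm = res$p_perm, p_adj = p_adj,
    significant = !is.na(effect) & p_adj <= config$fdr_rna &
      2^abs(effect) >= config$fc_cutoff_rna,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Protein-versus-mRNA comparison table
#'
#' One row per differential protein with the fold-change of its transcript
#' and the transcript's significance flags, classifying each protein as
#' `concordant` (mRNA passes fold-change and FDR thresholds with the same
#' sign), `discordant` (mRNA passes with opposite sign), `protein_only`
#' (mRNA fails either threshold) or `no_mrna` (no matching transcript).
#'
#' @param protein_results data.frame from [call_differential_proteins()]
#'   plus a `gene_id` column.
#' @param expression data.frame from [transcript_expression()].
#' @param config A [diff_config()].
#' @return data.frame: gene_id, protein_effect, mrna_effect,
#'   mrna_significant, class.
#' @export
protein_mrna_scatter <- function(protein_results, expression,
                                 config = diff_config()) {
  sig <- protein_results[protein_results$significant, , drop = FALSE]
  m <- match(sig$gene_id, expression$gene_id)
  mrna_effect <- expression$effect[m]
  mrna_sig <- expression$significant[m]
  cls <- ifelse(is.na(m), "no_mrna",
         ifelse(!mrna_sig | is.na(mrna_effect), "protein_only",
         ifelse(sign(mrna_effect) == sign(sig$effect),
                "concordant", "discordant")))
  data.frame(gene_id = sig$gene_id, protein_effect = sig$effect,
             mrna_effect = mrna_effect, mrna_significant = mrna_sig,
             class = cls, stringsAsFactors = FALSE, row.names = NULL)
}

#' Joint intron-removal / protein / junction-peptide validation table
#'
#' One row per gene and stimulus combining the strongest intron-removal
#' signal of the gene with its protein change and its junction-peptide
#' change. Classes: `validated` when a significant intron removal (negative
#' IR change) is accompanied by a significant junction-peptide or protein
#' increase; `partial` when the removal is significant but neither
#' accumulation is; `not_significant` otherwise. The class is a pure
#' function of the three flag/sign pairs.
#'
#' @param ir_results data.frame from [call_differential_introns()].
#' @param protein_results data.frame from [call_differential_proteins()]
#'   plus `gene_id`.
#' @param junction_peptides data.frame from [quantify_junction_peptides()].
#' @param intron_genes Named character vector: gene id per intron id.
#' @param junction_genes Named character vector: gene id per junction id.
#' @param stimulus Stimulus label recorded in the rows.
#' @return data.frame: gene_id, stimulus, delta_ir, ir_significant,
#'   protein_log2fc, protein_significant, junction_peptide_log2fc,
#'   peptide_significant, peptide_detected, class.
#' @export
build_validation_table <- function(ir_results, protein_results,
                                   junction_peptides, intron_genes,
                                   junction_genes, stimulus) {
  genes <- unique(unname(intron_genes[ir_results$feature_id]))
  rows <- lapply(genes, function(g) {
    iids <- names(intron_genes)[intron_genes == g]
    ir <- ir_results[ir_results$feature_id %in% iids, , drop = FALSE]
    # strongest removal signal: the significant intron with the most
    # negative change, else the intron with the smallest change
    pick <- if (any(ir$significant)) {
      s <- ir[ir$significant, , drop = FALSE]
      s[which.min(s$effect), ]
    } else ir[which.min(ir$effect), ]
    delta_ir <- pick$effect
    ir_sig <- pick$significant
    pr <- protein_results[protein_results$gene_id == g, , drop = FALSE]
    p_fc <- if (nrow(pr) > 0L) pr$effect[1L] else NA_real_
    p_sig <- if (nrow(pr) > 0L) pr$significant[1L] else FALSE
    jids <- names(junction_genes)[junction_genes == g]
    jp <- junction_peptides[junction_peptides$junction_id %in% jids &
                              junction_peptides$detected, , drop = FALSE]
    if (nrow(jp) > 0L) {
      jbest <- jp[which.max(abs(jp$effect)), ]
      jp_fc <- jbest$effect; jp_sig <- jbest$significant; jp_det <- TRUE
    } else {
      jp_fc <- NA_real_; jp_sig <- FALSE; jp_det <- FALSE
    }
    cls <- classify_validation(ir_sig, delta_ir, p_sig, p_fc, jp_sig, jp_fc)
    data.frame(gene_id = g, stimulus = stimulus, delta_ir = delta_ir,
               ir_significant = ir_sig, protein_log2fc = p_fc,
               protein_significant = p_sig, junction_peptide_log2fc = jp_fc,
               peptide_significant = jp_sig, peptide_detected = jp_det,
               class = cls, stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L) {
    return(data.frame(gene_id = character(), stimulus = character(),
                      delta_ir = numeric(), ir_significant = logical(),
                      protein_log2fc = numeric(),
                      protein_significant = logical(),
                      junction_peptide_log2fc = numeric(),
                      peptide_significant = logical(),
                      peptide_detected = logical(), class = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Validation class from flag/sign pairs
#'
#' @param ir_sig,delta_ir Intron-removal significance and IR change.
#' @param p_sig,p_fc Protein significance and log2FC.
#' @param jp_sig,jp_fc Junction-peptide significance and log2FC.
#' @return `"validated"`, `"partial"` or `"not_significant"`.
#' @export
classify_validation <- function(ir_sig, delta_ir, p_sig, p_fc,
                                jp_sig, jp_fc) {
  removal <- isTRUE(ir_sig) && !is.na(delta_ir) && delta_ir < 0
  accumulation <- (isTRUE(jp_sig) && !is.na(jp_fc) && jp_fc > 0) ||
    (isTRUE(p_sig) && !is.na(p_fc) && p_fc > 0)
  if (removal && accumulation) "validated"
  else if (removal) "partial"
  else "not_significant"
}
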