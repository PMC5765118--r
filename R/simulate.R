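#' Simulation configuration
#'
#' Bundles all parameters of the synthetic-data generator. Defaults emulate
#' the study design the package targets: three resting (CTRL) and three
#' stimulated biological replicates per agonist (COLL, TRAP), stranded
#' single-end gapped alignments, per-intron baseline retention with planted
#' removal effects in the stimulated groups, log-normal TMT-like protein
#' intensities with planted fold-changes, and junction-spanning peptides
#' whose abundance tracks splicing.
#'
#' @param seed Integer root seed; every stochastic stage derives its own
#'   stream from it.
#' @param n_genes Number of simulated genes (one transcript each, 2-4 exons).
#' @param n_replicates Biological replicates per group (>= 2).
#' @param stimuli Names of the stimulated groups.
#' @param exon_len,intron_len Length ranges (nt), inclusive.
#' @param read_len Read length (nt); must not exceed `min(intron_len)`.
#' @param depth Expected junction-evidence depth per intron and sample: the
#'   sum of expected intronic coverage and expected junction-read count.
#' @param ir_ctrl Range of the uniform baseline (resting) IR ratio.
#' @param removal_frac Fraction of introns planted with a removal effect,
#'   per stimulus.
#' @param removal_delta Treated-minus-control change in true IR for planted
#'   introns (negative = removal).
#' @param protein_fc Planted protein log2 fold-change (up) for genes whose
#'   intron removal is coupled to translation.
#' @param protein_frac_extra Fraction of remaining genes given an uncoupled
#'   planted protein change (random sign) per stimulus.
#' @param noise_sd Standard deviation of log2-intensity noise for protein
#'   and peptide tables.
#' @param junction_peptide_rate Fraction of planted-removal genes that also
#'   emit a junction-spanning peptide ("spliced and translated" genes).
#' @param peptide_fc Planted junction-peptide log2 fold-change in the
#'   stimulated group(s) where the intron is removed.
#' @param expr_reads Expected background exonic reads per transcript and
#'   sample (drives transcript read counts / FPKM).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 30L,
                       n_replicates = 3L,
                       stimuli = c("COLL", "TRAP"),
                       exon_len = c(90L, 150L),
                       intron_len = c(260L, 440L),
                       read_len = 50L,
                       depth = 60,
                       ir_ctrl = c(0.35, 0.75),
                       removal_frac = 0.25,
                       removal_delta = -0.4,
                       protein_fc = 1,
                       protein_frac_extra = 0.15,
                       noise_sd = 0.1,
                       junction_peptide_rate = 0.8,
                       peptide_fc = 1.5,
                       expr_reads = 120) {
  if (read_len > min(intron_len)) {
    stop("intron_len range must not fall below read_len")
  }
  if (n_replicates < 2L) stop("n_replicates must be >= 2")
  stopifnot(removal_delta <= 0, depth > 0, n_genes >= 1L)
  structure(as.list(environment()), class = "sim_config")
}

# Derive a per-stage seed from the root seed; stays below 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 7919 + as.double(offset) * 104729) %% 2147483629)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

runif_int <- function(n, range) {
  if (range[1L] == range[2L]) rep(as.integer(range[1L]), n)
  else sample(seq.int(range[1L], range[2L]), n, replace = TRUE)
}

#' Simulate a toy genome and gene annotation
#'
#' Genes are laid head-to-tail on a single contig with fixed spacers; each
#' gene has one transcript of 2-4 exons with i.i.d. uniform ACGT sequence.
#' Every tenth gene carries a snoRNA feature inside its first intron so that
#' exclusion masks are exercised downstream.
#'
#' @param config A [sim_config()].
#' @return A list with `genome` (DNAStringSet) and `annotation` (GRanges as
#'   from [read_annotation()]). Deterministic given `config$seed`.
#' @export
simulate_genome_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, 1L), {
    spacer <- 200L
    cursor <- spacer
    feats <- list()
    for (g in seq_len(config$n_genes)) {
      gid <- sprintf("g%03d", g)
      tid <- paste0(gid, ".t1")
      n_exons <- sample(2:4, 1L)
      elens <- runif_int(n_exons, config$exon_len)
      ilens <- runif_int(n_exons - 1L, config$intron_len)
      strand <- if (g %% 2L == 0L) "-" else "+"
      starts <- integer(n_exons)
      pos <- cursor
      for (i in seq_len(n_exons)) {
        starts[i] <- pos
        pos <- pos + elens[i] + if (i < n_exons) ilens[i] else 0L
      }
      ends <- starts + elens - 1L
      rows <- data.frame(
        start = c(starts[1L], starts[1L], starts),
        end = c(ends[n_exons], ends[n_exons], ends),
        type = c("gene", "transcript", rep("exon", n_exons)),
        strand = strand, gene_id = gid,
        transcript_id = c(NA, tid, rep(tid, n_exons)),
        stringsAsFactors = FALSE
      )
      if (g %% 10L == 0L && n_exons >= 2L) {
        mid <- (ends[1L] + starts[2L]) %/% 2L
        rows <- rbind(rows, data.frame(
          start = mid - 30L, end = mid + 29L, type = "snoRNA",
          strand = strand, gene_id = paste0(gid, ".sno"),
          transcript_id = NA, stringsAsFactors = FALSE
        ))
      }
      feats[[g]] <- rows
      cursor <- ends[n_exons] + spacer
    }
    feats <- do.call(rbind, feats)
    contig_len <- cursor + spacer
    genome <- Biostrings::DNAStringSet(paste(
      sample(c("A", "C", "G", "T"), contig_len, replace = TRUE),
      collapse = ""
    ))
    names(genome) <- "chr1"
    anno <- GenomicRanges::GRanges(
      seqnames = "chr1",
      ranges = IRanges::IRanges(feats$start, feats$end),
      strand = feats$strand,
      type = feats$type, gene_id = feats$gene_id,
      transcript_id = feats$transcript_id
    )
    list(genome = genome, annotation = S4Vectors::sort(anno, ignore.strand = TRUE))
  })
}

#' Plant ground-truth effects on a simulated annotation
#'
#' Draws baseline IR ratios per intron, selects planted removal introns per
#' stimulus, couples a subset of removal genes to protein and junction
#' peptide up-regulation ("spliced and translated" genes), and plants
#' additional uncoupled protein fold-changes.
#'
#' @param config A [sim_config()].
#' @param introns Introns from [derive_introns()] on the simulated annotation.
#' @return A list of class `sim_truth` with elements `ir` (data.frame:
#'   intron_id, gene_id, plus one true-IR column per group),
#'   `planted_removal` (list of intron-id vectors per stimulus),
#'   `protein_fc` (data.frame gene_id x stimulus log2FC), and `genes`
#'   (data.frame: gene_id, spliced_and_translated flag, emitting stimulus).
#' @export
simulate_truth <- function(config, introns) {
  with_seed(derive_seed(config$seed, 2L), {
    ids <- introns$intron_id
    n <- length(ids)
    base_ir <- stats::runif(n, config$ir_ctrl[1L], config$ir_ctrl[2L])
    ir <- data.frame(intron_id = ids, gene_id = introns$gene_id,
                     CTRL = base_ir, stringsAsFactors = FALSE)
    n_plant <- max(1L, round(config$removal_frac * n))
    # removal effects are planted on introns retained at baseline: the
    # filter-then-test design only ever calls removal for introns above the
    # per-sample retention cut in resting samples, so detectable planted
    # events must start from the upper part of the baseline IR distribution
    eligible <- which(base_ir > stats::quantile(base_ir, 0.4))
    planted <- list()
    for (stim in config$stimuli) {
      ir[[stim]] <- base_ir
      pick <- sort(sample(eligible, min(n_plant, length(eligible))))
      planted[[stim]] <- ids[pick]
      ir[[stim]][pick] <- pmin(1, pmax(0, base_ir[pick] + config$removal_delta))
    }
    removal_genes <- unique(ir$gene_id[ids %in% unlist(planted)])
    n_emit <- round(config$junction_peptide_rate * length(removal_genes))
    emitters <- sort(sample(removal_genes, n_emit))
    all_genes <- unique(introns$gene_id)
    pfc <- matrix(0, nrow = length(all_genes), ncol = length(config$stimuli),
                  dimnames = list(all_genes, config$stimuli))
    for (stim in config$stimuli) {
      stim_genes <- unique(ir$gene_id[ids %in% planted[[stim]]])
      coupled <- intersect(stim_genes, emitters)
      pfc[coupled, stim] <- config$protein_fc
      pool <- setdiff(all_genes, removal_genes)
      n_extra <- round(config$protein_frac_extra * length(pool))
      if (n_extra > 0L) {
        extra <- sample(pool, n_extra)
        pfc[extra, stim] <- sample(c(-1, 1), n_extra, replace = TRUE) *
          config$protein_fc
      }
    }
    genes <- data.frame(
      gene_id = all_genes,
      spliced_and_translated = all_genes %in% emitters,
      stringsAsFactors = FALSE
    )
    structure(list(ir = ir, planted_removal = planted,
                   protein_fc = as.data.frame(pfc), genes = genes),
              class = "sim_truth")
  })
}

#' Sample names and group labels of a simulated study
#'
#' @param config A [sim_config()].
#' @return Named character vector: names are sample ids, values are group
#'   labels (CTRL plus each stimulus).
#' @export
sim_samples <- function(config) {
  groups <- c("CTRL", config$stimuli)
  samples <- unlist(lapply(groups, function(g) {
    paste0(g, "_", seq_len(config$n_replicates))
  }))
  stats::setNames(rep(groups, each = config$n_replicates), samples)
}

#' Simulate one sample's stranded gapped alignments (SAM)
#'
#' For each intron with true IR ratio `psi` and configured depth `D`, the
#' generator draws `Pois((1 - psi) * D)` junction-spanning reads whose CIGAR
#' gap matches the intron exactly, and enough fully-intronic reads that the
#' expected interior per-base coverage is `psi * D`. Background exonic reads
#' provide transcript-level counts. Strand flags follow the dUTP
#' reverse-stranded protocol: the read aligns opposite to the transcript.
#'
#' @param config A [sim_config()].
#' @param sim Output of [simulate_genome_annotation()].
#' @param truth Output of [simulate_truth()].
#' @param sample_id Sample name (see [sim_samples()]).
#' @param group Group label of the sample (`"CTRL"` or a stimulus).
#' @param path Output SAM path.
#' @return `path`, invisibly. Deterministic given config seed and sample id.
#' @export
simulate_alignments <- function(config, sim, truth, sample_id, group, path) {
  introns <- derive_introns(sim$annotation)
  exons <- sim$annotation[sim$annotation$type == "exon"]
  stage_seed <- derive_seed(config$seed, 100L + match(sample_id, names(sim_samples(config))))
  L <- config$read_len
  contig_len <- Biostrings::width(sim$genome)[[1L]]
  with_seed(stage_seed, {
    recs <- character(0)
    flag_for <- function(gene_strand) if (gene_strand == "+") 16L else 0L
    k <- 0L
    emit <- function(qname, flag, pos, cigar) {
      sprintf("%s\t%d\tchr1\t%d\t255\t%s\t*\t0\t0\t*\t*", qname, flag, pos, cigar)
    }
    out <- vector("list", length(introns) + config$n_genes)
    oi <- 0L
    for (i in seq_along(introns)) {
      intr <- introns[i]
      psi <- truth$ir[[group]][truth$ir$intron_id == intr$intron_id]
      ist <- GenomicRanges::start(intr); ien <- GenomicRanges::end(intr)
      ilen <- ien - ist + 1L
      strand <- as.character(GenomicRanges::strand(intr))
      fl <- flag_for(strand)
      n_spl <- stats::rpois(1L, (1 - psi) * config$depth)
      n_int <- stats::rpois(1L, psi * config$depth * (ilen - L + 1) / L)
      lines <- character(n_spl + n_int)
      if (n_spl > 0L) {
        a <- sample(10:(L - 10L), n_spl, replace = TRUE)
        lines[seq_len(n_spl)] <- emit(
          sprintf("%s:%s:j%d", sample_id, intr$intron_id, seq_len(n_spl)),
          fl, ist - a,
          sprintf("%dM%dN%dM", a, ilen, L - a)
        )
      }
      if (n_int > 0L) {
        st <- sample(ist:(ien - L + 1L), n_int, replace = TRUE)
        lines[n_spl + seq_len(n_int)] <- emit(
          sprintf("%s:%s:i%d", sample_id, intr$intron_id, seq_len(n_int)),
          fl, st, sprintf("%dM", L)
        )
      }
      oi <- oi + 1L
      out[[oi]] <- lines
    }
    # background exonic reads, one stream per transcript
    byt <- transcript_exons(sim$annotation)
    for (tx in names(byt)) {
      ex <- byt[[tx]]
      strand <- as.character(GenomicRanges::strand(ex))[1L]
      fl <- flag_for(strand)
      n_bg <- stats::rpois(1L, config$expr_reads)
      if (n_bg == 0L) next
      widths <- GenomicRanges::width(ex)
      pick <- sample(seq_along(ex), n_bg, replace = TRUE, prob = widths)
      st0 <- GenomicRanges::start(ex)[pick]
      en0 <- GenomicRanges::end(ex)[pick]
      pos <- st0 + floor(stats::runif(n_bg) * pmax(1L, en0 - st0 - L + 2L))
      pos <- pmin(pos, contig_len - L + 1L)
      oi <- oi + 1L
      out[[oi]] <- emit(sprintf("%s:%s:e%d", sample_id, tx, seq_len(n_bg)),
                        fl, as.integer(pos), sprintf("%dM", L))
    }
    con <- file(path, "w")
    on.exit(close(con), add = TRUE)
    writeLines(c("@HD\tVN:1.6\tSO:unsorted",
                 sprintf("@SQ\tSN:chr1\tLN:%d", contig_len),
                 unlist(out[seq_len(oi)])), con)
  })
  invisible(path)
}

#' Simulate protein and junction-peptide quantification tables
#'
#' Protein intensities are log-normal around a per-protein baseline with the
#' planted log2 fold-changes applied in the stimulated groups. Junction
#' peptides are taken from the package's own three-frame junction
#' translations for the planted "spliced and translated" genes: for each
#' such gene a stop-free peptide spanning the junction of its planted intron
#' is emitted with abundance increased in the stimulated group where the
#' removal is planted. Non-planted retained-intron junctions contribute
#' flat-abundance junction peptides so that the peptide table carries a null
#' population too.
#'
#' @param config A [sim_config()].
#' @param sim Output of [simulate_genome_annotation()].
#' @param truth Output of [simulate_truth()].
#' @return A list with `proteins` (data.frame: protein_id, gene_id, one
#'   column per sample), `peptides` (data.frame: peptide_seq, junction_id of
#'   origin, gene_id, one column per sample), and `planted_peptides`
#'   (data.frame: gene_id, intron_id, stimulus, peptide_seq).
#' @export
simulate_quant_tables <- function(config, sim, truth) {
  samples <- sim_samples(config)
  introns <- derive_introns(sim$annotation)
  with_seed(derive_seed(config$seed, 3L), {
    genes <- truth$genes$gene_id
    base <- stats::rnorm(length(genes), mean = 20, sd = 1.5)
    prot <- matrix(NA_real_, nrow = length(genes), ncol = length(samples),
                   dimnames = list(genes, names(samples)))
    for (j in seq_along(samples)) {
      grp <- samples[[j]]
      fc <- if (grp == "CTRL") 0 else truth$protein_fc[[grp]]
      prot[, j] <- 2^(base + fc + stats::rnorm(length(genes), 0, config$noise_sd))
    }
    proteins <- data.frame(protein_id = paste0("P_", genes), gene_id = genes,
                           prot, check.names = FALSE, stringsAsFactors = FALSE)

    # junction peptides from the package's own junction translations
    jxn <- junctions_from_introns(introns, sim$annotation)
    windows <- extract_spliced_window(sim$genome, jxn, flank = 75L)
    pep_rows <- list()
    planted_rows <- list()
    pep_len <- 10L
    pick_peptide <- function(junction_id) {
      w <- windows[windows$junction_id == junction_id, ]
      if (nrow(w) == 0L) return(NULL)
      for (frame in 0:2) {
        entry <- translate_frame(w$spliced_seq, frame)
        # aa index range whose codons straddle the junction offset L
        Lnt <- w$L
        aa_cross <- floor((Lnt - frame - 1) / 3)  # 0-based aa containing junction boundary
        s0 <- aa_cross - pep_len %/% 2L
        if (s0 < 0L || s0 + pep_len > nchar(entry)) next
        pep <- substr(entry, s0 + 1L, s0 + pep_len)
        nt_start <- frame + 3 * s0
        nt_end <- frame + 3 * (s0 + pep_len)
        if (!grepl("[*X]", pep) && nt_start < Lnt && nt_end > Lnt) {
          return(list(seq = pep, frame = frame))
        }
      }
      NULL
    }
    emit_pep <- function(pep, junction_id, gene_id, fc_by_group) {
      b <- stats::rnorm(1L, 14, 1)
      ab <- vapply(seq_along(samples), function(j) {
        grp <- samples[[j]]
        fc <- if (grp %in% names(fc_by_group)) fc_by_group[[grp]] else 0
        2^(b + fc + stats::rnorm(1L, 0, config$noise_sd))
      }, numeric(1L))
      c(list(peptide_seq = pep, junction_id = junction_id, gene_id = gene_id),
        as.list(stats::setNames(ab, names(samples))))
    }
    emitters <- truth$genes$gene_id[truth$genes$spliced_and_translated]
    for (stim in config$stimuli) {
      for (iid in truth$planted_removal[[stim]]) {
        gid <- introns$gene_id[introns$intron_id == iid]
        if (!(gid %in% emitters)) next
        jid <- jxn$junction_id[jxn$intron_id == iid]
        if (length(jid) == 0L) next
        pk <- pick_peptide(jid)
        if (is.null(pk)) next
        key <- paste(jid, pk$seq)
        fc_by_group <- stats::setNames(config$peptide_fc, stim)
        prev <- vapply(planted_rows, function(r) r$key, character(1L))
        if (key %in% prev) {
          # same intron planted for a second stimulus: add its fold-change
          k <- which(prev == key)[1L]
          planted_rows[[k]]$fc <- c(planted_rows[[k]]$fc, fc_by_group)
          planted_rows[[k]]$stimulus <- c(planted_rows[[k]]$stimulus, stim)
        } else {
          planted_rows[[length(planted_rows) + 1L]] <- list(
            key = key, jid = jid, gid = gid, pep = pk$seq,
            fc = fc_by_group, stimulus = stim, intron_id = iid
          )
        }
      }
    }
    for (r in planted_rows) {
      pep_rows[[length(pep_rows) + 1L]] <- emit_pep(r$pep, r$jid, r$gid, r$fc)
    }
    # flat null peptides from junctions without planted removal
    null_jxn <- jxn[!(jxn$intron_id %in% unlist(truth$planted_removal)), ]
    for (jid in null_jxn$junction_id) {
      pk <- pick_peptide(jid)
      if (is.null(pk)) next
      gid <- null_jxn$gene_id[null_jxn$junction_id == jid]
      pep_rows[[length(pep_rows) + 1L]] <- emit_pep(pk$seq, jid, gid, list())
    }
    peptides <- do.call(rbind, lapply(pep_rows, function(r) {
      as.data.frame(r, check.names = FALSE, stringsAsFactors = FALSE)
    }))
    planted <- do.call(rbind, lapply(planted_rows, function(r) {
      data.frame(gene_id = r$gid, intron_id = r$intron_id,
                 stimulus = paste(r$stimulus, collapse = ";"),
                 junction_id = r$jid, peptide_seq = r$pep,
                 stringsAsFactors = FALSE)
    }))
    list(proteins = proteins, peptides = peptides,
         planted_peptides = planted)
  })
}

#' Simulate a complete synthetic study on disk
#'
#' Writes genome FASTA, annotation GTF, one SAM per sample, protein and
#' peptide TSVs, a protein-to-gene mapping and ground-truth TSVs under
#' `out_dir`. Byte-identical across runs for a fixed config.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if absent).
#' @return A list with `config`, `paths` (named list of all files),
#'   `samples`, and the in-memory `sim`, `truth`, `tables` objects.
#' @export
simulate_study <- function(config = sim_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_genome_annotation(config)
  introns <- derive_introns(sim$annotation)
  truth <- simulate_truth(config, introns)
  tables <- simulate_quant_tables(config, sim, truth)
  samples <- sim_samples(config)

  paths <- list(
    genome = file.path(out_dir, "genome.fa"),
    gtf = file.path(out_dir, "annotation.gtf"),
    proteins = file.path(out_dir, "proteins.tsv"),
    peptides = file.path(out_dir, "peptides.tsv"),
    protein_gene_map = file.path(out_dir, "protein_gene_map.tsv"),
    truth_ir = file.path(out_dir, "truth_ir.tsv"),
    truth_protein = file.path(out_dir, "truth_protein.tsv"),
    truth_genes = file.path(out_dir, "truth_genes.tsv"),
    sam = stats::setNames(
      file.path(out_dir, paste0(names(samples), ".sam")), names(samples))
  )
  write_genome(sim$genome, paths$genome)
  write_annotation(sim$annotation, paths$gtf)
  for (s in names(samples)) {
    simulate_alignments(config, sim, truth, s, samples[[s]], paths$sam[[s]])
  }
  write_tsv(tables$proteins, paths$proteins)
  write_tsv(tables$peptides, paths$peptides)
  write_tsv(data.frame(protein_id = tables$proteins$protein_id,
                       gene_id = tables$proteins$gene_id),
            paths$protein_gene_map)
  write_tsv(truth$ir, paths$truth_ir)
  tp <- truth$protein_fc
  tp <- cbind(data.frame(gene_id = rownames(tp)), tp)
  write_tsv(tp, paths$truth_protein)
  write_tsv(truth$genes, paths$truth_genes)
  list(config = config, paths = paths, samples = samples,
       sim = sim, truth = truth, tables = tables)
}

#' Simulate an IR measurement matrix directly at the count level
#'
#' Bypasses read-level simulation for statistical calibration experiments:
#' per intron and sample, the intronic median coverage is
#' `Pois(psi * depth * (len - L + 1) / L) * L / (len - L + 1)` and the
#' junction-read count is `Pois((1 - psi) * depth)` — the same sampling
#' model that the alignment-level generator induces, without SAM I/O.
#'
#' @param n_introns Number of introns.
#' @param depth Junction-evidence depth (see [sim_config()]).
#' @param n_replicates Replicates per group.
#' @param ir_ctrl Baseline IR range (uniform).
#' @param planted Integer indices of introns with a planted removal effect.
#' @param delta True IR change in the treated group for planted introns.
#' @param intron_len,read_len Geometry used in the coverage model.
#' @param seed Integer seed.
#' @return A list of class `ir_matrix` (see [ir_matrix()]) with groups
#'   `CTRL` and `TRT`, plus attribute-style element `truth` (data.frame of
#'   true IR per group).
#' @export
simulate_ir_matrix <- function(n_introns, depth = 60, n_replicates = 3L,
                               ir_ctrl = c(0.35, 0.75),
                               planted = integer(0), delta = -0.4,
                               intron_len = 350L, read_len = 50L, seed = 1L) {
  with_seed(seed, {
    base <- stats::runif(n_introns, ir_ctrl[1L], ir_ctrl[2L])
    trt <- base
    trt[planted] <- pmin(1, pmax(0, base[planted] + delta))
    groups <- stats::setNames(
      rep(c("CTRL", "TRT"), each = n_replicates),
      c(paste0("CTRL_", seq_len(n_replicates)),
        paste0("TRT_", seq_len(n_replicates)))
    )
    L <- read_len
    npos <- intron_len - L + 1L
    ir <- matrix(NA_real_, n_introns, length(groups),
                 dimnames = list(paste0("i", seq_len(n_introns)), names(groups)))
    intronic <- splice <- ir
    for (j in seq_along(groups)) {
      psi <- if (groups[[j]] == "CTRL") base else trt
      m <- stats::rpois(n_introns, psi * depth * npos / L) * L / npos
      s <- stats::rpois(n_introns, (1 - psi) * depth)
      intronic[, j] <- m
      splice[, j] <- s
      ir[, j] <- ifelse(m + s == 0, NA_real_, m / (m + s))
    }
    structure(list(ir = ir, intronic = intronic, splice = splice,
                   groups = groups,
                   truth = data.frame(intron_id = rownames(ir),
                                      CTRL = base, TRT = trt)),
              class = "ir_matrix")
  })
}

#' Simulate a standalone protein intensity table
#'
#' Log-normal intensities around per-protein baselines, with planted log2
#' fold-changes applied to the treated group. Two groups (CTRL, TRT) of
#' `n_replicates` samples each.
#'
#' @param n_proteins Number of proteins.
#' @param planted_fc Named numeric vector of log2 fold-changes (names are
#'   protein indices as `p<N>` or any subset of the generated ids).
#' @param noise_sd Log2-intensity noise standard deviation.
#' @param n_replicates Replicates per group.
#' @param seed Integer seed.
#' @return A list: `values` (matrix proteins x samples), `groups` (named
#'   labels), `truth` (named log2FC vector, zero for unplanted proteins).
#' @export
simulate_protein_table <- function(n_proteins, planted_fc = numeric(0),
                                   noise_sd = 0.1, n_replicates = 3L,
                                   seed = 1L) {
  with_seed(seed, {
    ids <- sprintf("p%03d", seq_len(n_proteins))
    truth <- stats::setNames(rep(0, n_proteins), ids)
    truth[names(planted_fc)] <- planted_fc
    groups <- stats::setNames(
      rep(c("CTRL", "TRT"), each = n_replicates),
      c(paste0("CTRL_", seq_len(n_replicates)),
        paste0("TRT_", seq_len(n_replicates)))
    )
    base <- stats::rnorm(n_proteins, 20, 1.5)
    vals <- vapply(seq_along(groups), function(j) {
      fc <- if (groups[[j]] == "TRT") truth else 0
      2^(base + fc + stats::rnorm(n_proteins, 0, noise_sd))
    }, numeric(n_proteins))
    dimnames(vals) <- list(ids, names(groups))
    list(values = vals, groups = groups, truth = truth)
  })
}

# TSV helpers: tab-separated, '.' decimal, header row, no quoting.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "")
}
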