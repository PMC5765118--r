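#' Retention-filter parameters
#'
#' @param quantile_cut Per-sample quantile of the non-missing IR-ratio
#'   distribution that an intron must exceed (strictly) to count as retained
#'   in that sample. Default 0.25, the first quartile.
#' @param min_replicates Minimum number of replicates (within a group) in
#'   which an intron must pass the per-sample cut. Default 2 of 3.
#' @param excluded_feature_types Annotation feature types masked out of the
#'   measurable intronic region (small RNAs nested in introns confound the
#'   intronic signal).
#' @return A list of class `ir_filter_params`.
#' @export
ir_filter_params <- function(quantile_cut = 0.25,
                             min_replicates = 2L,
                             excluded_feature_types = c("miRNA", "snoRNA")) {
  stopifnot(quantile_cut > 0, quantile_cut < 1, min_replicates >= 1L)
  structure(list(quantile_cut = quantile_cut,
                 min_replicates = as.integer(min_replicates),
                 excluded_feature_types = excluded_feature_types),
            class = "ir_filter_params")
}

#' Measurable region of an intron
#'
#' The intronic positions over which coverage is measured: the intron minus
#' any position overlapped by an exon of any transcript or by a feature of
#' an excluded small-RNA type. May be empty.
#'
#' @param intron A length-1 `GRanges` from [derive_introns()].
#' @param annotation Annotation `GRanges` ([read_annotation()]).
#' @param excluded_types Feature types to mask (default miRNA, snoRNA).
#' @return An `IRanges` of retained intronic positions (possibly empty).
#' @export
measurable_region <- function(intron, annotation,
                              excluded_types = c("miRNA", "snoRNA")) {
  stopifnot(length(intron) == 1L)
  mask <- annotation[annotation$type == "exon" |
                       annotation$type %in% excluded_types]
  mask <- mask[as.character(GenomicRanges::seqnames(mask)) ==
                 as.character(GenomicRanges::seqnames(intron))]
  IRanges::setdiff(IRanges::ranges(intron),
                   IRanges::reduce(IRanges::ranges(mask)))
}

#' Median intronic coverage over a measurable region
#'
#' @param aln A `platelet_alignments` object (one sample).
#' @param region `IRanges` from [measurable_region()].
#' @param contig Contig of the intron.
#' @param strand Fragment strand required of contributing reads
#'   (`"*"` accepts all).
#' @return Median per-base read depth over the region's positions; 0 for an
#'   empty region.
#' @export
intronic_abundance <- function(aln, region, contig, strand = "*") {
  if (sum(IRanges::width(region)) == 0L) return(0)
  sub <- subset_alignments(aln, contig, strand)
  cov <- .block_coverage(sub, width = max(IRanges::end(region)))
  stats::median(as.numeric(cov[region]))
}

.block_coverage <- function(aln, width) {
  blocks <- unlist(aln$blocks, use.names = FALSE)
  blocks <- blocks[IRanges::start(blocks) <= width]
  IRanges::coverage(IRanges::restrict(blocks, end = width), width = width)
}

#' Junction-read count for an intron
#'
#' Number of reads carrying an alignment gap (CIGAR `N`) whose genomic
#' interval equals the intron exactly; a read with several gaps is counted
#' at most once per intron.
#'
#' @param aln A `platelet_alignments` object.
#' @param intron Length-1 `GRanges`.
#' @param strand Required fragment strand (`"*"` accepts all).
#' @return Integer count of junction-spanning reads.
#' @export
splice_abundance <- function(aln, intron, strand = "*") {
  sub <- subset_alignments(aln, as.character(GenomicRanges::seqnames(intron)),
                           strand)
  g <- unlist(sub$gaps, use.names = FALSE)
  if (length(g) == 0L) return(0L)
  ridx <- rep(seq_along(sub$gaps), lengths(sub$gaps))
  hit <- IRanges::start(g) == GenomicRanges::start(intron) &
    IRanges::end(g) == GenomicRanges::end(intron)
  length(unique(ridx[hit]))
}

#' IR ratio
#'
#' `intronic / (intronic + splice)`; `NA` when the denominator is zero
#' (no evidence either way).
#'
#' @param intronic Intronic abundance (median coverage, >= 0).
#' @param splice Junction-read count (>= 0).
#' @return A value in \[0, 1\], or `NA`.
#' @export
ir_ratio <- function(intronic, splice) {
  den <- intronic + splice
  ifelse(den == 0, NA_real_, intronic / den)
}

#' Quantify intron retention across samples
#'
#' Computes, for every intron and sample, the median intronic coverage over
#' the measurable region, the exact-junction read count, and their IR ratio.
#'
#' @param alignments Named list of `platelet_alignments`, one per sample.
#' @param introns `GRanges` from [derive_introns()].
#' @param annotation Annotation `GRanges`.
#' @param groups Named character vector mapping sample id to group label.
#' @param params An [ir_filter_params()] (supplies the exclusion mask types).
#' @param stranded Use the fragment strand of the intron's gene when
#'   filtering reads (`TRUE`, default for a stranded protocol); `FALSE`
#'   counts reads of both strands.
#' @return A list of class `ir_matrix`: matrices `ir`, `intronic`, `splice`
#'   (introns x samples), `groups`, and `introns` (the input `GRanges`).
#' @export
quantify_ir <- function(alignments, introns, annotation, groups,
                        params = ir_filter_params(), stranded = TRUE) {
  stopifnot(all(names(alignments) %in% names(groups)))
  samples <- names(alignments)
  n <- length(introns)
  regions <- lapply(seq_len(n), function(i) {
    measurable_region(introns[i], annotation, params$excluded_feature_types)
  })
  contig <- as.character(GenomicRanges::seqnames(introns))
  strand <- if (stranded) as.character(GenomicRanges::strand(introns))
            else rep("*", n)
  dim_names <- list(introns$intron_id, samples)
  intr_m <- spl_m <- matrix(NA_real_, n, length(samples), dimnames = dim_names)
  for (s in samples) {
    aln <- alignments[[s]]
    # one coverage and one gap table per (contig, strand) combination
    combos <- unique(data.frame(contig = contig, strand = strand))
    covs <- list(); gapt <- list()
    for (k in seq_len(nrow(combos))) {
      key <- paste(combos$contig[k], combos$strand[k])
      sub <- subset_alignments(aln, combos$contig[k], combos$strand[k])
      width <- max(c(1L, IRanges::end(unlist(sub$blocks, use.names = FALSE))))
      covs[[key]] <- .block_coverage(sub, width = width)
      g <- unlist(sub$gaps, use.names = FALSE)
      gapt[[key]] <- data.frame(
        read = rep(seq_along(sub$gaps), lengths(sub$gaps)),
        start = IRanges::start(g), end = IRanges::end(g)
      )
    }
    for (i in seq_len(n)) {
      key <- paste(contig[i], strand[i])
      cov <- covs[[key]]
      reg <- regions[[i]]
      reg <- IRanges::restrict(reg, end = length(cov))
      ia <- if (sum(IRanges::width(regions[[i]])) == 0L) 0 else {
        pad <- sum(IRanges::width(regions[[i]])) - sum(IRanges::width(reg))
        v <- c(as.numeric(cov[reg]), rep(0, pad))  # positions past coverage end
        stats::median(v)
      }
      gt <- gapt[[key]]
      hit <- gt$start == GenomicRanges::start(introns)[i] &
        gt$end == GenomicRanges::end(introns)[i]
      intr_m[i, s] <- ia
      spl_m[i, s] <- length(unique(gt$read[hit]))
    }
  }
  structure(list(ir = ir_ratio(intr_m, spl_m), intronic = intr_m,
                 splice = spl_m, groups = groups[samples], introns = introns),
            class = "ir_matrix")
}

#' Construct an `ir_matrix` from components
#'
#' @param ir Matrix of IR ratios (introns x samples; `NA` = no evidence).
#' @param groups Named group labels for the columns.
#' @param intronic,splice Optional component matrices.
#' @param introns Optional intron `GRanges`.
#' @return A list of class `ir_matrix`.
#' @export
ir_matrix <- function(ir, groups, intronic = NULL, splice = NULL,
                      introns = NULL) {
  stopifnot(is.matrix(ir), !is.null(colnames(ir)),
            all(colnames(ir) %in% names(groups)))
  structure(list(ir = ir, intronic = intronic, splice = splice,
                 groups = groups[colnames(ir)], introns = introns),
            class = "ir_matrix")
}

#' @export
print.ir_matrix <- function(x, ...) {
  cat(sprintf("<ir_matrix> %d introns x %d samples (%s)\n",
              nrow(x$ir), ncol(x$ir),
              paste(sprintf("%s:%d", names(table(x$groups)),
                            table(x$groups)), collapse = ", ")))
  invisible(x)
}

#' Long-format view of an `ir_matrix`
#'
#' @param x An `ir_matrix`.
#' @param ... Unused.
#' @return data.frame: intron_id, sample, group, intronic_abundance,
#'   splice_abundance, ir_ratio (plus coordinates when introns are known).
#' @export
as.data.frame.ir_matrix <- function(x, ...) {
  long <- expand.grid(intron_id = rownames(x$ir), sample = colnames(x$ir),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$group <- unname(x$groups[long$sample])
  long$intronic_abundance <- as.vector(x$intronic)
  long$splice_abundance <- as.vector(x$splice)
  long$ir_ratio <- as.vector(x$ir)
  if (!is.null(x$introns)) {
    m <- match(long$intron_id, x$introns$intron_id)
    long$contig <- as.character(GenomicRanges::seqnames(x$introns))[m]
    long$start <- GenomicRanges::start(x$introns)[m]
    long$end <- GenomicRanges::end(x$introns)[m]
    long$strand <- as.character(GenomicRanges::strand(x$introns))[m]
    long <- long[, c("intron_id", "contig", "start", "end", "strand",
                     "sample", "group", "intronic_abundance",
                     "splice_abundance", "ir_ratio")]
  }
  long
}

#' Retained-intron filter
#'
#' An intron is called retained in a group when, in at least
#' `min_replicates` of the group's samples, its IR ratio is non-missing and
#' strictly greater than that sample's `quantile_cut` quantile of the
#' sample's non-missing IR-ratio distribution.
#'
#' @param x An `ir_matrix`.
#' @param params An [ir_filter_params()].
#' @param group Group label to filter within.
#' @return Character vector of retained intron ids.
#' @export
filter_retained <- function(x, params = ir_filter_params(), group) {
  stopifnot(inherits(x, "ir_matrix"))
  cols <- names(x$groups)[x$groups == group]
  if (length(cols) == 0L) stop("no samples in group: ", group)
  if (length(cols) < params$min_replicates) {
    stop("group ", group, " has fewer samples than min_replicates")
  }
  pass <- matrix(FALSE, nrow(x$ir), length(cols))
  for (j in seq_along(cols)) {
    v <- x$ir[, cols[j]]
    if (all(is.na(v))) next
    q <- stats::quantile(v, probs = params$quantile_cut, na.rm = TRUE,
                         names = FALSE)
    pass[, j] <- !is.na(v) & v > q
  }
  rownames(x$ir)[rowSums(pass) >= params$min_replicates]
}

#' Fragments per kilobase of exon per million mapped fragments
#'
#' @param fragment_counts Non-negative fragment counts per feature.
#' @param feature_lengths_nt Feature (exonic) lengths in nucleotides, > 0.
#' @param total_mapped Total mapped fragments in the sample, > 0.
#' @return Numeric FPKM vector.
#' @export
compute_fpkm <- function(fragment_counts, feature_lengths_nt, total_mapped) {
  if (any(feature_lengths_nt <= 0)) stop("feature lengths must be positive")
  if (total_mapped <= 0) stop("total_mapped must be positive")
  fragment_counts / (feature_lengths_nt / 1000) / (total_mapped / 1e6)
}
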