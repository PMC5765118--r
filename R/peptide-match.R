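.AA20 <- "ACDEFGHIKLMNPQRSTVWY"

#' Map peptides onto junction database entries
#'
#' Reports every exact substring occurrence of each peptide in each frame
#' translation. With `il_equivalent = TRUE`, isoleucine and leucine are
#' treated as interchangeable (they are isobaric and indistinguishable in
#' spectral searches). Occurrences whose span contains a stop (`*`) are
#' discarded — a peptide cannot arise from a reading frame interrupted by a
#' stop codon. For each occurrence the nucleotide span within the spliced
#' window is `nt_start = frame + 3*(aa_start)` to `nt_end = frame +
#' 3*(aa_end)` (0-based offsets, half-open), and the match spans the
#' junction when that span straddles the junction offset `L`.
#'
#' @param peptides Character vector of peptide sequences (20-letter amino
#'   acid alphabet, uppercase).
#' @param entries Junction entries from [translate_junction_windows()] or
#'   [read_junction_fasta()].
#' @param il_equivalent Treat I and L as equal (default `FALSE`).
#' @return data.frame: peptide_seq, junction_id, frame, aa_start, aa_end
#'   (0-based, half-open span in the frame translation), nt_start, nt_end
#'   (0-based, half-open span in the spliced window), L, spans_junction.
#' @export
match_peptides <- function(peptides, entries, il_equivalent = FALSE) {
  peptides <- unique(peptides)
  if (length(peptides) == 0L) {
    stop("no peptides supplied")
  }
  if (any(!nzchar(peptides))) stop("empty peptide sequence")
  bad <- grepl(sprintf("[^%s]", .AA20), peptides)
  if (any(bad)) {
    stop("peptide with invalid amino-acid alphabet: ", peptides[bad][1L])
  }
  canon <- function(x) if (il_equivalent) chartr("IL", "JJ", x) else x
  q <- canon(peptides)
  subj <- canon(entries$aa_seq)
  out <- list()
  for (p in seq_along(peptides)) {
    hits <- gregexpr(q[p], subj, fixed = TRUE)
    for (e in seq_along(subj)) {
      st <- hits[[e]]
      if (st[1L] == -1L) next
      len <- nchar(peptides[p])
      for (s in as.integer(st)) {
        span <- substr(entries$aa_seq[e], s, s + len - 1L)
        if (grepl("*", span, fixed = TRUE)) next
        aa_start <- s - 1L              # 0-based
        aa_end <- aa_start + len
        frame <- entries$frame[e]
        nt_start <- frame + 3L * aa_start
        nt_end <- frame + 3L * aa_end
        L <- entries$L[e]
        out[[length(out) + 1L]] <- data.frame(
          peptide_seq = peptides[p], junction_id = entries$junction_id[e],
          frame = frame, aa_start = aa_start, aa_end = aa_end,
          nt_start = nt_start, nt_end = nt_end, L = L,
          spans_junction = spans_junction(nt_start, nt_end, L),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(peptide_seq = character(), junction_id = character(),
                      frame = integer(), aa_start = integer(),
                      aa_end = integer(), nt_start = integer(),
                      nt_end = integer(), L = integer(),
                      spans_junction = logical(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Junction-spanning test for a matched span
#'
#' A match spans the exon-exon junction when its coding nucleotide span has
#' at least one base on each side of the junction offset: `nt_start < L`
#' and `nt_end > L` (0-based half-open span).
#'
#' @param nt_start,nt_end Nucleotide span of the match in the spliced window.
#' @param L Junction offset of the window (length of the left flank).
#' @return Logical.
#' @export
spans_junction <- function(nt_start, nt_end, L) {
  nt_start < L & nt_end > L
}

#' Quantify junction-spanning peptides per junction
#'
#' Sums the abundances of all junction-spanning peptides of each junction,
#' per sample, and reports the log2 fold-change of the summed abundance
#' (treated vs CTRL group medians) with permutation significance (BH-FDR at
#' `config$fdr_peptide`). Junctions without any spanning peptide are
#' reported with `detected = FALSE`.
#'
#' @param matches data.frame from [match_peptides()].
#' @param peptide_table data.frame with a `peptide_seq` column and one
#'   numeric abundance column per sample.
#' @param groups Named group labels for the sample columns.
#' @param stimulus Treated group to compare against CTRL.
#' @param config A [diff_config()].
#' @param junction_ids Junctions to report (default: those in `matches`).
#' @return data.frame: junction_id, n_spanning_peptides, effect (log2FC),
#'   t_stat, p_perm, p_adj, significant, detected.
#' @export
quantify_junction_peptides <- function(matches, peptide_table, groups,
                                       stimulus, config = diff_config(),
                                       junction_ids = NULL) {
  if (is.null(junction_ids)) junction_ids <- unique(matches$junction_id)
  samples <- intersect(names(groups), colnames(peptide_table))
  if (length(samples) == 0L) stop("peptide table has no sample columns")
  span <- matches[matches$spans_junction, , drop = FALSE]
  span <- unique(span[, c("peptide_seq", "junction_id")])
  sums <- matrix(0, nrow = length(junction_ids), ncol = length(samples),
                 dimnames = list(junction_ids, samples))
  n_pep <- stats::setNames(integer(length(junction_ids)), junction_ids)
  for (j in junction_ids) {
    peps <- span$peptide_seq[span$junction_id == j]
    rows <- peptide_table$peptide_seq %in% peps
    n_pep[[j]] <- length(unique(peptide_table$peptide_seq[rows]))
    if (any(rows)) {
      sums[j, ] <- colSums(as.matrix(peptide_table[rows, samples,
                                                   drop = FALSE]))
    }
  }
  detected <- n_pep > 0L
  out <- data.frame(junction_id = junction_ids,
                    n_spanning_peptides = as.integer(n_pep),
                    effect = NA_real_, t_stat = NA_real_, p_perm = NA_real_,
                    p_adj = NA_real_, significant = FALSE,
                    detected = unname(detected), stringsAsFactors = FALSE)
  if (!any(detected)) return(out)
  cols_ctrl <- samples[groups[samples] == "CTRL"]
  cols_trt <- samples[groups[samples] == stimulus]
  det <- sums[detected, c(cols_ctrl, cols_trt), drop = FALSE]
  labels <- factor(rep(c("CTRL", stimulus),
                       c(length(cols_ctrl), length(cols_trt))),
                   levels = c("CTRL", stimulus))
  res <- permutation_test(log2(det + 1), labels, config)
  med_trt <- apply(det[, cols_trt, drop = FALSE], 1L, stats::median)
  med_ctrl <- apply(det[, cols_ctrl, drop = FALSE], 1L, stats::median)
  res$effect <- ifelse(med_trt > 0 & med_ctrl > 0,
                       log2(med_trt) - log2(med_ctrl), NA_real_)
  res$p_adj <- adjust_p(res$p_perm, "bh_fdr")
  m <- match(res$feature_id, out$junction_id)
  out$effect[m] <- res$effect
  out$t_stat[m] <- res$t_stat
  out$p_perm[m] <- res$p_perm
  out$p_adj[m] <- res$p_adj
  out$significant[m] <- res$p_adj <= config$fdr_peptide
  out
}
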