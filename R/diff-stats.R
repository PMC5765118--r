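#' Differential-testing configuration
#'
#' @param n_perm Number of permutations when the label assignments cannot be
#'   enumerated exhaustively (default 10000).
#' @param alpha Significance level for adjusted protein p-values (default 0.01).
#' @param adjust Adjustment for protein tests: `"bonferroni"` (default) or
#'   `"bh_fdr"`.
#' @param fc_cutoff_protein Linear fold-change cutoff for proteins
#'   (default 1.2; a protein passes when its ratio is >= 1.2 or <= 1/1.2).
#' @param fc_cutoff_rna Linear fold-change cutoff for transcripts (default 1.5).
#' @param fdr_rna BH-FDR level for transcripts (default 0.05).
#' @param fdr_ir BH-FDR level for differential intron retention (default 0.01).
#' @param fdr_peptide BH-FDR level for junction-peptide changes (default 0.05).
#' @param seed Integer seed for permutation sampling.
#' @param s0 Variance-stabilization constant added to the t denominator
#'   (Tusher-style); `"auto"` (default) uses the median per-feature standard
#'   error, `0` gives the plain Student statistic.
#' @return A list of class `diff_config`.
#' @export
diff_config <- function(n_perm = 10000L, alpha = 0.01,
                        adjust = c("bonferroni", "bh_fdr"),
                        fc_cutoff_protein = 1.2, fc_cutoff_rna = 1.5,
                        fdr_rna = 0.05, fdr_ir = 0.01, fdr_peptide = 0.05,
                        seed = 1L, s0 = "auto") {
  adjust <- match.arg(adjust)
  stopifnot(fc_cutoff_protein > 1, fc_cutoff_rna > 1,
            alpha > 0, alpha < 1, fdr_rna > 0, fdr_rna < 1,
            fdr_ir > 0, fdr_ir < 1)
  structure(list(n_perm = as.integer(n_perm), alpha = alpha, adjust = adjust,
                 fc_cutoff_protein = fc_cutoff_protein,
                 fc_cutoff_rna = fc_cutoff_rna, fdr_rna = fdr_rna,
                 fdr_ir = fdr_ir, fdr_peptide = fdr_peptide,
                 seed = as.integer(seed), s0 = s0),
            class = "diff_config")
}

#' Log2 of the per-group median
#'
#' @param values Numeric matrix, features x samples.
#' @param samples Column names of the group to summarize.
#' @return Named vector: log2 of the median across the group's samples.
#' @export
log2_median_summary <- function(values, samples) {
  stopifnot(all(samples %in% colnames(values)))
  med <- apply(values[, samples, drop = FALSE], 1L, stats::median)
  bad <- which(med <= 0 | is.na(med))
  if (length(bad) > 0L) {
    stop("nonpositive median intensity for feature: ",
         paste(utils::head(rownames(values)[bad], 3L), collapse = ", "))
  }
  log2(med)
}

# Two-sample pooled-variance t for every row of `mat`.
# `idx1`, `idx2`: column indices of the two groups. A small `s0` added to the
# denominator stabilizes features with near-zero variance; when s0 = 0 and
# both groups have zero variance the statistic is 0.
row_t_stat <- function(mat, idx1, idx2, s0 = 0) {
  n1 <- length(idx1); n2 <- length(idx2)
  m1 <- rowMeans(mat[, idx1, drop = FALSE])
  m2 <- rowMeans(mat[, idx2, drop = FALSE])
  ss1 <- rowSums((mat[, idx1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((mat[, idx2, drop = FALSE] - m2)^2)
  sp2 <- (ss1 + ss2) / (n1 + n2 - 2L)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  d <- m2 - m1
  t <- ifelse(se + s0 == 0, 0, d / (se + s0))
  list(t = t, effect = d, se = se)
}

# All distinct assignments of `n2` of `n` samples to group 2, one per column.
all_assignments <- function(n, n2) utils::combn(n, n2)

#' Permutation two-sample test, pooled across features
#'
#' Computes a pooled-variance two-sample t statistic per feature (group 2
#' minus group 1), with a small stabilization constant `s0` in the
#' denominator, and a permutation p-value against a null distribution of
#' permuted statistics pooled across all features. `n_perm` label
#' assignments are sampled with replacement (deterministically from
#' `config$seed`); for the small designs this package targets the sampling
#' is realized as multinomial weights over the distinct assignments. The
#' observed labeling and its mirror are excluded from the null. p-values
#' carry +1 smoothing in numerator and denominator.
#'
#' With `mode = "exact-per-feature"`, each feature is instead compared with
#' its own exhaustive enumeration of all distinct assignments (the observed
#' labeling included), the classical exact per-feature permutation test.
#'
#' @param values Numeric matrix, features x samples (rownames = feature ids).
#' @param labels Character/factor vector of group labels, parallel to
#'   columns; exactly two levels, each with >= 2 samples. The effect sign is
#'   second level minus first level (by factor order).
#' @param config A [diff_config()].
#' @param mode `"pooled"` (default) or `"exact-per-feature"`.
#' @return data.frame: feature_id, effect (difference of group means),
#'   t_stat, p_perm.
#' @export
permutation_test <- function(values, labels, config = diff_config(),
                             mode = c("pooled", "exact-per-feature")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(values), ncol(values) == length(labels))
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) stop("exactly two groups required")
  if (any(table(labels) < 2L)) stop("each group needs >= 2 samples")
  idx1 <- which(labels == levels(labels)[1L])
  idx2 <- which(labels == levels(labels)[2L])
  n <- ncol(values); n2 <- length(idx2)
  obs0 <- row_t_stat(values, idx1, idx2, s0 = 0)
  s0 <- config$s0
  if (identical(s0, "auto")) {
    s0 <- stats::median(obs0$se)
    if (!is.finite(s0)) s0 <- 0
  }
  obs <- row_t_stat(values, idx1, idx2, s0 = s0)

  n_distinct <- choose(n, n2)
  if (mode == "exact-per-feature") {
    assign2 <- all_assignments(n, n2)
    perm_t <- vapply(seq_len(ncol(assign2)), function(k) {
      a2 <- assign2[, k]
      abs(row_t_stat(values, setdiff(seq_len(n), a2), a2, s0 = s0)$t)
    }, numeric(nrow(values)))
    if (nrow(values) == 1L) perm_t <- matrix(perm_t, nrow = 1L)
    p <- rowMeans(perm_t >= abs(obs$t) - 1e-12)
  } else {
    # n_perm label assignments sampled with replacement (the small designs
    # the package targets admit only choose(n, n2) distinct assignments, so
    # sampling is done as multinomial weights over the distinct ones);
    # the observed labeling and its mirror are excluded from the null.
    if (n_distinct <= 4096) {
      assign2 <- all_assignments(n, n2)
      is_obs <- apply(assign2, 2L, function(a) {
        setequal(a, idx2) || setequal(a, idx1)
      })
      assign2 <- assign2[, !is_obs, drop = FALSE]
      w <- with_seed(derive_seed(config$seed, 17L), {
        tabulate(sample.int(ncol(assign2), config$n_perm, replace = TRUE),
                 nbins = ncol(assign2))
      })
    } else {
      assign2 <- with_seed(derive_seed(config$seed, 17L), {
        vapply(seq_len(config$n_perm), function(i) sort(sample(n, n2)),
               integer(n2))
      })
      is_obs <- apply(assign2, 2L, function(a) {
        setequal(a, idx2) || setequal(a, idx1)
      })
      assign2 <- assign2[, !is_obs, drop = FALSE]
      w <- rep(1L, ncol(assign2))
    }
    m <- nrow(values)
    pool <- unlist(lapply(seq_len(ncol(assign2)), function(k) {
      a2 <- assign2[, k]
      abs(row_t_stat(values, setdiff(seq_len(n), a2), a2, s0 = s0)$t)
    }), use.names = FALSE)
    pool_w <- rep(as.double(w), each = m)
    ord <- order(pool)
    pool <- pool[ord]
    cum_w <- cumsum(pool_w[ord])
    N <- cum_w[length(cum_w)]
    # weighted count of pooled |t*| >= |t|, +1 smoothing on both sides
    lt <- findInterval(abs(obs$t) - 1e-12, pool)
    ge <- N - ifelse(lt == 0L, 0, cum_w[pmax(lt, 1L)])
    p <- (1 + ge) / (1 + N)
  }
  data.frame(feature_id = rownames(values), effect = obs$effect,
             t_stat = obs$t, p_perm = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Multiple-testing adjustment
#'
#' @param p Vector of p-values in (0, 1].
#' @param method `"bonferroni"` (min(1, p*m)) or `"bh_fdr"`
#'   (Benjamini-Hochberg step-up).
#' @return Adjusted p-values (empty input gives empty output).
#' @export
adjust_p <- function(p, method = c("bonferroni", "bh_fdr")) {
  method <- match.arg(method)
  if (length(p) == 0L) return(numeric(0))
  stats::p.adjust(p, method = if (method == "bonferroni") "bonferroni" else "BH")
}

#' Differential protein calling
#'
#' Permutation t-test on log2 intensities (treated vs CTRL), adjustment per
#' `config$adjust` (Bonferroni by default), and the linear fold-change rule:
#' a protein is significant when its adjusted p-value is at most
#' `config$alpha` and the ratio of group median intensities is >= the
#' fold-change cutoff in either direction. The reported effect is the log2
#' ratio of the group medians.
#'
#' @param values Intensity matrix, proteins x samples (positive values).
#' @param groups Named group labels for the columns.
#' @param stimulus Treated group to compare against `"CTRL"`.
#' @param config A [diff_config()].
#' @param mode Permutation mode, see [permutation_test()].
#' @return data.frame: feature_id, effect (log2FC of medians), t_stat,
#'   p_perm, p_adj, significant.
#' @export
call_differential_proteins <- function(values, groups, stimulus,
                                       config = diff_config(),
                                       mode = "pooled") {
  cols_ctrl <- names(groups)[groups == "CTRL"]
  cols_trt <- names(groups)[groups == stimulus]
  if (length(cols_ctrl) == 0L) stop("missing group: CTRL")
  if (length(cols_trt) == 0L) stop("missing group: ", stimulus)
  sub <- log2(values[, c(cols_ctrl, cols_trt), drop = FALSE])
  labels <- factor(rep(c("CTRL", stimulus), c(length(cols_ctrl),
                                              length(cols_trt))),
                   levels = c("CTRL", stimulus))
  res <- permutation_test(sub, labels, config, mode = mode)
  res$effect <- log2_median_summary(values, cols_trt) -
    log2_median_summary(values, cols_ctrl)
  res$p_adj <- adjust_p(res$p_perm, config$adjust)
  res$significant <- res$p_adj <= config$alpha &
    2^abs(res$effect) >= config$fc_cutoff_protein
  res
}

#' Differential intron retention calling
#'
#' Permutation t-test on IR ratios (treated vs CTRL) for the introns that
#' passed the retention filter, BH-FDR adjusted; an intron is significant at
#' `config$fdr_ir` and "removed" when additionally its mean IR change is
#' negative. Introns with a missing IR ratio in any compared sample are
#' dropped (no evidence in that sample).
#'
#' @param x An `ir_matrix`.
#' @param stimulus Treated group label.
#' @param config A [diff_config()].
#' @param introns Optional character vector restricting the tested introns
#'   (e.g. output of [filter_retained()]).
#' @param mode Permutation mode, see [permutation_test()].
#' @return data.frame: feature_id, effect (mean treated IR - mean CTRL IR),
#'   t_stat, p_perm, p_adj, significant, removed.
#' @export
call_differential_introns <- function(x, stimulus, config = diff_config(),
                                      introns = NULL, mode = "pooled") {
  stopifnot(inherits(x, "ir_matrix"))
  cols_ctrl <- names(x$groups)[x$groups == "CTRL"]
  cols_trt <- names(x$groups)[x$groups == stimulus]
  if (length(cols_trt) == 0L) stop("missing group: ", stimulus)
  mat <- x$ir[, c(cols_ctrl, cols_trt), drop = FALSE]
  if (!is.null(introns)) mat <- mat[rownames(mat) %in% introns, , drop = FALSE]
  mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  if (nrow(mat) == 0L) {
    return(data.frame(feature_id = character(), effect = numeric(),
                      t_stat = numeric(), p_perm = numeric(),
                      p_adj = numeric(), significant = logical(),
                      removed = logical(), stringsAsFactors = FALSE))
  }
  labels <- factor(rep(c("CTRL", stimulus),
                       c(length(cols_ctrl), length(cols_trt))),
                   levels = c("CTRL", stimulus))
  res <- permutation_test(mat, labels, config, mode = mode)
  res$p_adj <- adjust_p(res$p_perm, "bh_fdr")
  res$significant <- res$p_adj <= config$fdr_ir
  res$removed <- res$significant & res$effect < 0
  res
}

#' Histogram of significant introns per gene
#'
#' @param diff A data.frame from [call_differential_introns()].
#' @param gene_of Named character vector mapping intron id to gene id (or
#'   `NULL` to parse the `gene:transcript:index` intron-id convention).
#' @return data.frame: n_introns (k), n_genes (count of genes with exactly k
#'   significant introns). Empty input gives an empty table.
#' @export
introns_per_gene_summary <- function(diff, gene_of = NULL) {
  sig <- diff$feature_id[diff$significant]
  if (length(sig) == 0L) {
    return(data.frame(n_introns = integer(), n_genes = integer()))
  }
  genes <- if (is.null(gene_of)) sub(":.*$", "", sig) else unname(gene_of[sig])
  per_gene <- table(genes)
  tab <- table(factor(per_gene))
  data.frame(n_introns = as.integer(names(tab)), n_genes = as.integer(tab))
}
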