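mk_res <- function(ids, effects, sig = rep(TRUE, length(ids))) {
  data.frame(feature_id = ids, effect = effects, significant = sig,
             stringsAsFactors = FALSE)
}

test_that("stimulus partition performs exact set algebra", {
  a <- mk_res(c("A", "B", "C", "Z"), c(1, -1, 2, 0.5),
              c(TRUE, TRUE, TRUE, FALSE))
  b <- mk_res(c("B", "C", "D"), c(-2, -1, 1))
  p <- partition_stimulus_sets(a, b)
  expect_setequal(p$only_a, "A")
  expect_setequal(p$only_b, "D")
  expect_setequal(p$common, c("B", "C"))
  expect_equal(unname(p$common_direction["both_down"]), 1L)
  expect_equal(unname(p$common_direction["discordant"]), 1L)
  # empty second set
  p0 <- partition_stimulus_sets(a, mk_res(character(0), numeric(0),
                                          logical(0)))
  expect_length(p0$common, 0L)
  expect_setequal(p0$only_a, c("A", "B", "C"))
})

test_that("partition sets are disjoint and exhaustive on random inputs", {
  set.seed(71)
  for (i in 1:20) {
    ids_a <- sample(LETTERS, sample(5:15, 1))
    ids_b <- sample(LETTERS, sample(5:15, 1))
    a <- mk_res(ids_a, rnorm(length(ids_a)))
    b <- mk_res(ids_b, rnorm(length(ids_b)))
    p <- partition_stimulus_sets(a, b)
    all_ids <- c(p$only_a, p$only_b, p$common)
    expect_equal(anyDuplicated(all_ids), 0L)
    expect_setequal(all_ids, union(ids_a, ids_b))
  }
})

test_that("protein-mRNA table classifies concordance", {
  prot <- data.frame(feature_id = paste0("P", 1:4),
                     gene_id = paste0("g", 1:4),
                     effect = c(1, 1, -1, 1),
                     significant = c(TRUE, TRUE, TRUE, TRUE),
                     stringsAsFactors = FALSE)
  expr <- data.frame(gene_id = paste0("g", 1:3),
                     effect = c(1.2, 0.1, 1.5),
                     significant = c(TRUE, FALSE, TRUE),
                     stringsAsFactors = FALSE)
  out <- protein_mrna_scatter(prot, expr)
  expect_equal(out$class, c("concordant", "protein_only", "discordant",
                            "no_mrna"))
})

test_that("validation class is a pure function of flags and signs", {
  expect_equal(classify_validation(TRUE, -0.4, FALSE, NA, TRUE, 1),
               "validated")
  expect_equal(classify_validation(TRUE, -0.4, TRUE, 1, FALSE, NA),
               "validated")
  expect_equal(classify_validation(TRUE, -0.4, FALSE, NA, FALSE, NA),
               "partial")
  expect_equal(classify_validation(FALSE, -0.4, TRUE, 1, TRUE, 1),
               "not_significant")
  expect_equal(classify_validation(TRUE, 0.3, TRUE, 1, TRUE, 1),
               "not_significant")
  # significant protein DOWN is not accumulation
  expect_equal(classify_validation(TRUE, -0.4, TRUE, -1, FALSE, NA),
               "partial")
  # property: repeated random flag combinations re-derive the rule
  set.seed(72)
  for (i in 1:50) {
    ir_sig <- runif(1) < 0.5; d <- runif(1, -1, 1)
    p_sig <- runif(1) < 0.5; p_fc <- runif(1, -2, 2)
    j_sig <- runif(1) < 0.5; j_fc <- runif(1, -2, 2)
    got <- classify_validation(ir_sig, d, p_sig, p_fc, j_sig, j_fc)
    removal <- ir_sig && d < 0
    accum <- (j_sig && j_fc > 0) || (p_sig && p_fc > 0)
    want <- if (removal && accum) "validated"
            else if (removal) "partial" else "not_significant"
    expect_equal(got, want)
  }
})

test_that("build_validation_table joins per-gene evidence", {
  ir <- data.frame(feature_id = c("gA:t:1", "gA:t:2", "gB:t:1", "gC:t:1"),
                   effect = c(-0.5, -0.1, -0.4, 0.1),
                   significant = c(TRUE, FALSE, TRUE, FALSE),
                   stringsAsFactors = FALSE)
  prot <- data.frame(feature_id = c("P_gA", "P_gB", "P_gC"),
                     gene_id = c("gA", "gB", "gC"),
                     effect = c(1, 0.2, 0.5),
                     significant = c(TRUE, FALSE, FALSE),
                     stringsAsFactors = FALSE)
  jp <- data.frame(junction_id = c("J:gA:t:1", "J:gB:t:1"),
                   effect = c(2, 0.1), significant = c(TRUE, FALSE),
                   detected = c(TRUE, TRUE), stringsAsFactors = FALSE)
  intron_genes <- c("gA:t:1" = "gA", "gA:t:2" = "gA", "gB:t:1" = "gB",
                    "gC:t:1" = "gC")
  junction_genes <- c("J:gA:t:1" = "gA", "J:gB:t:1" = "gB")
  out <- build_validation_table(ir, prot, jp, intron_genes, junction_genes,
                                "COLL")
  expect_equal(out$class[out$gene_id == "gA"], "validated")
  expect_equal(out$class[out$gene_id == "gB"], "partial")
  expect_equal(out$class[out$gene_id == "gC"], "not_significant")
  expect_equal(out$delta_ir[out$gene_id == "gA"], -0.5)
  expect_true(all(out$stimulus == "COLL"))
})

test_that("transcript counting assigns strand-compatible overlapping reads", {
  p <- write_gtf(rbind(
    gtf_row("chr1", "exon", 1, 100, "+", "g1", "g1.t1"),
    gtf_row("chr1", "exon", 201, 300, "+", "g1", "g1.t1"),
    gtf_row("chr1", "exon", 401, 500, "-", "g2", "g2.t1")
  ))
  anno <- read_annotation(p)
  recs <- data.frame(
    qname = c("in_g1", "in_g1_junction", "in_g2", "wrong_strand", "nowhere"),
    flag = c(16L, 16L, 0L, 0L, 16L),
    pos = c(10L, 81L, 410L, 20L, 320L),
    cigar = c("50M", "20M100N20M", "50M", "50M", "50M")
  )
  aln <- read_alignments(write_sam(recs), strandedness = "reverse")
  counts <- count_reads_per_transcript(aln, anno)
  expect_equal(unname(counts["g1.t1"]), 2L)
  expect_equal(unname(counts["g2.t1"]), 1L)
})

test_that("expression records apply the read threshold and FC rule", {
  groups <- stats::setNames(rep(c("CTRL", "COLL"), each = 3),
                            c(paste0("C", 1:3), paste0("T", 1:3)))
  counts <- rbind(
    "g0.t1" = c(10000, 10100, 9900, 10000, 10050, 9950),  # bulk background
    "g1.t1" = c(100, 110, 90, 100, 105, 95),   # flat, expressed
    "g2.t1" = c(5, 6, 4, 5, 6, 4),             # below threshold
    "g3.t1" = c(50, 55, 45, 200, 210, 190)     # up-regulated
  )
  colnames(counts) <- names(groups)
  lens <- c("g0.t1" = 1000, "g1.t1" = 1000, "g2.t1" = 1000, "g3.t1" = 1000)
  out <- transcript_expression(counts, lens, groups, "COLL",
                               diff_config(seed = 73))
  expect_true(out$expressed_ctrl[out$transcript_id == "g1.t1"])
  expect_false(out$expressed_ctrl[out$transcript_id == "g2.t1"])
  expect_false(out$significant[out$transcript_id == "g1.t1"])
  g3 <- out[out$transcript_id == "g3.t1", ]
  expect_gt(g3$effect, log2(1.5))
})
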