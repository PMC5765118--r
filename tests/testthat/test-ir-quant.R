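test_that("measurable_region subtracts exons and excluded small RNAs", {
  p <- write_gtf(rbind(
    gtf_row("c1", "exon", 1, 100, "+", "g1", "t1"),
    gtf_row("c1", "exon", 201, 300, "+", "g1", "t1")
  ))
  anno <- read_annotation(p)
  intron <- derive_introns(anno)
  # no overlapping features: whole intron
  reg <- measurable_region(intron, anno)
  expect_equal(IRanges::start(reg), 101L)
  expect_equal(IRanges::end(reg), 200L)

  # snoRNA inside the intron: set subtraction leaves two pieces
  p2 <- write_gtf(rbind(
    gtf_row("c1", "exon", 1, 100, "+", "g1", "t1"),
    gtf_row("c1", "exon", 201, 300, "+", "g1", "t1"),
    gtf_row("c1", "snoRNA", 121, 140, "+", "sno1")
  ))
  anno2 <- read_annotation(p2)
  reg2 <- measurable_region(derive_introns(anno2), anno2)
  expect_equal(IRanges::start(reg2), c(101L, 141L))
  expect_equal(IRanges::end(reg2), c(120L, 200L))

  # exon of another transcript covering the whole intron: empty region
  p3 <- write_gtf(rbind(
    gtf_row("c1", "exon", 1, 100, "+", "g1", "t1"),
    gtf_row("c1", "exon", 201, 300, "+", "g1", "t1"),
    gtf_row("c1", "exon", 90, 210, "+", "g2", "t2")
  ))
  anno3 <- read_annotation(p3)
  introns3 <- derive_introns(anno3)
  i1 <- introns3[introns3$transcript_id == "t1"]
  reg3 <- measurable_region(i1, anno3)
  expect_equal(sum(IRanges::width(reg3)), 0L)
})

test_that("intronic_abundance matches uniform and empty coverage", {
  # 10 identical reads covering the whole intron: uniform 10x
  recs <- data.frame(qname = paste0("r", 1:10), flag = 0L, pos = 101L,
                     cigar = "100M")
  aln <- read_alignments(write_sam(recs), strandedness = "unstranded")
  region <- IRanges::IRanges(101L, 200L)
  expect_equal(intronic_abundance(aln, region, "chr1"), 10)
  # no reads at all
  aln0 <- read_alignments(write_sam(recs[0, , drop = FALSE]),
                          strandedness = "unstranded")
  expect_equal(intronic_abundance(aln0, region, "chr1"), 0)
})

test_that("intronic_abundance equals a brute-force pileup median", {
  set.seed(21)
  pos <- sample(80:220, 40, replace = TRUE)
  recs <- data.frame(qname = paste0("r", 1:40), flag = 0L, pos = pos,
                     cigar = "30M")
  aln <- read_alignments(write_sam(recs), strandedness = "unstranded")
  region <- IRanges::IRanges(c(101L, 161L), c(140L, 200L))
  blocks <- lapply(1:40, function(i) cbind(pos[i], pos[i] + 29L))
  positions <- c(101:140, 161:200)
  expect_equal(intronic_abundance(aln, region, "chr1"),
               oracle_pileup_median(blocks, positions))
})

test_that("splice_abundance requires exact boundary agreement", {
  recs <- data.frame(
    qname = c("exact", "short", "multi"),
    flag = 0L,
    pos = c(81L, 81L, 61L),
    cigar = c("20M100N20M", "20M50N20M", "20M20N20M100N20M")
  )
  aln <- read_alignments(write_sam(recs), strandedness = "unstranded")
  p <- write_gtf(rbind(
    gtf_row("chr1", "exon", 1, 100, "+", "g1", "t1"),
    gtf_row("chr1", "exon", 201, 300, "+", "g1", "t1")
  ))
  intron <- derive_introns(read_annotation(p))  # [101, 200]
  # "exact" has gap 101-200; "multi" has gaps 81-100 and 141-240
  expect_equal(splice_abundance(aln, intron), 1L)
})

test_that("splice_abundance equals an exhaustive gap scan on a mixed set", {
  set.seed(22)
  n <- 30
  gap_start <- sample(c(101L, 101L, 111L, 121L), n, replace = TRUE)
  gap_len <- sample(c(100L, 100L, 80L, 90L), n, replace = TRUE)
  recs <- data.frame(
    qname = paste0("r", 1:n), flag = 0L, pos = gap_start - 20L,
    cigar = sprintf("20M%dN20M", gap_len)
  )
  aln <- read_alignments(write_sam(recs), strandedness = "unstranded")
  p <- write_gtf(rbind(
    gtf_row("chr1", "exon", 1, 100, "+", "g1", "t1"),
    gtf_row("chr1", "exon", 201, 300, "+", "g1", "t1")
  ))
  intron <- derive_introns(read_annotation(p))
  gaps <- lapply(1:n, function(i) {
    cbind(gap_start[i], gap_start[i] + gap_len[i] - 1L)
  })
  expect_equal(splice_abundance(aln, intron),
               oracle_gap_scan(gaps, 101L, 200L))
})

test_that("ir_ratio follows the defining equation", {
  expect_equal(ir_ratio(30, 70), 0.3)
  expect_equal(ir_ratio(5, 0), 1)
  expect_true(is.na(ir_ratio(0, 0)))
})

test_that("ir_ratio is bounded and monotone in intronic abundance", {
  set.seed(23)
  intronic <- runif(200, 0, 50)
  splice <- rpois(200, 10)
  r <- ir_ratio(intronic, splice)
  expect_true(all(r >= 0 & r <= 1, na.rm = TRUE))
  # monotone non-decreasing in intronic abundance at fixed splice count
  s <- 7
  x <- sort(runif(50, 0, 30))
  expect_true(all(diff(ir_ratio(x, rep(s, 50))) >= 0))
})

test_that("filter_retained applies the per-sample quantile rule", {
  groups <- c(s1 = "CTRL", s2 = "CTRL", s3 = "CTRL")
  # all missing: empty result
  m_all_na <- matrix(NA_real_, 3, 3,
                     dimnames = list(paste0("i", 1:3), names(groups)))
  expect_length(filter_retained(ir_matrix(m_all_na, groups),
                                group = "CTRL"), 0L)

  # a 5-intron toy matrix checked against direct rule evaluation
  set.seed(24)
  m <- matrix(runif(15), 5, 3,
              dimnames = list(paste0("i", 1:5), names(groups)))
  m[2, 1] <- NA
  params <- ir_filter_params(quantile_cut = 0.25, min_replicates = 2L)
  got <- filter_retained(ir_matrix(m, groups), params, "CTRL")
  want <- oracle_filter_rule(m, names(groups), 0.25, 2L)
  expect_setequal(got, want)

  # an intron above the cut in exactly 2 of 3 samples is kept
  m2 <- matrix(c(0.9, 0.9, 0.1,
                 0.5, 0.5, 0.5,
                 0.1, 0.1, 0.9,
                 0.2, 0.2, 0.2,
                 0.05, 0.05, 0.05), 5, 3, byrow = TRUE,
               dimnames = list(paste0("i", 1:5), names(groups)))
  kept <- filter_retained(ir_matrix(m2, groups), params, "CTRL")
  expect_true("i1" %in% kept)
  expect_error(filter_retained(ir_matrix(m2, groups), params, "COLL"),
               "no samples")
})

test_that("compute_fpkm implements the definition", {
  expect_equal(compute_fpkm(100, 1000, 1e6), 100)
  expect_equal(compute_fpkm(0, 1000, 1e6), 0)
  expect_equal(compute_fpkm(50, 500, 2e6), 50)
  expect_error(compute_fpkm(10, 0, 1e6), "length")
  expect_error(compute_fpkm(10, 1000, 0), "total")
})

test_that("quantify_ir agrees with brute-force oracles on a toy dataset", {
  cfg <- sim_config(seed = 31L, n_genes = 3L, depth = 30, expr_reads = 30)
  sim <- simulate_genome_annotation(cfg)
  introns <- derive_introns(sim$annotation)
  truth <- simulate_truth(cfg, introns)
  sam <- tempfile(fileext = ".sam")
  simulate_alignments(cfg, sim, truth, "CTRL_1", "CTRL", sam)
  aln <- read_alignments(sam)
  irm <- quantify_ir(list(CTRL_1 = aln), introns, sim$annotation,
                     c(CTRL_1 = "CTRL"))
  for (i in seq_along(introns)) {
    intr <- introns[i]
    strand <- as.character(GenomicRanges::strand(intr))
    keep <- aln$reads$fragment_strand == strand
    blocks <- lapply(which(keep), function(r) {
      b <- aln$blocks[[r]]
      cbind(IRanges::start(b), IRanges::end(b))
    })
    gaps <- lapply(which(keep), function(r) {
      g <- aln$gaps[[r]]
      if (length(g) == 0) NULL else cbind(IRanges::start(g), IRanges::end(g))
    })
    reg <- measurable_region(intr, sim$annotation)
    positions <- unlist(lapply(seq_along(reg), function(k) {
      IRanges::start(reg)[k]:IRanges::end(reg)[k]
    }))
    expect_equal(irm$intronic[intr$intron_id, "CTRL_1"],
                 oracle_pileup_median(blocks, positions))
    expect_equal(irm$splice[intr$intron_id, "CTRL_1"],
                 oracle_gap_scan(gaps, GenomicRanges::start(intr),
                                 GenomicRanges::end(intr)))
  }
})

test_that("replicate IR profiles correlate under identical truth", {
  m <- simulate_ir_matrix(150, depth = 60, seed = 32L)
  ctrl <- m$ir[, m$groups == "CTRL"]
  cors <- c(cor(ctrl[, 1], ctrl[, 2]), cor(ctrl[, 1], ctrl[, 3]),
            cor(ctrl[, 2], ctrl[, 3]))
  expect_true(all(cors >= 0.8))
})
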