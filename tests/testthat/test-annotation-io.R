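test_that("read_genome loads, uppercases and validates FASTA records", {
  p <- write_fasta_raw(c(">c1", "acgt"))
  g <- read_genome(p)
  expect_equal(as.character(g[["c1"]]), "ACGT")

  p2 <- write_fasta_raw(c(">c1 desc", "ACGT", ">c2", "GGGG"))
  g2 <- read_genome(p2)
  expect_equal(names(g2), c("c1", "c2"))
  expect_length(g2, 2L)

  pdup <- write_fasta_raw(c(">c1", "ACGT", ">c1", "AAAA"))
  expect_error(read_genome(pdup), "duplicate")
  pempty <- write_fasta_raw(character(0))
  expect_error(read_genome(pempty))
})

test_that("read_annotation converts GTF records and sorts exons", {
  p <- write_gtf(rbind(
    gtf_row("c1", "exon", 201, 300, "+", "g1", "t1"),
    gtf_row("c1", "exon", 101, 200, "+", "g1", "t1"),
    gtf_row("c1", "gene", 101, 300, "+", "g1")
  ))
  anno <- read_annotation(p)
  ex <- anno[anno$type == "exon"]
  expect_equal(GenomicRanges::start(ex), c(101L, 201L))
  expect_equal(GenomicRanges::end(ex), c(200L, 300L))
  expect_equal(GenomicRanges::width(ex), c(100L, 100L))
  # non-exon feature types are retained for exclusion masks
  expect_true("gene" %in% anno$type)
})

test_that("read_annotation rejects exons without transcript_id", {
  p <- write_gtf(gtf_row("c1", "exon", 101, 200, "+", "g1", NA))
  expect_error(read_annotation(p), "transcript_id")
})

test_that("GTF round-trip preserves exon coordinates exactly", {
  set.seed(11)
  rows <- do.call(rbind, lapply(1:5, function(g) {
    start <- g * 1000L
    rbind(
      gtf_row("c1", "exon", start, start + 99L, "+", paste0("g", g),
              paste0("t", g)),
      gtf_row("c1", "exon", start + 300L, start + 450L, "+", paste0("g", g),
              paste0("t", g))
    )
  }))
  p <- write_gtf(rows)
  anno <- read_annotation(p)
  p2 <- tempfile(fileext = ".gtf")
  write_annotation(anno, p2)
  anno2 <- read_annotation(p2)
  ex1 <- anno[anno$type == "exon"]; ex2 <- anno2[anno2$type == "exon"]
  expect_equal(GenomicRanges::start(ex1), GenomicRanges::start(ex2))
  expect_equal(GenomicRanges::end(ex1), GenomicRanges::end(ex2))
  expect_equal(ex1$transcript_id, ex2$transcript_id)
})

test_that("derive_introns yields the gaps between consecutive exons", {
  p <- write_gtf(rbind(
    gtf_row("c1", "exon", 1, 100, "+", "g1", "t1"),
    gtf_row("c1", "exon", 201, 300, "+", "g1", "t1")
  ))
  introns <- derive_introns(read_annotation(p))
  expect_length(introns, 1L)
  expect_equal(GenomicRanges::start(introns), 101L)
  expect_equal(GenomicRanges::end(introns), 200L)

  # single-exon transcript: no introns
  p1 <- write_gtf(gtf_row("c1", "exon", 1, 100, "+", "g1", "t1"))
  expect_length(derive_introns(read_annotation(p1)), 0L)

  # minus strand: same genomic interval, strand carried through
  pm <- write_gtf(rbind(
    gtf_row("c1", "exon", 1, 100, "-", "g1", "t1"),
    gtf_row("c1", "exon", 201, 300, "-", "g1", "t1")
  ))
  im <- derive_introns(read_annotation(pm))
  expect_equal(GenomicRanges::start(im), 101L)
  expect_equal(as.character(GenomicRanges::strand(im)), "-")
})

test_that("introns with identical coordinates are merged across transcripts", {
  p <- write_gtf(rbind(
    gtf_row("c1", "exon", 1, 100, "+", "g1", "t1"),
    gtf_row("c1", "exon", 201, 300, "+", "g1", "t1"),
    gtf_row("c1", "exon", 1, 100, "+", "g1", "t2"),
    gtf_row("c1", "exon", 201, 320, "+", "g1", "t2")
  ))
  introns <- derive_introns(read_annotation(p))
  expect_length(introns, 1L)
})

test_that("read_alignments applies CIGAR reference-consumption rules", {
  p <- write_sam(data.frame(qname = c("r1", "r2", "r3"), flag = 0L,
                            pos = c(1L, 1L, 1L),
                            cigar = c("50M100N50M", "100M", "10M5I10M")))
  aln <- read_alignments(p)
  expect_equal(length(aln), 3L)
  b1 <- aln$blocks[[1]]
  expect_equal(IRanges::start(b1), c(1L, 151L))
  expect_equal(IRanges::end(b1), c(50L, 200L))
  g1 <- aln$gaps[[1]]
  expect_equal(IRanges::start(g1), 51L)
  expect_equal(IRanges::end(g1), 150L)
  expect_equal(IRanges::width(aln$blocks[[2]]), 100L)
  # insertions consume no reference
  expect_equal(IRanges::width(aln$blocks[[3]]), 20L)
  expect_length(aln$gaps[[3]], 0L)
})

test_that("read_alignments rejects unknown CIGAR ops and missing @SQ", {
  p <- write_sam(data.frame(qname = "r1", flag = 0L, pos = 1L,
                            cigar = "10M2P10M"))
  expect_error(read_alignments(p), "CIGAR")
  p2 <- write_sam(data.frame(qname = "r1", flag = 0L, pos = 1L,
                             cigar = "10M", contig = "chrX"))
  expect_error(read_alignments(p2), "@SQ")
})

test_that("fragment strand follows the configured library protocol", {
  p <- write_sam(data.frame(qname = c("fwd", "rev"), flag = c(0L, 16L),
                            pos = 1L, cigar = "10M"))
  rev <- read_alignments(p, strandedness = "reverse")
  expect_equal(rev$reads$fragment_strand, c("-", "+"))
  fwd <- read_alignments(p, strandedness = "forward")
  expect_equal(fwd$reads$fragment_strand, c("+", "-"))
  uns <- read_alignments(p, strandedness = "unstranded")
  expect_equal(uns$reads$fragment_strand, c("*", "*"))
})

test_that("block lengths agree with an independent CIGAR walker", {
  set.seed(5)
  cigars <- replicate(25, {
    n_blocks <- sample(1:3, 1)
    parts <- c()
    for (b in seq_len(n_blocks)) {
      parts <- c(parts, paste0(sample(20:80, 1), "M"))
      if (runif(1) < 0.4) parts <- c(parts, paste0(sample(1:5, 1), "I"),
                                     paste0(sample(20:40, 1), "M"))
      if (b < n_blocks) parts <- c(parts, paste0(sample(50:500, 1), "N"))
    }
    paste(parts, collapse = "")
  })
  pos <- sample(1:5000, 25)
  p <- write_sam(data.frame(qname = paste0("r", 1:25), flag = 0L,
                            pos = pos, cigar = cigars))
  aln <- read_alignments(p)
  for (i in 1:25) {
    oracle <- oracle_cigar_walk(pos[i], cigars[i])
    b <- aln$blocks[[i]]
    expect_equal(cbind(IRanges::start(b), IRanges::end(b)), oracle$blocks,
                 ignore_attr = TRUE)
    g <- aln$gaps[[i]]
    if (is.null(oracle$gaps)) {
      expect_length(g, 0L)
    } else {
      expect_equal(cbind(IRanges::start(g), IRanges::end(g)), oracle$gaps,
                   ignore_attr = TRUE)
    }
  }
})
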