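# Fixture builders and independent oracles shared across test files.
# Oracles are deliberately naive re-implementations (per-base loops, direct
# rule evaluation, hand-written codon table) kept independent of the
# package's code paths.

make_genome <- function(...) {
  seqs <- c(...)
  g <- Biostrings::DNAStringSet(unname(seqs))
  names(g) <- names(seqs)
  g
}

write_fasta_raw <- function(lines, path = tempfile(fileext = ".fa")) {
  writeLines(lines, path)
  path
}

# hand-written GTF (1-based inclusive coordinates, ensembl-style attributes)
write_gtf <- function(rows, path = tempfile(fileext = ".gtf")) {
  lines <- vapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    attr <- if (is.na(r$transcript_id)) {
      sprintf('gene_id "%s";', r$gene_id)
    } else {
      sprintf('gene_id "%s"; transcript_id "%s";', r$gene_id, r$transcript_id)
    }
    sprintf("%s\ttest\t%s\t%d\t%d\t.\t%s\t.\t%s",
            r$contig, r$type, r$start, r$end, r$strand, attr)
  }, character(1L))
  writeLines(lines, path)
  path
}

gtf_row <- function(contig, type, start, end, strand, gene_id,
                    transcript_id = NA) {
  data.frame(contig = contig, type = type, start = start, end = end,
             strand = strand, gene_id = gene_id,
             transcript_id = transcript_id, stringsAsFactors = FALSE)
}

# minimal SAM writer: records = data.frame(qname, flag, pos, cigar)
write_sam <- function(records, sq = c(chr1 = 100000L),
                      path = tempfile(fileext = ".sam"),
                      contig = "chr1") {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(sq), unname(sq)))
  body <- sprintf("%s\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t*\t*",
                  records$qname, records$flag,
                  if ("contig" %in% names(records)) records$contig else contig,
                  records$pos, records$cigar)
  writeLines(c(hdr, body), path)
  path
}

# independent CIGAR walker: returns reference-consumed blocks and gaps
# (1-based closed) by scanning op-by-op
oracle_cigar_walk <- function(pos, cigar) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  lens <- as.integer(sub("[A-Z=]$", "", ops))
  kinds <- sub("^[0-9]+", "", ops)
  cur <- pos
  blocks <- list(); gaps <- list()
  bstart <- NA
  for (i in seq_along(kinds)) {
    k <- kinds[i]; l <- lens[i]
    if (k %in% c("M", "=", "X", "D")) {
      if (is.na(bstart)) bstart <- cur
      cur <- cur + l
    } else if (k == "N") {
      if (!is.na(bstart)) blocks[[length(blocks) + 1]] <- c(bstart, cur - 1)
      gaps[[length(gaps) + 1]] <- c(cur, cur + l - 1)
      cur <- cur + l
      bstart <- NA
    }
    # I and S consume no reference
  }
  if (!is.na(bstart)) blocks[[length(blocks) + 1]] <- c(bstart, cur - 1)
  list(blocks = do.call(rbind, blocks), gaps = do.call(rbind, gaps))
}

# brute-force per-base pileup median over given 1-based positions: walk
# every aligned block and increment a depth counter base by base
oracle_pileup_median <- function(block_list, positions) {
  if (length(positions) == 0) return(0)
  width <- max(positions,
               unlist(lapply(block_list, function(b) b[, 2]), use.names = FALSE))
  depth <- integer(width)
  for (b in block_list) {
    if (is.null(b)) next
    for (k in seq_len(nrow(b))) {
      idx <- b[k, 1]:b[k, 2]
      depth[idx] <- depth[idx] + 1L
    }
  }
  stats::median(depth[positions])
}

# brute-force exact-gap scan: count reads with any gap equal to [s, e]
oracle_gap_scan <- function(gap_list, s, e) {
  sum(vapply(gap_list, function(g) {
    !is.null(g) && any(g[, 1] == s & g[, 2] == e)
  }, logical(1)))
}

# hand-written standard codon table
.oracle_codons <- local({
  bases <- c("T", "C", "A", "G")
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  codons <- character(64)
  k <- 0
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    k <- k + 1
    codons[k] <- paste0(b1, b2, b3)
  }
  stats::setNames(aa, codons)
})

oracle_translate <- function(seq, frame) {
  n <- (nchar(seq) - frame) %/% 3
  if (n <= 0) return("")
  out <- character(n)
  for (i in seq_len(n)) {
    codon <- substr(seq, frame + 3 * i - 2, frame + 3 * i)
    out[i] <- if (grepl("[^ACGT]", codon)) "X"
              else unname(.oracle_codons[codon])
  }
  paste(out, collapse = "")
}

# naive all-positions substring scan over junction entries
oracle_substring_scan <- function(peptide, entries, il_equivalent = FALSE) {
  canon <- function(x) if (il_equivalent) chartr("IL", "JJ", x) else x
  hits <- list()
  for (e in seq_len(nrow(entries))) {
    aa <- entries$aa_seq[e]
    np <- nchar(peptide)
    if (nchar(aa) < np) next
    for (s in seq_len(nchar(aa) - np + 1)) {
      span <- substr(aa, s, s + np - 1)
      if (canon(span) == canon(peptide) && !grepl("*", span, fixed = TRUE)) {
        hits[[length(hits) + 1]] <- data.frame(
          peptide_seq = peptide, junction_id = entries$junction_id[e],
          frame = entries$frame[e], aa_start = s - 1L,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0) return(NULL)
  do.call(rbind, hits)
}

# direct evaluation of the retention-filter rule on an IR matrix
oracle_filter_rule <- function(ir, cols, quantile_cut, min_replicates) {
  keep <- character(0)
  qs <- vapply(cols, function(s) {
    stats::quantile(ir[, s], quantile_cut, na.rm = TRUE, names = FALSE)
  }, numeric(1))
  for (i in rownames(ir)) {
    n_pass <- sum(vapply(seq_along(cols), function(j) {
      v <- ir[i, cols[j]]
      !is.na(v) && v > qs[j]
    }, logical(1)))
    if (n_pass >= min_replicates) keep <- c(keep, i)
  }
  keep
}

# random DNA string
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# a small two-exon gene fixture on a random genome: returns genome,
# annotation GRanges and the single intron
two_exon_fixture <- function(e1 = c(1L, 100L), e2 = c(201L, 300L),
                             strand = "+", glen = 400L, seed = 42L) {
  set.seed(seed)
  genome <- make_genome(chr1 = rand_dna(glen))
  gtf <- write_gtf(rbind(
    gtf_row("chr1", "exon", e1[1], e1[2], strand, "g1", "t1"),
    gtf_row("chr1", "exon", e2[1], e2[2], strand, "g1", "t1")
  ))
  anno <- read_annotation(gtf)
  list(genome = genome, annotation = anno, introns = derive_introns(anno))
}
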