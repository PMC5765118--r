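#' Exon-exon junction sites of retained introns
#'
#' One junction per retained intron, defined by the exons flanking the
#' intron in its source transcript. Introns identical in coordinates across
#' transcripts were already merged by [derive_introns()], so junctions are
#' deduplicated by construction.
#'
#' @param introns `GRanges` of (retained) introns from [derive_introns()].
#' @param annotation Annotation `GRanges`.
#' @return data.frame: junction_id, intron_id, gene_id, contig, strand,
#'   left_start/left_end (flanking exon with lower coordinates; `left_end`
#'   is the donor coordinate on "+"), right_start/right_end (higher-
#'   coordinate exon; `right_start` is the acceptor on "+").
#' @export
junctions_from_introns <- function(introns, annotation) {
  byt <- transcript_exons(annotation)
  if (length(introns) == 0L) {
    return(data.frame(junction_id = character(), intron_id = character(),
                      gene_id = character(), contig = character(),
                      strand = character(), left_start = integer(),
                      left_end = integer(), right_start = integer(),
                      right_end = integer(), stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_along(introns), function(i) {
    intr <- introns[i]
    ex <- byt[[intr$transcript_id]]
    if (is.null(ex)) stop("transcript not in annotation: ", intr$transcript_id)
    k <- intr$index
    if (k + 1L > length(ex)) stop("intron without flanking exons: ",
                                  intr$intron_id)
    left <- ex[k]; right <- ex[k + 1L]
    if (GenomicRanges::end(left) + 1L != GenomicRanges::start(intr) ||
        GenomicRanges::start(right) - 1L != GenomicRanges::end(intr)) {
      stop("intron does not match its transcript's exon gap: ",
           intr$intron_id)
    }
    data.frame(
      junction_id = paste0("J:", intr$intron_id),
      intron_id = intr$intron_id, gene_id = intr$gene_id,
      contig = as.character(GenomicRanges::seqnames(intr)),
      strand = as.character(GenomicRanges::strand(intr)),
      left_start = GenomicRanges::start(left),
      left_end = GenomicRanges::end(left),
      right_start = GenomicRanges::start(right),
      right_end = GenomicRanges::end(right),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Spliced sequence window around a junction
#'
#' Extracts up to `flank` exonic nucleotides on each side of the exon-exon
#' junction of the matured (spliced) mRNA. On the minus strand the
#' mRNA-upstream exon is the higher-coordinate exon, and both flanks are
#' reverse-complemented so the spliced window reads 5' to 3' on the mRNA.
#' Exons shorter than `flank` are truncated, never extended into the next
#' exon.
#'
#' @param genome A `DNAStringSet` from [read_genome()].
#' @param junctions data.frame from [junctions_from_introns()].
#' @param flank Maximum exonic nucleotides per side (default 75).
#' @return data.frame: junction_id, gene_id, contig, strand, donor,
#'   acceptor (genomic coordinates of the last/first exonic base flanking
#'   the intron), left_seq, right_seq, spliced_seq, L (= nchar(left_seq),
#'   the junction offset within `spliced_seq`).
#' @export
extract_spliced_window <- function(genome, junctions, flank = 75L) {
  fetch <- function(contig, start, end) {
    if (!(contig %in% names(genome))) stop("contig not in genome: ", contig)
    if (start < 1L || end > length(genome[[contig]])) {
      stop("window outside contig ", contig, ": ", start, "-", end)
    }
    as.character(Biostrings::subseq(genome[[contig]], start, end))
  }
  revcomp <- function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  rows <- lapply(seq_len(nrow(junctions)), function(i) {
    j <- junctions[i, ]
    llen <- min(flank, j$left_end - j$left_start + 1L)
    rlen <- min(flank, j$right_end - j$right_start + 1L)
    left_gseq <- fetch(j$contig, j$left_end - llen + 1L, j$left_end)
    right_gseq <- fetch(j$contig, j$right_start, j$right_start + rlen - 1L)
    if (j$strand == "-") {
      left_seq <- revcomp(right_gseq)   # mRNA-upstream exon = genomic right
      right_seq <- revcomp(left_gseq)
      donor <- j$right_start; acceptor <- j$left_end
    } else {
      left_seq <- left_gseq; right_seq <- right_gseq
      donor <- j$left_end; acceptor <- j$right_start
    }
    data.frame(junction_id = j$junction_id, gene_id = j$gene_id,
               contig = j$contig, strand = j$strand,
               donor = donor, acceptor = acceptor,
               left_seq = left_seq, right_seq = right_seq,
               spliced_seq = paste0(left_seq, right_seq),
               L = nchar(left_seq), stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L) {
    return(data.frame(junction_id = character(), gene_id = character(),
                      contig = character(), strand = character(),
                      donor = integer(), acceptor = integer(),
                      left_seq = character(), right_seq = character(),
                      spliced_seq = character(), L = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Translate a nucleotide sequence in one reading frame
#'
#' Standard genetic code; codons start at offset `frame`, trailing 1-2 nt
#' are dropped, stop codons render `*`, and any codon containing a non-ACGT
#' base renders `X`.
#'
#' @param seq Nucleotide string.
#' @param frame 0, 1 or 2.
#' @return Amino-acid string of length `floor((nchar(seq) - frame) / 3)`.
#' @export
translate_frame <- function(seq, frame) {
  stopifnot(length(seq) == 1L, frame %in% 0:2)
  n_codons <- (nchar(seq) - frame) %/% 3L
  if (n_codons <= 0L) return("")
  sub <- substr(seq, frame + 1L, frame + 3L * n_codons)
  as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                     if.fuzzy.codon = "X",
                                     no.init.codon = TRUE))
}

#' Three-frame junction database entries
#'
#' @param windows data.frame from [extract_spliced_window()].
#' @return data.frame with one row per (junction, frame): junction_id,
#'   gene_id, contig, strand, donor, acceptor, frame, L, aa_seq.
#' @export
translate_junction_windows <- function(windows) {
  rows <- lapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    data.frame(junction_id = w$junction_id, gene_id = w$gene_id,
               contig = w$contig, strand = w$strand,
               donor = w$donor, acceptor = w$acceptor,
               frame = 0:2, L = w$L,
               aa_seq = vapply(0:2, function(f) {
                 translate_frame(w$spliced_seq, f)
               }, character(1L)),
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L) {
    return(data.frame(junction_id = character(), gene_id = character(),
                      contig = character(), strand = character(),
                      donor = integer(), acceptor = integer(),
                      frame = integer(), L = integer(),
                      aa_seq = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Build the three-frame junction peptide database
#'
#' Convenience wrapper: junction sites from retained introns, spliced
#' windows of `flank` exonic nt per side, translated in three frames.
#'
#' @param genome `DNAStringSet`.
#' @param annotation Annotation `GRanges`.
#' @param retained_introns `GRanges` of retained introns.
#' @param flank Window half-width in exonic nt (default 75).
#' @return data.frame of entries, see [translate_junction_windows()].
#' @export
build_junction_db <- function(genome, annotation, retained_introns,
                              flank = 75L) {
  jxn <- junctions_from_introns(retained_introns, annotation)
  translate_junction_windows(extract_spliced_window(genome, jxn, flank))
}

#' Write junction database entries as FASTA
#'
#' Header format:
#' `>jxn|<junction_id>|<gene>|<contig>|<donor>|<acceptor>|<strand>|frame=<f>|L=<L>`.
#'
#' @param entries data.frame from [translate_junction_windows()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_junction_fasta <- function(entries, path) {
  key <- paste(entries$junction_id, entries$frame)
  if (anyDuplicated(key)) {
    stop("duplicate (junction, frame) entry: ", key[duplicated(key)][1L])
  }
  aa <- Biostrings::AAStringSet(entries$aa_seq)
  names(aa) <- sprintf("jxn|%s|%s|%s|%d|%d|%s|frame=%d|L=%d",
                       entries$junction_id, entries$gene_id, entries$contig,
                       entries$donor, entries$acceptor, entries$strand,
                       entries$frame, entries$L)
  Biostrings::writeXStringSet(aa, filepath = path, width = 80L)
  invisible(path)
}

#' Read a junction FASTA back into entries
#'
#' Inverse of [write_junction_fasta()]; header fields round-trip losslessly.
#'
#' @param path Junction FASTA path.
#' @return data.frame of entries, see [translate_junction_windows()].
#' @export
read_junction_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) {
    return(data.frame(junction_id = character(), gene_id = character(),
                      contig = character(), strand = character(),
                      donor = integer(), acceptor = integer(),
                      frame = integer(), L = integer(),
                      aa_seq = character(), stringsAsFactors = FALSE))
  }
  f <- strsplit(names(aa), "|", fixed = TRUE)
  if (any(lengths(f) != 9L)) stop("malformed junction FASTA header in ", path)
  f <- do.call(rbind, f)
  data.frame(junction_id = f[, 2L], gene_id = f[, 3L], contig = f[, 4L],
             strand = f[, 7L],
             donor = as.integer(f[, 5L]), acceptor = as.integer(f[, 6L]),
             frame = as.integer(sub("frame=", "", f[, 8L], fixed = TRUE)),
             L = as.integer(sub("L=", "", f[, 9L], fixed = TRUE)),
             aa_seq = as.character(aa), stringsAsFactors = FALSE)
}
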