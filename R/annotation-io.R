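#' Read a genome FASTA file
#'
#' Loads all records of a (plain-text) FASTA file into a
#' \link[Biostrings]{DNAStringSet}, upper-casing the sequences. Record ids are
#' taken as the first whitespace-delimited token of each header.
#'
#' @param path Path to a FASTA file.
#' @return A \link[Biostrings]{DNAStringSet}, one element per contig.
#' @export
read_genome <- function(path) {
  stopifnot(file.exists(path))
  dna <- Biostrings::readDNAStringSet(path)
  if (length(dna) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(dna))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate FASTA header(s): ", paste(dup, collapse = ", "))
  }
  names(dna) <- ids
  if (any(Biostrings::width(dna) == 0L)) stop("empty sequence in FASTA: ", path)
  # uppercase via DNAStringSet round-trip (readDNAStringSet keeps case)
  dna <- Biostrings::DNAStringSet(toupper(as.character(dna)))
  dna
}

#' Write a genome FASTA file
#'
#' @param genome A \link[Biostrings]{DNAStringSet}.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, filepath = path, width = 70L)
  invisible(path)
}

#' Read a GTF gene annotation
#'
#' Imports an Ensembl-style GTF into a \link[GenomicRanges]{GRanges} with
#' metadata columns `type`, `gene_id` and `transcript_id`. Exon records must
#' carry both a `gene_id` and a `transcript_id`; all other feature types
#' (gene, transcript, miRNA, snoRNA, ...) are retained so they can serve as
#' exclusion masks downstream. Coordinates follow the usual R convention
#' (1-based, closed intervals).
#'
#' @param path Path to a GTF file.
#' @return A `GRanges` sorted by contig and start, with mcols
#'   `type`, `gene_id`, `transcript_id`.
#' @export
read_annotation <- function(path) {
  stopifnot(file.exists(path))
  gr <- rtracklayer::import(path, format = "gtf")
  if (length(gr) == 0L) stop("no features in GTF: ", path)
  mc <- S4Vectors::mcols(gr)
  if (is.null(mc$gene_id)) stop("GTF has no gene_id attributes: ", path)
  if (is.null(mc$transcript_id)) mc$transcript_id <- NA_character_
  is_exon <- as.character(mc$type) == "exon"
  bad <- which(is_exon & (is.na(mc$transcript_id) | mc$transcript_id == ""))
  if (length(bad) > 0L) {
    stop("exon record ", bad[1L], " is missing a transcript_id")
  }
  out <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(gr),
    ranges   = IRanges::ranges(gr),
    strand   = GenomicRanges::strand(gr),
    type          = as.character(mc$type),
    gene_id       = as.character(mc$gene_id),
    transcript_id = as.character(mc$transcript_id)
  )
  S4Vectors::sort(out, ignore.strand = TRUE)
}

#' Write a GTF gene annotation
#'
#' Inverse of [read_annotation()]: exon coordinates round-trip exactly.
#'
#' @param annotation A `GRanges` as returned by [read_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  rtracklayer::export(annotation, path, format = "gtf")
  invisible(path)
}

#' Exon records of an annotation, grouped by transcript
#'
#' @param annotation A `GRanges` from [read_annotation()].
#' @return A `GRangesList`, one element per transcript, exons sorted by start.
#' @export
transcript_exons <- function(annotation) {
  ex <- annotation[annotation$type == "exon"]
  ex <- S4Vectors::sort(ex, ignore.strand = TRUE)
  S4Vectors::split(ex, ex$transcript_id)
}

#' Derive introns from a gene annotation
#'
#' One intron per consecutive exon pair per transcript, in genomic order.
#' Introns sharing identical genomic coordinates across transcripts are
#' merged under a single id (the first transcript, in sorted order, labels
#' the merged intron). Intron retention is a genomic measurement, so the
#' deduplicated genomic interval is the unit of analysis.
#'
#' @param annotation A `GRanges` from [read_annotation()].
#' @return A `GRanges` of introns with mcols `intron_id` (gene:transcript:index),
#'   `gene_id`, `transcript_id`, `index`.
#' @export
derive_introns <- function(annotation) {
  byt <- transcript_exons(annotation)
  pieces <- lapply(names(byt), function(tx) {
    ex <- byt[[tx]]
    n <- length(ex)
    if (n < 2L) return(NULL)
    st <- GenomicRanges::start(ex)
    en <- GenomicRanges::end(ex)
    if (any(st[-1L] <= en[-n])) {
      stop("overlapping or adjacent exons in transcript ", tx)
    }
    GenomicRanges::GRanges(
      seqnames = GenomicRanges::seqnames(ex)[1L],
      ranges   = IRanges::IRanges(start = en[-n] + 1L, end = st[-1L] - 1L),
      strand   = GenomicRanges::strand(ex)[1L],
      intron_id = sprintf("%s:%s:%d", ex$gene_id[1L], tx, seq_len(n - 1L)),
      gene_id = ex$gene_id[1L],
      transcript_id = tx,
      index = seq_len(n - 1L)
    )
  })
  pieces <- pieces[!vapply(pieces, is.null, logical(1L))]
  if (length(pieces) == 0L) {
    return(GenomicRanges::GRanges(
      intron_id = character(), gene_id = character(),
      transcript_id = character(), index = integer()
    ))
  }
  introns <- do.call(c, pieces)
  key <- paste(GenomicRanges::seqnames(introns),
               GenomicRanges::start(introns),
               GenomicRanges::end(introns),
               GenomicRanges::strand(introns))
  introns[!duplicated(key)]
}

.REF_CONSUMING <- c("M", "D", "N", "=", "X")
.KNOWN_OPS <- c("M", "I", "D", "N", "S", "=", "X")

#' Read gapped alignments from a SAM file
#'
#' Parses a plain-text SAM file into per-read aligned blocks and the gaps
#' (`N` CIGAR operations) between them. `M`, `=`, `X` and `D` operations
#' consume reference within a block; `I` and `S` consume none; each `N`
#' operation opens a gap between blocks. Unmapped reads (flag 0x4) are
#' skipped. The strand of the sequenced fragment is inferred from the
#' reverse-complement flag (0x10) under a configurable library protocol:
#' for a dUTP/TruSeq reverse-stranded library (the default) the fragment
#' strand is the opposite of the read alignment strand, for a
#' forward-stranded library it is the same, and for an unstranded library
#' it is `*` (compatible with both).
#'
#' @param path Path to a SAM file with an `@SQ`-bearing header.
#' @param strandedness One of `"reverse"` (default), `"forward"`,
#'   `"unstranded"`.
#' @return An object of class `platelet_alignments`: a list with
#'   `reads` (data.frame: read_id, contig, read_strand, fragment_strand),
#'   `blocks` and `gaps` (both `IRangesList`, parallel to `reads`).
#' @export
read_alignments <- function(path,
                            strandedness = c("reverse", "forward", "unstranded")) {
  strandedness <- match.arg(strandedness)
  stopifnot(file.exists(path))
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  sq <- hdr[startsWith(hdr, "@SQ")]
  sq_names <- vapply(strsplit(sq, "\t", fixed = TRUE), function(x) {
    sn <- x[startsWith(x, "SN:")]
    if (length(sn) == 0L) NA_character_ else substring(sn[1L], 4L)
  }, character(1L))
  sq_names <- sq_names[!is.na(sq_names)]
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (length(body) == 0L) {
    return(.new_alignments(
      data.frame(read_id = character(), contig = character(),
                 read_strand = character(), fragment_strand = character(),
                 stringsAsFactors = FALSE),
      IRanges::IRangesList(), IRanges::IRangesList()
    ))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 11L)) stop("malformed SAM record at line ", which(nf < 11L)[1L])
  f <- do.call(rbind, lapply(f, `[`, 1:6))
  flag <- as.integer(f[, 2L])
  mapped <- bitwAnd(flag, 4L) == 0L
  f <- f[mapped, , drop = FALSE]
  flag <- flag[mapped]
  if (nrow(f) == 0L) {
    return(.new_alignments(
      data.frame(read_id = character(), contig = character(),
                 read_strand = character(), fragment_strand = character(),
                 stringsAsFactors = FALSE),
      IRanges::IRangesList(), IRanges::IRangesList()
    ))
  }
  contig <- f[, 3L]
  missing_sq <- setdiff(unique(contig), sq_names)
  if (length(missing_sq) > 0L) {
    stop("contig(s) absent from @SQ header: ", paste(missing_sq, collapse = ", "))
  }
  cigar <- f[, 6L]
  ops <- unique(unlist(strsplit(gsub("[0-9]+", "", cigar), "")))
  bad_ops <- setdiff(ops, .KNOWN_OPS)
  if (length(bad_ops) > 0L) {
    stop("unsupported CIGAR operation(s): ", paste(bad_ops, collapse = ", "))
  }
  pos <- as.integer(f[, 4L])
  blocks <- GenomicAlignments::extractAlignmentRangesOnReference(
    cigar, pos = pos, drop.D.ranges = FALSE
  )
  gaps <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cigar, pos = pos, ops = "N"
  )
  read_strand <- ifelse(bitwAnd(flag, 16L) == 16L, "-", "+")
  fragment_strand <- switch(
    strandedness,
    reverse    = ifelse(read_strand == "+", "-", "+"),
    forward    = read_strand,
    unstranded = rep("*", length(read_strand))
  )
  reads <- data.frame(
    read_id = f[, 1L], contig = contig,
    read_strand = read_strand, fragment_strand = fragment_strand,
    stringsAsFactors = FALSE
  )
  .new_alignments(reads, blocks, gaps)
}

.new_alignments <- function(reads, blocks, gaps) {
  structure(list(reads = reads, blocks = blocks, gaps = gaps),
            class = "platelet_alignments")
}

#' @export
length.platelet_alignments <- function(x) nrow(x$reads)

#' @export
print.platelet_alignments <- function(x, ...) {
  cat(sprintf("<platelet_alignments> %d reads on %d contig(s)\n",
              length(x), length(unique(x$reads$contig))))
  invisible(x)
}

#' Subset alignments to one contig and fragment strand
#'
#' Reads with fragment strand `*` (unstranded protocol) match any strand;
#' `strand = "*"` matches all reads on the contig.
#'
#' @param aln A `platelet_alignments` object.
#' @param contig Contig name.
#' @param strand `"+"`, `"-"` or `"*"`.
#' @return A `platelet_alignments` subset.
#' @export
subset_alignments <- function(aln, contig, strand = "*") {
  keep <- aln$reads$contig == contig
  if (strand != "*") {
    keep <- keep & (aln$reads$fragment_strand == strand |
                      aln$reads$fragment_strand == "*")
  }
  .new_alignments(aln$reads[keep, , drop = FALSE],
                  aln$blocks[keep], aln$gaps[keep])
}
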