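#' Read alignment records from a SAM file
#'
#' Loads SAM records into a flat data.frame, one row per record, with the
#' CIGAR string kept verbatim and the linked-read barcode tag captured
#' when present. Text SAM is converted through the standard htslib-backed
#' I/O layer (`Rsamtools::asBam`) rather than parsed by hand; BAM input is
#' read directly. An optional region keeps only records whose leftmost
#' mapped position falls inside `chrom:start-end`.
#'
#' @param path SAM (or BAM) file.
#' @param region optional string `"chrom:start-end"`; records are filtered
#'   by leftmost position.
#' @param barcode_tag SAM tag holding the molecule barcode (default "BX").
#' @return A `dm_alignments` data.frame with columns `qname`, `flag`,
#'   `chrom`, `pos`, `mapq`, `cigar`, `mate_chrom`, `mate_pos`, `isize`,
#'   `seq`, `barcode`.
#' @export
read_alignments <- function(path, region = NULL, barcode_tag = "BX") {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    validate_sam_text(path)
    dest <- tempfile(fileext = "")
    bam <- suppressMessages(Rsamtools::asBam(path, destination = dest,
                                             overwrite = TRUE,
                                             indexDestination = FALSE))
  }
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar",
            "mrnm", "mpos", "isize", "seq")
  param <- Rsamtools::ScanBamParam(what = what, tag = barcode_tag)
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  bc <- res$tag[[barcode_tag]]
  if (is.null(bc)) bc <- rep(NA_character_, length(res$qname))
  df <- data.frame(qname = res$qname, flag = res$flag,
                   chrom = as.character(res$rname), pos = res$pos,
                   mapq = res$mapq, cigar = res$cigar,
                   mate_chrom = as.character(res$mrnm), mate_pos = res$mpos,
                   isize = res$isize,
                   seq = as.character(res$seq), barcode = bc,
                   stringsAsFactors = FALSE)
  validate_alignments(df)
  if (!is.null(region)) {
    r <- parse_region(region)
    keep <- !is.na(df$chrom) & df$chrom == r$chrom &
      !is.na(df$pos) & df$pos >= r$start & df$pos <= r$end
    df <- df[keep, , drop = FALSE]
    row.names(df) <- NULL
  }
  class(df) <- c("dm_alignments", "data.frame")
  df
}

parse_region <- function(region) {
  m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
  if (length(m) != 4) stop("malformed region: ", region)
  list(chrom = m[[2]], start = as.numeric(m[[3]]), end = as.numeric(m[[4]]))
}

# htslib silently truncates a SAM file at a malformed record, so check
# CIGAR/sequence consistency on the text before conversion
validate_sam_text <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) return(invisible(TRUE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  qname <- vapply(fields, `[[`, "", 1L)
  cigar <- vapply(fields, `[[`, "", 6L)
  seqs <- vapply(fields, `[[`, "", 10L)
  ok <- cigar != "*" & seqs != "*"
  if (!any(ok)) return(invisible(TRUE))
  qw <- GenomicAlignments::cigarWidthAlongQuerySpace(cigar[ok])
  bad <- which(qw != nchar(seqs[ok]))
  if (length(bad))
    stop("CIGAR/sequence length mismatch for read ", qname[ok][bad[[1]]])
  invisible(TRUE)
}

validate_alignments <- function(df) {
  has_seq <- !is.na(df$seq) & df$seq != "*" & !is.na(df$cigar) &
    df$cigar != "*"
  if (!any(has_seq)) return(invisible(TRUE))
  qw <- GenomicAlignments::cigarWidthAlongQuerySpace(
    df$cigar[has_seq], after.soft.clipping = FALSE)
  bad <- which(qw != nchar(df$seq[has_seq]))
  if (length(bad))
    stop("CIGAR/sequence length mismatch for read ",
         df$qname[has_seq][bad[[1]]])
  invisible(TRUE)
}

#' Reference span width of alignment records
#'
#' Number of reference bases consumed by each CIGAR (M/=/X/D/N ops).
#' @param aln a `dm_alignments` data.frame.
#' @return integer vector.
#' @export
aln_ref_width <- function(aln) {
  w <- rep(NA_integer_, nrow(aln))
  ok <- !is.na(aln$cigar) & aln$cigar != "*"
  w[ok] <- GenomicAlignments::cigarWidthAlongReferenceSpace(aln$cigar[ok])
  w
}

#' @rdname aln_ref_width
#' @export
aln_end <- function(aln) aln$pos + aln_ref_width(aln) - 1L

aln_is_minus <- function(flag) bitwAnd(flag, 16L) > 0L
aln_mate_is_minus <- function(flag) bitwAnd(flag, 32L) > 0L
aln_is_unmapped <- function(flag) bitwAnd(flag, 4L) > 0L
aln_mate_unmapped <- function(flag) bitwAnd(flag, 8L) > 0L
aln_is_paired <- function(flag) bitwAnd(flag, 1L) > 0L

#' Parse a CIGAR string into (op, length) pairs
#' @param cigar a single CIGAR string.
#' @return data.frame with columns `op` and `len`.
#' @export
parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*")
    return(data.frame(op = character(), len = integer()))
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
  data.frame(op = ops, len = lens, stringsAsFactors = FALSE)
}

#' Write simulated reads as FASTQ
#'
#' Exports reads in sequencing orientation (reverse-strand records are
#' reverse-complemented back) with uniform qualities, for users who want
#' to run a real aligner on simulated data.
#'
#' @param aln a `dm_alignments` data.frame.
#' @param path output FASTQ file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(aln, path) {
  seqs <- aln$seq
  minus <- aln_is_minus(aln$flag)
  if (any(minus))
    seqs[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs[minus])))
  mate <- ifelse(bitwAnd(aln$flag, 128L) > 0L, "/2",
                 ifelse(bitwAnd(aln$flag, 64L) > 0L, "/1", ""))
  out <- as.vector(rbind(paste0("@", aln$qname, mate), seqs, "+",
                         vapply(nchar(seqs), function(n)
                           paste(rep("I", n), collapse = ""), "")))
  writeLines(out, path)
  invisible(path)
}

#' Write alignment records as SAM text
#'
#' Emits a valid SAM file (with `@HD`/`@SQ` header) from a
#' `dm_alignments`-shaped data.frame. Used by the simulator; quality
#' strings are written as `*`.
#'
#' @param aln data.frame with the `dm_alignments` columns.
#' @param path output file.
#' @param ref_lengths named integer vector of reference sequence lengths.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, path, ref_lengths) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths),
                   as.integer(ref_lengths)))
  if (nrow(aln)) {
    rnext <- ifelse(is.na(aln$mate_chrom) | is.na(aln$mate_pos), "*",
                    ifelse(aln$mate_chrom == aln$chrom, "=", aln$mate_chrom))
    body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t*",
                    aln$qname, aln$flag, aln$chrom, aln$pos, aln$mapq,
                    aln$cigar, rnext,
                    ifelse(is.na(aln$mate_pos), 0L, aln$mate_pos),
                    ifelse(is.na(aln$isize), 0L, aln$isize), aln$seq)
    has_bc <- !is.na(aln$barcode)
    body[has_bc] <- paste0(body[has_bc], "\tBX:Z:", aln$barcode[has_bc])
  } else body <- character()
  writeLines(c(hdr, body), path)
  invisible(path)
}
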