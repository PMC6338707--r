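#' Read a copy-number segment table
#'
#' Reads a BED-like TSV of copy-number segments (columns `chrom`, `start`,
#' `end`, `log2r`, with or without a header line). Internally all
#' coordinates are 1-based inclusive (SAM convention); BED input, which is
#' 0-based half-open, must be declared with `dialect = "bed"` and is
#' shifted at the edge. Segments are sorted by (chrom, start) and assigned
#' ids `1..n` in that order.
#'
#' @param path path to the TSV file.
#' @param dialect `"onebased"` (default; coordinates used as given) or
#'   `"bed"` (0-based half-open start is shifted up by one).
#' @return A `dm_segments` data.frame with columns
#'   `id`, `chrom`, `start`, `end`, `log2r`.
#' @export
read_segment_table <- function(path, dialect = c("onebased", "bed")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (!length(lines)) stop("no segment rows in ", path)
  fields <- strsplit(lines, "\t|\\s+")
  # a header line (column names instead of coordinates) maps columns by
  # name; headerless input is positional chrom/start/end/log2r
  cols <- c(chrom = 1L, start = 2L, end = 3L, log2r = 4L)
  if (all(c("chrom", "start", "end") %in% fields[[1]])) {
    cols <- setNames(match(names(cols), fields[[1]]), names(cols))
    lines <- lines[-1]
    fields <- fields[-1]
    if (!length(lines)) stop("no segment rows in ", path)
  }
  bad <- which(vapply(fields, length, 1L) < max(cols, na.rm = TRUE))
  if (length(bad))
    stop("malformed segment row at line ", bad[[1]], " of ", path)
  getcol <- function(nm) {
    if (is.na(cols[[nm]])) return(rep(NA_character_, length(fields)))
    vapply(fields, `[[`, "", cols[[nm]])
  }
  df <- data.frame(
    chrom = getcol("chrom"),
    start = suppressWarnings(as.numeric(getcol("start"))),
    end   = suppressWarnings(as.numeric(getcol("end"))),
    log2r = suppressWarnings(as.numeric(getcol("log2r"))),
    stringsAsFactors = FALSE)
  if (anyNA(df$start) || anyNA(df$end))
    stop("non-numeric coordinate in segment table ", path, " (line ",
         which(is.na(df$start) | is.na(df$end))[[1]], ")")
  if (dialect == "bed") df$start <- df$start + 1
  as_dm_segments(df)
}

#' Construct a segment table from a data.frame
#'
#' Validates coordinates, sorts by (chrom, start) and assigns 1-based ids.
#'
#' @param df data.frame with columns `chrom`, `start`, `end`, `log2r`.
#' @return A `dm_segments` data.frame.
#' @export
as_dm_segments <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (is.null(df$log2r)) df$log2r <- NA_real_
  if (any(df$start > df$end))
    stop("segment with start > end: row ",
         which(df$start > df$end)[[1]])
  ord <- order(df$chrom, df$start, df$end)
  df <- df[ord, c("chrom", "start", "end", "log2r"), drop = FALSE]
  df <- data.frame(id = seq_len(nrow(df)), df, row.names = NULL,
                   stringsAsFactors = FALSE)
  class(df) <- c("dm_segments", "data.frame")
  df
}

#' Segment boundaries
#'
#' Expands a segment table into its two boundaries per segment: `L`
#' (5'/start) and `R` (3'/end). Boundaries are the nodes of the boundary
#' graph and the anchors of all SV evidence collection.
#'
#' @param segments a `dm_segments` data.frame.
#' @return data.frame with columns `segment_id`, `side`, `position`,
#'   `chrom`, and `key` (e.g. `"7R"`).
#' @export
dm_boundaries <- function(segments) {
  b <- rbind(
    data.frame(segment_id = segments$id, side = "L",
               position = segments$start, chrom = segments$chrom,
               stringsAsFactors = FALSE),
    data.frame(segment_id = segments$id, side = "R",
               position = segments$end, chrom = segments$chrom,
               stringsAsFactors = FALSE))
  b <- b[order(b$segment_id, b$side), , drop = FALSE]
  b$key <- paste0(b$segment_id, b$side)
  row.names(b) <- NULL
  b
}

#' Read an SNV table
#'
#' Accepts either a TSV with columns `chrom`, `pos`, `ref`, `alt`,
#' `ref_count`, `alt_count`, `origin` (header required; `origin` is
#' `germline` or `somatic`) or, when `format = "vcf"`, a minimal
#' uncompressed VCF whose records carry an `AD` (allelic depth) FORMAT
#' field for the first sample and an optional `ORIGIN` INFO key.
#'
#' @param path input file.
#' @param format `"tsv"` (default) or `"vcf"`.
#' @return A `dm_snvs` data.frame with columns `chrom`, `pos`, `ref`,
#'   `alt`, `ref_count`, `alt_count`, `vaf`, `origin`.
#' @export
read_snv_table <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("chrom", "pos", "ref_count", "alt_count")
    if (!all(need %in% names(df)))
      stop("SNV table must have columns: ", paste(need, collapse = ", "))
    if (is.null(df$ref)) df$ref <- "N"
    if (is.null(df$alt)) df$alt <- "N"
    if (is.null(df$origin)) df$origin <- "germline"
  } else {
    if (!requireNamespace("vcfR", quietly = TRUE))
      stop("VCF input requires the vcfR package")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    ad <- vcfR::extract.gt(v, element = "AD")[, 1]
    counts <- do.call(rbind, lapply(strsplit(ad, ","), as.numeric))
    fix <- vcfR::getFIX(v, getINFO = TRUE)
    info <- fix[, "INFO"]
    origin <- ifelse(grepl("ORIGIN=somatic", info), "somatic", "germline")
    df <- data.frame(chrom = fix[, "CHROM"], pos = as.numeric(fix[, "POS"]),
                     ref = fix[, "REF"], alt = fix[, "ALT"],
                     ref_count = counts[, 1], alt_count = counts[, 2],
                     origin = origin, stringsAsFactors = FALSE)
  }
  as_dm_snvs(df)
}

#' Construct an SNV table from a data.frame
#' @param df data.frame with at least `chrom`, `pos`, `ref_count`,
#'   `alt_count`; optional `ref`, `alt`, `origin`.
#' @return A `dm_snvs` data.frame with `vaf` filled in.
#' @export
as_dm_snvs <- function(df) {
  if (is.null(df$ref)) df$ref <- "N"
  if (is.null(df$alt)) df$alt <- "N"
  if (is.null(df$origin)) df$origin <- "germline"
  if (any(df$ref_count < 0 | df$alt_count < 0))
    stop("negative allele counts")
  if (!all(df$origin %in% c("germline", "somatic")))
    stop("origin must be 'germline' or 'somatic'")
  df$vaf <- compute_vaf(df$alt_count, df$ref_count)
  df <- df[order(df$chrom, df$pos), c("chrom", "pos", "ref", "alt",
                                      "ref_count", "alt_count",
                                      "vaf", "origin"), drop = FALSE]
  row.names(df) <- NULL
  class(df) <- c("dm_snvs", "data.frame")
  df
}

#' Write a deterministic report
#'
#' Serializes a data.frame to TSV or JSON with a fixed column order and
#' rows sorted by the given keys, so that repeated runs diff cleanly.
#' JSON reports round-trip losslessly through [read_report()].
#'
#' @param objects a data.frame (possibly zero rows).
#' @param path output file.
#' @param format `"tsv"` or `"json"`.
#' @param sort_by character vector of columns to sort rows by (default:
#'   all columns, left to right).
#' @return `path`, invisibly.
#' @export
write_report <- function(objects, path, format = c("tsv", "json"),
                         sort_by = NULL) {
  format <- match.arg(format)
  df <- as.data.frame(objects, stringsAsFactors = FALSE)
  if (is.null(sort_by)) sort_by <- names(df)
  if (nrow(df) && length(sort_by))
    df <- df[do.call(order, unname(as.list(df[sort_by]))), ,
             drop = FALSE]
  row.names(df) <- NULL
  ok <- tryCatch({
    if (format == "tsv") {
      write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
      jsonlite::write_json(df, path, dataframe = "rows", digits = NA,
                           na = "null", auto_unbox = FALSE)
    }
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write report to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Read a report written by [write_report()]
#' @param path input file.
#' @param format `"tsv"` or `"json"`.
#' @return data.frame.
#' @export
read_report <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    read.delim(path, stringsAsFactors = FALSE)
  } else {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE),
                  stringsAsFactors = FALSE)
  }
}
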