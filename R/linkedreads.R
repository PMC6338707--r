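#' Barcode-sharing matrix between two genomic windows
#'
#' Bins each window at `bin_size` bp and counts, for every bin pair, the
#' number of distinct barcodes with at least one read in bin i of window
#' a and at least one read in bin j of window b. A barcode is counted at
#' most once per bin pair. Barcodes act as proxies for long input
#' molecules, so off-diagonal enrichment between two loci indicates they
#' co-occur on the same molecules.
#'
#' @param aln barcode-tagged alignments (`dm_alignments`; rows without a
#'   barcode are ignored).
#' @param window_a,window_b lists `(chrom, start, end)`.
#' @param bin_size bp per bin (default 1000).
#' @return A `barcode_matrix`: list with `counts` (bins of a in rows,
#'   bins of b in columns), `window_a`, `window_b`, `bin_size`.
#' @export
barcode_sharing_matrix <- function(aln, window_a, window_b,
                                   bin_size = 1000) {
  bc_bins <- function(w) {
    nb <- ceiling((w$end - w$start + 1) / bin_size)
    keep <- !is.na(aln$barcode) & !is.na(aln$pos) &
      !aln_is_unmapped(aln$flag) & aln$chrom == w$chrom &
      aln$pos >= w$start & aln$pos <= w$end
    bin <- ((aln$pos[keep] - w$start) %/% bin_size) + 1L
    list(nb = nb, df = unique(data.frame(barcode = aln$barcode[keep],
                                         bin = bin,
                                         stringsAsFactors = FALSE)))
  }
  a <- bc_bins(window_a)
  b <- bc_bins(window_b)
  counts <- matrix(0L, nrow = a$nb, ncol = b$nb)
  if (!nrow(a$df) || !nrow(b$df)) {
    warning("no barcoded reads in one of the windows; empty matrix")
  } else {
    m <- merge(a$df, b$df, by = "barcode",
               suffixes = c("_a", "_b"))
    if (nrow(m)) {
      tab <- table(factor(m$bin_a, levels = seq_len(a$nb)),
                   factor(m$bin_b, levels = seq_len(b$nb)))
      counts <- matrix(as.integer(tab), nrow = a$nb)
    }
  }
  structure(list(counts = counts, window_a = window_a,
                 window_b = window_b, bin_size = bin_size),
            class = "barcode_matrix")
}

#' @export
print.barcode_matrix <- function(x, ...) {
  cat(sprintf("barcode-sharing matrix %dx%d (bin %d bp): %s:%d-%d vs %s:%d-%d, %d shared-barcode counts\n",
              nrow(x$counts), ncol(x$counts), x$bin_size,
              x$window_a$chrom, x$window_a$start, x$window_a$end,
              x$window_b$chrom, x$window_b$start, x$window_b$end,
              sum(x$counts)))
  invisible(x)
}

# quadrant means of a matrix: list lowlow, lowhigh, highlow, highhigh
# ("low"/"high" = first/second half of the axis)
matrix_quadrants <- function(counts) {
  hx <- nrow(counts) %/% 2
  hy <- ncol(counts) %/% 2
  if (hx < 1 || hy < 1) return(NULL)
  xlow <- seq_len(hx); xhigh <- seq(nrow(counts) - hx + 1, nrow(counts))
  ylow <- seq_len(hy); yhigh <- seq(ncol(counts) - hy + 1, ncol(counts))
  list(low_low = counts[xlow, ylow, drop = FALSE],
       low_high = counts[xlow, yhigh, drop = FALSE],
       high_low = counts[xhigh, ylow, drop = FALSE],
       high_high = counts[xhigh, yhigh, drop = FALSE])
}

#' Classify the enriched corner of a barcode matrix against a claimed
#' junction orientation
#'
#' With window a on the x axis and window b on the y axis (both in
#' reference orientation), molecules crossing a junction that uses a's R
#' boundary occupy the high half of x (and the low half for side L), and
#' likewise for b on y. A head-to-tail junction (R with L) therefore
#' lights the lower-right or upper-left corner, tail-to-tail (L with L)
#' the lower-left, head-to-head (R with R) the upper-right. The claim is
#' supported when the expected corner quadrant's mean count is at least
#' `corner_fold_min` times the mean of the other three quadrants and the
#' quadrant holds at least `corner_min_barcodes` shared-barcode counts.
#'
#' @param matrix a `barcode_matrix` whose windows are the two segments
#'   (or boundary regions), a on x, b on y.
#' @param side_a,side_b the boundary sides the claimed junction uses.
#' @param params a [dm_params()] object.
#' @param collapse_a,collapse_b when a window is shorter than the typical
#'   molecule, crossing molecules blanket its whole axis and the corner
#'   degenerates to a half-plane along the other axis; set the flag for
#'   that axis. With both flags set the test is `"untestable"`.
#' @return list `verdict` (`"supported"`/`"unsupported"`/`"untestable"`),
#'   `corner`, `fold`, `corner_total`.
#' @export
classify_junction_corner <- function(matrix, side_a, side_b,
                                     params = dm_params(),
                                     collapse_a = FALSE,
                                     collapse_b = FALSE) {
  co <- matrix$counts
  if (collapse_a && collapse_b)
    return(list(verdict = "untestable", corner = NA, fold = NA,
                corner_total = NA))
  hx <- nrow(co) %/% 2
  hy <- ncol(co) %/% 2
  if (hx < 1 || hy < 1)
    return(list(verdict = "unsupported", corner = NA, fold = NA,
                corner_total = 0))
  half <- function(n, h, which)
    if (which == "low") seq_len(h) else seq(n - h + 1, n)
  half_a <- if (side_a == "R") "high" else "low"
  half_b <- if (side_b == "R") "high" else "low"
  rows_e <- if (collapse_a) seq_len(nrow(co)) else
    half(nrow(co), hx, half_a)
  cols_e <- if (collapse_b) seq_len(ncol(co)) else
    half(ncol(co), hy, half_b)
  expected <- co[rows_e, cols_e, drop = FALSE]
  if (collapse_a || collapse_b) {
    # background: the complementary half-plane along the informative axis
    if (collapse_a) {
      other <- half(ncol(co), hy, setdiff(c("high", "low"), half_b))
      bgm <- co[, other, drop = FALSE]
    } else {
      other <- half(nrow(co), hx, setdiff(c("high", "low"), half_a))
      bgm <- co[other, , drop = FALSE]
    }
    bg <- mean(bgm)
    corner <- paste(if (collapse_a) "any" else half_a,
                    if (collapse_b) "any" else half_b, sep = "_")
  } else {
    # background: the two quadrants adjacent to the expected corner; the
    # diagonally opposite corner is excluded because on a circular
    # structure it hosts the complementary junction between the same
    # two segments
    corner <- paste(half_a, half_b, sep = "_")
    adj1 <- co[rows_e, half(ncol(co), hy,
                            setdiff(c("high", "low"), half_b)),
               drop = FALSE]
    adj2 <- co[half(nrow(co), hx, setdiff(c("high", "low"), half_a)),
               cols_e, drop = FALSE]
    bg <- mean(c(mean(adj1), mean(adj2)))
  }
  fg <- mean(expected)
  fold <- if (bg == 0) ifelse(fg > 0, Inf, 0) else fg / bg
  total <- sum(expected)
  supported <- is.finite(total) && total >= params$corner_min_barcodes &&
    fold >= params$corner_fold_min
  list(verdict = if (supported) "supported" else "unsupported",
       corner = corner, fold = fold, corner_total = total)
}

# window over a segment (reference orientation), padded
segment_window <- function(segments, seg_id, pad = 0) {
  s <- segments[segments$id == seg_id, ]
  list(chrom = s$chrom, start = max(1, s$start - pad), end = s$end + pad)
}

#' Validate a candidate cycle with linked-read barcode sharing
#'
#' Every consecutive junction of the cycle is tested with
#' [classify_junction_corner()] on the two segments' barcode matrix.
#' Additionally, every segment skip (A, skip B, C) whose middle segment
#' is shorter than the average molecule length is tested for A-C barcode
#' sharing -- molecules long enough to span B must link A and C if the
#' three segments are truly contiguous on the amplicon. The cycle is
#' `invalidated` if any junction is unsupported, `validated` if all
#' junctions and all testable skips are supported, otherwise
#' `inconclusive`.
#'
#' @param cycle a `dm_cycle`.
#' @param graph the `dm_boundary_graph` it came from.
#' @param aln barcode-tagged linked-read alignments.
#' @param avg_molecule_length bp; mean length of the input molecules.
#' @param params a [dm_params()] object.
#' @return A `dm_validation` list: `junctions` and `skips` data.frames
#'   plus overall `verdict`.
#' @export
validate_cycle_paths <- function(cycle, graph, aln, avg_molecule_length,
                                 params = dm_params()) {
  segments <- graph$segments
  seglen <- setNames(segments$end - segments$start + 1, segments$id)
  short <- function(id) seglen[as.character(id)] < avg_molecule_length
  jx <- cycle_junctions(cycle, graph)
  jx$verdict <- NA_character_
  jx$fold <- NA_real_
  for (i in seq_len(nrow(jx))) {
    m <- barcode_sharing_matrix(aln,
                                segment_window(segments, jx$seg_a[i]),
                                segment_window(segments, jx$seg_b[i]),
                                params$bin_size)
    cl <- classify_junction_corner(m, jx$side_a[i], jx$side_b[i], params,
                                   collapse_a = short(jx$seg_a[i]),
                                   collapse_b = short(jx$seg_b[i]))
    jx$verdict[i] <- cl$verdict
    jx$fold[i] <- cl$fold
  }
  # segment skips
  k <- length(cycle$segment_ids)
  skips <- NULL
  if (k >= 3) {
    seglen <- setNames(segments$end - segments$start + 1, segments$id)
    rows <- lapply(seq_len(k), function(i) {
      jmid <- (i %% k) + 1L
      jnext <- (jmid %% k) + 1L
      mid <- cycle$segment_ids[jmid]
      testable <- seglen[as.character(mid)] < avg_molecule_length
      data.frame(seg_a = cycle$segment_ids[i], seg_skip = mid,
                 seg_c = cycle$segment_ids[jnext],
                 side_a = if (cycle$orients[i] == "+") "R" else "L",
                 side_c = if (cycle$orients[jnext] == "+") "L" else "R",
                 testable = testable, stringsAsFactors = FALSE)
    })
    skips <- do.call(rbind, rows)
    skips$verdict <- NA_character_
    skips$fold <- NA_real_
    for (i in which(skips$testable)) {
      m <- barcode_sharing_matrix(aln,
                                  segment_window(segments, skips$seg_a[i]),
                                  segment_window(segments, skips$seg_c[i]),
                                  params$bin_size)
      cl <- classify_junction_corner(m, skips$side_a[i],
                                     skips$side_c[i], params,
                                     collapse_a = short(skips$seg_a[i]),
                                     collapse_b = short(skips$seg_c[i]))
      skips$verdict[i] <- cl$verdict
      skips$fold[i] <- cl$fold
    }
  }
  testable_j <- jx$verdict != "untestable"
  verdict <- if (any(jx$verdict == "unsupported")) {
    "invalidated"
  } else if (any(testable_j) &&
             all(jx$verdict[testable_j] == "supported") &&
             (is.null(skips) ||
                all(skips$verdict[skips$testable] %in%
                      c("supported", "untestable")))) {
    "validated"
  } else "inconclusive"
  structure(list(junctions = jx, skips = skips, verdict = verdict,
                 structure = cycle_structure_string(cycle)),
            class = "dm_validation")
}

#' @export
print.dm_validation <- function(x, ...) {
  cat(sprintf("%s: %s (%d/%d junctions supported)\n", x$structure,
              x$verdict, sum(x$junctions$verdict == "supported"),
              nrow(x$junctions)))
  invisible(x)
}
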