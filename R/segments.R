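#' Select highly amplified segments
#'
#' Retains segments whose log2 tumor/normal coverage ratio falls in the
#' right tail of the empirical log2R distribution: strictly greater than
#' an explicit numeric cutoff, or, with `"auto"`, greater than
#' mean + 2 sd computed over all input segments. The cutoff actually used
#' is attached as attribute `cutoff`.
#'
#' @param segments a `dm_segments` data.frame.
#' @param params a [dm_params()] object (field `amplified_log2r_cutoff`).
#' @return the amplified subset, with attribute `cutoff`.
#' @export
select_amplified_segments <- function(segments, params = dm_params()) {
  if (!nrow(segments)) stop("no segments supplied")
  l2r <- segments$log2r
  if (any(!is.finite(l2r))) stop("non-finite log2r values")
  cutoff <- params$amplified_log2r_cutoff
  if (identical(cutoff, "auto")) {
    s <- sd(l2r)
    if (!is.finite(s) || s == 0)
      stop("log2r has zero spread; supply an explicit cutoff")
    cutoff <- mean(l2r) + 2 * s
  }
  out <- segments[l2r > cutoff, , drop = FALSE]
  row.names(out) <- NULL
  attr(out, "cutoff") <- cutoff
  out
}

#' Find adjacent amplified segment pairs
#'
#' Two amplified segments are adjacent when they are consecutive on the
#' same chromosome with a reference gap of at most
#' `params$adjacency_max_gap` bp. Each pair contributes one adjacent edge
#' to the boundary graph, joining the left segment's R boundary to the
#' right segment's L boundary.
#'
#' @param amplified a `dm_segments` data.frame (sorted, as returned by
#'   the readers).
#' @param params a [dm_params()] object.
#' @return data.frame with columns `seg_a`, `seg_b`, `gap`.
#' @export
find_adjacent_pairs <- function(amplified, params = dm_params()) {
  empty <- data.frame(seg_a = integer(), seg_b = integer(), gap = integer())
  if (nrow(amplified) < 2) return(empty)
  s <- amplified[order(amplified$chrom, amplified$start), , drop = FALSE]
  i <- seq_len(nrow(s) - 1)
  same <- s$chrom[i] == s$chrom[i + 1]
  gap <- s$start[i + 1] - s$end[i] - 1
  keep <- same & gap <= params$adjacency_max_gap
  out <- data.frame(seg_a = s$id[i][keep], seg_b = s$id[i + 1][keep],
                    gap = as.integer(gap[keep]))
  row.names(out) <- NULL
  out
}

#' Compute per-segment log2 tumor/normal coverage ratio
#'
#' Mean read depth over each segment is computed from the
#' reference-consuming CIGAR bases (M/=/X/D) of the tumor and normal
#' alignments; log2R = log2((tumor + eps) / (normal + eps)) with
#' eps = 0.5 guarding against empty segments. This gives the simulator
#' round trip a self-contained coverage-ratio signal; it is not a
#' change-point segmenter, which must be run upstream on real data.
#'
#' @param tumor_aln,normal_aln `dm_alignments` data.frames.
#' @param segments a `dm_segments` data.frame (log2r may be `NA`).
#' @param normal_scale optional multiplier applied to normal depth to
#'   equalize sequencing yield between samples (default 1).
#' @return `segments` with `log2r` filled in.
#' @export
compute_segment_log2r <- function(tumor_aln, normal_aln, segments,
                                  normal_scale = 1) {
  eps <- 0.5
  seg_depth <- function(aln) {
    depth <- numeric(nrow(segments))
    ok <- !is.na(aln$pos) & !aln_is_unmapped(aln$flag)
    a <- aln[ok, , drop = FALSE]
    ends <- aln_end(a)
    for (k in seq_len(nrow(segments))) {
      on <- a$chrom == segments$chrom[k]
      ov <- pmin(ends[on], segments$end[k]) -
        pmax(a$pos[on], segments$start[k]) + 1
      depth[k] <- sum(pmax(ov, 0)) /
        (segments$end[k] - segments$start[k] + 1)
    }
    depth
  }
  td <- seg_depth(tumor_aln)
  nd <- seg_depth(normal_aln) * normal_scale
  segments$log2r <- log2((td + eps) / (nd + eps))
  segments
}
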