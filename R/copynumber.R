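#' Variant allele frequency
#'
#' VAF = alternative allele read count / (reference + alternative read
#' count). Errors on zero total depth, where the quantity is undefined.
#'
#' @param alt_count,ref_count non-negative read counts (vectorized).
#' @return numeric vector in \[0, 1\].
#' @export
#' @examples
#' compute_vaf(3, 1) # 0.75
compute_vaf <- function(alt_count, ref_count) {
  depth <- alt_count + ref_count
  if (any(depth == 0)) stop("VAF undefined at zero coverage depth")
  if (any(alt_count < 0 | ref_count < 0)) stop("negative allele count")
  alt_count / depth
}

#' Assign SNVs to the amplified segments containing them
#'
#' Each SNV is assigned to the unique segment whose 1-based inclusive
#' interval contains its position; SNVs falling outside every segment are
#' dropped (their number is reported via a message). Overlapping segments
#' are an input error.
#'
#' @param snvs a `dm_snvs` data.frame.
#' @param segments a `dm_segments` data.frame.
#' @return the SNV table with an added `segment_id` column, containing
#'   only the assigned SNVs.
#' @export
assign_snvs_to_segments <- function(snvs, segments) {
  if (nrow(segments) > 1) {
    for (ch in unique(segments$chrom)) {
      s <- segments[segments$chrom == ch, , drop = FALSE]
      s <- s[order(s$start), , drop = FALSE]
      if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)]))
        stop("overlapping segments on ", ch)
    }
  }
  sq <- IRanges::IRanges(start = segments$start, end = segments$end)
  qq <- IRanges::IRanges(start = snvs$pos, width = 1L)
  hit <- rep(NA_integer_, nrow(snvs))
  for (ch in unique(segments$chrom)) {
    si <- which(segments$chrom == ch)
    qi <- which(snvs$chrom == ch)
    if (!length(si) || !length(qi)) next
    ov <- IRanges::findOverlaps(qq[qi], sq[si], select = "first")
    hit[qi] <- segments$id[si][ov]
  }
  dropped <- sum(is.na(hit))
  if (dropped) message(dropped, " SNVs outside all segments dropped")
  out <- snvs[!is.na(hit), , drop = FALSE]
  out$segment_id <- hit[!is.na(hit)]
  row.names(out) <- NULL
  out
}

#' Select germline SNVs whose alternative allele is amplified
#'
#' On a highly amplified segment a pre-existing heterozygous SNV drifts
#' from VAF 0.5 toward 1 when its alternative allele sits on the amplified
#' haplotype (the "upper branch"), or toward 0 when the reference allele
#' does. The copy-number estimator uses the upper branch (`vaf > 0.5`);
#' the lower branch is returned as well for symmetry checks. Ties at
#' exactly 0.5 are excluded from both.
#'
#' @param snvs SNV table (germline rows are used; others ignored).
#' @return list with elements `upper`, `lower` (both `dm_snvs`-shaped) and
#'   `n_ties`.
#' @export
select_amplified_alt_branch <- function(snvs) {
  g <- snvs[snvs$origin == "germline", , drop = FALSE]
  list(upper = g[g$vaf > 0.5, , drop = FALSE],
       lower = g[g$vaf < 0.5, , drop = FALSE],
       n_ties = sum(g$vaf == 0.5))
}

#' Estimate amplicon copies per cell from allele ratios
#'
#' The copy number of an amplicon relative to one set of chromosomes is
#' estimated as the median, over upper-branch germline SNVs, of the ratio
#' of alternative to reference allele read counts. SNVs with zero
#' reference reads (infinite ratio) or depth below `min_depth` are
#' excluded.
#'
#' @param snvs upper-branch SNV table (see
#'   [select_amplified_alt_branch()]).
#' @param target label for the structure being estimated.
#' @param min_depth minimum total read depth per SNV (default 10).
#' @return A `dm_cn_estimate` list: `target`, `copies_per_cell`, `n_snvs`,
#'   `method`.
#' @export
estimate_copies_from_ratios <- function(snvs, target = "dm",
                                        min_depth = 10) {
  keep <- snvs$ref_count > 0 &
    (snvs$ref_count + snvs$alt_count) >= min_depth
  n_excl <- sum(!keep)
  if (n_excl) message(n_excl, " SNVs excluded (zero ref reads or low depth)")
  s <- snvs[keep, , drop = FALSE]
  if (!nrow(s))
    stop("no informative SNVs: cannot estimate copy number for ", target)
  est <- list(target = target,
              copies_per_cell = median(s$alt_count / s$ref_count),
              n_snvs = nrow(s),
              method = "unique_segments")
  class(est) <- "dm_cn_estimate"
  est
}

#' @export
as.data.frame.dm_cn_estimate <- function(x, ...) {
  data.frame(target = x$target, copies_per_cell = x$copies_per_cell,
             n_snvs = x$n_snvs, method = x$method,
             stringsAsFactors = FALSE)
}

#' @export
print.dm_cn_estimate <- function(x, ...) {
  cat(sprintf("%s: %.1f copies per cell (%s, %d SNVs)\n",
              x$target, x$copies_per_cell, x$method, x$n_snvs))
  invisible(x)
}

#' Copy number of a structure without unique segments
#'
#' When a structure has no private segment, its copy number is obtained
#' from segments it shares with otherwise-quantified structures: the
#' shared-segment estimate minus the sum of the co-occupants' estimates.
#' Negative results are clamped to zero with a warning.
#'
#' @param shared_estimate copies-per-cell estimate over the shared
#'   segments.
#' @param known_estimates numeric vector of the co-occupant structures'
#'   estimates.
#' @return numeric copy number.
#' @export
#' @examples
#' shared_segment_subtraction(33, 20) # 13
#' shared_segment_subtraction(57, c(23, 20)) # 14
shared_segment_subtraction <- function(shared_estimate, known_estimates) {
  out <- shared_estimate - sum(known_estimates)
  if (out < 0) {
    warning("negative copy number after subtraction; clamped to 0")
    out <- 0
  }
  out
}

#' Fraction of a structure carrying a sub-segment
#'
#' Given the copy number of a segment present on a fraction of one
#' structure plus all of another, the fraction of the first structure
#' carrying it is (cn_with_feature - cn_other_structure) / cn_total.
#'
#' @param cn_with_feature copy number of the feature segment.
#' @param cn_other_structure copy number of the other structure carrying
#'   it constitutively.
#' @param cn_total total copy number of the structure of interest.
#' @return percentage (0-100), rounded to one decimal.
#' @export
#' @examples
#' fraction_by_subsegment_presence(19, 15, 24) # 16.7
fraction_by_subsegment_presence <- function(cn_with_feature,
                                            cn_other_structure,
                                            cn_total) {
  if (cn_total <= 0) stop("cn_total must be positive")
  if (cn_with_feature < cn_other_structure)
    stop("cn_with_feature must be >= cn_other_structure")
  round(100 * (cn_with_feature - cn_other_structure) / cn_total, 1)
}

#' Intersect two SNV tables by genomic location
#'
#' Pairs SNVs matched on (chrom, pos, ref, alt); unmatched rows are
#' dropped and their counts reported in attributes `n_only_a` /
#' `n_only_b`.
#'
#' @param snvs_a,snvs_b SNV tables.
#' @return data.frame with the matched keys plus `_a` / `_b` suffixed
#'   count and VAF columns.
#' @export
intersect_snvs_by_location <- function(snvs_a, snvs_b) {
  key <- function(x) paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
  ka <- key(snvs_a); kb <- key(snvs_b)
  m <- match(ka, kb)
  paired <- which(!is.na(m))
  a <- snvs_a[paired, , drop = FALSE]
  b <- snvs_b[m[paired], , drop = FALSE]
  out <- data.frame(chrom = a$chrom, pos = a$pos, ref = a$ref, alt = a$alt,
                    origin = a$origin,
                    ref_count_a = a$ref_count, alt_count_a = a$alt_count,
                    vaf_a = a$vaf,
                    ref_count_b = b$ref_count, alt_count_b = b$alt_count,
                    vaf_b = b$vaf, stringsAsFactors = FALSE)
  row.names(out) <- NULL
  attr(out, "n_only_a") <- nrow(snvs_a) - nrow(out)
  attr(out, "n_only_b") <- nrow(snvs_b) - nrow(out)
  out
}

#' Flag cross-sample VAF shifts
#'
#' Flags paired SNVs whose VAF is at most `low_max` in one sample and at
#' least `high_min` in the other, in either direction; the direction is
#' labelled `"gain_in_b"` (low in a, high in b) or `"gain_in_a"`.
#'
#' @param paired output of [intersect_snvs_by_location()].
#' @param low_max,high_min thresholds (defaults 0.10 and 0.90).
#' @return the flagged subset with an added `direction` column.
#' @export
detect_vaf_shift <- function(paired, low_max = 0.10, high_min = 0.90) {
  up <- paired$vaf_a <= low_max & paired$vaf_b >= high_min
  dn <- paired$vaf_b <= low_max & paired$vaf_a >= high_min
  out <- paired[up | dn, , drop = FALSE]
  out$direction <- ifelse(up[up | dn], "gain_in_b", "gain_in_a")
  row.names(out) <- NULL
  out
}
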