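#' Analysis parameters
#'
#' Bundles every tunable distance, threshold and seed used across the
#' pipeline stages. Defaults follow the windows commonly used for
#' boundary-focused SV evidence collection on ~100 bp paired-end data:
#' reads are pulled from a +/- 50 bp window around each amplified-segment
#' boundary, clipped bases and discordant mates are matched against
#' +/- 1 kb boundary flanks, a pair is called discordant at >= 800 bp
#' separation (or on another chromosome), and bridging mate clusters may
#' be up to 10 kb apart. All of them are adjustable per sample.
#'
#' @param boundary_flank bp; half-width of the window around a segment
#'   boundary from which reads are pulled (default 50).
#' @param search_flank bp; half-width of the boundary flank against which
#'   clipped bases and discordant mates are matched (default 1000).
#' @param discordant_min_distance bp; minimum same-chromosome mate
#'   separation for a pair to count as discordant (default 800).
#' @param bridge_max_distance bp; maximum distance between the mate
#'   clusters of two boundaries for bridging evidence (default 10000).
#' @param amplified_log2r_cutoff numeric cutoff on log2R for calling a
#'   segment highly amplified, or `"auto"` for mean + 2 sd of the
#'   empirical log2R distribution.
#' @param adjacency_max_gap bp; maximum reference gap between two
#'   consecutive segments still called adjacent (default 10).
#' @param min_clip_match bp; minimum clipped-segment length considered
#'   for local realignment (default 20).
#' @param min_clip_identity minimum percent identity (0-1) of a clipped-base
#'   local alignment hit (default 0.95).
#' @param uniqueness_ratio a clip placement is unique when the best hit
#'   scores at least this multiple of the second best (default 1.2).
#' @param min_snv_depth minimum SNV read depth used by the copy-number
#'   estimator (default 10).
#' @param vaf_low_max,vaf_high_min VAF thresholds flagging a cross-sample
#'   allele-frequency shift (defaults 0.10 and 0.90).
#' @param corner_fold_min minimum fold enrichment of the orientation-expected
#'   barcode-matrix corner over background (default 5).
#' @param corner_min_barcodes minimum shared barcodes in the expected corner
#'   (default 10).
#' @param bin_size bp; barcode-sharing matrix bin width (default 1000).
#' @param max_cycle_segments guard on candidate cycle length in segments
#'   (default 12).
#' @param max_candidates guard on the number of enumerated raw cycles
#'   (default 100000).
#' @param barcode_tag SAM tag carrying the linked-read barcode
#'   (default "BX").
#' @param seed integer seed for stochastic components.
#'
#' @return An object of class `dm_params` (a named list).
#' @export
#' @examples
#' p <- dm_params(amplified_log2r_cutoff = 4)
#' p$boundary_flank
dm_params <- function(boundary_flank = 50,
                      search_flank = 1000,
                      discordant_min_distance = 800,
                      bridge_max_distance = 10000,
                      amplified_log2r_cutoff = "auto",
                      adjacency_max_gap = 10,
                      min_clip_match = 20,
                      min_clip_identity = 0.95,
                      uniqueness_ratio = 1.2,
                      min_snv_depth = 10,
                      vaf_low_max = 0.10,
                      vaf_high_min = 0.90,
                      corner_fold_min = 5,
                      corner_min_barcodes = 10,
                      bin_size = 1000,
                      max_cycle_segments = 12,
                      max_candidates = 100000,
                      barcode_tag = "BX",
                      seed = 1L) {
  dists <- c(boundary_flank = boundary_flank, search_flank = search_flank,
             discordant_min_distance = discordant_min_distance,
             bridge_max_distance = bridge_max_distance,
             adjacency_max_gap = adjacency_max_gap,
             min_clip_match = min_clip_match, bin_size = bin_size)
  if (any(!is.finite(dists)) || any(dists <= 0))
    stop("all distance parameters must be positive")
  if (boundary_flank > search_flank)
    stop("boundary_flank must not exceed search_flank")
  if (!identical(amplified_log2r_cutoff, "auto") &&
      !is.numeric(amplified_log2r_cutoff))
    stop("amplified_log2r_cutoff must be numeric or \"auto\"")
  p <- list(boundary_flank = as.integer(boundary_flank),
            search_flank = as.integer(search_flank),
            discordant_min_distance = as.integer(discordant_min_distance),
            bridge_max_distance = as.integer(bridge_max_distance),
            amplified_log2r_cutoff = amplified_log2r_cutoff,
            adjacency_max_gap = as.integer(adjacency_max_gap),
            min_clip_match = as.integer(min_clip_match),
            min_clip_identity = min_clip_identity,
            uniqueness_ratio = uniqueness_ratio,
            min_snv_depth = as.integer(min_snv_depth),
            vaf_low_max = vaf_low_max,
            vaf_high_min = vaf_high_min,
            corner_fold_min = corner_fold_min,
            corner_min_barcodes = corner_min_barcodes,
            bin_size = as.integer(bin_size),
            max_cycle_segments = as.integer(max_cycle_segments),
            max_candidates = as.integer(max_candidates),
            barcode_tag = barcode_tag,
            seed = as.integer(seed))
  class(p) <- "dm_params"
  p
}

#' @export
print.dm_params <- function(x, ...) {
  cat("double-minute reconstruction parameters:\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
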