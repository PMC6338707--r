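#' Apply manual boundary overrides to a segment table
#'
#' Segment boundaries from coverage segmentation occasionally disagree
#' with the coverage signal seen in a browser; this applies a reviewed
#' override table in place of automating that judgement. Ids are kept
#' stable; coordinates are validated after adjustment.
#'
#' @param segments a `dm_segments` data.frame.
#' @param overrides data.frame with columns `id` and one or both of
#'   `new_start`, `new_end` (NA leaves a side untouched).
#' @return the adjusted `dm_segments`.
#' @export
apply_boundary_overrides <- function(segments, overrides) {
  if (is.null(overrides) || !nrow(overrides)) return(segments)
  bad <- setdiff(overrides$id, segments$id)
  if (length(bad)) stop("override for unknown segment id: ",
                        paste(bad, collapse = ", "))
  for (k in seq_len(nrow(overrides))) {
    i <- match(overrides$id[k], segments$id)
    if (!is.null(overrides$new_start) && !is.na(overrides$new_start[k]))
      segments$start[i] <- overrides$new_start[k]
    if (!is.null(overrides$new_end) && !is.na(overrides$new_end[k]))
      segments$end[i] <- overrides$new_end[k]
  }
  if (any(segments$start > segments$end))
    stop("override produced start > end")
  segments
}

sv_pair_key <- function(sv) {
  paste0(pmin(paste0(sv$seg_a, sv$side_a), paste0(sv$seg_b, sv$side_b)),
         "-",
         pmax(paste0(sv$seg_a, sv$side_a), paste0(sv$seg_b, sv$side_b)))
}

#' Apply a reviewed whitelist/blacklist to an SV table
#'
#' The machine-readable counterpart of manual curation: SVs named in the
#' blacklist are dropped; when a whitelist is given, only listed SVs are
#' kept. SVs are named by their unordered boundary pair, e.g. `"2R-4L"`.
#'
#' @param sv a `dm_sv` data.frame.
#' @param whitelist,blacklist character vectors of pair keys.
#' @return the filtered `dm_sv`.
#' @export
apply_sv_curation <- function(sv, whitelist = NULL, blacklist = NULL) {
  key <- sv_pair_key(sv)
  keep <- rep(TRUE, nrow(sv))
  if (!is.null(whitelist)) keep <- key %in% whitelist
  if (!is.null(blacklist)) keep <- keep & !(key %in% blacklist)
  out <- sv[keep, , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Per-SV supporting-read review report
#'
#' Writes the read names behind every evidence count, one row per
#' (SV, class, read), so each call can be reviewed against the
#' alignments without re-running the scan.
#'
#' @param sv a `dm_sv` from [collect_sv_evidence()] (which attaches the
#'   supporting reads as an attribute).
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
sv_review_report <- function(sv, path) {
  sup <- attr(sv, "supporting_reads")
  if (is.null(sup))
    sup <- data.frame(pair = character(), class = character(),
                      qname = character())
  write_report(sup, path, "tsv", sort_by = c("pair", "class", "qname"))
}

#' Rank candidate structures by evidence-weighted coverage
#'
#' An optional, explicitly heuristic aid for choosing a parsimonious set
#' among many surviving cycles: greedy set cover over segments and SV
#' edges, ties broken by total supporting-read count. It makes no claim
#' of recovering the biologically true set and is off by default in the
#' pipeline.
#'
#' @param cycles a `dm_cycles` list.
#' @param graph the `dm_boundary_graph`.
#' @return data.frame with `cycle` (index into `cycles`), `new_segments`,
#'   `new_svs`, `evidence`, in greedy selection order; cycles adding no
#'   new coverage are omitted.
#' @export
rank_structures <- function(cycles, graph) {
  if (!length(cycles))
    return(data.frame(cycle = integer(), new_segments = integer(),
                      new_svs = integer(), evidence = numeric()))
  ed <- graph$edges
  sv <- graph$sv
  ev_weight <- function(cyc) {
    rows <- ed$sv_row[cyc$junction_edges]
    rows <- rows[!is.na(rows)]
    if (!length(rows) || is.null(sv)) return(0)
    sum(sv$softclip_count[rows] + sv$discordant_count[rows] +
          sv$bridging_count[rows])
  }
  covered_seg <- integer()
  covered_sv <- integer()
  left <- seq_along(cycles)
  picks <- list()
  while (length(left)) {
    gain <- vapply(left, function(i) {
      cyc <- cycles[[i]]
      svs <- ed$sv_row[cyc$junction_edges]
      length(setdiff(cyc$segment_ids, covered_seg)) +
        length(setdiff(svs[!is.na(svs)], covered_sv))
    }, 1)
    if (max(gain) == 0) break
    w <- vapply(left, function(i) ev_weight(cycles[[i]]), 1)
    best <- left[order(-gain, -w)][1]
    cyc <- cycles[[best]]
    svs <- ed$sv_row[cyc$junction_edges]
    picks[[length(picks) + 1L]] <- data.frame(
      cycle = best,
      new_segments = length(setdiff(cyc$segment_ids, covered_seg)),
      new_svs = length(setdiff(svs[!is.na(svs)], covered_sv)),
      evidence = ev_weight(cyc))
    covered_seg <- union(covered_seg, cyc$segment_ids)
    covered_sv <- union(covered_sv, svs[!is.na(svs)])
    left <- setdiff(left, best)
  }
  do.call(rbind, picks)
}

#' Non-negative least-squares copy numbers over shared segments
#'
#' When more than two structures overlap, sequential subtraction becomes
#' order-dependent; this solves all structure copy numbers jointly as
#' `min || M x - b ||` with `x >= 0`, where `b` holds per-segment
#' copy-number estimates and `M[s, k] = 1` when structure `k` carries
#' segment `s`.
#'
#' @param segment_estimates named numeric vector of per-segment
#'   copy-number estimates (names = segment ids).
#' @param membership logical/0-1 matrix, segments (rows, matching the
#'   names of `segment_estimates`) by structures (columns).
#' @return named numeric vector of structure copy numbers.
#' @export
estimate_copies_nnls <- function(segment_estimates, membership) {
  if (!requireNamespace("pracma", quietly = TRUE))
    stop("the NNLS mode requires the pracma package")
  M <- as.matrix(membership) * 1
  stopifnot(nrow(M) == length(segment_estimates))
  fit <- pracma::lsqnonneg(M, as.numeric(segment_estimates))
  setNames(fit$x, colnames(membership))
}

#' Export CIRCOS-ready segment and link files
#'
#' Writes plain-text data files for external circular plotters: one
#' segment track (chrom, start, end, log2R) and one link file per
#' reconstructed SV junction (both breakend coordinates, orientation,
#' counts).
#'
#' @param result a `dm_reconstruction`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
export_circos <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  segs <- as.data.frame(result$amplified)
  write_report(segs[c("chrom", "start", "end", "log2r")],
               file.path(dir, "circos_segments.txt"), "tsv",
               sort_by = c("chrom", "start"))
  sv <- result$sv
  amp <- result$amplified
  bpos <- function(seg, side, bp) {
    ifelse(!is.na(bp), bp,
           ifelse(side == "L", amp$start[match(seg, amp$id)],
                  amp$end[match(seg, amp$id)]))
  }
  links <- data.frame(
    chrom_a = amp$chrom[match(sv$seg_a, amp$id)],
    pos_a = bpos(sv$seg_a, sv$side_a, sv$breakpoint_a),
    chrom_b = amp$chrom[match(sv$seg_b, amp$id)],
    pos_b = bpos(sv$seg_b, sv$side_b, sv$breakpoint_b),
    orientation = sv$orientation,
    support = sv$softclip_count + sv$discordant_count +
      sv$bridging_count)
  write_report(links, file.path(dir, "circos_links.txt"), "tsv",
               sort_by = c("chrom_a", "pos_a"))
  invisible(dir)
}
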