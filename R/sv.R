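#' Orientation class of a junction from its boundary sides
#'
#' A junction breakend uses a segment's R boundary when the retained
#' sequence runs leftward (reference-forward) into the junction, and the
#' L boundary when it runs rightward. The unordered side pair fixes the
#' rearrangement class: \{R, L\} is head-to-tail, \{R, R\} head-to-head,
#' \{L, L\} tail-to-tail.
#'
#' @param side_a,side_b `"L"` or `"R"` (vectorized).
#' @return character vector: `"head_to_tail"`, `"head_to_head"` or
#'   `"tail_to_tail"`.
#' @export
orientation_from_sides <- function(side_a, side_b) {
  ifelse(side_a != side_b, "head_to_tail",
         ifelse(side_a == "R", "head_to_head", "tail_to_tail"))
}

#' Reads overlapping a boundary window
#'
#' Returns the alignment records whose mapped reference span overlaps
#' `[position - boundary_flank, position + boundary_flank]`.
#'
#' @param aln a `dm_alignments` data.frame.
#' @param boundary one row of [dm_boundaries()] (fields `chrom`,
#'   `position`).
#' @param params a [dm_params()] object.
#' @return the overlapping subset of `aln`.
#' @export
reads_near_boundary <- function(aln, boundary, params = dm_params()) {
  lo <- boundary$position - params$boundary_flank
  hi <- boundary$position + params$boundary_flank
  ok <- !is.na(aln$pos) & !aln_is_unmapped(aln$flag) &
    aln$chrom == boundary$chrom
  ends <- rep(NA_integer_, nrow(aln))
  ends[ok] <- aln$pos[ok] +
    GenomicAlignments::cigarWidthAlongReferenceSpace(aln$cigar[ok]) - 1L
  keep <- ok & aln$pos <= hi & ends >= lo
  out <- aln[keep, , drop = FALSE]
  row.names(out) <- NULL
  out
}

# Soft-clip descriptors of one alignment record: side ("left"/"right"),
# clipped sequence, and the reference coordinate where the alignment stops.
clip_info <- function(rec) {
  cg <- parse_cigar(rec$cigar)
  if (!nrow(cg) || !any(cg$op == "S") || !any(cg$op %in% c("M", "=", "X")))
    return(NULL)
  refw <- sum(cg$len[cg$op %in% c("M", "=", "X", "D", "N")])
  out <- list()
  if (cg$op[1] == "S") {
    out$left <- list(side = "left",
                     seq = substr(rec$seq, 1, cg$len[1]),
                     at = rec$pos)
  }
  n <- nrow(cg)
  if (cg$op[n] == "S") {
    out$right <- list(side = "right",
                      seq = substr(rec$seq, nchar(rec$seq) - cg$len[n] + 1,
                                   nchar(rec$seq)),
                      at = rec$pos + refw - 1L)
  }
  out
}

# Flank sequence of a boundary: [position - flank, position + flank],
# clipped to the reference. Returns list(seq, offset) with offset = ref
# coordinate of the first base.
boundary_flank_seq <- function(reference, boundary, flank) {
  chrseq <- reference[[boundary$chrom]]
  lo <- max(1L, boundary$position - flank)
  hi <- min(length(chrseq), boundary$position + flank)
  list(seq = Biostrings::subseq(chrseq, lo, hi), offset = lo)
}

# Local alignment of clip sequences against one flank, one strand.
# clips: character vector; returns data.frame(score, pid, alen, sstart, send)
# in flank-local coordinates (forward strand of the flank).
align_clips_to_flank <- function(clips, flank_seq, strand,
                                 submat, gap_open = 5, gap_ext = 2) {
  pats <- Biostrings::DNAStringSet(clips)
  if (strand == "-") pats <- Biostrings::reverseComplement(pats)
  pa <- Biostrings::pairwiseAlignment(pats, flank_seq, type = "local",
                                      substitutionMatrix = submat,
                                      gapOpening = gap_open,
                                      gapExtension = gap_ext)
  data.frame(score = Biostrings::score(pa),
             pid = Biostrings::pid(pa),
             alen = Biostrings::nchar(pa),
             sstart = IRanges::start(Biostrings::subject(pa)),
             send = IRanges::end(Biostrings::subject(pa)))
}

# For a set of clipped sequences, find the qualifying local-alignment hits
# against every candidate boundary flank on both strands. Returns a
# data.frame with one row per (clip, boundary, strand) qualifying hit.
scan_clips_against_boundaries <- function(clips, boundaries, reference,
                                          params) {
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 2,
                                                     mismatch = -3)
  hits <- list()
  for (bi in seq_len(nrow(boundaries))) {
    fl <- boundary_flank_seq(reference, boundaries[bi, ],
                             params$search_flank)
    for (strand in c("+", "-")) {
      al <- align_clips_to_flank(clips, fl$seq, strand, submat)
      qual <- al$alen >= params$min_clip_match &
        al$pid >= 100 * params$min_clip_identity
      if (!any(qual)) next
      idx <- which(qual)
      hits[[length(hits) + 1L]] <- data.frame(
        clip = idx, b_idx = bi, strand = strand,
        score = al$score[idx],
        hit_start = fl$offset + al$sstart[idx] - 1L,
        hit_end = fl$offset + al$send[idx] - 1L)
    }
  }
  if (!length(hits)) return(NULL)
  do.call(rbind, hits)
}

# Partner side and breakpoint implied by (clip side, hit strand).
partner_side_of_hit <- function(clip_side, strand) {
  if (clip_side == "right") {
    if (strand == "+") "L" else "R"
  } else {
    if (strand == "+") "R" else "L"
  }
}

#' Soft-clipped read evidence around amplified-segment boundaries
#'
#' For every soft-clipped read near a boundary (clip on the boundary's
#' side: right clips at R boundaries, left clips at L boundaries), the
#' clipped bases (at least `min_clip_match` of them) are locally aligned
#' against the `search_flank` window of every other boundary, both
#' strands. A read yields evidence only when exactly one boundary flank
#' gives a qualifying hit (identity and uniqueness thresholds in
#' `params`); the clip side and hit strand fix the partner side and the
#' two breakpoints.
#'
#' @param aln tumor alignments (`dm_alignments`).
#' @param boundaries output of [dm_boundaries()] on the amplified
#'   segments.
#' @param reference a named `DNAStringSet`.
#' @param params a [dm_params()] object.
#' @return data.frame of per-read increments: `qname`, `seg_a`, `side_a`,
#'   `seg_b`, `side_b`, `breakpoint_a`, `breakpoint_b`.
#' @keywords internal
softclip_scan <- function(aln, boundaries, reference, params) {
  inc <- list()
  # gather candidate clips: one entry per (read near boundary, matching side)
  cand <- list()
  for (bi in seq_len(nrow(boundaries))) {
    b <- boundaries[bi, ]
    near <- reads_near_boundary(aln, b, params)
    if (!nrow(near)) next
    want <- if (b$side == "R") "right" else "left"
    for (k in seq_len(nrow(near))) {
      ci <- clip_info(near[k, ])
      cl <- ci[[want]]
      if (is.null(cl) || nchar(cl$seq) < params$min_clip_match) next
      cand[[length(cand) + 1L]] <- list(qname = near$qname[k],
                                        b_idx = bi, clip = cl)
    }
  }
  if (!length(cand)) return(empty_sv_increments())
  clips <- vapply(cand, function(x) x$clip$seq, "")
  hits <- scan_clips_against_boundaries(clips, boundaries, reference,
                                        params)
  if (is.null(hits)) return(empty_sv_increments())
  for (i in seq_along(cand)) {
    src <- cand[[i]]
    h <- hits[hits$clip == i, , drop = FALSE]
    # a hit on the source boundary itself is self-alignment, not evidence
    h <- h[h$b_idx != src$b_idx, , drop = FALSE]
    if (!nrow(h)) next
    # unique placement: best-scoring boundary must dominate, and only one
    # boundary may hold the top score
    h <- h[order(-h$score), , drop = FALSE]
    best_per_b <- h[!duplicated(h$b_idx), , drop = FALSE]
    if (nrow(best_per_b) > 1 &&
        best_per_b$score[1] < params$uniqueness_ratio * best_per_b$score[2])
      next
    top <- best_per_b[1, ]
    pside <- partner_side_of_hit(src$clip$side, top$strand)
    bsrc <- boundaries[src$b_idx, ]
    btgt <- boundaries[top$b_idx, ]
    if (btgt$side != pside) next   # hit flank inconsistent with geometry
    inc[[length(inc) + 1L]] <- data.frame(
      qname = src$qname,
      seg_a = bsrc$segment_id, side_a = bsrc$side,
      seg_b = btgt$segment_id, side_b = btgt$side,
      breakpoint_a = src$clip$at,
      breakpoint_b = if (pside == "L") top$hit_start else top$hit_end,
      stringsAsFactors = FALSE)
  }
  if (!length(inc)) return(empty_sv_increments())
  do.call(rbind, inc)
}

empty_sv_increments <- function() {
  data.frame(qname = character(), seg_a = integer(), side_a = character(),
             seg_b = integer(), side_b = character(),
             breakpoint_a = integer(), breakpoint_b = integer(),
             stringsAsFactors = FALSE)
}

# Reads near a boundary that are discordant (mate on another chromosome or
# >= discordant_min_distance away) and whose own strand points into the
# boundary's junction (R boundaries are approached by forward-strand
# reads, L boundaries by reverse-strand reads).
discordant_flank_reads <- function(aln, boundary, params) {
  near <- reads_near_boundary(aln, boundary, params)
  if (!nrow(near)) return(near)
  minus <- aln_is_minus(near$flag)
  side_ok <- if (boundary$side == "R") !minus else minus
  mate_ok <- !aln_mate_unmapped(near$flag) & !is.na(near$mate_pos)
  disc <- mate_ok & (near$mate_chrom != near$chrom |
                       abs(near$mate_pos - near$pos) >=
                         params$discordant_min_distance)
  out <- near[side_ok & disc, , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Discordant read-pair evidence between two boundaries
#'
#' For each read in a boundary's `boundary_flank` window whose mate maps
#' to another chromosome or at least `discordant_min_distance` away, the
#' mate is matched against the `search_flank` windows of the other
#' boundaries. The strand of a read encodes which side of its segment it
#' supports (forward = R, reverse = L), and likewise for the mate, so the
#' strand pair in the FLAG field fixes the junction orientation. Each
#' template is counted once per boundary pair.
#'
#' @inheritParams softclip_scan
#' @return data.frame of per-template increments (same shape as
#'   soft-clip increments, breakpoints `NA`).
#' @keywords internal
discordant_scan <- function(aln, boundaries, params) {
  inc <- list()
  for (bi in seq_len(nrow(boundaries))) {
    b <- boundaries[bi, ]
    dr <- discordant_flank_reads(aln, b, params)
    if (!nrow(dr)) next
    mate_minus <- aln_mate_is_minus(dr$flag)
    mate_side <- ifelse(mate_minus, "L", "R")
    for (k in seq_len(nrow(dr))) {
      cand <- boundaries[boundaries$side == mate_side[k] &
                           boundaries$chrom == dr$mate_chrom[k] &
                           abs(boundaries$position - dr$mate_pos[k]) <=
                             params$search_flank, , drop = FALSE]
      cand <- cand[!(cand$segment_id == b$segment_id &
                       cand$side == b$side), , drop = FALSE]
      if (!nrow(cand)) next
      # nearest matching boundary wins if several are in range
      tgt <- cand[which.min(abs(cand$position - dr$mate_pos[k])), ]
      inc[[length(inc) + 1L]] <- data.frame(
        qname = dr$qname[k],
        seg_a = b$segment_id, side_a = b$side,
        seg_b = tgt$segment_id, side_b = tgt$side,
        breakpoint_a = NA_integer_, breakpoint_b = NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(inc)) return(empty_sv_increments())
  do.call(rbind, inc)
}

#' Bridging discordant evidence between two boundaries
#'
#' Considers, for each boundary, its flank reads whose mates are
#' discordant but do not fall inside any boundary's `search_flank` window
#' (those were already consumed as direct discordant evidence). If the
#' mate clusters of two boundaries lie within `bridge_max_distance` of
#' each other on the same chromosome and their predominant strands are
#' opposite -- consistent with a single intervening fragment joining the
#' two boundaries -- the pair is reported as bridging evidence. The
#' breakpoints stay unresolved.
#'
#' @inheritParams softclip_scan
#' @return data.frame of increments, one row per supporting template.
#' @keywords internal
bridging_scan <- function(aln, boundaries, params) {
  # per boundary: discordant flank reads with "free" mates
  free <- vector("list", nrow(boundaries))
  for (bi in seq_len(nrow(boundaries))) {
    dr <- discordant_flank_reads(aln, boundaries[bi, ], params)
    if (!nrow(dr)) { free[[bi]] <- dr; next }
    near_any <- vapply(seq_len(nrow(dr)), function(k) {
      any(boundaries$chrom == dr$mate_chrom[k] &
            abs(boundaries$position - dr$mate_pos[k]) <=
              params$search_flank)
    }, TRUE)
    free[[bi]] <- dr[!near_any, , drop = FALSE]
  }
  inc <- list()
  nb <- nrow(boundaries)
  for (i in seq_len(nb - 1L)) {
    for (j in seq(i + 1L, nb)) {
      a <- free[[i]]; b <- free[[j]]
      if (!nrow(a) || !nrow(b)) next
      if (boundaries$segment_id[i] == boundaries$segment_id[j] &&
          boundaries$side[i] == boundaries$side[j]) next
      chroms <- intersect(a$mate_chrom, b$mate_chrom)
      for (ch in chroms) {
        am <- a[a$mate_chrom == ch, , drop = FALSE]
        bm <- b[b$mate_chrom == ch, , drop = FALSE]
        if (abs(median(am$mate_pos) - median(bm$mate_pos)) >
            params$bridge_max_distance) next
        sa <- mean(aln_mate_is_minus(am$flag)) >= 0.5
        sb <- mean(aln_mate_is_minus(bm$flag)) >= 0.5
        if (sa == sb) next  # not a single intervening fragment
        qn <- unique(c(am$qname, bm$qname))
        inc[[length(inc) + 1L]] <- data.frame(
          qname = qn,
          seg_a = boundaries$segment_id[i], side_a = boundaries$side[i],
          seg_b = boundaries$segment_id[j], side_b = boundaries$side[j],
          breakpoint_a = NA_integer_, breakpoint_b = NA_integer_,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(inc)) return(empty_sv_increments())
  do.call(rbind, inc)
}

# canonical unordered boundary-pair ordering: (seg, side) lexicographic
canonicalize_pairs <- function(df) {
  flip <- df$seg_a > df$seg_b |
    (df$seg_a == df$seg_b & df$side_a > df$side_b)
  tmp <- df
  df$seg_a[flip] <- tmp$seg_b[flip];  df$seg_b[flip] <- tmp$seg_a[flip]
  df$side_a[flip] <- tmp$side_b[flip]; df$side_b[flip] <- tmp$side_a[flip]
  df$breakpoint_a[flip] <- tmp$breakpoint_b[flip]
  df$breakpoint_b[flip] <- tmp$breakpoint_a[flip]
  df
}

aggregate_increments <- function(inc) {
  if (!nrow(inc)) {
    inc$pair <- character()
    return(inc)
  }
  inc <- canonicalize_pairs(inc)
  inc$pair <- paste0(inc$seg_a, inc$side_a, "-", inc$seg_b, inc$side_b)
  # one count per template per pair
  inc <- inc[!duplicated(paste(inc$pair, inc$qname)), , drop = FALSE]
  inc
}

#' Collect all SV evidence around amplified-segment boundaries
#'
#' Runs the three evidence scans (soft-clipped reads, discordant read
#' pairs, bridging discordant reads) and aggregates the per-template
#' increments into one row per (unordered boundary pair, orientation).
#' Breakpoints are reported only when soft-clip evidence resolved them
#' (majority position across supporting reads).
#'
#' @param aln tumor alignments (`dm_alignments`).
#' @param amplified amplified segments (`dm_segments`).
#' @param reference named `DNAStringSet`.
#' @param params a [dm_params()] object.
#' @return A `dm_sv` data.frame with columns `seg_a`, `side_a`, `seg_b`,
#'   `side_b`, `orientation`, `softclip_count`, `discordant_count`,
#'   `bridging_count`, `breakpoint_a`, `breakpoint_b`.
#' @export
collect_sv_evidence <- function(aln, amplified, reference,
                                params = dm_params()) {
  boundaries <- dm_boundaries(amplified)
  sc <- aggregate_increments(softclip_scan(aln, boundaries, reference,
                                           params))
  dc <- aggregate_increments(discordant_scan(aln, boundaries, params))
  br <- aggregate_increments(bridging_scan(aln, boundaries, params))
  pairs <- unique(rbind(sc[c("seg_a", "side_a", "seg_b", "side_b", "pair")],
                        dc[c("seg_a", "side_a", "seg_b", "side_b", "pair")],
                        br[c("seg_a", "side_a", "seg_b", "side_b", "pair")]))
  if (!nrow(pairs)) return(empty_dm_sv())
  mode_int <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_integer_)
    as.integer(names(sort(table(x), decreasing = TRUE))[1])
  }
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    p <- pairs$pair[k]
    s <- sc[sc$pair == p, , drop = FALSE]
    data.frame(
      seg_a = pairs$seg_a[k], side_a = pairs$side_a[k],
      seg_b = pairs$seg_b[k], side_b = pairs$side_b[k],
      orientation = orientation_from_sides(pairs$side_a[k],
                                           pairs$side_b[k]),
      softclip_count = nrow(s),
      discordant_count = sum(dc$pair == p),
      bridging_count = sum(br$pair == p),
      breakpoint_a = mode_int(s$breakpoint_a),
      breakpoint_b = mode_int(s$breakpoint_b),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$seg_a, out$side_a, out$seg_b, out$side_b), ,
             drop = FALSE]
  row.names(out) <- NULL
  class(out) <- c("dm_sv", "data.frame")
  # machine-readable review dump: read names behind every count
  sup <- rbind(
    if (nrow(sc)) data.frame(pair = sc$pair, class = "softclip",
                             qname = sc$qname),
    if (nrow(dc)) data.frame(pair = dc$pair, class = "discordant",
                             qname = dc$qname),
    if (nrow(br)) data.frame(pair = br$pair, class = "bridging",
                             qname = br$qname))
  if (!is.null(sup)) {
    sup <- sup[order(sup$pair, sup$class, sup$qname), , drop = FALSE]
    row.names(sup) <- NULL
  }
  attr(out, "supporting_reads") <- sup
  out
}

empty_dm_sv <- function() {
  out <- data.frame(seg_a = integer(), side_a = character(),
                    seg_b = integer(), side_b = character(),
                    orientation = character(), softclip_count = integer(),
                    discordant_count = integer(), bridging_count = integer(),
                    breakpoint_a = integer(), breakpoint_b = integer(),
                    stringsAsFactors = FALSE)
  class(out) <- c("dm_sv", "data.frame")
  out
}

#' Search known breakpoints in another sample
#'
#' For each SV in `sv_list`, counts in `aln` (an independent sample's
#' alignments) the soft-clipped reads at either boundary whose clipped
#' bases align to the partner boundary's flank, plus the discordant
#' templates linking the two boundary flanks. SVs with zero support are
#' reported `"absent"`.
#'
#' @param aln the other sample's alignments.
#' @param sv_list a `dm_sv` data.frame.
#' @param segments the segment table the SVs refer to.
#' @param reference named `DNAStringSet`.
#' @param params a [dm_params()] object.
#' @return `sv_list` with added columns `other_softclip`,
#'   `other_discordant` and `status` (`"present"`/`"absent"`).
#' @export
search_breakpoints_in_sample <- function(aln, sv_list, segments, reference,
                                         params = dm_params()) {
  boundaries <- dm_boundaries(segments)
  sc <- aggregate_increments(softclip_scan(aln, boundaries, reference,
                                           params))
  dc <- aggregate_increments(discordant_scan(aln, boundaries, params))
  key <- function(df) paste0(df$seg_a, df$side_a, "-", df$seg_b, df$side_b)
  svk <- key(canonicalize_pairs(sv_list))
  sv_list$other_softclip <- vapply(svk, function(p) sum(sc$pair == p), 1L,
                                   USE.NAMES = FALSE)
  sv_list$other_discordant <- vapply(svk, function(p) sum(dc$pair == p), 1L,
                                     USE.NAMES = FALSE)
  sv_list$status <- ifelse(sv_list$other_softclip +
                             sv_list$other_discordant > 0,
                           "present", "absent")
  sv_list
}
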