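## Synthetic-data simulator: a small random reference, planted circular
## amplicons (ordered, oriented segments), tumor/normal paired-end reads
## emitted pre-aligned (soft-clip CIGARs, discordant mate fields and
## strand flags computed from the planted geometry), SNV tables with
## binomial allele counts reflecting amplicon copy number, and
## barcode-tagged linked reads from long molecules.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rc_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# circular substring of a character sequence
cyc_substr <- function(seq, len, p, L) {
  p <- ((p - 1L) %% len) + 1L
  if (p + L - 1L <= len) substr(seq, p, p + L - 1L)
  else paste0(substr(seq, p, len), substr(seq, 1L, p + L - 1L - len))
}

#' Plan of a synthetic amplicon study
#'
#' Describes the synthetic reference, the planted circular structures
#' (ordered, oriented segments with per-junction types), the SNV spec and
#' the read/molecule spec. A fixed seed makes every downstream simulation
#' byte-identical.
#'
#' @param ref_length bp of the single synthetic chromosome.
#' @param segments data.frame with `start`, `end` (1-based inclusive,
#'   non-overlapping): the planted amplified segments.
#' @param structures list of structures; each a list with `segments`
#'   (indices into `segments`), `orients` (`"+"`/`"-"`), `copies`
#'   (amplicon copies per cell) and optional `junctions` (one of
#'   `"clean"`/`"bridge"` per adjacency, default all clean;
#'   reference-contiguous forward pairs are traversed as adjacent,
#'   without an SV).
#' @param decoy_junctions optional list of lists `(seg_a, side_a, seg_b,
#'   side_b, n_softclip, n_discordant)`: fabricated junction evidence
#'   with no underlying molecule, for false-positive studies.
#' @param chrom chromosome name.
#' @param n_background_segments neutral (diploid) segments added to the
#'   emitted segment table.
#' @param snvs_per_segment heterozygous germline SNVs planted per
#'   segment.
#' @param somatic_shifts optional data.frame `segment`, `n`, `vaf_a`,
#'   `vaf_b`: somatic SNVs whose VAF differs between time points a and b.
#' @param sample_tag `"a"` or `"b"`; selects which somatic-shift VAF
#'   column this plan's counts are drawn from.
#' @param read_length,insert_mean,insert_sd paired-end read geometry
#'   (bp).
#' @param normal_depth haploid-pair (diploid) sequencing depth of the
#'   normal sample and of the tumor background.
#' @param snv_depth diploid depth used for SNV allele-count draws
#'   (defaults to `normal_depth`; SNV tables are cheap to simulate, so
#'   they can follow a deeper design than the read simulation).
#' @param mol_mean_length mean linked-read molecule length (bp).
#' @param mol_coverage molecule coverage (average molecules overlapping a
#'   position) on each amplicon.
#' @param mol_background_coverage molecule coverage of the diploid
#'   background.
#' @param mol_read_spacing mean bp between consecutive reads of one
#'   molecule.
#' @param seed integer; fixes all draws derived from this plan.
#' @return An `amplicon_plan` object.
#' @export
amplicon_plan <- function(ref_length, segments, structures,
                          decoy_junctions = NULL,
                          chrom = "chr1",
                          n_background_segments = 4,
                          snvs_per_segment = 40,
                          somatic_shifts = NULL,
                          sample_tag = "a",
                          read_length = 100, insert_mean = 350,
                          insert_sd = 35, normal_depth = 30,
                          snv_depth = NULL,
                          mol_mean_length = 31000, mol_coverage = 40,
                          mol_background_coverage = 3,
                          mol_read_spacing = 400,
                          seed = 1L) {
  segments <- as.data.frame(segments)
  stopifnot(all(segments$start <= segments$end))
  o <- order(segments$start)
  if (any(segments$start[o][-1] <= segments$end[o][-nrow(segments)]))
    stop("planted segments overlap")
  for (st in structures) {
    stopifnot(length(st$segments) == length(st$orients),
              all(st$orients %in% c("+", "-")),
              st$copies >= 0)
    if (!is.null(st$junctions))
      stopifnot(length(st$junctions) == length(st$segments),
                all(st$junctions %in% c("clean", "bridge")))
  }
  plan <- list(ref_length = as.integer(ref_length), segments = segments,
               structures = structures, decoy_junctions = decoy_junctions,
               chrom = chrom,
               n_background_segments = as.integer(n_background_segments),
               snvs_per_segment = as.integer(snvs_per_segment),
               somatic_shifts = somatic_shifts, sample_tag = sample_tag,
               read_length = as.integer(read_length),
               insert_mean = insert_mean, insert_sd = insert_sd,
               normal_depth = normal_depth,
               snv_depth = if (is.null(snv_depth)) normal_depth
               else snv_depth,
               mol_mean_length = mol_mean_length,
               mol_coverage = mol_coverage,
               mol_background_coverage = mol_background_coverage,
               mol_read_spacing = mol_read_spacing,
               seed = as.integer(seed))
  class(plan) <- "amplicon_plan"
  plan
}

# exit side of an oriented segment (the boundary its sequence runs into
# when leaving it along the amplicon) and entry side (when entering it)
exit_side <- function(orient) ifelse(orient == "+", "R", "L")
entry_side <- function(orient) ifelse(orient == "+", "L", "R")

# pick a donor locus for bridging inserts: middle of the largest gap
# between planted segments, well away from every boundary
pick_donor_base <- function(plan) {
  s <- plan$segments[order(plan$segments$start), ]
  gaps <- data.frame(start = c(1, s$end + 1),
                     end = c(s$start - 1, plan$ref_length))
  gaps <- gaps[gaps$end - gaps$start > 8000, , drop = FALSE]
  if (!nrow(gaps)) stop("reference too crowded to place a bridge donor")
  g <- gaps[which.max(gaps$end - gaps$start), ]
  as.integer((g$start + g$end) / 2)
}

BRIDGE_PAD <- 80L
BRIDGE_DONOR <- 400L

#' Build the synthetic reference and structure truth
#'
#' Generates the random reference sequence and, for every planted
#' structure, its circular coordinate system (mapping units) and the
#' truth table of junctions (boundary pair, sides, orientation class,
#' junction type, breakpoints).
#'
#' @param plan an [amplicon_plan()].
#' @return A `dm_reference` list: `reference` (named `DNAStringSet`),
#'   `circles` (per structure), `truth_junctions` (data.frame),
#'   `plan`.
#' @export
build_reference <- function(plan) {
  set.seed(plan$seed)
  refseq <- random_dna(plan$ref_length)
  reference <- Biostrings::DNAStringSet(setNames(refseq, plan$chrom))
  donor_base <- NULL
  n_bridges <- sum(vapply(plan$structures, function(st)
    sum((st$junctions %||% rep("clean", length(st$segments))) == "bridge"),
    1L))
  if (n_bridges > 0) donor_base <- pick_donor_base(plan)
  bridge_i <- 0L
  circles <- list()
  truth <- list()
  for (si in seq_along(plan$structures)) {
    st <- plan$structures[[si]]
    jt <- st$junctions %||% rep("clean", length(st$segments))
    units <- list()
    juncs <- list()
    off <- 0L
    k <- length(st$segments)
    for (i in seq_len(k)) {
      seg <- plan$segments[st$segments[i], ]
      seglen <- seg$end - seg$start + 1L
      units[[length(units) + 1L]] <- data.frame(
        type = "ref", ref_start = seg$start, ref_end = seg$end,
        orient = st$orients[i], len = seglen)
      off <- off + seglen
      jnxt <- if (i == k) 1L else i + 1L
      sa <- exit_side(st$orients[i])
      sb <- entry_side(st$orients[jnxt])
      sega <- plan$segments[st$segments[i], ]
      segb <- plan$segments[st$segments[jnxt], ]
      bp_a <- if (sa == "R") sega$end else sega$start
      bp_b <- if (sb == "L") segb$start else segb$end
      type <- jt[i]
      ins_start <- NA_integer_; ins_end <- NA_integer_
      if (type == "bridge") {
        bridge_i <- bridge_i + 1L
        dstart <- donor_base + (bridge_i - 1L) * (BRIDGE_DONOR + 600L)
        ins_start <- off + 1L
        units[[length(units) + 1L]] <- data.frame(
          type = "pad", ref_start = NA_integer_, ref_end = NA_integer_,
          orient = "+", len = BRIDGE_PAD)
        units[[length(units) + 1L]] <- data.frame(
          type = "ref", ref_start = dstart,
          ref_end = dstart + BRIDGE_DONOR - 1L, orient = "+",
          len = BRIDGE_DONOR)
        units[[length(units) + 1L]] <- data.frame(
          type = "pad", ref_start = NA_integer_, ref_end = NA_integer_,
          orient = "+", len = BRIDGE_PAD)
        off <- off + 2L * BRIDGE_PAD + BRIDGE_DONOR
        ins_end <- off
      } else if (st$orients[i] == "+" && st$orients[jnxt] == "+" &&
                 segb$start == sega$end + 1L) {
        type <- "adjacent"
      }
      juncs[[length(juncs) + 1L]] <- data.frame(
        structure = si, junction = i,
        seg_a = st$segments[i], side_a = sa,
        seg_b = st$segments[jnxt], side_b = sb,
        orientation = orientation_from_sides(sa, sb),
        type = type, breakpoint_a = bp_a, breakpoint_b = bp_b,
        offset = if (i == k && type != "bridge") off else
          if (type == "bridge") ins_start - 1L else off,
        insert_start = ins_start, insert_end = ins_end,
        stringsAsFactors = FALSE)
    }
    units <- do.call(rbind, units)
    # junction offsets: circle position of the last base before the break
    offsets <- cumsum(units$len)
    # recompute clean-junction offsets as end of each segment unit
    juncs <- do.call(rbind, juncs)
    circ_len <- sum(units$len)
    # sequence
    pieces <- vapply(seq_len(nrow(units)), function(u) {
      if (units$type[u] == "pad") return(random_dna(units$len[u]))
      s <- substr(refseq, units$ref_start[u], units$ref_end[u])
      if (units$orient[u] == "-") rc_chr(s) else s
    }, "")
    seq <- paste(pieces, collapse = "")
    # merge reference-contiguous forward units for mapping
    munits <- units[1, , drop = FALSE]
    for (u in seq_len(nrow(units))[-1]) {
      lastu <- nrow(munits)
      if (units$type[u] == "ref" && munits$type[lastu] == "ref" &&
          munits$orient[lastu] == "+" && units$orient[u] == "+" &&
          !is.na(munits$ref_end[lastu]) &&
          units$ref_start[u] == munits$ref_end[lastu] + 1L) {
        munits$ref_end[lastu] <- units$ref_end[u]
        munits$len[lastu] <- munits$len[lastu] + units$len[u]
      } else munits <- rbind(munits, units[u, ])
    }
    munits$offset <- c(0L, cumsum(munits$len)[-nrow(munits)])
    circles[[si]] <- list(units = munits, len = circ_len, seq = seq,
                          copies = st$copies, junctions = juncs)
    truth[[si]] <- juncs
  }
  truth <- if (length(truth)) do.call(rbind, truth) else NULL
  out <- list(reference = reference, chrom = plan$chrom,
              circles = circles, truth_junctions = truth, plan = plan)
  class(out) <- "dm_reference"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# map one read on a circle (or linear track): amplicon interval
# [p, p + L - 1], direction d ("+"/"-" along the track). Returns a list
# of SAM-record fields, or NULL when unmappable.
map_read_on_track <- function(track, p, L, d, min_anchor = 25L) {
  len <- track$len
  circ <- isTRUE(track$circular) || is.null(track$circular)
  p <- if (circ) ((p - 1L) %% len) + 1L else p
  un <- track$units
  # spans of the read across units
  spans <- list()
  rem <- L; cur <- p; q0 <- 0L
  while (rem > 0L) {
    u <- findInterval(cur - 1L, un$offset)
    within <- cur - un$offset[u]         # 1-based offset inside unit
    take <- as.integer(min(rem, un$len[u] - within + 1L))
    spans[[length(spans) + 1L]] <- list(u = u, off = within, len = take,
                                        q0 = q0)
    rem <- rem - take
    q0 <- q0 + take
    cur <- cur + take
    if (cur > len) { if (circ) cur <- cur - len else break }
  }
  if (rem > 0L) return(NULL)
  mappable <- Filter(function(s) un$type[s$u] == "ref" &&
                       s$len >= min_anchor, spans)
  if (!length(mappable)) return(NULL)
  anchor <- mappable[[which.max(vapply(mappable, `[[`, 1L, "len"))]]
  u <- anchor$u
  o_u <- un$orient[u]
  if (o_u == "+") {
    rstart <- un$ref_start[u] + anchor$off - 1L
  } else {
    rstart <- un$ref_end[u] - anchor$off - anchor$len + 2L
  }
  raw <- cyc_substr(track$seq, len, p, L)
  stored <- if (o_u == "+") raw else rc_chr(raw)
  if (o_u == "+") {
    lclip <- anchor$q0
    rclip <- L - anchor$q0 - anchor$len
  } else {
    lclip <- L - anchor$q0 - anchor$len
    rclip <- anchor$q0
  }
  cigar <- paste0(if (lclip > 0) paste0(lclip, "S") else "",
                  anchor$len, "M",
                  if (rclip > 0) paste0(rclip, "S") else "")
  minus <- d != o_u
  list(pos = rstart, cigar = cigar, seq = stored, minus = minus,
       ref_end = rstart + anchor$len - 1L)
}

# vectorized read mapping on a track: positions p (track coordinates),
# direction d ("+"/"-" along the track, recycled). Returns a data.frame
# with one row per input read: pos, cigar, seq, minus, mapped.
map_reads_vec <- function(track, p, d, L) {
  n <- length(p)
  d <- rep_len(d, n)
  len <- track$len
  circ <- isTRUE(track$circular)
  pm <- if (circ) ((p - 1L) %% len) + 1L else p
  un <- track$units
  out <- data.frame(pos = rep(NA_integer_, n), cigar = NA_character_,
                    seq = NA_character_, minus = NA,
                    mapped = FALSE, stringsAsFactors = FALSE)
  u <- findInterval(pm - 1L, un$offset)
  off <- pm - un$offset[u]                  # 1-based offset inside unit
  fast <- off + L - 1L <= un$len[u] & un$type[u] == "ref"
  if (any(fast)) {
    i <- which(fast)
    ou <- un$orient[u[i]]
    plus <- ou == "+"
    pos <- ifelse(plus, un$ref_start[u[i]] + off[i] - 1L,
                  un$ref_end[u[i]] - off[i] - L + 2L)
    raw <- substring(track$seq, pm[i], pm[i] + L - 1L)
    if (any(!plus)) raw[!plus] <- rc_chr(raw[!plus])
    out$pos[i] <- as.integer(pos)
    out$cigar[i] <- paste0(L, "M")
    out$seq[i] <- raw
    out$minus[i] <- d[i] != ou
    out$mapped[i] <- TRUE
  }
  for (i in which(!fast)) {
    r <- map_read_on_track(track, pm[i], L, d[i])
    if (is.null(r)) next
    out$pos[i] <- r$pos; out$cigar[i] <- r$cigar; out$seq[i] <- r$seq
    out$minus[i] <- r$minus; out$mapped[i] <- TRUE
  }
  out
}

# paired-end simulation on a track; returns list(aln = data.frame,
# frags = data.frame(qname, start, len) in track coordinates)
sim_read_pairs <- function(track, n_pairs, plan, prefix,
                           positions = NULL, frag_lens = NULL) {
  L <- plan$read_length
  len <- track$len
  circ <- isTRUE(track$circular)
  if (is.null(positions)) {
    fr <- pmax(2L * L + 10L,
               as.integer(round(rnorm(n_pairs, plan$insert_mean,
                                      plan$insert_sd))))
    fr <- pmin(fr, len)
    if (circ) {
      st <- sample.int(len, n_pairs, replace = TRUE)
    } else {
      st <- vapply(fr, function(f)
        sample.int(max(1L, len - f + 1L), 1L), 1L)
    }
  } else {
    st <- as.integer(positions); fr <- as.integer(frag_lens)
    n_pairs <- length(st)
  }
  if (!n_pairs)
    return(list(aln = empty_alignments(),
                frags = data.frame(qname = character(), start = integer(),
                                   len = integer())))
  qname <- sprintf("%s%06d", prefix, seq_len(n_pairs))
  r1 <- map_reads_vec(track, st, "+", L)
  r2 <- map_reads_vec(track, st + fr - L, "-", L)
  build <- function(r, o, first) {
    flag <- 1L + (if (first) 64L else 128L) + ifelse(r$minus, 16L, 0L) +
      ifelse(o$mapped & o$minus, 32L, 0L) + ifelse(!o$mapped, 8L, 0L)
    proper <- o$mapped & abs(o$pos - r$pos) < 2L * plan$insert_mean &
      r$minus != o$minus
    flag <- flag + ifelse(!is.na(proper) & proper, 2L, 0L)
    data.frame(qname = qname, flag = flag, chrom = track$chrom,
               pos = r$pos, mapq = 60L, cigar = r$cigar,
               mate_chrom = ifelse(o$mapped, track$chrom, track$chrom),
               mate_pos = ifelse(o$mapped, o$pos, r$pos),
               isize = 0L, seq = r$seq, barcode = NA_character_,
               stringsAsFactors = FALSE)[r$mapped, , drop = FALSE]
  }
  aln <- rbind(build(r1, r2, TRUE), build(r2, r1, FALSE))
  list(aln = aln, frags = data.frame(qname = qname, start = st, len = fr))
}

empty_alignments <- function() {
  data.frame(qname = character(), flag = integer(), chrom = character(),
             pos = integer(), mapq = integer(), cigar = character(),
             mate_chrom = character(), mate_pos = integer(),
             isize = integer(), seq = character(), barcode = character(),
             stringsAsFactors = FALSE)
}

# classify junction-supporting templates of one circle's fragments
junction_truth_supporters <- function(circle, frags, plan) {
  L <- plan$read_length
  len <- circle$len
  out <- list()
  for (ji in seq_len(nrow(circle$junctions))) {
    j <- circle$junctions[ji, ]
    if (j$type == "adjacent") next
    if (j$type == "bridge") {
      # templates with a read in a neighboring segment and a read
      # overlapping the insert
      a <- j$insert_start - 1L   # circle offset of last segment base
      rel <- ((frags$start - a - 1L) %% len)   # 0 = first insert base
      span <- j$insert_end - j$insert_start + 1L
      crosses <- rel > len - frags$len | rel < span
      if (any(crosses))
        out[[length(out) + 1L]] <- data.frame(
          structure = j$structure, junction = j$junction,
          qname = frags$qname[crosses], class = "bridging",
          stringsAsFactors = FALSE)
      next
    }
    c0 <- j$offset  # last circle base before the break
    rel <- ((frags$start - c0 - 1L) %% len)
    crosses <- rel > len - frags$len
    if (!any(crosses)) next
    fc <- frags[crosses, , drop = FALSE]
    relc <- len - rel[crosses]        # bases of fragment before break
    r1_span <- relc >= plan$min_clip_truth & relc <= L - plan$min_clip_truth
    r2_off <- relc - (fc$len - L)     # bases of read2 before break
    r2_span <- r2_off >= plan$min_clip_truth &
      r2_off <= L - plan$min_clip_truth
    cls <- ifelse(r1_span | r2_span, "softclip", "discordant")
    # pairs whose break sits inside a read but with a tiny clip are
    # neither clean split reads nor discordant: skip them
    tiny <- (relc < plan$min_clip_truth & relc > 0 & !r2_span) |
      (r2_off > 0 & r2_off < plan$min_clip_truth & !r1_span) |
      (relc > L - plan$min_clip_truth & relc < L & !r2_span) |
      (r2_off > L - plan$min_clip_truth & r2_off < L & !r1_span)
    keep <- !tiny | cls == "softclip"
    if (any(keep))
      out[[length(out) + 1L]] <- data.frame(
        structure = j$structure, junction = j$junction,
        qname = fc$qname[keep], class = cls[keep],
        stringsAsFactors = FALSE)
  }
  if (!length(out)) return(NULL)
  unique(do.call(rbind, out))
}

#' Simulate tumor and normal paired-end alignments
#'
#' The normal sample is uniform diploid background over the reference;
#' the tumor adds, for every planted structure, reads drawn from its
#' circular amplicon sequence at depth `normal_depth * copies / 2`.
#' Reads spanning a junction are emitted pre-aligned with the correct
#' soft-clip CIGAR and position; pairs straddling a junction get
#' discordant mate fields and strand flags; bridging-insert pads are
#' unmappable random sequence. Decoy junctions from the plan are
#' fabricated the same way.
#'
#' @param plan an [amplicon_plan()].
#' @param ref a `dm_reference` from [build_reference()].
#' @return list with `tumor`, `normal` (`dm_alignments`) and
#'   `truth_supporters` (data.frame `structure`, `junction`, `qname`,
#'   `class`).
#' @export
simulate_alignments <- function(plan, ref) {
  set.seed(plan$seed + 1000L +
             1000000L * (match(plan$sample_tag, c("a", "b")) - 1L))
  plan$min_clip_truth <- 20L
  L <- plan$read_length
  refseq <- as.character(ref$reference[[plan$chrom]])
  bg_track <- list(units = data.frame(type = "ref", ref_start = 1L,
                                      ref_end = plan$ref_length,
                                      orient = "+", len = plan$ref_length,
                                      offset = 0L),
                   len = plan$ref_length, seq = refseq,
                   circular = FALSE, chrom = plan$chrom)
  n_bg <- round(plan$normal_depth * plan$ref_length / (2 * L))
  normal <- sim_read_pairs(bg_track, n_bg, plan, "n")$aln
  tumor_parts <- list(sim_read_pairs(bg_track, n_bg, plan, "t")$aln)
  supporters <- list()
  for (si in seq_along(ref$circles)) {
    circ <- ref$circles[[si]]
    if (circ$copies <= 0) next
    track <- c(circ, list(circular = TRUE, chrom = plan$chrom))
    cov <- plan$normal_depth * circ$copies / 2
    n_pairs <- round(cov * circ$len / (2 * L))
    sim <- sim_read_pairs(track, n_pairs, plan, sprintf("s%d_", si))
    tumor_parts[[length(tumor_parts) + 1L]] <- sim$aln
    sup <- junction_truth_supporters(circ, sim$frags, plan)
    if (!is.null(sup)) supporters[[length(supporters) + 1L]] <- sup
  }
  # decoy junction evidence (reads with no underlying molecule)
  for (di in seq_along(plan$decoy_junctions %||% list())) {
    d <- plan$decoy_junctions[[di]]
    sega <- plan$segments[d$seg_a, ]; segb <- plan$segments[d$seg_b, ]
    oa <- if (d$side_a == "R") "+" else "-"
    ob <- if (d$side_b == "L") "+" else "-"
    units <- data.frame(
      type = "ref",
      ref_start = c(sega$start, segb$start),
      ref_end = c(sega$end, segb$end),
      orient = c(oa, ob),
      len = c(sega$end - sega$start + 1L, segb$end - segb$start + 1L))
    units$offset <- c(0L, units$len[1])
    seqs <- vapply(1:2, function(u) {
      s <- substr(refseq, units$ref_start[u], units$ref_end[u])
      if (units$orient[u] == "-") rc_chr(s) else s
    }, "")
    track <- list(units = units, len = sum(units$len),
                  seq = paste(seqs, collapse = ""), circular = FALSE,
                  chrom = plan$chrom)
    lenA <- units$len[1]
    sc_before <- sample(30:70, d$n_softclip, replace = TRUE)
    sc_pos <- lenA - sc_before + 1L
    disc_gap <- sample(0:40, d$n_discordant, replace = TRUE)
    disc_pos <- lenA - L - disc_gap + 1L
    sim <- sim_read_pairs(track, NULL, plan, sprintf("decoy%d_", di),
                          positions = c(sc_pos, disc_pos),
                          frag_lens = rep(as.integer(plan$insert_mean),
                                          d$n_softclip + d$n_discordant))
    tumor_parts[[length(tumor_parts) + 1L]] <- sim$aln
    supporters[[length(supporters) + 1L]] <- data.frame(
      structure = NA_integer_, junction = -di, qname = sim$frags$qname,
      class = ifelse(seq_len(nrow(sim$frags)) <= d$n_softclip,
                     "softclip", "discordant"), stringsAsFactors = FALSE)
  }
  tumor <- do.call(rbind, tumor_parts)
  row.names(tumor) <- NULL
  class(tumor) <- class(normal) <- c("dm_alignments", "data.frame")
  truth <- if (length(supporters)) do.call(rbind, supporters) else NULL
  list(tumor = tumor, normal = normal, truth_supporters = truth)
}

# total amplicon copies carried by each planted segment
segment_total_copies <- function(plan) {
  cn <- numeric(nrow(plan$segments))
  for (st in plan$structures)
    cn[st$segments] <- cn[st$segments] + st$copies
  cn
}

#' Simulate SNV tables for tumor and normal
#'
#' Plants heterozygous germline SNVs on every planted segment. On a
#' segment carried by `CN` amplicon copies per cell, an SNV whose
#' alternative allele sits on the amplified haplotype (the upper branch;
#' half the SNVs) draws its tumor alt count binomially with expected
#' alt:ref of CN:1; the other half mirrors this. Somatic shift SNVs from
#' the plan draw their counts at the plan's `sample_tag` VAF. SNV
#' positions and branch assignments depend only on the seed and segment
#' layout, so two plans differing in `sample_tag` share their loci.
#'
#' @param plan an [amplicon_plan()].
#' @return list with `tumor`, `normal` (`dm_snvs`) and `truth`
#'   (data.frame `segment`, `pos`, `branch`, `is_shift`).
#' @export
simulate_snvs <- function(plan) {
  set.seed(plan$seed + 2L)   # loci: shared across sample tags
  cn <- segment_total_copies(plan)
  loci <- list()
  for (k in seq_len(nrow(plan$segments))) {
    seg <- plan$segments[k, ]
    n <- plan$snvs_per_segment
    pos <- sort(sample(seq(seg$start, seg$end), n))
    upper <- sample(c(TRUE, FALSE), n, replace = TRUE)
    loci[[k]] <- data.frame(segment = k, pos = pos, upper = upper,
                            cn = cn[k], is_shift = FALSE,
                            vaf_a = NA_real_, vaf_b = NA_real_)
  }
  loci <- do.call(rbind, loci)
  if (!is.null(plan$somatic_shifts)) {
    for (r in seq_len(nrow(plan$somatic_shifts))) {
      sh <- plan$somatic_shifts[r, ]
      seg <- plan$segments[sh$segment, ]
      pos <- sort(sample(seq(seg$start + 1L, seg$end - 1L), sh$n))
      loci <- rbind(loci, data.frame(
        segment = sh$segment, pos = pos, upper = NA, cn = cn[sh$segment],
        is_shift = TRUE, vaf_a = sh$vaf_a, vaf_b = sh$vaf_b))
    }
  }
  alleles <- matrix(c("A", "C", "G", "T"), ncol = 1)
  refb <- sample(alleles, nrow(loci), replace = TRUE)
  altb <- vapply(refb, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
  # counts: sample-specific draws
  set.seed(plan$seed + 3L +
             1000000L * (match(plan$sample_tag, c("a", "b")) - 1L))
  tumor_depth <- rpois(nrow(loci),
                       plan$snv_depth * (2 + loci$cn) / 2)
  tumor_depth <- pmax(tumor_depth, 1L)
  # copies are counted relative to one set of chromosomes, so the
  # amplified haplotype of a het SNV has expected alt:ref = CN:1 on the
  # upper branch; an unamplified segment (CN 0) stays at 1:1
  cn1 <- pmax(loci$cn, 1)
  p_alt <- ifelse(loci$is_shift,
                  if (plan$sample_tag == "a") loci$vaf_a else loci$vaf_b,
                  ifelse(loci$upper, cn1 / (cn1 + 1), 1 / (cn1 + 1)))
  alt <- rbinom(nrow(loci), tumor_depth, p_alt)
  tumor <- as_dm_snvs(data.frame(
    chrom = plan$chrom, pos = loci$pos, ref = refb, alt = altb,
    ref_count = tumor_depth - alt, alt_count = alt,
    origin = ifelse(loci$is_shift, "somatic", "germline"),
    stringsAsFactors = FALSE))
  ndepth <- pmax(rpois(nrow(loci), plan$snv_depth), 1L)
  nalt <- rbinom(nrow(loci), ndepth, ifelse(loci$is_shift, 0, 0.5))
  normal <- as_dm_snvs(data.frame(
    chrom = plan$chrom, pos = loci$pos, ref = refb, alt = altb,
    ref_count = ndepth - nalt, alt_count = nalt,
    origin = ifelse(loci$is_shift, "somatic", "germline"),
    stringsAsFactors = FALSE))
  # truth rows follow the sorted order of the emitted tables
  loci <- loci[order(loci$pos), , drop = FALSE]
  list(tumor = tumor, normal = normal,
       truth = data.frame(segment = loci$segment, pos = loci$pos,
                          branch = ifelse(is.na(loci$upper), "shift",
                                          ifelse(loci$upper, "upper",
                                                 "lower")),
                          cn = loci$cn, is_shift = loci$is_shift))
}

#' Simulate barcode-tagged linked reads
#'
#' Draws long molecules (exponential length around the plan mean,
#' truncated below at 1 kb) along each amplicon circle and along the
#' diploid background, then emits single-end reads every
#' `mol_read_spacing` bp on average, all reads of a molecule sharing its
#' barcode.
#'
#' @param plan an [amplicon_plan()].
#' @param ref a `dm_reference`.
#' @param background_only simulate only diploid background molecules
#'   (for false-positive studies).
#' @return list with `aln` (`dm_alignments`, barcoded) and `truth`
#'   (data.frame of molecules crossing each junction: `structure`,
#'   `junction`, `barcode`).
#' @export
simulate_linked_reads <- function(plan, ref, background_only = FALSE) {
  set.seed(plan$seed + 4L +
             1000000L * (match(plan$sample_tag, c("a", "b")) - 1L))
  L <- plan$read_length
  refseq <- as.character(ref$reference[[plan$chrom]])
  recs <- list()
  truth <- list()
  bc_i <- 0L
  emit_molecules <- function(track, n_mol, circ_juncs = NULL) {
    for (m in seq_len(n_mol)) {
      bc_i <<- bc_i + 1L
      bc <- sprintf("BC%06d", bc_i)
      # exponential length around the mean, truncated below at 1 kb and
      # above at 2.5x the mean (finite high-molecular-weight fragments)
      mlen <- min(track$len, as.integer(2.5 * plan$mol_mean_length),
                  max(1000L, as.integer(rexp(1, 1 / plan$mol_mean_length))))
      mstart <- if (isTRUE(track$circular)) {
        sample.int(track$len, 1L)
      } else sample.int(max(1L, track$len - mlen + 1L), 1L)
      nreads <- max(2L, as.integer(round(mlen / plan$mol_read_spacing)))
      offs <- sort(sample.int(mlen - L + 1L, min(nreads, mlen - L + 1L)))
      p <- mstart + offs - 1L
      r <- map_reads_vec(track, p, "+", L)
      if (any(r$mapped))
        recs[[length(recs) + 1L]] <<- data.frame(
          qname = sprintf("%s_r%d", bc, p[r$mapped]),
          flag = ifelse(r$minus[r$mapped], 16L, 0L), chrom = track$chrom,
          pos = r$pos[r$mapped], mapq = 60L, cigar = r$cigar[r$mapped],
          mate_chrom = NA_character_, mate_pos = NA_integer_,
          isize = 0L, seq = r$seq[r$mapped], barcode = bc,
          stringsAsFactors = FALSE)
      if (!is.null(circ_juncs)) {
        for (ji in seq_len(nrow(circ_juncs))) {
          c0 <- circ_juncs$offset[ji]
          rel <- (mstart - c0 - 1L) %% track$len
          if (rel > track$len - mlen)
            truth[[length(truth) + 1L]] <<- data.frame(
              structure = circ_juncs$structure[ji],
              junction = circ_juncs$junction[ji], barcode = bc,
              stringsAsFactors = FALSE)
        }
      }
    }
  }
  bg_track <- list(units = data.frame(type = "ref", ref_start = 1L,
                                      ref_end = plan$ref_length,
                                      orient = "+", len = plan$ref_length,
                                      offset = 0L),
                   len = plan$ref_length, seq = refseq,
                   circular = FALSE, chrom = plan$chrom)
  n_bg_mol <- round(plan$mol_background_coverage * plan$ref_length /
                      plan$mol_mean_length)
  emit_molecules(bg_track, n_bg_mol)
  if (!background_only) {
    for (si in seq_along(ref$circles)) {
      circ <- ref$circles[[si]]
      if (circ$copies <= 0) next
      track <- c(circ, list(circular = TRUE, chrom = plan$chrom))
      n_mol <- round(plan$mol_coverage * circ$len / plan$mol_mean_length)
      emit_molecules(track, max(n_mol, 5L), circ$junctions)
    }
  }
  aln <- do.call(rbind, recs)
  if (is.null(aln)) aln <- empty_alignments()
  row.names(aln) <- NULL
  class(aln) <- c("dm_alignments", "data.frame")
  list(aln = aln,
       truth = if (length(truth)) do.call(rbind, truth) else NULL)
}
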