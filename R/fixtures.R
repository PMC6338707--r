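## Named, ground-truthed simulation fixtures. Each bundles plans,
## reference, alignments, SNV tables, linked reads and truth tables for
## one study design; all content is derived from the seed.

fixture_plans <- function(name, seed) {
  switch(
    name,
    tiny = list(tumor = amplicon_plan(
      ref_length = 180000,
      segments = data.frame(start = c(20001, 80001),
                            end = c(50000, 120000)),
      structures = list(list(segments = c(1, 2), orients = c("+", "+"),
                             copies = 12)),
      normal_depth = 20, snvs_per_segment = 40, snv_depth = 36,
      mol_mean_length = 8000, seed = seed)),
    bridging = list(tumor = amplicon_plan(
      ref_length = 240000,
      segments = data.frame(start = c(20001, 140001),
                            end = c(50000, 170000)),
      structures = list(list(segments = c(1, 2), orients = c("+", "+"),
                             copies = 10,
                             junctions = c("clean", "bridge"))),
      normal_depth = 20, snvs_per_segment = 40, snv_depth = 36,
      mol_mean_length = 8000, seed = seed)),
    invalid_cycle = list(tumor = amplicon_plan(
      ref_length = 280000,
      segments = data.frame(start = c(20001, 80001, 110001),
                            end = c(56000, 86000, 146000)),
      structures = list(list(segments = c(1, 2, 3),
                             orients = c("+", "+", "+"), copies = 12)),
      decoy_junctions = list(list(seg_a = 2, side_a = "R", seg_b = 1,
                                  side_b = "L", n_softclip = 30,
                                  n_discordant = 15)),
      normal_depth = 20, snvs_per_segment = 40, snv_depth = 36,
      mol_mean_length = 8000, seed = seed)),
    relapse_like = list(tumor = amplicon_plan(
      ref_length = 500000,
      segments = data.frame(
        start = c(20001, 75001, 100001, 150001, 205001, 260001, 315001,
                  380001),
        end = c(45000, 100000, 125000, 175000, 230000, 285000, 340000,
                405000)),
      structures = list(
        list(segments = c(1, 7), orients = c("+", "+"), copies = 16),
        list(segments = c(2, 3, 7), orients = c("+", "+", "+"),
             copies = 23),
        list(segments = c(4, 5), orients = c("+", "-"), copies = 43),
        list(segments = c(6, 8), orients = c("+", "+"), copies = 20),
        list(segments = c(6, 7), orients = c("+", "+"), copies = 13)),
      normal_depth = 8, snvs_per_segment = 250, snv_depth = 36,
      mol_mean_length = 8000, seed = seed)),
    two_timepoint = {
      segs <- data.frame(
        start = c(20001, 55001, 95001, 130001, 170001, 210001),
        end = c(32000, 67000, 107000, 142000, 182000, 222000))
      shifts <- data.frame(segment = 1, n = 4, vaf_a = 0.02,
                           vaf_b = 0.96)
      list(
        a = amplicon_plan(
          ref_length = 300000, segments = segs,
          structures = list(
            list(segments = c(1, 2), orients = c("+", "+"), copies = 24),
            list(segments = c(3, 4), orients = c("+", "+"), copies = 18)),
          somatic_shifts = shifts, sample_tag = "a",
          normal_depth = 20, snvs_per_segment = 40, snv_depth = 36,
          seed = seed),
        b = amplicon_plan(
          ref_length = 300000, segments = segs,
          structures = list(
            list(segments = c(1, 2), orients = c("+", "+"), copies = 43),
            list(segments = c(5, 6), orients = c("+", "+"), copies = 20)),
          somatic_shifts = shifts, sample_tag = "b",
          normal_depth = 20, snvs_per_segment = 40, snv_depth = 36,
          seed = seed))
    },
    stop("unknown fixture '", name, "'; choices: tiny, relapse_like, ",
         "bridging, invalid_cycle, two_timepoint"))
}

# background (diploid) segments filling the gaps between planted ones
background_segments <- function(plan) {
  s <- plan$segments[order(plan$segments$start), ]
  gaps <- data.frame(start = c(1, s$end + 1),
                     end = c(s$start - 1, plan$ref_length))
  gaps <- gaps[gaps$end - gaps$start + 1 >= 5000, , drop = FALSE]
  n <- min(plan$n_background_segments, nrow(gaps))
  if (!n) return(NULL)
  g <- gaps[order(-(gaps$end - gaps$start))[seq_len(n)], , drop = FALSE]
  # trim so background segments stay clear of boundary flank windows
  data.frame(start = g$start + 2000, end = g$end - 2000)
}

assemble_sample <- function(plan, with_linked = TRUE) {
  ref <- build_reference(plan)
  als <- simulate_alignments(plan, ref)
  snvs <- simulate_snvs(plan)
  linked <- if (with_linked) simulate_linked_reads(plan, ref) else NULL
  bg <- background_segments(plan)
  tab <- rbind(data.frame(start = plan$segments$start,
                          end = plan$segments$end),
               bg)
  tab$chrom <- plan$chrom
  segtab <- as_dm_segments(tab)
  segtab <- compute_segment_log2r(als$tumor, als$normal, segtab)
  seg_id_map <- vapply(seq_len(nrow(plan$segments)), function(k)
    segtab$id[segtab$start == plan$segments$start[k]], 1L)
  tj <- ref$truth_junctions
  if (!is.null(tj)) {
    tj$seg_a_tid <- seg_id_map[tj$seg_a]
    tj$seg_b_tid <- seg_id_map[tj$seg_b]
  }
  list(plan = plan, ref = ref, tumor_aln = als$tumor,
       normal_aln = als$normal, truth_supporters = als$truth_supporters,
       snvs_tumor = snvs$tumor, snvs_normal = snvs$normal,
       snv_truth = snvs$truth,
       linked_aln = if (with_linked) linked$aln else NULL,
       linked_truth = if (with_linked) linked$truth else NULL,
       segments = segtab, seg_id_map = seg_id_map,
       truth_junctions = tj)
}

#' Build a named simulation fixture
#'
#' Five bundled study designs exercise the whole pipeline: `tiny` (one
#' two-segment circle; end-to-end in seconds), `relapse_like` (five
#' structures with distinct copy numbers sharing segments, one of them
#' quantifiable only by shared-segment subtraction), `bridging` (a
#' junction whose intervening fragment is flanked by unmappable sequence,
#' recoverable only as bridging evidence), `invalid_cycle` (fabricated
#' junction evidence admitting a cycle that linked reads refute) and
#' `two_timepoint` (a conserved structure with somatic VAF-shift SNVs
#' plus time-point-specific structures).
#'
#' @param name one of `"tiny"`, `"relapse_like"`, `"bridging"`,
#'   `"invalid_cycle"`, `"two_timepoint"`.
#' @param seed integer seed; fixed seed gives identical content.
#' @param out_dir optional directory; when given the fixture is also
#'   written to disk via [write_fixture()].
#' @param with_linked simulate linked reads (default TRUE except for
#'   `two_timepoint`).
#' @return A `dm_fixture` list: `name`, `samples` (one entry per sample,
#'   each with plan, reference, alignments, SNV tables, segment table
#'   and truth tables).
#' @export
make_fixture <- function(name, seed = 1L, out_dir = NULL,
                         with_linked = name %in% c("tiny", "bridging",
                                                   "invalid_cycle")) {
  plans <- fixture_plans(name, seed)
  samples <- lapply(plans, assemble_sample, with_linked = with_linked)
  fx <- structure(list(name = name, seed = seed, samples = samples),
                  class = "dm_fixture")
  if (!is.null(out_dir)) write_fixture(fx, out_dir)
  fx
}

#' @export
print.dm_fixture <- function(x, ...) {
  cat(sprintf("fixture '%s' (seed %d): %d sample(s)\n", x$name, x$seed,
              length(x$samples)))
  for (nm in names(x$samples)) {
    s <- x$samples[[nm]]
    cat(sprintf("  %s: %d planted segments, %d structures, %d tumor records\n",
                nm, nrow(s$plan$segments), length(s$plan$structures),
                nrow(s$tumor_aln)))
  }
  invisible(x)
}

#' Write a fixture to a directory
#'
#' Emits, per sample: the reference FASTA (shared), tumor/normal/linked
#' SAM files, the segment table TSV, SNV TSVs and a truth JSON with the
#' planted junctions and structure copy numbers.
#'
#' @param fixture a `dm_fixture`.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  first <- fixture$samples[[1]]
  Biostrings::writeXStringSet(first$ref$reference,
                              file.path(dir, "reference.fa"))
  for (nm in names(fixture$samples)) {
    s <- fixture$samples[[nm]]
    pre <- if (length(fixture$samples) > 1) paste0(nm, "_") else ""
    rl <- setNames(s$plan$ref_length, s$plan$chrom)
    write_sam(s$tumor_aln, file.path(dir, paste0(pre, "tumor.sam")), rl)
    write_sam(s$normal_aln, file.path(dir, paste0(pre, "normal.sam")), rl)
    if (!is.null(s$linked_aln))
      write_sam(s$linked_aln, file.path(dir, paste0(pre, "linked.sam")),
                rl)
    write_report(s$segments, file.path(dir, paste0(pre, "segments.tsv")),
                 "tsv", sort_by = "id")
    write_report(s$snvs_tumor,
                 file.path(dir, paste0(pre, "snvs_tumor.tsv")), "tsv",
                 sort_by = c("chrom", "pos"))
    truth <- list(junctions = s$truth_junctions,
                  copies = lapply(s$plan$structures, `[[`, "copies"))
    jsonlite::write_json(truth, file.path(dir, paste0(pre, "truth.json")),
                         dataframe = "rows", auto_unbox = TRUE,
                         na = "null")
  }
  invisible(dir)
}
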