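mk_snvs <- function(pos, alt, ref, origin = "germline", chrom = "chr1") {
  as_dm_snvs(data.frame(chrom = chrom, pos = pos, ref = "A", alt = "T",
                        ref_count = ref, alt_count = alt,
                        origin = origin))
}

test_that("SNV-to-segment assignment matches a brute-force containment scan", {
  set.seed(21)
  segs <- as_dm_segments(data.frame(chrom = "chr1",
                                    start = c(1000, 5000, 20000),
                                    end = c(2000, 9000, 30000),
                                    log2r = 5))
  pos <- sample(35000, 1000)
  snvs <- mk_snvs(pos, alt = 5, ref = 5)
  got <- suppressMessages(assign_snvs_to_segments(snvs, segs))
  oracle <- vapply(snvs$pos, function(p) {
    hit <- which(segs$start <= p & segs$end >= p)
    if (length(hit)) segs$id[hit] else NA_integer_
  }, 1L)
  expect_equal(nrow(got), sum(!is.na(oracle)))
  expect_equal(got$segment_id, oracle[!is.na(oracle)])

  # boundary inclusivity: on the edge in, one past out
  edge <- mk_snvs(c(2000, 2001), alt = 5, ref = 5)
  g2 <- suppressMessages(assign_snvs_to_segments(edge, segs))
  expect_equal(g2$pos, 2000)

  over <- as_dm_segments(data.frame(chrom = "chr1",
                                    start = c(1000, 1500),
                                    end = c(2000, 2500), log2r = 5))
  expect_error(assign_snvs_to_segments(snvs, over), "overlapping")
})

test_that("branch selection keeps VAF > 0.5 and excludes exact ties", {
  snvs <- mk_snvs(1:4, alt = c(96, 4, 50, 60), ref = c(4, 96, 50, 40))
  br <- select_amplified_alt_branch(snvs)
  expect_equal(sort(br$upper$pos), c(1, 4))
  expect_equal(br$lower$pos, 2)
  expect_equal(br$n_ties, 1)
  som <- mk_snvs(9, alt = 90, ref = 10, origin = "somatic")
  expect_equal(nrow(select_amplified_alt_branch(som)$upper), 0)
})

test_that("the median allele-ratio estimator behaves on constants, filters and errors", {
  const <- mk_snvs(1:3, alt = 43 * 10, ref = 10)
  est <- estimate_copies_from_ratios(const, target = "dmIII")
  expect_equal(est$copies_per_cell, 43)
  expect_equal(est$n_snvs, 3)

  # zero-reference SNVs are excluded, and all-zero-reference errors
  mixed <- mk_snvs(1:3, alt = c(20, 20, 50), ref = c(1, 1, 0))
  est2 <- suppressMessages(estimate_copies_from_ratios(mixed))
  expect_equal(est2$n_snvs, 2)
  allzero <- mk_snvs(1:2, alt = 50, ref = 0)
  expect_error(suppressMessages(estimate_copies_from_ratios(allzero)),
               "no informative")

  # low-depth SNVs are dropped by the depth filter
  lowd <- mk_snvs(1:3, alt = c(4, 400, 400), ref = c(1, 10, 10))
  est3 <- suppressMessages(estimate_copies_from_ratios(lowd,
                                                       min_depth = 10))
  expect_equal(est3$n_snvs, 2)
})

test_that("the median estimator is order-invariant and outlier-robust", {
  set.seed(31)
  alt <- rpois(50, 200); ref <- rpois(50, 10) + 1
  snvs <- mk_snvs(seq_len(50), alt = alt, ref = ref)
  e1 <- estimate_copies_from_ratios(snvs)
  perm <- snvs[sample(50), ]
  expect_equal(estimate_copies_from_ratios(perm)$copies_per_cell,
               e1$copies_per_cell)
  # replace 20% of ratios with wild outliers: median moves only within
  # the bulk of the distribution
  out <- snvs
  out$alt_count[1:10] <- 1e6
  e2 <- estimate_copies_from_ratios(out)
  expect_lt(abs(e2$copies_per_cell - e1$copies_per_cell),
            0.2 * e1$copies_per_cell)
})

test_that("planted copy numbers 5/20/50 are recovered within 15% and in order", {
  ests <- vapply(c(5, 20, 50), function(cn) {
    plan <- amplicon_plan(ref_length = 60000,
                          segments = data.frame(start = 10001, end = 30000),
                          structures = list(list(segments = 1,
                                                 orients = "+",
                                                 copies = cn)),
                          snvs_per_segment = 200, normal_depth = 30,
                          seed = 4L)
    sim <- simulate_snvs(plan)
    br <- select_amplified_alt_branch(sim$tumor)
    suppressMessages(
      estimate_copies_from_ratios(br$upper)$copies_per_cell)
  }, 1)
  expect_equal(ests, c(5, 20, 50), tolerance = 0.15)
  expect_true(all(diff(ests) > 0))
})

test_that("recoding alt and ref mirrors the branches symmetrically", {
  plan <- amplicon_plan(ref_length = 60000,
                        segments = data.frame(start = 10001, end = 30000),
                        structures = list(list(segments = 1, orients = "+",
                                               copies = 20)),
                        snvs_per_segment = 300, normal_depth = 30,
                        seed = 9L)
  sim <- simulate_snvs(plan)
  flipped <- sim$tumor
  tmp <- flipped$alt_count
  flipped$alt_count <- flipped$ref_count
  flipped$ref_count <- tmp
  flipped <- as_dm_snvs(flipped)
  b1 <- select_amplified_alt_branch(sim$tumor)
  b2 <- select_amplified_alt_branch(flipped)
  expect_equal(nrow(b2$upper), nrow(b1$lower))
  # the mirrored branch's ratio estimate agrees within sampling noise
  e1 <- suppressMessages(estimate_copies_from_ratios(b1$upper))
  low <- b2$upper
  e2 <- suppressMessages(estimate_copies_from_ratios(low))
  expect_equal(e2$copies_per_cell, e1$copies_per_cell, tolerance = 0.2)
})

test_that("shared-segment subtraction reproduces the worked examples", {
  expect_equal(shared_segment_subtraction(33, 20), 13)
  expect_equal(shared_segment_subtraction(57, c(23, 20)), 14)
  expect_equal(suppressWarnings(shared_segment_subtraction(10, 10)), 0)
  expect_warning(shared_segment_subtraction(10, 12), "clamped")
})

test_that("sub-segment presence fractions match the worked example", {
  expect_equal(fraction_by_subsegment_presence(19, 15, 24), 16.7)
  expect_equal(fraction_by_subsegment_presence(15, 15, 24), 0)
  expect_equal(fraction_by_subsegment_presence(24, 0, 24), 100)
  expect_error(fraction_by_subsegment_presence(19, 15, 0), "positive")
  expect_error(fraction_by_subsegment_presence(10, 15, 24), ">=")
})

test_that("location intersection equals a hash-join oracle", {
  a <- mk_snvs(c(10, 20, 30), alt = 5, ref = 5)
  expect_equal(nrow(intersect_snvs_by_location(a, a)), 3)
  b <- mk_snvs(c(40, 50), alt = 5, ref = 5)
  expect_equal(nrow(intersect_snvs_by_location(a, b)), 0)

  set.seed(13)
  x <- mk_snvs(sample(1000, 200), alt = 5, ref = 5)
  y <- mk_snvs(sample(1000, 200), alt = 7, ref = 3)
  got <- intersect_snvs_by_location(x, y)
  oracle <- intersect(paste(x$chrom, x$pos), paste(y$chrom, y$pos))
  expect_equal(nrow(got), length(oracle))
  expect_setequal(paste(got$chrom, got$pos), oracle)
  expect_equal(attr(got, "n_only_a"), 200 - length(oracle))
})

test_that("VAF-shift flagging equals the threshold predicate in both directions", {
  paired <- data.frame(chrom = "chr1", pos = 1:6, ref = "A", alt = "T",
                       origin = "somatic",
                       ref_count_a = 10, alt_count_a = 1,
                       vaf_a = c(0.02, 0.96, 0.95, 0.5, 0.10, 0.9),
                       ref_count_b = 1, alt_count_b = 10,
                       vaf_b = c(0.96, 0.95, 0.02, 0.5, 0.90, 0.1))
  fl <- detect_vaf_shift(paired)
  expect_equal(fl$pos, c(1, 3, 5, 6))
  expect_equal(fl$direction, c("gain_in_b", "gain_in_a", "gain_in_b",
                               "gain_in_a"))
  # sweep: flags equal the predicate applied pairwise
  set.seed(17)
  sweep <- data.frame(chrom = "chr1", pos = 1:500, ref = "A", alt = "T",
                      origin = "germline", ref_count_a = 1,
                      alt_count_a = 1, vaf_a = runif(500),
                      ref_count_b = 1, alt_count_b = 1,
                      vaf_b = runif(500))
  fl2 <- detect_vaf_shift(sweep, low_max = 0.2, high_min = 0.8)
  pred <- (sweep$vaf_a <= 0.2 & sweep$vaf_b >= 0.8) |
    (sweep$vaf_b <= 0.2 & sweep$vaf_a >= 0.8)
  expect_equal(sort(fl2$pos), sweep$pos[pred])
})
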