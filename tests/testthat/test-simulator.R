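small_plan <- function(seed = 3L, copies = 15, junctions = NULL) {
  amplicon_plan(ref_length = 80000,
                segments = data.frame(start = c(10001, 40001),
                                      end = c(22000, 55000)),
                structures = list(list(segments = c(1, 2),
                                       orients = c("+", "+"),
                                       copies = copies,
                                       junctions = junctions)),
                normal_depth = 10, snvs_per_segment = 20,
                mol_mean_length = 6000, seed = seed)
}

test_that("reference building records planted intervals and junction truth", {
  plan <- amplicon_plan(ref_length = 100000,
                        segments = data.frame(
                          start = c(10001, 30001, 60001),
                          end = c(20000, 40000, 70000)),
                        structures = list(list(segments = 1:3,
                                               orients = c("+", "-", "+"),
                                               copies = 10)),
                        seed = 2L)
  ref <- build_reference(plan)
  expect_equal(length(ref$reference[[1]]), 100000)
  tj <- ref$truth_junctions
  expect_equal(nrow(tj), 3)
  # orientation follows the planted segment orientations
  expect_equal(tj$side_a, c("R", "L", "R"))
  expect_equal(tj$side_b, c("R", "L", "L"))
  expect_equal(tj$orientation, c("head_to_head", "tail_to_tail",
                                 "head_to_tail"))

  bad <- plan
  bad$segments$start[2] <- 15000
  expect_error(amplicon_plan(ref_length = 1e5, segments = bad$segments,
                             structures = plan$structures),
               "overlap")
})

test_that("fixed seeds reproduce byte-identical simulations", {
  p1 <- small_plan(seed = 8L)
  r1 <- build_reference(p1)
  r2 <- build_reference(small_plan(seed = 8L))
  expect_identical(as.character(r1$reference), as.character(r2$reference))
  a1 <- simulate_alignments(p1, r1)
  a2 <- simulate_alignments(small_plan(seed = 8L), r2)
  expect_identical(a1$tumor, a2$tumor)
  expect_identical(a1$normal, a2$normal)
  s1 <- simulate_snvs(p1); s2 <- simulate_snvs(small_plan(seed = 8L))
  expect_identical(s1$tumor, s2$tumor)
  l1 <- simulate_linked_reads(p1, r1)
  l2 <- simulate_linked_reads(small_plan(seed = 8L), r2)
  expect_identical(l1$aln, l2$aln)
  # and written fixtures are byte-identical too
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  fx <- structure(list(name = "custom", seed = 8L,
                       samples = list(tumor = circamp:::assemble_sample(p1))),
                  class = "dm_fixture")
  write_fixture(fx, d1)
  write_fixture(fx, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), info = f)
  }
})

test_that("a clean junction at high copy number yields dozens of supporters", {
  plan <- small_plan(copies = 20)
  ref <- build_reference(plan)
  sim <- simulate_alignments(plan, ref)
  sup <- sim$truth_supporters
  tab <- table(sup$junction, sup$class)
  expect_true(all(tab[, "softclip"] >= 24))
  expect_true(all(tab[, "discordant"] >= 24))
  # truth-table conservation: one class per template per junction
  expect_false(any(duplicated(sup[c("junction", "qname")])))
})

test_that("without an amplicon the tumor matches the normal and has no junction reads", {
  plan <- small_plan(copies = 0)
  ref <- build_reference(plan)
  sim <- simulate_alignments(plan, ref)
  expect_null(sim$truth_supporters)
  expect_equal(nrow(sim$tumor), nrow(sim$normal), tolerance = 0.02)
  expect_false(any(grepl("S", sim$tumor$cigar)))
})

test_that("unmappable-gap junctions are bridging-only by construction", {
  plan <- small_plan(junctions = c("clean", "bridge"))
  ref <- build_reference(plan)
  sim <- simulate_alignments(plan, ref)
  sup <- sim$truth_supporters
  bridge_j <- ref$truth_junctions$junction[
    ref$truth_junctions$type == "bridge"]
  expect_length(bridge_j, 1)
  cls <- sup$class[sup$junction == bridge_j]
  expect_false(any(cls == "softclip"))
  expect_true(sum(cls == "bridging") > 0)
})

test_that("binomial SNV counts track the planted copy number", {
  plan <- amplicon_plan(ref_length = 60000,
                        segments = data.frame(start = 10001, end = 30000),
                        structures = list(list(segments = 1, orients = "+",
                                               copies = 43)),
                        snvs_per_segment = 400, normal_depth = 30,
                        seed = 6L)
  sim <- simulate_snvs(plan)
  upper <- sim$tumor[sim$truth$branch == "upper", ]
  expect_equal(mean(upper$vaf), 43 / 44, tolerance = 0.01)
  lower <- sim$tumor[sim$truth$branch == "lower", ]
  expect_equal(mean(lower$vaf), 1 / 44, tolerance = 0.25)
  # normal counts stay heterozygous
  expect_equal(mean(sim$normal$vaf[sim$truth$branch != "shift"]), 0.5,
               tolerance = 0.03)
})

test_that("unamplified segments draw heterozygous counts", {
  plan <- amplicon_plan(ref_length = 60000,
                        segments = data.frame(start = 10001, end = 30000),
                        structures = list(list(segments = 1, orients = "+",
                                               copies = 0)),
                        snvs_per_segment = 300, normal_depth = 30,
                        seed = 6L)
  sim <- simulate_snvs(plan)
  expect_equal(mean(sim$tumor$vaf), 0.5, tolerance = 0.03)
})

test_that("somatic shift specs plant exactly the requested flagged SNVs", {
  shifts <- data.frame(segment = 1, n = 4, vaf_a = 0.02, vaf_b = 0.96)
  mk <- function(tag) amplicon_plan(
    ref_length = 60000, segments = data.frame(start = 10001, end = 30000),
    structures = list(list(segments = 1, orients = "+", copies = 30)),
    somatic_shifts = shifts, sample_tag = tag, snvs_per_segment = 50,
    normal_depth = 30, seed = 12L)
  sa <- simulate_snvs(mk("a"))
  sb <- simulate_snvs(mk("b"))
  expect_equal(sum(sa$truth$is_shift), 4)
  # loci shared across sample tags
  expect_equal(sa$tumor$pos, sb$tumor$pos)
  sh_a <- sa$tumor[sa$truth$is_shift, ]
  sh_b <- sb$tumor[sb$truth$is_shift, ]
  expect_true(all(sh_a$vaf < 0.1))
  expect_true(all(sh_b$vaf > 0.9))
})

test_that("unknown fixture names list the available choices", {
  expect_error(make_fixture("nope"), "tiny, relapse_like")
})
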