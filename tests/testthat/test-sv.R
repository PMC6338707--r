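# Hand-built two-segment reference for unit-level evidence tests:
# segment 1 = [2001, 6000], segment 2 = [10001, 14000] on a 20 kb contig.
sv_setup <- function(seed = 11, third_segment = FALSE) {
  set.seed(seed)
  refseq <- paste(sample(c("A", "C", "G", "T"), 20000, replace = TRUE),
                  collapse = "")
  segs <- data.frame(chrom = "chr1", start = c(2001, 10001),
                     end = c(6000, 14000), log2r = 5)
  if (third_segment) {
    # duplicate segment 2's L-flank sequence around a third boundary so
    # clip placement becomes ambiguous
    refseq <- paste0(substr(refseq, 1, 15000),
                     substr(refseq, 9001, 11000),
                     substr(refseq, 17001, 20000))
    segs <- rbind(segs, data.frame(chrom = "chr1", start = 16001,
                                   end = 18000, log2r = 5))
  }
  list(ref = Biostrings::DNAStringSet(c(chr1 = refseq)),
       refseq = refseq,
       segs = as_dm_segments(segs))
}

rc1 <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

test_that("boundary windows include exactly the overlapping reads", {
  p <- dm_params()
  b <- data.frame(segment_id = 1, side = "R", position = 100,
                  chrom = "chr1")
  near <- mk_aln("in", pos = 60)       # spans [60, 159]
  far <- mk_aln("out", pos = 200)      # spans [200, 299]
  aln <- rbind(near, far)
  got <- reads_near_boundary(aln, b, p)
  expect_equal(got$qname, "in")
})

test_that("a uniquely placed clip yields oriented evidence with breakpoints", {
  su <- sv_setup()
  p <- dm_params()
  b <- dm_boundaries(su$segs)
  # head-to-tail: retained [.., 6000] then continues at [10001, ..]
  seqht <- paste0(substr(su$refseq, 5951, 6000),
                  substr(su$refseq, 10001, 10050))
  ht <- mk_aln("ht1", pos = 5951L, cigar = "50M50S", seq = seqht)
  inc <- circamp:::softclip_scan(ht, b, su$ref, p)
  expect_equal(nrow(inc), 1)
  expect_equal(inc$seg_a, 1); expect_equal(inc$side_a, "R")
  expect_equal(inc$seg_b, 2); expect_equal(inc$side_b, "L")
  expect_equal(inc$breakpoint_a, 6000)
  expect_equal(inc$breakpoint_b, 10001)

  # head-to-head: continues into segment 2 read leftward from its R end
  seqhh <- paste0(substr(su$refseq, 5951, 6000),
                  rc1(substr(su$refseq, 13951, 14000)))
  hh <- mk_aln("hh1", pos = 5951L, cigar = "50M50S", seq = seqhh)
  inc2 <- circamp:::softclip_scan(hh, b, su$ref, p)
  expect_equal(inc2$side_b, "R")
  expect_equal(inc2$breakpoint_b, 14000)
  expect_equal(orientation_from_sides(inc2$side_a, inc2$side_b),
               "head_to_head")

  # the same junction seen from the partner side: left clip at 2L... and
  # a tail-to-tail junction entering segment 1 at its L boundary
  seqtt <- paste0(rc1(substr(su$refseq, 2001, 2050)),
                  substr(su$refseq, 10001, 10050))
  tt <- mk_aln("tt1", pos = 10001L, cigar = "50S50M", seq = seqtt)
  inc3 <- circamp:::softclip_scan(tt, b, su$ref, p)
  expect_equal(inc3$seg_a, 2); expect_equal(inc3$side_a, "L")
  expect_equal(inc3$seg_b, 1); expect_equal(inc3$side_b, "L")
  expect_equal(orientation_from_sides(inc3$side_a, inc3$side_b),
               "tail_to_tail")
})

test_that("ambiguous clips (duplicated flank) and unclipped reads give nothing", {
  su <- sv_setup(third_segment = TRUE)
  p <- dm_params()
  b <- dm_boundaries(su$segs)
  seqht <- paste0(substr(su$refseq, 5951, 6000),
                  substr(su$refseq, 10001, 10050))
  amb <- mk_aln("amb", pos = 5951L, cigar = "50M50S", seq = seqht)
  expect_equal(nrow(circamp:::softclip_scan(amb, b, su$ref, p)), 0)

  plain <- mk_aln("m", pos = 5951L, cigar = "100M",
                  seq = substr(su$refseq, 5951, 6050))
  expect_equal(nrow(circamp:::softclip_scan(plain, b, su$ref, p)), 0)
})

test_that("discordant pairs need distance, flank placement and one count per template", {
  su <- sv_setup()
  p <- dm_params()
  b <- dm_boundaries(su$segs)
  seq100 <- substr(su$refseq, 5951, 6050)
  # mate only 450 bp away: concordant
  close <- mk_aln("c1", flag = 1L + 32L, pos = 5951L, seq = seq100,
                  mate_pos = 6400L)
  expect_equal(nrow(circamp:::discordant_scan(close, b, p)), 0)
  # mate in the partner boundary's 1 kb flank, > 800 bp away
  far <- mk_aln("d1", flag = 1L + 32L, pos = 5951L, seq = seq100,
                mate_pos = 10100L)
  inc <- circamp:::discordant_scan(far, b, p)
  expect_equal(nrow(inc), 1)
  expect_equal(paste0(inc$seg_a, inc$side_a, inc$seg_b, inc$side_b),
               "1R2L")
  # both records of the same template: still one count
  both <- rbind(far,
                mk_aln("d1", flag = 1L + 16L, pos = 10080L,
                       seq = substr(su$refseq, 10080, 10179),
                       mate_pos = 5951L))
  agg <- circamp:::aggregate_increments(circamp:::discordant_scan(both, b, p))
  expect_equal(nrow(agg), 1)
})

test_that("interchromosomal mates near a boundary flank count as discordant", {
  segs <- as_dm_segments(data.frame(chrom = c("chr7", "chr8"),
                                    start = c(2001, 5001),
                                    end = c(6000, 9000), log2r = 5))
  b <- dm_boundaries(segs)
  p <- dm_params()
  r <- mk_aln("x1", flag = 1L + 32L, chrom = "chr7", pos = 5951L,
              mate_chrom = "chr8", mate_pos = 5100L)
  inc <- circamp:::discordant_scan(r, b, p)
  expect_equal(nrow(inc), 1)
  expect_equal(inc$seg_b, 2)
  expect_equal(inc$side_b, "L")
})

test_that("bridging needs nearby, strand-opposed free mate clusters", {
  su <- sv_setup()
  p <- dm_params()
  b <- dm_boundaries(su$segs)
  mk_side <- function(qn, pos, flag, mpos)
    mk_aln(qn, flag = flag, pos = pos,
           seq = substr(su$refseq, pos, pos + 99), mate_pos = mpos)
  a_reads <- do.call(rbind, lapply(1:4, function(i)
    mk_side(paste0("a", i), 5930L + i, 1L + 32L, 17000L + i * 10L)))
  b_reads <- do.call(rbind, lapply(1:4, function(i)
    mk_side(paste0("b", i), 9960L + i, 1L + 16L, 17200L + i * 10L)))
  inc <- circamp:::bridging_scan(rbind(a_reads, b_reads), b, p)
  expect_equal(sort(unique(paste0(inc$seg_a, inc$side_a,
                                  inc$seg_b, inc$side_b))), "1R2L")
  expect_equal(length(unique(inc$qname)), 8)

  # clusters 12 kb apart exceed the bridge distance
  b_far <- do.call(rbind, lapply(1:4, function(i)
    mk_side(paste0("f", i), 9960L + i, 1L + 16L, 29000L + i * 10L)))
  inc2 <- circamp:::bridging_scan(rbind(a_reads, b_far), b, p)
  expect_equal(nrow(inc2), 0)

  # same-strand mate clusters are not a single intervening fragment
  b_same <- do.call(rbind, lapply(1:4, function(i)
    mk_side(paste0("s", i), 9960L + i, 1L + 16L + 32L, 17200L + i * 10L)))
  inc3 <- circamp:::bridging_scan(rbind(a_reads, b_same), b, p)
  expect_equal(nrow(inc3), 0)
})

test_that("collected evidence matches the planted truth on the tiny fixture", {
  fx <- get_fixture("tiny")
  s <- fx$samples$tumor
  res <- run_fixture("tiny")
  sv <- res$sv
  tj <- s$truth_junctions
  expect_equal(nrow(sv), nrow(tj))
  key <- function(a, sa, bb, sb)
    paste(pmin(paste0(a, sa), paste0(bb, sb)),
          pmax(paste0(a, sa), paste0(bb, sb)))
  expect_setequal(key(sv$seg_a, sv$side_a, sv$seg_b, sv$side_b),
                  key(tj$seg_a_tid, tj$side_a, tj$seg_b_tid, tj$side_b))
  m <- match(key(sv$seg_a, sv$side_a, sv$seg_b, sv$side_b),
             key(tj$seg_a_tid, tj$side_a, tj$seg_b_tid, tj$side_b))
  expect_equal(sv$orientation, tj$orientation[m])
  # soft-clip breakpoints are exact
  expect_equal(sort(c(sv$breakpoint_a, sv$breakpoint_b)),
               sort(c(tj$breakpoint_a, tj$breakpoint_b)))
  # per-junction soft-clip counts equal the simulator's truth table
  sup <- s$truth_supporters
  tab <- table(sup$junction[sup$class == "softclip"])
  expect_equal(sv$softclip_count,
               as.integer(tab[as.character(tj$junction[m])]))
})

test_that("evidence collection is invariant to record order and scan side", {
  fx <- get_fixture("tiny")
  s <- fx$samples$tumor
  res <- run_fixture("tiny")
  set.seed(3)
  shuffled <- s$tumor_aln[sample(nrow(s$tumor_aln)), ]
  class(shuffled) <- c("dm_alignments", "data.frame")
  sv2 <- collect_sv_evidence(shuffled, res$amplified, s$ref$reference,
                             res$params)
  expect_equal(as.data.frame(sv2), as.data.frame(res$sv))
})

test_that("breakpoint search reports known SVs absent from the matched normal", {
  fx <- get_fixture("tiny")
  s <- fx$samples$tumor
  res <- run_fixture("tiny")
  p <- res$params
  in_normal <- search_breakpoints_in_sample(s$normal_aln, res$sv,
                                            res$amplified,
                                            s$ref$reference, p)
  expect_true(all(in_normal$status == "absent"))
  expect_true(all(in_normal$other_softclip == 0))
  in_tumor <- search_breakpoints_in_sample(s$tumor_aln, res$sv,
                                           res$amplified,
                                           s$ref$reference, p)
  expect_true(all(in_tumor$status == "present"))
})
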