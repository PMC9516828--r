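# Evidence: depth computation, the half-diploid rule, gap and depth-gap
# signals, discordant+concordant anchoring, and the confirmation policy.

test_that("compute_depth conserves read bases and honors exclusions", {
  a <- assembly_index(c(s1 = strrep("A", 500)))
  one <- aln_row("s1", 100, 200, "s1", 300, 400)
  d <- compute_depth(one, a)
  expect_equal(sum(d$coverage$s1), 200)  # two 100 bp mates
  expect_equal(sum(d$coverage$s1[101:200]), 100)
  expect_equal(d$coverage$s1[250], 0L)

  dup <- aln_row("s1", 100, 200, "s1", 300, 400, dup = TRUE)
  expect_equal(sum(compute_depth(dup, a)$coverage$s1), 0)

  ambig <- aln_row("s1", 100, 200, "s1", 300, 400, mapq1 = 0L)
  expect_equal(sum(compute_depth(ambig, a)$coverage$s1), 100)
  expect_equal(sum(compute_depth(ambig, a, min_mapq = 0)$coverage$s1), 200)

  two <- rbind(one, aln_row("s1", 150, 250, NA))
  d2 <- compute_depth(two, a)
  expect_equal(d2$coverage$s1[175], 2L)
  expect_equal(d2$total_aligned_bases, 300)

  oob <- aln_row("s1", 450, 550, NA)
  d3 <- compute_depth(oob, a)
  expect_equal(d3$rejected, 1)
})

test_that("the half-diploid depth rule is strict", {
  cov <- list(s1 = c(rep(29L, 100), rep(30L, 100), rep(0L, 100)))
  depth <- make_depth(cov)
  cut <- make_cutoffs(60)
  pairs <- rbind(toy_pair("s1", 0, 100, "s1", 100, 200),
                 toy_pair("s1", 100, 200, "s1", 200, 300))
  pairs$confirmed <- NULL
  out <- depth_filter(pairs, depth, cut)
  expect_equal(out$depthA, c(29, 30))
  expect_true(out$low_depth[1])    # 29 < 30
  expect_true(out$low_depth[2])    # member at 0 qualifies via "either"
  out_both <- depth_filter(pairs, depth, cut, member_rule = "both")
  expect_false(out_both$low_depth[2])  # 30 == half fails the strict rule

  solo <- depth_filter(toy_pair("s1", 100, 200, "s1", 100, 200), depth, cut)
  expect_false(solo$low_depth)     # exactly the boundary: not flagged
})

test_that("gap evidence distinguishes assembly gaps and depth gaps", {
  seq <- paste0(strrep("A", 40000), strrep("N", 100), strrep("C", 20000))
  a <- assembly_index(c(s1 = seq))
  cov <- list(s1 = rep(30L, nchar(seq)))
  cov$s1[40001:40100] <- 0L  # the N gap is uncovered
  pair <- toy_pair("s1", 30000, 40000, "s1", 40100, 50000)
  g <- gap_evidence(pair, a, make_depth(cov))
  expect_true(g$assembly_gap)
  expect_true(g$depth_gap)

  # continuous coverage, no gap between the copies
  a2 <- assembly_index(c(s1 = strrep("A", 60000)))
  cov2 <- list(s1 = rep(30L, 60000))
  g2 <- gap_evidence(toy_pair("s1", 10000, 20000, "s1", 30000, 40000),
                     a2, make_depth(cov2))
  expect_false(g2$assembly_gap)
  expect_false(g2$depth_gap)

  # a zero-coverage window between the copies is a depth gap on its own
  cov3 <- list(s1 = rep(30L, 60000))
  cov3$s1[25001:25200] <- 0L
  g3 <- gap_evidence(toy_pair("s1", 10000, 20000, "s1", 30000, 40000),
                     a2, make_depth(cov3))
  expect_false(g3$assembly_gap)
  expect_true(g3$depth_gap)

  # different-scaffold pair: zero coverage at the copy's contig end
  a4 <- assembly_index(c(s1 = strrep("A", 40000), s2 = strrep("C", 5000)))
  cov4 <- list(s1 = rep(30L, 40000), s2 = c(0L, rep(28L, 4999)))
  g4 <- gap_evidence(toy_pair("s1", 10000, 15000, "s2", 0, 5000),
                     a4, make_depth(cov4))
  expect_true(g4$depth_gap)
  cov5 <- list(s1 = rep(30L, 40000), s2 = rep(28L, 5000))
  g5 <- gap_evidence(toy_pair("s1", 10000, 15000, "s2", 0, 5000),
                     a4, make_depth(cov5))
  expect_false(g5$depth_gap)
})

test_that("discordant evidence needs a shared flank with a concordant pair", {
  pair <- toy_pair("s1", 10000, 15000, "s2", 0, 5000)
  # discordant: mates on different scaffolds; anchored in the left flank of A
  disc <- aln_row("s1", 9600, 9750, "s2", 100, 250)
  # concordant: both mates on s1, insert <= 550, one mate in the same flank,
  # the other inside member A
  conc <- aln_row("s1", 9700, 9850, "s1", 10100, 10250)
  both <- rbind(disc, conc)
  expect_true(discordant_evidence(pair, both)$discordant)
  expect_false(discordant_evidence(pair, disc)$discordant)   # no concordant
  expect_false(discordant_evidence(pair, conc)$discordant)   # no discordant

  # same-scaffold pair: an outer insert of 551 bp is discordant, 550 is not
  pair2 <- toy_pair("s1", 10000, 10100, "s1", 10200, 10300)
  d551 <- aln_row("s1", 9700, 9850, "s1", 10101, 10251)  # outer span 551
  c_ok <- aln_row("s1", 9800, 9950, "s1", 10000, 10090)  # concordant, in A
  expect_true(discordant_evidence(pair2, rbind(d551, c_ok))$discordant)
  d550 <- aln_row("s1", 9700, 9850, "s1", 10100, 10250)  # outer span 550
  expect_false(discordant_evidence(pair2, rbind(d550, c_ok))$discordant)
})

test_that("confirmation combines mandatory depth with supporting signals", {
  p <- toy_pair("s1", 0, 100, "s1", 200, 300)
  p$confirmed <- NULL
  flags <- function(low, ag, dg, disc) {
    p$low_depth <- low; p$assembly_gap <- ag; p$depth_gap <- dg
    p$discordant <- disc
    p
  }
  pol <- evidence_policy()
  expect_true(confirm_false_duplications(flags(TRUE, TRUE, FALSE, FALSE), pol)$confirmed)
  expect_false(confirm_false_duplications(flags(TRUE, FALSE, FALSE, FALSE), pol)$confirmed)
  # full diploid depth is never confirmed even with gap + discordant signals
  expect_false(confirm_false_duplications(flags(FALSE, TRUE, TRUE, TRUE), pol)$confirmed)
  expect_error(confirm_false_duplications(p, pol), "not populated")

  # monotone: relaxing supporting_needed never unconfirms
  for (comb in list(c(TRUE, TRUE, TRUE, FALSE), c(TRUE, TRUE, FALSE, FALSE),
                    c(TRUE, FALSE, FALSE, FALSE))) {
    f <- flags(comb[1], comb[2], comb[3], comb[4])
    strict <- confirm_false_duplications(f, evidence_policy(supporting_needed = 2))
    loose <- confirm_false_duplications(f, evidence_policy(supporting_needed = 1))
    expect_true(!strict$confirmed || loose$confirmed)
  }
})

test_that("simulated confirmation recovers truth with high precision", {
  sim <- small_sim()
  self <- self_alignment_candidates(sim$assembly, depth = sim$depth,
                                    cutoffs = sim$cutoffs)
  cand <- union_candidates(self, self[0, ])
  cand <- add_evidence(cand, sim$assembly, sim$depth, sim$aln, sim$cutoffs)
  cand <- confirm_false_duplications(cand)
  sc <- score_against_truth(cand, sim$truth)
  expect_gt(sc$recall, 0.9)
  expect_gt(sc$precision, 0.95)
})
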