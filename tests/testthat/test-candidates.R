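# Candidate detection: gap segmentation, block filters, one-to-many
# cross-assembly pairs, self-alignment pairs, depth cutoffs, union set.

test_that("segment_at_gaps returns maximal gap-free contigs", {
  a <- assembly_index(c(s1 = paste0(strrep("A", 40), strrep("N", 20),
                                    strrep("C", 40))))
  ctg <- segment_at_gaps(a)
  expect_equal(ctg$start, c(0, 60))
  expect_equal(ctg$end, c(40, 100))

  a2 <- assembly_index(c(s1 = strrep("ACGT", 10)))
  expect_equal(nrow(segment_at_gaps(a2)), 1)

  a3 <- assembly_index(c(s1 = strrep("N", 30)))
  expect_equal(nrow(segment_at_gaps(a3)), 0)
})

mkblock <- function(qname, qstart, qend, tname, tstart, tend, strand = "+") {
  data.frame(qname = qname, qstart = qstart, qend = qend, strand = strand,
             tname = tname, tstart = tstart, tend = tend,
             matches = qend - qstart, block_len = qend - qstart,
             identity = 1, aligned_bp = qend - qstart,
             stringsAsFactors = FALSE)
}

test_that("block filters use the 20 bp / 80% boundaries strictly", {
  b19 <- mkblock("q", 0, 19, "t", 0, 19)
  b20 <- mkblock("q", 100, 120, "t", 100, 120)
  out <- filter_alignment_blocks(rbind(b19, b20))
  expect_equal(nrow(out), 1)
  expect_equal(out$qstart, 100)

  # two fragments covering exactly 80% of their chained query interval
  frag <- rbind(mkblock("q", 0, 400, "t", 0, 400),
                mkblock("q", 600, 1000, "t", 600, 1000))
  expect_equal(nrow(filter_alignment_blocks(frag)), 1)  # 800/1000 kept
  frag2 <- rbind(mkblock("q", 0, 390, "t", 0, 390),
                 mkblock("q", 600, 1000, "t", 600, 1000))
  expect_equal(nrow(filter_alignment_blocks(frag2)), 0)  # 790/1000 < 0.8

  expect_equal(nrow(filter_alignment_blocks(falsedup:::empty_blocks())), 0)
})

test_that("block filtering is idempotent and order-independent", {
  b <- rbind(mkblock("q", 0, 400, "t", 0, 400),
             mkblock("q", 600, 1000, "t", 600, 1000),
             mkblock("q2", 0, 19, "t", 50, 69),
             mkblock("q2", 2000, 2600, "t2", 0, 600))
  f1 <- filter_alignment_blocks(b)
  f2 <- filter_alignment_blocks(b[sample(nrow(b)), ])
  ord <- function(d) { d <- d[order(d$qname, d$qstart), ]; rownames(d) <- NULL; d }
  expect_equal(ord(f1), ord(f2))
  expect_equal(ord(filter_alignment_blocks(f1)), ord(f1))
})

test_that("one-to-many reference coverage produces query pairs", {
  # one reference locus aligned by two query scaffolds
  b <- rbind(mkblock("s1", 0, 10000, "ref", 0, 10000),
             mkblock("s2", 0, 10000, "ref", 0, 10000))
  p <- cross_assembly_candidates(b)
  expect_equal(nrow(p), 1)
  expect_false(p$same_scaffold)
  expect_setequal(c(p$scaffoldA, p$scaffoldB), c("s1", "s2"))

  # a single alignment produces nothing
  expect_equal(nrow(cross_assembly_candidates(
    mkblock("s1", 0, 10000, "ref", 0, 10000))), 0)

  # three query homologs give C(3,2) = 3 pairs
  b3 <- rbind(b, mkblock("s3", 500, 10000, "ref", 500, 10000))
  expect_equal(nrow(cross_assembly_candidates(b3)), 3)
})

test_that("cross-assembly projections map reference coordinates precisely", {
  # query copies at offset loci; only [2000,7000) of ref is double-covered
  b <- rbind(mkblock("s1", 1000, 8000, "ref", 1000, 8000),
             mkblock("s1", 20000, 25000, "ref", 2000, 7000))
  p <- cross_assembly_candidates(b)
  expect_equal(nrow(p), 1)
  expect_equal(p$startA, 2000)
  expect_equal(p$endA, 7000)
  expect_equal(p$startB, 20000)
  expect_equal(p$endB, 25000)
})

test_that("depth cutoffs follow the modal rule and Sanger mean rule", {
  h <- numeric(81)
  h[61] <- 1000  # depth 60
  h[31] <- 400   # depth 30
  cut <- estimate_depth_cutoffs(h)
  expect_equal(cut$diploid_depth, 60)
  expect_equal(cut$half_diploid, 30)

  cut2 <- estimate_depth_cutoffs(h, sanger_mode = TRUE)
  mean_d <- sum((0:80) * h) / sum(h)
  expect_equal(cut2$half_diploid, mean_d * 0.75)

  # sanger example: mean 6 -> threshold 4.5
  h6 <- numeric(13); h6[7] <- 100
  expect_equal(estimate_depth_cutoffs(h6, sanger_mode = TRUE)$half_diploid, 4.5)

  # tie -> smallest depth
  ht <- numeric(81); ht[31] <- 500; ht[61] <- 500
  expect_equal(estimate_depth_cutoffs(ht)$diploid_depth, 30)

  expect_error(estimate_depth_cutoffs(numeric(10)), "degenerate")
})

test_that("self-alignment finds duplication pairs and screens by depth", {
  sim <- small_sim()
  p <- self_alignment_candidates(sim$assembly, depth = sim$depth,
                                 cutoffs = sim$cutoffs)
  expect_error(self_alignment_candidates(sim$assembly, depth = NULL,
                                         cutoffs = sim$cutoffs), "depth")
  # no pair pairs an interval with itself
  same <- p$scaffoldA == p$scaffoldB &
    pmin(p$endA, p$endB) - pmax(p$startA, p$startB) > 0.5 * (p$endA - p$startA)
  expect_false(any(same))
  # every truth duplication is recovered by some self pair (either orientation)
  tr <- sim$truth[sim$truth$type != "true_dup", ]
  hit <- vapply(seq_len(nrow(tr)), function(i) {
    any(vapply(seq_len(nrow(p)), function(j) {
      q <- p[j, ]
      tt <- tr[i, ]
      (q$scaffoldA == tt$scaffoldA && q$scaffoldB == tt$scaffoldB &&
         min(q$endA, tt$endA) - max(q$startA, tt$startA) > 0.9 * (tt$endA - tt$startA)) ||
      (q$scaffoldA == tt$scaffoldB && q$scaffoldB == tt$scaffoldA)
    }, TRUE))
  }, TRUE)
  expect_true(all(hit))
})

test_that("union of candidate sources merges matching pairs", {
  pa <- toy_pair("s1", 0, 1000, "s2", 0, 1000)
  pa$source <- "cross"
  pb <- toy_pair("s1", 100, 1000, "s2", 0, 900)
  pb$source <- "self"
  pc <- toy_pair("s3", 0, 500, "s4", 0, 500)
  pc$source <- "self"
  pa$confirmed <- pb$confirmed <- pc$confirmed <- NULL

  u <- union_candidates(pa, rbind(pb, pc))
  expect_equal(nrow(u), 2)
  merged <- u[u$scaffoldA == "s1", ]
  expect_equal(merged$source, "both")
  expect_equal(merged$startA, 0)    # interval union
  expect_equal(merged$endB, 1000)

  # commutative and idempotent
  u2 <- union_candidates(rbind(pb, pc), pa)
  expect_equal(u[, -1], u2[, -1])  # pair ids are positional
  u3 <- union_candidates(u, u[0, ])
  expect_equal(nrow(u3), 2)
  expect_lte(sum((u3$endA - u3$startA) + (u3$endB - u3$startB)),
             sum((rbind(pa, pb, pc)$endA - rbind(pa, pb, pc)$startA) +
                 (rbind(pa, pb, pc)$endB - rbind(pa, pb, pc)$startB)))

  # containment with reciprocal overlap >= 50% merges to the larger span
  pd <- toy_pair("s1", 200, 800, "s2", 200, 800)
  pd$source <- "self"; pd$confirmed <- NULL
  u4 <- union_candidates(pa, pd)
  expect_equal(nrow(u4), 1)
  expect_equal(u4$startA, 0)
  expect_equal(u4$endA, 1000)
})
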