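# Variant calling with the allele-balance filter, heterozygosity, bootstrap
# comparisons, partition enrichment, correction arithmetic, summary.


test_that("the allele-balance filter keeps balanced sites only", {
  bal <- pileup_fixture(list(A = 15, G = 15))
  v <- call_variants(bal$aln, bal$reads, bal$assembly)
  expect_equal(nrow(v), 1)
  expect_equal(v$pos, 100)
  expect_equal(v$ref, "A")
  expect_equal(v$alt, "G")

  skewed <- pileup_fixture(list(A = 24, G = 6))   # fractions 0.8 / 0.2
  expect_equal(nrow(call_variants(skewed$aln, skewed$reads, skewed$assembly)), 0)

  multi <- pileup_fixture(list(A = 10, C = 10, G = 10))  # 1/3 each: kept
  v3 <- call_variants(multi$aln, multi$reads, multi$assembly)
  expect_equal(nrow(v3), 1)
  expect_setequal(strsplit(v3$alt, ",")[[1]], c("C", "G"))

  # a stray error read does not break a balanced site
  err <- pileup_fixture(list(A = 15, G = 14, T = 1))
  expect_equal(nrow(call_variants(err$aln, err$reads, err$assembly)), 1)

  # below min_depth nothing is called
  thin <- pileup_fixture(list(A = 4, G = 4))
  expect_equal(nrow(call_variants(thin$aln, thin$reads, thin$assembly,
                                  min_depth = 10)), 0)
})

test_that("region heterozygosity divides sites by region length", {
  v <- data.frame(scaffold = "s1", pos = seq(0, 999, 100),
                  stringsAsFactors = FALSE)
  r <- data.frame(scaffold = "s1", start = 0, end = 1000)
  expect_equal(region_heterozygosity(v, r), 0.01)
  expect_equal(region_heterozygosity(v[0, ], r), 0)
  expect_error(region_heterozygosity(v, r[0, ]), "zero-length")
})

test_that("bootstrap comparison is seeded, guarded, and null-calibrated", {
  v <- data.frame(scaffold = "s1", pos = sort(sample.int(100000, 1000)) - 1,
                  stringsAsFactors = FALSE)
  r <- data.frame(scaffold = "s1", start = 0, end = 100000)
  b1 <- bootstrap_compare(r, r, "heterozygosity", variants = v, seed = 5)
  b2 <- bootstrap_compare(r, r, "heterozygosity", variants = v, seed = 5)
  expect_identical(b1, b2)
  expect_lt(abs(b1$meanA - b1$meanB), 0.001)
  expect_gte(b1$p_value, 0)
  expect_lte(b1$p_value, 1)
  expect_error(bootstrap_compare(r, r, "heterozygosity", variants = v,
                                 n_boot = 1), "at least 2")
  tiny <- data.frame(scaffold = "s1", start = 0, end = 800)
  expect_error(bootstrap_compare(tiny, r, "heterozygosity", variants = v),
               "resampling units")
})

test_that("partition enrichment arithmetic and guards are exact", {
  a <- assembly_index(c(s1 = strrep("A", 100000)))
  parts <- list(
    CDS = data.frame(scaffold = "s1", start = 0, end = 10000),
    intron = data.frame(scaffold = "s1", start = 10000, end = 30000),
    intergenic = data.frame(scaffold = "s1", start = 30000, end = 100000))
  # all duplication bases inside the 10% CDS partition
  fds <- data.frame(scaffold = "s1", start = c(1000, 6000),
                    end = c(3000, 8000))
  pe <- partition_enrichment(fds, parts, a, n_boot = 20, seed = 1)
  expect_equal(pe$table$observed, c(1, 0, 0))
  expect_equal(pe$table$expected, c(0.1, 0.2, 0.7))
  expect_equal(pe$table$difference[1], 0.9)
  expect_equal(sum(pe$table$observed), 1)
  expect_equal(sum(pe$table$expected), 1)

  expect_error(partition_enrichment(fds[0, ], parts, a), "empty")
  bad <- parts
  bad$intron <- rbind(bad$intron,
                      data.frame(scaffold = "s1", start = 5000, end = 15000))
  expect_error(partition_enrichment(fds, bad, a), "overlap")
})

test_that("uncorrected-duplication arithmetic is exact and monotone", {
  r1 <- assess_correction(100, 100, 0)
  expect_equal(r1$uncorrected, 0)
  expect_true(r1$corrected)

  r2 <- assess_correction(100, 200, 150)
  expect_equal(r2$uncorrected, 50)
  expect_false(r2$corrected)

  # sum_H_new = 0 corrects any duplication not exceeding sum_H_old
  r3 <- assess_correction(c(50, 100, 200), 200, 0)
  expect_equal(r3$corrected, c(TRUE, TRUE, TRUE))
  # corrected is monotone non-increasing in sum_H_new
  hs <- seq(0, 300, 50)
  cc <- assess_correction(100, 200, hs)$corrected
  expect_true(all(diff(as.integer(cc)) <= 0))
})

test_that("correction assessment from blocks sums homologous overlap", {
  fds <- data.frame(scaffold = "old1", start = 1000, end = 2000)
  blocks <- rbind(
    data.frame(qname = "old1", qstart = 500, qend = 2500, strand = "+",
               tname = "new1", tstart = 0, tend = 2000,
               matches = 2000, block_len = 2000, identity = 1,
               aligned_bp = 2000, stringsAsFactors = FALSE),
    data.frame(qname = "old1", qstart = 1000, qend = 2000, strand = "+",
               tname = "new2", tstart = 0, tend = 1000,
               matches = 1000, block_len = 1000, identity = 1,
               aligned_bp = 1000, stringsAsFactors = FALSE))
  out <- correction_from_blocks(fds, blocks)
  expect_equal(out$sum_H_old, 2000)  # 1000 bp from each block
  expect_equal(out$uncorrected, 2000 - (2000 - 1000))
  expect_false(out$corrected)
  expect_warning(correction_from_blocks(
    data.frame(scaffold = "nowhere", start = 0, end = 10), blocks),
    "no homologous")
})

test_that("the duplication summary adds up by type and placement", {
  pairs <- rbind(
    toy_pair("s1", 0, 10000, "s1", 10000, 20000, fd_type = "heterotype"),
    toy_pair("s2", 0, 10000, "s2", 10000, 20000, fd_type = "heterotype"),
    toy_pair("s3", 0, 5000, "s4", 0, 5000, fd_type = "homotype"))
  a <- assembly_index(c(s1 = strrep("A", 50)))
  a$total_length <- 1e6  # summary only needs the total
  s <- summarize_duplications(pairs, a)
  expect_equal(s$total_bp, 25000)
  expect_equal(s$heterotype_bp, 20000)
  expect_equal(s$homotype_bp, 5000)
  expect_equal(s$same_scaffold_bp, 20000)
  expect_equal(s$different_scaffold_bp, 5000)
  expect_equal(s$heterotype_bp + s$homotype_bp, s$total_bp)
  expect_equal(s$same_scaffold_bp + s$different_scaffold_bp, s$total_bp)
  expect_equal(s$total_pct, 100 * 25000 / 1e6)

  s0 <- summarize_duplications(pairs[0, ], a)
  expect_equal(s0$total_bp, 0)
})

test_that("masking one copy restores variants over the surviving copy", {
  sim <- small_sim()
  tr <- sim$truth[sim$truth$type == "heterotype", ]
  pairs <- data.frame(pair_id = tr$pair_id, scaffoldA = tr$scaffoldA,
                      startA = tr$startA, endA = tr$endA,
                      scaffoldB = tr$scaffoldB, startB = tr$startB,
                      endB = tr$endB, source = "self",
                      same_scaffold = tr$scaffoldA == tr$scaffoldB,
                      confirmed = TRUE, stringsAsFactors = FALSE)
  masked <- mask_and_recompute_het(sim$assembly, pairs, sim$reads, seed = 9)
  # masking restores near-diploid depth over the surviving member
  d <- interval_mean_depth(masked$depth, masked$regions$scaffold,
                           masked$regions$start, masked$regions$end)
  expect_gt(mean(d) / sim$cutoffs$diploid_depth, 0.8)
  # injected SNPs inside the duplications reappear as heterozygous variants
  hs <- sim$dip$het_sites
  in_src <- vapply(seq_len(nrow(tr)), function(i)
    sum(hs$scaffold == tr$scaffoldA[i] & hs$pos >= tr$startA[i] &
        hs$pos < tr$endA[i]), 0)
  expect_gt(sum(in_src), 50)
  src <- data.frame(scaffold = tr$scaffoldA, start = tr$startA, end = tr$endA)
  recall <- falsedup:::count_sites_in(masked$variants, src) / sum(in_src)
  expect_gt(recall, 0.8)
  # without masking the duplicated regions are variant-free
  v0 <- call_variants(sim$aln, sim$reads, sim$assembly, depth = sim$depth)
  expect_lt(region_heterozygosity(v0, src),
            0.2 * region_heterozygosity(masked$variants, masked$regions))
})
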