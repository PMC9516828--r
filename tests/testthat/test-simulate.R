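# Simulator: diploid genome, duplication injection, reads, mapper.

test_that("heterozygous site counts follow the binomial model", {
  cfg <- sim_config(genome_length = 2e5, n_scaffolds = 1, het_rate = 0.01,
                    n_heterotype_same = 0, n_heterotype_diff = 0,
                    n_homotype = 0, seed = 5)
  dip <- gen_diploid_genome(cfg)
  n <- nrow(dip$het_sites)
  expected <- 2e5 * 0.01
  sigma <- sqrt(2e5 * 0.01 * 0.99)
  expect_lt(abs(n - expected), 3 * sigma)
  # hapB differs from hapA exactly at the recorded sites
  diffs <- which(strsplit(dip$hapA$seq[[1]], "")[[1]] !=
                 strsplit(dip$hapB$seq[[1]], "")[[1]])
  expect_equal(diffs - 1L, sort(dip$het_sites$pos))
})

test_that("zero heterozygosity leaves the haplotypes identical", {
  cfg <- sim_config(genome_length = 5e4, n_scaffolds = 1, het_rate = 0,
                    n_heterotype_same = 1, n_heterotype_diff = 0,
                    n_homotype = 0, fd_len_range = c(5000, 6000), seed = 5)
  dip <- gen_diploid_genome(cfg)
  expect_identical(dip$hapA$seq, dip$hapB$seq)
  expect_equal(nrow(dip$het_sites), 0)
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- sim_config(genome_length = 1e5, n_scaffolds = 2,
                    n_heterotype_same = 1, n_heterotype_diff = 1,
                    n_homotype = 1, fd_len_range = c(5000, 8000), seed = 9)
  d1 <- gen_diploid_genome(cfg)
  d2 <- gen_diploid_genome(cfg)
  expect_identical(d1$hapA$seq, d2$hapA$seq)
  expect_identical(d1$het_sites, d2$het_sites)
  i1 <- inject_false_duplications(d1, cfg)
  i2 <- inject_false_duplications(d2, cfg)
  expect_identical(i1$assembly$seq, i2$assembly$seq)
  expect_identical(i1$truth, i2$truth)
  r1 <- simulate_paired_reads(d1, cfg)
  r2 <- simulate_paired_reads(d2, cfg)
  expect_identical(r1$seq1, r2$seq1)
  a1 <- map_reads(r1, i1$assembly, seed = 3)
  a2 <- map_reads(r2, i2$assembly, seed = 3)
  expect_identical(a1, a2)
})

test_that("injection conserves truth lengths and places copies correctly", {
  sim <- small_sim()
  gap_bp <- sum(sim$assembly$gaps$end - sim$assembly$gaps$start)
  copy_bp <- sum(sim$truth$endB - sim$truth$startB)
  expect_equal(sim$assembly$total_length,
               sim$dip$hapA$total_length + copy_bp + gap_bp)
  # same-scaffold copies sit behind an N gap right after the source
  same <- sim$truth[sim$truth$placement == "same_scaffold_gap", ]
  expect_equal(same$startB, same$endA + sim$cfg$gap_len)
  # heterotype copies equal the haplotype-B source (modulo injection offsets)
  for (i in seq_len(nrow(same))) {
    got <- substr(sim$assembly$seq[[same$scaffoldB[i]]],
                  same$startB[i] + 1, same$endB[i])
    expect_false(grepl("N", got))
    expect_equal(nchar(got), same$endA[i] - same$startA[i])
  }
})

test_that("homotype copies carry substitutions at the configured rate", {
  cfg <- sim_config(genome_length = 2e5, n_scaffolds = 1,
                    n_heterotype_same = 0, n_heterotype_diff = 0,
                    n_homotype = 1, fd_len_range = c(10000, 10000),
                    homotype_error_rate = 0.02, seed = 11)
  dip <- gen_diploid_genome(cfg)
  inj <- inject_false_duplications(dip, cfg)
  tr <- inj$truth
  src <- substr(dip$hapA$seq[[tr$scaffoldA]], tr$startA + 1, tr$endA)
  cpy <- substr(inj$assembly$seq[[tr$scaffoldB]], tr$startB + 1, tr$endB)
  ham <- sum(strsplit(src, "")[[1]] != strsplit(cpy, "")[[1]])
  expect_lt(abs(ham - 200), 3 * sqrt(10000 * 0.02 * 0.98))
})

test_that("read pair counts and error-free substring property hold", {
  cfg <- sim_config(genome_length = 1e5, n_scaffolds = 1, coverage = 60,
                    read_length = 150, base_error_rate = 0,
                    n_heterotype_same = 0, n_heterotype_diff = 0,
                    n_homotype = 0, seed = 13)
  dip <- gen_diploid_genome(cfg)
  rs <- simulate_paired_reads(dip, cfg)
  expect_lt(abs(rs$n_pairs - 20000), 0.05 * 20000)
  hap <- function(i) if (rs$origin$haplotype[i] == "A") dip$hapA else dip$hapB
  for (i in c(1, 50, 1999)) {
    h <- hap(i)
    o <- rs$origin[i, ]
    expect_identical(rs$seq1[i],
                     substr(h$seq[[o$scaffold]], o$pos + 1, o$pos + 150))
    m2 <- substr(h$seq[[o$scaffold]], o$pos + o$insert - 149, o$pos + o$insert)
    expect_identical(rs$seq2[i], as.character(falsedup:::revcomp_cpp(m2)))
  }
})

test_that("the mapper recovers unique loci exactly and handles strand", {
  a <- toy_assembly()
  read_fwd <- substr(a$seq[[1]], 501, 650)
  read_rev <- as.character(falsedup:::revcomp_cpp(substr(a$seq[[1]], 1001, 1150)))
  rs <- list(seq1 = c(read_fwd, read_rev), seq2 = c(read_fwd, read_rev))
  aln <- map_reads(rs, a, seed = 2)
  expect_equal(aln$start1, c(500, 1000))
  expect_equal(aln$strand1, c("+", "-"))
  expect_equal(aln$nm1, c(0L, 0L))
  expect_equal(aln$mapq1, c(60L, 60L))
})

test_that("reads from a perfect duplication split between copies reproducibly", {
  set.seed(3)
  uniq <- paste(sample(c("A", "C", "G", "T"), 4000, replace = TRUE), collapse = "")
  dup <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE), collapse = "")
  a <- assembly_index(c(s1 = paste0(uniq, dup), s2 = dup))
  read <- substr(dup, 501, 650)
  rs <- list(seq1 = rep(read, 400), seq2 = rep(read, 400))
  a1 <- map_reads(rs, a, seed = 10)
  a2 <- map_reads(rs, a, seed = 10)
  expect_identical(a1, a2)                      # tie-break reproducible
  expect_equal(unique(a1$mapq1), 0L)            # ambiguous placements flagged
  expect_gt(length(unique(a1$scaffold1)), 1)    # both copies used
  share <- mean(a1$scaffold1 == "s1")
  expect_gt(share, 0.35)
  expect_lt(share, 0.65)
})

test_that("mean depth over heterotype duplications is near haploid", {
  sim <- small_sim()
  het <- sim$truth[sim$truth$type == "heterotype", ]
  d <- c(interval_mean_depth(sim$depth, het$scaffoldA, het$startA, het$endA),
         interval_mean_depth(sim$depth, het$scaffoldB, het$startB, het$endB))
  ratio <- mean(d) / sim$cutoffs$diploid_depth
  expect_gt(ratio, 0.4)
  expect_lt(ratio, 0.6)
})

test_that("make_benchmark writes a cross-consistent file set", {
  out <- tempfile()
  cfg <- sim_config(genome_length = 2e5, n_scaffolds = 1,
                    n_heterotype_same = 1, n_heterotype_diff = 1,
                    n_homotype = 1, fd_len_range = c(6000, 10000),
                    coverage = 8, seed = 21)
  bm <- make_benchmark(cfg, out)
  expect_true(all(file.exists(unlist(bm$paths))))
  asm <- load_assembly(bm$paths$assembly)
  expect_identical(asm$seq, bm$assembly$seq)
  truth <- read.delim(bm$paths$truth_tsv)
  for (i in seq_len(nrow(truth)))
    expect_lte(truth$endB[i], asm$length[[truth$scaffoldB[i]]])
  aln <- load_read_alignments(bm$paths$alignments)
  expect_equal(nrow(aln), bm$reads$n_pairs)
  genes <- load_gene_models(bm$paths$genes)
  expect_gt(length(genes), 0)
  reads1 <- Biostrings::readDNAStringSet(bm$paths$reads1, format = "fastq")
  expect_equal(length(reads1), bm$reads$n_pairs)
})
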