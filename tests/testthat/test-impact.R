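# Annotation impact: longest isoform, FGG/FEG/FCG, repeats, "-like" screen.

test_that("longest-CDS isoform selection with ties and missing CDS", {
  g <- toy_gene("g1", "s1", c(0, 1000), c(300, 1600))        # CDS 900
  g$isoforms[[2]] <- list(isoform_id = "g1.t2",
                          exons = data.frame(scaffold = "s1", start = 0, end = 1200),
                          cds = data.frame(scaffold = "s1", start = 0, end = 1200))
  sel <- select_longest_isoform(toy_genes(g1 = g))
  expect_equal(sel$g1$isoforms[[1]]$isoform_id, "g1.t2")  # 1200 > 900

  g2 <- toy_gene("g2", "s1", 0, 500)
  sel2 <- select_longest_isoform(toy_genes(g2 = g2))
  expect_equal(sel2$g2$isoforms[[1]]$isoform_id, "g2.t1")

  # equal lengths -> lexicographically first isoform id
  g3 <- toy_gene("g3", "s1", 0, 500)
  g3$isoforms[[2]] <- list(isoform_id = "g3.t0",
                           exons = data.frame(scaffold = "s1", start = 100, end = 600),
                           cds = data.frame(scaffold = "s1", start = 100, end = 600))
  sel3 <- select_longest_isoform(toy_genes(g3 = g3))
  expect_equal(sel3$g3$isoforms[[1]]$isoform_id, "g3.t0")

  g4 <- toy_gene("g4", "s1", 0, 500)
  g4$isoforms[[1]]$cds <- g4$isoforms[[1]]$cds[0, ]
  expect_warning(sel4 <- select_longest_isoform(toy_genes(g4 = g4)), "without CDS")
  expect_length(sel4, 0)
})

test_that("gene impact classes follow the CDS-fraction and partner rules", {
  # geneA: 3 exons of 500 bp; two fully inside the duplication -> 66% -> FGG
  geneA <- toy_gene("geneA", "s1", c(1000, 2000, 5000), c(1500, 2500, 5500))
  pairs <- toy_pair("s1", 900, 2600, "s2", 0, 1700)
  calls <- classify_gene_impacts(pairs, toy_genes(geneA = geneA))
  expect_equal(calls$impact_class, "FGG")
  expect_equal(calls$duplicated_cds_fraction, 1000 / 1500)

  # geneB: one of four exons duplicated, partner in unannotated sequence -> FEG
  geneB <- toy_gene("geneB", "s1", c(1000, 2000, 3000, 4000),
                    c(1400, 2400, 3400, 4400))
  pairsB <- toy_pair("s1", 1900, 2600, "s2", 0, 700)
  callsB <- classify_gene_impacts(pairsB, toy_genes(geneB = geneB))
  expect_equal(callsB$impact_class, "FEG")

  # same exon, but the partner interval lies within a second gene -> FCG
  geneC <- toy_gene("geneC", "s2", c(0, 900), c(800, 1200))
  callsC <- classify_gene_impacts(pairsB, toy_genes(geneB = geneB,
                                                    geneC = geneC))
  expect_equal(callsC$impact_class[callsC$gene_id == "geneB"], "FCG")
  expect_equal(callsC$partner_gene_id[callsC$gene_id == "geneB"], "geneC")

  # FEG when the partner projection stays within the same gene's span
  geneD <- toy_gene("geneD", "s1", c(1000, 2000, 3000, 8000),
                    c(1400, 2400, 3400, 8400))
  pairsD <- toy_pair("s1", 1900, 2600, "s1", 2900, 3600)
  callsD <- classify_gene_impacts(pairsD, toy_genes(geneD = geneD))
  expect_equal(callsD$impact_class, "FEG")
})

test_that("a call requires a completely duplicated coding exon", {
  gene <- toy_gene("g", "s1", c(1000, 2000), c(1500, 2500))
  # 1 bp of exon overlap only -> no call
  graze <- toy_pair("s1", 1499, 1800, "s2", 0, 301)
  expect_equal(nrow(classify_gene_impacts(graze, toy_genes(g = gene))), 0)
  # full exon containment -> a call
  contain <- toy_pair("s1", 900, 1600, "s2", 0, 700)
  expect_equal(nrow(classify_gene_impacts(contain, toy_genes(g = gene))), 1)
})

test_that("impact calls are invariant to gene input order", {
  sim <- small_sim()
  genes <- gen_gene_models(sim$assembly, sim$truth, seed = 77)
  tr <- sim$truth[sim$truth$type == "heterotype", ]
  pairs <- data.frame(pair_id = tr$pair_id, scaffoldA = tr$scaffoldA,
                      startA = tr$startA, endA = tr$endA,
                      scaffoldB = tr$scaffoldB, startB = tr$startB,
                      endB = tr$endB, source = "self",
                      same_scaffold = tr$scaffoldA == tr$scaffoldB,
                      confirmed = TRUE, stringsAsFactors = FALSE)
  c1 <- classify_gene_impacts(pairs, genes)
  c2 <- classify_gene_impacts(pairs, structure(rev(genes), class = "gene_models"))
  expect_equal(c1, c2)
  expect_gt(nrow(c1), 0)
})

test_that("repeat elements count as affected on >= 1 bp overlap", {
  reps <- data.frame(scaffold = "s1", start = seq(0, 900, 100),
                     end = seq(50, 950, 100),
                     repeat_class = rep(c("LTR", "SINE"), 5),
                     stringsAsFactors = FALSE)
  pairs <- toy_pair("s1", 0, 120, "s1", 500, 620)
  out <- repeat_element_fd_counts(pairs, reps)
  expect_equal(out$n_affected[out$repeat_class == "LTR"], 2)   # 0-50, 600-650
  expect_equal(out$n_total[out$repeat_class == "LTR"], 5)
  expect_equal(out$fraction[out$repeat_class == "LTR"], 0.4)
  expect_equal(out$n_affected[out$repeat_class == "SINE"], 2)  # 100-150, 500-550

  none <- repeat_element_fd_counts(pairs[0, ], reps)
  expect_true(all(none$n_affected == 0))

  # exactly abutting intervals (half-open) are not affected
  abut <- toy_pair("s1", 50, 100, "s1", 150, 200)
  out2 <- repeat_element_fd_counts(abut, reps)
  expect_equal(sum(out2$n_affected), 0)
})

test_that("the -like gene scaffold screen applies all three conditions", {
  set.seed(8)
  big <- paste(sample(c("A", "C", "G", "T"), 30000, replace = TRUE), collapse = "")
  scaf <- substr(big, 10001, 13000)  # 3 kbp scaffold = part of geneX's locus
  a <- assembly_index(c(chrM = big, tiny = scaf))
  geneX <- toy_gene("geneX", "chrM", c(9000, 12000), c(11000, 14000),
                    product = "growth factor")
  likeg <- toy_gene("geneX_like", "tiny", c(200, 1500), c(1200, 2600),
                    product = "growth factor-like")
  blocks <- align_assemblies(a, a, self = TRUE)
  out <- screen_like_gene_scaffolds(a, toy_genes(geneX = geneX,
                                                 geneXlike = likeg), blocks)
  expect_true(out$flagged)
  expect_equal(out$original_gene, "geneX")

  # covering only 40% of its scaffold: not flagged
  small_gene <- toy_gene("geneX_like", "tiny", 200, 1300,
                         product = "growth factor-like")
  out2 <- screen_like_gene_scaffolds(a, toy_genes(geneX = geneX,
                                                  geneXlike = small_gene),
                                     blocks)
  expect_false(out2$flagged)

  # no original gene to match: reported, not fatal
  orphan <- toy_gene("y", "tiny", 200, 2600, product = "mystery-like")
  out3 <- screen_like_gene_scaffolds(a, toy_genes(y = orphan), blocks)
  expect_equal(out3$status, "unmatched")
  expect_false(out3$flagged)
})
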