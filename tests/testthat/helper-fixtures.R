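# Shared fixtures. The simulated data sets are built once per test run and
# memoized; everything is seeded so runs are reproducible.

.fx_env <- new.env(parent = emptyenv())

fx_memo <- function(name, build) {
  if (is.null(.fx_env[[name]])) assign(name, build(), envir = .fx_env)
  .fx_env[[name]]
}

# Small two-scaffold simulation used by most module tests.
small_sim <- function() fx_memo("small_sim", function() {
  cfg <- sim_config(genome_length = 8e5, n_scaffolds = 2,
                    n_heterotype_same = 3, n_heterotype_diff = 2,
                    n_homotype = 2, seed = 42)
  dip <- gen_diploid_genome(cfg)
  inj <- inject_false_duplications(dip, cfg)
  rs <- simulate_paired_reads(dip, cfg)
  aln <- map_reads(rs, inj$assembly, seed = 1)
  depth <- compute_depth(aln, inj$assembly)
  list(cfg = cfg, dip = dip, assembly = inj$assembly, truth = inj$truth,
       reads = rs, aln = aln, depth = depth,
       cutoffs = estimate_depth_cutoffs(depth))
})

# The benchmark study conditions: full simulation + complete scan.
default_scan <- function() fx_memo("default_scan", function() {
  cfg <- sim_config(seed = 101)
  dip <- gen_diploid_genome(cfg)
  inj <- inject_false_duplications(dip, cfg)
  rs <- simulate_paired_reads(dip, cfg)
  genes <- gen_gene_models(inj$assembly, inj$truth, seed = 102)
  scan <- run_false_duplication_scan(
    inj$assembly, reads = rs, reference = dip$hapA, genes = genes,
    repeats = gen_repeats(inj$assembly, seed = 103), truth = inj$truth,
    seed = 104)
  # keep only what the checks read; the read set and haplotypes are large
  list(cfg = cfg, truth = inj$truth, scan = scan)
})

# Hand-built assembly with one duplication pair at known coordinates.
toy_assembly <- function() {
  set.seed(7)
  base <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
                collapse = "")
  assembly_index(c(s1 = base))
}

# Alignment table row constructor for hand-built evidence fixtures.
aln_row <- function(s1, st1, en1, s2 = NA, st2 = NA, en2 = NA, dup = FALSE,
                    mapq1 = 60L, mapq2 = 60L, strand1 = "+", strand2 = "-") {
  data.frame(read_id = "r", scaffold1 = s1, start1 = st1, end1 = en1,
             strand1 = strand1, nm1 = 0L, mapped1 = !is.na(s1), mapq1 = mapq1,
             scaffold2 = s2, start2 = st2, end2 = en2, strand2 = strand2,
             nm2 = 0L, mapped2 = !is.na(s2), mapq2 = mapq2, duplicate = dup,
             stringsAsFactors = FALSE)
}

# Depth profile built directly from per-scaffold coverage vectors.
make_depth <- function(cov_list) {
  hist <- tabulate(unlist(cov_list) + 1L)
  structure(list(coverage = cov_list, histogram = hist,
                 mean = mean(unlist(cov_list)),
                 mode = which.max(hist) - 1L,
                 total_aligned_bases = sum(unlist(cov_list)), rejected = 0L),
            class = "depth_profile")
}

make_cutoffs <- function(diploid = 60, error_depth = 5, het_min_depth = 5) {
  structure(list(error_depth = error_depth, diploid_depth = diploid,
                 half_diploid = diploid / 2, het_min_depth = het_min_depth,
                 sanger_mode = FALSE, mean_depth = diploid),
            class = "coverage_cutoffs")
}

# One pair row with the given member intervals.
toy_pair <- function(sA, stA, enA, sB, stB, enB, confirmed = TRUE,
                     fd_type = NULL) {
  d <- data.frame(pair_id = "pair_001", scaffoldA = sA, startA = stA,
                  endA = enA, scaffoldB = sB, startB = stB, endB = enB,
                  source = "self", same_scaffold = sA == sB,
                  confirmed = confirmed, stringsAsFactors = FALSE)
  if (!is.null(fd_type)) d$fd_type <- fd_type
  d
}

# Simple gene model constructor (single isoform, CDS == exons).
toy_gene <- function(id, scaffold, exon_starts, exon_ends, product = NA,
                     strand = "+") {
  ex <- data.frame(scaffold = scaffold, start = exon_starts, end = exon_ends,
                   stringsAsFactors = FALSE)
  g <- list(gene_id = id, product = product, strand = strand,
            scaffold = scaffold, start = min(exon_starts), end = max(exon_ends),
            isoforms = list(list(isoform_id = paste0(id, ".t1"), exons = ex,
                                 cds = ex)))
  g
}

toy_genes <- function(...) structure(list(...), class = "gene_models")

# Independent base-R k-mer counting oracle (tiny inputs only).
oracle_kmer_counts <- function(seqs, k) {
  revcomp <- function(s) chartr("ACGT", "TGCA",
                                paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  all <- character(0)
  for (s in seqs) {
    s <- toupper(s)
    if (nchar(s) < k) next
    for (i in seq_len(nchar(s) - k + 1)) {
      w <- substr(s, i, i + k - 1)
      if (grepl("[^ACGT]", w)) next
      all <- c(all, min(w, revcomp(w)))
    }
  }
  table(all)
}

# Build an alignment table + reads giving an exact pileup at position 100.
pileup_fixture <- function(allele_counts, assembly_len = 400) {
  set.seed(31)
  s <- paste(sample(c("A", "C", "G", "T"), assembly_len, replace = TRUE),
             collapse = "")
  substr(s, 101, 101) <- "A"
  a <- assembly_index(c(s1 = s))
  bases <- rep(names(allele_counts), unlist(allele_counts))
  n <- length(bases)
  reads <- vapply(bases, function(b) {
    r <- substr(s, 51, 150)   # 100 bp read covering position 100 at offset 50
    substr(r, 51, 51) <- b
    r
  }, "")
  aln <- do.call(rbind, lapply(seq_len(n), function(i)
    aln_row("s1", 50, 150, NA)))
  aln$strand1 <- "+"
  list(assembly = a, reads = list(seq1 = unname(reads),
                                  seq2 = rep("", n)), aln = aln)
}
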