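# Synthetic diploid-genome benchmark generator. Produces a diploid genome
# with heterozygosity hotspots, a corrupted haploid assembly carrying
# heterotype and homotype false duplications (plus optional true segmental
# duplications), paired short reads, read alignments and a ground-truth
# table. A single seed determines every output.

derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 48271 + stage * 7919) %% 2147483647) + 1L
}

#' Simulation configuration
#'
#' Defaults describe the benchmark conditions used throughout the package:
#' a 5 Mbp diploid genome over 5 scaffolds at 1% SNP heterozygosity with
#' 1.8x heterozygosity hotspots, 15 same-scaffold (gap-separated) and 15
#' different-scaffold heterotype false duplications plus 10 homotype
#' duplications carrying 2% extra substitutions, lengths 5-50 kbp, and 60x
#' diploid coverage of 150 bp read pairs with 550 +/- 100 bp inserts and
#' 0.1% base error.
#'
#' @param genome_length haploid genome length in bp.
#' @param n_scaffolds number of main scaffolds (equal sizes).
#' @param het_rate background per-base SNP heterozygosity.
#' @param hotspot_multiplier heterozygosity multiplier inside hotspots.
#' @param hotspot_fd_fraction fraction of false-duplication bases whose
#'   source region is designated a hotspot (allocated by bp, greedily).
#' @param hotspot_margin bp of hotspot extension beyond an FD source region.
#' @param n_heterotype_same,n_heterotype_diff,n_homotype counts of false
#'   duplications by type/placement.
#' @param homotype_placement placement of homotype copies
#'   ("different_scaffold" or "same_scaffold_gap").
#' @param fd_len_range min/max false-duplication length (bp).
#' @param homotype_error_rate substitution rate injected into homotype copies.
#' @param n_true_dup number of true segmental duplications present in both
#'   haplotypes (used to test that true duplications are not called).
#' @param true_dup_len_range min/max true-duplication length (bp).
#' @param true_dup_divergence substitution divergence between the two loci
#'   of a true duplication (identical across haplotypes).
#' @param gap_len length of the N gap inserted between same-scaffold copies.
#' @param coverage total (diploid) read coverage.
#' @param read_length read length in bp.
#' @param insert_mean,insert_sd insert-size distribution (bp); inserts are
#'   truncated at twice the read length.
#' @param base_error_rate per-base substitution error rate in reads.
#' @param seed integer seed determining all outputs.
#' @return a `sim_config` list.
#' @export
sim_config <- function(genome_length = 5e6, n_scaffolds = 5, het_rate = 0.01,
                       hotspot_multiplier = 1.8, hotspot_fd_fraction = 0.8,
                       hotspot_margin = 500, n_heterotype_same = 15,
                       n_heterotype_diff = 15, n_homotype = 10,
                       homotype_placement = "different_scaffold",
                       fd_len_range = c(5000, 50000),
                       homotype_error_rate = 0.02, n_true_dup = 0,
                       true_dup_len_range = c(5000, 20000),
                       true_dup_divergence = 0.01, gap_len = 100,
                       coverage = 60, read_length = 150, insert_mean = 550,
                       insert_sd = 100, base_error_rate = 0.001, seed = 1) {
  cfg <- as.list(environment())
  rates <- c(het_rate, homotype_error_rate, base_error_rate,
             hotspot_fd_fraction)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (hotspot_multiplier < 1) stop("hotspot_multiplier must be >= 1")
  if (read_length > insert_mean) stop("read length exceeds mean insert size")
  if (genome_length < n_scaffolds * 10) stop("genome too short")
  cfg$homotype_placement <- match.arg(homotype_placement,
                                      c("different_scaffold", "same_scaffold_gap"))
  structure(cfg, class = "sim_config")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Draw non-overlapping source intervals across scaffolds, margin away from
# scaffold ends and separated by >= sep.
draw_source_intervals <- function(lengths, scaf_len, margin, sep = 2000) {
  chosen <- iv_df()
  for (len in lengths) {
    ok <- FALSE
    for (attempt in 1:2000) {
      s <- sample(names(scaf_len), 1, prob = scaf_len)
      lo <- margin
      hi <- scaf_len[[s]] - margin - len
      if (hi <= lo) next
      st <- floor(runif(1, lo, hi))
      if (!iv_overlaps_any(chosen, s, st - sep, st + len + sep)) {
        chosen <- rbind(chosen, iv_df(scaffold = s, start = st, end = st + len))
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("requested duplication bp exceeds what fits in the genome")
  }
  chosen
}

#' Generate a diploid genome with heterozygosity hotspots
#'
#' Haplotype A is i.i.d. uniform over ACGT; haplotype B is derived by
#' per-base Bernoulli substitutions at `het_rate` (times the hotspot
#' multiplier inside hotspots) with a random non-reference allele. The
#' source regions of the planned false duplications are drawn here, and a
#' bp-stratified subset of them is designated as hotspots, so that the
#' configured fraction of duplicated bases falls in elevated-heterozygosity
#' sequence. True segmental duplications are realized in both haplotypes as
#' an extra scaffold carrying a copy of the source region.
#'
#' @param config a [sim_config()].
#' @return a `diploid_genome` list with haplotypes, het sites, hotspots and
#'   the duplication plan.
#' @export
gen_diploid_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 1))
  n <- config$n_scaffolds
  base_len <- floor(config$genome_length / n)
  lens <- rep(base_len, n)
  lens[n] <- config$genome_length - base_len * (n - 1)
  scafs <- paste0("chr", seq_len(n))
  hapA <- setNames(vapply(lens, random_dna, ""), scafs)
  scaf_len <- setNames(lens, scafs)

  # duplication plan ---------------------------------------------------------
  plan_types <- c(rep("heterotype", config$n_heterotype_same),
                  rep("heterotype", config$n_heterotype_diff),
                  rep("homotype", config$n_homotype),
                  rep("true_dup", config$n_true_dup))
  plan_place <- c(rep("same_scaffold_gap", config$n_heterotype_same),
                  rep("different_scaffold", config$n_heterotype_diff),
                  rep(config$homotype_placement, config$n_homotype),
                  rep("different_scaffold", config$n_true_dup))
  n_plan <- length(plan_types)
  plan <- NULL
  if (n_plan > 0) {
    fd_sel <- plan_types != "true_dup"
    lengths <- numeric(n_plan)
    lengths[fd_sel] <- floor(runif(sum(fd_sel), config$fd_len_range[1],
                                   config$fd_len_range[2] + 1))
    lengths[!fd_sel] <- floor(runif(sum(!fd_sel), config$true_dup_len_range[1],
                                    config$true_dup_len_range[2] + 1))
    ord <- sample.int(n_plan)
    src <- draw_source_intervals(lengths[ord], scaf_len,
                                 margin = config$insert_mean + 1000)
    plan <- cbind(src,
                  data.frame(plan_id = paste0("fd_", seq_len(n_plan)),
                             type = plan_types[ord], placement = plan_place[ord],
                             len = lengths[ord], stringsAsFactors = FALSE))
    # hotspot designation: greedy bp stratification over FD sources
    plan$in_hotspot <- FALSE
    fd_rows <- which(plan$type != "true_dup")
    target_bp <- config$hotspot_fd_fraction * sum(plan$len[fd_rows])
    acc <- 0
    for (i in sample(fd_rows)) {
      if (acc >= target_bp) break
      plan$in_hotspot[i] <- TRUE
      acc <- acc + plan$len[i]
    }
  } else {
    plan <- cbind(iv_df(), data.frame(plan_id = character(), type = character(),
                                      placement = character(), len = numeric(),
                                      in_hotspot = logical()))
  }

  hotspots <- if (any(plan$in_hotspot)) {
    h <- plan[plan$in_hotspot, c("scaffold", "start", "end")]
    h$start <- pmax(0, h$start - config$hotspot_margin)
    h$end <- pmin(scaf_len[h$scaffold], h$end + config$hotspot_margin)
    h$multiplier <- config$hotspot_multiplier
    h
  } else cbind(iv_df(), data.frame(multiplier = numeric()))

  # heterozygous sites -------------------------------------------------------
  het_sites <- list()
  hapB <- hapA
  if (config$het_rate > 0) {
    for (s in scafs) {
      hot <- iv_union(hotspots[hotspots$scaffold == s, c("scaffold", "start", "end")])
      segs <- rbind(
        if (nrow(hot)) cbind(hot, rate = config$het_rate * config$hotspot_multiplier),
        cbind(iv_setdiff(iv_df(scaffold = s, start = 0, end = scaf_len[[s]]), hot),
              rate = config$het_rate))
      pos <- unlist(lapply(seq_len(nrow(segs)), function(i) {
        len <- segs$end[i] - segs$start[i]
        k <- rbinom(1, len, segs$rate[i])
        if (k == 0) return(integer(0))
        segs$start[i] + sample.int(len, k) - 1L
      }))
      if (length(pos) == 0) next
      pos <- sort(pos)
      ref <- substring(hapA[[s]], pos + 1, pos + 1)
      alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
      hapB[[s]] <- mutate_bases(hapB[[s]], pos, alt)
      het_sites[[s]] <- data.frame(scaffold = s, pos = pos, ref = ref, alt = alt,
                                   stringsAsFactors = FALSE)
    }
  }
  het_sites <- if (length(het_sites)) do.call(rbind, het_sites) else
    data.frame(scaffold = character(), pos = integer(), ref = character(),
               alt = character(), stringsAsFactors = FALSE)
  rownames(het_sites) <- NULL

  # true segmental duplications exist in both haplotypes: copy the (mutated)
  # source region onto a fresh scaffold in each haplotype
  plan$sd_name <- rep(NA_character_, nrow(plan))
  td_rows <- which(plan$type == "true_dup")
  if (length(td_rows)) {
    plan$sd_name[td_rows] <- paste0("sd_scaffold_", seq_along(td_rows))
    td <- plan[td_rows, , drop = FALSE]
    for (i in seq_len(nrow(td))) {
      nm <- td$sd_name[i]
      hapA[[nm]] <- substr(hapA[[td$scaffold[i]]], td$start[i] + 1, td$end[i])
      hapB[[nm]] <- substr(hapB[[td$scaffold[i]]], td$start[i] + 1, td$end[i])
      hs <- het_sites[het_sites$scaffold == td$scaffold[i] &
                      het_sites$pos >= td$start[i] & het_sites$pos < td$end[i], ]
      if (nrow(hs)) {
        hs$scaffold <- nm
        hs$pos <- hs$pos - td$start[i]
        het_sites <- rbind(het_sites, hs)
      }
      # real segmental duplications are diverged between loci but identical
      # across haplotypes: same substitutions applied to both copies
      if (config$true_dup_divergence > 0) {
        len <- nchar(hapA[[nm]])
        k <- rbinom(1, len, config$true_dup_divergence)
        if (k > 0) {
          pos <- sort(sample.int(len, k) - 1L)
          pos <- setdiff(pos, hs$pos)
          if (length(pos)) {
            cur <- substring(hapA[[nm]], pos + 1, pos + 1)
            alt <- vapply(cur, function(b)
              sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
            hapA[[nm]] <- mutate_bases(hapA[[nm]], pos, alt)
            hapB[[nm]] <- mutate_bases(hapB[[nm]], pos, alt)
          }
        }
      }
    }
  }

  structure(list(hapA = assembly_index(hapA), hapB = assembly_index(hapB),
                 het_sites = het_sites, hotspots = hotspots, plan = plan,
                 config = config),
            class = "diploid_genome")
}

#' Inject false duplications into a haploid assembly
#'
#' The assembly starts as haplotype A. Heterotype duplications add the
#' haplotype-B copy of the source region, either immediately downstream on
#' the same scaffold separated by an N gap, or as a new unplaced scaffold.
#' Homotype duplications add a haplotype-A copy carrying i.i.d.
#' substitutions at the configured error rate. True segmental duplications
#' (already present in both haplotypes) are recorded in the truth table but
#' leave the assembly unchanged.
#'
#' @param diploid a `diploid_genome` from [gen_diploid_genome()].
#' @param config the same [sim_config()].
#' @return list with `assembly` (an `assembly_index`) and `truth`
#'   (the ground-truth table of duplication pairs).
#' @export
inject_false_duplications <- function(diploid, config) {
  stopifnot(inherits(diploid, "diploid_genome"))
  set.seed(derive_seed(config$seed, 2))
  seqs <- diploid$hapA$seq
  plan <- diploid$plan
  truth <- list()
  if (nrow(plan)) {
    plan <- plan[order(plan$scaffold, plan$start), ]
    offset <- setNames(rep(0, length(seqs)), names(seqs))
    gapN <- paste(rep("N", config$gap_len), collapse = "")
    for (i in seq_len(nrow(plan))) {
      p <- plan[i, ]
      off <- offset[[p$scaffold]]
      iA <- c(p$start + off, p$end + off)
      len <- p$len
      err <- 0
      if (p$type == "true_dup") {
        rec <- list(scafB = p$sd_name, sB = 0, eB = len)
      } else if (p$type == "heterotype") {
        copy <- substr(diploid$hapB$seq[[p$scaffold]], p$start + 1, p$end)
        rec <- insert_copy(copy, p, seqs, offset, iA, gapN, config)
        seqs <- rec$seqs; offset <- rec$offset
      } else {  # homotype
        copy <- substr(diploid$hapA$seq[[p$scaffold]], p$start + 1, p$end)
        err <- config$homotype_error_rate
        if (err > 0) {
          k <- rbinom(1, len, err)
          if (k > 0) {
            pos <- sample.int(len, k) - 1L
            cur <- strsplit(substr(copy, 1, len), "")[[1]][pos + 1]
            alt <- vapply(cur, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
            copy <- mutate_bases(copy, pos, alt)
          }
        }
        rec <- insert_copy(copy, p, seqs, offset, iA, gapN, config)
        seqs <- rec$seqs; offset <- rec$offset
      }
      truth[[p$plan_id]] <- data.frame(
        pair_id = p$plan_id, type = p$type, placement = p$placement,
        scaffoldA = p$scaffold, startA = iA[1], endA = iA[2],
        scaffoldB = rec$scafB, startB = rec$sB, endB = rec$eB,
        injected_error_rate = err, in_hotspot = p$in_hotspot,
        stringsAsFactors = FALSE)
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else data.frame(
    pair_id = character(), type = character(), placement = character(),
    scaffoldA = character(), startA = numeric(), endA = numeric(),
    scaffoldB = character(), startB = numeric(), endB = numeric(),
    injected_error_rate = numeric(), in_hotspot = logical(),
    stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  list(assembly = assembly_index(seqs), truth = truth)
}

# Splice a duplication copy into the growing assembly; returns updated state
# plus the copy's interval.
insert_copy <- function(copy, p, seqs, offset, iA, gapN, config) {
  len <- nchar(copy)
  if (p$placement == "same_scaffold_gap") {
    s <- seqs[[p$scaffold]]
    at <- iA[2]  # insert right after the source copy
    seqs[[p$scaffold]] <- paste0(substr(s, 1, at), gapN, copy,
                                 substr(s, at + 1, nchar(s)))
    offset[[p$scaffold]] <- offset[[p$scaffold]] + config$gap_len + len
    list(seqs = seqs, offset = offset, scafB = p$scaffold,
         sB = at + config$gap_len, eB = at + config$gap_len + len)
  } else {
    nm <- paste0("fd_scaffold_", sub("^fd_", "", p$plan_id))
    seqs[[nm]] <- copy
    list(seqs = seqs, offset = offset, scafB = nm, sB = 0, eB = len)
  }
}

#' Simulate paired-end reads from a diploid genome
#'
#' Fragments are sampled length-weighted across both haplotypes (equal in
#' expectation), with insert sizes Normal(mean, sd) truncated at twice the
#' read length, and i.i.d. substitution errors at the configured base error
#' rate. Total bases approximate `coverage * genome_length`.
#'
#' @param diploid a `diploid_genome`.
#' @param config the [sim_config()].
#' @return a `read_set` list with mate sequences and per-pair origin.
#' @export
simulate_paired_reads <- function(diploid, config) {
  stopifnot(inherits(diploid, "diploid_genome"))
  if (config$coverage <= 0) stop("coverage must be positive")
  n_pairs <- round(config$coverage * diploid$hapA$total_length /
                   (2 * config$read_length))
  seqs <- c(setNames(diploid$hapA$seq, paste0("A|", names(diploid$hapA$seq))),
            setNames(diploid$hapB$seq, paste0("B|", names(diploid$hapB$seq))))
  r <- simulate_reads_cpp(unname(seqs), n_pairs, config$read_length,
                          config$insert_mean, config$insert_sd,
                          config$base_error_rate,
                          derive_seed(config$seed, 3))
  origin_name <- names(seqs)[r$origin]
  structure(list(
    seq1 = as.character(r$seq1), seq2 = as.character(r$seq2),
    origin = data.frame(
      haplotype = substr(origin_name, 1, 1),
      scaffold = substr(origin_name, 3, nchar(origin_name)),
      pos = r$pos, insert = r$insert, stringsAsFactors = FALSE),
    read_length = config$read_length, n_pairs = n_pairs),
    class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set: %d pairs of %d bp reads\n", x$n_pairs, x$read_length))
  invisible(x)
}

#' Map paired reads to an assembly
#'
#' Desk-scale seed-and-extend mapper: exact 31-mer seeds anchor candidate
#' placements, each scored by full-length Hamming distance (reads carry
#' substitutions only); the minimum-mismatch placement wins and equal-best
#' ties are broken uniformly at random under the seed. Mates are mapped
#' independently; unplaceable mates are flagged unmapped.
#'
#' @param reads a `read_set` (or list with `seq1`/`seq2` character vectors).
#' @param assembly target `assembly_index`.
#' @param seed integer seed for tie-breaking.
#' @param seed_len anchor seed length (bp).
#' @param n_seeds seed positions probed per read and orientation.
#' @param max_mm_frac maximum mismatch fraction for a valid placement.
#' @return paired-read alignment data.frame (one row per pair).
#' @export
map_reads <- function(reads, assembly, seed = 1, seed_len = 31, n_seeds = 6,
                      max_mm_frac = 0.1) {
  tnames <- names(assembly$seq)
  m1 <- map_reads_cpp(reads$seq1, unname(assembly$seq), seed_len, n_seeds,
                      max_mm_frac, derive_seed(seed, 41))
  m2 <- map_reads_cpp(reads$seq2, unname(assembly$seq), seed_len, n_seeds,
                      max_mm_frac, derive_seed(seed, 42))
  len1 <- nchar(reads$seq1)
  len2 <- nchar(reads$seq2)
  data.frame(
    read_id = sprintf("read_%d", seq_along(reads$seq1)),
    scaffold1 = tnames[m1$tid], start1 = as.numeric(m1$start),
    end1 = as.numeric(m1$start) + len1, strand1 = as.character(m1$strand),
    nm1 = m1$nm, mapped1 = !is.na(m1$tid),
    mapq1 = ifelse(!is.na(m1$n_ties) & m1$n_ties > 1L, 0L, 60L),
    scaffold2 = tnames[m2$tid], start2 = as.numeric(m2$start),
    end2 = as.numeric(m2$start) + len2, strand2 = as.character(m2$strand),
    nm2 = m2$nm, mapped2 = !is.na(m2$tid),
    mapq2 = ifelse(!is.na(m2$n_ties) & m2$n_ties > 1L, 0L, 60L),
    duplicate = FALSE, stringsAsFactors = FALSE)
}

#' Generate a complete benchmark data set on disk
#'
#' Runs the full simulation (diploid genome, corrupted assembly, reads,
#' alignments, gene models, repeats) and writes standard-format files plus a
#' JSON manifest of realized parameters.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the generated objects and file paths.
#' @export
make_benchmark <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dip <- gen_diploid_genome(config)
  inj <- inject_false_duplications(dip, config)
  rs <- simulate_paired_reads(dip, config)
  aln <- map_reads(rs, inj$assembly, seed = derive_seed(config$seed, 4))
  genes <- gen_gene_models(inj$assembly, inj$truth, seed = derive_seed(config$seed, 5))
  repeats <- gen_repeats(inj$assembly, seed = derive_seed(config$seed, 6))

  paths <- list(
    assembly = file.path(out_dir, "assembly.fasta"),
    reference = file.path(out_dir, "reference_hapA.fasta"),
    truth_tsv = file.path(out_dir, "truth.tsv"),
    truth_bed = file.path(out_dir, "truth.bed"),
    reads1 = file.path(out_dir, "reads_1.fastq"),
    reads2 = file.path(out_dir, "reads_2.fastq"),
    alignments = file.path(out_dir, "alignments.tsv"),
    genes = file.path(out_dir, "genes.gff3"),
    repeats = file.path(out_dir, "repeats.bed"),
    manifest = file.path(out_dir, "manifest.json"))

  write_assembly_fasta(inj$assembly, paths$assembly)
  write_assembly_fasta(dip$hapA, paths$reference)
  write.table(inj$truth, paths$truth_tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  tb <- rbind(iv_df(scaffold = inj$truth$scaffoldA, start = inj$truth$startA,
                    end = inj$truth$endA),
              iv_df(scaffold = inj$truth$scaffoldB, start = inj$truth$startB,
                    end = inj$truth$endB))
  write_bed(tb, paths$truth_bed, name = rep(inj$truth$pair_id, 2),
            score = rep(match(inj$truth$type,
                              c("heterotype", "homotype", "true_dup")), 2))
  write_fastq(rs$seq1, paths$reads1)
  write_fastq(rs$seq2, paths$reads2)
  write_read_alignments(aln, paths$alignments)
  write_gff3(genes, paths$genes)
  write_bed(repeats, paths$repeats, name = repeats$repeat_class)
  manifest <- list(
    config = unclass(config), n_read_pairs = rs$n_pairs,
    assembly_bp = inj$assembly$total_length,
    reference_bp = dip$hapA$total_length,
    truth_fd_bp = sum((inj$truth$endB - inj$truth$startB)[
      inj$truth$type != "true_dup"]),
    n_het_sites = nrow(dip$het_sites), n_genes = length(genes))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, digits = NA)
  invisible(list(diploid = dip, assembly = inj$assembly, truth = inj$truth,
                 reads = rs, alignments = aln, genes = genes,
                 repeats = repeats, paths = paths))
}

write_fastq <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- sprintf("read_%d", seq_along(seqs))
  q <- Biostrings::BStringSet(vapply(nchar(seqs), function(n)
    paste(rep("I", n), collapse = ""), ""))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Random annotation for the benchmark: gene models (with impact fixtures
# placed on heterotype duplications) and labeled repeat intervals.

make_gene <- function(id, scaffold, strand, exons, product = NA_character_) {
  list(gene_id = id, product = product, strand = strand, scaffold = scaffold,
       start = min(exons$start), end = max(exons$end),
       isoforms = list(list(isoform_id = paste0(id, ".t1"),
                            exons = exons, cds = exons)))
}

random_exons <- function(scaffold, start, max_end) {
  exons <- iv_df()
  pos <- start
  n_ex <- sample(2:15, 1)
  for (i in seq_len(n_ex)) {
    len <- sample(100:300, 1)
    if (pos + len > max_end) break
    exons <- rbind(exons, iv_df(scaffold = scaffold, start = pos, end = pos + len))
    pos <- pos + len + sample(200:2000, 1)
  }
  exons
}

#' Generate gene models for a simulated assembly
#'
#' Places random multi-exon genes across the assembly and, when the truth
#' table contains suitable heterotype duplications, adds three deterministic
#' impact fixtures: a gene fully inside a duplication source (a false gene
#' gain once the duplication is confirmed), a gene with exactly one exon
#' inside a duplication (false exon gain), and an exon pair whose partner
#' copy lies inside a second gene (false chimeric gain).
#'
#' @param assembly the corrupted `assembly_index`.
#' @param truth truth table from [inject_false_duplications()].
#' @param seed integer seed.
#' @param gene_every approximate spacing between random genes (bp).
#' @return a `gene_models` list.
#' @export
gen_gene_models <- function(assembly, truth, seed = 1, gene_every = 10000) {
  set.seed(seed)
  genes <- list()
  # gaps are off limits; duplicated copies are not, mirroring annotation
  # pipelines that annotate both copies of a duplication
  occupied <- assembly$gaps
  gi <- 0
  add_gene <- function(g) {
    gi <<- gi + 1
    genes[[g$gene_id]] <<- g
    occupied <<- rbind(occupied, iv_df(scaffold = g$scaffold,
                                       start = g$start - 200, end = g$end + 200))
  }

  # impact fixtures on same-scaffold heterotype duplications; the FEG/FCG
  # constructions reach 4.5 kbp upstream and 2.1 kbp past the copy, so only
  # duplications with that much room qualify
  fx <- if (nrow(truth)) {
    room <- truth$startA >= 5000 &
      truth$endB + 2500 <= assembly$length[truth$scaffoldB]
    truth[truth$type == "heterotype" &
          truth$placement == "same_scaffold_gap" &
          truth$endA - truth$startA >= 6000 & room, ]
  } else truth[0, ]
  fx <- head(fx[order(-(fx$endA - fx$startA)), ], 3)
  if (nrow(fx) >= 1) {  # gene fully inside the duplication source -> FGG
    p <- fx[1, ]
    ex <- random_exons(p$scaffoldA, p$startA + 200,
                       min(p$endA - 200, p$startA + 5500))
    add_gene(make_gene("fixture_fgg", p$scaffoldA, "+", ex, "fixture FGG protein"))
  }
  if (nrow(fx) >= 2) {  # one exon inside the duplication -> FEG
    p <- fx[2, ]
    s <- p$scaffoldA
    ex <- rbind(iv_df(scaffold = s, start = p$startA - 3000, end = p$startA - 2800),
                iv_df(scaffold = s, start = p$startA - 1500, end = p$startA - 1300),
                iv_df(scaffold = s, start = p$startA + 200, end = p$startA + 600))
    add_gene(make_gene("fixture_feg", s, "+", ex, "fixture FEG protein"))
  }
  if (nrow(fx) >= 3) {  # partner copy of the exon lands inside a second gene -> FCG
    p <- fx[3, ]
    s <- p$scaffoldA
    ex <- rbind(iv_df(scaffold = s, start = p$startA - 4500, end = p$startA - 4200),
                iv_df(scaffold = s, start = p$startA - 3000, end = p$startA - 2700),
                iv_df(scaffold = s, start = p$startA - 1500, end = p$startA - 1200),
                iv_df(scaffold = s, start = p$startA + 300, end = p$startA + 700))
    add_gene(make_gene("fixture_fcg_donor", s, "+", ex, "fixture FCG donor protein"))
    ex2 <- rbind(iv_df(scaffold = p$scaffoldB, start = p$startB + 250,
                       end = p$startB + 750),
                 iv_df(scaffold = p$scaffoldB, start = p$endB + 500,
                       end = p$endB + 1100),
                 iv_df(scaffold = p$scaffoldB, start = p$endB + 1500,
                       end = p$endB + 2100))
    add_gene(make_gene("fixture_fcg_host", p$scaffoldB, "+", ex2,
                       "fixture FCG host protein"))
  }

  # keep random genes off the FEG fixture's partner copy: a gene there
  # would legitimately turn the constructed exon gain into a chimeric gain
  if (nrow(fx) >= 2)
    occupied <- rbind(occupied, iv_df(scaffold = fx$scaffoldB[2],
                                      start = fx$startB[2], end = fx$endB[2]))

  # random background genes (small unplaced scaffolds get annotated too)
  for (s in names(assembly$seq)) {
    L <- assembly$length[[s]]
    if (L < 12000) next
    starts <- seq(2000, L - 8000, by = gene_every)
    starts <- starts + sample(0:2000, length(starts), replace = TRUE)
    for (st in starts) {
      if (iv_overlaps_any(occupied, s, st - 200, st + 6000)) next
      ex <- random_exons(s, st, min(st + 6000, L - 500))
      if (nrow(ex) < 2) next
      add_gene(make_gene(sprintf("gene_%03d", gi + 1), s,
                         sample(c("+", "-"), 1), ex,
                         sprintf("hypothetical protein %d", gi + 1)))
    }
  }
  structure(genes, class = "gene_models")
}

#' Generate labeled repeat intervals for a simulated assembly
#'
#' @param assembly an `assembly_index`.
#' @param seed integer seed.
#' @param every approximate spacing (bp).
#' @return repeat data.frame (scaffold/start/end/repeat_class).
#' @export
gen_repeats <- function(assembly, seed = 1, every = 5000) {
  set.seed(seed)
  out <- lapply(names(assembly$seq), function(s) {
    L <- assembly$length[[s]]
    if (L < 2 * every) return(NULL)
    starts <- seq(500, L - 2500, by = every)
    starts <- starts + sample(0:1500, length(starts), replace = TRUE)
    lens <- sample(100:2000, length(starts), replace = TRUE)
    keep <- c(TRUE, diff(starts) > head(lens, -1))
    d <- iv_df(scaffold = s, start = starts[keep],
               end = pmin(starts[keep] + lens[keep], L))
    d$repeat_class <- sample(c("LTR", "SINE", "LINE", "DNA", "satellite"),
                             nrow(d), replace = TRUE)
    d
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
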