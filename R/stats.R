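# Heterozygosity and error-rate estimation with bootstrap tests, genomic
# partition enrichment, correction assessment between assembly versions,
# and the summary table.

#' Call variants from mapped reads (simple pileup caller)
#'
#' Emits a site when at least two alleles are observed at `min_depth` or
#' more and every considered allele's fraction (alleles at `min_allele_frac`
#' of the depth or more) lies strictly inside the allele-balance bounds.
#' Multiallelic sites are retained. Intended for the bundled synthetic data;
#' real-data users can supply a VCF via [load_variants()] instead.
#'
#' @param alignments paired-read alignment data.frame.
#' @param reads the `read_set` the alignments refer to.
#' @param assembly an `assembly_index`.
#' @param min_depth minimum site depth.
#' @param af_bounds strict allele-fraction bounds, default `c(0.25, 0.75)`.
#' @param min_allele_frac fraction below which an allele (e.g. a stray
#'   sequencing error) is not considered part of the genotype.
#' @param depth optional precomputed `depth_profile`.
#' @return variant data.frame (0-based positions).
#' @export
call_variants <- function(alignments, reads, assembly, min_depth = 10,
                          af_bounds = c(0.25, 0.75), min_allele_frac = 0.1,
                          depth = NULL) {
  depth <- depth %||% compute_depth(alignments, assembly)
  a <- alignments[!alignments$duplicate, , drop = FALSE]
  snames <- names(assembly$seq)
  ev <- list()
  for (m in 1:2) {
    mapped <- a[[paste0("mapped", m)]]
    tid <- ifelse(mapped, match(a[[paste0("scaffold", m)]], snames), NA_integer_)
    seqs <- if (m == 1) reads$seq1 else reads$seq2
    ev[[m]] <- mismatch_events_cpp(
      seqs[seq_len(nrow(a))], as.integer(tid),
      as.integer(a[[paste0("start", m)]]), a[[paste0("strand", m)]],
      unname(assembly$seq))
  }
  etid <- c(ev[[1]]$tid, ev[[2]]$tid)
  epos <- c(ev[[1]]$pos, ev[[2]]$pos)
  ebase <- c(ev[[1]]$base, ev[[2]]$base)

  out <- list()
  bases <- c("A", "C", "G", "T")
  for (ti in sort(unique(etid))) {
    s <- snames[ti]
    sel <- etid == ti
    key <- epos[sel] * 4 + ebase[sel]
    key <- sort(key)
    r <- rle(key)
    kpos <- r$values %/% 4
    kbase <- r$values %% 4
    pu <- unique(kpos)
    cnts <- matrix(0, nrow = length(pu), ncol = 4)
    cnts[cbind(match(kpos, pu), kbase + 1)] <- r$lengths
    dp <- depth$coverage[[s]][pu + 1]
    refb <- substring(assembly$seq[[s]], pu + 1, pu + 1)
    refi <- match(refb, bases)
    ok <- !is.na(refi)
    refcnt <- pmax(dp - rowSums(cnts), 0)
    idx <- which(ok)
    cnts[cbind(idx, refi[idx])] <- cnts[cbind(idx, refi[idx])] + refcnt[idx]
    fr <- cnts / pmax(dp, 1)
    considered <- fr >= min_allele_frac & cnts > 0
    nall <- rowSums(considered)
    frc <- fr
    frc[!considered] <- NA
    maxf <- apply(frc, 1, max, na.rm = TRUE)
    minf <- suppressWarnings(apply(frc, 1, min, na.rm = TRUE))
    keep <- ok & dp >= min_depth & nall >= 2 &
      maxf < af_bounds[2] & minf > af_bounds[1]
    if (!any(keep)) next
    ki <- which(keep)
    alt <- vapply(ki, function(i)
      paste(bases[considered[i, ] & seq_len(4) != refi[i]], collapse = ","),
      "")
    out[[s]] <- data.frame(scaffold = s, pos = pu[ki], ref = refb[ki],
                           alt = alt, depth = dp[ki], af_major = maxf[ki],
                           af_minor = minf[ki], stringsAsFactors = FALSE)
  }
  out <- if (length(out)) do.call(rbind, out) else data.frame(
    scaffold = character(), pos = numeric(), ref = character(),
    alt = character(), depth = numeric(), af_major = numeric(),
    af_minor = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Heterozygosity of a region set
#'
#' The number of variant sites inside the regions divided by the total
#' region length (bp).
#'
#' @param variants variant data.frame from [call_variants()].
#' @param regions interval data.frame.
#' @return variants per bp.
#' @export
region_heterozygosity <- function(variants, regions) {
  bp <- iv_total_bp(regions)
  if (bp == 0) stop("zero-length region set")
  n <- count_sites_in(variants, regions)
  n / bp
}

count_sites_in <- function(variants, regions) {
  if (nrow(variants) == 0 || nrow(regions) == 0) return(0)
  regions <- iv_union(regions)
  n <- 0
  for (s in unique(regions$scaffold)) {
    vp <- variants$pos[variants$scaffold == s]
    if (length(vp) == 0) next
    ir <- .iv_to_ir(regions[regions$scaffold == s, ])
    n <- n + sum(IRanges::countOverlaps(
      IRanges::IRanges(vp + 1, vp + 1), ir) > 0)
  }
  n
}

# Per-tile variant counts and lengths (bootstrap resampling units).
variant_tiles <- function(variants, regions, tile = 1000) {
  tiles <- iv_tile(iv_union(regions), tile)
  num <- vapply(seq_len(nrow(tiles)), function(i)
    count_sites_in(variants, tiles[i, , drop = FALSE]), 0)
  data.frame(num = num, den = iv_len(tiles))
}

#' Bootstrap comparison of a metric between two region sets
#'
#' The regions are tiled into ~1 kbp resampling units; each bootstrap
#' replicate resamples units with replacement and recomputes the metric
#' (heterozygosity: variant sites per bp; erroneous k-mer rate: erroneous
#' k-mer instances per instance). A two-sided Student's t-test is applied
#' between the two bootstrap distributions. Note the replicates are treated
#' as independent samples, which makes the test anti-conservative by
#' construction; it is reproduced this way deliberately and should be read
#' as a descriptive contrast.
#'
#' @param regionsA,regionsB interval data.frames.
#' @param metric "heterozygosity" or "erroneous_kmer_rate".
#' @param variants variant data.frame (heterozygosity metric).
#' @param assembly,kclass assembly and `kmer_class` (erroneous-k-mer metric).
#' @param n_boot bootstrap replicates (default 1000).
#' @param tile resampling-unit size in bp.
#' @param seed integer seed.
#' @return list with point estimates, bootstrap means, their ratio and the
#'   t-test p-value.
#' @export
bootstrap_compare <- function(regionsA, regionsB,
                              metric = c("heterozygosity", "erroneous_kmer_rate"),
                              variants = NULL, assembly = NULL, kclass = NULL,
                              n_boot = 1000, tile = 1000, seed = 1) {
  metric <- match.arg(metric)
  if (n_boot < 2) stop("n_boot must be at least 2")
  tiles_of <- function(r) {
    if (metric == "heterozygosity") variant_tiles(variants, r, tile)
    else erroneous_kmer_tiles(r, assembly, kclass, tile)
  }
  ta <- tiles_of(regionsA)
  tb <- tiles_of(regionsB)
  boot_tiles(ta, tb, n_boot = n_boot, seed = seed)
}

# Bootstrap comparison given precomputed per-tile numerator/denominator.
boot_tiles <- function(ta, tb, n_boot = 1000, seed = 1) {
  if (n_boot < 2) stop("n_boot must be at least 2")
  if (nrow(ta) < 2 || nrow(tb) < 2)
    stop("need at least 2 resampling units per region set")
  boot <- function(tl) {
    n <- nrow(tl)
    vapply(seq_len(n_boot), function(i) {
      j <- sample.int(n, n, replace = TRUE)
      sum(tl$num[j]) / max(1, sum(tl$den[j]))
    }, 0)
  }
  set.seed(derive_seed(seed, 11))
  da <- boot(ta)
  set.seed(derive_seed(seed, 12))
  db <- boot(tb)
  p <- if (stats::sd(da) == 0 && stats::sd(db) == 0) {
    as.numeric(mean(da) == mean(db))
  } else t.test(da, db)$p.value
  list(estimateA = sum(ta$num) / sum(ta$den),
       estimateB = sum(tb$num) / sum(tb$den),
       meanA = mean(da), meanB = mean(db),
       ratio = mean(da) / mean(db), p_value = p, n_boot = n_boot)
}

#' Heterozygosity of introduced false duplications via masking
#'
#' One member of each confirmed pair is masked to N (the member not
#' overlapping annotation when gene models are given, else the lower-depth
#' member), the reads are remapped to the masked assembly, variants are
#' recalled, and heterozygosity is computed over the surviving members'
#' intervals. Masking restores diploid depth over the surviving copy, so
#' the haplotype difference between the two copies reappears as
#' heterozygous variants.
#'
#' @param assembly an `assembly_index`.
#' @param pairs confirmed duplication pairs.
#' @param reads the `read_set` used for mapping.
#' @param genes optional `gene_models` deciding which member is "original".
#' @param depth optional `depth_profile` on the unmasked assembly.
#' @param seed integer seed for remapping.
#' @param min_depth variant-caller minimum depth.
#' @return list with heterozygosity, variants, surviving regions, the new
#'   alignments/depth, and per-tile counts for bootstrapping.
#' @export
mask_and_recompute_het <- function(assembly, pairs, reads, genes = NULL,
                                   depth = NULL, seed = 1, min_depth = 10) {
  if (!is.null(pairs$confirmed)) pairs <- pairs[pairs$confirmed, , drop = FALSE]
  if (nrow(pairs) == 0) stop("no confirmed pairs to mask")
  gene_spans <- if (!is.null(genes) && length(genes)) do.call(rbind, lapply(
    genes, function(g) iv_df(scaffold = g$scaffold, start = g$start,
                             end = g$end))) else iv_df()
  mask_B <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    p <- pairs[i, ]
    gA <- iv_overlaps_any(gene_spans, p$scaffoldA, p$startA, p$endA)
    gB <- iv_overlaps_any(gene_spans, p$scaffoldB, p$startB, p$endB)
    if (gA != gB) {
      mask_B[i] <- gA  # mask the copy without annotation
    } else if (!is.null(p$depthA) && !is.null(p$depthB) &&
               !is.na(p$depthA) && !is.na(p$depthB) && p$depthA != p$depthB) {
      mask_B[i] <- p$depthB < p$depthA
    } else mask_B[i] <- TRUE
  }
  mask_iv <- iv_df(
    scaffold = ifelse(mask_B, pairs$scaffoldB, pairs$scaffoldA),
    start = ifelse(mask_B, pairs$startB, pairs$startA),
    end = ifelse(mask_B, pairs$endB, pairs$endA))
  surviving <- iv_df(
    scaffold = ifelse(mask_B, pairs$scaffoldA, pairs$scaffoldB),
    start = ifelse(mask_B, pairs$startA, pairs$startB),
    end = ifelse(mask_B, pairs$endA, pairs$endB))
  masked <- mask_intervals(assembly, mask_iv)
  aln2 <- map_reads(reads, masked, seed = seed)
  depth2 <- compute_depth(aln2, masked)
  variants <- call_variants(aln2, reads, masked, min_depth = min_depth,
                            depth = depth2)
  list(heterozygosity = region_heterozygosity(variants, surviving),
       variants = variants, regions = surviving, masked = mask_iv,
       alignments = aln2, depth = depth2,
       tiles = variant_tiles(variants, surviving))
}

#' Genomic partitions (CDS / intron / intergenic) from gene models
#'
#' CDS is the union of all CDS intervals of the longest isoforms; introns
#' are within-gene non-exonic sequence minus CDS; intergenic is the
#' remaining sequence excluding CDS and intron.
#'
#' @param genes a `gene_models` list.
#' @param assembly an `assembly_index`.
#' @return named list of disjoint interval data.frames.
#' @export
derive_genomic_partitions <- function(genes, assembly) {
  genes <- select_longest_isoform(genes)
  cds <- iv_union(do.call(rbind, lapply(genes, function(g) g$isoforms[[1]]$cds)))
  exons <- iv_union(do.call(rbind, lapply(genes, function(g) g$isoforms[[1]]$exons)))
  spans <- iv_union(do.call(rbind, lapply(genes, function(g) {
    e <- g$isoforms[[1]]$exons
    iv_df(scaffold = g$scaffold, start = min(e$start), end = max(e$end))
  })))
  intron <- iv_setdiff(iv_setdiff(spans, exons), cds)
  genome <- iv_df(scaffold = names(assembly$seq), start = 0,
                  end = unname(assembly$length))
  intergenic <- iv_setdiff(iv_setdiff(genome, cds), intron)
  list(CDS = cds, intron = intron, intergenic = intergenic)
}

#' Observed vs expected false-duplication load per genomic partition
#'
#' Observed is the proportion of false-duplication bases in each partition
#' (overlap bp / total FD bp); expected is the partition's share of the
#' assembly. The per-partition differences are tested with a one-way ANOVA
#' across bootstrap replicates of the FD interval set (the package's own
#' construction of the test, noted in the output).
#'
#' @param fds confirmed pair data.frame or plain interval data.frame.
#' @param partitions named list of disjoint interval sets.
#' @param assembly an `assembly_index`.
#' @param n_boot bootstrap replicates for the ANOVA.
#' @param seed integer seed.
#' @return list with the partition table and ANOVA p-value.
#' @export
partition_enrichment <- function(fds, partitions, assembly, n_boot = 200,
                                 seed = 1) {
  fd_iv <- if (!is.null(fds$scaffoldA)) {
    d <- if (!is.null(fds$confirmed)) fds[fds$confirmed, ] else fds
    iv_df(scaffold = c(d$scaffoldA, d$scaffoldB),
          start = c(d$startA, d$startB), end = c(d$endA, d$endB))
  } else fds
  if (nrow(fd_iv) == 0 || iv_total_bp(fd_iv) == 0)
    stop("empty false-duplication set: observed proportions undefined")
  for (nm in names(partitions)) {
    p <- partitions[[nm]]
    if (iv_total_bp(p) != sum(iv_len(p)))
      stop("overlapping features within partition ", nm)
  }
  nms <- names(partitions)
  if (length(nms) > 1) {
    cmb <- utils::combn(nms, 2)
    for (i in seq_len(ncol(cmb)))
      if (iv_intersect_bp(partitions[[cmb[1, i]]], partitions[[cmb[2, i]]]) > 0)
        stop("partitions overlap: ", cmb[1, i], " and ", cmb[2, i])
  }
  obs_of <- function(iv) {
    tot <- iv_total_bp(iv)
    vapply(partitions, function(p) iv_intersect_bp(iv, p) / tot, 0)
  }
  observed <- obs_of(fd_iv)
  expected <- vapply(partitions, iv_total_bp, 0) / assembly$total_length
  tab <- data.frame(partition = nms, observed = unname(observed),
                    expected = unname(expected),
                    difference = unname(observed - expected),
                    stringsAsFactors = FALSE)
  set.seed(derive_seed(seed, 21))
  reps <- lapply(seq_len(n_boot), function(b) {
    j <- sample.int(nrow(fd_iv), nrow(fd_iv), replace = TRUE)
    obs_of(fd_iv[j, , drop = FALSE]) - expected
  })
  long <- data.frame(diff = unlist(reps),
                     partition = factor(rep(nms, times = n_boot)))
  p <- tryCatch(summary(aov(diff ~ partition, data = long))[[1]][
    "partition", "Pr(>F)"], error = function(e) NA_real_)
  list(table = tab, anova_p = p, n_boot = n_boot,
       note = "ANOVA over bootstrap replicates of observed - expected")
}

#' Uncorrected false duplication between assembly versions
#'
#' For a false duplication of length `fd` in the prior assembly with total
#' homologous block length `sum_H_old` there and `sum_H_new` in the new
#' assembly, `uncorrected = sum_H_new - (sum_H_old - fd)`; the duplication
#' is corrected when `uncorrected <= 0`.
#'
#' @param fd false-duplication lengths (bp).
#' @param sum_H_old,sum_H_new homologous block length sums (bp).
#' @return data.frame with `uncorrected` and `corrected`.
#' @export
assess_correction <- function(fd, sum_H_old, sum_H_new) {
  uncorrected <- sum_H_new - (sum_H_old - fd)
  data.frame(fd = fd, sum_H_old = sum_H_old, sum_H_new = sum_H_new,
             uncorrected = uncorrected, corrected = uncorrected <= 0)
}

#' Correction assessment from cross-version alignment blocks
#'
#' Computes, per false duplication of the prior assembly, the homologous
#' block length sums on each side from alignment blocks (query = prior
#' assembly, target = new assembly) and applies [assess_correction()].
#' Duplications with no overlapping block get `sum_H_old = 0` with a
#' warning.
#'
#' @param fds_old intervals of false duplications in the prior assembly.
#' @param blocks alignment blocks prior -> new.
#' @return [assess_correction()] result with one row per duplication.
#' @export
correction_from_blocks <- function(fds_old, blocks) {
  n <- nrow(fds_old)
  h_old <- h_new <- numeric(n)
  for (i in seq_len(n)) {
    ov <- blocks$qname == fds_old$scaffold[i] &
      blocks$qend > fds_old$start[i] & blocks$qstart < fds_old$end[i]
    b <- blocks[ov, , drop = FALSE]
    if (nrow(b) == 0) next
    clip <- pmin(b$qend, fds_old$end[i]) - pmax(b$qstart, fds_old$start[i])
    h_old[i] <- sum(clip)
    h_new[i] <- sum(clip * (b$tend - b$tstart) / (b$qend - b$qstart))
  }
  if (any(h_old == 0))
    warning(sum(h_old == 0), " duplication(s) had no homologous blocks")
  res <- assess_correction(iv_len(fds_old), h_old, h_new)
  cbind(fds_old[, c("scaffold", "start", "end")], res[, -1])
}

#' Summary of confirmed false duplications
#'
#' Totals and assembly percentages by duplication type and placement. The
#' length of one duplication is the mean length of its two homologous
#' members, so type and placement breakdowns each sum to the total.
#'
#' @param pairs typed, confirmed pair data.frame.
#' @param assembly an `assembly_index`.
#' @return list of totals (bp and percent).
#' @export
summarize_duplications <- function(pairs, assembly) {
  if (!is.null(pairs$confirmed)) pairs <- pairs[pairs$confirmed, , drop = FALSE]
  len <- if (nrow(pairs)) ((pairs$endA - pairs$startA) +
                           (pairs$endB - pairs$startB)) / 2 else numeric(0)
  type <- pairs$fd_type %||% rep("unclassified", nrow(pairs))
  tot <- sum(len)
  pct <- function(x) if (assembly$total_length > 0) 100 * x / assembly$total_length else 0
  list(n_pairs = nrow(pairs),
       total_bp = tot, total_pct = pct(tot),
       heterotype_bp = sum(len[type == "heterotype"]),
       homotype_bp = sum(len[type == "homotype"]),
       unclassified_bp = sum(len[type == "unclassified"]),
       same_scaffold_bp = sum(len[pairs$same_scaffold]),
       different_scaffold_bp = sum(len[!pairs$same_scaffold]),
       heterotype_pct = pct(sum(len[type == "heterotype"])),
       homotype_pct = pct(sum(len[type == "homotype"])),
       assembly_bp = assembly$total_length)
}
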