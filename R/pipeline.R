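# Pipeline orchestration: candidates -> evidence -> typing -> impact ->
# statistics, with optional ground-truth scoring, as one classed result.

#' Run the complete false-duplication scan
#'
#' Orchestrates the pipeline: depth profile and cutoffs, cross-assembly and
#' self-alignment candidates, the union set, the three evidence criteria,
#' heterotype/homotype typing from k-mers, annotation impact, and the
#' heterozygosity / erroneous-k-mer statistics. Stages whose inputs are
#' missing (reference assembly, reads, gene models, repeats, truth) are
#' skipped gracefully.
#'
#' @param assembly `assembly_index` under test.
#' @param alignments paired-read alignment table; computed from `reads` with
#'   the internal mapper when NULL.
#' @param reads a `read_set` (needed for k-mer typing, variant calling and
#'   masking-based heterozygosity).
#' @param reference optional second assembly of the same individual/species
#'   for cross-assembly candidates.
#' @param genes optional `gene_models`.
#' @param repeats optional repeat data.frame.
#' @param truth optional ground-truth table (from the simulator).
#' @param cross_blocks,self_blocks optional precomputed alignment blocks
#'   (e.g. from PAF files); computed internally when NULL.
#' @param policy an [evidence_policy()].
#' @param kconfig a [kmer_class_config()].
#' @param error_depth sequencing-error depth preset.
#' @param sanger_mode use the mean*0.75 haploid threshold.
#' @param compute_heterozygosity run the variant/masking statistics stage.
#' @param n_boot bootstrap replicates for the heterozygosity contrast.
#' @param seed integer seed for every stochastic step.
#' @param verbose print stage progress.
#' @return an object of class `fd_scan`.
#' @export
run_false_duplication_scan <- function(assembly, alignments = NULL,
                                       reads = NULL, reference = NULL,
                                       genes = NULL, repeats = NULL,
                                       truth = NULL, cross_blocks = NULL,
                                       self_blocks = NULL,
                                       policy = evidence_policy(),
                                       kconfig = kmer_class_config(),
                                       error_depth = 5, sanger_mode = FALSE,
                                       compute_heterozygosity = TRUE,
                                       n_boot = 1000, seed = 1,
                                       verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.null(alignments)) {
    if (is.null(reads)) stop("need either alignments or reads")
    say("mapping %d read pairs", reads$n_pairs)
    alignments <- map_reads(reads, assembly, seed = derive_seed(seed, 101))
  }
  say("computing depth profile")
  depth <- compute_depth(alignments, assembly)
  cutoffs <- estimate_depth_cutoffs(depth, sanger_mode = sanger_mode,
                                    error_depth = error_depth,
                                    het_min_depth = kconfig$het_min_depth)
  say("depth mode %dx, half-diploid cutoff %.1fx", cutoffs$diploid_depth,
      cutoffs$half_diploid)

  cross <- empty_pairs()
  if (!is.null(reference) || !is.null(cross_blocks)) {
    blocks <- cross_blocks %||% align_assemblies(assembly, reference)
    blocks <- filter_alignment_blocks(blocks)
    cross <- cross_assembly_candidates(blocks)
    say("cross-assembly candidates: %d", nrow(cross))
  }
  self <- self_alignment_candidates(assembly, blocks = self_blocks,
                                    depth = depth, cutoffs = cutoffs)
  say("self-alignment candidates: %d", nrow(self))
  cand <- union_candidates(cross, self)
  say("union candidates: %d", nrow(cand))

  cand <- add_evidence(cand, assembly, depth, alignments, cutoffs, policy)
  cand <- confirm_false_duplications(cand, policy)
  say("confirmed: %d of %d", sum(cand$confirmed), nrow(cand))

  kclass <- NULL
  kmer_stats <- NULL
  cand$fd_type <- rep("unclassified", nrow(cand))
  if (!is.null(reads)) {
    say("counting %d-mers", kconfig$k)
    asm_db <- count_kmers(assembly, k = kconfig$k)
    reads_db <- count_kmers(reads, k = kconfig$k)
    kclass <- classify_kmers(asm_db, reads_db, kconfig)
    conf <- cand[cand$confirmed, , drop = FALSE]
    if (nrow(conf)) {
      typed <- classify_duplication_type(conf, assembly, kclass, depth, kconfig)
      cand$fd_type[match(typed$pair_id, cand$pair_id)] <- typed$fd_type
    }
    dup_prop <- tryCatch(kmer_duplication_proportion(asm_db, reads_db, kconfig),
                         error = function(e) NA_real_)
    kmer_stats <- list(duplication_proportion = as.numeric(dup_prop),
                       haploid_peak = attr(dup_prop, "haploid_peak"))
  }

  confirmed <- cand[cand$confirmed, , drop = FALSE]
  fd_iv <- if (nrow(confirmed)) iv_df(
    scaffold = c(confirmed$scaffoldA, confirmed$scaffoldB),
    start = c(confirmed$startA, confirmed$startB),
    end = c(confirmed$endA, confirmed$endB)) else iv_df()

  impacts <- NULL
  enrichment <- NULL
  if (!is.null(genes) && length(genes)) {
    say("classifying gene impacts")
    impacts <- classify_gene_impacts(confirmed, genes)
    if (nrow(confirmed)) {
      parts <- derive_genomic_partitions(genes, assembly)
      enrichment <- tryCatch(
        partition_enrichment(confirmed, parts, assembly,
                             seed = derive_seed(seed, 102)),
        error = function(e) NULL)
    }
  }
  repeat_counts <- if (!is.null(repeats) && nrow(repeats))
    repeat_element_fd_counts(confirmed, repeats) else NULL

  het <- NULL
  if (compute_heterozygosity && !is.null(reads) && nrow(confirmed)) {
    say("variant calling and masked remapping")
    variants <- call_variants(alignments, reads, assembly, depth = depth)
    genome <- iv_df(scaffold = names(assembly$seq), start = 0,
                    end = unname(assembly$length))
    background <- iv_setdiff(iv_setdiff(genome, fd_iv), assembly$gaps)
    bg_het <- region_heterozygosity(variants, background)
    masked <- mask_and_recompute_het(assembly, confirmed, reads,
                                     genes = genes, depth = depth,
                                     seed = derive_seed(seed, 103))
    cmp <- boot_tiles(masked$tiles, variant_tiles(variants, background),
                      n_boot = n_boot, seed = derive_seed(seed, 104))
    err_stats <- if (!is.null(kclass)) list(
      fd = as.numeric(erroneous_kmer_rate(fd_iv, assembly, kclass)),
      background = as.numeric(erroneous_kmer_rate(background, assembly, kclass)))
    het <- list(background = bg_het, introduced_fd = masked$heterozygosity,
                ratio = cmp$ratio, p_value = cmp$p_value,
                bootstrap = cmp, variants = variants,
                erroneous_kmer_rate = err_stats)
  }

  score <- if (!is.null(truth)) score_against_truth(cand, truth) else NULL

  structure(list(pairs = cand, confirmed = confirmed, depth = depth,
                 cutoffs = cutoffs,
                 summary = summarize_duplications(cand, assembly),
                 impacts = impacts, enrichment = enrichment,
                 repeat_counts = repeat_counts, het = het,
                 kmer = kmer_stats, score = score, policy = policy,
                 kconfig = kconfig, seed = seed,
                 assembly_length = assembly$total_length),
            class = "fd_scan")
}

#' Score confirmed duplications against simulator ground truth
#'
#' Base-level recall and precision by interval intersection (both members
#' of each pair), plus type- and placement-label accuracy over matched
#' pairs (reciprocal overlap of both members >= 0.5). True segmental
#' duplications in the truth table are not counted as recoverable bases,
#' and any confirmed overlap with them is reported separately.
#'
#' @param pairs pair data.frame with `confirmed` (and optionally `fd_type`).
#' @param truth simulator truth table.
#' @param min_ro reciprocal-overlap threshold for pair matching.
#' @return a list of scores in `[0, 1]`.
#' @export
score_against_truth <- function(pairs, truth, min_ro = 0.5) {
  conf <- if (!is.null(pairs$confirmed))
    pairs[pairs$confirmed, , drop = FALSE] else pairs
  fd_truth <- truth[truth$type %in% c("heterotype", "homotype"), , drop = FALSE]
  truth_iv <- iv_df(scaffold = c(fd_truth$scaffoldA, fd_truth$scaffoldB),
                    start = c(fd_truth$startA, fd_truth$startB),
                    end = c(fd_truth$endA, fd_truth$endB))
  pred_iv <- if (nrow(conf)) iv_df(
    scaffold = c(conf$scaffoldA, conf$scaffoldB),
    start = c(conf$startA, conf$startB),
    end = c(conf$endA, conf$endB)) else iv_df()
  inter <- iv_intersect_bp(pred_iv, truth_iv)
  tbp <- iv_total_bp(truth_iv)
  pbp <- iv_total_bp(pred_iv)
  recall <- if (tbp > 0) inter / tbp else NA_real_
  precision <- if (pbp > 0) inter / pbp else 0  # empty prediction convention
  f1 <- if (!is.na(recall) && recall + precision > 0)
    2 * recall * precision / (recall + precision) else 0

  type_ok <- place_ok <- logical(0)
  type_truth <- character(0)
  matched <- 0
  for (i in seq_len(nrow(fd_truth))) {
    tr <- data.frame(scaffoldA = fd_truth$scaffoldA[i],
                     startA = fd_truth$startA[i], endA = fd_truth$endA[i],
                     scaffoldB = fd_truth$scaffoldB[i],
                     startB = fd_truth$startB[i], endB = fd_truth$endB[i],
                     stringsAsFactors = FALSE)
    hit <- 0L
    for (j in seq_len(nrow(conf)))
      if (pair_match(conf[j, ], tr, min_ro) > 0) { hit <- j; break }
    if (hit > 0) {
      matched <- matched + 1
      if (!is.null(conf$fd_type)) {
        type_ok <- c(type_ok, conf$fd_type[hit] == fd_truth$type[i])
        type_truth <- c(type_truth, fd_truth$type[i])
      }
      place_ok <- c(place_ok,
                    conf$same_scaffold[hit] ==
                      (fd_truth$placement[i] == "same_scaffold_gap"))
    }
  }
  acc_of <- function(t) if (any(type_truth == t)) mean(type_ok[type_truth == t])
    else NA_real_
  sd_truth <- truth[truth$type == "true_dup", , drop = FALSE]
  sd_iv <- if (nrow(sd_truth)) iv_df(
    scaffold = c(sd_truth$scaffoldA, sd_truth$scaffoldB),
    start = c(sd_truth$startA, sd_truth$startB),
    end = c(sd_truth$endA, sd_truth$endB)) else iv_df()
  list(recall = recall, precision = precision, f1 = f1,
       type_accuracy = if (length(type_ok)) mean(type_ok) else NA_real_,
       heterotype_accuracy = acc_of("heterotype"),
       homotype_accuracy = acc_of("homotype"),
       placement_accuracy = if (length(place_ok)) mean(place_ok) else NA_real_,
       matched_pairs = matched, n_truth = nrow(fd_truth),
       n_confirmed = nrow(conf),
       true_dup_overlap_bp = iv_intersect_bp(pred_iv, sd_iv),
       empty_prediction = nrow(conf) == 0)
}

#' @export
print.fd_scan <- function(x, ...) {
  s <- x$summary
  cat("False-duplication scan\n")
  cat(sprintf("  assembly: %s bp; depth mode %dx (half-diploid %.1fx)\n",
              format(x$assembly_length, big.mark = ","),
              x$cutoffs$diploid_depth, x$cutoffs$half_diploid))
  cat(sprintf("  candidates: %d, confirmed: %d\n", nrow(x$pairs),
              nrow(x$confirmed)))
  cat(sprintf("  confirmed duplication: %.1f kbp (%.2f%% of assembly)\n",
              s$total_bp / 1e3, s$total_pct))
  cat(sprintf("    heterotype %.1f kbp | homotype %.1f kbp | same scaffold %.1f kbp | different %.1f kbp\n",
              s$heterotype_bp / 1e3, s$homotype_bp / 1e3,
              s$same_scaffold_bp / 1e3, s$different_scaffold_bp / 1e3))
  if (!is.null(x$het))
    cat(sprintf("  heterozygosity: background %.4f%%, introduced FD %.4f%% (ratio %.2f, p=%.2g)\n",
                100 * x$het$background, 100 * x$het$introduced_fd,
                x$het$ratio, x$het$p_value))
  if (!is.null(x$kmer))
    cat(sprintf("  k-mer duplication proportion: %.4f\n",
                x$kmer$duplication_proportion))
  if (!is.null(x$score))
    cat(sprintf("  vs truth: recall %.3f, precision %.3f, type acc %.3f\n",
                x$score$recall, x$score$precision, x$score$type_accuracy))
  invisible(x)
}

#' @export
summary.fd_scan <- function(object, ...) {
  out <- list(summary = object$summary, cutoffs = unclass(object$cutoffs),
              het = object$het[c("background", "introduced_fd", "ratio",
                                 "p_value")],
              kmer = object$kmer, score = object$score,
              n_impact_calls = if (!is.null(object$impacts))
                nrow(object$impacts) else NA)
  class(out) <- "summary.fd_scan"
  out
}

#' @export
print.summary.fd_scan <- function(x, ...) {
  utils::str(x, max.level = 2, give.attr = FALSE)
  invisible(x)
}

#' @export
plot.fd_scan <- function(x, ...) {
  h <- x$depth$histogram
  d <- seq_along(h) - 1
  keep <- d <= max(x$cutoffs$diploid_depth * 2, 20)
  graphics::plot(d[keep], h[keep], type = "h", xlab = "read depth",
                 ylab = "positions", main = "Assembly depth profile", ...)
  graphics::abline(v = x$cutoffs$diploid_depth, col = "steelblue", lwd = 2)
  graphics::abline(v = x$cutoffs$half_diploid, col = "firebrick", lwd = 2,
                   lty = 2)
  if (nrow(x$confirmed)) {
    md <- c(x$confirmed$depthA, x$confirmed$depthB)
    graphics::points(md, rep(max(h[keep]) * 0.05, length(md)), pch = 17,
                     col = "darkorange")
  }
  graphics::legend("topright", legend = c("diploid mode", "half-diploid",
                                          "confirmed FD depth"),
                   col = c("steelblue", "firebrick", "darkorange"),
                   lty = c(1, 2, NA), pch = c(NA, NA, 17), bty = "n")
  invisible(x)
}

#' Write scan outputs to a directory
#'
#' Writes confirmed duplication intervals as BED (name = pair id, score =
#' type code: 1 heterotype, 2 homotype, 0 unclassified), a per-pair TSV
#' with all evidence flags, and a JSON summary with totals by type and
#' placement.
#'
#' @param scan an `fd_scan` (or a pair data.frame plus `assembly`).
#' @param out_dir output directory (created if needed).
#' @param assembly required when `scan` is a plain pair table.
#' @return invisibly, the written paths.
#' @export
write_outputs <- function(scan, out_dir, assembly = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(scan, "fd_scan")) {
    pairs <- scan$pairs
    summ <- scan$summary
  } else {
    pairs <- scan
    if (is.null(assembly)) stop("assembly required for a plain pair table")
    summ <- summarize_duplications(pairs, assembly)
  }
  conf <- if (!is.null(pairs$confirmed))
    pairs[pairs$confirmed, , drop = FALSE] else pairs
  bed <- file.path(out_dir, "false_duplications.bed")
  tsv <- file.path(out_dir, "pairs.tsv")
  js <- file.path(out_dir, "summary.json")
  type_code <- function(t) c(heterotype = 1, homotype = 2)[t]
  iv <- if (nrow(conf)) iv_df(
    scaffold = c(conf$scaffoldA, conf$scaffoldB),
    start = c(conf$startA, conf$startB), end = c(conf$endA, conf$endB)) else
      iv_df()
  sc <- if (nrow(conf)) {
    v <- type_code(conf$fd_type %||% rep(NA, nrow(conf)))
    v[is.na(v)] <- 0
    rep(v, 2)
  } else 0
  write_bed(iv, bed, name = if (nrow(conf)) rep(conf$pair_id, 2) else ".",
            score = sc)
  write.table(pairs, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(summ, js, auto_unbox = TRUE, digits = NA)
  invisible(list(bed = bed, tsv = tsv, json = js))
}
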