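# Read-depth profiles and the three confirmation criteria: haploid-level
# depth, assembly-gap / depth-gap between the duplicated pair, and
# discordant + concordant read-pair anchoring in a shared flank.

#' Compute a per-base read-depth profile
#'
#' Per-base coverage counts over the assembly from a paired-read alignment
#' table; duplicate-flagged pairs and zero-mapping-quality (multi-mapping)
#' reads are excluded, and records outside scaffold bounds are rejected
#' with a count. Read bases of the retained records are conserved exactly:
#' the summed coverage equals their summed aligned read lengths.
#'
#' @param alignments paired-read alignment data.frame.
#' @param assembly an `assembly_index`.
#' @param exclude_duplicates drop duplicate-flagged pairs (default TRUE).
#' @param min_mapq minimum per-mate mapping quality (default 1, which drops
#'   reads placed by a random choice among equal-best locations; tables
#'   without mapping qualities are used in full).
#' @return a `depth_profile` with per-scaffold coverage, genome-wide
#'   histogram, mean and mode.
#' @export
compute_depth <- function(alignments, assembly, exclude_duplicates = TRUE,
                          min_mapq = 1) {
  a <- alignments
  if (exclude_duplicates) a <- a[!a$duplicate, , drop = FALSE]
  q1 <- a$mapq1 %||% rep(60L, nrow(a))
  q2 <- a$mapq2 %||% rep(60L, nrow(a))
  use1 <- a$mapped1 & !is.na(a$scaffold1) & (is.na(q1) | q1 >= min_mapq)
  use2 <- a$mapped2 & !is.na(a$scaffold2) & (is.na(q2) | q2 >= min_mapq)
  cov <- vector("list", length(assembly$seq))
  names(cov) <- names(assembly$seq)
  rejected <- 0
  hist_acc <- numeric(0)
  for (s in names(assembly$seq)) {
    L <- assembly$length[[s]]
    st <- c(a$start1[use1 & a$scaffold1 == s], a$start2[use2 & a$scaffold2 == s])
    en <- c(a$end1[use1 & a$scaffold1 == s], a$end2[use2 & a$scaffold2 == s])
    bad <- st < 0 | en > L
    rejected <- rejected + sum(bad)
    st <- st[!bad]; en <- en[!bad]
    d <- cumsum(tabulate(st + 1, nbins = L + 1) - tabulate(en + 1, nbins = L + 1))
    cov[[s]] <- as.integer(d[seq_len(L)])
    h <- tabulate(cov[[s]] + 1L, nbins = max(cov[[s]], 0) + 1L)
    n <- max(length(hist_acc), length(h))
    hist_acc <- c(hist_acc, numeric(n - length(hist_acc))) +
      c(h, numeric(n - length(h)))
  }
  total_bases <- sum(vapply(cov, function(x) sum(as.numeric(x)), 0))
  structure(list(coverage = cov, histogram = hist_acc,
                 mean = total_bases / assembly$total_length,
                 mode = which.max(hist_acc) - 1L,
                 total_aligned_bases = total_bases, rejected = rejected),
            class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("depth_profile: mean %.1fx, mode %dx over %d scaffold(s)\n",
              x$mean, x$mode, length(x$coverage)))
  invisible(x)
}

#' Mean coverage over intervals
#'
#' @param depth a `depth_profile`.
#' @param scaffold,start,end equal-length vectors describing intervals.
#' @return numeric vector of mean depths.
#' @export
interval_mean_depth <- function(depth, scaffold, start, end) {
  vapply(seq_along(scaffold), function(i) {
    v <- depth$coverage[[scaffold[i]]]
    if (is.null(v) || end[i] <= start[i]) return(NA_real_)
    mean(v[(start[i] + 1):end[i]])
  }, 0)
}

#' Evidence policy for confirming false duplications
#'
#' The default policy requires near-haploid read depth plus at least one
#' supporting signal among assembly gap, depth gap and discordant read
#' pairs. The 550 bp flank and insert threshold follow the mean insert size
#' of the linked reads the method was designed around.
#'
#' @param require_low_depth low depth is mandatory (default TRUE).
#' @param supporting_needed minimum number of supporting flags.
#' @param flank flanking-window size in bp.
#' @param insert_threshold inserts larger than this are discordant (bp).
#' @param member_rule flag a pair when "either" member (default) or "both"
#'   members are below the depth cutoff.
#' @return an `evidence_policy` list.
#' @export
evidence_policy <- function(require_low_depth = TRUE, supporting_needed = 1,
                            flank = 550, insert_threshold = 550,
                            member_rule = c("either", "both")) {
  stopifnot(flank > 0, insert_threshold > 0)
  structure(list(require_low_depth = require_low_depth,
                 supporting_needed = supporting_needed, flank = flank,
                 insert_threshold = insert_threshold,
                 member_rule = match.arg(member_rule)),
            class = "evidence_policy")
}

#' Flag candidate pairs with sub-half-diploid read depth
#'
#' A pair is flagged `low_depth` when the mean coverage of a member interval
#' is strictly below the half-diploid cutoff (either member by default).
#'
#' @param pairs candidate pair data.frame.
#' @param depth a `depth_profile`.
#' @param cutoffs [estimate_depth_cutoffs()] result.
#' @param member_rule "either" or "both".
#' @return pairs with `depthA`, `depthB` and `low_depth` columns.
#' @export
depth_filter <- function(pairs, depth, cutoffs,
                         member_rule = c("either", "both")) {
  member_rule <- match.arg(member_rule)
  if (nrow(pairs) == 0) {
    pairs$depthA <- pairs$depthB <- numeric(0)
    pairs$low_depth <- logical(0)
    return(pairs)
  }
  pairs$depthA <- interval_mean_depth(depth, pairs$scaffoldA, pairs$startA,
                                      pairs$endA)
  pairs$depthB <- interval_mean_depth(depth, pairs$scaffoldB, pairs$startB,
                                      pairs$endB)
  lowA <- pairs$depthA < cutoffs$half_diploid
  lowB <- pairs$depthB < cutoffs$half_diploid
  pairs$low_depth <- if (member_rule == "either") lowA | lowB else lowA & lowB
  pairs
}

#' Assembly-gap and depth-gap evidence for duplication pairs
#'
#' For same-scaffold pairs, `assembly_gap` is true when an N gap lies
#' between the two copies and `depth_gap` when at least one zero-coverage
#' position lies between them. Different-scaffold pairs cannot have a
#' "between" region; for them the same signals are sought within `flank` bp
#' of the duplication-facing contig end (an end of the member's gap-free
#' contig that the member interval approaches within `flank`).
#'
#' @param pairs candidate pair data.frame.
#' @param assembly an `assembly_index`.
#' @param depth a `depth_profile`.
#' @param flank flank size in bp.
#' @return pairs with `assembly_gap` and `depth_gap` columns.
#' @export
gap_evidence <- function(pairs, assembly, depth, flank = 550) {
  contigs <- segment_at_gaps(assembly)
  ag <- dg <- logical(nrow(pairs))
  zero_in <- function(s, a, b) {
    v <- depth$coverage[[s]]
    a <- max(a, 0); b <- min(b, length(v))
    b > a && any(v[(a + 1):b] == 0L)
  }
  gap_in <- function(s, a, b) {
    g <- assembly$gaps
    any(g$scaffold == s & g$start < b & g$end > a)
  }
  for (i in seq_len(nrow(pairs))) {
    p <- pairs[i, ]
    if (p$same_scaffold) {
      a <- min(p$endA, p$endB); b <- max(p$startA, p$startB)
      if (b > a) {
        ag[i] <- gap_in(p$scaffoldA, a, b)
        dg[i] <- zero_in(p$scaffoldA, a, b)
      }
    } else {
      for (m in 1:2) {
        s <- if (m == 1) p$scaffoldA else p$scaffoldB
        st <- if (m == 1) p$startA else p$startB
        en <- if (m == 1) p$endA else p$endB
        ag[i] <- ag[i] || gap_in(s, st - flank, st) || gap_in(s, en, en + flank)
        ctg <- contigs[contigs$scaffold == s & contigs$start <= st &
                       contigs$end >= en, ]
        if (nrow(ctg) == 0)
          ctg <- contigs[contigs$scaffold == s & contigs$start < en &
                         contigs$end > st, ]
        for (j in seq_len(nrow(ctg))) {
          if (st - ctg$start[j] <= flank)  # member faces the left contig end
            dg[i] <- dg[i] || zero_in(s, ctg$start[j], ctg$start[j] + flank)
          if (ctg$end[j] - en <= flank)    # member faces the right contig end
            dg[i] <- dg[i] || zero_in(s, ctg$end[j] - flank, ctg$end[j])
        }
      }
    }
  }
  pairs$assembly_gap <- ag
  pairs$depth_gap <- dg
  pairs
}

# Long form of pairs of mate intervals (both orders), restricted by a
# predicate on the pair rows.
mates_long <- function(a, sel) {
  d <- a[sel, , drop = FALSE]
  data.frame(
    scaf_a = c(d$scaffold1, d$scaffold2), st_a = c(d$start1, d$start2),
    en_a = c(d$end1, d$end2),
    scaf_b = c(d$scaffold2, d$scaffold1), st_b = c(d$start2, d$start1),
    en_b = c(d$end2, d$end1), stringsAsFactors = FALSE)
}

#' Discordant read-pair evidence for duplication pairs
#'
#' A read pair is discordant when its insert (outer distance between mate
#' starts and ends on one scaffold) exceeds the insert threshold or its
#' mates map to different scaffolds. Evidence for a duplication pair
#' requires, in a single flanking window (`flank` bp beside either member),
#' one mate of a discordant pair whose other mate lies in the partner
#' duplication AND one mate of a concordant pair whose other mate lies in
#' the local duplication.
#'
#' @param pairs candidate pair data.frame.
#' @param alignments paired-read alignment data.frame.
#' @param policy an [evidence_policy()].
#' @return pairs with a `discordant` column.
#' @export
discordant_evidence <- function(pairs, alignments, policy = evidence_policy()) {
  a <- alignments[!alignments$duplicate & alignments$mapped1 &
                  alignments$mapped2, , drop = FALSE]
  same <- !is.na(a$scaffold1) & !is.na(a$scaffold2) & a$scaffold1 == a$scaffold2
  span <- pmax(a$end1, a$end2) - pmin(a$start1, a$start2)
  disc <- mates_long(a, !same | (same & span > policy$insert_threshold))
  conc <- mates_long(a, same & span <= policy$insert_threshold)
  fl <- policy$flank

  window_hit <- function(tbl, ws, wst, wen, os, ost, oen) {
    sel <- tbl$scaf_a == ws & tbl$st_a < wen & tbl$en_a > wst
    any(sel & tbl$scaf_b == os & tbl$st_b < oen & tbl$en_b > ost)
  }
  out <- logical(nrow(pairs))
  # pre-split by flank scaffold to keep the scans short
  disc_by <- split(disc, disc$scaf_a)
  conc_by <- split(conc, conc$scaf_a)
  for (i in seq_len(nrow(pairs))) {
    p <- pairs[i, ]
    members <- list(
      list(s = p$scaffoldA, st = p$startA, en = p$endA,
           os = p$scaffoldB, ost = p$startB, oen = p$endB),
      list(s = p$scaffoldB, st = p$startB, en = p$endB,
           os = p$scaffoldA, ost = p$startA, oen = p$endA))
    for (m in members) {
      dtbl <- disc_by[[m$s]]
      ctbl <- conc_by[[m$s]]
      if (is.null(dtbl) || is.null(ctbl)) next
      for (w in list(c(m$st - fl, m$st), c(m$en, m$en + fl))) {
        if (window_hit(dtbl, m$s, w[1], w[2], m$os, m$ost, m$oen) &&
            window_hit(ctbl, m$s, w[1], w[2], m$s, m$st, m$en)) {
          out[i] <- TRUE
          break
        }
      }
      if (out[i]) break
    }
  }
  pairs$discordant <- out
  pairs
}

#' Populate all evidence flags for candidate pairs
#'
#' Convenience wrapper running [depth_filter()], [gap_evidence()] and
#' [discordant_evidence()].
#'
#' @param pairs candidate pair data.frame.
#' @param assembly an `assembly_index`.
#' @param depth a `depth_profile`.
#' @param alignments paired-read alignment data.frame.
#' @param cutoffs [estimate_depth_cutoffs()] result.
#' @param policy an [evidence_policy()].
#' @return pairs with all evidence columns.
#' @export
add_evidence <- function(pairs, assembly, depth, alignments, cutoffs,
                         policy = evidence_policy()) {
  pairs <- depth_filter(pairs, depth, cutoffs, member_rule = policy$member_rule)
  pairs <- gap_evidence(pairs, assembly, depth, flank = policy$flank)
  discordant_evidence(pairs, alignments, policy)
}

#' Confirm false duplications from populated evidence flags
#'
#' A pair is confirmed when it is flagged `low_depth` (if the policy
#' requires it) and carries at least `supporting_needed` of the supporting
#' flags (assembly gap, depth gap, discordant pairs). Relaxing
#' `supporting_needed` never removes a confirmed pair.
#'
#' @param pairs pair data.frame with evidence columns.
#' @param policy an [evidence_policy()].
#' @return pairs with a `confirmed` column.
#' @export
confirm_false_duplications <- function(pairs, policy = evidence_policy()) {
  need <- c("low_depth", "assembly_gap", "depth_gap", "discordant")
  missing <- setdiff(need, names(pairs))
  if (length(missing))
    stop("evidence flags not populated: ", paste(missing, collapse = ", "))
  support <- pairs$assembly_gap + pairs$depth_gap + pairs$discordant
  pairs$confirmed <- (!policy$require_low_depth | pairs$low_depth) &
    support >= policy$supporting_needed
  pairs
}
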