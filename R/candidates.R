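# Candidate duplication pairs from cross-assembly and self alignment.

pair_cols <- c("pair_id", "scaffoldA", "startA", "endA", "scaffoldB",
               "startB", "endB", "source", "same_scaffold")

empty_pairs <- function() {
  data.frame(pair_id = character(), scaffoldA = character(), startA = numeric(),
             endA = numeric(), scaffoldB = character(), startB = numeric(),
             endB = numeric(), source = character(), same_scaffold = logical(),
             stringsAsFactors = FALSE)
}

make_pairs <- function(scafA, startA, endA, scafB, startB, endB, source) {
  d <- data.frame(pair_id = NA_character_, scaffoldA = scafA, startA = startA,
                  endA = endA, scaffoldB = scafB, startB = startB, endB = endB,
                  source = source, same_scaffold = scafA == scafB,
                  stringsAsFactors = FALSE)
  swap <- d$scaffoldB < d$scaffoldA |
    (d$scaffoldB == d$scaffoldA & d$startB < d$startA)
  if (any(swap)) {
    tmp <- d[swap, c("scaffoldA", "startA", "endA")]
    d[swap, c("scaffoldA", "startA", "endA")] <-
      d[swap, c("scaffoldB", "startB", "endB")]
    d[swap, c("scaffoldB", "startB", "endB")] <- tmp
  }
  d
}

finalize_pairs <- function(d) {
  if (nrow(d) == 0) return(empty_pairs())
  d <- d[order(d$scaffoldA, d$startA, d$scaffoldB, d$startB), , drop = FALSE]
  d$pair_id <- sprintf("pair_%03d", seq_len(nrow(d)))
  rownames(d) <- NULL
  d
}

# Match two duplication pairs: both members must reciprocally overlap by
# >= min_ro, in either orientation. Returns 0 (no match), 1 (direct), 2
# (swapped).
pair_match <- function(p, q, min_ro) {
  direct <- iv_reciprocal_overlap(p$scaffoldA, p$startA, p$endA,
                                  q$scaffoldA, q$startA, q$endA) >= min_ro &&
            iv_reciprocal_overlap(p$scaffoldB, p$startB, p$endB,
                                  q$scaffoldB, q$startB, q$endB) >= min_ro
  if (direct) return(1L)
  swapped <- iv_reciprocal_overlap(p$scaffoldA, p$startA, p$endA,
                                   q$scaffoldB, q$startB, q$endB) >= min_ro &&
             iv_reciprocal_overlap(p$scaffoldB, p$startB, p$endB,
                                   q$scaffoldA, q$startA, q$endA) >= min_ro
  if (swapped) 2L else 0L
}

# Greedy merge of matching pairs (interval union per member).
merge_pairs <- function(d, min_ro = 0.5) {
  if (nrow(d) <= 1) return(d)
  kept <- d[1, , drop = FALSE]
  for (i in 2:nrow(d)) {
    p <- d[i, ]
    hit <- 0L
    for (j in seq_len(nrow(kept))) {
      m <- pair_match(kept[j, ], p, min_ro)
      if (m > 0) { hit <- j; mode <- m; break }
    }
    if (hit == 0L) { kept <- rbind(kept, p); next }
    q <- kept[hit, ]
    if (mode == 2L)  # align orientations before the union
      p[, c("scaffoldA", "startA", "endA", "scaffoldB", "startB", "endB")] <-
        p[, c("scaffoldB", "startB", "endB", "scaffoldA", "startA", "endA")]
    kept$startA[hit] <- min(q$startA, p$startA)
    kept$endA[hit] <- max(q$endA, p$endA)
    kept$startB[hit] <- min(q$startB, p$startB)
    kept$endB[hit] <- max(q$endB, p$endB)
    if (q$source != p$source) kept$source[hit] <- "both"
  }
  kept
}

#' Filter and chain alignment blocks
#'
#' Removes blocks whose aligned query span is shorter than `min_len`, chains
#' collinear blocks of the same query/target/strand combination when the gap
#' on both sequences is at most `join_distance`, and removes chained blocks
#' whose query interval is covered by alignment for less than
#' `min_query_cov` of its length. Both removals use strict inequalities, so
#' a 20 bp block and exactly 80% coverage are retained.
#'
#' @param blocks alignment blocks (from [load_alignment_blocks()] or
#'   [align_assemblies()]).
#' @param min_len minimum aligned query span (bp).
#' @param min_query_cov minimum aligned fraction of the chained query interval.
#' @param join_distance maximum gap bridged when chaining (bp).
#' @return filtered, chained block data.frame.
#' @export
filter_alignment_blocks <- function(blocks, min_len = 20, min_query_cov = 0.80,
                                    join_distance = 1000) {
  if (nrow(blocks) == 0) return(blocks)
  blocks <- blocks[blocks$qend - blocks$qstart >= min_len, , drop = FALSE]
  if (nrow(blocks) == 0) return(blocks)
  chains <- chain_blocks(blocks, join_distance)
  cov <- pmin(1, chains$aligned_bp / (chains$qend - chains$qstart))
  out <- chains[cov >= min_query_cov, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Merge blocks of the same (qname, tname, strand) whose query and target
# intervals are within `join` bp of each other.
chain_blocks <- function(blocks, join) {
  if (nrow(blocks) == 0) return(blocks)
  if (is.null(blocks$aligned_bp)) blocks$aligned_bp <- blocks$qend - blocks$qstart
  key <- paste(blocks$qname, blocks$tname, blocks$strand, sep = "\r")
  parts <- split(blocks, key)
  out <- lapply(parts, function(d) {
    d <- d[order(d$qstart), , drop = FALSE]
    grp <- integer(nrow(d))
    g <- 1L
    grp[1] <- g
    if (nrow(d) > 1) {
      # a block continues the chain only when it advances both sequences in
      # the orientation's direction by at most `join` (bounded diagonal
      # drift); otherwise it starts a new chain
      q_end <- d$qend[1]
      t_lo <- d$tstart[1]
      t_hi <- d$tend[1]
      for (i in 2:nrow(d)) {
        qgap <- d$qstart[i] - q_end
        tgap <- if (d$strand[i] == "+") d$tstart[i] - t_hi else t_lo - d$tend[i]
        if (qgap > join || tgap > join || tgap < -join) {
          g <- g + 1L
          q_end <- d$qend[i]
          t_lo <- d$tstart[i]
          t_hi <- d$tend[i]
        } else {
          q_end <- max(q_end, d$qend[i])
          t_lo <- min(t_lo, d$tstart[i])
          t_hi <- max(t_hi, d$tend[i])
        }
        grp[i] <- g
      }
    }
    do.call(rbind, lapply(split(d, grp), function(e) data.frame(
      qname = e$qname[1], qstart = min(e$qstart), qend = max(e$qend),
      strand = e$strand[1], tname = e$tname[1], tstart = min(e$tstart),
      tend = max(e$tend), matches = sum(e$matches),
      block_len = sum(e$block_len),
      identity = sum(e$matches) / max(1, sum(e$block_len)),
      aligned_bp = min(sum(e$aligned_bp), max(e$qend) - min(e$qstart)),
      stringsAsFactors = FALSE)))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Align two assemblies (or an assembly to itself) at desk scale
#'
#' Exact shared 31-mer anchors are chained on a common (anti)diagonal;
#' chains of at least `min_chain` bp with anchor-density-estimated identity
#' of at least `min_identity` become alignment blocks. This substitution-only
#' chainer is the package's internal stand-in for a whole-genome aligner at
#' the scale of the bundled simulations. For self-alignment the assembly is
#' segmented at N gaps first and hits of a contig to itself are excluded;
#' block coordinates are reported in scaffold coordinates.
#'
#' @param query,target `assembly_index` objects (pass the same object with
#'   `self = TRUE` for self-alignment).
#' @param k anchor length (bp, max 31).
#' @param max_gap maximum anchor gap within a chain (bp).
#' @param min_chain minimum chain span (bp).
#' @param min_identity minimum estimated identity.
#' @param max_hits anchors occurring more often than this in the target are
#'   skipped (repeat shielding).
#' @param self logical; self-alignment mode.
#' @return alignment block data.frame (same shape as
#'   [load_alignment_blocks()]).
#' @export
align_assemblies <- function(query, target, k = 31, max_gap = 1000,
                             min_chain = 500, min_identity = 0.9,
                             max_hits = 64, self = FALSE) {
  if (self) {
    ctg <- segment_at_gaps(query)
    seqs <- vapply(seq_len(nrow(ctg)), function(i)
      asm_seq(query, ctg$scaffold[i], ctg$start[i], ctg$end[i]), "")
    qmap <- tmap <- ctg
    qseqs <- tseqs <- seqs
  } else {
    qmap <- iv_df(scaffold = names(query$seq), start = 0,
                  end = unname(query$length))
    tmap <- iv_df(scaffold = names(target$seq), start = 0,
                  end = unname(target$length))
    qseqs <- unname(query$seq)
    tseqs <- unname(target$seq)
  }
  ch <- anchor_chain_cpp(qseqs, tseqs, k, max_gap, max_hits, self)
  if (nrow(ch) == 0) return(empty_blocks())
  span <- ch$qend - ch$qstart
  dens <- pmin(1, ch$n_anchors / pmax(1, span - k + 1))
  ident <- dens^(1 / k)
  keep <- span >= min_chain & ident >= min_identity
  ch <- ch[keep, , drop = FALSE]
  if (nrow(ch) == 0) return(empty_blocks())
  span <- span[keep]; ident <- ident[keep]
  data.frame(
    qname = qmap$scaffold[ch$qid], qstart = qmap$start[ch$qid] + ch$qstart,
    qend = qmap$start[ch$qid] + ch$qend, strand = ch$strand,
    tname = tmap$scaffold[ch$tid], tstart = tmap$start[ch$tid] + ch$tstart,
    tend = tmap$start[ch$tid] + ch$tend,
    matches = round(ident * span), block_len = span, identity = ident,
    aligned_bp = pmin(span, ch$anchor_cov), stringsAsFactors = FALSE)
}

#' Candidate duplication pairs from cross-assembly alignment
#'
#' Reference intervals hit by two or more distinct query intervals (after
#' chaining query fragments of the same homolog within `join_distance`) are
#' one-to-many homologs: each unordered pair of query projections of a
#' multiply-covered reference region becomes a candidate duplication pair on
#' the query assembly.
#'
#' @param blocks filtered alignment blocks, query = assembly under test,
#'   target = the other assembly of the same species.
#' @param join_distance merge distance for fragments of one homolog (bp).
#' @param min_pair_len minimum projected member length (bp).
#' @return candidate pair data.frame (`source = "cross"`).
#' @export
cross_assembly_candidates <- function(blocks, join_distance = 5000,
                                      min_pair_len = 100) {
  if (nrow(blocks) == 0) return(empty_pairs())
  ch <- chain_blocks(blocks, join_distance)
  out <- empty_pairs()
  for (tn in unique(ch$tname)) {
    d <- ch[ch$tname == tn, , drop = FALSE]
    if (nrow(d) < 2) next
    cov <- IRanges::coverage(IRanges::IRanges(d$tstart + 1, d$tend))
    multi <- IRanges::slice(cov, lower = 2, rangesOnly = TRUE)
    if (length(multi) == 0) next
    for (ri in seq_along(multi)) {
      rs <- IRanges::start(multi)[ri] - 1
      re <- IRanges::end(multi)[ri]
      hit <- which(pmin(d$tend, re) - pmax(d$tstart, rs) >= min_pair_len)
      if (length(hit) < 2) next
      proj <- lapply(hit, function(i) {
        a <- max(d$tstart[i], rs); b <- min(d$tend[i], re)
        if (d$strand[i] == "+")
          c(d$qstart[i] + (a - d$tstart[i]), d$qstart[i] + (b - d$tstart[i]))
        else
          c(d$qstart[i] + (d$tend[i] - b), d$qstart[i] + (d$tend[i] - a))
      })
      cmb <- utils::combn(seq_along(hit), 2)
      for (ci in seq_len(ncol(cmb))) {
        i <- cmb[1, ci]; j <- cmb[2, ci]
        ro <- iv_reciprocal_overlap(d$qname[hit[i]], proj[[i]][1], proj[[i]][2],
                                    d$qname[hit[j]], proj[[j]][1], proj[[j]][2])
        if (ro >= 0.5) next  # same query locus aligned twice, not a pair
        out <- rbind(out, make_pairs(d$qname[hit[i]], proj[[i]][1], proj[[i]][2],
                                     d$qname[hit[j]], proj[[j]][1], proj[[j]][2],
                                     "cross"))
      }
    }
  }
  if (nrow(out) == 0) return(empty_pairs())
  finalize_pairs(merge_pairs(out, min_ro = 0.5))
}

#' Candidate duplication pairs from self-alignment
#'
#' Pairs of homologous intervals between gap-segmented contigs (self-hits of
#' a contig to itself excluded) where at least one member's mean read depth
#' is below the half-diploid cutoff.
#'
#' @param assembly an `assembly_index`.
#' @param blocks optional precomputed self-alignment blocks; when `NULL` the
#'   internal aligner is used.
#' @param depth a `depth_profile` (required).
#' @param cutoffs [estimate_depth_cutoffs()] result.
#' @param join_distance merge distance for fragments of one homolog (bp).
#' @param ... passed to [align_assemblies()].
#' @return candidate pair data.frame (`source = "self"`).
#' @export
self_alignment_candidates <- function(assembly, blocks = NULL, depth, cutoffs,
                                      join_distance = 5000, ...) {
  if (missing(depth) || is.null(depth))
    stop("self-alignment candidates require a depth profile")
  if (is.null(blocks))
    blocks <- align_assemblies(assembly, assembly, self = TRUE, ...)
  blocks <- filter_alignment_blocks(blocks)
  if (nrow(blocks) == 0) return(empty_pairs())
  ch <- chain_blocks(blocks, join_distance)
  p <- make_pairs(ch$qname, ch$qstart, ch$qend, ch$tname, ch$tstart, ch$tend,
                  "self")
  # drop residual self-hits (both members essentially the same interval)
  same <- p$scaffoldA == p$scaffoldB &
    mapply(iv_reciprocal_overlap, p$scaffoldA, p$startA, p$endA,
           p$scaffoldB, p$startB, p$endB) >= 0.5
  p <- p[!same, , drop = FALSE]
  if (nrow(p) == 0) return(empty_pairs())
  p <- merge_pairs(p, min_ro = 0.8)
  mA <- interval_mean_depth(depth, p$scaffoldA, p$startA, p$endA)
  mB <- interval_mean_depth(depth, p$scaffoldB, p$startB, p$endB)
  p <- p[pmin(mA, mB) < cutoffs$half_diploid, , drop = FALSE]
  finalize_pairs(p)
}

#' Union of cross-assembly and self-alignment candidates
#'
#' Pairs from the two independent sources whose members reciprocally
#' overlap by at least `min_ro` are merged (interval union,
#' `source = "both"`); the rest are concatenated. The operation is
#' commutative and idempotent.
#'
#' @param cross,self candidate pair data.frames.
#' @param min_ro reciprocal-overlap threshold for merging.
#' @return merged candidate pair data.frame.
#' @export
union_candidates <- function(cross, self, min_ro = 0.5) {
  d <- rbind(cross[, pair_cols], self[, pair_cols])
  if (nrow(d) == 0) return(empty_pairs())
  finalize_pairs(merge_pairs(d, min_ro = min_ro))
}

#' Estimate read-depth cutoffs from a coverage histogram
#'
#' The diploid depth is the modal depth above the sequencing-error depth
#' (smallest depth among tied bins); the haploid threshold is half of it,
#' or `mean * 0.75` in `sanger_mode` (for unimodal low-coverage data).
#' `error_depth` and `het_min_depth` are dataset presets.
#'
#' @param depth a `depth_profile`, or a numeric histogram of per-base depth
#'   counts (first element = depth 0).
#' @param sanger_mode use the mean-based haploid threshold.
#' @param error_depth depth at or below which coverage is treated as error.
#' @param het_min_depth minimum average depth for heterotype single-copy
#'   k-mer evidence.
#' @return a `coverage_cutoffs` list.
#' @export
estimate_depth_cutoffs <- function(depth, sanger_mode = FALSE, error_depth = 5,
                                   het_min_depth = 5) {
  if (inherits(depth, "depth_profile")) {
    hist <- depth$histogram
    mean_depth <- depth$mean
  } else {
    hist <- as.numeric(depth)
    mean_depth <- sum((seq_along(hist) - 1) * hist) / max(1, sum(hist))
  }
  depths <- seq_along(hist) - 1
  usable <- depths > error_depth
  if (!any(usable) || sum(hist[usable]) == 0)
    stop("degenerate depth histogram: no mass above the error depth")
  diploid <- depths[usable][which.max(hist[usable])]
  half <- if (sanger_mode) mean_depth * 0.75 else diploid / 2
  structure(list(error_depth = error_depth, diploid_depth = diploid,
                 half_diploid = half, het_min_depth = het_min_depth,
                 sanger_mode = sanger_mode, mean_depth = mean_depth),
            class = "coverage_cutoffs")
}
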