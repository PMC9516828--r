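# Impact of confirmed false duplications on gene annotation: false gene
# gains (FGG), false exon gains (FEG), false chimeric gains (FCG), affected
# repeat elements, and the "-like" gene scaffold screen.

#' Keep the longest-CDS isoform of each gene
#'
#' Retains, per gene, the isoform with the largest total CDS length (ties
#' broken by lexicographically smallest isoform id). Genes without CDS are
#' dropped with a warning.
#'
#' @param genes a `gene_models` list.
#' @return `gene_models` with exactly one isoform per gene.
#' @export
select_longest_isoform <- function(genes) {
  out <- list()
  dropped <- character(0)
  for (g in genes) {
    lens <- vapply(g$isoforms, function(i) sum(iv_len(i$cds)), 0)
    if (length(lens) == 0 || max(lens) == 0) {
      dropped <- c(dropped, g$gene_id)
      next
    }
    best <- which(lens == max(lens))
    ids <- vapply(g$isoforms[best], `[[`, "", "isoform_id")
    g$isoforms <- g$isoforms[best[order(ids)][1]]
    out[[g$gene_id]] <- g
  }
  if (length(dropped))
    warning("dropped ", length(dropped), " gene(s) without CDS: ",
            paste(utils::head(dropped, 5), collapse = ", "))
  structure(out, class = "gene_models")
}

# CDS span of the (single) isoform of a gene.
gene_cds_span <- function(g) {
  cds <- g$isoforms[[1]]$cds
  c(min(cds$start), max(cds$end))
}

# Map a position interval from one pair member onto the other (linear,
# length-scaled; members of a pair are homologous and near-equal length).
project_to_partner <- function(st, en, m_st, m_en, p_st, p_en) {
  scale <- (p_en - p_st) / (m_en - m_st)
  c(p_st + (st - m_st) * scale, p_st + (en - m_st) * scale)
}

#' Classify gene-annotation impacts of confirmed false duplications
#'
#' A gene (longest isoform) qualifies for a call only when at least one of
#' its coding exons is completely contained in a confirmed duplication
#' interval. It is a false gene gain (FGG) when more than half of its CDS
#' length is duplicated; otherwise a false chimeric gain (FCG) when the
#' homologous partner interval of the duplicated part lies within a
#' different gene's CDS span, and a false exon gain (FEG) otherwise
#' (including partners landing in intergenic sequence). FGG takes
#' precedence over FCG over FEG.
#'
#' @param pairs confirmed duplication pairs.
#' @param genes a `gene_models` list.
#' @param partner_min_frac fraction of the projected partner interval that
#'   must fall inside another gene's span for an FCG call.
#' @return data.frame of impact calls.
#' @export
classify_gene_impacts <- function(pairs, genes, partner_min_frac = 0.5) {
  if (!is.null(pairs$confirmed)) pairs <- pairs[pairs$confirmed, , drop = FALSE]
  genes <- select_longest_isoform(genes)
  empty <- data.frame(gene_id = character(), impact_class = character(),
                      duplicated_cds_fraction = numeric(),
                      partner_gene_id = character(), pair_ids = character(),
                      stringsAsFactors = FALSE)
  if (nrow(pairs) == 0 || length(genes) == 0) return(empty)

  members <- rbind(
    data.frame(pair_id = pairs$pair_id, scaffold = pairs$scaffoldA,
               start = pairs$startA, end = pairs$endA,
               p_scaffold = pairs$scaffoldB, p_start = pairs$startB,
               p_end = pairs$endB, stringsAsFactors = FALSE),
    data.frame(pair_id = pairs$pair_id, scaffold = pairs$scaffoldB,
               start = pairs$startB, end = pairs$endB,
               p_scaffold = pairs$scaffoldA, p_start = pairs$startA,
               p_end = pairs$endA, stringsAsFactors = FALSE))

  spans <- do.call(rbind, lapply(genes, function(g) {
    sp <- gene_cds_span(g)
    data.frame(gene_id = g$gene_id, scaffold = g$scaffold, start = sp[1],
               end = sp[2], stringsAsFactors = FALSE)
  }))

  calls <- empty
  for (gid in sort(names(genes))) {
    g <- genes[[gid]]
    cds <- g$isoforms[[1]]$cds
    sp <- gene_cds_span(g)
    ov <- members$scaffold == g$scaffold & members$start < sp[2] &
      members$end > sp[1]
    if (!any(ov)) next
    mem <- members[ov, , drop = FALSE]
    complete <- vapply(seq_len(nrow(mem)), function(i)
      any(cds$start >= mem$start[i] & cds$end <= mem$end[i]), TRUE)
    if (!any(complete)) next
    fd_iv <- iv_df(scaffold = mem$scaffold, start = mem$start, end = mem$end)
    frac <- iv_intersect_bp(cds, fd_iv) / sum(iv_len(cds))
    cls <- NA_character_
    partner_gene <- NA_character_
    if (frac > 0.5) {
      cls <- "FGG"
    } else {
      # project each completely duplicated coding exon onto the homologous
      # partner interval; landing inside a different gene's span makes the
      # call chimeric
      for (i in which(complete)) {
        inside <- which(cds$start >= mem$start[i] & cds$end <= mem$end[i])
        others <- spans[spans$gene_id != gid &
                        spans$scaffold == mem$p_scaffold[i], , drop = FALSE]
        if (nrow(others) == 0) next
        for (e in inside) {
          pr <- project_to_partner(cds$start[e], cds$end[e], mem$start[i],
                                   mem$end[i], mem$p_start[i], mem$p_end[i])
          inb <- pmin(others$end, pr[2]) - pmax(others$start, pr[1])
          j <- which(inb / (pr[2] - pr[1]) > partner_min_frac)
          if (length(j)) {
            cls <- "FCG"
            partner_gene <- others$gene_id[j[1]]
            break
          }
        }
        if (!is.na(cls)) break
      }
      if (is.na(cls)) cls <- "FEG"
    }
    calls <- rbind(calls, data.frame(
      gene_id = gid, impact_class = cls, duplicated_cds_fraction = frac,
      partner_gene_id = partner_gene,
      pair_ids = paste(sort(unique(mem$pair_id)), collapse = ","),
      stringsAsFactors = FALSE))
  }
  rownames(calls) <- NULL
  calls
}

#' Count repeat elements affected by false duplications
#'
#' A repeat copy is affected when its interval overlaps a confirmed
#' duplication interval by at least one base (half-open intervals, so
#' abutting features do not count).
#'
#' @param pairs confirmed duplication pairs.
#' @param repeats repeat data.frame (scaffold/start/end/repeat_class).
#' @return per-class counts and affected fractions.
#' @export
repeat_element_fd_counts <- function(pairs, repeats) {
  if (!is.null(pairs$confirmed)) pairs <- pairs[pairs$confirmed, , drop = FALSE]
  repeats$repeat_class <- normalize_repeat_class(repeats$repeat_class)
  fd_iv <- if (nrow(pairs)) iv_df(
    scaffold = c(pairs$scaffoldA, pairs$scaffoldB),
    start = c(pairs$startA, pairs$startB),
    end = c(pairs$endA, pairs$endB)) else iv_df()
  affected <- vapply(seq_len(nrow(repeats)), function(i)
    iv_overlaps_any(fd_iv, repeats$scaffold[i], repeats$start[i],
                    repeats$end[i]), TRUE)
  agg <- lapply(split(affected, repeats$repeat_class), function(x)
    data.frame(n_total = length(x), n_affected = sum(x),
               fraction = sum(x) / length(x)))
  out <- do.call(rbind, agg)
  out <- cbind(data.frame(repeat_class = rownames(out),
                          stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}

#' Screen scaffolds for "-like" false gene gains
#'
#' Flags scaffolds where (a) a gene whose product name is an existing
#' gene's product plus the pattern suffix resides, (b) the scaffold aligns
#' within the original gene's genic region, and (c) the "-like" gene covers
#' more than `min_fraction` of the scaffold. When a depth profile is given,
#' the half-diploid depth criterion is added.
#'
#' @param assembly an `assembly_index`.
#' @param genes a `gene_models` list.
#' @param blocks alignment blocks from the "-like" scaffolds to the rest of
#'   the assembly (e.g. self-alignment blocks).
#' @param pattern suffix identifying copy-named genes (default "-like").
#' @param min_fraction minimum fraction of the scaffold covered by the
#'   "-like" gene.
#' @param min_align_fraction minimum fraction of the scaffold aligned into
#'   the original gene's genic region.
#' @param depth,cutoffs optional depth criterion inputs.
#' @return data.frame of screened "-like" genes with a `flagged` column.
#' @export
screen_like_gene_scaffolds <- function(assembly, genes, blocks,
                                       pattern = "-like", min_fraction = 0.5,
                                       min_align_fraction = 0.9, depth = NULL,
                                       cutoffs = NULL) {
  prods <- vapply(genes, function(g) g$product %||% NA_character_, "")
  is_like <- !is.na(prods) & endsWith(prods, pattern)
  out <- data.frame(like_gene = character(), scaffold = character(),
                    original_gene = character(), gene_fraction = numeric(),
                    align_fraction = numeric(), low_depth = logical(),
                    flagged = logical(), status = character(),
                    stringsAsFactors = FALSE)
  for (g in genes[is_like]) {
    base <- substr(g$product, 1, nchar(g$product) - nchar(pattern))
    orig <- genes[!is_like & !is.na(prods) & prods == base]
    row <- data.frame(like_gene = g$gene_id, scaffold = g$scaffold,
                      original_gene = NA_character_, gene_fraction = NA_real_,
                      align_fraction = NA_real_, low_depth = NA,
                      flagged = FALSE, status = "unmatched",
                      stringsAsFactors = FALSE)
    if (length(orig)) {
      o <- orig[[1]]
      slen <- assembly$length[[g$scaffold]]
      row$original_gene <- o$gene_id
      row$gene_fraction <- (g$end - g$start) / slen
      b <- blocks[blocks$qname == g$scaffold & blocks$tname == o$scaffold &
                  blocks$tstart < o$end & blocks$tend > o$start, , drop = FALSE]
      row$align_fraction <- if (nrow(b))
        iv_total_bp(iv_df(scaffold = b$qname, start = b$qstart, end = b$qend)) /
          slen else 0
      row$low_depth <- if (!is.null(depth) && !is.null(cutoffs))
        interval_mean_depth(depth, g$scaffold, 0, slen) < cutoffs$half_diploid
        else NA
      row$flagged <- row$gene_fraction > min_fraction &
        row$align_fraction >= min_align_fraction &
        (is.na(row$low_depth) | row$low_depth)
      row$status <- "matched"
    }
    out <- rbind(out, row)
  }
  rownames(out) <- NULL
  out
}
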