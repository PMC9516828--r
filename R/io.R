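# Readers/writers for the standard formats the pipeline touches and the
# internal tabular formats it defines.

#' Load pairwise alignment blocks from a PAF file
#'
#' Coordinates are kept 0-based half-open as in PAF; `matches` is column 10,
#' `block_len` column 11, and `identity = matches / block_len`.
#'
#' @param path PAF file (12+ columns).
#' @return data.frame of alignment blocks.
#' @export
load_alignment_blocks <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_blocks())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- vapply(fields, length, 0L)
  if (any(n < 12))
    stop("malformed PAF line ", which(n < 12)[1], ": fewer than 12 columns")
  num <- function(i) suppressWarnings(as.numeric(vapply(fields, `[[`, "", i)))
  chr <- function(i) vapply(fields, `[[`, "", i)
  b <- data.frame(
    qname = chr(1), qlen = num(2), qstart = num(3), qend = num(4),
    strand = chr(5), tname = chr(6), tlen = num(7), tstart = num(8),
    tend = num(9), matches = num(10), block_len = num(11),
    stringsAsFactors = FALSE)
  bad <- which(is.na(b$qstart) | is.na(b$qend) | is.na(b$tstart) |
               is.na(b$tend) | is.na(b$matches) | is.na(b$block_len) |
               !(b$strand %in% c("+", "-")))
  if (length(bad))
    stop("malformed PAF line ", bad[1], ": non-numeric coordinate or bad strand")
  b$identity <- ifelse(b$block_len > 0, b$matches / b$block_len, NA_real_)
  b$aligned_bp <- b$qend - b$qstart
  b[, c("qname", "qstart", "qend", "strand", "tname", "tstart", "tend",
        "matches", "block_len", "identity", "aligned_bp")]
}

empty_blocks <- function() {
  data.frame(qname = character(), qstart = numeric(), qend = numeric(),
             strand = character(), tname = character(), tstart = numeric(),
             tend = numeric(), matches = numeric(), block_len = numeric(),
             identity = numeric(), aligned_bp = numeric(),
             stringsAsFactors = FALSE)
}

#' Write alignment blocks as PAF
#'
#' @param blocks block data.frame (as from [load_alignment_blocks()]).
#' @param qlens,tlens named lengths of query/target sequences.
#' @param path output path.
#' @export
write_paf <- function(blocks, qlens, tlens, path) {
  lines <- vapply(seq_len(nrow(blocks)), function(i) {
    paste(blocks$qname[i], qlens[[blocks$qname[i]]], blocks$qstart[i],
          blocks$qend[i], blocks$strand[i], blocks$tname[i],
          tlens[[blocks$tname[i]]], blocks$tstart[i], blocks$tend[i],
          round(blocks$matches[i]), round(blocks$block_len[i]), 60L,
          sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write intervals as BED6
#'
#' @param iv intervals (scaffold/start/end, 0-based half-open).
#' @param path output path.
#' @param name,score optional per-record name and score vectors.
#' @export
write_bed <- function(iv, path, name = ".", score = 0) {
  if (nrow(iv) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  d <- data.frame(iv$scaffold, format(iv$start, scientific = FALSE, trim = TRUE),
                  format(iv$end, scientific = FALSE, trim = TRUE),
                  rep_len(name, nrow(iv)), rep_len(score, nrow(iv)), ".")
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Load a BED file of intervals
#'
#' @param path BED3+ file.
#' @return interval data.frame (plus `name`, `score` when present).
#' @export
load_bed <- function(path) {
  d <- tryCatch(read.delim(path, header = FALSE, stringsAsFactors = FALSE),
                error = function(e) NULL)
  if (is.null(d) || nrow(d) == 0) return(iv_df())
  out <- iv_df(scaffold = d[[1]], start = d[[2]], end = d[[3]])
  if (ncol(d) >= 4) out$name <- as.character(d[[4]])
  if (ncol(d) >= 5) out$score <- d[[5]]
  out
}

#' Load repeat annotations from BED
#'
#' Column 4 is mapped onto the controlled repeat vocabulary
#' (LTR/SINE/LINE/DNA/RNA/satellite); anything else becomes "other".
#'
#' @param path BED file with the repeat class in column 4.
#' @return interval data.frame with a `repeat_class` column.
#' @export
load_repeats <- function(path) {
  d <- load_bed(path)
  if (nrow(d) == 0) return(cbind(iv_df(), data.frame(repeat_class = character())))
  d$repeat_class <- normalize_repeat_class(d$name %||% "other")
  d[, c("scaffold", "start", "end", "repeat_class")]
}

normalize_repeat_class <- function(x) {
  vocab <- c("LTR", "SINE", "LINE", "DNA", "RNA", "satellite")
  up <- toupper(x)
  out <- rep("other", length(x))
  for (v in vocab) out[startsWith(up, toupper(v))] <- v
  out
}

# ---------------------------------------------------------------------------
# Paired-read alignment table (internal TSV) and SAM/BAM input.

aln_columns <- c("read_id", "scaffold1", "start1", "end1", "strand1", "nm1",
                 "mapped1", "mapq1", "scaffold2", "start2", "end2", "strand2",
                 "nm2", "mapped2", "mapq2", "duplicate")

#' Write a paired-read alignment table (TSV)
#'
#' @param aln alignment data.frame (one row per read pair).
#' @param path output path.
#' @export
write_read_alignments <- function(aln, path) {
  write.table(aln[, aln_columns], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Load paired-read alignments
#'
#' Accepts the internal TSV produced by [write_read_alignments()] or a
#' coordinate-sorted SAM/BAM file (read via Rsamtools); mate pairs are joined
#' on the read name and duplicate-marked pairs keep their flag.
#'
#' @param path TSV, SAM or BAM path.
#' @return alignment data.frame, one row per read pair.
#' @export
load_read_alignments <- function(path) {
  if (grepl("\\.(sam|bam)$", path, ignore.case = TRUE))
    return(load_sam_pairs(path))
  d <- read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(aln_columns, names(d))
  if (length(missing))
    stop("alignment TSV is missing columns: ", paste(missing, collapse = ", "))
  d$mapped1 <- as.logical(d$mapped1)
  d$mapped2 <- as.logical(d$mapped2)
  d$duplicate <- as.logical(d$duplicate)
  d
}

load_sam_pairs <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  } else bam <- path
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "qwidth", "strand", "mapq"),
    tag = "NM")
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  flag <- x$flag
  keep <- bitwAnd(flag, 256L) == 0L & bitwAnd(flag, 2048L) == 0L
  d <- data.frame(qname = x$qname, flag = flag,
                  scaffold = as.character(x$rname), pos = x$pos,
                  width = x$qwidth, strand = as.character(x$strand),
                  mapq = x$mapq, nm = x$tag$NM %||% NA_integer_,
                  stringsAsFactors = FALSE)[keep, ]
  d$mapped <- bitwAnd(d$flag, 4L) == 0L
  d$first <- bitwAnd(d$flag, 128L) == 0L  # first-in-pair or unpaired
  d$dup <- bitwAnd(d$flag, 1024L) != 0L
  m1 <- d[d$first, ]
  m2 <- d[!d$first, ]
  i <- match(m1$qname, m2$qname)
  pair_row <- function(m, suffix) {
    out <- data.frame(
      scaffold = ifelse(m$mapped, m$scaffold, NA_character_),
      start = ifelse(m$mapped, m$pos - 1L, NA_real_),
      end = ifelse(m$mapped, m$pos - 1L + m$width, NA_real_),
      strand = ifelse(m$mapped, m$strand, NA_character_),
      nm = m$nm, mapped = m$mapped,
      mapq = ifelse(m$mapped, m$mapq, NA_integer_), stringsAsFactors = FALSE)
    names(out) <- paste0(c("scaffold", "start", "end", "strand", "nm",
                           "mapped", "mapq"), suffix)
    out
  }
  m2m <- m2[ifelse(is.na(i), 1L, i), ]
  none2 <- is.na(i)
  r2 <- pair_row(m2m, "2")
  r2[none2, ] <- list(NA_character_, NA_real_, NA_real_, NA_character_,
                      NA_integer_, FALSE, NA_integer_)
  aln <- cbind(data.frame(read_id = m1$qname, stringsAsFactors = FALSE),
               pair_row(m1, "1"), r2)
  aln$duplicate <- m1$dup | (!none2 & m2m$dup)
  aln[, aln_columns]
}

# ---------------------------------------------------------------------------
# GFF3 gene models.

#' Load gene models from GFF3
#'
#' Builds one gene model per gene feature, with isoforms (mRNA) linked by
#' Parent and their exon/CDS intervals converted to internal 0-based
#' half-open coordinates.
#'
#' @param path GFF3 file with gene/mRNA/exon/CDS features.
#' @return list of gene models (class `gene_models`).
#' @export
load_gene_models <- function(path) {
  g <- rtracklayer::import(path, format = "gff3")
  d <- data.frame(scaffold = as.character(GenomicRanges::seqnames(g)),
                  start = GenomicRanges::start(g) - 1L,
                  end = GenomicRanges::end(g),
                  strand = as.character(GenomicRanges::strand(g)),
                  type = as.character(g$type),
                  id = as.character(g$ID),
                  stringsAsFactors = FALSE)
  d$parent <- vapply(as.list(g$Parent), function(p)
    if (length(p)) as.character(p[1]) else NA_character_, "")
  d$product <- if (!is.null(g$product)) as.character(g$product) else NA_character_
  genes <- d[d$type == "gene", ]
  mrnas <- d[d$type == "mRNA", ]
  exons <- d[d$type == "exon", ]
  cdss <- d[d$type == "CDS", ]
  orphan <- !(cdss$parent %in% mrnas$id)
  if (any(orphan))
    stop("CDS without parent mRNA: ", cdss$id[orphan][1])
  out <- lapply(seq_len(nrow(genes)), function(i) {
    gid <- genes$id[i]
    iso_rows <- mrnas[!is.na(mrnas$parent) & mrnas$parent == gid, ]
    isoforms <- lapply(seq_len(nrow(iso_rows)), function(j) {
      mid <- iso_rows$id[j]
      ex <- exons[!is.na(exons$parent) & exons$parent == mid, ]
      cd <- cdss[!is.na(cdss$parent) & cdss$parent == mid, ]
      ex <- ex[order(ex$start), ]
      cd <- cd[order(cd$start), ]
      if (nrow(cd) > 1 && any(cd$start[-1] < cd$end[-nrow(cd)]))
        stop("overlapping CDS within isoform ", mid)
      list(isoform_id = mid,
           exons = iv_df(scaffold = ex$scaffold, start = ex$start, end = ex$end),
           cds = iv_df(scaffold = cd$scaffold, start = cd$start, end = cd$end))
    })
    list(gene_id = gid, product = genes$product[i], strand = genes$strand[i],
         scaffold = genes$scaffold[i], start = genes$start[i],
         end = genes$end[i], isoforms = isoforms)
  })
  names(out) <- genes$id
  structure(out, class = "gene_models")
}

#' Write gene models as GFF3
#'
#' @param genes a `gene_models` list.
#' @param path output path.
#' @export
write_gff3 <- function(genes, path) {
  lines <- "##gff-version 3"
  fmt <- function(scaffold, type, start, end, strand, attrs)
    sprintf("%s\tfalsedup\t%s\t%d\t%d\t.\t%s\t.\t%s",
            scaffold, type, as.integer(start) + 1L, as.integer(end), strand, attrs)
  for (g in genes) {
    prod <- if (is.na(g$product %||% NA)) "" else
      paste0(";product=", g$product)
    lines <- c(lines, fmt(g$scaffold, "gene", g$start, g$end, g$strand,
                          paste0("ID=", g$gene_id, prod)))
    for (iso in g$isoforms) {
      lines <- c(lines, fmt(g$scaffold, "mRNA", min(iso$exons$start),
                            max(iso$exons$end), g$strand,
                            paste0("ID=", iso$isoform_id, ";Parent=", g$gene_id)))
      for (i in seq_len(nrow(iso$exons)))
        lines <- c(lines, fmt(g$scaffold, "exon", iso$exons$start[i],
                              iso$exons$end[i], g$strand,
                              paste0("ID=", iso$isoform_id, ".exon", i,
                                     ";Parent=", iso$isoform_id)))
      for (i in seq_len(nrow(iso$cds)))
        lines <- c(lines, fmt(g$scaffold, "CDS", iso$cds$start[i],
                              iso$cds$end[i], g$strand,
                              paste0("ID=", iso$isoform_id, ".cds", i,
                                     ";Parent=", iso$isoform_id)))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Variants: minimal VCF output for the internal caller, VCF input via vcfR.

#' Write called variants as VCF
#'
#' @param variants variant data.frame from [call_variants()].
#' @param assembly the `assembly_index` the variants are on.
#' @param path output path.
#' @export
write_vcf <- function(variants, assembly, path) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(assembly$length),
                   assembly$length),
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(variants)) sprintf(
    "%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d", variants$scaffold,
    as.integer(variants$pos) + 1L, variants$ref, variants$alt,
    as.integer(variants$depth)) else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Load variants from a VCF file
#'
#' Reads a VCF (via vcfR) and applies only the allele-balance filter used by
#' the internal caller when allele depths (AD) are present: a site is kept
#' when every considered allele fraction is strictly between the bounds.
#'
#' @param path VCF file.
#' @param af_bounds allele-fraction bounds, default `c(0.25, 0.75)`.
#' @return variant data.frame with scaffold/pos (0-based)/ref/alt.
#' @export
load_variants <- function(path, af_bounds = c(0.25, 0.75)) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  out <- data.frame(scaffold = fix$CHROM, pos = as.numeric(fix$POS) - 1,
                    ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  ad <- tryCatch(vcfR::extract.gt(v, element = "AD"), error = function(e) NULL)
  if (!is.null(ad) && ncol(ad) >= 1) {
    keep <- vapply(seq_len(nrow(out)), function(i) {
      counts <- suppressWarnings(as.numeric(strsplit(ad[i, 1], ",")[[1]]))
      counts <- counts[!is.na(counts)]
      tot <- sum(counts)
      if (tot == 0 || length(counts) < 2) return(FALSE)
      fr <- counts[counts > 0] / tot
      all(fr > af_bounds[1] & fr < af_bounds[2])
    }, TRUE)
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
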