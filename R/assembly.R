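# Assembly container: named sequence set with N-gap annotation.

#' Build an assembly index from sequences
#'
#' An assembly index holds per-scaffold sequence (uppercase character
#' strings over A/C/G/T/N), scaffold lengths, the maximal runs of N
#' (assembly gaps) as 0-based half-open intervals, and the total length.
#'
#' @param seqs named character vector of scaffold sequences.
#' @return an object of class `assembly_index`.
#' @export
assembly_index <- function(seqs) {
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("all scaffolds must be named")
  if (anyDuplicated(names(seqs)))
    stop("duplicate scaffold names: ", names(seqs)[duplicated(names(seqs))][1])
  seqs <- toupper(seqs)
  bad <- regexpr("[^ACGTN]", seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop(sprintf("non-ACGTN character in scaffold '%s' at position %d",
                 names(seqs)[i], bad[i]))
  }
  gaps <- lapply(seq_along(seqs), function(i) {
    m <- gregexpr("N+", seqs[[i]])[[1]]
    if (m[1] == -1) return(iv_df())
    iv_df(scaffold = names(seqs)[i], start = as.integer(m) - 1L,
          end = as.integer(m) + attr(m, "match.length") - 1L)
  })
  gaps <- do.call(rbind, gaps)
  structure(list(seq = seqs, length = setNames(nchar(seqs), names(seqs)),
                 gaps = gaps, total_length = sum(nchar(seqs))),
            class = "assembly_index")
}

#' Load an assembly from a FASTA file
#'
#' @param path FASTA file path.
#' @return an `assembly_index`.
#' @export
load_assembly <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(x))
  s <- as.character(x)
  names(s) <- nm
  assembly_index(s)
}

#' Write an assembly to FASTA
#'
#' @param assembly an `assembly_index`.
#' @param path output path.
#' @export
write_assembly_fasta <- function(assembly, path) {
  x <- Biostrings::DNAStringSet(assembly$seq)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @export
print.assembly_index <- function(x, ...) {
  cat(sprintf("assembly_index: %d scaffolds, %s bp, %d N-gap(s)\n",
              length(x$seq), format(x$total_length, big.mark = ","),
              nrow(x$gaps)))
  invisible(x)
}

# Extract a subsequence (0-based half-open).
asm_seq <- function(assembly, scaffold, start, end) {
  substr(assembly$seq[[scaffold]], start + 1, end)
}

#' Segment an assembly into gap-free contigs
#'
#' Returns the maximal N-free contig intervals of every scaffold, in
#' scaffold coordinates (0-based half-open). Scaffolds made entirely of N
#' contribute no contig.
#'
#' @param assembly an `assembly_index`.
#' @return interval data.frame with columns scaffold/start/end.
#' @export
segment_at_gaps <- function(assembly) {
  out <- lapply(names(assembly$seq), function(s) {
    L <- assembly$length[[s]]
    g <- assembly$gaps[assembly$gaps$scaffold == s, ]
    if (nrow(g) == 0) return(iv_df(scaffold = s, start = 0, end = L))
    iv_setdiff(iv_df(scaffold = s, start = 0, end = L), g)
  })
  out <- do.call(rbind, out)
  out <- out[iv_len(out) > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mask intervals of an assembly with N
#'
#' @param assembly an `assembly_index`.
#' @param iv intervals to mask (scaffold/start/end, 0-based half-open).
#' @return a new `assembly_index` with the intervals replaced by N.
#' @export
mask_intervals <- function(assembly, iv) {
  seqs <- assembly$seq
  for (s in unique(iv$scaffold)) {
    r <- charToRaw(seqs[[s]])
    d <- iv[iv$scaffold == s, ]
    for (i in seq_len(nrow(d)))
      r[(d$start[i] + 1):d$end[i]] <- charToRaw("N")
    seqs[[s]] <- rawToChar(r)
  }
  assembly_index(seqs)
}

# Substitute bases at 0-based positions (used by the simulator).
mutate_bases <- function(seq, pos0, new_bases) {
  r <- charToRaw(seq)
  r[pos0 + 1L] <- charToRaw(paste(new_bases, collapse = ""))
  rawToChar(r)
}
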