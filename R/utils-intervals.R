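# Interval utilities. All intervals are data.frames with columns
# scaffold/start/end in 0-based half-open coordinates; IRanges (1-based
# closed) is used internally for the set arithmetic.

iv_df <- function(scaffold = character(), start = integer(), end = integer(), ...) {
  d <- data.frame(scaffold = as.character(scaffold), start = as.numeric(start),
                  end = as.numeric(end), ..., stringsAsFactors = FALSE)
  if (any(d$start < 0) || any(d$end < d$start))
    stop("invalid interval: need 0 <= start <= end")
  d
}

iv_len <- function(iv) iv$end - iv$start

.iv_to_ir <- function(iv) IRanges::IRanges(start = iv$start + 1L, end = iv$end)

.ir_to_iv <- function(ir, scaffold) {
  iv_df(scaffold = rep(scaffold, length(ir)),
        start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

# Union (merge overlapping/adjacent-not-merged intervals) per scaffold.
iv_union <- function(iv) {
  if (nrow(iv) == 0) return(iv_df())
  out <- lapply(split(iv, iv$scaffold), function(d)
    .ir_to_iv(IRanges::reduce(.iv_to_ir(d)), d$scaffold[1]))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$scaffold, out$start), , drop = FALSE]
}

iv_total_bp <- function(iv) {
  if (nrow(iv) == 0) return(0)
  sum(iv_len(iv_union(iv)))
}

# Total bp in the intersection of the unions of two interval sets.
iv_intersect_bp <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(0)
  a <- iv_union(a); b <- iv_union(b)
  shared <- intersect(unique(a$scaffold), unique(b$scaffold))
  tot <- 0
  for (s in shared) {
    ia <- .iv_to_ir(a[a$scaffold == s, ])
    ib <- .iv_to_ir(b[b$scaffold == s, ])
    tot <- tot + sum(IRanges::width(IRanges::intersect(ia, ib)))
  }
  tot
}

# Set difference a \ b, per scaffold.
iv_setdiff <- function(a, b) {
  if (nrow(a) == 0) return(iv_df())
  a <- iv_union(a)
  if (nrow(b) == 0) return(a)
  b <- iv_union(b)
  out <- lapply(split(a, a$scaffold), function(d) {
    s <- d$scaffold[1]
    bb <- b[b$scaffold == s, ]
    if (nrow(bb) == 0) return(d[, c("scaffold", "start", "end")])
    .ir_to_iv(IRanges::setdiff(.iv_to_ir(d), .iv_to_ir(bb)), s)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Reciprocal overlap of two single intervals (same scaffold required).
iv_reciprocal_overlap <- function(sa, starta, enda, sb, startb, endb) {
  if (sa != sb) return(0)
  ov <- max(0, min(enda, endb) - max(starta, startb))
  if (ov == 0) return(0)
  min(ov / (enda - starta), ov / (endb - startb))
}

# Does interval (s,st,en) overlap any interval in iv by >= minbp?
iv_overlaps_any <- function(iv, s, st, en, minbp = 1) {
  if (nrow(iv) == 0) return(FALSE)
  sel <- iv$scaffold == s & pmin(iv$end, en) - pmax(iv$start, st) >= minbp
  any(sel)
}

# Tile intervals into ~tile-bp resampling units (remainder kept when >= min_tile).
iv_tile <- function(iv, tile = 1000, min_tile = 200) {
  if (nrow(iv) == 0) return(iv_df())
  pieces <- lapply(seq_len(nrow(iv)), function(i) {
    st <- seq(iv$start[i], iv$end[i] - 1, by = tile)
    en <- pmin(st + tile, iv$end[i])
    keep <- en - st >= min_tile | st == iv$start[i]
    iv_df(scaffold = iv$scaffold[i], start = st[keep], end = en[keep])
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x
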