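#' Genomic interval
#'
#' Light-weight 0-based half-open genomic interval used throughout the
#' package. All internal coordinates are 0-based half-open (BED
#' convention); 1-based conversion happens only in display code.
#'
#' @param chrom Chromosome / contig name.
#' @param start 0-based start (inclusive).
#' @param end End (exclusive); must be strictly greater than `start`.
#' @param name Optional feature name.
#' @param strand One of `"+"`, `"-"`, `"."`.
#' @return An object of class `"GenomicInterval"`.
#' @export
genomic_interval <- function(chrom, start, end, name = NULL, strand = ".") {
  start <- as.integer(start)
  end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start >= end) {
    stop("invalid interval: need 0 <= start < end, got [", start, ",", end, ")")
  }
  if (!strand %in% c("+", "-", ".")) stop("strand must be one of +, -, .")
  structure(
    list(chrom = as.character(chrom), start = start, end = end,
         name = name, strand = strand),
    class = "GenomicInterval"
  )
}

#' @export
print.GenomicInterval <- function(x, ...) {
  cat(sprintf("<GenomicInterval> %s:%d-%d (%s)%s\n", x$chrom, x$start, x$end,
              x$strand, if (is.null(x$name)) "" else paste0(" ", x$name)))
  invisible(x)
}

#' @export
length.GenomicInterval <- function(x) 1L

iv_width <- function(x) x$end - x$start

## width of the overlap of [s1,e1) with [s2,e2); vectorised
iv_overlap_width <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

## interval matrices: integer matrix with columns start, end (0-based
## half-open), used for per-fiber footprint / MSP lists
iv_matrix <- function(start = integer(0), end = integer(0)) {
  m <- cbind(start = as.integer(start), end = as.integer(end))
  if (nrow(m) && any(m[, "start"] >= m[, "end"])) {
    stop("interval matrix with start >= end")
  }
  m[order(m[, "start"]), , drop = FALSE]
}

iv_matrix_overlaps_self <- function(m) {
  if (nrow(m) < 2L) return(FALSE)
  m <- m[order(m[, "start"]), , drop = FALSE]
  any(m[-nrow(m), "end"] > m[-1L, "start"])
}

## merge overlapping/abutting rows of an interval matrix; gap < merge_gap
## (strict) is merged when merge_gap > 0
iv_matrix_merge <- function(m, merge_gap = 0L) {
  if (nrow(m) < 2L) return(m)
  m <- m[order(m[, "start"]), , drop = FALSE]
  out_s <- integer(0); out_e <- integer(0)
  cs <- m[1L, "start"]; ce <- m[1L, "end"]
  for (i in seq_len(nrow(m))[-1L]) {
    if (m[i, "start"] - ce < merge_gap || m[i, "start"] <= ce) {
      ce <- max(ce, m[i, "end"])
    } else {
      out_s <- c(out_s, cs); out_e <- c(out_e, ce)
      cs <- m[i, "start"]; ce <- m[i, "end"]
    }
  }
  iv_matrix(c(out_s, cs), c(out_e, ce))
}

## subtract the intervals in `sub` from those in `m`, dropping any
## remaining fragment shorter than min_len
iv_matrix_subtract <- function(m, sub, min_len = 1L) {
  if (!nrow(m) || !nrow(sub)) {
    keep <- if (nrow(m)) (m[, "end"] - m[, "start"]) >= min_len else logical(0)
    return(m[keep, , drop = FALSE])
  }
  sub <- iv_matrix_merge(sub)
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_len(nrow(m))) {
    s <- m[i, "start"]; e <- m[i, "end"]
    for (j in seq_len(nrow(sub))) {
      ss <- sub[j, "start"]; se <- sub[j, "end"]
      if (se <= s || ss >= e) next
      if (ss > s) { out_s <- c(out_s, s); out_e <- c(out_e, ss) }
      s <- max(s, se)
      if (s >= e) break
    }
    if (s < e) { out_s <- c(out_s, s); out_e <- c(out_e, e) }
  }
  keep <- (out_e - out_s) >= min_len
  iv_matrix(out_s[keep], out_e[keep])
}
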