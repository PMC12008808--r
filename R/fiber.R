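#' Construct a single chromatin fiber
#'
#' A `Fiber` is one sequenced chromatin molecule with its aligned span and
#' per-molecule chromatin features: m6A event positions (MTase-accessible
#' adenines), MTase-protected footprints ("nucleosomes"), MTase-sensitive
#' patches (MSPs) and per-site CpG methylation calls. All positions are
#' reference coordinates, 0-based; intervals half-open.
#'
#' @param fiber_id Unique molecule identifier.
#' @param chrom Chromosome name.
#' @param start,end Aligned span (0-based half-open).
#' @param m6a Integer vector of m6A event reference positions. Duplicates
#'   are removed with a warning; the stored vector is strictly increasing.
#' @param nucleosomes,msps Two-column integer matrices (`start`, `end`) of
#'   protected footprints and MTase-sensitive patches. Each list must be
#'   internally non-overlapping and lie within the aligned span.
#' @param cpg Data frame with columns `pos` (reference position of the CpG
#'   cytosine) and `meth` (logical, per-molecule call).
#' @return An object of class `"Fiber"`.
#' @export
fiber <- function(fiber_id, chrom, start, end,
                  m6a = integer(0),
                  nucleosomes = iv_matrix(),
                  msps = iv_matrix(),
                  cpg = data.frame(pos = integer(0), meth = logical(0))) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start >= end) {
    stop("fiber ", fiber_id, ": invalid span [", start, ",", end, ")")
  }
  m6a <- as.integer(m6a)
  if (anyDuplicated(m6a)) {
    warning("fiber ", fiber_id, ": duplicated m6A positions removed")
    m6a <- unique(m6a)
  }
  m6a <- sort(m6a)
  f <- structure(
    list(fiber_id = as.character(fiber_id), chrom = as.character(chrom),
         start = start, end = end, m6a = m6a,
         nucleosomes = nucleosomes, msps = msps,
         cpg = cpg[order(cpg$pos), , drop = FALSE]),
    class = "Fiber"
  )
  validate_fiber(f)
  f
}

#' Validate a Fiber's invariants
#'
#' Checks that every feature lies within the aligned span and that the
#' footprint and MSP lists are each internally non-overlapping.
#'
#' @param f A `Fiber`.
#' @return `f`, invisibly; errors on violation.
#' @export
validate_fiber <- function(f) {
  id <- f$fiber_id
  if (length(f$m6a) &&
      (min(f$m6a) < f$start || max(f$m6a) >= f$end)) {
    stop("fiber ", id, ": m6A position outside aligned span")
  }
  for (nm in c("nucleosomes", "msps")) {
    m <- f[[nm]]
    if (!nrow(m)) next
    if (any(m[, "start"] >= m[, "end"])) {
      stop("fiber ", id, ": ", nm, " interval with start >= end")
    }
    if (min(m[, "start"]) < f$start || max(m[, "end"]) > f$end) {
      stop("fiber ", id, ": ", nm, " interval outside aligned span")
    }
    if (iv_matrix_overlaps_self(m)) {
      stop("fiber ", id, ": overlapping ", nm)
    }
  }
  if (nrow(f$cpg)) {
    if (min(f$cpg$pos) < f$start || max(f$cpg$pos) >= f$end) {
      stop("fiber ", id, ": CpG call outside aligned span")
    }
    if (anyDuplicated(f$cpg$pos)) stop("fiber ", id, ": duplicated CpG call")
  }
  invisible(f)
}

#' @export
print.Fiber <- function(x, ...) {
  cat(sprintf(
    "<Fiber %s> %s:%d-%d | %d m6A, %d footprints, %d MSPs, %d CpG calls\n",
    x$fiber_id, x$chrom, x$start, x$end, length(x$m6a),
    nrow(x$nucleosomes), nrow(x$msps), nrow(x$cpg)))
  invisible(x)
}

fiber_span <- function(f) f$end - f$start

## overlap of a fiber with an interval, in bp
fiber_overlap <- function(f, region) {
  if (f$chrom != region$chrom) return(0L)
  iv_overlap_width(f$start, f$end, region$start, region$end)
}

fiber_spans_interval <- function(f, region) {
  f$chrom == region$chrom && f$start <= region$start && f$end >= region$end
}

#' Satellite annotation table
#'
#' @param chrom,start,end Interval coordinates (0-based half-open).
#' @param sat_class Character vector drawn from the recognised satellite
#'   classes: `active_hor`, `inactive_hor`, `divergent_monomeric`,
#'   `other_satellite`, `non_satellite`.
#' @return Data frame of class `"SatelliteAnnotation"`.
#' @export
satellite_annotation <- function(chrom, start, end, sat_class) {
  cls <- c("active_hor", "inactive_hor", "divergent_monomeric",
           "other_satellite", "non_satellite")
  if (!all(sat_class %in% cls)) {
    stop("unknown sat_class: ", paste(setdiff(sat_class, cls), collapse = ", "))
  }
  d <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                  end = as.integer(end), sat_class = as.character(sat_class),
                  stringsAsFactors = FALSE)
  if (any(d$start >= d$end)) stop("satellite annotation with start >= end")
  d <- d[order(d$chrom, d$start), ]
  ## classes must be disjoint per bp
  for (ch in unique(d$chrom)) {
    dd <- d[d$chrom == ch, ]
    if (nrow(dd) > 1L && any(dd$end[-nrow(dd)] > dd$start[-1L])) {
      stop("overlapping satellite annotations on ", ch)
    }
  }
  class(d) <- c("SatelliteAnnotation", "data.frame")
  d
}
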