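#' Naive run-length fiber segmentation
#'
#' A documented fallback segmenter for fibers that arrive with m6A events
#' but no footprint annotation: maximal m6A-free runs of at least
#' `min_footprint` bp become protected footprints, and the complementary
#' maximal runs (whose internal m6A spacing is below `min_footprint` by
#' construction) of at least `min_msp` bp become MTase-sensitive patches.
#' Production segmentation from upstream callers is preferred when
#' available; this fallback makes no use of modification probabilities.
#'
#' @param f A `Fiber` with empty `nucleosomes` and `msps`.
#' @param min_footprint Minimum m6A-free run length to call a footprint
#'   (bp, default 147).
#' @param min_msp Minimum accessible run length to call an MSP (bp,
#'   default 85).
#' @return A `Fiber` with footprints and MSPs filled in; they tile the
#'   span without overlap.
#' @export
segment_fiber_naive <- function(f, min_footprint = 147L, min_msp = 85L) {
  if (nrow(f$nucleosomes) || nrow(f$msps)) {
    stop("fiber ", f$fiber_id,
         " already carries footprints; refusing to overwrite")
  }
  ## m6A-free gaps: [start, first), (p_i, p_{i+1}) exclusive, (last, end)
  bounds_l <- c(f$start, f$m6a + 1L)
  bounds_r <- c(f$m6a, f$end)
  glen <- bounds_r - bounds_l
  is_fp <- glen >= min_footprint
  nuc <- iv_matrix(bounds_l[is_fp], bounds_r[is_fp])
  ## complementary runs between footprints / fiber edges
  edges <- c(f$start, as.vector(t(nuc)), f$end)
  cs <- edges[seq(1L, length(edges), by = 2L)]
  ce <- edges[seq(2L, length(edges), by = 2L)]
  keep <- (ce - cs) >= min_msp
  f$nucleosomes <- nuc
  f$msps <- iv_matrix(cs[keep], ce[keep])
  validate_fiber(f)
}

#' Aggregate a per-bp single-molecule feature density track
#'
#' For each bp of `region`, counts the fibers whose chosen feature covers
#' that bp and divides by the number of fibers spanning the bp. Positions
#' with zero coverage carry `NA` density (undefined, distinct from 0).
#'
#' @param fibers List of `Fiber`s.
#' @param feature One of `"m6a"`, `"nucleosome"`, `"msp"`.
#' @param region Target `GenomicInterval`.
#' @return A list of class `"DensityTrack"` with fields `chrom`, `start`,
#'   `feature_count`, `coverage`, `density`.
#' @export
aggregate_density_track <- function(fibers,
                                    feature = c("m6a", "nucleosome", "msp"),
                                    region) {
  feature <- match.arg(feature)
  w <- iv_width(region)
  cov <- integer(w); cnt <- integer(w)
  add_iv <- function(v, s, e) {      # add 1 over clipped [s,e)
    s <- pmax(s, region$start); e <- pmin(e, region$end)
    ok <- s < e
    for (k in which(ok)) {
      i <- (s[k] - region$start + 1L):(e[k] - region$start)
      v[i] <- v[i] + 1L
    }
    v
  }
  for (f in fibers) {
    if (f$chrom != region$chrom) next
    if (f$end <= region$start || f$start >= region$end) next
    cov <- add_iv(cov, f$start, f$end)
    if (feature == "m6a") {
      p <- f$m6a[f$m6a >= region$start & f$m6a < region$end]
      if (length(p)) {
        i <- p - region$start + 1L
        cnt[i] <- cnt[i] + 1L
      }
    } else {
      m <- if (feature == "nucleosome") f$nucleosomes else f$msps
      if (nrow(m)) cnt <- add_iv(cnt, m[, "start"], m[, "end"])
    }
  }
  dens <- ifelse(cov > 0L, cnt / cov, NA_real_)
  structure(list(chrom = region$chrom, start = region$start,
                 feature = feature, feature_count = cnt,
                 coverage = cov, density = dens),
            class = "DensityTrack")
}

#' @export
print.DensityTrack <- function(x, ...) {
  cat(sprintf("<DensityTrack %s> %s:%d-%d | mean density %.4f (%d bp covered)\n",
              x$feature, x$chrom, x$start, x$start + length(x$density),
              mean(x$density, na.rm = TRUE), sum(x$coverage > 0L)))
  invisible(x)
}

#' Aggregate per-site CpG methylation across fibers
#'
#' @param fibers List of `Fiber`s carrying `cpg` calls.
#' @param region Target `GenomicInterval`.
#' @return Data frame with columns `pos`, `n_called`, `n_methylated`,
#'   `fraction`; positions called on no fiber are omitted.
#' @export
aggregate_methylation <- function(fibers, region) {
  pos <- integer(0); meth <- logical(0)
  for (f in fibers) {
    if (f$chrom != region$chrom || !nrow(f$cpg)) next
    keep <- f$cpg$pos >= region$start & f$cpg$pos < region$end
    pos <- c(pos, f$cpg$pos[keep])
    meth <- c(meth, f$cpg$meth[keep])
  }
  if (!length(pos)) {
    return(data.frame(pos = integer(0), n_called = integer(0),
                      n_methylated = integer(0), fraction = numeric(0)))
  }
  n_called <- tapply(meth, pos, length)
  n_meth <- tapply(meth, pos, sum)
  d <- data.frame(pos = as.integer(names(n_called)),
                  n_called = as.integer(n_called),
                  n_methylated = as.integer(n_meth),
                  fraction = as.numeric(n_meth / n_called))
  d[order(d$pos), , drop = FALSE]
}
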