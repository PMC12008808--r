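#' Binarize a fiber's m6A pattern
#'
#' One value per bp of the fiber span (optionally intersected with a
#' region): 1 exactly at m6A event positions, 0 elsewhere.
#'
#' @param f A `Fiber`.
#' @param region Optional `GenomicInterval` to intersect with.
#' @return List of class `"BinaryFiberVector"`: `fiber_id`, `offset`
#'   (reference position of the first element), `values` (0/1 integer).
#' @export
binarize_m6a <- function(f, region = NULL) {
  s <- f$start; e <- f$end
  if (!is.null(region)) {
    if (f$chrom != region$chrom) stop("fiber and region on different chroms")
    s <- max(s, region$start); e <- min(e, region$end)
    if (s >= e) stop("fiber ", f$fiber_id, " does not overlap the region")
  }
  v <- integer(e - s)
  p <- f$m6a[f$m6a >= s & f$m6a < e]
  v[p - s + 1L] <- 1L
  structure(list(fiber_id = f$fiber_id, offset = s, values = v),
            class = "BinaryFiberVector")
}

#' Per-fiber periodogram on the repeat-length grid
#'
#' Standard one-sided periodogram of the binary m6A vector at unit
#' sampling (rectangular window, no detrending unless requested):
#' density at frequency k/n is `|DFT_k|^2 / n`, doubled for one-sided
#' reporting except at the Nyquist bin. Densities are reported against
#' repeat length `n/k` restricted to `[min_period, max_period]`, plus
#' one guard bin on each side so downstream interpolation covers the
#' band edges.
#'
#' @param vec A [binarize_m6a()] vector.
#' @param min_period,max_period Analysis band in bp (default 120-300).
#' @param min_events Minimum m6A events required (default 10).
#' @param detrend `"none"` (default) or `"mean"` (subtract the vector
#'   mean first; affects only the zero-frequency bin, which lies outside
#'   the band).
#' @return List of class `"SpectralDensity"`: `repeat_lengths`
#'   (decreasing bp grid), `densities`, `n_fibers = 1`; or `NULL` with a
#'   message when the fiber is too short or has too few events.
#' @export
fiber_periodogram <- function(vec, min_period = 120L, max_period = 300L,
                              min_events = 10L,
                              detrend = c("none", "mean")) {
  detrend <- match.arg(detrend)
  x <- vec$values
  n <- length(x)
  if (n < 2L * max_period) {
    message("fiber ", vec$fiber_id, " skipped: shorter than 2 x max_period")
    return(NULL)
  }
  if (sum(x) < min_events) {
    message("fiber ", vec$fiber_id, " skipped: fewer than ", min_events,
            " m6A events")
    return(NULL)
  }
  if (detrend == "mean") x <- x - mean(x)
  X <- stats::fft(x)
  nk <- n %/% 2L
  k <- seq_len(nk)
  dens <- Mod(X[k + 1L])^2 / n
  scale <- rep(2, nk)
  if (n %% 2L == 0L) scale[nk] <- 1
  dens <- dens * scale
  period <- n / k
  keep <- which(period >= min_period & period <= max_period)
  if (!length(keep)) {
    message("fiber ", vec$fiber_id, " skipped: no frequency in band")
    return(NULL)
  }
  ## guard bins so interpolation can reach the band edges
  keep <- unique(c(max(min(keep) - 1L, 1L), keep, min(max(keep) + 1L, nk)))
  structure(list(repeat_lengths = period[keep], densities = dens[keep],
                 n_fibers = 1L),
            class = "SpectralDensity")
}

#' Aggregate per-fiber spectra to a median spectral density
#'
#' Each fiber's spectrum is linearly interpolated onto a common 1 bp
#' repeat-length grid over the band, then the per-gridpoint median is
#' taken across fibers.
#'
#' @param spectra List of per-fiber `SpectralDensity` objects (`NULL`
#'   entries from skipped fibers are dropped).
#' @param min_period,max_period Common grid band in bp.
#' @return A `SpectralDensity` with the 1 bp grid (decreasing), median
#'   densities, and `n_fibers` contributing.
#' @export
aggregate_spectra <- function(spectra, min_period = 120L, max_period = 300L) {
  spectra <- spectra[!vapply(spectra, is.null, logical(1))]
  if (!length(spectra)) stop("no accepted fiber spectra to aggregate")
  grid <- seq(max_period, min_period)   # decreasing, 1 bp
  mat <- vapply(spectra, function(sp) {
    o <- order(sp$repeat_lengths)
    stats::approx(sp$repeat_lengths[o], sp$densities[o], xout = grid,
                  method = "linear", rule = 2)$y
  }, numeric(length(grid)))
  med <- apply(matrix(mat, nrow = length(grid)), 1L, stats::median)
  structure(list(repeat_lengths = grid, densities = med,
                 n_fibers = length(spectra)),
            class = "SpectralDensity")
}

#' @export
print.SpectralDensity <- function(x, ...) {
  pk <- peak_repeat_length(x, 1L)
  cat(sprintf(
    "<SpectralDensity> %d gridpoints over %d-%d bp, %d fiber(s); peak at %d bp\n",
    length(x$repeat_lengths), round(min(x$repeat_lengths)),
    round(max(x$repeat_lengths)), x$n_fibers, pk$repeat_length[1L]))
  invisible(x)
}

#' Peak chromatin repeat length(s)
#'
#' Repeat lengths at the `n_peaks` largest local maxima of the spectrum;
#' the global maximum is always first and ties break toward the shorter
#' repeat length. A flat spectrum returns its first maximum with a
#' warning.
#'
#' @param spec A `SpectralDensity`.
#' @param n_peaks Number of peaks to report.
#' @return Data frame with columns `repeat_length`, `density`.
#' @export
peak_repeat_length <- function(spec, n_peaks = 1L) {
  rl <- spec$repeat_lengths; d <- spec$densities
  o <- order(rl)                      # increasing repeat length
  rl <- rl[o]; d <- d[o]
  n <- length(d)
  if (length(unique(d)) == 1L) {
    warning("flat spectrum: peak is ill-defined, returning first maximum")
    return(data.frame(repeat_length = rl[1L], density = d[1L]))
  }
  is_max <- vapply(seq_len(n), function(i) {
    left <- if (i > 1L) d[i] >= d[i - 1L] else TRUE
    right <- if (i < n) d[i] >= d[i + 1L] else TRUE
    left && right
  }, logical(1))
  cand <- which(is_max)
  ## order by density desc, ties toward shorter repeat length
  cand <- cand[order(-d[cand], rl[cand])]
  ## global max first even if not a strict local max bookkeeping artifact
  gm <- which.max(d + 0)  # ties -> smallest index = shortest length
  cand <- unique(c(gm, cand))
  take <- cand[seq_len(min(n_peaks, length(cand)))]
  data.frame(repeat_length = rl[take], density = d[take])
}

#' Region-wise spectral analysis of a fiber set
#'
#' Binarizes each fiber over the region, computes per-fiber
#' periodograms and aggregates them to the median spectral density.
#'
#' @param fibers List of `Fiber`s.
#' @param region Optional `GenomicInterval` restriction.
#' @param min_period,max_period Analysis band, bp.
#' @param min_events Per-fiber minimum m6A events.
#' @param detrend Passed to [fiber_periodogram()].
#' @return An aggregated `SpectralDensity`.
#' @export
region_spectrum <- function(fibers, region = NULL, min_period = 120L,
                            max_period = 300L, min_events = 10L,
                            detrend = "none") {
  specs <- lapply(fibers, function(f) {
    v <- tryCatch(binarize_m6a(f, region), error = function(e) NULL)
    if (is.null(v)) return(NULL)
    fiber_periodogram(v, min_period, max_period, min_events, detrend)
  })
  aggregate_spectra(specs, min_period, max_period)
}
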