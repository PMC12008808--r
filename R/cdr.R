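#' Parameters for centromere dip region (CDR) calling
#'
#' Defaults follow the stepped-window percentile algorithm: satellite
#' stretches closer than 25 bp are merged and only arrays of at least
#' 100 kb kept; 1190 bp windows advance by 170 bp (about one satellite
#' monomer); windows below the 35th percentile of window-mean CpG
#' methylation are selected and merged; merged candidates must be at
#' least 15 kb long, have mean window methylation below the 20th
#' percentile and avoid the terminal 70 kb of the array (15 kb for the
#' chrY-style variant).
#'
#' @param merge_gap Maximum satellite gap to merge, bp (strict `<`).
#' @param min_array Minimum merged array length, bp.
#' @param window_size,step Window geometry, bp.
#' @param window_percentile Selection percentile for single windows.
#' @param merged_percentile Percentile bound on candidate mean.
#' @param min_cdr_length Minimum candidate length, bp.
#' @param terminal_exclusion Terminal zone excluded at each array end, bp.
#' @return List of class `"CdrParams"`.
#' @export
cdr_params <- function(merge_gap = 25L, min_array = 100000L,
                       window_size = 1190L, step = 170L,
                       window_percentile = 35, merged_percentile = 20,
                       min_cdr_length = 15000L,
                       terminal_exclusion = 70000L) {
  p <- list(merge_gap = as.integer(merge_gap),
            min_array = as.integer(min_array),
            window_size = as.integer(window_size), step = as.integer(step),
            window_percentile = window_percentile,
            merged_percentile = merged_percentile,
            min_cdr_length = as.integer(min_cdr_length),
            terminal_exclusion = as.integer(terminal_exclusion))
  if (p$window_size < p$step) stop("window_size must be >= step")
  if (any(c(p$window_percentile, p$merged_percentile) <= 0) ||
      any(c(p$window_percentile, p$merged_percentile) >= 100)) {
    stop("percentiles must lie in (0, 100)")
  }
  structure(p, class = "CdrParams")
}

#' Merge satellite annotations into candidate arrays
#'
#' Intervals of the selected class(es) with an inter-interval gap
#' strictly below `merge_gap` are merged; only merged stretches of at
#' least `min_array` bp are kept.
#'
#' @param annotations A [satellite_annotation()] table.
#' @param params A [cdr_params()].
#' @param sat_class Character vector of classes to merge (default the
#'   active higher-order-repeat class).
#' @return List of `GenomicInterval`s, named `array1`, `array2`, ...
#' @export
merge_satellite_arrays <- function(annotations, params = cdr_params(),
                                   sat_class = "active_hor") {
  d <- annotations[annotations$sat_class %in% sat_class, , drop = FALSE]
  out <- list()
  for (ch in unique(d$chrom)) {
    dd <- d[d$chrom == ch, , drop = FALSE]
    m <- iv_matrix_merge(iv_matrix(dd$start, dd$end),
                         merge_gap = params$merge_gap)
    keep <- (m[, "end"] - m[, "start"]) >= params$min_array
    for (r in which(keep)) {
      out[[length(out) + 1L]] <- genomic_interval(ch, m[r, "start"], m[r, "end"])
    }
  }
  if (length(out)) names(out) <- paste0("array", seq_along(out))
  out
}

#' Windowed mean CpG methylation over one array
#'
#' Windows start at the array start and advance by `step`; the last
#' window is the last one fully inside the array. Each window's mean is
#' taken over the CpG sites it contains; windows with no sites are kept
#' but flagged by `n_sites = 0` and excluded from percentile
#' computations downstream.
#'
#' @param array A `GenomicInterval` (one merged satellite array).
#' @param meth_table Per-site table with columns `pos` and `fraction`
#'   (as from [aggregate_methylation()], or a parsed bedGraph).
#' @param params A [cdr_params()].
#' @return Data frame with columns `start`, `end`, `mean_fraction`,
#'   `n_sites`; empty (with a warning) if the array is shorter than one
#'   window.
#' @export
window_methylation <- function(array, meth_table, params = cdr_params()) {
  w <- params$window_size; st <- params$step
  if (iv_width(array) < w) {
    warning("array ", array$chrom, ":", array$start, "-", array$end,
            " shorter than one window")
    return(data.frame(start = integer(0), end = integer(0),
                      mean_fraction = numeric(0), n_sites = integer(0)))
  }
  starts <- seq.int(array$start, array$end - w, by = st)
  pos <- meth_table$pos; frac <- meth_table$fraction
  o <- order(pos); pos <- pos[o]; frac <- frac[o]
  ## cumulative sums allow O(1) per-window means
  csum <- c(0, cumsum(frac))
  lo <- findInterval(starts - 0.5, pos)        # sites strictly before start
  hi <- findInterval(starts + w - 0.5, pos)    # sites before end
  n <- hi - lo
  mean_fraction <- ifelse(n > 0L, (csum[hi + 1L] - csum[lo + 1L]) / n, NA_real_)
  data.frame(start = as.integer(starts), end = as.integer(starts + w),
             mean_fraction = mean_fraction, n_sites = as.integer(n))
}

## percentile with linear interpolation between order statistics
.pctl <- function(x, p) as.numeric(stats::quantile(x, p / 100, type = 7, names = FALSE))

## strict "below" with a relative guard so float accumulation never
## splits exactly-tied window means around the percentile value
.strictly_below <- function(x, thr) {
  !is.na(x) & x < thr - 1e-9 * max(1, abs(thr))
}

#' Call CDRs from windowed methylation
#'
#' Windows whose mean methylation lies strictly below the
#' `window_percentile` of the array's window-mean distribution are
#' selected; runs of neighboring (overlapping or abutting) selected
#' windows form candidates. Because the percentile rule necessarily
#' selects a fraction of ordinary background windows as well, a raw
#' window union bleeds by up to a window width and can chain background
#' windows onto a dip; candidate boundaries are therefore localised at
#' half depth: the reference background level is the array's median
#' window mean, and the candidate interval runs from the central step
#' cell of the first member window below the midpoint of candidate core
#' level and background level to that of the last (full-width at
#' half-depth edge localisation, at step resolution). Candidates with
#' no member window below half depth keep their union trimmed by
#' `window_size - step` per side. Candidates pass when (1) at least
#' `min_cdr_length` long, (2) mean of member-window means strictly below
#' the `merged_percentile` value, and (3) not intersecting the terminal
#' `terminal_exclusion` bp at either array end. All three outcomes are
#' recorded per candidate.
#'
#' @param windows Output of [window_methylation()] for one array.
#' @param array The source array interval.
#' @param params A [cdr_params()].
#' @param array_id Label recorded with each call.
#' @return Data frame of class `"CdrCalls"`: one row per candidate with
#'   `chrom`, `start`, `end`, `mean_window_fraction`, `array_id`,
#'   `pass_length`, `pass_percentile`, `pass_terminal`, `passed`.
#' @export
call_cdrs <- function(windows, array, params = cdr_params(),
                      array_id = "array1") {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), mean_window_fraction = numeric(0),
                      array_id = character(0), pass_length = logical(0),
                      pass_percentile = logical(0), pass_terminal = logical(0),
                      passed = logical(0))
  class(empty) <- c("CdrCalls", "data.frame")
  if (!nrow(windows)) return(empty)
  ok <- windows$n_sites > 0L
  if (!any(ok)) {
    stop("array ", array_id, ": every window is CpG-site-less")
  }
  means <- windows$mean_fraction[ok]
  thr_win <- .pctl(means, params$window_percentile)
  thr_merged <- .pctl(means, params$merged_percentile)
  sel <- which(ok & .strictly_below(windows$mean_fraction, thr_win))
  if (!length(sel)) return(empty)
  ## group selected windows into runs of overlapping/abutting neighbors
  brk <- c(TRUE, windows$start[sel[-1L]] > windows$end[sel[-length(sel)]])
  grp <- cumsum(brk)
  trim <- params$window_size - params$step
  bg_level <- stats::median(means)
  ## central step cell of a window starting at s
  cell_start <- (params$window_size - params$step) %/% 2L
  rows <- lapply(split(sel, grp), function(idx) {
    core_level <- min(windows$mean_fraction[idx], na.rm = TRUE)
    half <- (core_level + bg_level) / 2
    deep <- idx[.strictly_below(windows$mean_fraction[idx], half)]
    if (length(deep)) {
      s <- windows$start[deep[1L]] + cell_start
      e <- windows$start[deep[length(deep)]] + cell_start + params$step
    } else {
      s <- windows$start[idx[1L]] + trim
      e <- windows$end[idx[length(idx)]] - trim
    }
    if (e <= s) return(NULL)
    cand_mean <- mean(windows$mean_fraction[idx], na.rm = TRUE)
    pass_len <- (e - s) >= params$min_cdr_length
    pass_pct <- .strictly_below(cand_mean, thr_merged)
    term <- params$terminal_exclusion
    pass_term <- s >= array$start + term && e <= array$end - term
    data.frame(chrom = array$chrom, start = s, end = e,
               mean_window_fraction = cand_mean, array_id = array_id,
               pass_length = pass_len, pass_percentile = pass_pct,
               pass_terminal = pass_term,
               passed = pass_len && pass_pct && pass_term)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("CdrCalls", "data.frame")
  out
}

#' Call CDRs across all arrays of an annotation set
#'
#' Convenience wrapper: merges satellite arrays, windows the methylation
#' table over each, and calls candidates. Returns the concatenated audit
#' table; final calls are the rows with `passed == TRUE`.
#'
#' @param annotations A [satellite_annotation()] table.
#' @param meth_table Per-site methylation (`pos`, `fraction`).
#' @param params A [cdr_params()].
#' @param sat_class Satellite class(es) forming arrays.
#' @return A `CdrCalls` data frame over all arrays.
#' @export
find_cdrs <- function(annotations, meth_table, params = cdr_params(),
                      sat_class = "active_hor") {
  arrays <- merge_satellite_arrays(annotations, params, sat_class)
  out <- lapply(names(arrays), function(id) {
    wins <- window_methylation(arrays[[id]], meth_table, params)
    call_cdrs(wins, arrays[[id]], params, array_id = id)
  })
  res <- if (length(out)) do.call(rbind, out) else call_cdrs(
    data.frame(start = integer(0), end = integer(0),
               mean_fraction = numeric(0), n_sites = integer(0)),
    genomic_interval("none", 0L, 1L), params)
  rownames(res) <- NULL
  class(res) <- c("CdrCalls", "data.frame")
  res
}
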