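#' Scan a reference for CENP-B boxes
#'
#' Exact IUPAC matching of the 17 bp consensus `NTTCGNNNNANNCGGGN` on
#' both strands (an optional mismatch budget covers degenerate boxes),
#' keeping matches whose 17-mer contains exactly 2 CG dinucleotides.
#' Minus-strand matches are reported in reference coordinates with
#' `strand = "-"`. The box center is the 9th motif base — the middle of
#' the 17-mer, hence the same reference position on either strand.
#'
#' @param reference A `DNAStringSet` (or single `DNAString` named via
#'   `chrom`).
#' @param regions Optional [satellite_annotation()] table; sites fully
#'   inside an annotation inherit its class as `region`, others are
#'   dropped. `NULL` scans everything.
#' @param max_mismatches Allowed mismatches against the consensus
#'   (default 0; the two CpGs must survive the 2-CG filter regardless).
#' @param chrom Chromosome name when `reference` is a bare `DNAString`.
#' @return Data frame of class `"CenpBSites"`: `site_id`, `chrom`,
#'   `start`, `end`, `strand`, `center`, `cpg1`, `cpg2`, `region`.
#' @export
scan_cenpb_boxes <- function(reference, regions = NULL, max_mismatches = 0L,
                             chrom = "chr") {
  if (inherits(reference, "DNAString")) {
    reference <- Biostrings::DNAStringSet(reference)
    names(reference) <- chrom
  }
  pat <- Biostrings::DNAString(CENPB_CONSENSUS)
  rows <- list()
  for (ci in seq_along(reference)) {
    seq <- reference[[ci]]
    L <- length(seq)
    ch <- names(reference)[ci]
    plus <- Biostrings::matchPattern(pat, seq, fixed = FALSE,
                                     max.mismatch = max_mismatches)
    minus <- Biostrings::matchPattern(
      pat, Biostrings::reverseComplement(seq), fixed = FALSE,
      max.mismatch = max_mismatches)
    starts <- c(Biostrings::start(plus) - 1L,
                L - Biostrings::end(minus))
    strands <- c(rep("+", length(plus)), rep("-", length(minus)))
    if (!length(starts)) next
    o <- order(starts)
    starts <- starts[o]; strands <- strands[o]
    for (i in seq_along(starts)) {
      s <- starts[i]
      sub <- Biostrings::subseq(seq, s + 1L, s + 17L)
      cg <- Biostrings::start(Biostrings::matchPattern("CG", sub))
      if (length(cg) != 2L) next
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start = s, end = s + 17L, strand = strands[i],
        center = s + 8L, cpg1 = s + cg[1L] - 1L, cpg2 = s + cg[2L] - 1L)
    }
  }
  if (!length(rows)) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      center = integer(0), cpg1 = integer(0),
                      cpg2 = integer(0))
  } else {
    out <- do.call(rbind, rows)
    out <- out[!duplicated(out[, c("chrom", "start", "strand")]), ]
  }
  out$region <- rep(NA_character_, nrow(out))
  if (!is.null(regions) && nrow(out)) {
    keep <- logical(nrow(out))
    for (r in seq_len(nrow(regions))) {
      hit <- out$chrom == regions$chrom[r] &
        out$start >= regions$start[r] & out$end <= regions$end[r]
      out$region[hit] <- regions$sat_class[r]
      keep <- keep | hit
    }
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  out$site_id <- if (nrow(out)) {
    sprintf("%s:%d:%s", out$chrom, out$start, out$strand)
  } else character(0)
  class(out) <- c("CenpBSites", "data.frame")
  out
}

#' Per-fiber observations over CENP-B boxes
#'
#' One observation per (site, fiber) pair where the fiber fully spans
#' `center +/- profile_halfwidth`. The m6A window is extracted in motif
#' orientation (reversed for minus-strand sites). The molecule's box
#' CpG state is the number of methylated calls among the site's 2 CpGs
#' when both are called, otherwise `NA` (missing, excluded from
#' strata).
#'
#' @param fibers List of `Fiber`s.
#' @param sites A [scan_cenpb_boxes()] table.
#' @param profile_halfwidth Half-width of the profile window, bp
#'   (default 50).
#' @return List of class `"BoxObservations"`: `meta` (data frame:
#'   `site_id`, `fiber_id`, `strand`, `region`, `mcpg_state`) and
#'   `windows` (integer matrix, one row per observation, columns =
#'   offsets `-hw..hw` in motif orientation).
#' @export
observe_boxes <- function(fibers, sites, profile_halfwidth = 50L) {
  hw <- as.integer(profile_halfwidth)
  metas <- list(); wins <- list()
  for (f in fibers) {
    ss <- sites[sites$chrom == f$chrom &
                  sites$center - hw >= f$start &
                  sites$center + hw < f$end, , drop = FALSE]
    if (!nrow(ss)) next
    for (i in seq_len(nrow(ss))) {
      ctr <- ss$center[i]
      w <- integer(2L * hw + 1L)
      p <- f$m6a[f$m6a >= ctr - hw & f$m6a <= ctr + hw]
      w[p - (ctr - hw) + 1L] <- 1L
      if (ss$strand[i] == "-") w <- rev(w)
      c1 <- match(ss$cpg1[i], f$cpg$pos)
      c2 <- match(ss$cpg2[i], f$cpg$pos)
      state <- if (is.na(c1) || is.na(c2)) NA_integer_ else
        as.integer(f$cpg$meth[c1]) + as.integer(f$cpg$meth[c2])
      metas[[length(metas) + 1L]] <- data.frame(
        site_id = ss$site_id[i], fiber_id = f$fiber_id,
        strand = ss$strand[i], region = ss$region[i], mcpg_state = state)
      wins[[length(wins) + 1L]] <- w
    }
  }
  meta <- if (length(metas)) do.call(rbind, metas) else
    data.frame(site_id = character(0), fiber_id = character(0),
               strand = character(0), region = character(0),
               mcpg_state = integer(0))
  windows <- if (length(wins)) do.call(rbind, wins) else
    matrix(integer(0), 0L, 2L * hw + 1L)
  colnames(windows) <- as.character(seq(-hw, hw))
  structure(list(meta = meta, windows = windows, halfwidth = hw),
            class = "BoxObservations")
}

## rolling mean of width 10 with window [-5, +4], truncated at the ends
.roll10 <- function(x) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - 5L):min(n, i + 4L)])
  }, numeric(1))
}

#' Smoothed m6A frequency profile of an observation stratum
#'
#' Per-offset mean of the binary windows across observations, smoothed
#' by a 10 bp rolling average (window `[-5, +4]`, truncated at the
#' profile boundaries).
#'
#' @param windows Binary observation matrix (rows = observations,
#'   columns = offsets, as in [observe_boxes()]).
#' @return Named numeric vector of smoothed frequencies per offset.
#' @export
aggregate_profile <- function(windows) {
  if (!nrow(windows)) stop("empty observation stratum")
  raw <- colMeans(windows)
  out <- .roll10(raw)
  names(out) <- colnames(windows)
  out
}

#' CENP-B footprint score of a smoothed profile
#'
#' Mean smoothed m6A frequency over the flanks (offsets -35..-27 and
#' +22..+27, inclusive) divided by the mean over the box core (offsets
#' -7..+1), with a pseudocount in the denominator so fully protected
#' cores score finite.
#'
#' @param profile Named smoothed profile from [aggregate_profile()];
#'   must cover offsets -50..50.
#' @param pseudocount Added to the core mean (default 1e-3).
#' @return A single non-negative number; higher = stronger footprint
#'   (greater occupancy).
#' @export
footprint_score <- function(profile, pseudocount = 1e-3) {
  off <- as.integer(names(profile))
  need <- c(-35:-27, 22:27, -7:1)
  if (!all(need %in% off)) {
    stop("profile does not cover offsets -50..50 around the box center")
  }
  flank <- mean(profile[off %in% c(-35:-27, 22:27)])
  core <- mean(profile[off %in% (-7:1)])
  flank / (core + pseudocount)
}

#' Subsampled footprint-score distribution of a stratum
#'
#' Draws `n_subsamples` subsamples of
#' `ceiling(subsample_fraction * n)` observations without replacement,
#' collapses each to a smoothed profile and scores it.
#'
#' @param obs A `BoxObservations` object (already restricted to one
#'   stratum, e.g. one region x mcpg state).
#' @param subsample_fraction Fraction of observations per draw (default
#'   0.10).
#' @param n_subsamples Number of draws (default 1000).
#' @param seed Integer seed; the distribution is reproducible from it.
#' @param pseudocount Passed to [footprint_score()].
#' @return List of class `"FootprintScore"`: `score` (full stratum),
#'   `n_fibers`, `distribution` (length `n_subsamples`), `quantiles`.
#' @export
score_distribution <- function(obs, subsample_fraction = 0.10,
                               n_subsamples = 1000L, seed = 1L,
                               pseudocount = 1e-3) {
  n <- nrow(obs$windows)
  m <- ceiling(subsample_fraction * n)
  if (subsample_fraction * n < 5) {
    stop("stratum too small: need at least ", ceiling(5 / subsample_fraction),
         " observations at fraction ", subsample_fraction)
  }
  set.seed(seed)
  dist <- vapply(seq_len(n_subsamples), function(i) {
    idx <- sample.int(n, m, replace = FALSE)
    footprint_score(aggregate_profile(obs$windows[idx, , drop = FALSE]),
                    pseudocount)
  }, numeric(1))
  structure(
    list(score = footprint_score(aggregate_profile(obs$windows), pseudocount),
         n_fibers = n, distribution = dist,
         quantiles = stats::quantile(dist, c(0.05, 0.25, 0.5, 0.75, 0.95))),
    class = "FootprintScore")
}

#' @export
print.FootprintScore <- function(x, ...) {
  cat(sprintf(
    "<FootprintScore> full-stratum %.3f | median subsample %.3f (n=%d obs, %d draws)\n",
    x$score, stats::median(x$distribution), x$n_fibers,
    length(x$distribution)))
  invisible(x)
}

#' Subset box observations to a stratum
#'
#' @param obs A `BoxObservations` object.
#' @param mcpg_state Optional state (0, 1, 2) to keep; `NA` states are
#'   always dropped when a state is requested.
#' @param region Optional region label to keep.
#' @return A filtered `BoxObservations`.
#' @export
filter_observations <- function(obs, mcpg_state = NULL, region = NULL) {
  keep <- rep(TRUE, nrow(obs$meta))
  if (!is.null(mcpg_state)) {
    keep <- keep & !is.na(obs$meta$mcpg_state) &
      obs$meta$mcpg_state == mcpg_state
  }
  if (!is.null(region)) keep <- keep & obs$meta$region %in% region
  structure(list(meta = obs$meta[keep, , drop = FALSE],
                 windows = obs$windows[keep, , drop = FALSE],
                 halfwidth = obs$halfwidth),
            class = "BoxObservations")
}

#' Closest nucleosome edges around CENP-B boxes
#'
#' For every (site, fiber spanning `center +/- halfwidth`) pair, finds
#' the boundary of the nearest strictly upstream footprint (its
#' center-facing edge, recorded as a negative offset) and of the
#' nearest strictly downstream footprint (its start, positive offset),
#' in motif orientation. Footprints covering the center itself (e.g.
#' the occupied-box footprint) are not edges and are skipped. Offsets
#' are tallied as percentages of upstream / downstream observations per
#' mCpG stratum.
#'
#' @param fibers List of `Fiber`s.
#' @param sites A [scan_cenpb_boxes()] table.
#' @param halfwidth Search half-width around the center, bp (default
#'   500).
#' @return Named list (one entry per mCpG state present, names "0",
#'   "1", "2") of data frames `offset`, `pct_upstream`,
#'   `pct_downstream`.
#' @export
nucleosome_edge_positioning <- function(fibers, sites, halfwidth = 500L) {
  hw <- as.integer(halfwidth)
  recs <- list()
  for (f in fibers) {
    ss <- sites[sites$chrom == f$chrom &
                  sites$center - hw >= f$start &
                  sites$center + hw < f$end, , drop = FALSE]
    if (!nrow(ss) || !nrow(f$nucleosomes)) next
    ns <- f$nucleosomes[, "start"]; ne <- f$nucleosomes[, "end"]
    for (i in seq_len(nrow(ss))) {
      ctr <- ss$center[i]
      c1 <- match(ss$cpg1[i], f$cpg$pos); c2 <- match(ss$cpg2[i], f$cpg$pos)
      state <- if (is.na(c1) || is.na(c2)) NA_integer_ else
        as.integer(f$cpg$meth[c1]) + as.integer(f$cpg$meth[c2])
      if (is.na(state)) next
      up <- which(ne <= ctr & ne > ctr - hw)
      dn <- which(ns > ctr & ns < ctr + hw)
      up_off <- if (length(up)) max(ne[up]) - ctr else NA_integer_
      dn_off <- if (length(dn)) min(ns[dn]) - ctr else NA_integer_
      if (ss$strand[i] == "-") {   # flip into motif orientation
        tmp <- up_off
        up_off <- if (is.na(dn_off)) NA_integer_ else -dn_off
        dn_off <- if (is.na(tmp)) NA_integer_ else -tmp
      }
      recs[[length(recs) + 1L]] <- data.frame(
        state = state, up = up_off, dn = dn_off)
    }
  }
  if (!length(recs)) return(list())
  d <- do.call(rbind, recs)
  out <- list()
  for (st in sort(unique(d$state))) {
    dd <- d[d$state == st, , drop = FALSE]
    offs <- seq(-hw, hw)
    upc <- table(factor(dd$up[!is.na(dd$up)], levels = offs))
    dnc <- table(factor(dd$dn[!is.na(dd$dn)], levels = offs))
    out[[as.character(st)]] <- data.frame(
      offset = offs,
      pct_upstream = 100 * as.numeric(upc) / max(1L, sum(upc)),
      pct_downstream = 100 * as.numeric(dnc) / max(1L, sum(dnc)))
  }
  out
}
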