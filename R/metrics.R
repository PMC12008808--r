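#' Classify a fiber's footprints and patches
#'
#' A protected footprint is di-nucleosome-sized when strictly longer
#' than `dinuc_cutoff` (210 bp); an MTase-sensitive patch is a "large
#' MSP" (accessible chromatin patch) when strictly longer than
#' `msp_cutoff` (150 bp). Percentages are per fiber; a zero denominator
#' yields `NA` (flagged undefined, not 0).
#'
#' @param f A `Fiber`.
#' @param dinuc_cutoff,msp_cutoff Length cutoffs in bp (strict `>`).
#' @return One-row data frame: `fiber_id`, `n_nucleosomes`,
#'   `pct_dinucleosome`, `n_msps`, `pct_large_msp`.
#' @export
classify_features <- function(f, dinuc_cutoff = 210L, msp_cutoff = 150L) {
  nl <- f$nucleosomes[, "end"] - f$nucleosomes[, "start"]
  ml <- f$msps[, "end"] - f$msps[, "start"]
  data.frame(
    fiber_id = f$fiber_id,
    n_nucleosomes = length(nl),
    pct_dinucleosome = if (length(nl)) 100 * mean(nl > dinuc_cutoff) else NA_real_,
    n_msps = length(ml),
    pct_large_msp = if (length(ml)) 100 * mean(ml > msp_cutoff) else NA_real_)
}

#' Per-region single-molecule dichromatin summaries
#'
#' Each fiber is assigned to the labeled region holding at least 50% of
#' its aligned span (ties broken toward the earlier region in the list;
#' fibers overlapping no region get `"unassigned"`). Features are
#' counted only when fully contained in the assigned region.
#'
#' @param fibers List of `Fiber`s.
#' @param regions Named list of `GenomicInterval`s with disjoint labels.
#' @param dinuc_cutoff,msp_cutoff Passed to the per-fiber classifier.
#' @return Data frame with one row per fiber: region label plus the
#'   [classify_features()] columns and `n_large_msps_in_region`.
#' @export
regional_summaries <- function(fibers, regions, dinuc_cutoff = 210L,
                               msp_cutoff = 150L) {
  if (is.null(names(regions)) || anyDuplicated(names(regions))) {
    stop("regions must carry unique labels")
  }
  rows <- lapply(fibers, function(f) {
    ov <- vapply(regions, function(r) fiber_overlap(f, r), integer(1))
    lab <- if (any(ov >= 0.5 * fiber_span(f))) {
      names(regions)[which.max(ov)]
    } else if (all(ov == 0L)) "unassigned" else "unassigned"
    if (lab == "unassigned") {
      s <- classify_features(f, dinuc_cutoff, msp_cutoff)
      s$n_large_msps_in_region <- NA_integer_
    } else {
      r <- regions[[lab]]
      inreg <- function(m) {
        m[m[, "start"] >= r$start & m[, "end"] <= r$end, , drop = FALSE]
      }
      fr <- f
      fr$nucleosomes <- inreg(f$nucleosomes)
      fr$msps <- inreg(f$msps)
      s <- classify_features(fr, dinuc_cutoff, msp_cutoff)
      ml <- fr$msps[, "end"] - fr$msps[, "start"]
      s$n_large_msps_in_region <- sum(ml > msp_cutoff)
    }
    s$region <- lab
    s
  })
  out <- do.call(rbind, rows)
  out[, c("fiber_id", "region", "n_nucleosomes", "pct_dinucleosome",
          "n_msps", "pct_large_msp", "n_large_msps_in_region")]
}

#' Observed and expected spacing between accessible patches
#'
#' Observed distances are start-to-start gaps between consecutive large
#' MSPs on the same fiber, both fully contained in `region`. The
#' expected distance follows the density argument: count large MSPs
#' fully contained in the region, divide by the total sequenced bases
#' overlapping the region to get a patch-per-bp rate, multiply by the
#' region length to get the expected patch count, and divide the region
#' length by that count — algebraically `sequenced_bases / n_contained`.
#'
#' @param fibers List of `Fiber`s (must overlap `region` by >= 1 bp to
#'   contribute sequenced bases).
#' @param region A `GenomicInterval` (typically a CDR call).
#' @param msp_cutoff Large-MSP length cutoff, bp (strict `>`).
#' @return List of class `"SpacingResult"`: `observed` (bp vector),
#'   `expected` (bp, `NA` when no patch is contained),
#'   `n_msps_contained`, `sequenced_bases`.
#' @export
patch_spacing <- function(fibers, region, msp_cutoff = 150L) {
  observed <- integer(0)
  n_contained <- 0L
  sequenced <- 0
  for (f in fibers) {
    ov <- fiber_overlap(f, region)
    if (ov == 0L) next
    sequenced <- sequenced + ov
    m <- f$msps
    if (!nrow(m)) next
    big <- (m[, "end"] - m[, "start"]) > msp_cutoff
    inside <- m[, "start"] >= region$start & m[, "end"] <= region$end
    mm <- m[big & inside, , drop = FALSE]
    n_contained <- n_contained + nrow(mm)
    if (nrow(mm) >= 2L) observed <- c(observed, diff(mm[, "start"]))
  }
  structure(
    list(observed = observed,
         expected = if (n_contained > 0L) sequenced / n_contained else NA_real_,
         n_msps_contained = n_contained, sequenced_bases = sequenced),
    class = "SpacingResult")
}

#' @export
print.SpacingResult <- function(x, ...) {
  cat(sprintf(
    "<SpacingResult> %d contained patches over %s sequenced bp | median observed %s bp, expected %s bp\n",
    x$n_msps_contained, format(x$sequenced_bases, big.mark = ","),
    if (length(x$observed)) format(stats::median(x$observed)) else "NA",
    if (is.na(x$expected)) "NA" else format(round(x$expected, 1))))
  invisible(x)
}

#' Estimated accessible-patch count for a full traversal of a region
#'
#' `(n_contained / sequenced_bases) * region_length`: the expected
#' number of large MSPs a single molecule would carry if it spanned the
#' whole region.
#'
#' @inheritParams patch_spacing
#' @return A single number.
#' @export
estimate_patch_count <- function(fibers, region, msp_cutoff = 150L) {
  sp <- patch_spacing(fibers, region, msp_cutoff)
  if (sp$sequenced_bases == 0) stop("no sequenced bases overlap the region")
  (sp$n_msps_contained / sp$sequenced_bases) * iv_width(region)
}

#' Fraction of spanning fibers with a single covering footprint
#'
#' The point-centromere occupancy statistic: among fibers that fully
#' span `target`, the fraction that contain one protected footprint
#' covering at least `min_span_fraction` of the target ("well
#' positioned" is operationalised as 90% coverage by a single
#' footprint).
#'
#' @param fibers List of `Fiber`s.
#' @param target The element interval (e.g. CDEI-III).
#' @param min_span_fraction Minimum fraction of the target one footprint
#'   must cover (default 0.9, inclusive).
#' @return Fraction in `[0, 1]`, or `NA` when no fiber spans the target.
#' @export
interval_span_fraction <- function(fibers, target, min_span_fraction = 0.9) {
  spanning <- 0L; hit <- 0L
  need <- min_span_fraction * iv_width(target)
  for (f in fibers) {
    if (!fiber_spans_interval(f, target)) next
    spanning <- spanning + 1L
    m <- f$nucleosomes
    if (!nrow(m)) next
    cov <- iv_overlap_width(m[, "start"], m[, "end"], target$start, target$end)
    if (any(cov >= need)) hit <- hit + 1L
  }
  if (!spanning) return(NA_real_)
  hit / spanning
}

#' Footprint length distribution within a region
#'
#' @param fibers List of `Fiber`s.
#' @param region Optional `GenomicInterval`; when given, only footprints
#'   fully contained in it are tallied.
#' @param breaks Passed to [graphics::hist()] semantics via
#'   [base::cut()]-free binning; default 25 bp bins from 0 to the
#'   maximum length.
#' @return List with `lengths` (all footprint lengths), `counts`,
#'   `mids`, and `quantiles` (0/25/50/75/100%).
#' @export
footprint_size_distribution <- function(fibers, region = NULL, breaks = NULL) {
  lens <- integer(0)
  for (f in fibers) {
    m <- f$nucleosomes
    if (!nrow(m)) next
    if (!is.null(region)) {
      keep <- m[, "start"] >= region$start & m[, "end"] <= region$end &
        f$chrom == region$chrom
      m <- m[keep, , drop = FALSE]
    }
    lens <- c(lens, m[, "end"] - m[, "start"])
  }
  if (!length(lens)) {
    return(list(lengths = integer(0), counts = integer(0), mids = numeric(0),
                quantiles = stats::setNames(rep(NA_real_, 5),
                                            c("0%", "25%", "50%", "75%", "100%"))))
  }
  if (is.null(breaks)) breaks <- seq(0, 25 * ceiling(max(lens) / 25), by = 25)
  h <- graphics::hist(lens, breaks = breaks, plot = FALSE)
  list(lengths = lens, counts = h$counts, mids = h$mids,
       quantiles = stats::quantile(lens, c(0, 0.25, 0.5, 0.75, 1)))
}
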