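#' Build and validate a pipeline run configuration
#'
#' Either a simulation block (fixture parameters) or paths to an
#' existing fiber table plus satellite BED must be supplied; an optional
#' externally supplied core BED (e.g. CENP-A CUT&RUN enriched regions)
#' bypasses methylation-based CDR calling.
#'
#' @param config A named list or a path to a YAML file with (any of)
#'   fields: `outdir`, `seed`, `simulate` (fixture overrides, or `TRUE`
#'   for defaults), `fibers`, `reference`, `satellites`, `core_bed`,
#'   `cdr`, `metrics`, `spectra`, `cenpb`.
#' @return Validated config list of class `"RunConfig"`.
#' @export
run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$outdir)) stop("config requires 'outdir'")
  if (is.null(config$seed)) config$seed <- 1L
  sim <- !is.null(config$simulate) && !identical(config$simulate, FALSE)
  if (!sim) {
    for (fld in c("fibers", "satellites")) {
      if (is.null(config[[fld]])) {
        stop("config requires '", fld, "' (or a 'simulate' block)")
      }
      if (!file.exists(config[[fld]])) {
        stop("config ", fld, ": no such file: ", config[[fld]])
      }
    }
    if (!is.null(config$core_bed) && !file.exists(config$core_bed)) {
      stop("config core_bed: no such file: ", config$core_bed)
    }
  }
  config$simulate_requested <- sim
  structure(config, class = "RunConfig")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full dichromatin pipeline
#'
#' Executes (optional) simulation, CDR calling, dichromatin metrics,
#' repeat spectra and CENP-B footprint scoring, writing all outputs and
#' a manifest under `config$outdir`. Stages are deterministic under the
#' configured seed.
#'
#' @param config A [run_config()] (or anything it accepts).
#' @return Named list of output paths, invisibly.
#' @export
run_all <- function(config) {
  config <- run_config(config)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  if (config$simulate_requested) {
    fc <- .stage("simulate", {
      over <- if (isTRUE(config$simulate)) list() else config$simulate
      over$seed <- config$seed
      do.call(fixture_config, over)
    })
    fx <- .stage("simulate",
                 emit_fixture(fc, file.path(outdir, "fixture"), force = TRUE))
    config$fibers <- fx$fibers
    config$satellites <- fx$satellites
    config$reference <- fx$fasta
  }

  fibers <- .stage("io", read_fiber_table(config$fibers))
  sat <- .stage("io", read_satellite_bed(config$satellites))

  cdrp <- do.call(cdr_params, if (is.null(config$cdr)) list() else config$cdr)
  calls <- .stage("cdr", {
    if (!is.null(config$core_bed)) {
      gr <- rtracklayer::import(config$core_bed, format = "BED")
      data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                 start = GenomicRanges::start(gr) - 1L,
                 end = GenomicRanges::end(gr),
                 mean_window_fraction = NA_real_, array_id = "external",
                 pass_length = TRUE, pass_percentile = TRUE,
                 pass_terminal = TRUE, passed = TRUE)
    } else {
      arrays <- merge_satellite_arrays(sat, cdrp)
      if (!length(arrays)) stop("no satellite array passes the size filter")
      meth <- do.call(rbind, lapply(arrays, function(a)
        aggregate_methylation(fibers, a)))
      find_cdrs(sat, meth, cdrp)
    }
  })
  paths$cdr_audit <- file.path(outdir, "cdr_audit.tsv")
  utils::write.table(calls, paths$cdr_audit, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  final <- calls[calls$passed, , drop = FALSE]
  paths$cdr_bed <- file.path(outdir, "cdr_calls.bed")
  write_bed(data.frame(chrom = final$chrom, start = final$start,
                       end = final$end,
                       name = paste0("CDR_", seq_len(nrow(final)))),
            paths$cdr_bed)

  mc <- config$metrics
  dinuc_cutoff <- if (is.null(mc$dinuc_cutoff)) 210L else mc$dinuc_cutoff
  msp_cutoff <- if (is.null(mc$msp_cutoff)) 150L else mc$msp_cutoff
  .stage("metrics", {
    regions <- list()
    for (i in seq_len(nrow(final))) {
      regions[[paste0("CDR_", i)]] <-
        genomic_interval(final$chrom[i], final$start[i], final$end[i])
    }
    if (length(regions)) {
      summ <- regional_summaries(fibers, regions, dinuc_cutoff, msp_cutoff)
      paths$metrics <- file.path(outdir, "dichromatin_summaries.tsv")
      utils::write.table(summ, paths$metrics, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      spacing <- lapply(regions, function(r) {
        sp <- patch_spacing(fibers, r, msp_cutoff)
        list(observed_median = if (length(sp$observed))
          stats::median(sp$observed) else NA,
          expected = sp$expected, n_contained = sp$n_msps_contained,
          sequenced_bases = sp$sequenced_bases,
          estimated_patch_count = if (sp$sequenced_bases > 0)
            estimate_patch_count(fibers, r, msp_cutoff) else NA)
      })
      paths$spacing <- file.path(outdir, "patch_spacing.json")
      jsonlite::write_json(spacing, paths$spacing, auto_unbox = TRUE,
                           digits = NA)
    }
  })

  sc <- config$spectra
  min_p <- if (is.null(sc$min_period)) 120L else sc$min_period
  max_p <- if (is.null(sc$max_period)) 300L else sc$max_period
  .stage("spectra", {
    regs <- list(all = NULL)
    for (i in seq_len(nrow(final))) {
      regs[[paste0("CDR_", i)]] <-
        genomic_interval(final$chrom[i], final$start[i], final$end[i])
    }
    rows <- list()
    for (nm in names(regs)) {
      sp <- suppressMessages(tryCatch(
        region_spectrum(fibers, regs[[nm]], min_p, max_p),
        error = function(e) NULL))
      if (is.null(sp)) next
      rows[[nm]] <- data.frame(region = nm,
                               repeat_length = sp$repeat_lengths,
                               median_density = sp$densities,
                               n_fibers = sp$n_fibers)
    }
    paths$spectra <- file.path(outdir, "repeat_spectra.tsv")
    utils::write.table(do.call(rbind, rows), paths$spectra, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  })

  if (!is.null(config$reference) && file.exists(config$reference)) {
    cb <- config$cenpb
    .stage("cenpb", {
      ref <- read_reference(config$reference)
      sites <- scan_cenpb_boxes(ref, regions = sat)
      paths$cenpb_sites <- file.path(outdir, "cenpb_sites.bed")
      write_bed(data.frame(chrom = sites$chrom, start = sites$start,
                           end = sites$end, name = sites$site_id,
                           score = 0L, strand = sites$strand),
                paths$cenpb_sites)
      obs <- observe_boxes(fibers, sites)
      scores <- list()
      for (st in 0:2) {
        o <- filter_observations(obs, mcpg_state = st)
        if (nrow(o$windows) * 0.10 < 5) next
        sd <- score_distribution(
          o, seed = config$seed,
          n_subsamples = if (is.null(cb$n_subsamples)) 1000L else cb$n_subsamples)
        scores[[as.character(st)]] <- list(
          score = sd$score, n_observations = sd$n_fibers,
          median_subsample = stats::median(sd$distribution),
          quantiles = as.list(sd$quantiles))
      }
      paths$cenpb_scores <- file.path(outdir, "cenpb_scores.json")
      jsonlite::write_json(scores, paths$cenpb_scores, auto_unbox = TRUE,
                           digits = NA)
    })
  }

  manifest <- list(
    package = "dichrom",
    version = as.character(utils::packageVersion("dichrom")),
    seed = config$seed,
    config = unclass(config)[setdiff(names(config), "simulate_requested")],
    outputs = lapply(paths, normalizePath))
  paths$manifest <- file.path(outdir, "manifest.yaml")
  yaml::write_yaml(manifest, paths$manifest)
  invisible(paths)
}
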