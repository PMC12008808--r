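## Synthetic Fiber-seq fixture generator.
##
## Emits a reference with a tandem alpha-satellite-like monomer array
## flanked by non-satellite sequence, plus single-molecule fibers with
## planted dichromatin structure: nucleosome arrays phased one per
## monomer inside a hypo-CpG-methylated core (CDR), unphased arrays at
## the euchromatic repeat length elsewhere, clustered large accessible
## patches, CENP-B boxes whose occupancy depends on the molecule's CpG
## methylation state, and m6A stenciling of accessible A/T bases.

CENPB_CONSENSUS <- "NTTCGNNNNANNCGGGN"   # 17 bp, CpGs at offsets 3 and 12

#' Fixture configuration for the synthetic fiber generator
#'
#' Defaults encode the study conditions the generator emulates: a 170 bp
#' satellite monomer, a 20 kb hypomethylated core (methylation 0.05)
#' inside a high-methylation (0.85) 300 kb array, 190 bp euchromatic
#' nucleosome spacing, 147 bp nucleosomes with a 1/3 chance of
#' di-nucleosome-sized (211-300 bp) footprints in the core, CENP-B boxes
#' every second monomer with occupancy probabilities 0.8/0.1/0.05 for
#' 0/1/2 methylated box CpGs, and per-accessible-A/T m6A probability 0.4.
#'
#' @param monomer_length Satellite monomer length in bp (>= 50).
#' @param array_length Target satellite array length in bp (rounded down
#'   to a whole number of monomers).
#' @param flank_length Non-satellite flank length on each side, bp.
#' @param cdr_start,cdr_end Planted core interval, bp relative to the
#'   array start.
#' @param cdr_meth,background_meth Per-CpG methylation probability inside
#'   / outside the planted core.
#' @param cpg_dropout Per-CpG probability that a molecule's call is
#'   missing (models uncalled sites).
#' @param euchromatic_spacing Nucleosome start-to-start spacing outside
#'   the core, bp.
#' @param nucleosome_len Mononucleosome footprint length, bp.
#' @param dinucleosome_rate_core Probability that a phased core
#'   nucleosome pair is replaced by one 211-300 bp footprint.
#' @param msp_rate_core,msp_rate_flank Expected large MSPs per kb inside
#'   / outside the core.
#' @param msp_cluster_factor Per-fiber rate overdispersion (>= 1); the
#'   fiber-level rate multiplier is Gamma with mean 1 and variance
#'   `msp_cluster_factor - 1` (1 = Poisson).
#' @param msp_len_min,msp_len_max Planted MSP length range, bp.
#' @param cenpb_spacing Monomers between consecutive CENP-B boxes.
#' @param box_offset Box start offset within its monomer, bp.
#' @param box_clearance_up,box_clearance_down Accessible clearance
#'   upstream / downstream of the box center inside the core (bp): the
#'   phased nucleosome is pushed back so the box sits in an open linker,
#'   emulating the accessible flanks seen around CENP-B elements.
#' @param occupied_footprint Footprint length centered on an occupied
#'   box, bp (default 44, a DNaseI-footprint-sized protected core lying
#'   inside the clearance window).
#' @param p_occupy_given_mcpg Length-3 numeric: occupancy probability for
#'   0, 1, 2 methylated box CpGs.
#' @param m6a_density_accessible Per-A/T m6A probability in accessible
#'   (unfootprinted) DNA.
#' @param fiber_length,n_fibers Simulated molecule length and count.
#' @param seed Master seed; all draws derive from it.
#' @return A validated list of class `"FixtureConfig"`.
#' @export
fixture_config <- function(monomer_length = 170L,
                           array_length = 300000L,
                           flank_length = 20000L,
                           cdr_start = 140000L,
                           cdr_end = 160000L,
                           cdr_meth = 0.05,
                           background_meth = 0.85,
                           cpg_dropout = 0.05,
                           euchromatic_spacing = 190L,
                           nucleosome_len = 147L,
                           dinucleosome_rate_core = 1 / 3,
                           msp_rate_core = 0.2,
                           msp_rate_flank = 0.05,
                           msp_cluster_factor = 1,
                           msp_len_min = 150L,
                           msp_len_max = 800L,
                           cenpb_spacing = 2L,
                           box_offset = 130L,
                           box_clearance_up = 38L,
                           box_clearance_down = 32L,
                           occupied_footprint = 44L,
                           p_occupy_given_mcpg = c(0.8, 0.1, 0.05),
                           m6a_density_accessible = 0.4,
                           fiber_length = 15000L,
                           n_fibers = 300L,
                           seed = 1L) {
  cfg <- list(
    monomer_length = as.integer(monomer_length),
    array_length = as.integer(array_length),
    flank_length = as.integer(flank_length),
    cdr_start = as.integer(cdr_start), cdr_end = as.integer(cdr_end),
    cdr_meth = cdr_meth, background_meth = background_meth,
    cpg_dropout = cpg_dropout,
    euchromatic_spacing = as.integer(euchromatic_spacing),
    nucleosome_len = as.integer(nucleosome_len),
    dinucleosome_rate_core = dinucleosome_rate_core,
    msp_rate_core = msp_rate_core, msp_rate_flank = msp_rate_flank,
    msp_cluster_factor = msp_cluster_factor,
    msp_len_min = as.integer(msp_len_min),
    msp_len_max = as.integer(msp_len_max),
    cenpb_spacing = as.integer(cenpb_spacing),
    box_offset = as.integer(box_offset),
    box_clearance_up = as.integer(box_clearance_up),
    box_clearance_down = as.integer(box_clearance_down),
    occupied_footprint = as.integer(occupied_footprint),
    p_occupy_given_mcpg = as.numeric(p_occupy_given_mcpg),
    m6a_density_accessible = m6a_density_accessible,
    fiber_length = as.integer(fiber_length),
    n_fibers = as.integer(n_fibers),
    seed = as.integer(seed))
  probs <- c(cfg$cdr_meth, cfg$background_meth, cfg$cpg_dropout,
             cfg$dinucleosome_rate_core, cfg$p_occupy_given_mcpg,
             cfg$m6a_density_accessible)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0,1]")
  if (cfg$monomer_length < 50L) stop("monomer_length must be >= 50 bp")
  if (cfg$array_length < cfg$monomer_length) {
    stop("array shorter than one monomer")
  }
  if (cfg$cdr_start < 0L || cfg$cdr_end > cfg$array_length ||
      cfg$cdr_start >= cfg$cdr_end) {
    stop("planted CDR must lie inside the array")
  }
  if (cfg$fiber_length < 2L * cfg$monomer_length) {
    stop("fiber_length must be at least two monomers")
  }
  if (cfg$msp_cluster_factor < 1) stop("msp_cluster_factor must be >= 1")
  if (length(cfg$p_occupy_given_mcpg) != 3L) {
    stop("p_occupy_given_mcpg must give probabilities for states 0, 1, 2")
  }
  if (cfg$box_offset + 17L > cfg$monomer_length) {
    stop("CENP-B box does not fit in the monomer at box_offset")
  }
  structure(cfg, class = "FixtureConfig")
}

## counter-based child seeds: every module draws from its own stream so
## reference, fibers etc. can be regenerated independently
child_seed <- function(seed, k) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, 16L)[k]
}

.rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.fill_box <- function() {
  ch <- strsplit(CENPB_CONSENSUS, "")[[1L]]
  ch[ch == "N"] <- sample(c("A", "T"), sum(ch == "N"), replace = TRUE)
  paste(ch, collapse = "")
}

#' Build the synthetic reference bundle
#'
#' Tandem monomer array carrying an exact-consensus CENP-B box every
#' `cenpb_spacing` monomers (degenerate positions filled from A/T so the
#' matched 17-mer carries exactly its 2 consensus CpGs), flanked by
#' non-satellite random sequence. The monomer is redrawn until it holds
#' at least four CpG dinucleotides and no spurious box match, so every
#' methylation window has sites and planted boxes are the only array
#' matches.
#'
#' @param config A [fixture_config()].
#' @return List of class `"ReferenceBundle"`: `chrom`, `seq`
#'   (`DNAString`), `annotations`, `boxes` (data frame: start, end,
#'   strand, center, cpg1, cpg2), `cdr` (truth interval), `array`
#'   interval, `monomer` sequence.
#' @export
make_reference <- function(config) {
  stopifnot(inherits(config, "FixtureConfig"))
  set.seed(child_seed(config$seed, 1L))
  mlen <- config$monomer_length
  n_mono <- config$array_length %/% mlen
  pat <- Biostrings::DNAString(CENPB_CONSENSUS)
  repeat {
    monomer <- .rand_dna(mlen)
    md <- Biostrings::DNAString(monomer)
    n_cg <- length(Biostrings::matchPattern("CG", md))
    fwd <- length(Biostrings::matchPattern(pat, md, fixed = FALSE))
    rev <- length(Biostrings::matchPattern(
      pat, Biostrings::reverseComplement(md), fixed = FALSE))
    if (n_cg >= 4L && fwd == 0L && rev == 0L) break
  }
  array_start <- config$flank_length
  monomers <- character(n_mono)
  box_start <- integer(0)
  for (m in seq_len(n_mono)) {
    s <- monomer
    if ((m - 1L) %% config$cenpb_spacing == 0L) {
      box <- .fill_box()
      substr(s, config$box_offset + 1L, config$box_offset + 17L) <- box
      box_start <- c(box_start, array_start + (m - 1L) * mlen + config$box_offset)
    }
    monomers[m] <- s
  }
  left <- .rand_dna(config$flank_length)
  right <- .rand_dna(config$flank_length)
  seq <- Biostrings::DNAString(paste0(left, paste(monomers, collapse = ""), right))
  array_end <- array_start + n_mono * mlen
  chrom <- "chrS"
  ann <- satellite_annotation(
    chrom = rep(chrom, 3L),
    start = c(0L, array_start, array_end),
    end = c(array_start, array_end, array_end + config$flank_length),
    sat_class = c("non_satellite", "active_hor", "non_satellite"))
  boxes <- data.frame(
    start = box_start, end = box_start + 17L, strand = "+",
    center = box_start + 8L, cpg1 = box_start + 3L, cpg2 = box_start + 12L)
  structure(
    list(chrom = chrom, seq = seq, annotations = ann, boxes = boxes,
         cdr = genomic_interval(chrom, array_start + config$cdr_start,
                                array_start + config$cdr_end, name = "CDR_truth"),
         array = genomic_interval(chrom, array_start, array_end,
                                  name = "active_hor"),
         monomer = monomer),
    class = "ReferenceBundle")
}

## split [s,e) into maximal runs inside/outside [cs,ce)
.split_by_cdr <- function(s, e, cs, ce) {
  cuts <- sort(unique(c(s, e, max(s, min(e, cs)), max(s, min(e, ce)))))
  segs <- data.frame(start = cuts[-length(cuts)], end = cuts[-1L])
  segs <- segs[segs$end > segs$start, , drop = FALSE]
  segs$in_cdr <- segs$start >= cs & segs$end <= ce
  segs
}

.place_msps <- function(segs, config, mult) {
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_len(nrow(segs))) {
    rate <- if (segs$in_cdr[i]) config$msp_rate_core else config$msp_rate_flank
    len_kb <- (segs$end[i] - segs$start[i]) / 1000
    k <- stats::rpois(1L, rate * len_kb * mult)
    for (j in seq_len(k)) {
      for (try in 1:50) {
        L <- sample(config$msp_len_min:config$msp_len_max, 1L)
        if (segs$end[i] - segs$start[i] <= L) break
        st <- segs$start[i] + sample.int(segs$end[i] - segs$start[i] - L, 1L) - 1L
        if (!length(out_s) ||
            all(st + L <= out_s | st >= out_e)) {
          out_s <- c(out_s, st); out_e <- c(out_e, st + L)
          break
        }
      }
    }
  }
  iv_matrix(out_s, out_e)
}

#' Simulate fibers over a reference bundle
#'
#' Each fiber samples an alignment span within the requested region,
#' draws per-CpG methylation (core vs background rate), places phased
#' nucleosomes on the monomer grid inside the planted core (with
#' di-nucleosome replacements) and unphased arrays at the euchromatic
#' spacing elsewhere, draws occupancy for every spanned CENP-B box from
#' the molecule's true box-CpG state and plants a protected footprint on
#' occupied boxes, scatters large MSPs as an (optionally overdispersed)
#' point process, and finally stencils m6A onto accessible A/T bases.
#' Footprinted bases never carry m6A.
#'
#' @param config A [fixture_config()].
#' @param ref A [make_reference()] bundle built from the same config.
#' @param region Where to sample fibers: `"array"` (whole satellite
#'   array), `"core"` (inside the planted CDR), or `"flank"` (left
#'   non-satellite flank; euchromatic fixture).
#' @return List with `fibers` (list of `Fiber`) and `truth` (`TruthSet`:
#'   planted CDR, per-box per-fiber state/occupancy table, planted
#'   spacings, config).
#' @export
simulate_fibers <- function(config, ref, region = c("array", "core", "flank")) {
  stopifnot(inherits(config, "FixtureConfig"), inherits(ref, "ReferenceBundle"))
  region <- match.arg(region)
  set.seed(child_seed(config$seed, 2L))
  flen <- config$fiber_length
  lim <- switch(region,
    array = c(ref$array$start, ref$array$end),
    core = c(ref$cdr$start, ref$cdr$end),
    flank = c(0L, config$flank_length))
  if (lim[2L] - lim[1L] < flen) {
    stop("region '", region, "' is shorter than fiber_length")
  }
  chars <- strsplit(as.character(ref$seq), "")[[1L]]
  cg_all <- Biostrings::start(Biostrings::matchPattern("CG", ref$seq)) - 1L
  cs <- ref$cdr$start; ce <- ref$cdr$end
  mlen <- config$monomer_length
  nlen <- config$nucleosome_len
  fibers <- vector("list", config$n_fibers)
  truth_boxes <- list()
  mcf <- config$msp_cluster_factor
  for (i in seq_len(config$n_fibers)) {
    fs <- lim[1L] + sample.int(lim[2L] - lim[1L] - flen + 1L, 1L) - 1L
    fe <- fs + flen
    ## per-molecule CpG methylation: truth, then dropout to calls
    cg <- cg_all[cg_all >= fs & cg_all < fe]
    p <- ifelse(cg >= cs & cg < ce, config$cdr_meth, config$background_meth)
    meth_true <- stats::runif(length(cg)) < p
    called <- stats::runif(length(cg)) >= config$cpg_dropout
    ## nucleosome placement, piecewise by core membership
    segs <- .split_by_cdr(fs, fe, cs, ce)
    nuc_s <- integer(0); nuc_e <- integer(0)
    for (k in seq_len(nrow(segs))) {
      s <- segs$start[k]; e <- segs$end[k]
      if (segs$in_cdr[k]) {
        j0 <- (s - ref$array$start) %/% mlen
        j1 <- (e - 1L - ref$array$start) %/% mlen
        ms <- ref$array$start + (j0:j1) * mlen
        ps <- pmax(ms, s); pe <- pmin(ms + nlen, e)
        ok <- (pe - ps) >= 40L
        ps <- ps[ok]; pe <- pe[ok]
        ## di-nucleosome replacement of adjacent pairs
        ds <- integer(0); de <- integer(0)
        j <- 1L
        while (j <= length(ps)) {
          if (j < length(ps) &&
              stats::runif(1L) < config$dinucleosome_rate_core) {
            L <- sample(211:300, 1L)
            ds <- c(ds, ps[j]); de <- c(de, min(ps[j] + L, e))
            j <- j + 2L
          } else {
            ds <- c(ds, ps[j]); de <- c(de, pe[j])
            j <- j + 1L
          }
        }
        nuc_s <- c(nuc_s, ds); nuc_e <- c(nuc_e, de)
      } else {
        phase <- sample.int(config$euchromatic_spacing, 1L) - 1L
        st <- seq.int(s + phase - config$euchromatic_spacing, e,
                      by = config$euchromatic_spacing)
        ps <- pmax(st, s); pe <- pmin(st + nlen, e)
        ok <- (pe - ps) >= 40L
        nuc_s <- c(nuc_s, ps[ok]); nuc_e <- c(nuc_e, pe[ok])
      }
    }
    nuc <- iv_matrix_merge(iv_matrix(nuc_s, nuc_e))
    ## CENP-B box occupancy from the molecule's true box-CpG state
    bx <- ref$boxes[ref$boxes$start >= fs & ref$boxes$end <= fe, , drop = FALSE]
    if (nrow(bx)) {
      st1 <- meth_true[match(bx$cpg1, cg)]
      st2 <- meth_true[match(bx$cpg2, cg)]
      state <- as.integer(st1) + as.integer(st2)
      occ <- stats::runif(nrow(bx)) < config$p_occupy_given_mcpg[state + 1L]
      ## inside the core, boxes sit in an open linker: push phased
      ## nucleosomes out of the clearance window around the center
      in_core <- bx$center >= cs & bx$center < ce
      clr <- iv_matrix(
        pmax(bx$center[in_core] - config$box_clearance_up, fs),
        pmin(bx$center[in_core] + config$box_clearance_down, fe))
      if (nrow(clr)) nuc <- iv_matrix_subtract(nuc, clr, min_len = 40L)
      half <- config$occupied_footprint %/% 2L
      bfp_s <- pmax(bx$center - half, fs)
      bfp_e <- pmin(bx$center + (config$occupied_footprint - half), fe)
      bfp <- iv_matrix(bfp_s[occ], bfp_e[occ])
      if (nrow(bfp)) {
        nuc <- iv_matrix_subtract(nuc, bfp, min_len = 40L)
        nuc <- iv_matrix(c(nuc[, "start"], bfp[, "start"]),
                         c(nuc[, "end"], bfp[, "end"]))
      }
      truth_boxes[[length(truth_boxes) + 1L]] <- data.frame(
        fiber_id = sprintf("fib%04d", i), box_start = bx$start,
        center = bx$center, mcpg_state = state, occupied = occ)
    }
    ## clustered large MSPs, then carve them out of footprints
    mult <- if (mcf > 1) {
      stats::rgamma(1L, shape = 1 / (mcf - 1), scale = mcf - 1)
    } else 1
    msp <- .place_msps(segs, config, mult)
    if (nrow(msp)) nuc <- iv_matrix_subtract(nuc, msp, min_len = 40L)
    ## m6A stencil on accessible A/T bases
    prot <- logical(flen)
    for (r in seq_len(nrow(nuc))) {
      prot[(nuc[r, "start"] - fs + 1L):(nuc[r, "end"] - fs)] <- TRUE
    }
    at <- chars[(fs + 1L):fe] %in% c("A", "T")
    acc <- which(at & !prot)
    hit <- acc[stats::runif(length(acc)) < config$m6a_density_accessible]
    fibers[[i]] <- fiber(
      sprintf("fib%04d", i), ref$chrom, fs, fe,
      m6a = fs + hit - 1L,
      nucleosomes = nuc, msps = msp,
      cpg = data.frame(pos = cg[called], meth = meth_true[called]))
  }
  truth <- structure(
    list(cdr = ref$cdr,
         boxes = if (length(truth_boxes)) do.call(rbind, truth_boxes) else
           data.frame(fiber_id = character(0), box_start = integer(0),
                      center = integer(0), mcpg_state = integer(0),
                      occupied = logical(0)),
         spacing = list(core = config$monomer_length,
                        flank = config$euchromatic_spacing),
         region = region, config = unclass(config)),
    class = "TruthSet")
  list(fibers = fibers, truth = truth)
}

#' Write a complete fixture to disk
#'
#' Emits the reference FASTA, satellite / CENP-B box / truth-CDR BEDs,
#' the fiber table, a truth JSON and a manifest recording config and
#' seed. Refuses to write into an existing non-empty directory unless
#' `force = TRUE`.
#'
#' @param config A [fixture_config()].
#' @param outdir Output directory.
#' @param region Fiber sampling region passed to [simulate_fibers()].
#' @param force Overwrite an existing non-empty directory.
#' @return Named list of written paths, invisibly.
#' @export
emit_fixture <- function(config, outdir, region = "array", force = FALSE) {
  if (dir.exists(outdir) && length(list.files(outdir)) && !force) {
    stop("output directory ", outdir, " is non-empty; use force = TRUE")
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ref <- make_reference(config)
  sim <- simulate_fibers(config, ref, region = region)
  paths <- list(
    fasta = file.path(outdir, "reference.fa"),
    satellites = file.path(outdir, "satellites.bed"),
    boxes = file.path(outdir, "cenpb_boxes.bed"),
    cdr = file.path(outdir, "cdr_truth.bed"),
    fibers = file.path(outdir, "fibers.tsv"),
    truth = file.path(outdir, "truth.json"),
    manifest = file.path(outdir, "manifest.yaml"))
  ss <- Biostrings::DNAStringSet(ref$seq)
  names(ss) <- ref$chrom
  Biostrings::writeXStringSet(ss, paths$fasta)
  write_bed(data.frame(chrom = ref$annotations$chrom,
                       start = ref$annotations$start,
                       end = ref$annotations$end,
                       name = ref$annotations$sat_class), paths$satellites)
  write_bed(data.frame(chrom = ref$chrom, start = ref$boxes$start,
                       end = ref$boxes$end, name = "CENP-B_box",
                       score = 0L, strand = ref$boxes$strand), paths$boxes)
  write_bed(list(ref$cdr), paths$cdr)
  write_fiber_table(sim$fibers, paths$fibers)
  jsonlite::write_json(
    list(cdr = list(chrom = ref$cdr$chrom, start = ref$cdr$start,
                    end = ref$cdr$end),
         spacing = sim$truth$spacing,
         boxes = sim$truth$boxes),
    paths$truth, auto_unbox = TRUE, digits = NA)
  yaml::write_yaml(list(schema = FIBER_TABLE_VERSION, region = region,
                        seed = config$seed, config = unclass(config)),
                   paths$manifest)
  invisible(paths)
}
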