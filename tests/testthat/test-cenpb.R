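# CENP-B box scanning, per-molecule stratification, profile smoothing,
# footprint scoring and nucleosome edge positioning

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

## brute-force regex oracle for the consensus on one strand
regex_hits <- function(seq) {
  pat <- "(?=([ACGT]TTCG[ACGT]{4}A[ACGT]{2}CGGG[ACGT]))"
  m <- gregexpr(pat, seq, perl = TRUE)[[1]]
  if (m[1] == -1) return(integer(0))
  starts <- as.integer(m) - 1L
  keep <- vapply(starts, function(s) {
    sub <- substr(seq, s + 1, s + 17)
    length(gregexpr("(?=CG)", sub, perl = TRUE)[[1]]) == 2 &&
      gregexpr("(?=CG)", sub, perl = TRUE)[[1]][1] != -1
  }, logical(1))
  starts[keep]
}

test_that("scanning finds planted plus- and minus-strand boxes", {
  box <- "ATTCGAAAAATACGGGT"
  seq <- paste0(strrep("T", 100), box, strrep("T", 100))
  sites <- scan_cenpb_boxes(Biostrings::DNAString(seq), chrom = "c")
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$start, 100L)
  expect_equal(sites$end, 117L)
  expect_equal(sites$strand, "+")
  expect_equal(sites$center, 108L)
  expect_equal(sites$cpg1, 103L)
  expect_equal(sites$cpg2, 112L)
  ## the reverse complement of the sequence carries the mirrored site
  rc <- revcomp(seq)
  sites_rc <- scan_cenpb_boxes(Biostrings::DNAString(rc), chrom = "c")
  expect_equal(nrow(sites_rc), 1L)
  expect_equal(sites_rc$strand, "-")
  expect_equal(sites_rc$start, nchar(seq) - 117L)
  expect_equal(sites_rc$center, sites_rc$start + 8L)
  ## poly-A carries nothing
  expect_equal(nrow(scan_cenpb_boxes(Biostrings::DNAString(strrep("A", 500)),
                                     chrom = "c")), 0L)
})

test_that("scanning agrees with a regex oracle on random sequence", {
  set.seed(43)
  for (i in 1:15) {
    seq <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
                 collapse = "")
    ## plant a couple of boxes so matches are guaranteed
    box1 <- "ATTCGTATAAAACGGGA"
    box2 <- revcomp("TTTCGGATTAGACGGGC")
    substr(seq, 2001, 2017) <- box1
    substr(seq, 7001, 7017) <- box2
    sites <- scan_cenpb_boxes(Biostrings::DNAString(seq), chrom = "c")
    plus <- sort(regex_hits(seq))
    minus_rc <- regex_hits(revcomp(seq))
    minus <- sort(10000L - (minus_rc + 17L))
    expect_equal(sort(sites$start[sites$strand == "+"]), plus)
    expect_equal(sort(sites$start[sites$strand == "-"]), minus)
    expect_true(2000L %in% sites$start[sites$strand == "+"])
    expect_true(7000L %in% sites$start[sites$strand == "-"])
  }
})

make_site <- function(center, strand = "+", chrom = "chr1") {
  s <- center - 8L
  structure(data.frame(chrom = chrom, start = s, end = s + 17L,
                       strand = strand, center = center, cpg1 = s + 3L,
                       cpg2 = s + 12L, region = NA_character_,
                       site_id = paste0(chrom, ":", s, ":", strand)),
            class = c("CenpBSites", "data.frame"))
}

test_that("box observations capture windows and trinary CpG states", {
  site <- make_site(500L)
  f2 <- make_plain_fiber("two", m6a = c(460L, 540L),
                         cpg = data.frame(pos = c(495L, 504L),
                                          meth = c(TRUE, TRUE)))
  f1 <- make_plain_fiber("one",
                         cpg = data.frame(pos = c(495L, 504L),
                                          meth = c(TRUE, FALSE)))
  fm <- make_plain_fiber("miss",
                         cpg = data.frame(pos = 495L, meth = TRUE))
  fshort <- make_plain_fiber("short", start = 460L, end = 530L)
  obs <- observe_boxes(list(f2, f1, fm, fshort), site)
  expect_equal(nrow(obs$meta), 3L)             # non-spanning fiber skipped
  expect_equal(obs$meta$mcpg_state, c(2L, 1L, NA_integer_))
  ## window lookup: offsets -40 and +40 relative to the center
  expect_equal(unname(obs$windows[1, c("-40", "0", "40")]), c(1L, 0L, 1L))
  ## minus-strand windows are flipped into motif orientation
  site_m <- make_site(500L, strand = "-")
  obs_m <- observe_boxes(list(f2), site_m)
  expect_equal(unname(obs_m$windows[1, c("-40", "40")]), c(1L, 1L))
  f_asym <- make_plain_fiber("asym", m6a = 530L)
  o_p <- observe_boxes(list(f_asym), site)
  o_m <- observe_boxes(list(f_asym), site_m)
  expect_equal(unname(o_p$windows[1, "30"]), 1L)
  expect_equal(unname(o_m$windows[1, "-30"]), 1L)
  ## lookup oracle on random fibers
  set.seed(47)
  for (i in 1:10) {
    f <- make_plain_fiber("r", m6a = sort(sample(430:570, 25L)))
    o <- observe_boxes(list(f), site)
    for (off in sample(-50:50, 12)) {
      expect_equal(unname(o$windows[1, as.character(off)]),
                   as.integer((500L + off) %in% f$m6a))
    }
  }
})

test_that("profile smoothing is mean-then-rolling-mean with truncation", {
  w <- matrix(0L, nrow = 3, ncol = 101,
              dimnames = list(NULL, as.character(-50:50)))
  expect_equal(unname(aggregate_profile(w)), rep(0, 101))
  expect_equal(unname(aggregate_profile(w + 1L)), rep(1, 101))
  set.seed(53)
  w[] <- as.integer(runif(303) < 0.3)
  prof <- aggregate_profile(w)
  raw <- colMeans(w)
  oracle <- vapply(1:101, function(i)
    mean(raw[max(1, i - 5):min(101, i + 4)]), numeric(1))
  expect_equal(unname(prof), unname(oracle))
  expect_error(aggregate_profile(w[0, , drop = FALSE]), "empty")
})

test_that("footprint scores follow the stated flank/core arithmetic", {
  prof <- stats::setNames(rep(0.25, 101), as.character(-50:50))
  ## flank 0.4, core 0.1 -> 0.4 / 0.101
  prof[as.character(c(-35:-27, 22:27))] <- 0.4
  prof[as.character(-7:1)] <- 0.1
  expect_equal(footprint_score(prof), 0.4 / 0.101)
  ## flat profile scores ~1 within pseudocount tolerance
  flat <- stats::setNames(rep(0.3, 101), as.character(-50:50))
  expect_equal(footprint_score(flat), 1, tolerance = 0.01)
  ## fully protected core is finite through the pseudocount
  prot <- flat; prot[as.character(-7:1)] <- 0
  expect_equal(footprint_score(prot), 0.3 / 1e-3)
  ## incomplete profiles are refused
  expect_error(footprint_score(prof[1:40]), "offsets")
})

test_that("subsampled score distributions are reproducible and degenerate at fraction 1", {
  set.seed(59)
  w <- matrix(as.integer(runif(50 * 101) < 0.25), nrow = 50,
              dimnames = list(NULL, as.character(-50:50)))
  obs <- structure(list(meta = data.frame(site_id = "s", fiber_id = 1:50,
                                          strand = "+", region = NA,
                                          mcpg_state = 0L),
                        windows = w, halfwidth = 50L),
                   class = "BoxObservations")
  full <- score_distribution(obs, subsample_fraction = 1, n_subsamples = 20,
                             seed = 2)
  expect_true(all(full$distribution == full$score))
  d1 <- score_distribution(obs, n_subsamples = 50, seed = 9)
  d2 <- score_distribution(obs, n_subsamples = 50, seed = 9)
  expect_identical(d1$distribution, d2$distribution)
  tiny <- structure(list(meta = obs$meta[1:20, ], windows = w[1:20, ],
                         halfwidth = 50L), class = "BoxObservations")
  expect_error(score_distribution(tiny), "at least")
})

test_that("median scores order by planted occupancy across mCpG states", {
  cfg <- small_core_config(61, cdr_meth = 0.5, n_fibers = 80L)
  ref <- make_reference(cfg)
  sim <- simulate_fibers(cfg, ref, region = "core")
  sites <- scan_cenpb_boxes(ref_as_stringset(ref))
  obs <- observe_boxes(sim$fibers, sites)
  med <- vapply(0:2, function(st) {
    o <- filter_observations(obs, mcpg_state = st)
    stats::median(score_distribution(o, n_subsamples = 100,
                                     seed = 61)$distribution)
  }, numeric(1))
  expect_gt(med[1], med[2])
  expect_gt(med[2], med[3])
})

test_that("nucleosome edge offsets are recorded relative to the box center", {
  site <- make_site(500L)
  out <- nucleosome_edge_positioning(list(
    make_plain_fiber("d", end = 1100L, nuc = iv(510L, 657L),
                     cpg = data.frame(pos = c(495L, 504L),
                                      meth = c(FALSE, FALSE)))), site)
  dn <- out[["0"]]
  expect_equal(dn$pct_downstream[dn$offset == 10], 100)
  expect_true(all(dn$pct_downstream[dn$offset != 10] == 0))
  ## mirror-symmetric input gives mirror-symmetric histograms
  fsym <- make_plain_fiber("s", end = 1100L,
                           nuc = iv(c(340L, 510L), c(490L, 660L)),
                           cpg = data.frame(pos = c(495L, 504L),
                                            meth = c(FALSE, FALSE)))
  sym <- nucleosome_edge_positioning(list(fsym), site)[["0"]]
  expect_equal(sym$pct_upstream[sym$offset == -10],
               sym$pct_downstream[sym$offset == 10])
  ## planted clearance geometry: occupied-core fixture puts modes at the
  ## configured clearance edges
  cfg <- small_core_config(67, n_fibers = 30L)
  ref <- make_reference(cfg)
  sim <- simulate_fibers(cfg, ref, region = "core")
  sites <- scan_cenpb_boxes(ref_as_stringset(ref))
  hist0 <- nucleosome_edge_positioning(sim$fibers, sites)[["0"]]
  expect_equal(hist0$offset[which.max(hist0$pct_upstream)], -38L)
  expect_equal(hist0$offset[which.max(hist0$pct_downstream)], 32L)
})
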