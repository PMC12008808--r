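# di-nucleosome / large-MSP classification, spacing statistics and the
# point-centromere occupancy statistic

test_that("feature classification uses strict cutoffs", {
  f <- make_plain_fiber(nuc = iv(c(0L, 300L), c(147L, 511L)))   # 147, 211
  s <- classify_features(f)
  expect_equal(s$pct_dinucleosome, 50)
  f2 <- make_plain_fiber(nuc = iv(0L, 210L))                    # exactly 210
  expect_equal(classify_features(f2)$pct_dinucleosome, 0)
  f3 <- make_plain_fiber(msp = iv(c(0L, 300L), c(150L, 451L)))  # 150, 151
  s3 <- classify_features(f3)
  expect_equal(s3$pct_large_msp, 50)
  ## zero denominators are flagged undefined, not zero
  expect_true(is.na(classify_features(make_plain_fiber())$pct_dinucleosome))
  ## random fibers against a direct filter; cutoff monotonicity
  set.seed(13)
  for (i in 1:10) {
    lens <- sample(60:400, 8)
    st <- as.integer(c(0L, cumsum(lens[-8] + 50L)) + 100L)
    f <- make_plain_fiber(end = 5000L, nuc = iv(st, st + lens))
    expect_equal(classify_features(f)$pct_dinucleosome, 100 * mean(lens > 210))
    expect_gte(classify_features(f, dinuc_cutoff = 180L)$pct_dinucleosome,
               classify_features(f, dinuc_cutoff = 240L)$pct_dinucleosome)
  }
})

test_that("fibers are assigned to regions by majority span", {
  regions <- list(left = genomic_interval("chr1", 0, 700),
                  right = genomic_interval("chr1", 700, 2000))
  f <- make_plain_fiber("straddle", start = 0L, end = 1000L,
                        nuc = iv(c(100L, 800L), c(350L, 950L)))
  out <- regional_summaries(list(f), regions)
  expect_equal(out$region, "left")                # 70/30 split
  expect_equal(out$n_nucleosomes, 1L)             # only the contained one
  f2 <- make_plain_fiber("outside", chrom = "chr9")
  expect_equal(regional_summaries(list(f2), regions)$region, "unassigned")
})

test_that("core fibers carry more di-nucleosomes than flank fibers", {
  cfg <- small_core_config(41, n_fibers = 25L, fiber_length = 4000L)
  ref <- make_reference(cfg)
  core <- simulate_fibers(cfg, ref, region = "core")$fibers
  flank <- simulate_fibers(cfg, ref, region = "flank")$fibers
  pct <- function(fs) mean(vapply(fs, function(f)
    classify_features(f)$pct_dinucleosome, numeric(1)), na.rm = TRUE)
  expect_gt(pct(core), pct(flank))
})

test_that("patch spacing reproduces the stated observed/expected arithmetic", {
  region <- genomic_interval("chr1", 0, 10000)
  f <- make_plain_fiber(end = 10000L,
                        msp = iv(c(100L, 400L, 1000L), c(300L, 700L, 1400L)))
  sp <- patch_spacing(list(f), region)
  expect_equal(sp$observed, c(300L, 600L))
  ## ten spanning molecules with 20 contained patches over 100 kb
  fibers <- lapply(1:10, function(i)
    make_plain_fiber(paste0("f", i), end = 10000L,
                     msp = iv(c(2000L, 6000L), c(2300L, 6400L))))
  sp10 <- patch_spacing(fibers, region)
  expect_equal(sp10$sequenced_bases, 100000)
  expect_equal(sp10$n_msps_contained, 20L)
  expect_equal(sp10$expected, 5000)
  expect_equal(estimate_patch_count(fibers, region), 2.0)
  ## duplication invariance of the estimate
  expect_equal(estimate_patch_count(c(fibers, fibers), region), 2.0)
  ## identity: expected == sequenced / contained on arbitrary inputs
  set.seed(17)
  for (i in 1:10) {
    fs <- lapply(1:5, function(j) {
      st <- sort(sample(seq(0L, 8000L, by = 400L), 4))
      make_plain_fiber(paste0("g", j), start = 0L, end = 10000L,
                       msp = iv(st, st + sample(160:350, 4)))
    })
    sp <- patch_spacing(fs, region)
    expect_equal(sp$expected, sp$sequenced_bases / sp$n_msps_contained)
  }
  ## no contained patch: expected undefined-flagged
  empty <- patch_spacing(list(make_plain_fiber()), region)
  expect_true(is.na(empty$expected))
})

test_that("clustered patches sit closer than expected; Poisson do not", {
  med_ratio <- function(cf, seed) {
    cfg <- fixture_config(seed = seed, array_length = 60000L,
                          flank_length = 5000L, cdr_start = 10000L,
                          cdr_end = 50000L, fiber_length = 12000L,
                          n_fibers = 60L, msp_cluster_factor = cf,
                          msp_rate_core = 1.0, m6a_density_accessible = 0)
    ref <- make_reference(cfg)
    sim <- simulate_fibers(cfg, ref, region = "core")
    sp <- patch_spacing(sim$fibers, ref$cdr)
    c(median = stats::median(sp$observed) / sp$expected,
      mean = mean(sp$observed) / sp$expected)
  }
  pois <- med_ratio(1, 71)
  clus <- med_ratio(4, 71)
  expect_lt(clus[["median"]], pois[["median"]])
  expect_lt(clus[["median"]], 1)
  ## for an unclustered process the mean observed spacing matches the
  ## density-based expectation up to edge truncation
  expect_lt(abs(pois[["mean"]] - 1), 0.15)
})

test_that("the interval-span occupancy statistic counts covering footprints", {
  target <- genomic_interval("chr1", 400, 500)
  covered <- lapply(1:9, function(i)
    make_plain_fiber(paste0("c", i), nuc = iv(390L, 510L)))
  bare <- make_plain_fiber("b", nuc = iv(700L, 850L))
  expect_equal(interval_span_fraction(c(covered, list(bare)), target), 0.9)
  ## an 89% footprint does not count at the 0.9 threshold
  f89 <- make_plain_fiber("x", nuc = iv(400L, 489L))
  expect_equal(interval_span_fraction(list(f89), target), 0)
  expect_equal(interval_span_fraction(list(f89), target,
                                      min_span_fraction = 0.85), 1)
  ## permutation invariance; undefined when no fiber spans the target
  fs <- c(covered, list(bare, f89))
  expect_equal(interval_span_fraction(fs, target),
               interval_span_fraction(rev(fs), target))
  far <- genomic_interval("chr1", 5000, 6000)
  expect_true(is.na(interval_span_fraction(fs, far)))
})

test_that("planted point-centromere occupancy is recovered", {
  set.seed(23)
  p <- 0.85
  target <- genomic_interval("chr1", 450, 610)   # 160 bp element
  fibers <- lapply(1:400, function(i) {
    if (runif(1) < p) {
      make_plain_fiber(paste0("y", i), nuc = iv(440L, 620L))
    } else {
      make_plain_fiber(paste0("y", i), nuc = iv(100L, 247L))
    }
  })
  got <- interval_span_fraction(fibers, target)
  expect_lt(abs(got - p), 3 * sqrt(p * (1 - p) / 400))
})

test_that("footprint length distributions tally correctly", {
  fs <- list(make_plain_fiber("a", nuc = iv(c(0L, 200L, 500L),
                                            c(100L, 300L, 700L))))
  d <- footprint_size_distribution(fs)
  expect_equal(unname(d$quantiles[["50%"]]), 100)
  expect_equal(sum(d$counts), 3L)
  expect_equal(sort(d$lengths), c(100L, 100L, 200L))
  empty <- footprint_size_distribution(list(make_plain_fiber()))
  expect_length(empty$lengths, 0)
})
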