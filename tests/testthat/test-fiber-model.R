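test_that("fiber construction enforces span and overlap invariants", {
  expect_error(fiber("f", "chr1", 50, 40), "invalid span")
  expect_error(make_plain_fiber(m6a = 1200L), "outside aligned span")
  expect_error(make_plain_fiber(nuc = iv(c(10, 100), c(120, 200))),
               "overlapping nucleosomes")
  expect_warning(f <- make_plain_fiber(m6a = c(10L, 10L, 12L)), "duplicated")
  expect_identical(f$m6a, c(10L, 12L))
})

test_that("fiber table write/read round-trips canonical fibers", {
  set.seed(42)
  fibers <- lapply(1:5, function(i) random_fiber(paste0("f", i)))
  fibers[[1]]$cpg <- data.frame(pos = c(600L, 700L), meth = c(TRUE, FALSE))
  fibers[[1]]$msps <- iv(2100L, 2300L)
  fibers[[1]]$end <- 2600L
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fiber_table(fibers, path)
  back <- read_fiber_table(path)
  expect_equal(back, fibers, ignore_attr = TRUE)
  ## a second write of what was read is byte-identical
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_fiber_table(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("fiber table rejects malformed rows with their location", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#dichrom_fiber_table_v1",
               paste("fiber_id", "chrom", "start", "end", "m6a", "nuc_starts",
                     "nuc_lens", "msp_starts", "msp_lens", "cpg_pos",
                     "cpg_meth", sep = "\t"),
               "bad\tchr1\t0\t100\t.\t50\t-10\t.\t.\t.\t."), path)
  expect_error(read_fiber_table(path), "row 1")
  writeLines(c("#dichrom_fiber_table_v1",
               paste("fiber_id", "chrom", "start", "end", "m6a", "nuc_starts",
                     "nuc_lens", "msp_starts", "msp_lens", "cpg_pos",
                     "cpg_meth", sep = "\t"),
               "f9\tchr1\t0\t100\t250\t.\t.\t.\t.\t.\t."), path)
  expect_error(read_fiber_table(path), "f9")
  writeLines("#some_other_schema", path)
  expect_error(read_fiber_table(path), "schema")
})

test_that("naive segmentation matches a brute-force run-length scan", {
  ## forced single-gap example
  f <- make_plain_fiber(start = 0L, end = 201L, m6a = c(0L, 200L))
  seg <- segment_fiber_naive(f, min_footprint = 147L)
  expect_equal(unname(seg$nucleosomes[, "start"]), 1L)
  expect_equal(unname(seg$nucleosomes[, "end"]), 200L)
  ## saturated fiber has no gap of the required size
  f2 <- make_plain_fiber(start = 0L, end = 50L, m6a = 0:49)
  expect_equal(nrow(segment_fiber_naive(f2, 10L, 5L)$nucleosomes), 0L)
  ## refuses to overwrite existing footprints
  f3 <- make_plain_fiber(nuc = iv(10L, 200L), m6a = 500L)
  expect_error(segment_fiber_naive(f3), "refusing")
  ## random fibers against a per-bp brute-force scan
  set.seed(7)
  for (i in 1:20) {
    start <- 0L; end <- 1500L
    m6a <- sort(sample(0:1499, 40L))
    f <- make_plain_fiber(start = start, end = end, m6a = m6a)
    seg <- segment_fiber_naive(f, min_footprint = 80L, min_msp = 60L)
    ## oracle: mark m6A bp, find maximal free runs
    marked <- logical(1500); marked[m6a + 1L] <- TRUE
    r <- rle(marked)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths
    fp <- !r$values & r$lengths >= 80L
    expect_equal(unname(seg$nucleosomes[, "start"]), starts[fp])
    expect_equal(unname(seg$nucleosomes[, "end"]), ends[fp])
    ## tiling invariants: no overlap, footprint interiors m6A-free
    allv <- rbind(seg$nucleosomes, seg$msps)
    expect_false(dichrom:::iv_matrix_overlaps_self(allv))
    for (j in seq_len(nrow(seg$nucleosomes))) {
      expect_false(any(m6a >= seg$nucleosomes[j, "start"] &
                         m6a < seg$nucleosomes[j, "end"]))
    }
  }
})

test_that("density track equals per-bp brute-force count over coverage", {
  region <- genomic_interval("chr1", 0, 10)
  f <- make_plain_fiber(start = 0L, end = 10L, nuc = iv(2L, 6L))
  tr <- aggregate_density_track(list(f), "nucleosome", region)
  expect_equal(tr$density, c(0, 0, 1, 1, 1, 1, 0, 0, 0, 0))
  ## duplicating molecules leaves the normalised track unchanged
  tr2 <- aggregate_density_track(list(f, f), "nucleosome", region)
  expect_equal(tr2$density, tr$density)
  ## empty input: all-undefined, not an error
  tr0 <- aggregate_density_track(list(), "m6a", region)
  expect_true(all(is.na(tr0$density)))
  ## 50 random fibers vs brute force, all three features
  set.seed(11)
  fibers <- lapply(1:50, function(i) {
    f <- random_fiber(paste0("r", i))
    f$msps <- iv(f$start + 10L, f$start + 100L)
    f
  })
  region <- genomic_interval("chr1", 200, 1200)
  for (feat in c("m6a", "nucleosome", "msp")) {
    tr <- aggregate_density_track(fibers, feat, region)
    for (bp in seq(region$start, region$end - 1L, by = 97L)) {
      cov <- sum(vapply(fibers, function(f) f$start <= bp && f$end > bp,
                        logical(1)))
      cnt <- sum(vapply(fibers, function(f) {
        if (feat == "m6a") return(bp %in% f$m6a)
        m <- if (feat == "nucleosome") f$nucleosomes else f$msps
        any(m[, "start"] <= bp & m[, "end"] > bp)
      }, logical(1)))
      i <- bp - region$start + 1L
      expect_identical(tr$coverage[i], cov)
      expect_identical(tr$feature_count[i], cnt)
      expect_equal(tr$density[i], if (cov > 0) cnt / cov else NA_real_)
    }
    ok <- tr$coverage > 0
    expect_true(all(tr$density[ok] >= 0 & tr$density[ok] <= 1))
    expect_true(all(tr$feature_count <= tr$coverage))
  }
})

test_that("methylation aggregation equals a brute-force tally", {
  region <- genomic_interval("chr1", 0, 1000)
  mk <- function(id, pos, meth) {
    make_plain_fiber(id, cpg = data.frame(pos = pos, meth = meth))
  }
  fibers <- list(mk("a", 100L, TRUE), mk("b", 100L, TRUE), mk("c", 100L, FALSE))
  tab <- aggregate_methylation(fibers, region)
  expect_equal(tab$fraction, 2 / 3)
  expect_equal(tab$n_called, 3L)
  ## a site called on no fiber is absent
  expect_false(200L %in% tab$pos)
  ## random tally oracle
  set.seed(3)
  fibers <- lapply(1:30, function(i) {
    pos <- sort(sample(seq(0L, 999L, by = 10L), 40L))
    mk(paste0("f", i), pos, runif(40) < 0.5)
  })
  tab <- aggregate_methylation(fibers, region)
  allcalls <- do.call(rbind, lapply(fibers, function(f) f$cpg))
  for (p in sample(tab$pos, 20L)) {
    ref <- allcalls[allcalls$pos == p, ]
    expect_equal(tab$fraction[tab$pos == p], mean(ref$meth))
    expect_equal(tab$n_called[tab$pos == p], nrow(ref))
  }
})
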