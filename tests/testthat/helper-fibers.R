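# shared fixture builders: everything is generated in code at test time

make_plain_fiber <- function(id = "f1", chrom = "chr1", start = 0L, end = 1000L,
                             m6a = integer(0), nuc = NULL, msp = NULL,
                             cpg = NULL) {
  fiber(id, chrom, start, end, m6a = m6a,
        nucleosomes = if (is.null(nuc)) dichrom:::iv_matrix() else nuc,
        msps = if (is.null(msp)) dichrom:::iv_matrix() else msp,
        cpg = if (is.null(cpg)) data.frame(pos = integer(0), meth = logical(0))
        else cpg)
}

iv <- function(s, e) dichrom:::iv_matrix(s, e)

# random fiber with non-overlapping features, for oracle comparisons
random_fiber <- function(id, span = 2000L, n_m6a = 60L, n_feat = 4L,
                         chrom = "chr1") {
  start <- sample.int(500L, 1L)
  end <- start + span
  m6a <- sort(sample(seq.int(start, end - 1L), n_m6a))
  fs <- sort(sample(seq.int(start, end - 200L), n_feat))
  fs <- fs[c(TRUE, diff(fs) > 180L)]
  nuc <- iv(fs, fs + sample(100:170, length(fs), replace = TRUE))
  make_plain_fiber(id, chrom, start, end, m6a = m6a, nuc = nuc)
}

# small fixture configs keep test runtimes down; geometry is the same as
# the full-size defaults, just fewer/shorter molecules
small_core_config <- function(seed, n_fibers = 60L, fiber_length = 10000L, ...) {
  fixture_config(seed = seed, array_length = 40000L, flank_length = 5000L,
                 cdr_start = 5000L, cdr_end = 25000L,
                 fiber_length = fiber_length, n_fibers = n_fibers, ...)
}

cdr_test_config <- function(seed, ...) {
  fixture_config(seed = seed, n_fibers = 150L, m6a_density_accessible = 0, ...)
}

ref_as_stringset <- function(ref) {
  ss <- Biostrings::DNAStringSet(ref$seq)
  names(ss) <- ref$chrom
  ss
}
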