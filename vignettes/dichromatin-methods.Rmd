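---
title: "Methods: single-molecule dichromatin analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-molecule dichromatin analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dichrom)
```

## The data model

A *fiber* is one sequenced chromatin molecule carrying, in reference
coordinates (0-based, half-open intervals throughout; 1-based only at
display): its aligned span, the positions of exogenous m6A marks
(deposited by the accessibility-probing MTase on unprotected adenines),
MTase-protected footprints (nucleosomes or bound proteins),
MTase-sensitive patches (MSPs, accessible stretches), and per-site CpG
methylation calls. The package consumes these features from
modified-base BAMs (MM/ML tags, with `ns`/`nl` and `as`/`al` footprint
tags when present) or from a plain versioned TSV. Modification calling
from raw kinetics and production footprint segmentation are upstream
concerns; a naive run-length segmenter (`segment_fiber_naive()`) is
provided only as a documented fallback and uses no probability
information.

Consumption thresholds for MM/ML probabilities default to 0.8 for both
m6A and 5mCpG. CpG calls are trinary: methylated at probability ≥ 0.8,
unmethylated at ≤ 0.2, otherwise "not called" — intermediate-confidence
calls carry no information either way and would otherwise dilute
per-molecule methylation states.

Aggregate tracks divide, per bp, the number of molecules carrying the
feature by the number of molecules covering the bp; zero-coverage
positions are undefined (`NA`), deliberately distinct from an observed
density of zero.

## CDR calling

Centromere cores are hypo-CpG-methylated regions within the
alpha-satellite array. The caller merges satellite annotations closer
than 25 bp (strict), keeps merged arrays ≥ 100 kb, and computes mean CpG
methylation in 1190 bp windows stepped every 170 bp (seven step cells
per window; the step approximates the satellite monomer). Windows
strictly below the 35th percentile of the array's window means are
selected; runs of overlapping/abutting selected windows form
candidates; candidates pass when ≥ 15 kb long, below the 20th
percentile in mean of member-window means (unweighted), and not
intersecting the terminal 70 kb of the array (candidates touching the
zone are dropped, not trimmed; a 15 kb variant serves short arrays such
as chrY's). Percentiles use linear interpolation between order
statistics and are computed **per array**: each array has its own
methylation baseline, and a genome-wide reference set would let a
globally hypermethylated array mask dips elsewhere.

Two numerical choices deserve emphasis:

* *Strict "below" with an epsilon guard.* Window means are compared to
  the percentile value strictly; a relative epsilon (1e-9) keeps float
  accumulation from splitting exactly-tied means, so a constant
  methylation profile yields zero calls rather than arbitrary ones.
* *Half-depth boundary localisation.* A percentile threshold by
  construction selects a fraction of ordinary background windows (35%
  minus the dip's share), so the raw union of selected windows both
  bleeds by up to a window width at each dip edge and chains nearby
  background windows onto the candidate — kb-scale boundary error. The
  candidate interval is therefore localised at half depth: with the
  array's median window mean as the background reference and the
  candidate's deepest window as its core level, the call runs from the
  central step cell of the first member window below the midpoint of
  the two to that of the last. This is the full-width-at-half-maximum
  convention of peak calling, is invariant under adding a constant to
  all methylation fractions (both reference levels shift equally), and
  places boundaries at step (170 bp) resolution. Candidates with no
  member window below half depth — shallow background chains — keep
  their union trimmed by `window_size - step` per side and are in
  practice removed by the length and percentile filters.

All three filter outcomes are recorded per candidate in an audit table,
so rejected candidates remain inspectable. An externally supplied core
BED (the CENP-A CUT&RUN route, for samples where hypomethylation cannot
be assumed) bypasses calling entirely.

## Dichromatin metrics

Footprints are di-nucleosome-sized when strictly longer than 210 bp;
MSPs are "large" (accessible chromatin patches) when strictly longer
than 150 bp; both cutoffs are strict on the stated values and
per-fiber percentages flag empty denominators as undefined. For
regional summaries a fiber belongs to the region holding ≥ 50% of its
span, and features count only when fully contained in it.

Patch spacing compares, within a region (typically a CDR call), the
observed start-to-start distances between consecutive large MSPs on the
same molecule (both fully contained) against the density-based
expectation: patches per sequenced bp, times the region length, divided
into the region length — algebraically `sequenced_bases /
n_contained`. The mean observed spacing telescopes to the expectation
for any stationary placement process (up to edge truncation by finite
molecules), whereas the *median* falls below it when patches cluster
within molecules; the package reports the observed distribution so
either summary can be taken.

The point-centromere occupancy statistic is the fraction of molecules
fully spanning a target element that carry a single footprint covering
at least 90% of it. The 0.9 coverage fraction operationalises "well
positioned"; it is a package convention exposed as a parameter, not a
value inherited from any reference analysis.

## Chromatin repeat spectra

Each fiber's m6A pattern becomes a per-bp 0/1 vector; its periodogram
is the standard one-sided estimate at unit sampling: density
`|DFT_k|^2 / n` (doubled except at the Nyquist bin), rectangular
window, no detrending by default. Removing the vector mean would alter
only the zero-frequency bin, far outside the 120–300 bp analysis band;
a `detrend = "mean"` option exists for symmetry with common practice.
Fibers shorter than twice the maximum period or with fewer than 10
events are skipped with a logged reason — their spectra are degenerate.

Raw DFT frequencies depend on fiber length, so per-fiber spectra are
linearly interpolated onto a common 1 bp repeat-length grid over the
band and combined as the per-gridpoint **median** across fibers, which
is robust to individual molecules with strong line components. Peaks
report the largest local maxima, ties broken toward the shorter repeat
length. The 120–300 bp band covers every repeat scale of interest
(~147 bp nucleosome cores through di-nucleosome-scale spacings) while
excluding the DC ramp and the first harmonic of the satellite monomer.

Because the periodogram magnitude is phase-blind, the estimator
recovers a planted spacing whether or not molecules share a common
phase — the property that lets a repeat length be measured on arrays
that lack satellite phasing altogether.

## CENP-B footprint scoring

Boxes are found by exact IUPAC matching of the 17 bp consensus
`NTTCGNNNNANNCGGGN` on both strands, keeping matches whose 17-mer
contains exactly two CG dinucleotides (an optional mismatch budget
covers degenerate boxes; for exact-consensus synthetic sequence, exact
matching is the deterministic equivalent of a motif-scanner run). The
box *center* is the 9th motif base — the middle of the 17-mer, hence
the same reference position on either strand; the printed asymmetric
scoring windows are a convention of the analysis, and all offsets are
taken in motif orientation (minus-strand profiles are flipped).

Per (site, molecule) observation: the m6A window over center ± 50 bp
and the molecule's box state — the number of methylated calls among the
box's two CpGs when both are called, else missing and excluded from
strata. Stratum profiles are the per-offset mean across observations
smoothed by a 10 bp rolling average (window [−5, +4], truncated at the
profile ends). The footprint score divides the mean smoothed m6A over
the flanks (−35..−27 and +22..+27, inclusive) by the box core (−7..+1)
plus a 1e-3 pseudocount, so fully protected cores score finite; a flat
profile scores 1 within pseudocount tolerance. Score distributions
come from 1000 subsamples of 10% of observations drawn **without
replacement** (each observation enters a subsample at most once), seeded
and bit-reproducible.

Nucleosome positioning around boxes records, per observation, the
center-facing boundary of the nearest strictly upstream footprint and
the start of the nearest strictly downstream footprint within ±500 bp;
footprints covering the center itself (the occupied-box footprint) are
not edges. Offsets are tallied as percentages per mCpG stratum.

## The synthetic generator

The generator emulates the data-generating process the operators
target, with every parameter exposed in `fixture_config()`:

* a 170 bp monomer (redrawn until it carries ≥ 4 CpGs and no spurious
  box match) tandem-repeated to a 300 kb array inside 20 kb
  non-satellite flanks; an exact-consensus CENP-B box every second
  monomer, degenerate positions filled from A/T so each instance keeps
  exactly its two consensus CpGs;
* a planted 20 kb core at array offsets 140–160 kb with per-CpG
  methylation 0.05 inside versus 0.85 outside, and a per-call dropout
  of 0.05 modelling uncalled sites;
* nucleosomes of 147 bp phased one per monomer inside the core — with
  probability 1/3 an adjacent pair is replaced by one 211–300 bp
  di-nucleosome-sized footprint — and unphased arrays at 190 bp
  start-to-start spacing (random per-molecule phase) elsewhere;
* box occupancy drawn per molecule from the *true* methylation state of
  the box CpGs with probabilities 0.8 / 0.1 / 0.05 for states 0/1/2 —
  the direction of methylation-abrogated binding; occupancy rates are
  not quantified by any reference, so these encode direction and
  contrast, not measured values;
* around each in-core box, an accessible clearance from −38 to +32
  around the center (the phased nucleosome is pushed back), and a 44 bp
  protected footprint centered on occupied boxes. The clearance and
  footprint geometry is chosen so that the scoring windows mean what
  they should: the flank windows (−35..−27, +22..+27) fall in
  accessible linker DNA and the core window (−7..+1) inside the
  protectable footprint. A wider (e.g. 60 bp) centered footprint would
  cover the +22..+27 flank window and a box buried in a 23 bp linker
  would put −35..−27 under the phased nucleosome, making the score
  insensitive or inverted by construction; both values are
  config-exposed;
* large MSPs of 150–800 bp placed as a point process at 0.2/kb in the
  core and 0.05/kb in the flanks, with a per-molecule Gamma rate
  multiplier of mean 1 and variance `msp_cluster_factor - 1` — the
  simplest overdispersed model of within-fiber clustering (factor 1 is
  Poisson); footprints are carved around patches;
* finally m6A stencils every accessible A/T base at probability 0.4;
  footprinted bases never carry m6A.

All draws derive from one master seed through counter-based child
seeds, so the reference and the fiber sets can be regenerated
independently and byte-identically. Truth files record the planted CDR,
per-box per-molecule states and occupancy, and the planted spacings.

What the generator does *not* model — sequencing error beyond CpG
dropout, satellite higher-order-repeat phylogeny, kinetics-level
modification uncertainty, mappability — bounds what green tests mean:
they validate the operators against a faithful but idealised process,
not the full noise structure of real fibers.

## Problem sizes and test design

The test suite regenerates every fixture in code. Study sizes were
fixed once: spectral recovery uses the full default fixture (300
fibers × 15 kb); CDR recovery uses 150 fibers per seed (about 7.5×
coverage of the 300 kb array) across 20 seeds for both the 20 kb
(recovered, boundary error ≤ 170 bp) and 10 kb (rejected by the length
filter) plantings; the footprint-score discrimination study uses boxes
on every monomer and 120 molecules per seed so each mCpG stratum holds
enough observations to resolve the 0.10 versus 0.05 occupancy contrast
over the stencil noise; spacing comparisons use a 1/kb patch rate so
edge truncation stays small relative to the signal. Periodogram
correctness is pinned to an independent O(n²) DFT oracle at 1e-9
relative tolerance; the motif scanner to a regular-expression oracle on
random sequence, both strands.

## Known limitations

* CDR calling assumes a unimodal background methylation level per
  array; arrays with genuinely bimodal backgrounds would shift the
  half-depth reference.
* The expected-spacing statistic inherits finite-molecule censoring:
  gaps longer than a molecule are unobservable, so even unclustered
  data show mean observed/expected slightly below 1 at low patch
  densities.
* Exact IUPAC box matching (default mismatch budget 0) will miss
  diverged boxes that a position-weight-matrix scanner with a
  significance threshold would recover; raise `max_mismatches` for
  divergent arrays, at the cost of the 2-CpG filter doing more work.
* The naive fallback segmenter thresholds run lengths only and should
  not be used where a probability-aware segmenter's output is
  available.
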