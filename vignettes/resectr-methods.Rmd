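---
title: "Measuring DSB resection, re-synthesis and gene conversion from population sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring DSB resection, re-synthesis and gene conversion from population sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resectr)
```

## The assay

A site-specific DNA double-strand break (DSB) is induced by the HO
endonuclease at a *MAT*a-like locus on a recipient chromosome. Repair by
homologous recombination uses a polymorphic *MAT*a′-like donor cassette
inserted on another chromosome: two homology arms flanking an
uncleavable HO-inc site, carrying 23 single-nucleotide polymorphisms
(three of which create EcoRI sites on the donor). Because the silent
donor loci normally used for mating-type switching are deleted, every
repair event is inter-chromosomal gene conversion (GC) templated by this
cassette.

The population of cells is sampled over a time course and sequenced with
75-bp paired-end reads after tagmentation. Tagmentation only
incorporates double-stranded fragments, so 5′→3′ end resection — which
converts duplex DNA into 3′-tailed ssDNA around the break — depletes
sequencing coverage, and repair synthesis restores it. Coverage along
the recipient chromosome therefore *is* the readout: its decay maps
resection, its recovery maps re-synthesis, and reads carrying donor
alleles map conversion tracts.

`resectr` implements the full analysis — alignment under a 0-mismatch
contract, coverage normalization, resection and re-synthesis estimators,
per-polymorphism conversion fractions, and discordant-read-pair tract
mapping — together with a synthetic reference genome and a population
simulator, so that every estimator can be validated against known ground
truth without any external data.

## The synthetic reference

`build_reference()` generates a three-chromosome genome:

* **chrIII** (recipient, 120 kb): background sequence with the homology
  cassette centered at the HO cut coordinate (default 60,000), and EcoRI
  sites planted 2.5 kb left and 4.3 kb right of the cut so that the
  uncut homology fragment is 6.8 kb and the HO-cut left product 2.5 kb —
  the fragment sizes a Southern blot of this strain shows. A
  resection-blocking element (a Ty1-LTR analogue) is annotated 32 kb
  left of the cut; its effect is applied in the simulator.
* **chrV** (donor, 340 kb): the same cassette with donor alleles and the
  HO-inc point substitution, inserted at 100 kb; a 120-kb control region
  at coordinates 210,000–330,000 (the default of `analysis_config()`)
  lies well away from it.
* **chrVIII** (background, 40 kb): a chromosome uninvolved in repair,
  used to measure the background rate of spurious inter-chromosomal read
  pairs.

The donor insert is 1,300 nt: two 638-nt arms around a 24-nt HO core.
The printed strain description ("two 0.7 kb regions", "1.3 kb
fragment") cannot both be exact, so the 1.3-kb total is taken as the
constraint and the arm length is configurable. Polymorphisms sit every
55 nt starting 25 nt from the cut (12 left, 11 right) — 55 nt is the
largest spacing at which 12 sites fit a 638-nt arm, and is within the
"approximately 60 nt" the strain design quotes. Crucially the spacing
is below the read length, so *every* 75-mer in the arm interior
overlaps at least one polymorphic site; reads without a site are
ambiguous between the two loci and are discarded by the mapper, while
reads with a site are locus-specific.

Background sequence is i.i.d. uniform over {A,C,G,T}, and every
spurious EcoRI motif is scrubbed (one base mutated) so that in-silico
digests see exactly the designed sites. `in_silico_digest()` partitions
each chromosome at the annotated sites plus arbitrary extra cuts (e.g.
the HO break), and is property-tested for conservation: fragment
lengths always sum to the chromosome length.

All coordinates are 0-based half-open internally; files (SAM, BedGraph)
use the 1-based/0-based conventions of their formats.

## The population model

`simulate_population()` describes each cell by latent variables drawn
once per seed (so the state at any time is a deterministic function of
seed and time, and adding timepoints never perturbs earlier ones):

* cut with probability `cut_efficiency` (default 0.95) shortly after
  induction;
* per-side resection velocities drawn from a gamma distribution (mean
  5,000 nt/h, shape 8 by default; `velocity_shape = Inf` makes them
  deterministic). The gamma-across-cells model produces the smooth
  sigmoid coverage decay seen in real profiles with two parameters.
  Left-side resection halts at the blocking element;
* a repairing subpopulation (`repair_fraction`, default 0.8) with
  gamma-distributed repair times (mean 6 h); on repair, resection stops
  (`resection_stop_on_repair = TRUE`, the wild-type-like mode) and
  duplex DNA is restored from the break outward at
  `resynthesis_velocity` (default 2,000 nt/h). Setting
  `resection_stop_on_repair = FALSE` with a small repair fraction
  emulates a resection-inhibition mutant that keeps resecting to the
  block and the chromosome end;
* a conversion tract `[-L, +R]` around the cut with geometric tails
  beyond the HO core (means 600 nt left, 100 nt right, matching the
  asymmetry of observed tract-length scales), always covering the core
  so every repaired cell incorporates the uncleavable donor site.
  `gc_tract_fixed = TRUE` freezes the tract at its means — used by the
  validation suites, where a known boundary is needed.

The in-vivo per-cell velocity distribution is not measurable directly;
the defaults are chosen so that the half-coverage front reaches ~20 kb
by 4 h, the scale real profiles show, and are documented here as
package choices, not literature values.

`emit_read_pairs()` samples a uniformly chosen anchor base from the
union of all cells' double-stranded intervals, extends a
truncated-normal insert (mean 300, sd 50) in a random direction, and
truncates at the duplex edge — a tagmentation fragment cannot span an
ssDNA junction, so coverage tapers within one insert length of the
resection front. Mates are the forward start and reverse-complemented
end of the fragment. Fragments from repaired cells substitute donor
alleles at every polymorphic position inside the cell's tract. No
sequencing errors are modelled: under a 0-mismatch alignment contract an
error can only discard a read, so error modelling would only rescale
depth.

Two analytic oracles accompany the simulator. The expected
T0-normalized coverage at a position equals the fraction of cells in
which that position is duplex (`expected_relative_coverage()`), and a
qPCR amplicon contributes per cell 1 (duplex), 0.5 (single-stranded —
one template strand left), or 0 (degraded), so a fully resected,
non-degraded amplicon reads 50% of the undamaged control
(`simulate_qpcr_signal()`).

### What the simulator does not model

Checkpoint signalling, protein dynamics, D-loop intermediates,
break-induced replication and single-strand annealing, chromatin,
replication, sequencing errors and base-quality structure, GC-content
bias, and mappability structure beyond the two homologous loci. Tests
passing on these simulations therefore validate the *estimators* under
the stated generative model; they do not certify performance on real
libraries, where mappability and coverage biases add structure the T0
normalization only partly removes.

## Mapping

`build_index()` stores every read-length substring of both strands in a
keyed table; `map_reads()` reports a read as mapped iff it matches the
reference exactly, with its number of perfect-match loci (`n_hits`).
This reproduces an end-to-end, 0-mismatch, report-one-alignment
contract, with one deliberate divergence: multi-hit reads are *dropped*
rather than assigned one arbitrary locus, because dropping is
deterministic; on this genome the only ambiguous reads are arm reads
carrying no polymorphism, which are uninformative either way. A pair is
*discordant* iff both mates map uniquely to different chromosomes — the
filter used for GC analysis; concordant pairs must lie on one
chromosome, opposite strands, within the insert bounds. Reads whose
length differs from the index k and reads containing non-ACGT symbols
are counted but never mapped.

## Coverage normalization

The normalization chain follows the sequencing-analysis protocol of the
assay:

1. **RPGC scaling** (`rpgc_scale()`): per-base counts divided by the
   genome-wide mean, so the mean becomes 1.
2. **T0 masking** (`t0_mask()`): positions whose scaled coverage in the
   undamaged sample falls below 0.2 are excluded from every sample —
   they reflect low intrinsic mappability (here: the polymorphism-free
   arm positions), not resection. The threshold is applied per base;
   whether it should apply per base or per bin is not fixed by the
   protocol, so it is configurable.
3. **Ratio profiles** (`ratio_profile()`): per-position ratio against
   T0, averaged in 100-nt bins anchored at coordinate 0. The ratio is
   computed per position and then binned (not binned first) because the
   mask is per-position; the difference is second order. The bin
   containing the cut is split at the cut, so position 0 belongs to
   neither side. Division by zero cannot occur after masking.
4. **Control-region correction**: when a control region is supplied,
   every ratio is divided by the control-region ratio of the same
   sample pair. RPGC forces the genome mean to 1 even when part of the
   genome is single-stranded, which inflates every intact position; the
   control region on the uninvolved part of the donor chromosome
   measures exactly that inflation. The section profiles
   (`section_normalize()`) apply the same correction by definition —
   `C_N = (C_sec_Tx / C_sec_T0) / (C_ctrl_Tx / C_ctrl_T0)` over 2-kb
   sections — and this package extends it to the binned ratio profiles
   feeding the estimators, since parameter recovery on simulations
   fails measurably without it (apparent recovery factors of 1.4–1.6
   instead of 1.0 when much of the recipient is resected).
   `colormap_matrix()` stacks section profiles into the time-by-section
   matrix behind the colormap charts; rendering is out of scope.

## Resection and re-synthesis estimators

* **Short-range resection** (`short_range_resection()`): mean coverage
  decline over ±100 nt at 1 h, per side, plus the left/right asymmetry.
* **Half-coverage front** (`distance_at_level()`): scanning outward,
  the linearly interpolated distance of the outermost upward crossing
  of 0.5 — the last point below the level before the profile stays at
  or above it. Counting noise creates spurious crossings, so a 3-bin
  running median is applied first (width configurable, 1 disables);
  ties break toward the break (the conservative, shorter distance).
  Whether the innermost or outermost crossing is "the" front under
  noise is a genuine choice; outermost-after-smoothing tracks the
  deepest cell population and is the default. If the profile never
  rises above the level the estimate is censored at the blocking
  element or chromosome end, and censored values are excluded (not
  imputed) downstream.
* **Long-range rate** (`long_range_rate()`): least-squares slope of the
  front distance against time over 1–4 h (`v = Δs/Δt`; exactly the
  difference quotient for two points). Recovery of configured
  velocities of 1, 2 and 4 kb/h is within 10% at 30× depth (acceptance
  suite).
* **Maximum extent** (`max_resection_extent()`): outward scan for the
  first distance at which binned coverage reaches 0.9 × the recipient
  chromosome mean *of the same sample*. The chromosome mean is computed
  over unmasked positions after RPGC scaling and before T0 division —
  so the effective cutoff decreases for ssDNA-rich samples, as the
  protocol notes.
* **Re-synthesis** (`coverage_time_series()`, `synthesis_rate()`,
  `initiation_rate()`): the T0-normalized coverage at fixed distances
  of 0.5 and 15 kb per side is followed over time; a least-squares
  trend line `y = mx + b` over the post-resection window (4 h to the
  end of the course) gives the synthesis rate S = m, and the initiation
  rate is `v = Δs/Δt` with Δs fixed at 0.5 (kb) and
  `Δt = (0.5 − b)/m − (0 − b)/m = 0.5/m` — numerically equal to m.
  Non-positive slopes are flagged undefined rather than extrapolated.

## Gene conversion from site coverage

For each polymorphic site, coverage is averaged over the 75-nt window
centered on the site (any overlapping 0-mismatch read is
allele-informative) at the donor and recipient coordinates, each
normalized to its own T0 and control-corrected. Two statistics are
reported: the donor share `d/(d+r)` (0.5 at baseline), and the donor
excess `d − 1` (0 at baseline). The corrected conversion estimate
divides the donor excess by the repair-fraction correction factor — the
maximum over the post-induction time course of the 0.5-kb coverage
recovery, per side (left sites use the left recovery; a pooled factor
is available). In expectation the donor excess equals the probability
that a cell is repaired *and* its tract covers the site, and the factor
equals the repaired fraction, so the corrected estimate recovers the
tract-overlap probability among repaired cells — invariantly across
repair fractions of 0.25–1.0 in the validation suite.

Two structural limitations, shared with the underlying method, are
worth stating. First, the factor is only unbiased when the 0.5-kb probe
lies beyond the conversion tract; cells whose tract covers the probe
emit donor-allele reads there, depressing recipient-side recovery (with
600-nt left tracts the left factor collapses). Second, sites within one
read length of a tract boundary lose coverage to chimeric reads that
span sites of both genotypes and therefore map nowhere; recovery is
exact only for sites deeper inside the tract.

## Discordant read pairs

A read pair from a repaired cell whose fragment straddles a tract
boundary has one mate carrying donor alleles (mapping to the donor
locus) and one carrying recipient alleles (mapping to the recipient):
an inter-chromosomal discordant pair marking that boundary to within an
insert length. `extract_discordant()` keeps unique×unique
inter-chromosomal pairs; recipient×donor pairs are the signal,
recipient×background-chromosome pairs estimate the false-positive rate
(exactly zero in error-free simulations — the zero-background
acceptance check).

Each pair is summarised by the leftmost aligned base of each mate (the
scatter-plot convention; a midpoint convention is available). The
recipient axis divides at the HO cut, the donor axis at HO-inc;
`classify_quadrant()` assigns LB/RB/LT/RT with on-axis pairs going
right/top. Bottom quadrants are boundaries of left-side conversion
events, top quadrants right-side events.

`discordant_coverage()` accumulates the recipient mates and the donor
mates (translated into the break-centered frame via the homology-arm
correspondence `donor_pos − ho_inc + ho`) into two per-base tracks;
where the two peaks intersect — the sign change of their difference,
linearly interpolated after a 51-nt running mean — is a tract boundary
estimate (`boundary_estimate()`). On fixed tracts of (−200, +100),
(−600, +100) and (−600, +600) at 50× depth the boundary error is under
one read length (acceptance suite). `classify_regions()` buckets each
pair's boundary position (midpoint between the mates' inner edges) into
distance bands; the bands have no algorithmic definition in the
underlying method (they are drawn on the figure), so the defaults
derived from the two strongest peak intersections per side
(`default_regions()`) are an interpretation and fully overridable.

## The pipeline

`run_pipeline(run_config(...))` sequences all stages — reference,
simulation per timepoint, mapping, normalization, and the four reports
— deterministically from one seed, writing FASTA/FASTQ/SAM/BedGraph/TSV
artifacts and a JSON summary with per-stage read counts (so discordant
fractions have auditable denominators). `ingest_external()` re-enters
the pipeline at the coverage stage from user-supplied SAM files plus a
reference and site annotation, rejecting (and counting) reads of the
wrong length. Sub-analyses whose time course is too sparse (fewer than
two points in their window) are skipped rather than fabricated.

## Problem sizes and numerical choices

The default genome keeps full-scale coordinates (120/340/40-kb
chromosomes) so the canonical control region at 210,000–330,000 exists;
a full 11-timepoint, 30×, 2,000-cell run completes in a few minutes on
one CPU. The test and validation suites use a proportionally reduced
genome (60/60/20-kb chromosomes, 30-kb control region) and depths of
10–50×, with statistical tolerances stated in standard errors of the
quantity under test: Poisson bounds for per-bin coverage ratios, 3 SE
for recovery of means, a 10% relative band for rate recovery, one read
length for boundary recovery. Crossing detection interpolates linearly
between bin centers; running-median widths, the T0 threshold, all bin
and section sizes, and every distance constant are surfaced in
`analysis_config()` with the assay's canonical values as defaults.
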