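---
title: "Models and methods behind beditscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind beditscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beditscan)
```

# Overview

`beditscan` covers the computational chain of a reporter-coupled CRISPRi
screen for cytosine base-editing outcomes: simulating editing amplicons
and sorted-population sgRNA counts with known ground truth, calling
editing outcomes at allele level from amplicon reads, testing gene-level
enrichment with α-robust-rank-aggregation (α-RRA), and computing the
statistics used in arrayed validation. This vignette explains the models,
the tunable parameters, and the design choices, in that order.

# Coordinates and site geometry

A `target_site` fixes the geometry everything else relies on. Protospacer
positions are 1-based from the PAM-distal 5′ end (so "C10" is the tenth
protospacer base) with the PAM 3′ of the protospacer; this is the
convention used for editing-window positions throughout the field. The
site records which protospacer positions carry target cytosines, the
strand of the protospacer on the amplicon, and the nick position. The
default `nick_offset = 17` places the nick between protospacer positions
17 and 18 — 3 bp 5′ of the PAM on the sgRNA-complementary strand, the
canonical Cas9n HNH cut.

The quantification window is centred on the nick with halfwidth 10 *in
protospacer coordinates* and must lie inside the amplicon. A window
defined in amplicon offsets would drift with primer placement; defining
it in protospacer coordinates keeps analyses of different amplicons
comparable at the cost of not reproducing any particular external tool's
offset convention bit-for-bit.

The built-in `default_sites()` are deterministic synthetic constructs
with the geometries used throughout the package (a single-target-C
reporter-like site, a HEK3-like site with targets at C10/C16, an
RNF2-like site at C10/C14 on the reverse strand). They are stand-ins:
the real reporter and endogenous amplicon sequences are not bundled, and
real loci can be supplied through `target_site()` or a site file.

# The read simulator

`simulate_reads()` draws a multinomial sample of outcome categories,
applies each category's substitutions at the target cytosines, plants
indels (deletions of 1–10 nt or insertions of 1–3 nt overlapping the
window, lengths sampled uniformly) for the `indel` category, and then
applies uniform per-base substitution errors. Reads span the full
amplicon and qualities are constant Q30: single merged amplicon reads
with no quality model, because the caller applies no quality filter by
default.

Defaults mirror the screen conditions the package emulates: the NC-like
mixture used in examples is 15.6% single C→T and 6.6% single C→G (the
non-targeting-control means of a C→T reporter), sequencing error 0.1%
per base, and 50,000 reads where recovery is being tested. What the
simulator does *not* model — PCR amplification bias, paired-end overlap,
position-dependent error profiles, UMI structure — bounds what passing
recovery tests show about real data: they validate the classification
and aggregation arithmetic, not robustness to amplification artifacts.

# The screen simulator

`simulate_screen()` uses composition reweighting rather than per-cell
simulation: per sgRNA *s* of gene *g*, a lognormal library weight
*w\_s* (sdlog 0.5 by default, a typical cloning skew), a conversion
probability π\_s = min(1, π₀·effect\[g\]), bulk count means proportional
to *w\_s* (times a day-13 depletion factor, default 0.3, for essential
genes), and sorted means proportional to *w\_s·π\_s* renormalised to the
same total depth. Counts are negative-binomial with configurable
dispersion (default 0.1, in the range typical of pooled screens;
Poisson in the dispersion→0 limit). The baseline sorted fraction
defaults to π₀ = 0.132, matching the observed GFP⁺ fraction of a C→T
screen; depth defaults to 200× per sgRNA, the sequencing floor of such
screens; two replicates per arm. The truth table records each sgRNA's
expected sorted-vs-bulk LFC, log2(π\_s/π̄) with π̄ the library-weighted
mean conversion probability, which is what the enrichment stage should
recover.

This count-level model matches the statistics the enrichment stage
consumes but does not model MOI, infection stochasticity, or sorting
purity; detection-rate results are therefore statements about the
analysis chain, not about FACS physics.

# Outcome calling

`align_read()` performs global (Needleman–Wunsch) alignment with affine
gaps: match +2, mismatch −3, and a length-L gap costing 10 + L. These
weights make a single mismatch cheap relative to opening a gap, which is
appropriate for amplicon reads where most deviations are substitutions
or short planted indels. Reads scoring below 0.6 of the perfect score
are unalignable and excluded (and tallied). Ambiguous bases score as
mismatches.

`classify_read()` applies the taxonomy with indel precedence: any
internal gap overlapping the window makes the read `indel`, matching the
mutually exclusive category lists of tract plots; otherwise the
base calls at the target cytosines (read on the protospacer strand,
reverse-complemented for reverse-strand sites) define `WT` or a joint
category such as `T10`, `T10/T16`, `T10/G14`. Reads whose only window
substitutions sit at non-target positions are flagged `other-edit`:
they are counted in read totals but excluded from the taxonomy, since a
mixture of sequencing error and incidental variation at non-target
positions would otherwise contaminate every category. Terminal gaps
across the window mean the window was not sequenced; such reads are
dropped rather than called indel. The batch path used by
`call_outcomes()` classifies full-length, few-mismatch reads by direct
byte comparison — provably equivalent to alignment under the scoring
above, since two gaps cost more than four mismatches — and sends
everything else through the aligner; tests assert the two paths agree
read-for-read.

`aggregate_outcomes()` reports absolute efficiencies as percent of
classified reads (the mutually exclusive categories plus WT sum to 100)
and relative efficiencies as percent of edited (non-WT) reads. Indel
reads count toward the edited denominator by default
(`include_indel_in_edited = FALSE` to exclude them); with zero edited
reads the relative table is absent, not zero. Per-position C→T/C→G/C→A
marginals sum every joint category containing that conversion.

# Screen enrichment

`median_normalize()` is the median-of-ratios: size factor per sample is
the median over sgRNAs (with positive geometric mean) of
count/geometric-mean. A second application applies no further
*differential* correction — its size factors are a single constant, the
geometric mean of the first pass — which is the meaningful form of
idempotence for a relative normalization.

`sgrna_stats()` computes LFCs on normalized counts with pseudocount 0.5
averaged over paired replicates, and two-sided p-values from a pooled
negative-binomial model. The dispersion is a single method-of-moments
estimate from the non-targeting sgRNAs' within-condition replicate
variability (a pooled ratio `sum(v − μ)/sum(μ²)`, which avoids the
small-replicate bias of a per-sgRNA median), falling back to all sgRNAs
below 10 non-targeting guides. The two-sided tail uses the
equal-distance convention around the null mean, so a treatment identical
to its control gives p = 1 exactly. By default the null variance also
carries the sampling noise of the control mean
(`propagate_control_noise = TRUE`); without that propagation a
conditional test of random-vs-random arms is anti-conservative and its
null p-values are visibly non-uniform. With propagation off, the
dispersion→0 limit is the textbook Poisson tail, which is how the test
is verified against a closed form. This is deliberately a simplified
pooled-dispersion test, not a fitted mean–variance regression.

`alpha_rra()` is the gene-level score: percentile ranks in (0, 1] with
average ranks for ties (deterministic and permutation-safe), an α-screen
admitting only sgRNAs in the top α fraction (default 0.25), and
ρ = min over the passing prefix of Beta(j, k−j+1) order-statistic tails.
Genes with no passing sgRNA get ρ = 1. The permutation null reassigns
the observed percentiles to gene-sized groups, stratified by gene size,
with p = (1 + #{ρ\_perm ≤ ρ\_obs})/(1 + n\_perm); drawing from the
sorted percentile vector makes results invariant to sgRNA row order.
Depletion and enrichment are separate one-sided analyses (ranks
ascending vs descending); the default contrast is sorted vs day-13 bulk,
with the day-0 comparison available by role. The α-screen leaves a
*conservative* point mass at p = 1 (under a global null, a fraction
(1−α)^k of genes has no sgRNA in the top α); null p-values are therefore
uniform conditionally on passing the screen and sub-uniform overall,
which is what the calibration tests assert. α and the permutation count
are exposed as arguments since conventions vary between tools.

`rra_screen()` is the package's fitting function, tying normalization,
sgRNA statistics, gene phenotypes (median sgRNA LFC; even counts use the
central-pair mean) and both RRA directions into a classed object with
`print`/`summary`/`plot`/`coef` methods. The single reported FDR column
adjusts the doubled smaller one-sided p, a conservative two-sided
combination; both one-sided p-values are always reported alongside.
`screen_qc()` reports essential-gene dropout (median day-13-vs-day-0
LFC, essential vs non-targeting) and the replicate Pearson correlation,
flagging r < 0.7.

# Validation statistics

z-scores use z = (x − μ)/σ against the non-targeting-control
distribution, with |z| > 3 flagged as a strong effect. The SD convention
defaults to the sample SD (n−1); the population SD is a flag, and the
printed-precision worked examples are insensitive to the choice. The
adjusted z-score over replicates is |mean(z)| − σ(z), a conservative
consistency-rewarding measure that never exceeds |mean(z)| and equals it
only when replicates agree exactly. Tier thresholds at 1.5/2/3 are
half-open upward (exactly 2 is `**`, exactly 3 is `***`): the source
convention leaves the boundaries undefined, and assigning them upward is
the monotone choice. Fold changes are ratios of means, reported as the
larger-over-smaller ratio rounded half-up to one decimal with a separate
direction — the convention that reproduces every printed knockdown fold
at one decimal. ΔΔCt relative expression is 2^(−ΔΔCt); a negative
expression level being impossible, the occasionally printed "−2^ΔΔCt"
form is read as a typesetting artifact. Pooled NC replicates (all
sgRNA × replicate values) form the default control distribution.

# Numerical choices and degenerate inputs

Frequencies must sum to 1 within 1e−9; zero negative-control SD is an
error instructing more replicates; a single replicate falls back to |z|
with a warning; zero edited reads make relative quantities absent rather
than zero; all-zero sgRNA rows are dropped with a logged count, and
sgRNAs with a zero in any compared sample are removed before testing.
Every stochastic operation runs under a named seed through an internal
RNG-scoping helper, so identical configurations are byte-identical,
including FASTQ and manifest digests in `run_pipeline()`.

# Problem sizes used in tests

The suites validate at desk scale, chosen to make sampling tolerances
meaningful: 50,000 reads for recovery (3 binomial SE bounds), 500
planted-mutation reads against a brute-force affine-gap DP oracle, a
200-gene null screen with 2,000 permutations for calibration, and 20
seeded runs for spiked-gene recovery (effect 0.25 at π₀ = 0.132,
detection required in ≥ 90%). Real screens are one to two orders of
magnitude larger in sgRNA count; all algorithms are linear or
n·log n in the number of reads or sgRNAs.

# Known limitations

Single-read amplicons only (no paired-end merging); no base-quality
modelling or filtering; the NB test is pooled-dispersion, not
mean–variance regressed; no copy-number correction; the real screens'
hit lists depend on deposited sequencing data and are outside what
synthetic validation can reproduce — the package validates the machinery
that would analyse them.
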