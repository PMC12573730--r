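---
title: "Inversions, gene flow and 3D genome structure: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inversions, gene flow and 3D genome structure: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invtad)
```

# What the pipeline computes

`invtad` connects two questions about a pair of diverging, hybridising
species: whether chromosomal inversions behave as barriers to gene
flow, and whether inversion breakpoints preferentially occur at
3D-genome boundaries (TAD and A/B-compartment boundaries). This
vignette documents the models, the tunable parameters, the numerical
choices, and what the synthetic-data generator does and does not
emulate. It states no empirical result beyond what the package's test
suite and acceptance script themselves compute.

# Coordinate frame and genome partition

All internal coordinates are 0-based half-open; VCF (1-based) and BED
(0-based) are converted at the I/O boundary. One internal convention
avoids off-by-one drift between the popgen and Hi-C halves of the
pipeline.

The structural-variant VCF from a whole-genome aligner is parsed by ID:
`INV<n>` records become inversions (span from POS to INFO/END, query
coordinates from ChrB/StartB/EndB when present), `SYNAL<n>` records
become colinear blocks. The genome partition gives inverted bases
priority over colinear ones — aligners can emit syntenic blocks that
overlap inversions, and classification must be per-base even though
breakpoints stay per-event. Bases in neither class are unassigned and
contribute to no statistic. Sex chromosomes are excluded via
`genome_layout(..., excluded_chromosomes=)`; hardmasked intervals are
excluded from null models through the `allowed` set.

"Larger than 25 kbp" for the headline inversion set is read strictly
(`length > 25000`); `filter_inversions(strict = FALSE)` includes ties,
since a tie sitting exactly at the bin size is a defensible borderline
case.

# Windowed differentiation and divergence

Statistics are computed in fixed 25-kbp windows; a window containing
both inverted and colinear bases is evaluated once per class over its
class-restricted sites. The definition thresholds — 25 genotyped SNPs
for F_ST, 2500 genotyped sites for d_xy — apply to each class-restricted
cell separately. This is the conservative reading of computing the
statistics "separately" for mixed windows: a mixed window must earn
each class's estimate on that class's own data.

F_ST is the two-population Weir–Cockerham (1984) estimator: per-SNP
variance components a (among populations), b (among individuals within
populations) and c (within individuals) computed from sample sizes,
allele frequencies and observed heterozygosity, combined as
Σa / Σ(a+b+c) over the window (ratio of sums, never a mean of ratios —
the ratio of sums is invariant to re-chunking the SNPs, which the test
suite asserts). Monomorphic sites and sites with fewer than two
genotyped individuals in either group contribute nothing.

d_xy needs invariant sites in its denominator: a SNP-only input
silently inflates it. The all-sites reader and the synthetic generator
therefore both carry invariant sites explicitly.

Site filtering mirrors standard variant-toolkit semantics: genotypes
with depth < 10 or genotype quality < 30 are set missing at read time;
sites then need QUAL ≥ 30, per-group missingness ≤ 20%, mean depth
below mean + 4·√mean (computed from the data when no cap is supplied),
biallelic non-indel records. ABBA–BABA mode additionally demands a
fully genotyped outgroup and minor allele count ≥ 1. Missingness is
enforced per population group rather than jointly: a site missing 30%
of one group's genotypes is uninformative for that group's allele
frequency even if the overall call rate looks fine.

# Introgression

D = Σ(ABBA−BABA) / Σ(ABBA+BABA) over sites, with the frequency forms
ABBA = (1−p₁)p₂p₃(1−p₄) and BABA = p₁(1−p₂)p₃(1−p₄). One D is computed
per region class over concatenated autosomes (single genome-wide values
per class are what the analysis design calls for; a per-chromosome
variant would need its own combination rule). Significance comes from a
weighted delete-one jackknife over contiguous SNP blocks — the
Busing-style weighting handles unequal block information — with 20
blocks by default; the block count is configurable because "standard
block jackknife" fixes no count, and 20 keeps each block large relative
to linkage scales while leaving enough degrees of freedom for a stable
variance. Identical leave-one-out estimates give SE 0; the result is
then flagged degenerate (Z = ±Inf, p = 0) instead of erroring, since
tiny synthetic runs can legitimately produce it.

# Rank tests

Region-class comparisons and the A/B expression comparison use the
Brunner–Munzel test: midranks over the pooled sample, the statistic
W = n_x n_y (R̄_y − R̄_x) / ((n_x+n_y)·√(n_x S²_x + n_y S²_y)), a
Satterthwaite t approximation, and the relative effect
P(X<Y) + ½P(X=Y). Two degenerate inputs get explicit conventions: all
values tied returns W = 0, p = 1 (no evidence, not an error), and
complete separation returns W = ±Inf, p = 0 with the correct relative
effect of 0 or 1 — both occur in small or strongly structured runs. The
t-approximate p agrees with the exhaustive permutation p to within 0.08
at n = 5+5 (asserted in the tests against an enumeration oracle).

# Hi-C: balancing, compartments, TAD boundaries

Contact matrices are KR-balanced (Knight–Ruiz inexact-Newton iteration)
so unmasked row sums are equal; bins with fewer than 10 nonzero
contacts are masked first, since near-empty rows destabilise both
balancing and the correlation matrix (the threshold is configurable; no
single coverage filter suits all depths). The balanced matrix is
normalised per diagonal (observed/expected) and compartments come from
the leading eigenvector of the Pearson correlation matrix of the O/E
matrix at 100-kb bins, signed per chromosome so score correlates
positively with GC (A = GC-rich, score > 0). Working on the O/E matrix
rather than the raw balanced matrix is the standard intermediate — the
distance decay otherwise dominates the first eigenvector; the choice is
exposed as a documented switch by passing a different matrix in. A
chromosome whose GC correlation is exactly zero cannot be oriented and
is labelled undefined rather than guessed.

Compartment segments are maximal same-label runs; a boundary is emitted
only between two *defined* adjacent bins, because a defined↔undefined
junction has only one observed side. Boundary positions are bin-edge
positions (start of the right-hand bin).

TAD tables may call the same interval at both hierarchy levels; exact
duplicates collapse to primary, intervals strictly contained in another
stay secondary. Both endpoints of both levels are boundaries,
deduplicated per chromosome. Because "boundary count per level" is
ambiguous between unique positions and raw endpoints,
`tad_boundary_counts()` reports both tallies.

The insulation-score boundary caller included here is a deliberately
simple domain caller — mean contact in a w×w square straddling each
bin, boundaries at local minima of the log2 mean-normalised score with
prominence above a threshold — used to exercise the pipeline end to end
on synthetic matrices. It is not a reimplementation of any published
spectral caller, whose output tables the pipeline consumes as input in
real-data mode.

Expression uses TPM (columns sum to 10⁶ by construction), averaged over
samples per gene; genes overlapping both compartments ("spanning") are
excluded before the A-vs-B rank test, as are genes overlapping neither.

# Breakpoint–boundary enrichment

For each breakpoint, the distance to the nearest boundary on the same
chromosome, also in bin units. "Within one bin" is distance ≤ 25,000 bp
inclusive (the natural reading when a distance of 1.67 bins counts as
an exception; a strict flag is available). The analytic expectation is
the length fraction of the allowed set covered by ±radius
neighbourhoods of the boundaries; the permutation null re-places the
same number of points uniformly and independently on the allowed set
(a paired variant placing whole inversions is available, since
independent placement is the simplest defensible null for per-breakpoint
counts). The allowed set defaults to non-excluded chromosomes minus
masked intervals; both masked and unmasked variants are computable
because the random-placement expectation depends on that choice and
real analyses differ in whether they exclude masks.

The full suite is 2 inversion sets (all, > 25 kbp) × 2 boundary kinds
(TAD, A/B) × 2 coordinate frames (reference and query assemblies) = 8
cells at radius 25 kbp. Frames are analysed separately — each species'
breakpoints against that species' own boundaries — matching per-species
expected values; the counts per frame are identical by construction
since each inversion has two ends in either frame.

Alongside the chi-square, a permutation p is always reported. The df-1
goodness-of-fit chi-square is the plain Pearson form (with a Yates
variant); printed chi-square values from real-data analyses of this
design are not always reproducible from k, n and the expected fraction
alone, so the package reports both standard variants and the
permutation p rather than guessing at any other construction.

# The synthetic-data generator

The generator emulates the study inputs with known ground truth:

* **Structure**: chromosomes tiled by primary TADs (normal sizes around
  330 kb — anchored to observed primary-TAD means in fish Hi-C — rounded
  to 25-kb bins, minimum 2 bins), about half carrying one nested
  secondary TAD; alternating A/B segments with mean length 450 kb at
  100-kb bins (between the observed A and B domain means); GC = 0.40 +
  0.04·1[A] + N(0, 0.01) — a teleost-like base composition with a
  modest A-compartment GC excess.
* **Contacts**: μ_ij = s·(1+|i−j|)^(−γ)·(1 + τ·1[same primary TAD])·
  (1 + τ/2·1[same secondary TAD])·(1 + κ·c_i·c_j), Poisson counts,
  symmetrised, scaled to an expected `depth` per chromosome (default
  5·10⁵; γ = 1, τ = 1, κ = 0.3).
* **Inversions**: each breakpoint lands on a uniformly chosen TAD
  boundary with probability β, else uniformly on the allowed genome;
  the end breakpoint sits a log-normal length downstream before its own
  snap. β = 0 is the uniform null and β = 1 puts every breakpoint on a
  boundary; both identities are asserted in tests. Snapping both ends
  while also fixing the length exactly is impossible, so lengths follow
  the configured distribution only approximately when β > 0 — the
  per-breakpoint snap probability is kept exact because the enrichment
  statistic counts breakpoints, not lengths.
* **Genotypes** (frequency model, not coalescent): ancestral derived
  frequency a ~ U(0.05, 0.95); P2 and P3 independent Balding–Nichols
  draws with the region's F (F_inverted = 0.8 inside inversions,
  F_colinear = 0.3 elsewhere — strong inversion differentiation over a
  moderately diverged background); P1 ~ BN(p₂, 0.05) around P2's
  pre-introgression frequency, making E[D] = 0 without gene flow;
  outgroup fixed ancestral. Introgression: P2's sampling frequency is
  (1−α)p₂ + αp₃ in colinear regions (α = 0.1), forced to α = 0 inside
  inversions — inversions are barriers by construction. Genotypes are
  Binomial(2, freq) per diploid, 10 per group; invariant sites are
  emitted at a configured per-window density (they need no random
  draws). A frequency model was chosen over coalescent simulation
  because it is desk-scale, analytically tractable (E[F̂_ST] ≈ F under
  Balding–Nichols; the introgression term gives E[ABBA−BABA] ∝
  α·F·a(1−a) > 0) and sufficient to exercise every statistic; a
  coalescent backend is a clean extension point.
* **Expression**: genes placed inside compartment segments (5%
  deliberately spanning boundaries to exercise the exclusion rule),
  negative-binomial counts over 7 samples, A-gene mean ×2.

Only one coordinate frame is simulated; query coordinates mirror the
reference ones, since cross-assembly alignment is out of the package's
scope. What the generator does **not** emulate: linkage disequilibrium
within windows (sites are exchangeable given their region), selection,
recombination-rate variation, realistic SV complexity (no nested or
overlapping inversions), mappability structure in the mask, or
sequencing-error models beyond uniform genotype missingness. Passing
tests on synthetic data therefore demonstrate correctness of the
estimators and the test calibration under the stated models, not
robustness to every artefact of real data.

# Problem sizes and numerical choices

The test suite and acceptance script run the generator at desk scale —
typically 2–3 chromosomes of 6–8 Mb (240–320 TAD bins per chromosome),
60 SNPs per 25-kb window, 10 diploids per group, 199–999 permutation
draws, 10–20 replicate seeds for stochastic claims; d_xy examples carry
explicit invariant sites while large multi-seed runs set the invariant
density to 0 when d_xy is not under test. These sizes were chosen so
each statistic has enough data to be estimated stably (hundreds of
windows, >20,000 ABBA-informative sites) while a full suite run stays
in minutes.

KR balancing converges to a 2-norm residual ≤ 10⁻⁶ (row-sum CV in
balanced matrices is asserted < 10⁻⁴); non-convergence or an unmasked
all-zero row is an error, never silently patched. Permutation p-values
use the add-one estimator (1+k)/(M+1) so p = 0 is unreachable. The
jackknife estimate always equals the plain ratio of sums regardless of
blocking. All randomness in a pipeline run flows from the single
configured seed; stage seeds are derived with fixed offsets so stages
are independently reproducible.

# Known limitations

* The D statistic is computed from population allele frequencies; with
  one outgroup individual, p₄ is coarse (here fixed ancestral in
  simulation).
* The insulation caller is intentionally minimal; its recall guarantee
  (≥ 0.8 of planted primary boundaries at 1-bin tolerance, τ ≥ 1) is a
  property of the generator's block-contrast model.
* Real-data mode consumes TAD tables and contact matrices in a minimal
  text dialect; converting from cooler/hic formats is left to external
  tooling.
* Windows are non-overlapping and fixed; no sliding-window variant.
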