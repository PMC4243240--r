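---
title: "Methods: copy-number landscapes and treatment-specific survival association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: copy-number landscapes and treatment-specific survival association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`cnsurv` implements a complete desk-scale pipeline for asking whether somatic
DNA copy-number aberrations in a multi-arm clinical trial cohort are
associated with progression-free survival (PFS) under specific drug
regimens, and for triaging the implicated regions down to genes and
drug-sensitivity evidence. The chain is:

1. probe-level log2-ratio preprocessing (background subtraction, wave
   removal, median normalisation);
2. circular binary segmentation (CBS);
3. post-segmentation mode normalisation and tumour-purity correction;
4. four-state calling (loss / normal / gain / amplification) with a
   Gaussian mixture;
5. reduction of the probe x sample call matrix to chromosomal subregions;
6. per-arm permutation log-rank association of region status with PFS,
   with permutation-based false discovery rates and between-arm
   comparisons;
7. dosage filtering of genes on associated regions against a paired copy
   number / expression data set, amplification cataloguing, and
   Kruskal-Wallis validation of region status against cell-line IC50
   values.

Because real trial, tumour-atlas and cell-line data cannot ship with a
package, a first-class synthetic-data generator emulates the statistical
structure of each of those inputs, with ground truth retained so every
stage can be tested for parameter recovery, calibration and power.

# Signal model and preprocessing

An aCGH probe measures the tumour/reference intensity ratio; on the log2
scale a diploid probe sits at 0, a single-copy loss at $\log_2(1/2) = -1$
and a single-copy gain at $\log_2(3/2) \approx 0.58$ in a pure tumour. A
specimen with tumour-cell fraction $p$ dilutes the linear ratio toward 1:

$$ r_{obs} = \log_2\!\big(p \cdot c/2 + (1 - p)\big) + \text{wave} + \varepsilon, $$

where $c$ is the tumour copy number and the wave term is a slowly varying
hybridisation artefact. Preprocessing inverts this model piece by piece, in
a fixed order: dewave, median-normalise, segment, mode-normalise,
purity-correct, call. The order matters: waves must be removed before
segmentation (they create spurious breakpoints), the mode shift needs
segment means, and calling expects purity-corrected levels.

**Dewaving** regresses each chromosome's profile on a wave reference — the
average profile of copy-number-normal hybridisations — and subtracts the
fitted component. The synthetic generator emits this reference as the mean
of 20 simulated normal samples. A caveat demonstrated by our own test
fixtures: if the wave period is comparable to the length of a true
aberration, the regression absorbs real signal. The generator's default
wave period (50 probes against 250-probe chromosomes) keeps roughly five
cycles per chromosome, which is the regime in which the regression is well
conditioned; `preprocess_cohort(..., wave_reference = NULL)` skips the step
entirely.

**Mode normalisation** re-centres the profile so its dominant copy-number
state sits at 0, protecting the downstream mixture from cohorts in which
the median state is not diploid. The mode is the peak of a Gaussian kernel
density (Silverman's bandwidth) over per-probe segment means; with a single
distinct mean the shift is that mean exactly, and density ties within
1e-12 resolve to the smallest shift.

**Purity correction** inverts the dilution law per segment mean:
$m^{corr} = \log_2\max\{(2^m - (1-p))/p,\ \varepsilon\}$ with
$\varepsilon = 2^{-10}$; the floor (hit for strong losses under low purity)
is logged. The correction is exact on noiseless means — the round-trip test
requires agreement to 1e-9.

**Quality control** uses the unscaled residual MAD,
$\mathrm{median}_i\,|r_i - \bar r_{seg(i)}|$, computed against segment means
so that genuine biology does not inflate it; profiles with MAD above 0.4
are excluded, boundary inclusive (0.40 is kept). No normal-consistency
factor (1.4826) is applied; the threshold is calibrated for the unscaled
quantity and is configuration-exposed.

# Segmentation

`segment_profile()` re-implements CBS: within a segment, the two-sample
t-like statistic between every circular arc $(i, j]$ and its complement is
maximised (exhaustively, in compiled code); the split is accepted when its
within-segment permutation p-value is below `alpha`, and the procedure
recurses. Defaults: `alpha = 0.01`, `n_perm = 1000`, `min_width = 2`, no
"undo" pruning. A pooled-variance denominator makes the statistic scale
free; a (near-)zero pooled variance with a non-zero mean difference is
treated as an infinite statistic, so noiseless steps are split exactly with
exact segment means. The scan is deterministic given a seed, and an
R-level exhaustive oracle checks the compiled scan on small instances in
the test suite.

# Calling

A four-component univariate Gaussian mixture with one shared variance is
fitted per sample to the purity-corrected segment means, weighted by
segment probe counts (EM, tolerance 1e-8, at most 500 iterations, initial
means -0.45, 0, 0.3, 0.9). Plain EM with only an ordered-means constraint
proved non-identifiable at this granularity: with few distinct levels in a
sample, the gain and amplification components drift onto the normal and
gain levels and relabel them. We therefore confine each component mean to a
per-state window — loss $\le -0.15$, normal $[-0.1, 0.1]$, gain
$[0.15, 0.75]$, amplification $\ge 0.8$ — which preserves the ordering by
construction and anchors the biological meaning of each component; a
component with no responsibility mass keeps its initial mean and a zero
mixing weight. A segment is called the posterior-argmax state when that
posterior reaches 0.5, otherwise normal. Amplification calls spanning more
than 3 Mb are downgraded to gain ("3 Mb or less" is inclusive: a 3.0 Mb
span remains an amplification). Calling is monotone: raising a segment
mean never lowers its call, a property the test suite checks directly.

# Subregions and total regions

`reduce_to_subregions()` compresses the probe x sample call matrix into
runs of probes with (near-)identical cohort-wide call signatures, by a
greedy left-to-right scan per chromosome: a probe joins the open subregion
while the fraction of samples disagreeing with the running per-sample modal
consensus stays within `tolerance` (default 0.01). At tolerance 0 the
reduction is provably lossless, which anchors correctness; the subregion
count is monotone non-increasing in the tolerance. Chromosome arms come
from a centromere table (synthetic genomes place the centromere at the
chromosome midpoint). Significant subregions concatenate into "total"
regions within one arm, either as maximal adjacent runs (used for
validation region sets) or as one region per arm.

# Survival association

Eligibility mirrors trial practice: at least three treatment cycles, or two
if the patient died of progressive disease, and no microsatellite
instability (MSI tumours carry few copy-number aberrations and would dilute
the genotype groups). Carriers of a region are samples with call $\ge 1$
for gains (amplification counts as gain) or $\le -1$ for losses; gains and
losses are tested separately. Within each arm, the two-group log-rank
statistic $U^2/V$ is computed for every region x type with at least 5
carriers and 5 non-carriers (`min_group`, configuration-exposed), and its
significance is assessed by permuting carrier labels within the arm —
10,000 permutations by default, with the plus-one convention
$p = (1 + \#\{T^{perm} \ge T\})/(B+1)$, so p is never 0. Permuted
statistics are compared with a 1e-9 tolerance because complementary
labelings yield mathematically equal statistics that can differ in the last
floating-point bit. All regions of an arm share one permutation stream,
which makes the permutation-based FDR coherent:
$\widehat{FDR}(t) = \overline{\#\{p^{perm}_b \le t\}} / \#\{p^{obs} \le t\}$,
averaging over permutation replicates.

Two significance tiers are flagged, mirroring the two thresholds used in
this kind of genome-wide PFS screen: p < 0.005 in any single arm, and
p < 0.05 in at least two arms for the same region and aberration type (the
second tier is evaluated per-arm without cross-arm correction). Between-arm
contrasts (`between_arm_tests()`) compare PFS across every pair of arms
separately within carriers and within non-carriers of a region, using the
asymptotic log-rank test with a 0.005 significance convention.
Kaplan-Meier medians (smallest $t$ with $\hat S(t) \le 0.5$, `NA` when the
curve never reaches 0.5) and their Greenwood log(-log) confidence limits
come from `survival::survfit`.

Unsupervised structure is explored with hierarchical clustering on ordinal
calls (distance: mean absolute call difference; Ward linkage), a
hard-call simplification of soft-call clustering approaches; cluster
membership can be tested for enrichment of a binary flag (e.g. MSI) with a
Pearson chi-square.

# Integration

Genes (0-based half-open intervals, like every coordinate in the package)
map to regions by 1-bp overlap. On regions passing either significance
tier, a gene is retained as dosage-sensitive when its copy number and
expression correlate positively in a paired data set: one-sided Spearman
(Pearson optional), $p < 0.05$ and $\rho > 0$. Amplification events
(maximal runs of +2 calls) group into recurrent loci by single-linkage
interval overlap per chromosome; the locus span is the intersection of its
events (union, flagged, when empty) and loci with at least 4 distinct
samples are reported. Cell lines are classified aberrant versus normal for
a small pre-declared region set by any-overlap of segments in the tested
state, and the drug's log-IC50 distribution is compared between statuses
with a Kruskal-Wallis test (midranks, tie correction, chi-square p),
uncorrected for multiplicity as appropriate for two or three pre-declared
regions.

# The synthetic generator

`simulate_cohort()` draws, per sample, an integer copy-number genome
(alphabet 0/1 loss, 2 normal, 3 gain, 6 amplification — amplification
events are capped at 3 Mb so truth matches the calling rule), observed
through the dilution-wave-noise model above. Its defaults emulate a
three-arm metastatic colorectal cancer trial at desk scale: arm sizes
105/111/133; probes at ~17 kb spacing; log2 noise sd 0.15 (residual MADs
then land near the 0.10-0.39 range seen in FFPE aCGH practice); wave
amplitude 0.10; tumour purity uniform on 0.7-1 (trial inclusion required
at least 70% tumour cells); about 8 background aberrant segments per
genome; a 6% MSI fraction whose genomes are copy-number silent; exponential
PFS with arm medians 180/240/320 days — the ordering and spacing of
capecitabine monotherapy, capecitabine-irinotecan, and
capecitabine-oxaliplatin-bevacizumab regimens — and 20% independent
exponential censoring, with the censoring rate found by bisection.
Exponential survival keeps every check closed-form (median $= \ln 2 /
\lambda$); planted drivers multiply the carrier's hazard by an arm-specific
ratio, which is the ground truth for recovery tests. Per-arm aberration
frequencies are free parameters: published frequency figures for this
disease cannot be read numerically, so the background landscape is
realistic in character (common arms-level gains/losses, focal
amplifications) but not locus-faithful.

What the generator deliberately does not model: correlated probe noise and
GC waves beyond a single sinusoid per chromosome, subclonal (fractional)
aberrations, stratification factors, non-exponential hazards, and
informative censoring. Passing tests therefore demonstrate that the
machinery is correct and calibrated under its stated model, not that the
biological findings of any particular cohort would be reproduced.

# Numerical choices and experiment sizes

- Intensity floors: background-corrected intensities below `epsilon`
  (1e-3) are floored and flagged; the purity clip floor is $2^{-10}$.
  Defaulted parameters are logged at run time.
- Permutation streams: every stochastic stage takes an explicit integer
  seed; child seeds derive from a Lehmer step and stay below $2^{31}$.
  Reruns are byte-identical, which the pipeline manifest (md5 per output
  file) makes checkable.
- Test-time experiment sizes were chosen as the smallest at which the
  properties under test are statistically crisp: null calibration uses
  three arms of 100 samples and 200 regions at 1,000 permutations;
  driver recovery uses 20 replicates of a three-arm, 100-per-arm cohort at
  10,000 permutations with complete follow-up (censoring would only blur
  the power property being verified); segmentation recovery uses 100 step
  profiles at jump/noise = 10; the demo pipeline runs 3 x 40 samples over
  2 x 200 probes at 500 permutations.
- The driver-recovery criterion (detection at p < 0.005 in its arm in at
  least 80% of 20 replicates) sits close to the test's true power
  (~0.85 under these conditions), so it is the one acceptance property
  with non-trivial replicate-to-replicate variability.

# Limitations

The CBS re-implementation omits the "undo" pruning refinement; the caller
fits per sample rather than pooling the cohort, trading some power for
sample independence; the subregion reduction is a greedy scan rather than a
global information-loss optimisation; clustering uses hard calls. Real
cohort sizes (180,000 probes x 349 samples) are supported by the
implementation but the shipped experiments run at desk scale; genome-build
lift-over is out of scope — all inputs must share one build.
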