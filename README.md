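# cnsurv

Copy-number landscapes and treatment-specific survival association for
multi-arm oncology cohorts.

## The problem

Tumour DNA copy-number profiles (array CGH log2 ratios) from patients
treated in a multi-arm trial can reveal chromosomal regions whose gain or
loss predicts progression-free survival (PFS) under a specific drug
regimen. Getting from raw probe signal to that statement takes a long
chain of steps, each with its own failure modes: wave artefacts, tumour-cell
dilution, segmentation, discrete calling, massive multiplicity across the
genome, and downstream triage of regions to genes and drug-sensitivity
evidence. `cnsurv` implements the whole chain as tested, reusable R
functions, for statisticians and computational biologists running
genotype-to-outcome screens on clinical cohorts.

## The model at the core

A probe's observed log2 ratio in a specimen with tumour-cell fraction *p*
and tumour copy number *c* is

    r = log2(p * c/2 + (1 - p)) + wave + noise .

Preprocessing inverts this per sample: wave regression on a normal-sample
reference, median normalisation, circular binary segmentation (maximal
arc statistic + within-segment permutation test, compiled), mode
normalisation of segment means, exact inversion of the dilution law, and
four-state calling (loss / normal / gain / amplification) with a
shared-variance Gaussian mixture; amplification calls are restricted to
spans of at most 3 Mb. The probe x sample call matrix is compressed to
chromosomal subregions (lossless at tolerance 0), and each subregion x
{gain, loss} is tested per treatment arm with the two-group log-rank
statistic U²/V whose significance comes from permuting carrier labels
(default 10,000 permutations, p = (1 + #{T* >= T})/(B + 1)), with
permutation-based false discovery rates from the retained permutation
archive. Associated regions feed three integration steps: dosage filtering
of overlapping genes (one-sided Spearman correlation of copy number and
expression in a paired data set), a recurrent-amplification catalogue, and
Kruskal-Wallis comparison of cell-line log-IC50 by region status.

A first-class synthetic-data generator simulates cohorts, paired
expression panels and cell-line panels with known ground truth (planted
hazard-ratio drivers, dosage genes, IC50 shifts), so calibration, power
and recovery are all testable without any private data.

## Worked example

Simulate a three-arm cohort of 60 samples per arm with one planted driver
— a chr1 2–5 Mb loss carried by 30% of samples that triples the
progression hazard under the irinotecan-containing arm only — then run the
full chain:

```r
library(cnsurv)

driver <- driver_spec("chr1", start = 2e6, end = 5e6, aberration = "loss",
                      carrier_fraction = 0.3,
                      hazard_ratio_per_arm = c(CAPIRI = 3))
cfg <- cohort_config(n_samples_per_arm = c(60, 60, 60),
                     probes_per_chromosome = 100, probe_spacing = 1e5,
                     driver_regions = list(driver), seed = 11)
cohort <- simulate_cohort(cfg)
purity <- setNames(cohort$clinical$tumour_cell_pct / 100,
                   cohort$clinical$sample_id)
pre <- preprocess_cohort(cohort$ratios, cohort$annotation, purity,
                         cohort$wave_reference,
                         cbs = cbs_params(n_perm = 500, seed = 1))
sub <- reduce_to_subregions(pre$calls, cohort$annotation, tolerance = 0.01)
assoc <- associate_genomewide(sub$consensus, cohort$clinical,
                              B = 2000, seed = 2)
summary(assoc, n = 5)
permutation_fdr(assoc, threshold = 0.005)
```

Output (abridged):

```
Preprocessed cohort: 180 QC-passing samples x 400 probes ( 0 excluded )
Aberrant probe fraction: median 0.211, max 0.517
Chromosomal subregions: 378 regions from 400 probes (tolerance 0.01 )
Genome-wide permutation log-rank association
Arms: CAP, CAPIRI, CAPOX-B; 1526 region x type tests (B = 2000)
Tier-1 hits (p < 0.005 in an arm): 27; tier-2 (p < 0.05 in >= 2 arms): 0

Top associations:
 region_id    arm type n_carrier     stat            p median_carrier median_noncarrier
     R0023 CAPIRI loss        20 13.28085 0.0004997501           90.3             206.6
...
$fdr
[1] 0.2825926
```

The top hits are exactly the subregions tiling the planted driver
interval: loss carriers under CAPIRI progress after a median 90 days
versus 207 for non-carriers (permutation p = 0.0005), while the same
regions show nothing in the other two arms — the treatment-specific
association the screen is designed to find. The permutation FDR reports
what fraction of the 27 tier-1 discoveries would be expected under
label permutation (~28% here; the subregions tiling one driver count as
correlated discoveries).

The same objects flow on to `select_candidate_genes()` (dosage filter
against a paired expression set), `detect_amplicons()` /
`recurrent_amplicons()` and `validate_regions_in_celllines()`; or run
everything at once with `run_pipeline()` (YAML-configurable, writes TSV
tables and a hash manifest; also exposed as the `inst/scripts/cnsurv`
command-line wrapper).

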