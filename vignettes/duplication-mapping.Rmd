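---
title: "Mapping a tandem duplication behind blue eyes: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a tandem duplication behind blue eyes: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irisdup)
```

## The problem

Blue eyes and heterochromia in Siberian Huskies segregate with a 98.6-kb
tandem duplication upstream of *ALX4* on canine chromosome 18. The evidence
chain that maps such a variant has five steps, each of which this package
implements as a testable module:

1. a genome-wide association scan on a breed-structured cohort
   (`lmm_wald_scan()`),
2. structural-variant detection from sequencing reads — scaled sliding-window
   depth plus opposite-orientation discordant read pairs
   (`scaled_window_depth()`, `find_discordant_clusters()`,
   `call_tandem_duplication()`),
3. duplication genotyping from SNP-array probe intensities via the
   delta log R statistic (`delta_logR()`, `genotype_from_delta()`),
4. core-haplotype fine-mapping with penetrance and modifier analysis
   (`find_shared_haplotype()`, `define_core()`, `count_core_copies()`,
   `haplotype_association()`, `penetrance_table()`, `modifier_test()`),
5. hard-filter triage of candidate variants (`hard_filter()`,
   `carrier_exclusive()`, `classify_consequence()`).

Because the original cohorts are private customer data, a first-class
synthetic generator (`simulate_cohort()`, `simulate_intensities()`,
`simulate_read_alignments()`) emulates their statistical structure so every
stage can be exercised and validated offline.

## The mixed model

The association scan fits, per marker,

$$ y = W\alpha + x\beta + u + \epsilon, \qquad
   u \sim N(0, \lambda \tau^{-1} K), \quad
   \epsilon \sim N(0, \tau^{-1} I), $$

where `y` is the case/control coding treated as quantitative, `W` the
covariates (intercept only by default), `x` the marker dosage, and `K` the
relatedness matrix of column-centred genotypes, `K = X_c X_c' / p`. The model
is rotated once by the eigenvectors of `K`; the variance ratio `lambda` is
then profiled out per marker by maximum likelihood over a log-spaced grid on
`[1e-5, 1e5]` (10 points per decade) with Brent/golden-section refinement in
the bracketing interval. Wald tests use `F(1, n - c - 1)`. ML rather than
REML, and the F reference, are conventions of the mixed-model association
literature; with `K = I` the scan reduces exactly to per-marker ordinary
least squares, which the test suite verifies against `lm()`.

Hits are tiered at the conventional strict thresholds `P < 5e-8`
(significant) and `P < 1e-5` (suggestive); QC removes samples with more than
2.5% missing genotypes, then markers called in fewer than 95% of samples.

## The synthetic cohort

`population_config()` holds the generative model. Defaults are chosen once,
to match the study conditions the pipeline targets:

* **Breed structure and LD.** Dogs are assigned uniformly to 5 breeds whose
  allele frequencies drift from a common ancestor under a Balding–Nichols
  model (`breed_fst = 0.1`). Haplotypes are assembled by copying blocks of
  25 markers from a pool of 20 founder haplotypes per breed. Block copying
  yields tag-SNP structure (markers within the causal block tag the
  duplication imperfectly) without coalescent machinery; it does not model
  recombination-distance decay of LD, so tests exercised on it say nothing
  about fine-scale recombination effects in real data.
* **The causal haplotype.** One founder haplotype of breed 1 carries the
  duplication; the blocks overlapping the duplication travel as a single
  identity-by-descent segment. The default haplotype frequency is tuned so
  the expected carrier fraction is 10% (`tune_dup_freq(0.10, n_breeds)`).
  Restricting the haplotype to one breed reproduces the strong
  breed–phenotype confounding the mixed model must correct.
* **Penetrance.** Carriers are blue-eyed with probability 0.65 (the
  discovery-panel carrier penetrance, 81 blue of 127 carriers, is about
  0.64); non-carriers with probability 0.01, raised to 0.25 for carriers of
  a merle-like phenocopy locus (allele frequency 0.05). A dominant
  melanistic-mask (Em) modifier (allele frequency 0.2) halves carrier
  penetrance (`mask_brown_boost = 0.5`).
* **Marker placement.** Six markers sit at the canonical in-duplication
  array positions; the rest are spread evenly over a 2-Mb region. The
  in-duplication marker count mirrors the six-marker exclusion list used
  when counting core-haplotype copies; the real array's regional density is
  not published, so this is a convention.
* **Background markers.** The generator also emits unlinked markers under
  the same breed structure (`n_background_markers`, default 400). The GRM is
  built from these rather than from the 2-Mb focal region: a genome-wide
  GRM, which they stand in for, receives a negligible contribution from any
  single region, whereas a region-only GRM is dominated by the causal
  haplotype and absorbs the very association being tested (the same logic
  that motivates leave-one-chromosome-out GRMs).

Intensities follow `intensity_model()`: log R shifts of 0 / 0.35 / 0.65 for
total copy number 2 / 3 / 4 at the probed locus, with iid per-marker noise
(SD 0.12). These defaults are consistent with a heterozygote calling bound
of delta log R > 0.15 (the observed minimum for heterozygotes) and a
published heterozygous example at 0.31; typical array probe noise is
0.1–0.2. With six in-duplication markers and a ~1-Mb flank set, the delta
log R standard deviation is about `0.12 * sqrt(1/6 + 1/n_flank)` ≈ 0.05, so
the 0.15 bound sits ~3 SD from both the non-carrier and heterozygote means
and misclassification stays below 1%.

The read simulator draws fragments uniformly from donor haplotypes that
carry 0, 1 or 2 head-to-tail copies of the duplicated interval (default
length 98,607 bp), with 100-bp reads and 350 ± 30 bp inserts in FR
orientation. Fragments crossing the duplication junction map back to the
reference as everted (reverse-forward) pairs roughly one duplication length
apart — the tandem-duplication signature the detector looks for. Reads
overlapping the junction itself are placed by their start coordinate
(split-read refinement is out of scope), which costs a few hundred bases of
breakpoint accuracy, well inside the `insert_mean + 3 * insert_sd`
recovery tolerance the tests assert.

## Structural-variant calling conventions

Depth profiles use 10-kb sliding windows stepped every 2.5 kb (the window
width is standard; the step is a package choice — 4x overlap resolves a
~100-kb event at negligible cost) and are scaled by the sample's mean depth
over the region. Discordant-pair clusters are built by single linkage:
two everted pairs join when both their left-read starts and their mate
starts lie within `max_span_slop_bp` (default 10 kb).

A call requires a cluster of at least 3 supporting pairs coinciding with a
depth ratio of at least 1.4. Breakpoints follow the convention that `start`
is the leftmost read start of the left span and `end` the leftmost mate
start of the right span; `end` is therefore the first base after the
duplicated segment and `length = end - start` (this is the arithmetic that
gives 98,607 bp from the published cluster coordinates). Copy classes come
from the depth ratio: heterozygous in `[1.4, 1.75)`, homozygous in
`[1.75, 2.25]`, anything else qualifying is flagged ambiguous, as are
overlapping conflicting calls. The class boundaries are conventions fitted
to the observed 1.5–2X elevation and are configurable.

## Haplotype analysis conventions

The shared haplotype extends marker by marker from the index SNP while every
case homozygote keeps at least one haplotype matching a single consensus
(majority allele among surviving haplotypes; ties to the lower code). The
core is the widest sub-interval containing the index on which at least 90%
of the case homozygotes are two-copy. Copy counting is strict — a haplotype
matches only if it equals the core allele at every non-excluded marker, with
missing data disqualifying — because recombinant and partial haplotypes are
treated as distinct categories; markers inside the duplication are excluded
from matching since array genotypes are unreliable there. Phasing is
consumed, never computed: inputs must already be phased, and the simulator
ships truth phase.

In the orchestrated pipeline the case homozygotes are additionally required
to sit in the homozygous delta-log-R class when intensities are available.
At desk scale the best tag SNP is imperfect, and without this screen a blue
phenocopy homozygous for the tag allele truncates the shared-haplotype
extension immediately; jointly using array intensity and phased haplotypes
is exactly how the fine-mapping step is meant to work.

The haplotype–phenotype test is a Pearson chi-square without continuity
correction on the dog-level carrier-by-phenotype table (an allele-level
variant is available via `level = "allele"`; the published chi-square is not
exactly reproducible from the printed dog-level counts, so neither mode is
asserted to match it). Penetrance uses Clopper–Pearson intervals; the
modifier analysis is a two-sided Fisher exact test among carriers with the
modifier coded dominantly. Distribution comparisons of delta log R use the
Mann–Whitney U test by default (the original analysis does not name its
test; Kolmogorov–Smirnov is available via `method = "ks"`).

## Variant triage conventions

Hard filters are applied exactly as strict rejection rules — depth < 2 (both
types), strand-bias FS > 60 (SNPs) / > 200 (indels), read-position rank-sum
< −8 / −20, and for SNPs RMS mapping quality < 40 and mapping-quality
rank-sum < −12.5 — with SNPs and indels filtered in separate passes. A
missing annotation skips that rule and is counted. Consequence
classification is deliberately minimal (containment plus codon translation
for CDS SNPs); it is a triage aid, not an annotation engine.

## Numerical and degenerate-input choices

* Monomorphic or collinear markers leave no variance after projecting out
  the covariates; they are flagged (`ok = FALSE`) and skipped, not fatal.
* Eigenvalues of `K` are clipped at zero (tolerance `-1e-8` of the largest).
* Ties at classification thresholds are resolved strictly: `P` equal to
  5e-8 is suggestive, delta log R equal to 0.15 is a non-carrier, FS equal
  to 60 is retained.
* Identical pooled samples make the rank test return `p = 1` rather than
  failing.
* A zero margin makes the chi-square undefined (error); the Fisher modifier
  test instead reports `p = 1` with a degenerate flag, since carrier-only
  subsets are routinely small.
* All generators are bit-reproducible given a seed; independent streams
  (genotypes, phenotypes, intensities, reads) derive distinct sub-seeds so
  regenerating one layer does not shift another.

## Problem sizes

The package targets desk-scale experiments: the test suite uses cohorts of
300–10,000 dogs over 50–5,000 regional markers, 20X read simulations over a
500-kb reference, and a 2,000-dog demonstration pipeline; these sizes were
chosen so the full suite and the acceptance script each complete in minutes
on one core while keeping every statistical check well-powered. The
cohort-scale headline statistics of the original study (association
P-values of order 1e-68 to 1e-290 on thousands of customer dogs) are not
reproducible at these sizes; the suite instead verifies the properties that
make them credible — calibration under the null, equivalence with
closed-form oracles, and recovery of planted truths.

## Known limitations

* LD is blockwise; no recombination map, no decay with distance.
* The read simulator has Poisson-like depth only: no sequencing errors,
  mapping ambiguity, GC bias, or split reads.
* The intensity model is iid Gaussian per marker: no per-sample baseline
  wave, no B-allele frequency channel.
* Consequence classification ignores splice sites and regulatory annotation.
* The pipeline reruns stages rather than caching them; at these problem
  sizes a content-addressed cache would add failure modes without saving
  noticeable time.
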