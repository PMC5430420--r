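---
title: "Methods: CNV calling, CNVR construction and cross-study comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CNV calling, CNVR construction and cross-study comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvrkit)
```

This vignette documents the statistical model, the tunable parameters,
the synthetic-data generator, and the design decisions behind `cnvrkit`.
It states no empirical result that the package's test suite does not
itself compute.

## Signals and quality control

SNP arrays summarise each marker by two signals: the **Log R Ratio**
(LRR), the log2 ratio of observed to expected total probe intensity,
which shifts with copy number; and the **B Allele Frequency** (BAF), the
normalised fraction of B-allele signal, which clusters by genotype. A
diploid marker has LRR near 0 and BAF near 0, 0.5 or 1; a hemizygous
deletion depresses LRR and removes the heterozygote cluster; a
duplication raises LRR and splits the heterozygote cluster towards 1/3
and 2/3.

Per-sample QC (`sample_qc()`) computes four gating metrics:

* **call rate** (fraction of non-missing genotype calls), threshold
  ≥ 0.90;
* **SD of LRR** over non-missing autosomal markers, threshold < 0.30;
* **BAF drift**, the fraction of BAF values in the artifact bands
  [0.2, 0.25] ∪ [0.75, 0.8], threshold < 0.01. These bands are the
  conventional definition of the metric: genuine genotype clusters
  essentially never produce BAF there, so mass in the bands indicates a
  contaminated or drifting BAF channel;
* **waviness**, the SD of per-window median LRR (1-Mb windows),
  threshold < 0.05. This captures long-range LRR oscillation with no
  external data. The widely used alternative definition regresses LRR
  on GC content, which requires a GC track; the window-median form does
  not, at the cost of also responding to genuine mega-base CNVs when
  the CNV burden is high (see *Limitations*).

Per-marker QC (`marker_qc()`) applies missingness ≤ 10 %, minor allele
frequency ≥ 5 %, and a Hardy–Weinberg goodness-of-fit chi-square test
(1 df) whose threshold of 10⁻⁵ is applied to the Bonferroni-adjusted
P value, `min(1, P · m)` for `m` tested markers. Bonferroni was chosen
as the simplest multiple-testing adjustment consistent with applying a
fixed threshold per cohort; monomorphic markers are defined to have
P = 1 (there is nothing to test). The **PFB** (`compute_pfb()`) of a
marker is the mean of its non-missing BAF values across the cohort,
clamped to [0.01, 0.99] so that binomial genotype priors downstream
never degenerate to point masses.

## The hidden Markov model

`hmm_spec()` defines five states, one per copy number 0–4. The cited
family of SNP-array callers also models copy-neutral loss of
heterozygosity; that state is omitted here because the downstream
region-level analysis only distinguishes losses and gains.

**Emissions.** For copy number `c`, LRR is Gaussian with mean `mu[c]`
and SD `lrr_sd[c]`. The default means (−3.5, −0.66, 0, +0.40, +0.68)
are the canonical values for Illumina arrays: a full deletion leaves
only background intensity (hence the very negative mean and a wide SD
of 1.5), and each added copy raises log2 intensity by a diminishing
step. The BAF term is a mixture over B-allele dosage `b = 0..c` with
weights `Binom(b; c, PFB)`, cluster centres `b/c`, and cluster SD
`baf_sd` (default 0.03, a typical tight Illumina cluster width).
Boundary clusters at 0 and 1 are half-Gaussians — doubled and truncated
to the unit interval — so each state's BAF density integrates to 1
(verified by quadrature in the test suite). Copy number 0 has no
genotype, so its BAF density is uniform. Missing LRR or BAF contributes
zero to its term, which makes a fully missing marker emission-neutral.

**Transitions.** Self-transition probability between markers at
distance `d` is `1 − (1 − p_stay)(1 − exp(−d/d0))` with defaults
`p_stay = 0.999` and `d0 = 100` kb, the remaining mass split uniformly
over the other four states. The decay term makes state changes cheaper
across large gaps — CNV breakpoints are more likely between distant
markers — while tightly spaced markers almost never switch. `d0 = Inf`
disables the distance dependence, in which case decoding is invariant
to marker spacing (a property the tests assert). The published
transition matrices of the reference tools are fitted to training data
that is not available here; this two-parameter family reproduces their
qualitative behaviour and is fully specified.

**Decoding.** Viterbi, per chromosome, entirely in log space (the
tests check finiteness on a 10⁵-marker chromosome). Viterbi was
preferred over forward–backward posterior masking because it yields
deterministic, testable segment boundaries. Maximal non-diploid runs
with at least `min_snps` markers (default 3, the field's convention)
become calls; shorter runs are absorbed into the diploid state. Call
boundaries are the positions of the run's first and last markers — the
resolution of the array, not of the underlying event.

## CNVR construction

`merge_to_cnvrs()` aggregates calls across samples by single-linkage
transitive union: intervals join iff they overlap by **at least 1 bp**,
and chains of overlaps join into one region. A region may therefore
span two calls that do not themselves overlap, a documented property of
this convention. Regions shorter than 1 kb are removed **after**
merging (CNVs are defined as variants of 1 kb and larger; the filter is
deliberately not applied to the input calls). Region state is `loss` or
`gain` when all contributing calls agree, `both` otherwise; frequency
is the percentage of the **post-QC cohort** (not of carriers) with at
least one overlapping call, counting a sample once however many calls
it contributes. With a cohort of 48, one carrier gives 100/48 ≈ 2.1 %.

`summarize_cnvrs()` reports per-chromosome counts, total/average CNVR
length, percent coverage, and inter-region distances
(`next start − current end − 1`; undefined below two regions), plus a
genome-wide OLS regression of CNVR count on chromosome length with R²
computed from residuals, and a length histogram over the bins <10,
10–50, 50–100, 100–500, 500–1000 and >1000 kb.

## Cross-study comparison

All comparisons use the same ≥ 1 bp overlap rule as merging; reciprocal
overlap fractions are deliberately not required, because the datasets
being compared come from platforms with very different resolution.
`classify_novelty()` flags a query region as *known* iff it overlaps at
least one region of at least one reference study. `build_composite()`
merges all studies' regions into a composite list and fills a binary
study × region presence matrix.

`ordinate()` performs PCA on the row-centred presence matrix (each
study's row mean subtracted; no scaling, the entries being binary) via
singular value decomposition, which is equivalent to an
eigen-decomposition of the covariance between study profiles — the
test suite checks this equivalence at 10⁻⁸. Rows are studies rather
than regions because the scientific question is how studies group.
Hierarchical clustering uses the Jaccard distance between binary rows
with average linkage: Jaccard ignores co-absences, which dominate a
sparse presence matrix, and average linkage is robust to the chaining
behaviour of single linkage on such data. Neither choice is forced by
the problem; both are stated here as the package's committed defaults.
The dendrogram is also serialised as Newick text.

`breed_specific()` first drops intervals under 100 kb — matching the
filtering used when comparing datasets produced on the same platform —
then re-merges within each dataset, and declares a region specific to
its dataset iff it overlaps no filtered region of any other dataset.

## Annotation and enrichment

`overlap_features()` and `gap_overlap()` apply the 1-bp rule to genes,
QTL intervals and assembly gaps (gaps under 1 kb ignored).
`enrich()` replaces web-service enrichment tools with a transparent
hypergeometric upper-tail test per gene set, Benjamini–Hochberg
corrected. The default universe is the supplied annotation's gene list,
not the whole genome — the appropriate background when hits can only
ever come from annotated genes; it is configurable. Note that
EASE-style modified Fisher scores used by some web tools are not
reproduced, so p-values are comparable only within this package.

## qPCR arithmetic

`ddct()` implements the standard double-delta-CT method with
amplification efficiency fixed at perfect doubling:
`ΔΔCT = (CT_tgt,test − CT_ref,test) − (CT_tgt,cal − CT_ref,cal)`, fold
change `2^−ΔΔCT`, and the diploid-normalized ratio `NR = 2·2^−ΔΔCT`.
Status thresholds (0.5, 1.5, 2.5) are the midpoints between the NR
values of integer copy numbers 0, 1, 2 and ≥3. A complete deletion
never amplifies; it enters the arithmetic through a CT ceiling of 40
cycles (the standard run length), giving an NR near 0. Replicates are
averaged before any differencing. When several calibrator samples are
available their CTs can be supplied as replicates, which averages them
— one of several defensible conventions, fixed here.

## The synthetic-data generator

`simulate_truth()`/`simulate_signals()` emulate: a multi-chromosome
autosomal genome; a dense uniform marker map with Beta-distributed PFB
clamped to [0.01, 0.99]; per-sample CNV truth with log-uniform lengths,
rejection of within-sample overlaps (kept, rather than merged, so
ground truth stays unambiguous for precision/recall), and a 10:1
loss:gain odds default mirroring the strong loss excess reported by
SNP-array CNV surveys; copy-number-shifted Gaussian LRR; genotype-
mixture BAF with half-Gaussian boundary clusters; and the two artifact
channels the QC module measures (BAF-drift contamination drawn uniform
in the QC metric's own bands, and sinusoidal LRR waviness).
`simulate_study_tables()` fabricates study CNVR tables with a
controlled shared fraction, optional boundary jitter and private
regions, retaining origin bookkeeping so comparison operations can be
validated against known labels.

Determinism: all randomness uses R's default Mersenne-Twister generator
seeded from `config$seed`; `simulate_signals()` seeds from
`config$seed + 1` so signal noise is reproducible regardless of whether
truth is regenerated first.

Default scales are chosen for desk-size experiments: 20 samples, six
40-Mb chromosomes, 60 markers/Mb, 0.05 CNVs per sample per Mb, CNV
lengths 200 kb – 1 Mb, LRR SD 0.2. Relative to a real 600 K array this
is roughly a 4-fold lower marker density on a 16-fold smaller genome,
with correspondingly longer CNVs so that a typical event still spans
~12 markers — the quantity that actually controls HMM detectability.
The recovery tests run at exactly these conditions and require
precision and recall ≥ 0.9 with a ±2-marker breakpoint tolerance.

What the generator does **not** emulate: linkage disequilibrium between
genotypes, GC-content waves correlated with real genome sequence,
probe-specific biases and outlier markers, segmental-duplication
hotspots where real arrays lose probe density, and X/Y chromosomes
(the analysis is autosome-only throughout). Passing tests on synthetic
data therefore demonstrate the correctness of the algorithms under the
stated noise model, not calling performance on any real array.

## Numerical choices and degenerate inputs

* BAF mixture densities are floored at 10⁻³⁰⁰ before logging.
* Viterbi ties at the argmax resolve to the lowest state index
  (`which.max`), making decoding deterministic.
* A chromosome with fewer markers than `min_snps` yields no calls,
  with a warning; a sample with fewer than two non-missing markers is
  an error.
* The count-vs-length regression returns R² = NA when all chromosomes
  have the same CNVR count (zero total variance), and an NA slope when
  all chromosomes have the same length.
* `interpret_nr` requires NR > 0; `cn_concordance` refuses
  zero-variance inputs, where Pearson correlation is undefined.
* Coordinates are 1-based inclusive everywhere internally (length =
  end − start + 1), the convention of the rawcnv dialect; BED files are
  converted at the boundary (`start + 1`), an exact bijection tested by
  round-trip. Chromosome labels are normalised by stripping a leading
  `chr`.

## Limitations

* The waviness metric responds to genuine CNVs whose length approaches
  the 1-Mb window, so cohorts with a high simulated CNV burden can sit
  near the 0.05 gate even without injected waviness; on real data the
  metric is intended to flag array artifacts, which dwarf real CNV
  signal at genome scale.
* The HMM omits copy-neutral LOH and GC correction, and applies no
  per-call confidence score beyond the marker-count minimum.
* Breed-specific regions are relative to the datasets supplied —
  "specific" means unobserved elsewhere in the comparison, not absent
  from the species.
* Enrichment p-values depend strongly on the chosen universe; the
  default (all annotated genes) is conservative when CNVRs
  preferentially hit gene-dense regions.
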