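---
title: "Models and methods behind scamp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind scamp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scamp)
```

This vignette explains the statistical models and procedural rules the
package implements, the assumptions behind them, what the synthetic-data
generator does and does not emulate, and the design choices made where the
methods left room for interpretation.

## The data and its noise sources

Droplet snDNA-seq encapsulates single nuclei, barcodes them, and amplifies
a targeted panel of ~200 bp amplicons. Three technical artifacts dominate
downstream analysis and each has a dedicated stage here:

1. **Background barcodes.** Most droplets carry no nucleus but still emit a
   trickle of ambient reads; cell calling removes them.
2. **Allelic dropout (ADO).** PCR from a single nucleus can fail to amplify
   one allele at a heterozygous site, producing a spuriously homozygous
   observation; the ADO module quantifies this from germline SNPs.
3. **Doublets.** Two nuclei in one droplet merge into a chimeric profile;
   the doublet module estimates the rate from a deliberate two-sample
   mixing experiment.

A fourth signal, uneven amplicon read depth, is both a nuisance (amplicon
efficiency) and the carrier of copy-number information; the ploidy module
separates the two by normalization.

## Cell calling

Three rules, all strict inequalities, applied in two passes to resolve the
circular dependency between "qualified barcode" and "working amplicon":

* qualify barcodes with total reads > 8 × (number of amplicons);
* call an amplicon *working* when its mean reads over qualified barcodes
  exceed 0.2 × the grand mean of per-amplicon means;
* call a qualified barcode a cell when the fraction of working amplicons
  with ≥ 1 read strictly exceeds 0.80.

"Data completeness" is interpreted as the fraction of working amplicons
with at least one read — the simplest reading; a depth-quantile variant
would need a parameter the rule set does not define. The thresholds are
`cell_calling_params()` arguments, defaulting to the published operating
point. Calling is monotone: adding reads to a barcode can only help it.

## Genotyping

Per cell–variant pair with depth DP and alternate count AD:

* DP < 5 → MISSING (too shallow to call);
* otherwise VAF = 100·AD/DP is binned WT ∈ [0, 20], HET ∈ (20, 80],
  HOM ∈ (80, 100] — the wide WT bin tolerates up to 20% contaminating
  reads per barcode;
* HET/HOM calls with AD < 3 are demoted to WT.

Two ambiguities are resolved explicitly and configurably. First, the
alternate-read threshold is read as a *minimum required count* (AD ≥ 3
retained, AD < 3 demoted). Second, the demotion applies to HOM as well as
HET calls: a HOM call with AD < 3 necessarily has DP < 4 at the relevant
VAFs and is exactly the low-depth/low-alt artifact the filter targets.
The bin boundaries at 20 and 80 are inclusive on the upper end, matching
the printed interval notation. The whole rule is verified in the tests
against an independent scalar evaluator for every (DP ≤ 15, AD ≤ DP) pair.

This genotyper assigns states for known, bulk-validated variants; it is
deliberately not a de-novo somatic caller.

The stricter de-novo variant filter regenotypes at DP ≥ 10 / AD ≥ 5, drops
variants MISSING in strictly more than 75% of cells — unless the gene is
whitelisted (*SMAD4*, *CDKN2A* by default), because homozygous deletion
produces biologically meaningful missingness — and keeps variants with a
HET/HOM call in at least 0.5% of all cells (closed bound: 5 carriers in
1,000 cells is kept, 4 is not).

Pseudobulk VAF is read-weighted (Σ AD / Σ DP), not a mean of per-cell
VAFs, so it matches what a bulk experiment on the pooled material would
measure; deep cells count for more, exactly as their DNA would.

## Allelic dropout

At a truly heterozygous SNP every nucleus should show both alleles, so the
per-SNP ADO rate is the fraction of nuclei with strictly zero reads of
exactly one allele (AD = 0 or AD = DP):

$$\mathrm{ADO} = \frac{\#\{\text{nuclei with exactly one allele at 0 reads}\}}
                      {\#\{\text{nuclei with } DP \ge 5\}}$$

Design choices: the denominator is restricted to nuclei with DP ≥ 5
(configurable) because shallower nuclei cannot distinguish one-allele from
both-allele dropout; nuclei with DP = 0 enter neither numerator nor
denominator (a site with no reads of either allele is unobservable); the
summary is the unweighted mean over SNPs. Germline SNPs are selected by
bulk-normal VAF > 0.2 and mean single-nucleus VAF in (0.2, 0.8), computed
ignoring zero VAFs, which excludes homozygous sites and somatic mosaicism.

Under the generator's symmetric per-allele dropout model with probability
q per allele class, the expected exactly-one-allele fraction is 2q(1−q).
The estimator's expectation is slightly higher, 2q(1−q)/(1−q²) = 2q/(1+q),
because both-allele dropouts (probability q²) vanish from its denominator;
at q = 0.1101 this is 19.8% versus 19.6% — well inside the ±1-point
tolerance the validation uses, and worth remembering when interpreting
estimates at high q. The estimator cannot distinguish technical dropout
from real mono-allelic states caused by copy-number loss; on real data it
is therefore an upper bound on technical ADO.

## Depth planning

Total reads required:
X = (expected nuclei) × (amplicons) × (target depth) ÷ (fraction of reads
assigned to cells), rounded up, with the expected nuclei given by the
loading rule (input concentration × 1 µl). Defaults: target depth 100
reads/cell/amplicon, fraction 0.5. At 4,000 nuclei/µl and 186 amplicons
this plans 148.8 million read pairs.

## Doublet rate from a mixing experiment

Nuclei from two patients' tumors, each with a private clonal driver, are
mixed and processed as one library. With population-A fraction p and
doublet rate d, and assuming doublet constituents are drawn independently
from the pooled suspension, the observable categories have probabilities

$$P(A) = (1-d)p + dp^2,\quad P(B) = (1-d)(1-p) + d(1-p)^2,\quad
  P(AB) = 2dp(1-p).$$

Same-population doublets are genotypically invisible and fold into the
singlet categories — d is the *total* doublet rate, identifiable because
cross-population doublets reveal it. Barcodes carrying neither driver are
uninformative and excluded (they are mostly dropout victims and background
survivors). The estimator maximizes the 3-category multinomial likelihood
over (d, p) ∈ [0,1]² with `stats::optim` (L-BFGS-B) from the moment start
p₀ = n_A/(n_A+n_B), d₀ = f_AB/(2p₀(1−p₀)); since P(A) − P(B) = 2p − 1
identically, interior solutions equal the plug-in inversion, and the
optimizer only matters at boundaries (f_AB larger than any interior d can
explain ⇒ d̂ = 1 with a warning). The 95% CI is a nonparametric bootstrap
over multinomial resamples (default 1,000, seeded).

Two biases are deliberately left uncorrected and documented: ADO can hide
one driver of a true AB barcode, and an AB barcode's driver VAFs center on
25% — close above the 20% WT/HET boundary — so depth noise demotes some AB
barcodes to singlets. Both deflate d̂. In the simulated recovery study
(p = 0.5, d = 0.04, 4,000 droplets, 200 replicates) the mean underestimate
is ~0.4 percentage points, within the half-point the validation demands,
but users should treat mixing-experiment estimates as mild lower bounds.

## Per-amplicon ploidy

Counts are normalized in two steps: each cell's row by its mean across
amplicons (removing library size), then each amplicon's column by its
median over good-quality cells (removing amplicon efficiency). Good
quality means ≥ 1/10 the total reads of the 10th-ranked cell ("at least"
is a closed bound; with fewer than 10 cells the rule keeps everything).
Ploidy is then 2 × the ratio of a cell's normalized value to the median
over an assumed-diploid baseline population — the factor 2 makes baseline
cells read as diploid by construction, and the baseline median is taken
over baseline ∩ good-quality cells. Clone summaries use per-amplicon
medians over member cells; homozygous deletion is flagged below median
ploidy 0.5 (the observed "ploidy ≈ 0" signature, with headroom for noise;
configurable).

Two intrinsic properties of this estimator deserve emphasis. It is
*relative*: within-cell normalization measures each amplicon against the
cell's average copy number, so a clone with a large aberrant fraction of
the panel has its whole profile rescaled by (mean copy number)/2 — with 3
aberrant amplicons of 60 the distortion is ~2%, but a clone with 7 of 20
amplicons homozygously deleted reads ~1.5× too high on its normal
amplicons. On a real 186-amplicon panel with focal events this is
negligible; for broad aneuploidy it is not, and the package makes no
attempt at genome-wide segmentation. It is also *baseline-dependent*: the
validation design splits presumed-normal cells into three groups
(norm_a/b/c), uses one as baseline, and checks the others' medians land in
[1.9, 2.1].

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
with truth labels for every latent quantity:

* **Clones** declare proportions, genotypes over panel variants, and
  per-amplicon copy numbers (2 = diploid, 0 = homozygous deletion).
* **Depth** is negative binomial per cell per amplicon with mean
  (mean depth) × (amplicon efficiency) × (copy number / 2). Defaults:
  mean 100 reads/cell/amplicon (the assay's planning target) and
  dispersion size 8, a moderate overdispersion consistent with amplicon
  count data; both are single knobs because the analysis normalizes away
  finer structure anyway.
* **Variants** map to their covering amplicon; a variant's DP *is* that
  amplicon's reads — amplicon reads are the physical unit, so CNV and
  coverage effects propagate to genotyping automatically.
* **ADO** is symmetric per-allele Bernoulli dropout with probability
  q = 0.1101 by default (the value whose exactly-one-allele fraction
  2q(1−q) matches a 19.6% observed rate). At a HET site, losing ref makes
  the site read HOM, losing alt makes it WT, losing both forces DP = 0
  (unobservable). At WT/HOM sites both copies are the same class, so only
  the double loss (q²) is visible, as DP = 0. Apparent dropout caused by
  real copy-number loss is a separate mechanism, produced by clone copy
  numbers and labeled as such in truth.
* **Doublets** (rate d = 0.04 by default, the middle of the observed
  3–5% range) occupy one droplet: the droplet's total per-amplicon reads
  are drawn once at the combined mean of the two constituent nuclei —
  overdispersion in droplet PCR is dominated by per-droplet amplification
  efficiency, which co-encapsulated nuclei share — and allocated between
  constituents binomially by template share. Constituent counts therefore
  sum exactly to the barcode's counts, and a doublet's driver VAF
  concentrates near 25% instead of being smeared by independent depth
  draws (under which the published mixing experiment could not have been
  genotyped at all).
* **Background barcodes** (default: as many as cells, at 5% depth) draw
  ambient reads whose per-variant alternate fraction is the
  clone-proportion-weighted expected VAF — an ambient pool of lysed-cell
  DNA.

What it does **not** emulate: sequencing errors and misalignment (the
alt-read filter's real target), barcode collisions, GC- or
fragment-length-dependent efficiency trends (only a static per-amplicon
factor), chimeric PCR products, and cell-cycle DNA content. Passing tests
therefore demonstrate that the *rules and estimators are implemented
correctly and are consistent with their own model*, not that the model
captures every failure mode of real libraries.

## Problem sizes and numerical choices

Validation runs use sizes where the checked property is several standard
errors wide: 10,000 nuclei × 20 SNPs for ADO (binomial SE ≈ 0.09 points);
4,000 droplets × 200 replicates for doublet recovery; 12,000 normal cells
(4,000 per norm_a/b/c group) for the diploid-baseline validation, where
per-amplicon group medians have SE ≈ 0.02 so the [1.9, 2.1] band is a
≥ 5σ statement. Medians use R's default midpoint-of-central-order-statistics
tie handling. Cells with zero total reads are excluded from normalization
medians and flagged rather than imputed; amplicons whose baseline median
is zero yield NA ploidy with a warning rather than infinities. The doublet
likelihood clamps category probabilities at 10⁻¹² to keep boundary
evaluations finite; the bootstrap CI is widened, if necessary, to contain
the point estimate. All simulation and bootstrap entry points take integer
seeds and are bit-reproducible given them.

## Known limitations

* Genotyping thresholds trade dropout-induced false WT calls against
  contamination-induced false positives; clone fractions inherit a small
  downward bias (visible in the README example: 28.1% called vs 30%
  simulated).
* The ADO estimate is an upper bound on technical dropout when real
  mono-allelic CNV states are present.
* The doublet model assumes independent constituent draws and cannot see
  same-population doublets; its estimate is a mild lower bound under ADO
  and near-boundary VAFs.
* Ploidy is relative to the within-cell average copy number and to the
  chosen baseline; broad aneuploidy distorts it, and no segmentation or
  allele-specific copy number is attempted.
* Clustering on the combined SNV + homdel features is left to external
  tools; the package only constructs the feature matrix.
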