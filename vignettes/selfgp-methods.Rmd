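---
title: "Methods: self-training for genomic prediction of residual feed intake"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: self-training for genomic prediction of residual feed intake}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the models implemented by `selfgp`, the assumptions
behind them, and the design decisions taken where more than one reasonable
choice existed. It is the companion to the function documentation: the *what*
lives there, the *why* lives here.

## The prediction problem

Residual feed intake (RFI) is the deviation of an animal's feed intake from
the expectation given its production level, body maintenance and management
environment; lower RFI means better feed efficiency. It is expensive to
measure — daily dry-matter intake (DMI) over a lactation — so reference
populations for genomic prediction of RFI are small (hundreds of animals),
while genotyped-but-unmeasured animals from the same breeding populations
number in the thousands. `selfgp` implements the self-training strategy that
tries to convert that imbalance into accuracy: label the unmeasured animals
with the model's own predictions, then retrain on everything.

## The RFI phenotype model

Per-animal phenotypes are derived from weekly DMI records with the linear
mixed model

$$ y = \mu + YSC + ParAge + \beta_1\,dim + \beta_2\,MilkE + \beta_3\,MBW
   + ration + e, $$

where $y$ is weekly DMI (kg/day), $YSC$ (year-season of calving) and
$ParAge$ (parity-by-age class) are fixed factors, $dim$ (days in milk),
$MilkE$ (energy in milk, Mcal/day) and $MBW$ (metabolic body weight,
$BW^{0.75}$, kg) are fixed covariates, $ration \sim N(0, I\sigma_r^2)$ is a
random feeding-cohort effect and $e \sim N(0, I\sigma_e^2)$ the residual.
Weekly RFI estimates are the residuals $\hat e$; an animal's RFI phenotype
is the unweighted arithmetic mean of its weekly residuals (no
minimum-week filter is applied, and animals with unequal numbers of weeks
are handled naturally by the per-record model).

Decisions taken here:

* **Parameterization.** Fixed factors use sum-to-zero contrasts with an
  explicit intercept. Any full-rank parameterization yields identical
  residuals — which is all that downstream stages consume — and the test
  suite verifies residual invariance against a treatment-contrast
  generalized-least-squares fit.
* **REML by one-dimensional profiling.** With a single random effect the
  restricted likelihood can be profiled down to the variance ratio
  $\gamma = \sigma_r^2/\sigma_e^2$; `fit_rfi_model()` maximizes it by
  bounded search on $\gamma \in [0, 10^3]$ with tolerance $10^{-8}$,
  evaluating each candidate in closed form via a diagonal Woodbury downdate
  (the cohort incidence matrix has orthogonal columns). The boundary
  $\gamma = 0$ is compared explicitly against the interior optimum. This is
  robust, dependency-free and exactly reproducible; `lme4` serves as an
  independent cross-check oracle in the tests, never as the implementation.
* **Degenerate inputs.** Rank-deficient fixed-effect designs raise an error
  naming the confounded columns; records with factor levels unseen at fit
  time raise an error rather than receiving a silent zero effect; fewer than
  two cohorts is an error because $\sigma_r^2$ would be unidentifiable.

## Genotype quality control

Markers are biallelic SNPs coded 0/1/2 as copies of the counted allele, with
missing entries allowed. QC runs in a fixed order: orient every marker to
count its **minor** allele (flip $g \mapsto 2-g$ when the counted-allele
frequency exceeds 0.5; exactly 0.5 is left alone), remove markers with
minor-allele frequency **strictly below** the threshold (default 5%) or with
all genotypes missing, then impute remaining missing genotypes as
$\mathrm{round}(2p_j)$ — the rounded expected allele count.

* Frequencies are always computed over non-missing entries *before*
  imputation, so imputed values can never feed back into the filter.
* Rounding halves ($2p = 0.5$ or $1.5$) go **up**; "rounded allele
  frequencies" fixes the rule only up to tie behavior, so the tie-break is
  documented and tested rather than left to platform rounding.
* Imputation defaults to within-dataset frequencies; a frequency table from
  an external reference population can be supplied instead
  (`impute_missing(G, frequencies = ...)`), which is the appropriate choice
  when one exists for the breed.
* The pipeline `recode -> filter -> impute` is idempotent, which the suite
  checks directly.

## The base predictor and self-training

The shipped learner is $\varepsilon$-insensitive support-vector regression
with RBF kernel (via `e1071`). Defaults are the library's documented
defaults — cost $C = 1$, $\gamma = 1/\text{n\_markers}$,
$\varepsilon = 0.1$ — with tuning **off** by default: a reproducible
baseline first, an opt-in seeded 5-fold grid search
($C \in \{0.25, 1, 4\}$, $\gamma$ multipliers $\{0.25, 1, 4\}$) for those
who want it. Marker columns are standardized by training-set statistics,
reapplied verbatim at prediction time; monomorphic columns are set to zero
rather than dropped so that marker sets stay aligned between labeled,
unlabeled and test matrices.

Self-training is exactly three steps: fit $f$ on $(G_1, P_1)$; predict
$\hat P_2 = f(G_2)$; refit on the plain concatenation with equal weight per
animal — no confidence filtering or weighting, and a single relabel-retrain
round. The identical predictor specification (including tuning mode) is
re-run at step 3; whether hyperparameters should instead be frozen from $f$
is not determined by the procedure's description, and re-running the spec is
the choice that treats step 3 as the same training problem on more data.
With an empty unlabeled set the procedure provably reduces to supervised
learning, and the suite requires agreement within $10^{-9}$.

A practical note the implementation surfaces honestly: a self-training model
learns from its own predictions, so nothing guarantees improvement on
arbitrary data — a weak base predictor can reinforce its own mistakes. The
test suite therefore asserts *non-inferiority* of the augmented predictor on
simulated data (mean test correlation within 0.005 of the supervised
baseline over 50 replicates) and reports the measured paired gain, rather
than asserting a gain that no theory promises.

## Validation designs

All experiment drivers share three conventions:

* **Pairing.** Within a replicate, $f$ and $f^*$ are trained from the same
  labeled draw and evaluated on the identical fixed test set; accuracy
  differences are paired differences.
* **Seed streams.** Every replicate of every setting derives its seed from
  the master seed and a label (`stream_seed()`), so a single cell can be
  re-run bit-identically without re-running the grid.
* **Intervals.** 95% confidence intervals use the $t$ distribution with
  $n_{\text{rep}} - 1$ degrees of freedom (a normal-quantile option exists).
  The interval machinery itself is validated by a coverage experiment on
  synthetic normal replicates.

The **plateau search** grows the self-trained set in increments (default
200 animals) and stops, per replicate, at the first step whose correlation
improvement falls below the tolerance — default $10^{-4}$, i.e. 0.01% on
the percentage scale on which genomic-prediction accuracies are
conventionally quoted, applied per replicate. Increments are *nested* (each
step adds animals to the previous draw), which makes successive steps differ
only by the added animals and reduces the variance of the stopping rule; a
tolerance of zero is the documented way to disable early stopping and run to
pool exhaustion (which is always flagged in the output). The search never
evaluates a step beyond the stopping point, and an oracle test replays the
stopping decision by brute force over the same seeded sequence.

## The simulator

`simulate_population()` generates the statistical structure the pipeline
assumes, so that every stage is testable without any external data:
independent biallelic loci in Hardy-Weinberg proportions with frequencies
uniform on `maf_range`, `n_qtl` additive QTL effects rescaled so that the
sample variance of breeding values is exactly $h^2 V$, the full
fixed/random-effect structure of the RFI model (19 year-season and 20
parity-age levels by default, 81 ration cohorts carrying 10% of variance),
weekly records over one 20-week lactation in the 50–200 days-in-milk
window, and birth dates placing a configurable fraction of animals
(default 252/792) after the train/test split date.

Variance is partitioned on the **per-animal** scale: heritability (default
0.15, the conventional estimate for RFI) is the genetic fraction of the
per-animal deviation variance, and the residual splits into a permanent
animal deviation plus week-to-week noise (`week_noise_fraction`, default
0.5) calibrated so that averaging an animal's weekly residuals reproduces
the configured partition exactly. This makes heritability recovery a sharp
test: the realized genetic-variance fraction at $n = 2000$ must sit within
±0.03 of the configured value.

What the simulator deliberately does **not** emulate: linkage
disequilibrium (loci are independent by default, which keeps closed-form
checks possible; an LD panel would mostly change the effective number of
independent loci), pedigree structure and selection, non-additive effects,
and genotyping-array artifacts. The genetic architecture of RFI itself
(number and size of QTL) is unknown; `n_qtl = 200` is a placeholder, not an
estimate. Consequently, passing tests demonstrate that the machinery is
correct under its stated assumptions — not that self-training will improve
accuracy on any particular real dataset, where the labeled/unlabeled
populations may differ systematically in ways the simulator does not model.

## Problem sizes

The default desk-scale sizes — 2000-marker panels, populations of 700–2000
animals, 20–50 replicates per setting in the test suite and acceptance
script — were chosen as the smallest sizes at which each property is
comfortably identifiable (variance-ratio recovery needs ~80 cohorts,
heritability recovery ~2000 animals, learning-curve ordering ~50
replicates). The full study-scale defaults (100 replicates, sizes 20–540,
~50k markers) remain the documented defaults of `experiment_config()` and
`sim_params()` and run unchanged, just longer.

## Known limitations

* Only one random effect is supported in the RFI model; repeated lactations
  or an animal genetic effect inside the phenotype model are out of scope.
* Milk energy is consumed as a supplied covariate; its computation from
  fat/protein/lactose percentages belongs to data preparation upstream.
* The predictor contract is open (any fit/predict learner can stand in for
  the SVR), but only the SVR ships; no random-forests implementation is
  included.
* VCF input uses the GT field of biallelic SNP records only; phasing,
  dosage fields and multi-allelic sites are ignored (the latter with a
  reported count).
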