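---
title: "Methods: CTC phenotyping, Poisson model selection and single-cell EMT scoring"
author: "ctcemt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CTC phenotyping, Poisson model selection and single-cell EMT scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctcemt)
```

# Overview

`ctcemt` implements an analysis chain for studies of circulating tumour
cells (CTCs) across the epithelial–mesenchymal transition (EMT) spectrum in
early breast cancer:

1. **Phenotype calling** of putative CTCs from thresholded
   immunofluorescence marker panels, with proportional extrapolation of
   counts to the full 5 mL blood draw and the spike-in performance metrics
   of the isolation procedure.
2. **Multi-response Poisson regression model selection**: an exhaustive
   search over predictor subsets scored by repeated 10-fold
   cross-validation, with incidence rate ratios (IRRs), Wald intervals, and
   a Nagelkerke pseudo-R² variance decomposition.
3. **Single-cell stages**: quality filtering, cell-origin classification
   (true CTC / potential normal cell / true normal cell), per-cell EMT
   scoring with quartile classes, and rule-based differential expression
   (DEG) calling on median-of-ratios normalized counts.
4. A **synthetic-data module** that generates cohort tables and
   overdispersed count matrices with the statistical structure the
   downstream stages assume, so the whole chain is testable without patient
   data.

The numbered scripts under `analysis/` run these stages in order and write
their tables under `results/`; every computation they perform lives in the
package and is unit-tested.

# Phenotype calling

A cell is a CTC only if the hematopoietic (CD45) and endothelial (CD31)
exclusion markers are absent, nuclear DAPI uptake is absent (dead cells take
up DAPI), and at least one cancer marker is present. The epithelial axis is
positive when EpCAM or E-cadherin is detected; the mesenchymal axis when
cell-surface vimentin or MCAM is detected. The three phenotypes are
epithelial-only (`eCTC`), doubly positive (`emCTC`) and mesenchymal-only
(`mCTC`). Two conventions worth making explicit:

* DAPI positivity is a *hard* exclusion — the assay targets living cells.
* EpCAM⁺/ECAD⁻ and ECAD⁺/EpCAM⁻ cells are not distinguished; either marker
  makes the epithelial axis positive.

When only a fraction $f \in (0, 1]$ of the enriched sample is screened, the
observed count $c$ is extrapolated as $c / f$, so per-patient counts are
comparable across samples and may be fractional (a median such as 1.1 mCTCs
per 5 mL is a legitimate product of this scaling). `screened_fraction` is an
input supplied per sample, not derived from volumes.

Spike-in performance metrics are plain ratios: the enrichment factor is
(cells after enrichment)/(cells before), its complement the depletion rate,
and the recovery rate is (spiked cells recovered)/(cells spiked). The qPCR
relative quantity is $RQ = 2^{Cq_{max} - Cq}$ with $Cq_{max} = 35$ the last
cycle considered quantifiable; undetected reactions and cycles beyond
$Cq_{max}$ give $RQ = 0$.

# The count model and its selection

## Model

Per-phenotype CTC counts $y_{i r}$ for patient $i$ and response
$r \in \{\text{eCTC}, \text{emCTC}, \text{mCTC}\}$ are modelled as
independent Poisson variables with a log link,

$$\log \mathbb{E}[y_{ir}] = \beta_{0r} + \sum_j x_{ij}\, \beta_{jr},$$

one regression per response on a *shared* predictor subset. "Multi-response"
is realized as three independent fits whose joint log-likelihood is the sum
of the three per-response log-likelihoods; no cross-response covariance is
modelled (the reported quantities — per-response IRRs and one overall R² —
are consistent with this construction). $\exp(\beta_{jr})$ is the incidence
rate ratio: the multiplicative change in the expected count when the
predictor is present. Confidence intervals and p-values are Wald
constructions from the coefficient and its standard error
($z = 1.959964$ at 95%). Fractional extrapolated counts are rounded half-up
before fitting (the Poisson likelihood requires integers); descriptive
statistics keep the fractions.

Fitting uses iteratively reweighted least squares with a tight convergence
tolerance. Two guards matter in sparse cohorts: non-convergence within 100
iterations, and any $|\beta| > 15$ — a practical flag for quasi-separation,
where a covariate level with all-zero counts drives a coefficient to
$-\infty$.

## Exhaustive search under repeated cross-validation

All $2^p$ subsets of the candidate predictors are enumerated in a fixed
order (binary expansion over candidate index), so reports are reproducible.
Subsets containing a flagged predictor pair — pairs known to produce
convergence pathologies, such as grade together with nodal status in the
motivating study — are kept in the ranking table but never compete.

Each competing subset is scored by $k$-fold cross-validation ($k = 10$)
repeated `reps` times (500 by default) with fresh random partitions. Per
fold the package records:

* the held-out joint log-likelihood,
* the training-fit joint AIC ($2k - 2\,\text{logLik}$),
* the RMSE of predicted means against observed counts, on the *count
  scale*, pooled over the three responses within the fold.

Metrics are averaged over folds within a repetition, then over repetitions.
The count-scale pooled RMSE is one defensible reading of an RMSE criterion
that is not otherwise pinned down; it has the useful property that
separation-driven pathologies surface as abnormally large `avg.RMSE`.

Ranking is lexicographic: minimum `avg.RMSE`, ties broken by maximum
`avg.logLik`, then minimum `avg.AIC`. The RMSE-first order is the documented
tie-break; in practice the three criteria rarely disagree on well-behaved
cohorts.

**Failed folds.** A fold in which any response fit fails (rank deficiency,
non-convergence, the separation guard) contributes nothing to the averages.
The API default excludes a specification on *any* failed fold — the
conservative reading. The pipeline's default configuration instead tolerates
up to 10% failed folds, because at a cohort size near 100 with a strong,
sparse response (an IRR above 10 on a response whose baseline rate is well
below one count per patient), random partitions sporadically produce
training folds with an all-zero level; excluding on a single such fold would
disqualify every specification containing the dominant predictor, which is
not how such models behave (or are reported) on real cohorts — fully
separated levels there surface as extreme IRRs with unbounded intervals
rather than as dropped models. The tolerance is configuration, visible in
every report.

## Variance decomposition

For log-likelihoods $\ell_1$ (fitted model) and $\ell_0$ (intercept-only
model) on $n$ patients, the Nagelkerke pseudo-R² is

$$R^2 = \frac{1 - \exp\!\big(\tfrac{2}{n}(\ell_0 - \ell_1)\big)}
             {1 - \exp\!\big(\tfrac{2}{n}\,\ell_0\big)} \in [0, 1).$$

The overall value uses the joint (summed) log-likelihoods with $n$ the
number of patients — not patients × responses. Per response, the partial
pseudo-R² of predictor $j$ is the drop in that response's R² when $j$ is
removed from the full model, both R²s computed against the response's own
null; a likelihood-ratio test of the removed predictor supplies the
accompanying p-value. For a single-predictor model the partial equals the
response's overall R² by construction.

# Single-cell stages

## Quality control and cell origin

Cells enter the analysis only with at least 800 detected genes (count > 0;
the boundary is inclusive) and, upstream of sequencing, at least two of the
three housekeeping genes (EEF1A1, ACTB, GAPDH) detected in the control
multiplex PCR.

Cell origin combines the protein panel a cell was picked on with its
transcripts. Protein-negative cells (no epithelial or mesenchymal marker)
are true normal cells (`tNC`) regardless of transcripts — the protein rule
dominates. Protein CTC-positive cells are true CTCs (`tCTC`) when every
configured immune/endothelial transcript marker sits strictly below the
expression threshold, and potential normal cells (`pNC`) when any marker
reaches it. The threshold defaults to 4 on size-factor-normalized
expression; both the value and its input scale are configuration because
the underlying convention is a display-level choice, not a stated unit. The
marker list defaults to PTPRC (CD45) and PECAM1 (CD31) and is deliberately
user-extensible; the configured list is echoed into every report. A panel
that is simultaneously cancer-marker- and CD45/CD31-positive is
contradictory and is an error rather than a silent class.

## EMT score and quartile classes

On reads-per-million (RPM) normalized expression, with the 10-gene panel
(mesenchymal: FN1, CDH2, SERPINE1; epithelial: KRT5, KRT7, KRT8, KRT18,
KRT19, EPCAM, CDH1),

$$\text{score} = \frac{\sum_{g \in M} \log_{10}(\text{RPM}_g + 1)
                    - \sum_{g \in E} \log_{10}(\text{RPM}_g + 1)}{10},$$

so positive scores indicate mesenchymal character. Panel genes missing from
the matrix (filtered upstream) contribute zero with a warning, not an
error. Quartiles of the score distribution *of the population being
classified* set the classes: strictly below Q1 epithelial-like, strictly
above Q3 mesenchymal-like, the rest intermediate. Quartiles use linear
interpolation between order statistics (plotting position $(k-1)/(n-1)$,
`stats::quantile` type 7). The convention is an argument and is recorded in
the output, because conventions can move tail membership by one cell on
small populations; strict inequalities mean constant score vectors
degenerate safely to all-intermediate.

## Normalization and DEG calling

Size factors are median-of-ratios: per cell, the median over reference
genes of the ratio of the cell's count to the gene's geometric mean across
cells. Reference genes are those nonzero in every cell; under dropout heavy
enough that none exist, the procedure falls back to genes nonzero in at
least half the cells (geometric means over their positive counts) and
reports that it did. The implementation is cross-checked in the test suite
against an independent reference implementation of the same estimator.

Before testing, genes on the bundled erythroid (n = 138) and platelet
(n = 173) exclusion panels are removed — these transcripts ride into CTC
preparations as ambient background. The bundled lists are synthetic
stand-ins sized like the published cell-atlas clusters: a core of genuine
marker symbols padded with clearly synthetic placeholders, because the full
cluster lists are not reproduced in any bundled source. Analyses of real
data should substitute the real lists; the files say so.

DEG calling is deliberately rule-based: per gene, a two-sided
equal-variance Student t-test on $\log_2(\text{normalized} + 1)$ between
groups (Welch available behind a flag), a fold change
$\log_2\!\big(\tfrac{\text{median}_A + 1}{\text{median}_B + 1}\big)$ of
group medians with a pseudocount of 1 (per-cell ratios are undefined across
unpaired cells; the pseudocount guards division by zero), and the call rule:
*down* if $\log_2 FC \le -1$ and significant, *up* if $\ge 1$ and
significant, otherwise unchanged. Significance gates on the raw p-value at
0.05 for discovery-style analyses and on the Benjamini–Hochberg adjusted
value in validation mode. Genes with zero variance in both groups have no
defined test; they are flagged and never called. The test's input scale
(log2 of normalized counts plus one) is a package decision — the convention
is not pinned down by the rule itself.

# The synthetic-data generator

The generator defines the conditions under which every downstream stage is
tested; it is first-class, tested code, not a fixture.

**Cohorts.** Binary clinical covariates are independent Bernoulli draws at
configured prevalences (an optional sampler hook admits correlated designs;
real clinical covariates are correlated, which is exactly why the
motivating analysis excluded some predictors — independence is the neutral
default, not a claim). Counts are Poisson with log-mean
$\text{baseline} + X\beta$, the exact generative inverse of the fitted
model, with ground truth returned alongside the table. The pipeline default
is a 104-patient cohort with Table-style IRRs (a ~14-fold lymph-node effect
on eCTCs, ~2.2–2.9-fold effects elsewhere, strong lobular-histology
deficits) and baseline rates of 0.1 / 0.15 / 0.5 expected
eCTC / emCTC / mCTC per 5 mL — chosen once so that epithelial counts are
sparse, mesenchymal counts dominate, and the median patient carries 0/0/~1
counts. A Poisson marginal cannot simultaneously reproduce a ~50% zero
fraction and a heavy-tailed mean near 4 as real, overdispersed cohorts
show; the synthetic cohort is therefore calibrated by configuration, not
matched to any cohort's descriptive table.

**Expression matrices.** Per-gene baseline means are log-normal; each cell
class multiplies the baselines of selected gene panels by $2^{\text{shift}}$
(defaults: epithelial genes up in epithelial-like cells, mesenchymal genes
up and ribosomal genes down ($2^{-2}$) in mesenchymal-like cells, immune
genes up in leukocytes and strongly down in tumour classes). Counts are
negative binomial — scRNA-seq counts are overdispersed — parameterized by
mean and a size-like `dispersion` such that the variance is
$\mu + \mu^2/\text{dispersion}$; the Poisson limit is recovered as
dispersion grows, which the tests verify as a moment check. Bernoulli
dropout then zeroes entries independently. The generator does *not*
simulate read-level data, batch effects or doublets, so passing tests
demonstrate correct statistical behaviour of the pipeline under its own
assumptions, not robustness to those artefacts.

All randomness flows from one global seed through deterministically derived
per-stage streams; fixed seed means bit-identical outputs.

# Numerical choices and degenerate inputs

* IRLS convergence: deviance tolerance $10^{-12}$, 100 iterations; the
  separation guard flags $|\beta| > 15$.
* Rank-deficient designs are errors in direct fits and flagged failures
  inside cross-validation folds.
* Counts are rounded half-up (`floor(x + 0.5)`) before Poisson fitting.
* Quartile ties and constant vectors: strict comparisons, degenerate inputs
  classify as intermediate.
* Zero-total cells are errors in RPM normalization (named in the message);
  all-zero genes are fine everywhere.
* Sub-seeds for stage streams stay below $2^{31}$ (R integers are 32-bit).

# Problem sizes used in the tests

The test suite exercises the machinery at sizes chosen to make Monte-Carlo
error small relative to the asserted tolerances while keeping a laptop-scale
run: parameter-recovery at $n = 10^4$–$2 \times 10^4$ patients, Wald
coverage over 200 replicates of $n = 1000$, selection consistency over 20
cohorts of $n = 300$ with 50 cross-validation repetitions (scaled down from
the 500 used in production runs), and DEG calibration on 2000 null genes.
The acceptance script re-runs the same computations at comparable sizes
from a caller-supplied seed.

# Known limitations

* Independent-Poisson responses ignore any cross-response covariance;
  patients shedding many cells of one phenotype plausibly shed more of the
  others too.
* No negative-binomial or zero-inflated count alternatives, mixed effects,
  or Bayesian fits; no multiplicity correction of the Wald p-values.
* The quartile convention, immune-marker list and the "<4" expression
  threshold are conventions, not discoveries; results near class boundaries
  move with them, which is why each is configuration echoed into reports.
* The synthetic single-cell matrix has block-structured panels and
  independent dropout — adequate for testing rank/threshold logic and
  score recovery, far simpler than real Smart-seq2 data.
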