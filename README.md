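# ctcemt

Analysis pipeline for circulating tumour cell (CTC) studies across the
epithelial–mesenchymal transition (EMT) spectrum in early breast cancer.

CTCs are cancer cells detected in peripheral blood. EMT changes their
surface markers, so detection uses a combined panel — epithelial (EpCAM,
E-cadherin), mesenchymal (cell-surface vimentin, MCAM) and exclusion
markers (CD45, CD31, DAPI) — yielding three phenotypes: epithelial
(`eCTC`), epithelial–mesenchymal (`emCTC`) and mesenchymal (`mCTC`).
This package implements, as tested R functions:

* **Phenotype calling** from thresholded marker panels, proportional
  extrapolation of counts to the 5 mL blood draw, spike-in performance
  metrics (enrichment/depletion, recovery rate) and the qPCR transform
  `RQ = 2^(Cq_max − Cq)` with `Cq_max = 35`.
* **Count modelling**: per-phenotype counts `y_ir ~ Poisson` with
  `log E[y_ir] = β_0r + Σ_j x_ij β_jr`, one regression per response on a
  shared predictor subset. All `2^p` predictor subsets are scored by
  repeated 10-fold cross-validation (avg.RMSE / avg.logLik / avg.AIC,
  averaged over folds then repetitions) and ranked RMSE-first; the winner
  is reported as incidence rate ratios `exp(β)` with 95% Wald intervals
  and a Nagelkerke pseudo-R² decomposition (overall, per response, and
  partial per predictor).
* **Single-cell stages**: ≥800-detected-genes QC, tCTC/pNC/tNC cell-origin
  classification from combined protein + transcript evidence, the 10-gene
  EMT score `(Σ_M log10(RPM+1) − Σ_E log10(RPM+1)) / 10` with quartile
  classes (`< Q1` epithelial-like, `> Q3` mesenchymal-like),
  median-of-ratios normalization, erythroid/platelet marker exclusion and
  rule-based DEG calling (Student t-test on log2 counts, `|log2FC| ≥ 1`
  on group medians).
* **Synthetic data**: generators for cohort tables (Poisson counts under a
  configurable log-linear covariate model) and overdispersed single-cell
  count matrices with marker-panel structure and dropout, so the whole
  chain runs and is tested without patient data.

The methods vignette (`vignettes/ctc-emt-methods.Rmd`) documents the
models, conventions and limitations in detail.

## Worked example

The numbered scripts under `analysis/` run the pipeline on synthetic data
and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R 1        # cohort + single-cell matrix
Rscript analysis/02_model_selection.R 1 # exhaustive CV model selection
Rscript analysis/03_single_cell.R 1     # QC, origin, EMT score, DEGs
```

Stage 2 prints, for the default 104-patient synthetic cohort (seed 1):

```
winner: cT234 + cNpos + lobular
overall Nagelkerke pseudo-R2: 0.788

IRRs with 95% Wald intervals:
  response    term    irr ci_low ci_high  p_value
1     eCTC   cT234  0.656 0.4081   1.055 8.21e-02
2     eCTC   cNpos 24.416 7.6764  77.659 6.22e-08
3     eCTC lobular  0.138 0.0337   0.567 6.00e-03
...
7     mCTC   cT234  2.031 1.4244   2.897 9.10e-05
8     mCTC   cNpos  2.239 1.6005   3.131 2.51e-06
9     mCTC lobular  0.198 0.0926   0.424 3.02e-05
```

Reading this: the cross-validated search over all 16 predictor subsets
picked tumour size + nodal status + histological type. Nodal involvement
(`cNpos`) is the dominant predictor — node-positive patients have ~24× the
expected eCTC count and ~2.2× the mCTC count of node-negative patients —
while lobular histology strongly reduces mesenchymal counts. The joint
model explains ~79% of count variability (Nagelkerke pseudo-R²). These
estimates recover the IRR structure the generator was configured with,
which is the point of the synthetic run.

Stage 3 prints the single-cell arm:

```
cell-origin labels:
tCTC  pNC  tNC
  30    0   20

EMT score range -2.02 .. 0.56; classes: eCTC=13, intermediate=24, mCTC=13

DEGs (tCTC vs tNC): 16 down, 8 up of 600 genes tested
```

All 30 simulated tumour cells classify as true CTCs (their immune
transcripts sit below the threshold), the 20 leukocytes as true normal
cells, and the EMT quartile classes split the scored population into the
expected tails.

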