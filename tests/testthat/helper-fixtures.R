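# Shared fixtures, built in code at test time.

# Full marker-panel truth table: all 2^7 boolean combinations.
all_marker_panels <- function() {
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), 7))
  names(grid) <- c("epcam", "ecad", "csvim", "mcam", "cd45", "cd31", "dapi")
  grid
}

# One marker panel row with the named fields set TRUE.
panel_row <- function(...) {
  p <- c(epcam = FALSE, ecad = FALSE, csvim = FALSE, mcam = FALSE,
         cd45 = FALSE, cd31 = FALSE, dapi = FALSE)
  pos <- c(...)
  p[pos] <- TRUE
  p
}

# Toy cohort: one binary predictor, known counts per group.
toy_cohort <- function() {
  data.frame(
    patient_id = sprintf("P%02d", 1:5),
    x = c(0, 0, 0, 1, 1),
    eCTC = c(1, 2, 3, 4, 6),
    emCTC = c(0, 1, 1, 2, 3),
    mCTC = c(2, 2, 4, 5, 7)
  )
}

# Strong two-predictor generative cohort used by the selection and coverage
# simulations: both cT- and cN-like predictors raise all three phenotype
# counts, the two remaining candidates are pure noise.
strong_cohort_config <- function(n, seed) {
  effects <- c(cT234 = log(2.2), cNpos = log(2.8), grade3 = 0, lobular = 0)
  cohort_config(
    n_patients = n,
    predictor_prevalences = c(cT234 = 0.5, cNpos = 0.4,
                              grade3 = 0.3, lobular = 0.15),
    true_log_irr = rbind(eCTC = effects, emCTC = effects, mCTC = effects),
    baseline_log_rate = c(eCTC = 0, emCTC = 0, mCTC = 0),
    seed = seed
  )
}

# Small single-cell count matrix with named genes and cells.
toy_counts <- function(genes = 6, cells = 4, seed = 42, lambda = 5) {
  set.seed(seed)
  m <- matrix(rpois(genes * cells, lambda), nrow = genes,
              dimnames = list(sprintf("G%02d", seq_len(genes)),
                              sprintf("c%02d", seq_len(cells))))
  m
}
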