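#' Call CTC EMT phenotypes from an immunofluorescence marker panel
#'
#' Classifies putative circulating tumour cells (CTCs) from already-thresholded
#' protein marker signals. A cell qualifies as a CTC only when the
#' hematopoietic (CD45) and endothelial (CD31) exclusion markers are absent,
#' the nuclear DAPI stain is absent (surface DAPI uptake marks dead cells),
#' and at least one cancer marker is present. Among CTCs, the epithelial axis
#' is positive when EpCAM or E-cadherin (ECAD) is detected, the mesenchymal
#' axis when cell-surface vimentin (csVIM) or MCAM is detected:
#' epithelial-only cells are `eCTC`, mesenchymal-only `mCTC`, and doubly
#' positive cells `emCTC`.
#'
#' @param panel a data frame (one row per cell) or a named logical vector with
#'   entries `epcam`, `ecad`, `csvim`, `mcam`, `cd45`, `cd31`, `dapi`. All
#'   fields must be `TRUE`/`FALSE`; missing values are rejected.
#'
#' @return a data frame with one row per cell and columns `label` (factor with
#'   levels `eCTC`, `emCTC`, `mCTC`, `not_CTC`) and `reason` (character,
#'   a short account of the decisive rule).
#'
#' @examples
#' call_phenotype(c(epcam = TRUE, ecad = FALSE, csvim = FALSE, mcam = FALSE,
#'                  cd45 = FALSE, cd31 = FALSE, dapi = FALSE))
#' @export
call_phenotype <- function(panel) {
  fields <- c("epcam", "ecad", "csvim", "mcam", "cd45", "cd31", "dapi")
  if (is.logical(panel) && !is.null(names(panel))) {
    panel <- as.data.frame(as.list(panel))
  }
  if (!is.data.frame(panel)) {
    stop("`panel` must be a data frame or a named logical vector")
  }
  missing_fields <- setdiff(fields, names(panel))
  if (length(missing_fields) > 0L) {
    stop("marker panel is missing fields: ", paste(missing_fields, collapse = ", "))
  }
  p <- panel[fields]
  for (f in fields) {
    if (!is.logical(p[[f]]) || anyNA(p[[f]])) {
      stop("marker field `", f, "` must be TRUE/FALSE with no missing values")
    }
  }

  epi <- p$epcam | p$ecad
  mes <- p$csvim | p$mcam
  excluded <- p$cd45 | p$cd31 | p$dapi

  label <- rep("not_CTC", nrow(p))
  reason <- rep("no cancer marker detected", nrow(p))
  reason[excluded & (p$cd45 | p$cd31)] <- "exclusion marker (CD45/CD31) positive"
  reason[excluded & p$dapi & !(p$cd45 | p$cd31)] <- "DAPI positive (dead cell)"

  ctc <- !excluded & (epi | mes)
  label[ctc & epi & !mes] <- "eCTC"
  label[ctc & !epi & mes] <- "mCTC"
  label[ctc & epi & mes] <- "emCTC"
  reason[ctc & epi & !mes] <- "epithelial markers only"
  reason[ctc & !epi & mes] <- "mesenchymal markers only"
  reason[ctc & epi & mes] <- "epithelial and mesenchymal markers"

  data.frame(
    label = factor(label, levels = c("eCTC", "emCTC", "mCTC", "not_CTC")),
    reason = reason,
    stringsAsFactors = FALSE
  )
}

#' Extrapolate an observed CTC count to the full 5 mL blood sample
#'
#' When only part of the enriched sample is screened, the observed count is
#' scaled proportionally by the screened fraction so that counts are
#' comparable across patients. Fractional counts (e.g. a median of 1.1 mCTCs)
#' are legitimate outputs of this scaling.
#'
#' @param observed_count nonnegative count(s) of cells observed.
#' @param screened_fraction fraction(s) of the sample screened, in (0, 1].
#' @return `observed_count / screened_fraction`, a (possibly fractional) count
#'   per full sample.
#' @export
scale_to_volume <- function(observed_count, screened_fraction) {
  if (any(!is.finite(observed_count)) || any(observed_count < 0)) {
    stop("`observed_count` must be nonnegative and finite")
  }
  if (any(!is.finite(screened_fraction)) ||
      any(screened_fraction <= 0) || any(screened_fraction > 1)) {
    stop("`screened_fraction` must lie in (0, 1]")
  }
  observed_count / screened_fraction
}

#' Enrichment factor of a CTC isolation procedure
#'
#' Ratio of the number of background mononuclear cells remaining after
#' enrichment to the initial number; the companion depletion rate is
#' `1 - enrichment_factor(...)` (see [depletion_rate()]).
#'
#' @param cells_before initial cell count (> 0).
#' @param cells_after cell count after the enrichment procedure (>= 0).
#' @return the enrichment factor `cells_after / cells_before`.
#' @export
enrichment_factor <- function(cells_before, cells_after) {
  if (any(cells_before <= 0)) stop("`cells_before` must be positive")
  if (any(cells_after < 0)) stop("`cells_after` must be nonnegative")
  cells_after / cells_before
}

#' @rdname enrichment_factor
#' @export
depletion_rate <- function(cells_before, cells_after) {
  1 - enrichment_factor(cells_before, cells_after)
}

#' Recovery rate of spiked cells
#'
#' Fraction of tumour cells spiked into a blood sample that survive the
#' complete isolation procedure. Recovering more cells than were spiked is
#' possible in principle (counting error) and only raises a warning.
#'
#' @param recovered number of spiked cells recovered (>= 0).
#' @param spiked number of cells spiked (> 0).
#' @return `recovered / spiked`.
#' @export
recovery_rate <- function(recovered, spiked) {
  if (any(spiked <= 0)) stop("`spiked` must be positive")
  if (any(recovered < 0)) stop("`recovered` must be nonnegative")
  if (any(recovered > spiked)) {
    warning("more cells recovered than spiked; check counts")
  }
  recovered / spiked
}

#' Relative quantity from a qPCR quantification cycle
#'
#' Transforms quantification cycles (Cq) into relative quantities,
#' `RQ = 2^(cq_max - cq)`, with `cq_max` the last cycle considered in
#' quantitative analysis (default 35). Undetected reactions (`NA`) and Cq
#' values beyond `cq_max` yield an RQ of 0.
#'
#' @param cq numeric vector of quantification cycles; `NA` means undetected.
#' @param cq_max last quantifiable cycle (positive integer, default 35).
#' @return nonnegative relative quantities, same length as `cq`.
#' @examples
#' rq_from_cq(c(35, 25, NA))  # 1, 1024, 0
#' @export
rq_from_cq <- function(cq, cq_max = 35) {
  if (length(cq_max) != 1L || !is.finite(cq_max) || cq_max <= 0) {
    stop("`cq_max` must be a single positive number")
  }
  if (any(!is.na(cq) & cq <= 0)) stop("detected `cq` values must be positive")
  rq <- ifelse(is.na(cq) | cq > cq_max, 0, 2^(cq_max - cq))
  as.numeric(rq)
}

#' Per-patient CTC phenotype counts scaled to the full blood volume
#'
#' Aggregates per-cell phenotype calls into one row per patient with counts of
#' each phenotype per full sample, applying the proportional screening
#' extrapolation patient-wise.
#'
#' @param labels per-cell phenotype labels as returned by [call_phenotype()]
#'   (the `label` column), or any vector coercible to those levels.
#' @param patient_id per-cell patient identifiers, same length as `labels`.
#' @param screened_fraction a single fraction in (0, 1] or one per cell
#'   (constant within patient).
#' @return data frame with columns `patient_id`, `eCTC`, `emCTC`, `mCTC`
#'   (scaled, possibly fractional counts; `not_CTC` cells are dropped).
#' @export
count_phenotypes <- function(labels, patient_id, screened_fraction = 1) {
  labels <- factor(labels, levels = c("eCTC", "emCTC", "mCTC", "not_CTC"))
  if (anyNA(labels)) stop("`labels` contains values outside the phenotype set")
  if (length(patient_id) != length(labels)) {
    stop("`labels` and `patient_id` must have the same length")
  }
  frac <- rep_len(screened_fraction, length(labels))
  patients <- unique(patient_id)
  out <- data.frame(
    patient_id = patients, eCTC = 0, emCTC = 0, mCTC = 0,
    stringsAsFactors = FALSE
  )
  for (i in seq_along(patients)) {
    sel <- patient_id == patients[i]
    f <- unique(frac[sel])
    if (length(f) != 1L) {
      stop("`screened_fraction` must be constant within patient ", patients[i])
    }
    tab <- table(labels[sel])
    out$eCTC[i] <- scale_to_volume(as.numeric(tab[["eCTC"]]), f)
    out$emCTC[i] <- scale_to_volume(as.numeric(tab[["emCTC"]]), f)
    out$mCTC[i] <- scale_to_volume(as.numeric(tab[["mCTC"]]), f)
  }
  out
}

#' Cohort-level CTC positivity and phenotype prevalence
#'
#' Summarizes a per-patient table of phenotype counts into the standard
#' cohort descriptors: overall CTC positivity and the prevalence of patients
#' carrying a single phenotype only or a mixture.
#'
#' @param counts data frame with one row per patient and numeric columns
#'   `eCTC`, `emCTC`, `mCTC` (counts per sample; fractional counts allowed,
#'   any value > 0 marks the phenotype present).
#' @return a list with `n_patients`, `n_positive`, and percentages (0-100):
#'   `pct_positive`, `pct_eCTC_only`, `pct_emCTC_only`, `pct_mCTC_only`,
#'   `pct_mixed`.
#' @export
phenotype_prevalence <- function(counts) {
  needed <- c("eCTC", "emCTC", "mCTC")
  if (!all(needed %in% names(counts))) {
    stop("`counts` must contain columns eCTC, emCTC, mCTC")
  }
  pres <- sapply(needed, function(ph) counts[[ph]] > 0)
  pres <- matrix(pres, ncol = 3, dimnames = list(NULL, needed))
  n <- nrow(pres)
  n_pheno <- rowSums(pres)
  pct <- function(x) 100 * sum(x) / n
  list(
    n_patients = n,
    n_positive = sum(n_pheno > 0),
    pct_positive = pct(n_pheno > 0),
    pct_eCTC_only = pct(pres[, "eCTC"] & n_pheno == 1),
    pct_emCTC_only = pct(pres[, "emCTC"] & n_pheno == 1),
    pct_mCTC_only = pct(pres[, "mCTC"] & n_pheno == 1),
    pct_mixed = pct(n_pheno >= 2)
  )
}
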