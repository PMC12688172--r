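# Synthetic cohort and single-cell data generators. These define the study
# conditions every downstream stage is tested under: Poisson phenotype counts
# from a log-linear covariate model, and overdispersed (negative binomial)
# expression matrices with marker-panel structure and dropout.

PHENOTYPES <- c("eCTC", "emCTC", "mCTC")

# Derive independent per-stage integer seeds from one global seed so no stage
# consults ambient random state.
stream_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Configuration for the synthetic clinical cohort generator
#'
#' Describes a cohort of breast cancer patients with binary clinical
#' covariates and per-phenotype CTC counts drawn from a Poisson law with
#' log-mean `baseline + sum(covariate * log IRR)` — the generative inverse of
#' the multi-response Poisson regression fitted downstream.
#'
#' @param n_patients number of patients (positive integer).
#' @param predictor_prevalences named numeric vector of covariate prevalences,
#'   each in (0, 1); names define the covariates.
#' @param true_log_irr numeric matrix of log incidence-rate ratios with rows
#'   `eCTC`, `emCTC`, `mCTC` and one column per covariate (missing
#'   covariates default to 0).
#' @param baseline_log_rate named numeric vector of per-phenotype baseline
#'   log rates (names `eCTC`, `emCTC`, `mCTC`).
#' @param seed integer seed; all randomness in [generate_cohort()] flows from
#'   it through deterministic per-stage streams.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients,
                          predictor_prevalences,
                          true_log_irr = NULL,
                          baseline_log_rate = c(eCTC = 0, emCTC = 0, mCTC = 0),
                          seed = 1L) {
  stopifnot(length(n_patients) == 1L, n_patients >= 1)
  if (is.null(names(predictor_prevalences)) ||
      any(!nzchar(names(predictor_prevalences)))) {
    stop("`predictor_prevalences` must be a named vector")
  }
  if (any(predictor_prevalences <= 0) || any(predictor_prevalences >= 1)) {
    stop("all prevalences must lie strictly in (0, 1)")
  }
  preds <- names(predictor_prevalences)
  irr <- matrix(0, nrow = 3, ncol = length(preds),
                dimnames = list(PHENOTYPES, preds))
  if (!is.null(true_log_irr)) {
    if (!is.matrix(true_log_irr) || is.null(rownames(true_log_irr)) ||
        is.null(colnames(true_log_irr))) {
      stop("`true_log_irr` must be a matrix with phenotype rownames and predictor colnames")
    }
    if (!all(rownames(true_log_irr) %in% PHENOTYPES)) {
      stop("phenotype set is exactly {eCTC, emCTC, mCTC}")
    }
    if (!all(colnames(true_log_irr) %in% preds)) {
      stop("`true_log_irr` references unknown predictors")
    }
    irr[rownames(true_log_irr), colnames(true_log_irr)] <- true_log_irr
  }
  if (!all(PHENOTYPES %in% names(baseline_log_rate))) {
    stop("`baseline_log_rate` must name all of eCTC, emCTC, mCTC")
  }
  baseline_log_rate <- baseline_log_rate[PHENOTYPES]
  if (any(!is.finite(irr)) || any(!is.finite(baseline_log_rate))) {
    stop("log rates and log IRRs must be finite")
  }
  structure(
    list(
      n_patients = as.integer(n_patients),
      predictor_prevalences = predictor_prevalences,
      true_log_irr = irr,
      baseline_log_rate = baseline_log_rate,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' Generate a synthetic clinical cohort with per-phenotype CTC counts
#'
#' Covariates are drawn as independent Bernoulli variables at the configured
#' prevalences (an optional sampler hook supports correlated designs); counts
#' for each of the three CTC phenotypes are Poisson with log-mean
#' `baseline_log_rate + X %*% log IRR`. Ground-truth parameters travel with
#' the table so parameter-recovery tests need no side channel.
#'
#' @param config a [cohort_config()].
#' @param covariate_sampler optional function `(n, prevalences)` returning an
#'   n-by-p 0/1 matrix; defaults to independent Bernoulli draws. Use it to
#'   inject correlated covariates.
#' @return list with `cohort` (data frame: `patient_id`, one 0/1 column per
#'   covariate, `eCTC`, `emCTC`, `mCTC`) and `truth` (the config).
#' @export
generate_cohort <- function(config, covariate_sampler = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  seeds <- stream_seeds(config$seed, 2L)
  preds <- names(config$predictor_prevalences)
  n <- config$n_patients

  set.seed(seeds[1])
  if (is.null(covariate_sampler)) {
    X <- vapply(preds, function(p) {
      stats::rbinom(n, 1L, config$predictor_prevalences[[p]])
    }, integer(n))
    X <- matrix(X, nrow = n, dimnames = list(NULL, preds))
  } else {
    X <- covariate_sampler(n, config$predictor_prevalences)
    X <- as.matrix(X)
    if (nrow(X) != n || ncol(X) != length(preds)) {
      stop("covariate_sampler must return an n-by-p matrix")
    }
    colnames(X) <- preds
  }

  set.seed(seeds[2])
  counts <- sapply(PHENOTYPES, function(ph) {
    log_mu <- config$baseline_log_rate[[ph]] +
      as.numeric(X %*% config$true_log_irr[ph, ])
    stats::rpois(n, exp(log_mu))
  })
  counts <- matrix(counts, nrow = n, dimnames = list(NULL, PHENOTYPES))

  cohort <- data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    X, counts,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  list(cohort = cohort, truth = config)
}

#' Configuration for the synthetic single-cell expression generator
#'
#' @param n_cells_per_class named integer vector, e.g.
#'   `c(eCTC = 20, mCTC = 20, WBC = 20)`.
#' @param n_genes total number of genes, at least the number of panel genes.
#' @param panel_genes named list of disjoint gene-symbol vectors (e.g.
#'   epithelial, mesenchymal, immune, ribosomal, RBC, PLT panels).
#' @param mean_shift_log2 named list, one element per cell class, each a named
#'   numeric vector of log2 mean shifts keyed by panel name. Unlisted
#'   class/panel pairs shift by 0.
#' @param dispersion negative-binomial size parameter (> 0); the variance of a
#'   count with mean mu is `mu + mu^2 / dispersion`, so large values approach
#'   the Poisson limit.
#' @param dropout_rate probability in \[0, 1\] that any count is zeroed.
#' @param base_mean_log_mu,base_mean_log_sd log-normal parameters for per-gene
#'   baseline means (defaults give a median baseline of about 5 counts).
#' @param seed integer seed.
#' @return an object of class `cellsim_config`.
#' @export
cellsim_config <- function(n_cells_per_class,
                           n_genes,
                           panel_genes,
                           mean_shift_log2 = list(),
                           dispersion = 0.5,
                           dropout_rate = 0.3,
                           base_mean_log_mu = log(5),
                           base_mean_log_sd = 1,
                           seed = 1L) {
  if (is.null(names(n_cells_per_class))) {
    stop("`n_cells_per_class` must be named by cell class")
  }
  stopifnot(all(n_cells_per_class >= 1), n_genes >= 1)
  if (!is.list(panel_genes) || is.null(names(panel_genes))) {
    stop("`panel_genes` must be a named list of gene vectors")
  }
  all_panel <- unlist(panel_genes, use.names = FALSE)
  if (anyDuplicated(all_panel)) {
    stop("panels must be disjoint within a simulation")
  }
  if (n_genes < length(all_panel)) {
    stop("`n_genes` must be at least the total number of panel genes")
  }
  for (cls in names(mean_shift_log2)) {
    shifts <- mean_shift_log2[[cls]]
    if (is.null(names(shifts))) stop("mean shifts must be named by panel")
    unknown <- setdiff(names(shifts), names(panel_genes))
    if (length(unknown) > 0L) {
      stop("mean shift references unknown panel(s): ",
           paste(unknown, collapse = ", "))
    }
    empty <- names(shifts)[lengths(panel_genes[names(shifts)]) == 0L]
    if (length(empty) > 0L) {
      stop("mean shift references empty panel(s): ",
           paste(empty, collapse = ", "))
    }
  }
  stopifnot(dispersion > 0, dropout_rate >= 0, dropout_rate <= 1)
  structure(
    list(
      n_cells_per_class = n_cells_per_class,
      n_genes = as.integer(n_genes),
      panel_genes = panel_genes,
      mean_shift_log2 = mean_shift_log2,
      dispersion = dispersion,
      dropout_rate = dropout_rate,
      base_mean_log_mu = base_mean_log_mu,
      base_mean_log_sd = base_mean_log_sd,
      seed = as.integer(seed)
    ),
    class = "cellsim_config"
  )
}

#' Generate a synthetic gene-by-cell count matrix with marker structure
#'
#' Per-gene baseline means are log-normal; each cell class multiplies the
#' baseline of every gene in a shifted panel by `2^shift` (e.g. a ribosomal
#' shift of -2 in mesenchymal-like cells emulates the ribosomal-gene
#' depression seen in mesenchymal CTCs). Counts are negative binomial with the
#' configured dispersion, then thinned by Bernoulli dropout.
#'
#' @param config a [cellsim_config()].
#' @return list with `counts` (integer matrix, genes x cells), `cell_class`
#'   (character vector per cell), `panels` (the configured gene lists) and
#'   `truth` (per-class expected means and the config).
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "cellsim_config"))
  seeds <- stream_seeds(config$seed, 3L)

  panel_genes <- config$panel_genes
  all_panel <- unlist(panel_genes, use.names = FALSE)
  n_filler <- config$n_genes - length(all_panel)
  genes <- c(all_panel,
             if (n_filler > 0) sprintf("FILLER%05d", seq_len(n_filler)))
  gene_panel <- rep("none", length(genes))
  names(gene_panel) <- genes
  for (pn in names(panel_genes)) gene_panel[panel_genes[[pn]]] <- pn

  set.seed(seeds[1])
  base_mean <- stats::rlnorm(length(genes), config$base_mean_log_mu,
                             config$base_mean_log_sd)
  names(base_mean) <- genes

  classes <- names(config$n_cells_per_class)
  class_mean <- sapply(classes, function(cls) {
    mu <- base_mean
    shifts <- config$mean_shift_log2[[cls]]
    for (pn in names(shifts)) {
      idx <- gene_panel == pn
      mu[idx] <- mu[idx] * 2^shifts[[pn]]
    }
    mu
  })
  class_mean <- matrix(class_mean, nrow = length(genes),
                       dimnames = list(genes, classes))

  cell_class <- rep(classes, times = config$n_cells_per_class)
  n_cells <- length(cell_class)

  set.seed(seeds[2])
  counts <- matrix(0L, nrow = length(genes), ncol = n_cells,
                   dimnames = list(genes, sprintf("cell%04d", seq_len(n_cells))))
  for (j in seq_len(n_cells)) {
    counts[, j] <- stats::rnbinom(length(genes), size = config$dispersion,
                                  mu = class_mean[, cell_class[j]])
  }

  if (config$dropout_rate > 0) {
    set.seed(seeds[3])
    keep <- matrix(stats::rbinom(length(counts), 1L, 1 - config$dropout_rate),
                   nrow = nrow(counts))
    counts <- counts * keep
  }

  list(
    counts = counts,
    cell_class = stats::setNames(cell_class, colnames(counts)),
    panels = panel_genes,
    truth = list(class_mean = class_mean, config = config)
  )
}
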