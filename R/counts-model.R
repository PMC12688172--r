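# Exhaustive, repeated-cross-validated selection among multi-response Poisson
# regression models of per-phenotype CTC counts, with incidence-rate-ratio
# estimation and Nagelkerke pseudo-R-squared variance decomposition.

# Poisson fitting defaults: IRLS iteration cap and the practical separation
# guard on coefficient magnitude (|beta| above this marks non-convergence).
POISSON_MAX_ITER <- 100L
POISSON_BETA_MAX <- 15

round_half_up <- function(x) floor(x + 0.5)

#' Fit a single-response Poisson regression by IRLS
#'
#' Maximum-likelihood Poisson regression with a log link on an explicit design
#' matrix, via iteratively reweighted least squares (`stats::glm.fit`).
#' Non-convergence within the iteration cap, boundary fits, or any
#' coefficient with `|beta| > 15` (a practical quasi-separation guard) flag
#' the fit as not converged but retain it so model-exclusion logic can act on
#' it downstream.
#'
#' @param y nonnegative integer response vector.
#' @param X numeric design matrix (including the intercept column), full
#'   column rank; rank deficiency is an error.
#' @return list with `coefficients`, `se` (Wald standard errors from the
#'   observed Fisher information), `loglik`, `fitted`, `converged`, `k`
#'   (number of parameters).
#' @export
fit_poisson <- function(y, X) {
  X <- as.matrix(X)
  if (length(y) != nrow(X)) stop("length(y) must match nrow(X)")
  if (any(y < 0) || any(y != round_half_up(y))) {
    stop("`y` must contain nonnegative integers")
  }
  fit <- stats::glm.fit(x = X, y = y, family = stats::poisson(),
                        control = stats::glm.control(maxit = POISSON_MAX_ITER,
                                                     epsilon = 1e-12))
  if (fit$rank < ncol(X)) {
    stop("design matrix is rank deficient (", fit$rank, " < ", ncol(X), ")")
  }
  beta <- fit$coefficients
  mu <- fit$fitted.values
  loglik <- sum(stats::dpois(y, mu, log = TRUE))
  # observed = expected information for the canonical log link: X' diag(mu) X
  info <- crossprod(X * sqrt(mu))
  se <- tryCatch(sqrt(diag(chol2inv(chol(info)))),
                 error = function(e) rep(NA_real_, ncol(X)))
  converged <- isTRUE(fit$converged) && !isTRUE(fit$boundary) &&
    all(is.finite(beta)) && all(abs(beta) <= POISSON_BETA_MAX)
  list(
    coefficients = stats::setNames(beta, colnames(X)),
    se = stats::setNames(se, colnames(X)),
    loglik = loglik,
    fitted = mu,
    converged = converged,
    k = ncol(X)
  )
}

# Shared design-matrix construction so training/held-out splits and reduced
# models use identical factor codings.
build_design <- function(data, predictors) {
  if (length(predictors) == 0L) {
    return(matrix(1, nrow = nrow(data), dimnames = list(NULL, "(Intercept)")))
  }
  missing <- setdiff(predictors, names(data))
  if (length(missing) > 0L) {
    stop("predictors not in data: ", paste(missing, collapse = ", "))
  }
  stats::model.matrix(
    stats::reformulate(sprintf("`%s`", predictors)),
    data = data
  )
}

response_matrix <- function(data, responses = PHENOTYPES) {
  missing <- setdiff(responses, names(data))
  if (length(missing) > 0L) {
    stop("response columns missing: ", paste(missing, collapse = ", "))
  }
  Y <- as.matrix(data[responses])
  # extrapolated CTC counts can be fractional; the Poisson likelihood needs
  # integers, so counts are rounded half-up before fitting
  round_half_up(Y)
}

#' Fit the multi-response Poisson model for the three CTC phenotypes
#'
#' Fits one Poisson regression per response (`eCTC`, `emCTC`, `mCTC`) on a
#' shared predictor subset; the joint log-likelihood is the sum of the three
#' per-response log-likelihoods and `AIC = 2k - 2 logLik` with `k` the total
#' parameter count. Fractional (volume-extrapolated) counts are rounded
#' half-up before fitting.
#'
#' @param data data frame with the three response columns and the predictor
#'   columns.
#' @param predictors character vector of predictor names (empty = the
#'   intercept-only null model).
#' @param responses response column names (default the three phenotypes).
#' @return object of class `ctc_modelfit`: per-response fits plus joint
#'   `loglik`, `k`, `aic`, `converged`, `n`.
#' @export
fit_multiresponse <- function(data, predictors = character(),
                              responses = PHENOTYPES) {
  X <- build_design(data, predictors)
  Y <- response_matrix(data, responses)
  fits <- lapply(responses, function(r) fit_poisson(Y[, r], X))
  names(fits) <- responses
  loglik <- sum(vapply(fits, `[[`, numeric(1), "loglik"))
  k <- sum(vapply(fits, `[[`, numeric(1), "k"))
  converged <- all(vapply(fits, `[[`, logical(1), "converged"))
  structure(
    list(
      fits = fits,
      predictors = predictors,
      responses = responses,
      loglik = loglik,
      k = k,
      aic = if (converged) 2 * k - 2 * loglik else NA_real_,
      converged = converged,
      n = nrow(X)
    ),
    class = "ctc_modelfit"
  )
}

#' Enumerate all predictor subsets as candidate model specifications
#'
#' Produces all `2^p` subsets of the candidate predictors in a deterministic
#' order (binary expansion over candidate index, i.e. the null model first and
#' the full model last). Subsets containing any excluded predictor pair are
#' kept in the output but flagged as non-competing, mirroring the exclusion
#' of model specifications with known convergence pathologies.
#'
#' @param candidates character vector of candidate predictor names (no
#'   duplicates).
#' @param exclusions list of length-2 character vectors; any subset containing
#'   both members of a pair is flagged.
#' @return list of specs, each a list with `predictors` (character) and
#'   `excluded_pair` (logical).
#' @examples
#' length(enumerate_models(c("cT", "cN", "grade", "hist")))  # 16
#' @export
enumerate_models <- function(candidates = character(), exclusions = list()) {
  if (anyDuplicated(candidates)) stop("duplicate candidate names")
  p <- length(candidates)
  specs <- vector("list", 2^p)
  for (i in seq_len(2^p)) {
    mask <- as.logical(bitwAnd(i - 1L, bitwShiftL(1L, seq_len(p) - 1L)))
    preds <- candidates[mask]
    flagged <- any(vapply(exclusions, function(pair) {
      all(pair %in% preds)
    }, logical(1)))
    specs[[i]] <- list(predictors = preds, excluded_pair = flagged)
  }
  specs
}

spec_label <- function(predictors) {
  if (length(predictors) == 0L) "(null)" else paste(predictors, collapse = "+")
}

# Fast per-fold Poisson fit: returns NULL on any failure (rank deficiency,
# IRLS non-convergence, separation guard) so the fold can be flagged.
fold_fit <- function(y, X) {
  fit <- tryCatch(
    stats::glm.fit(x = X, y = y, family = stats::poisson(),
                   control = stats::glm.control(maxit = POISSON_MAX_ITER)),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(fit) || !fit$converged || fit$boundary ||
      fit$rank < ncol(X) || any(!is.finite(fit$coefficients)) ||
      any(abs(fit$coefficients) > POISSON_BETA_MAX)) {
    return(NULL)
  }
  fit
}

#' Repeated k-fold cross-validation of one model specification
#'
#' For each repetition a fresh random partition into `k` folds is drawn. Per
#' fold, the three response models are fitted on the training folds; the fold
#' contributes the held-out joint log-likelihood, the training joint AIC, and
#' the RMSE of predicted means against observed counts on the count scale,
#' pooled over the three responses. Metrics are averaged across folds within
#' a repetition, then across repetitions. A fold in which any response fit
#' fails is flagged; by default any flagged fold marks the model excluded
#' (mirroring the treatment of specifications with convergence pathologies).
#'
#' @param data cohort data frame (responses + predictors).
#' @param predictors predictor subset to evaluate.
#' @param k number of folds (default 10).
#' @param reps number of repetitions of the whole k-fold procedure
#'   (default 500).
#' @param seed integer seed making the fold draws reproducible.
#' @param max_failed_folds number of failed folds tolerated before the model
#'   is excluded (default 0: any failure excludes).
#' @param responses response column names.
#' @return object of class `ctc_cvmetrics`: `avg_loglik`, `avg_aic`,
#'   `avg_rmse`, `n_failed_fits`, `excluded`, `reason`, `predictors`.
#' @export
crossval_model <- function(data, predictors = character(), k = 10, reps = 500,
                           seed = NULL, max_failed_folds = 0,
                           responses = PHENOTYPES) {
  n <- nrow(data)
  if (n < k) stop("need at least as many patients as folds")
  X <- build_design(data, predictors)
  Y <- response_matrix(data, responses)
  if (!is.null(seed)) set.seed(seed)

  rep_ll <- rep_aic <- rep_rmse <- rep(NA_real_, reps)
  n_failed <- 0L
  for (r in seq_len(reps)) {
    folds <- sample(rep_len(seq_len(k), n))
    ll <- aic <- rmse <- rep(NA_real_, k)
    for (f in seq_len(k)) {
      test <- folds == f
      Xtr <- X[!test, , drop = FALSE]
      Xte <- X[test, , drop = FALSE]
      fold_ll <- 0
      fold_aic <- 0
      sq_err <- numeric(0)
      ok <- TRUE
      for (resp in responses) {
        fit <- fold_fit(Y[!test, resp], Xtr)
        if (is.null(fit)) { ok <- FALSE; break }
        tr_ll <- sum(stats::dpois(Y[!test, resp], fit$fitted.values,
                                  log = TRUE))
        mu_te <- as.numeric(exp(Xte %*% fit$coefficients))
        fold_ll <- fold_ll + sum(stats::dpois(Y[test, resp], mu_te,
                                              log = TRUE))
        fold_aic <- fold_aic + (2 * ncol(X) - 2 * tr_ll)
        sq_err <- c(sq_err, (mu_te - Y[test, resp])^2)
      }
      if (!ok) { n_failed <- n_failed + 1L; next }
      ll[f] <- fold_ll
      aic[f] <- fold_aic
      rmse[f] <- sqrt(mean(sq_err))
    }
    rep_ll[r] <- mean(ll, na.rm = TRUE)
    rep_aic[r] <- mean(aic, na.rm = TRUE)
    rep_rmse[r] <- mean(rmse, na.rm = TRUE)
  }

  excluded <- n_failed > max_failed_folds
  structure(
    list(
      predictors = predictors,
      avg_loglik = mean(rep_ll, na.rm = TRUE),
      avg_aic = mean(rep_aic, na.rm = TRUE),
      avg_rmse = mean(rep_rmse, na.rm = TRUE),
      n_failed_fits = n_failed,
      excluded = excluded,
      reason = if (excluded) {
        sprintf("%d fold(s) failed to converge", n_failed)
      } else NA_character_,
      k = k, reps = reps
    ),
    class = "ctc_cvmetrics"
  )
}

#' Rank model specifications by the cross-validated selection criteria
#'
#' Non-excluded specifications are ranked lexicographically: minimum average
#' cross-validated RMSE first, ties broken by maximum average log-likelihood,
#' then minimum average AIC. Excluded specifications (convergence failures or
#' flagged predictor pairs) appear in the table but never compete.
#'
#' @param metrics list of `ctc_cvmetrics` (one per specification), e.g. from
#'   [crossval_model()] over [enumerate_models()] output. Elements may carry
#'   an `excluded` flag from either CV failures or pair exclusions.
#' @return object of class `ctc_selection`: `ranking` (data frame with model
#'   label, metrics, exclusion flag and rank) and `winner` (the best spec's
#'   predictor vector).
#' @export
select_best <- function(metrics) {
  tab <- data.frame(
    model = vapply(metrics, function(m) spec_label(m$predictors), ""),
    n_predictors = vapply(metrics, function(m) length(m$predictors), 0L),
    avg_rmse = vapply(metrics, function(m) m$avg_rmse %||% NA_real_, 0),
    avg_loglik = vapply(metrics, function(m) m$avg_loglik %||% NA_real_, 0),
    avg_aic = vapply(metrics, function(m) m$avg_aic %||% NA_real_, 0),
    excluded = vapply(metrics, function(m) isTRUE(m$excluded), TRUE),
    reason = vapply(metrics, function(m) m$reason %||% NA_character_, ""),
    stringsAsFactors = FALSE
  )
  if (all(tab$excluded)) stop("all model specifications are excluded")
  comp <- which(!tab$excluded)
  ord <- comp[order(tab$avg_rmse[comp], -tab$avg_loglik[comp],
                    tab$avg_aic[comp])]
  tab$rank <- NA_integer_
  tab$rank[ord] <- seq_along(ord)
  structure(
    list(
      ranking = tab[order(tab$rank, na.last = TRUE), ],
      winner = metrics[[ord[1]]]$predictors
    ),
    class = "ctc_selection"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Incidence rate ratios with Wald confidence intervals
#'
#' Exponentiates the non-intercept coefficients of every per-response fit into
#' incidence rate ratios (IRRs), with two-sided Wald confidence intervals
#' `exp(beta -/+ z se)` and Wald p-values.
#'
#' @param fit a `ctc_modelfit` from [fit_multiresponse()].
#' @param conf_level confidence level (default 0.95).
#' @return data frame with columns `response`, `term`, `irr`, `ci_low`,
#'   `ci_high`, `p_value`.
#' @export
irr_estimates <- function(fit, conf_level = 0.95) {
  stopifnot(inherits(fit, "ctc_modelfit"))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  rows <- lapply(fit$responses, function(r) {
    f <- fit$fits[[r]]
    terms <- setdiff(names(f$coefficients), "(Intercept)")
    if (length(terms) == 0L) return(NULL)
    beta <- f$coefficients[terms]
    se <- f$se[terms]
    data.frame(
      response = r, term = terms,
      irr = exp(beta),
      ci_low = exp(beta - z * se),
      ci_high = exp(beta + z * se),
      p_value = 2 * stats::pnorm(-abs(beta / se)),
      row.names = NULL, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Nagelkerke pseudo-R-squared
#'
#' `R2 = (1 - exp((2/n) (logLik_null - logLik_full))) /
#'       (1 - exp((2/n) logLik_null))`, the likelihood-ratio R-squared of Cox
#' and Snell rescaled to a \[0, 1) range.
#'
#' @param loglik_full log-likelihood of the fitted model (or a `ctc_modelfit`,
#'   whose joint log-likelihood is used).
#' @param loglik_null log-likelihood of the intercept-only model on the same
#'   data (or a `ctc_modelfit`).
#' @param n sample size (number of patients).
#' @return the pseudo-R-squared in \[0, 1).
#' @export
nagelkerke_r2 <- function(loglik_full, loglik_null, n) {
  if (inherits(loglik_full, "ctc_modelfit")) loglik_full <- loglik_full$loglik
  if (inherits(loglik_null, "ctc_modelfit")) loglik_null <- loglik_null$loglik
  stopifnot(is.finite(loglik_full), is.finite(loglik_null), n > 0)
  if (loglik_full < loglik_null - 1e-8) {
    warning("logLik of the full model is below the null's; numeric issue?")
  }
  cox_snell <- 1 - exp((2 / n) * (loglik_null - loglik_full))
  max_r2 <- 1 - exp((2 / n) * loglik_null)
  cox_snell / max_r2
}

#' Nagelkerke partial pseudo-R-squared decomposition
#'
#' For each response and each predictor in the full specification, the partial
#' pseudo-R-squared is the drop in that response's Nagelkerke R-squared when
#' the predictor is removed from the model (both R-squareds computed against
#' the response's intercept-only null). The overall value is the joint-model
#' Nagelkerke R-squared on the summed log-likelihoods, with `n` the number of
#' patients.
#'
#' @param data cohort data frame.
#' @param predictors the full model's predictor set (at least one).
#' @param responses response column names.
#' @return object of class `ctc_r2`: `overall_r2`, `per_response_r2` (named
#'   vector), `partial_r2` (responses x predictors matrix), and `partial_p`
#'   (likelihood-ratio p-values for each removed predictor).
#' @export
partial_r2 <- function(data, predictors, responses = PHENOTYPES) {
  if (length(predictors) == 0L) stop("the full model needs >= 1 predictor")
  n <- nrow(data)
  full <- fit_multiresponse(data, predictors, responses)
  null <- fit_multiresponse(data, character(), responses)

  per_resp <- vapply(responses, function(r) {
    nagelkerke_r2(full$fits[[r]]$loglik, null$fits[[r]]$loglik, n)
  }, numeric(1))

  part <- matrix(NA_real_, nrow = length(responses), ncol = length(predictors),
                 dimnames = list(responses, predictors))
  pval <- part
  for (p in predictors) {
    reduced <- fit_multiresponse(data, setdiff(predictors, p), responses)
    for (r in responses) {
      r2_red <- nagelkerke_r2(reduced$fits[[r]]$loglik, null$fits[[r]]$loglik, n)
      part[r, p] <- per_resp[[r]] - r2_red
      lr <- 2 * (full$fits[[r]]$loglik - reduced$fits[[r]]$loglik)
      df <- full$fits[[r]]$k - reduced$fits[[r]]$k
      pval[r, p] <- stats::pchisq(max(lr, 0), df = df, lower.tail = FALSE)
    }
  }
  structure(
    list(
      overall_r2 = nagelkerke_r2(full$loglik, null$loglik, n),
      per_response_r2 = per_resp,
      partial_r2 = part,
      partial_p = pval
    ),
    class = "ctc_r2"
  )
}

#' Exhaustive cross-validated model selection over all predictor subsets
#'
#' Orchestrates the full selection procedure: enumerate every subset of the
#' candidate predictors, run repeated k-fold cross-validation on every
#' non-flagged subset, rank by the (RMSE, logLik, AIC) criteria, then refit
#' the winner on the whole cohort to report incidence rate ratios and the
#' Nagelkerke R-squared decomposition.
#'
#' @param data cohort data frame.
#' @param candidates candidate predictor names.
#' @param exclusions list of excluded predictor pairs (see
#'   [enumerate_models()]).
#' @param k,reps,seed cross-validation settings (see [crossval_model()]).
#' @param max_failed_folds per-spec tolerance for failed folds before
#'   exclusion (default 0: any failure excludes; a tolerant value lets a spec
#'   with sporadic resampling-induced separation stay in the running, its
#'   failed folds simply contributing nothing to the averages).
#' @param responses response column names.
#' @return list with `selection` (a `ctc_selection`), `winner_fit`
#'   (`ctc_modelfit`), `irr` (data frame), `r2` (`ctc_r2`, `NULL` for a null
#'   winner), and `metrics` (per-spec `ctc_cvmetrics`).
#' @export
run_model_selection <- function(data, candidates, exclusions = list(),
                                k = 10, reps = 500, seed = 1L,
                                max_failed_folds = 0,
                                responses = PHENOTYPES) {
  specs <- enumerate_models(candidates, exclusions)
  spec_seeds <- stream_seeds(seed, length(specs))
  metrics <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    if (specs[[i]]$excluded_pair) {
      metrics[[i]] <- structure(
        list(predictors = specs[[i]]$predictors,
             avg_loglik = NA_real_, avg_aic = NA_real_, avg_rmse = NA_real_,
             n_failed_fits = NA_integer_, excluded = TRUE,
             reason = "contains an excluded predictor pair",
             k = k, reps = reps),
        class = "ctc_cvmetrics"
      )
    } else {
      metrics[[i]] <- crossval_model(data, specs[[i]]$predictors, k = k,
                                     reps = reps, seed = spec_seeds[i],
                                     max_failed_folds = max_failed_folds,
                                     responses = responses)
    }
  }
  selection <- select_best(metrics)
  winner_fit <- fit_multiresponse(data, selection$winner, responses)
  list(
    selection = selection,
    winner_fit = winner_fit,
    irr = irr_estimates(winner_fit),
    r2 = if (length(selection$winner) > 0L) {
      partial_r2(data, selection$winner, responses)
    },
    metrics = metrics
  )
}
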