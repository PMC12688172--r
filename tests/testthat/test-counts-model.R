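test_that("Poisson fit matches the two-group closed form", {
  y <- c(1, 2, 3, 4, 6)
  X <- cbind("(Intercept)" = 1, x = c(0, 0, 0, 1, 1))
  fit <- fit_poisson(y, X)
  # saturated two-group model: rates are the group means, IRR their ratio
  expect_equal(exp(fit$coefficients[["(Intercept)"]]), 2, tolerance = 1e-8)
  expect_equal(exp(fit$coefficients[["x"]]), 2.5, tolerance = 1e-8)
  expect_true(fit$converged)
  # intercept-only: rate is the sample mean
  fit0 <- fit_poisson(y, X[, 1, drop = FALSE])
  expect_equal(exp(fit0$coefficients[[1]]), mean(y), tolerance = 1e-8)
})

test_that("Poisson fit recovers a null effect and rejects bad input", {
  set.seed(77)
  x <- rbinom(2000, 1, 0.5)
  y <- rpois(2000, 3)
  fit <- fit_poisson(y, cbind(1, x))
  expect_lt(abs(exp(fit$coefficients[[2]]) - 1), 0.15)
  expect_error(fit_poisson(y, cbind(1, x, x)), "rank deficient")
  expect_error(fit_poisson(c(-1, 2), cbind(1, c(0, 1))), "nonnegative")
  expect_error(fit_poisson(c(1.5, 2), cbind(1, c(0, 1))), "nonnegative")
})

test_that("separation trips the convergence guard instead of erroring", {
  # a covariate level with all-zero counts drives its coefficient to -Inf
  y <- c(3, 4, 5, 0, 0, 0)
  X <- cbind(1, c(0, 0, 0, 1, 1, 1))
  fit <- fit_poisson(y, X)
  expect_false(fit$converged)
})

test_that("multi-response joint statistics are additive and AIC is exact", {
  coh <- toy_cohort()
  null <- fit_multiresponse(coh)
  per_resp <- vapply(c("eCTC", "emCTC", "mCTC"), function(r) {
    fit_poisson(coh[[r]], matrix(1, nrow(coh)))$loglik
  }, numeric(1))
  expect_equal(null$loglik, sum(per_resp))
  full <- fit_multiresponse(coh, "x")
  expect_equal(full$aic, 2 * full$k - 2 * full$loglik)
  expect_equal(full$k, 6)
  # adding a predictor never decreases in-sample joint log-likelihood
  expect_gte(full$loglik, null$loglik)
  set.seed(31)
  coh2 <- generate_cohort(strong_cohort_config(80, seed = 31))$cohort
  ll <- vapply(
    list(character(), "cT234", c("cT234", "cNpos"),
         c("cT234", "cNpos", "grade3")),
    function(p) fit_multiresponse(coh2, p)$loglik, numeric(1))
  expect_true(all(diff(ll) >= -1e-8))
})

test_that("fractional extrapolated counts are rounded half-up before fitting", {
  coh <- toy_cohort()
  coh$eCTC <- coh$eCTC + 0.5
  fit <- fit_multiresponse(coh)
  expect_equal(exp(fit$fits$eCTC$coefficients[[1]]),
               mean(floor(coh$eCTC + 0.5)), tolerance = 1e-8)
})

test_that("model enumeration is exhaustive, ordered and flags excluded pairs", {
  specs <- enumerate_models(c("cT", "cN", "grade", "hist"))
  expect_length(specs, 16)
  expect_equal(specs[[1]]$predictors, character(0))
  expect_equal(specs[[16]]$predictors, c("cT", "cN", "grade", "hist"))
  # deterministic order: re-enumeration is identical
  expect_identical(specs, enumerate_models(c("cT", "cN", "grade", "hist")))
  expect_length(enumerate_models(character()), 1)

  flagged <- enumerate_models(c("cT", "cN", "grade", "hist"),
                              exclusions = list(c("grade", "cN")))
  has_pair <- vapply(flagged, function(s) {
    all(c("grade", "cN") %in% s$predictors)
  }, logical(1))
  expect_equal(vapply(flagged, `[[`, logical(1), "excluded_pair"), has_pair)
  expect_equal(sum(has_pair), 4)
  expect_error(enumerate_models(c("a", "a")), "duplicate")
})

test_that("leave-one-out CV matches a brute-force oracle", {
  set.seed(19)
  coh <- generate_cohort(
    cohort_config(10, c(x = 0.5),
                  true_log_irr = rbind(mCTC = c(x = log(2))),
                  baseline_log_rate = c(eCTC = log(2), emCTC = log(2),
                                        mCTC = log(2)),
                  seed = 19))$cohort
  got <- crossval_model(coh, "x", k = 10, reps = 1, seed = 1)

  # independent oracle: n leave-one-out fits through the glm formula
  # interface, pooled count-scale RMSE per fold, then averaged
  rmse <- ll <- aic <- numeric(10)
  for (i in 1:10) {
    train <- coh[-i, ]
    test <- coh[i, ]
    sq <- numeric(0)
    fll <- 0; faic <- 0
    for (r in c("eCTC", "emCTC", "mCTC")) {
      g <- glm(reformulate("x", r), data = train, family = poisson())
      mu <- predict(g, newdata = test, type = "response")
      sq <- c(sq, (mu - test[[r]])^2)
      fll <- fll + dpois(test[[r]], mu, log = TRUE)
      faic <- faic + (2 * 2 - 2 * as.numeric(logLik(g)))
    }
    rmse[i] <- sqrt(mean(sq))
    ll[i] <- fll
    aic[i] <- faic
  }
  expect_equal(got$avg_rmse, mean(rmse), tolerance = 1e-6)
  expect_equal(got$avg_loglik, mean(ll), tolerance = 1e-6)
  expect_equal(got$avg_aic, mean(aic), tolerance = 1e-6)
})

test_that("cross-validation is reproducible and fold sizes are balanced", {
  coh <- generate_cohort(strong_cohort_config(95, seed = 3))$cohort
  a <- crossval_model(coh, c("cT234", "cNpos"), k = 10, reps = 3, seed = 42)
  b <- crossval_model(coh, c("cT234", "cNpos"), k = 10, reps = 3, seed = 42)
  expect_identical(a, b)
  set.seed(42)
  folds <- sample(rep_len(1:10, 95))
  expect_lte(diff(range(table(folds))), 1)
})

test_that("quasi-separation leads to exclusion or abnormal RMSE", {
  set.seed(8)
  coh <- generate_cohort(strong_cohort_config(60, seed = 8))$cohort
  # engineer a level whose mCTC counts are all zero
  coh$sep <- rbinom(60, 1, 0.2)
  coh$eCTC[coh$sep == 1] <- 0
  coh$emCTC[coh$sep == 1] <- 0
  coh$mCTC[coh$sep == 1] <- 0
  m <- crossval_model(coh, "sep", k = 10, reps = 5, seed = 2)
  clean <- crossval_model(coh, "cT234", k = 10, reps = 5, seed = 2)
  expect_true(m$excluded || m$avg_rmse > 5 * clean$avg_rmse)
})

test_that("selection ranks by RMSE first, then logLik, then AIC", {
  mk <- function(preds, rmse, ll, aic, excluded = FALSE, reason = NULL) {
    structure(list(predictors = preds, avg_rmse = rmse, avg_loglik = ll,
                   avg_aic = aic, n_failed_fits = 0L, excluded = excluded,
                   reason = reason, k = 10, reps = 1),
              class = "ctc_cvmetrics")
  }
  # rmse decides even when logLik and AIC prefer the other model
  sel <- select_best(list(mk("a", 1.0, -60, 130), mk("b", 1.1, -50, 110)))
  expect_equal(sel$winner, "a")
  # rmse tie: logLik decides
  sel <- select_best(list(mk("a", 1.0, -60, 110), mk("b", 1.0, -50, 130)))
  expect_equal(sel$winner, "b")
  # excluded specs never compete
  sel <- select_best(list(mk("a", 0.5, -10, 30, excluded = TRUE, reason = "x"),
                          mk("b", 1.0, -50, 110)))
  expect_equal(sel$winner, "b")
  expect_true(is.na(sel$ranking$rank[sel$ranking$model == "a"]))
  sel_single <- select_best(list(mk("only", 1, -5, 12)))
  expect_equal(sel_single$winner, "only")
  expect_error(select_best(list(mk("a", 1, -5, 12, excluded = TRUE))),
               "all model specifications")
})

test_that("IRR estimates carry ordered Wald intervals and p-values", {
  coh <- generate_cohort(strong_cohort_config(200, seed = 14))$cohort
  fit <- fit_multiresponse(coh, c("cT234", "cNpos"))
  irr <- irr_estimates(fit)
  expect_equal(nrow(irr), 6)
  expect_true(all(irr$ci_low < irr$irr & irr$irr < irr$ci_high))
  expect_true(all(irr$irr > 0))
  expect_true(all(irr$p_value >= 0 & irr$p_value <= 1))
  z <- qnorm(0.975)
  b <- fit$fits$mCTC$coefficients[["cT234"]]
  s <- fit$fits$mCTC$se[["cT234"]]
  row <- irr[irr$response == "mCTC" & irr$term == "cT234", ]
  expect_equal(row$ci_low, exp(b - z * s))
  expect_equal(row$ci_high, exp(b + z * s))
})

test_that("Nagelkerke pseudo-R2 matches its formula and stays in [0, 1)", {
  expect_equal(nagelkerke_r2(-10, -10, 20), 0)
  coh <- toy_cohort()
  full <- fit_multiresponse(coh, "x")
  null <- fit_multiresponse(coh)
  r2 <- nagelkerke_r2(full, null, nrow(coh))
  expect_gte(r2, 0)
  expect_lt(r2, 1)
  # monotone in the full log-likelihood for a fixed null
  lls <- seq(null$loglik, null$loglik + 5, by = 0.5)
  r2s <- vapply(lls, nagelkerke_r2, numeric(1),
                loglik_null = null$loglik, n = 5)
  expect_true(all(diff(r2s) > 0))
  expect_warning(nagelkerke_r2(-12, -10, 20), "numeric issue")
})

test_that("partial R2 reduces to the overall R2 for single-predictor models", {
  coh <- generate_cohort(strong_cohort_config(150, seed = 25))$cohort
  dec <- partial_r2(coh, "cNpos")
  for (r in c("eCTC", "emCTC", "mCTC")) {
    expect_equal(dec$partial_r2[r, "cNpos"], dec$per_response_r2[[r]])
  }
  expect_gte(dec$overall_r2, 0)
  expect_lt(dec$overall_r2, 1)
})

test_that("a zero-effect predictor has vanishing partial R2 at large n", {
  coh <- generate_cohort(strong_cohort_config(3000, seed = 26))$cohort
  dec <- partial_r2(coh, c("cNpos", "grade3"))
  expect_true(all(abs(dec$partial_r2[, "grade3"]) < 0.01))
  expect_true(all(dec$partial_r2[, "cNpos"] > 0.05))
  expect_error(partial_r2(coh, character()), ">= 1 predictor")
})
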