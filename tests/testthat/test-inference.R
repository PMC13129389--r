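# Maximum-likelihood fitters: closed-form oracles, cross-checks against
# stats::glm, likelihood oracles and parameter recovery.

test_that("logistic MLE on a 2x2 grouped table equals the closed form", {
  x <- rep(c(0, 1), each = 40)
  y <- c(rep(1, 30), rep(0, 10), rep(1, 10), rep(0, 30))
  fit <- logistic_mle(y, cbind("(Intercept)" = 1, x = x))
  expect_equal(unname(fit$coef["(Intercept)"]), log(3), tolerance = 1e-4)
  expect_equal(unname(fit$coef["x"]), log(1 / 9), tolerance = 1e-4)
  expect_true(fit$converged)
  expect_lte(fit$loglik, 0)
  expect_true(all(fit$ci95[, "lower"] < fit$ci95[, "upper"]))
})

test_that("logistic MLE matches stats::glm on simulated contests", {
  con <- generate_contests(contest_config(seed = 4, n_contests = 800))
  fit <- fit_logistic(con)
  ref <- stats::glm(focal_win ~ spread_diff + I(season == "winter") + rel_ndvi,
                    family = stats::binomial(), data = con)
  expect_equal(unname(fit$coef), unname(stats::coef(ref)), tolerance = 1e-6)
  expect_equal(unname(fit$se),
               unname(summary(ref)$coefficients[, "Std. Error"]),
               tolerance = 1e-4)
  expect_equal(fit$loglik, as.numeric(stats::logLik(ref)), tolerance = 1e-8)
})

test_that("logistic edge cases: one-outcome data and separation", {
  con <- generate_contests(contest_config(seed = 4, n_contests = 100))
  con$focal_win <- 1L
  expect_error(fit_logistic(con), "both outcomes")
  # perfectly separated predictor diverges and is flagged
  x <- c(rep(0, 20), rep(1, 20))
  y <- x
  expect_warning(fit <- logistic_mle(y, cbind(1, x)), "separation")
  expect_false(fit$converged)
  expect_true(fit$separation)
})

test_that("ordinal MLE with two categories reduces to binary logistic", {
  obs <- generate_spread_observations(spread_config(seed = 6, n_obs = 2000))
  obs$spread_category <- ifelse(obs$spread_category >= 3, 2L, 1L)
  ofit <- fit_ordinal(obs)
  sc <- obs$group_size - mean(obs$group_size)
  w <- as.numeric(obs$season == "winter")
  lfit <- logistic_mle(as.numeric(obs$spread_category == 2L),
                       cbind("(Intercept)" = 1, size = sc, winter = w,
                             inter = sc * w))
  # P(Y = 2) = plogis(eta - theta): slopes match, intercept = -theta
  expect_equal(unname(ofit$coef), unname(lfit$coef[-1]), tolerance = 1e-4)
  expect_equal(ofit$theta_base, -unname(lfit$coef[1]), tolerance = 1e-4)
  expect_true(is.na(ofit$theta_spacing))
})

test_that("ordinal MLE recovers the generating coefficients", {
  obs <- generate_spread_observations(spread_config(seed = 10, n_obs = 5000))
  fit <- fit_ordinal(obs)
  expect_true(fit$converged)
  expect_lt(abs(fit$coef[["beta_size"]] - 0.15), 0.03)
  expect_lt(abs(fit$coef[["beta_interaction"]] - 0.04), 0.02)
  expect_gt(fit$theta_spacing, 0)
  expect_lte(fit$loglik, 0)
  expect_true(all(fit$se > 0))
  # null data: slope estimate within 2 SE of zero
  null_obs <- generate_spread_observations(
    spread_config(seed = 10, n_obs = 5000, beta_size = 0,
                  beta_interaction = 0, beta_season = 0))
  nf <- fit_ordinal(null_obs)
  expect_lt(abs(nf$coef[["beta_size"]]), 2 * nf$se[["beta_size"]])
  # degenerate input: a single observed category cannot be fit
  one <- obs[obs$spread_category == 2L, ]
  expect_error(fit_ordinal(one), "one observed category")
})

test_that("reported log-likelihoods equal the naive summation oracle", {
  obs <- generate_spread_observations(spread_config(seed = 12, n_obs = 1500))
  ofit <- fit_ordinal(obs)
  expect_lt(abs(loglik_oracle(ofit, obs) - ofit$loglik), 1e-8)
  con <- generate_contests(contest_config(seed = 12, n_contests = 600))
  lfit <- fit_logistic(con)
  expect_lt(abs(loglik_oracle(lfit, con) - lfit$loglik), 1e-8)
  # empty record sets contribute zero log-likelihood
  expect_equal(loglik_oracle(lfit, con[0, ]), 0)
  expect_equal(loglik_oracle(ofit, obs[0, ]), 0)
})

test_that("the fitted point is a local maximum of the oracle likelihood", {
  con <- generate_contests(contest_config(seed = 13, n_contests = 600))
  fit <- fit_logistic(con)
  ll_hat <- loglik_oracle(fit, con)
  for (term in names(fit$coef)) {
    for (d in c(-0.1, 0.1)) {
      bumped <- fit
      bumped$coef[term] <- bumped$coef[term] + d
      expect_lt(loglik_oracle(bumped, con), ll_hat)
    }
  }
})

test_that("fits are invariant to record order", {
  con <- generate_contests(contest_config(seed = 14, n_contests = 500))
  f1 <- fit_logistic(con)
  set.seed(1)
  f2 <- fit_logistic(con[sample(nrow(con)), ])
  expect_lt(max(abs(f1$coef - f2$coef)), 1e-10)
  obs <- generate_spread_observations(spread_config(seed = 14, n_obs = 1500))
  o1 <- fit_ordinal(obs)
  o2 <- fit_ordinal(obs[sample(nrow(obs)), ])
  expect_lt(max(abs(o1$coef - o2$coef)), 1e-8)
})

test_that("predicted win curve is monotone and hits the closed-form ends", {
  fit <- structure(list(coef = c("(Intercept)" = 0, spread_diff = -0.52,
                                 season_winter = 0, rel_ndvi = 0),
                        converged = TRUE), class = "logistic_fit")
  curve <- predicted_win_curve(fit)
  expect_equal(curve$spread_diff, -3:3)
  expect_equal(curve$p_win[curve$spread_diff == -3],
               stats::plogis(1.56), tolerance = 1e-12)
  expect_equal(curve$p_win[curve$spread_diff == 3],
               stats::plogis(-1.56), tolerance = 1e-12)
  expect_equal(curve$p_win[curve$spread_diff == 0], 0.5)
  expect_true(all(diff(curve$p_win) < 0))
})
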