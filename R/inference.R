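# From-scratch maximum-likelihood fitting: Newton-Raphson binary logistic
# regression and an equidistant-threshold cumulative-logit (proportional
# odds) model. Fixed effects only, with Wald standard errors from the
# observed information; designed for parameter recovery on the synthetic
# generators of this package.

#' Binary logistic regression by Newton-Raphson
#'
#' Low-level maximum-likelihood engine: iteratively reweighted Newton steps
#' on the full log-likelihood, stopping when the score norm drops below
#' `grad_tol`. Complete separation is flagged (not silently returned) when a
#' coefficient diverges past `sep_limit`.
#'
#' @param y 0/1 response vector.
#' @param X design matrix (include an intercept column if wanted).
#' @param max_iter maximum Newton iterations.
#' @param grad_tol convergence threshold on the maximum absolute score.
#' @param sep_limit coefficient magnitude treated as divergence.
#' @return list of class `logistic_fit`: `coef`, `se`, `vcov`, `ci95`
#'   (matrix with columns `lower`, `upper`), `loglik`, `converged`,
#'   `separation`, `n_used`, `iter`.
#' @examples
#' x <- rep(c(0, 1), each = 40)
#' y <- c(rep(c(1, 0), c(30, 10)), rep(c(1, 0), c(10, 30)))
#' f <- logistic_mle(y, cbind(1, x))
#' f$coef   # log(3), log(1/9): the closed-form 2x2 log-odds
#' @export
logistic_mle <- function(y, X, max_iter = 50L, grad_tol = 1e-6,
                         sep_limit = 15) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stop("length(y) != nrow(X)", call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("'y' must be 0/1", call. = FALSE)
  if (all(y == 0) || all(y == 1))
    stop("both outcomes must be present to fit a logistic model",
         call. = FALSE)
  p_dim <- ncol(X)
  beta <- numeric(p_dim)
  converged <- FALSE
  separation <- FALSE
  iter <- 0L
  H <- diag(p_dim)
  for (iter in seq_len(max_iter)) {
    mu <- stats::plogis(drop(X %*% beta))
    score <- drop(crossprod(X, y - mu))
    w <- mu * (1 - mu)
    H <- crossprod(X, X * w)
    if (max(abs(score)) < grad_tol) { converged <- TRUE; break }
    step <- tryCatch(solve(H, score), error = function(e) NULL)
    if (is.null(step)) break
    beta <- beta + step
    if (any(abs(beta) > sep_limit)) { separation <- TRUE; break }
  }
  if (separation)
    warning("possible complete separation: a coefficient diverged beyond ",
            sep_limit)
  mu <- stats::plogis(drop(X %*% beta))
  loglik <- sum(y * log(mu) + (1 - y) * log1p(-mu))
  vcov <- tryCatch(solve(H), error = function(e) matrix(NA_real_, p_dim, p_dim))
  se <- sqrt(diag(vcov))
  names(beta) <- names(se) <- colnames(X)
  ci <- cbind(lower = beta - 1.959963984540054 * se,
              upper = beta + 1.959963984540054 * se)
  structure(list(coef = beta, se = se, vcov = vcov, ci95 = ci,
                 loglik = loglik, converged = converged && !separation,
                 separation = separation, n_used = length(y), iter = iter),
            class = "logistic_fit")
}

#' Fit the contest-outcome model
#'
#' Logistic regression of the focal-win indicator on the spread-category
#' difference, season (winter vs summer reference) and relative NDVI —
#' the fixed-effects analogue of the field analysis this package emulates.
#'
#' @param records data frame with columns `focal_win`, `spread_diff`,
#'   `season`, `rel_ndvi` (as from [generate_contests()]).
#' @return A `logistic_fit` (see [logistic_mle()]) with coefficients
#'   `(Intercept)`, `spread_diff`, `season_winter`, `rel_ndvi`.
#' @examples
#' con <- generate_contests(contest_config(seed = 1, n_contests = 500))
#' fit_logistic(con)
#' @export
fit_logistic <- function(records) {
  need <- c("focal_win", "spread_diff", "season", "rel_ndvi")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  X <- cbind("(Intercept)" = 1,
             spread_diff = records$spread_diff,
             season_winter = as.numeric(records$season == "winter"),
             rel_ndvi = records$rel_ndvi)
  logistic_mle(records$focal_win, X)
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic model fit by maximum likelihood (Newton-Raphson)\n")
  cat(sprintf("  n = %d, log-likelihood = %.4f, converged: %s\n",
              x$n_used, x$loglik, x$converged))
  print(data.frame(estimate = x$coef, se = x$se,
                   ci_low = x$ci95[, "lower"], ci_high = x$ci95[, "upper"]))
  invisible(x)
}

# negative log-likelihood of the equidistant-threshold cumulative-logit
# model; par = (beta, theta_base[, delta]); delta absent when n_cat == 2
ordinal_negll <- function(par, y, X, n_cat) {
  p_dim <- ncol(X)
  beta <- par[seq_len(p_dim)]
  theta_base <- par[p_dim + 1L]
  delta <- if (n_cat > 2L) par[p_dim + 2L] else 0
  if (n_cat > 2L && delta <= 0) return(1e10)
  theta <- theta_base + (0:(n_cat - 2L)) * delta
  eta <- drop(X %*% beta)
  upper <- ifelse(y == n_cat, 1, stats::plogis(theta[pmin(y, n_cat - 1L)] - eta))
  lower <- ifelse(y == 1L, 0, stats::plogis(theta[pmax(y - 1L, 1L)] - eta))
  pr <- upper - lower
  if (any(pr <= 0) || anyNA(pr)) return(1e10)
  -sum(log(pr))
}

#' Equidistant-threshold cumulative-logit regression
#'
#' Low-level maximum-likelihood engine for an ordinal response with
#' categories `1..n_cat` under the proportional-odds model
#' `P(Y <= j) = plogis(theta_j - x'beta)` with the thresholds constrained to
#' be equidistant, `theta_j = theta_base + (j - 1) * spacing` — two threshold
#' parameters regardless of the number of categories. Optimization is
#' quasi-Newton (BFGS) with slopes started at zero and thresholds at the
#' empirical cumulative logits; standard errors come from the numerically
#' differentiated observed information at the optimum. With `n_cat = 2` the
#' model reduces to binary logistic regression (the spacing is then
#' undefined and returned as `NA`).
#'
#' @param y integer response in `1..n_cat`.
#' @param X design matrix of slope covariates (no intercept; the thresholds
#'   absorb it).
#' @param n_cat number of ordinal categories (default `max(y)`).
#' @return list of class `ordinal_fit`: `coef` (slopes), `theta_base`,
#'   `theta_spacing`, `se` (slopes), `se_theta`, `vcov`, `loglik`,
#'   `converged`, `n_used`.
#' @export
ordinal_mle <- function(y, X, n_cat = max(y)) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(y) != nrow(X)) stop("length(y) != nrow(X)", call. = FALSE)
  if (any(y < 1L) || any(y > n_cat)) stop("'y' outside 1..n_cat", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("only one observed category: ordinal model is not identifiable",
         call. = FALSE)
  p_dim <- ncol(X)
  # starting thresholds from the empirical cumulative distribution
  cum <- cumsum(tabulate(y, n_cat))[seq_len(n_cat - 1L)] / length(y)
  cum <- pmin(pmax(cum, 1e-4), 1 - 1e-4)
  qh <- stats::qlogis(cum)
  if (n_cat > 2L) {
    d0 <- mean(diff(qh)); if (!is.finite(d0) || d0 <= 0) d0 <- 1
    par0 <- c(numeric(p_dim), qh[1L], d0)
  } else {
    par0 <- c(numeric(p_dim), qh[1L])
  }
  opt <- stats::optim(par0, ordinal_negll, y = y, X = X, n_cat = n_cat,
                      method = "BFGS",
                      control = list(maxit = 500L, reltol = 1e-12))
  hess <- stats::optimHess(opt$par, ordinal_negll, y = y, X = X, n_cat = n_cat)
  vcov <- tryCatch(solve(hess),
                   error = function(e) matrix(NA_real_, length(opt$par),
                                              length(opt$par)))
  se_all <- suppressWarnings(sqrt(diag(vcov)))
  beta <- opt$par[seq_len(p_dim)]
  names(beta) <- colnames(X)
  se <- se_all[seq_len(p_dim)]
  names(se) <- colnames(X)
  theta_spacing <- if (n_cat > 2L) opt$par[p_dim + 2L] else NA_real_
  converged <- opt$convergence == 0L &&
    (n_cat == 2L || theta_spacing > 0) && all(is.finite(se))
  structure(list(coef = beta, theta_base = opt$par[p_dim + 1L],
                 theta_spacing = theta_spacing, se = se,
                 se_theta = se_all[-seq_len(p_dim)], vcov = vcov,
                 loglik = -opt$value, converged = converged,
                 n_used = length(y), n_cat = n_cat),
            class = "ordinal_fit")
}

#' Fit the spread-category model
#'
#' Cumulative-logit regression (equidistant thresholds) of the ordinal
#' spatial-spread category on census group size, season and their
#' interaction — the fixed-effects analogue of the field analysis this
#' package emulates. Group size is centered at its sample mean before the
#' slope is applied (slopes are invariant to centering; the thresholds
#' absorb the shift).
#'
#' @param records data frame with columns `spread_category`, `group_size`,
#'   `season` (as from [generate_spread_observations()]).
#' @return An `ordinal_fit` (see [ordinal_mle()]) with slopes `beta_size`,
#'   `beta_season`, `beta_interaction`, plus the centering constant as
#'   element `size_center`.
#' @examples
#' obs <- generate_spread_observations(spread_config(seed = 1, n_obs = 1000))
#' fit_ordinal(obs)
#' @export
fit_ordinal <- function(records) {
  need <- c("spread_category", "group_size", "season")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  ctr <- mean(records$group_size)
  size_c <- records$group_size - ctr
  winter <- as.numeric(records$season == "winter")
  X <- cbind(beta_size = size_c, beta_season = winter,
             beta_interaction = size_c * winter)
  fit <- ordinal_mle(records$spread_category, X,
                     n_cat = max(records$spread_category))
  fit$size_center <- ctr
  fit
}

#' @export
print.ordinal_fit <- function(x, ...) {
  cat("Cumulative-logit model (equidistant thresholds), maximum likelihood\n")
  cat(sprintf("  n = %d, categories = %d, log-likelihood = %.4f, converged: %s\n",
              x$n_used, x$n_cat, x$loglik, x$converged))
  print(data.frame(estimate = x$coef, se = x$se))
  cat(sprintf("  thresholds: base = %.4f, spacing = %.4f\n",
              x$theta_base, x$theta_spacing))
  invisible(x)
}

#' Recompute a fit's log-likelihood by naive summation
#'
#' Independent verification oracle: loops over the records one at a time and
#' accumulates the log of each observation's category/outcome probability
#' with directly coded logistic expressions, bypassing the optimizer's
#' vectorized objective. Agrees with the fit's reported `loglik` to within
#' `1e-8` for any converged fit; returns 0 for an empty record set.
#'
#' @param fit a `logistic_fit` from [fit_logistic()] or an `ordinal_fit`
#'   from [fit_ordinal()].
#' @param records the data the fit was computed from (canonical columns).
#' @return the summed log-likelihood.
#' @export
loglik_oracle <- function(fit, records) UseMethod("loglik_oracle")

#' @export
loglik_oracle.logistic_fit <- function(fit, records) {
  if (is.null(records) || nrow(records) == 0L) return(0)
  b <- fit$coef
  ll <- 0
  for (i in seq_len(nrow(records))) {
    eta <- b[["(Intercept)"]] +
      b[["spread_diff"]] * records$spread_diff[i] +
      b[["season_winter"]] * (records$season[i] == "winter") +
      b[["rel_ndvi"]] * records$rel_ndvi[i]
    p <- 1 / (1 + exp(-eta))
    ll <- ll + log(if (records$focal_win[i] == 1) p else 1 - p)
  }
  ll
}

#' @export
loglik_oracle.ordinal_fit <- function(fit, records) {
  if (is.null(records) || nrow(records) == 0L) return(0)
  spacing <- if (is.na(fit$theta_spacing)) 0 else fit$theta_spacing
  theta <- fit$theta_base + (0:(fit$n_cat - 2L)) * spacing
  F <- function(x) 1 / (1 + exp(-x))
  ll <- 0
  for (i in seq_len(nrow(records))) {
    sc <- records$group_size[i] - fit$size_center
    w <- as.numeric(records$season[i] == "winter")
    eta <- fit$coef[["beta_size"]] * sc + fit$coef[["beta_season"]] * w +
      fit$coef[["beta_interaction"]] * sc * w
    j <- records$spread_category[i]
    up <- if (j == fit$n_cat) 1 else F(theta[j] - eta)
    lo <- if (j == 1L) 0 else F(theta[j - 1L] - eta)
    ll <- ll + log(up - lo)
  }
  ll
}

#' Predicted focal-win curve over spread differences
#'
#' Win probability at reference covariates (summer, relative NDVI 0) as a
#' function of the focal-minus-rival spread-category difference. Strictly
#' decreasing over the grid whenever the spread-difference coefficient is
#' negative.
#'
#' @param fit a converged `logistic_fit` from [fit_logistic()].
#' @param dq_grid spread-difference grid (default the integers -3..3).
#' @return data frame with columns `spread_diff`, `p_win`.
#' @examples
#' con <- generate_contests(contest_config(seed = 1, n_contests = 1000))
#' predicted_win_curve(fit_logistic(con))
#' @export
predicted_win_curve <- function(fit, dq_grid = -3:3) {
  stopifnot(inherits(fit, "logistic_fit"))
  if (!fit$converged)
    warning("predictions from a non-converged fit")
  p <- stats::plogis(fit$coef[["(Intercept)"]] +
                       fit$coef[["spread_diff"]] * dq_grid)
  data.frame(spread_diff = dq_grid, p_win = p)
}
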