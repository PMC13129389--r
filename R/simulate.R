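# Seed-reproducible generators emulating the structure of vervet-monkey field
# data: ordinal group spatial-spread observations (census size x season ->
# spread category 1-4) and dyadic contest records (spread difference ->
# win/lose). Defaults mirror the published study design: three observation
# groups (AK, NH, BD) with the reported size distributions, a group-size
# slope of 0.15 with a 0.04 winter interaction and a -0.03 season shift on
# the cumulative-logit scale, and 71 contests over four dyads with a
# spread-difference log-odds coefficient of -0.52.

#' Configuration for the spread-observation generator
#'
#' @param seed integer RNG seed.
#' @param n_obs number of observations.
#' @param group_probs sampling weights of the three groups (default: the
#'   reported shares of the pooled observations, 15.17/38.36/46.47%).
#' @param group_means,group_sds per-group census-size normal laws
#'   (individuals).
#' @param beta_size group-size slope (per individual, cumulative-logit
#'   scale).
#' @param beta_season additive winter shift.
#' @param beta_interaction extra size slope in winter.
#' @param theta_base first threshold; `theta_spacing` the common gap between
#'   consecutive thresholds (equidistant-threshold constraint).
#' @param theta_spacing see `theta_base`; must be positive.
#' @param p_winter probability an observation falls in winter.
#' @return list of class `spread_config`.
#' @export
spread_config <- function(seed = 1L, n_obs = 5000L,
                          group_probs = c(AK = 0.1517, NH = 0.3836, BD = 0.4647),
                          group_means = c(AK = 21.32, NH = 34.04, BD = 50.58),
                          group_sds = c(AK = 1.5, NH = 4.88, BD = 2.64),
                          beta_size = 0.15, beta_season = -0.03,
                          beta_interaction = 0.04,
                          theta_base = -1, theta_spacing = 2,
                          p_winter = 0.5) {
  if (n_obs < 1L) stop("'n_obs' must be positive", call. = FALSE)
  if (theta_spacing <= 0) stop("'theta_spacing' must be positive", call. = FALSE)
  if (any(group_sds < 0)) stop("'group_sds' must be non-negative", call. = FALSE)
  structure(list(seed = as.integer(seed), n_obs = as.integer(n_obs),
                 group_probs = group_probs / sum(group_probs),
                 group_means = group_means, group_sds = group_sds,
                 beta_size = beta_size, beta_season = beta_season,
                 beta_interaction = beta_interaction,
                 theta_base = theta_base, theta_spacing = theta_spacing,
                 p_winter = p_winter),
            class = "spread_config")
}

#' Generate ordinal group spatial-spread observations
#'
#' Draws per-observation group identities, census sizes (normal per group),
#' and seasons, then samples a spread category 1-4 (1 = 0-20 m, 2 = 20-50 m,
#' 3 = 50-100 m, 4 = >100 m) from a cumulative-logit law with equidistant
#' thresholds. The linear predictor is
#' `eta = beta_size * (size - mean(size)) + beta_season * winter +
#' beta_interaction * (size - mean(size)) * winter`
#' (size centered at the realized pooled mean), and
#' `P(Y <= j) = plogis(theta_j - eta)` with `theta_j = theta_base +
#' (j - 1) * theta_spacing`. Deterministic given the config (seed included).
#'
#' @param config a [spread_config()].
#' @return data frame with columns `group_id`, `group_size`, `season`
#'   (`"summer"`/`"winter"`), `spread_category` (integer 1-4), plus the
#'   centering constant as attribute `size_center`.
#' @examples
#' obs <- generate_spread_observations(spread_config(seed = 42, n_obs = 500))
#' table(obs$spread_category)
#' @export
generate_spread_observations <- function(config = spread_config()) {
  stopifnot(inherits(config, "spread_config"))
  set.seed(config$seed)
  n <- config$n_obs
  gid <- sample(names(config$group_probs), n, replace = TRUE,
                prob = config$group_probs)
  size <- stats::rnorm(n, config$group_means[gid], config$group_sds[gid])
  size <- pmax(size, 1)  # census sizes are positive
  winter <- stats::rbinom(n, 1L, config$p_winter)
  ctr <- mean(size)
  eta <- config$beta_size * (size - ctr) + config$beta_season * winter +
    config$beta_interaction * (size - ctr) * winter
  theta <- config$theta_base + (0:2) * config$theta_spacing
  u <- stats::runif(n)
  # category = 1 + number of cumulative probabilities below u
  cum <- vapply(theta, function(th) stats::plogis(th - eta), numeric(n))
  y <- 1L + rowSums(matrix(u > cum, nrow = n))
  out <- data.frame(group_id = gid, group_size = size,
                    season = ifelse(winter == 1L, "winter", "summer"),
                    spread_category = as.integer(y))
  attr(out, "size_center") <- ctr
  out
}

#' Configuration for the contest generator
#'
#' @param seed integer RNG seed.
#' @param dyad_counts named contest counts per group dyad; the defaults are
#'   the published 34/16/10/11 (71 contests in total).
#' @param n_contests optional total overriding `dyad_counts`; dyads are then
#'   sampled with probabilities proportional to `dyad_counts`.
#' @param intercept,beta_dq,beta_season,beta_ndvi logistic coefficients for
#'   the win probability: `plogis(intercept + beta_dq * spread_diff +
#'   beta_season * winter + beta_ndvi * rel_ndvi)`. The default `beta_dq =
#'   -0.52` makes spatially tighter focal groups (negative spread difference)
#'   more likely to win; season and greenness effects default to 0.
#' @param ndvi_sd standard deviation of the relative NDVI draw (mean 0).
#' @param p_winter probability a contest falls in winter.
#' @return list of class `contest_config`.
#' @export
contest_config <- function(seed = 1L,
                           dyad_counts = c("AK-BD" = 34L, "AK-NH" = 16L,
                                           "BD-CR" = 10L, "BD-NH" = 11L),
                           n_contests = NULL,
                           intercept = 0, beta_dq = -0.52, beta_season = 0,
                           beta_ndvi = 0, ndvi_sd = 0.1, p_winter = 0.5) {
  if (any(dyad_counts < 0L)) stop("'dyad_counts' must be >= 0", call. = FALSE)
  if (ndvi_sd < 0) stop("'ndvi_sd' must be non-negative", call. = FALSE)
  structure(list(seed = as.integer(seed),
                 dyad_counts = dyad_counts,
                 n_contests = if (is.null(n_contests)) NULL else as.integer(n_contests),
                 intercept = intercept, beta_dq = beta_dq,
                 beta_season = beta_season, beta_ndvi = beta_ndvi,
                 ndvi_sd = ndvi_sd, p_winter = p_winter),
            class = "contest_config")
}

#' Generate dyadic contest records
#'
#' One row per between-group contest: dyad, season, the focal-minus-rival
#' spread-category difference (`spread_diff`, uniform on the integers -3..3
#' excluding 0 — contests with identical spreads are excluded by design),
#' relative NDVI, and the focal-win indicator drawn from the logistic law of
#' [contest_config()]. Deterministic given the config.
#'
#' @param config a [contest_config()].
#' @return data frame with columns `dyad`, `season`, `spread_diff`,
#'   `rel_ndvi`, `focal_win`.
#' @examples
#' con <- generate_contests(contest_config(seed = 42))
#' nrow(con)               # 71 under the default dyad counts
#' table(con$dyad)
#' @export
generate_contests <- function(config = contest_config()) {
  stopifnot(inherits(config, "contest_config"))
  set.seed(config$seed)
  if (is.null(config$n_contests)) {
    dyad <- rep(names(config$dyad_counts), config$dyad_counts)
  } else if (config$n_contests == 0L) {
    dyad <- character(0)
  } else {
    dyad <- sample(names(config$dyad_counts), config$n_contests,
                   replace = TRUE,
                   prob = config$dyad_counts / sum(config$dyad_counts))
  }
  n <- length(dyad)
  if (n == 0L) {
    warning("zero contest counts: returning an empty record set")
    return(data.frame(dyad = character(0), season = character(0),
                      spread_diff = integer(0), rel_ndvi = numeric(0),
                      focal_win = integer(0)))
  }
  winter <- stats::rbinom(n, 1L, config$p_winter)
  spread_diff <- sample(c(-3:-1, 1:3), n, replace = TRUE)
  rel_ndvi <- stats::rnorm(n, 0, config$ndvi_sd)
  pwin <- stats::plogis(config$intercept + config$beta_dq * spread_diff +
                          config$beta_season * winter +
                          config$beta_ndvi * rel_ndvi)
  data.frame(dyad = dyad,
             season = ifelse(winter == 1L, "winter", "summer"),
             spread_diff = as.integer(spread_diff),
             rel_ndvi = rel_ndvi,
             focal_win = stats::rbinom(n, 1L, pwin))
}

#' Per-group spread-category composition
#'
#' For each observation group: the proportion of its observations falling in
#' each spread category (rows sum to 1) and the group's share of the pooled
#' sample.
#'
#' @param records data frame as from [generate_spread_observations()].
#' @return list with `proportions` (groups x categories matrix) and
#'   `group_share_pct` (named percentages summing to 100).
#' @examples
#' obs <- generate_spread_observations(spread_config(seed = 1, n_obs = 2000))
#' summarize_spread_by_group(obs)
#' @export
summarize_spread_by_group <- function(records) {
  if (is.null(records) || nrow(records) == 0L)
    stop("cannot summarize an empty record set", call. = FALSE)
  tab <- table(records$group_id,
               factor(records$spread_category, levels = 1:4))
  props <- prop.table(tab, margin = 1L)
  share <- 100 * rowSums(tab) / nrow(records)
  list(proportions = as.matrix(unclass(props)),
       group_share_pct = share)
}
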