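# Two-group contest resolution, model thresholds and the (n1, n2) phase
# diagram of which census group wins.

#' Resolve a two-group contest
#'
#' Both groups are evaluated under the same ecology (cost, resource,
#' motivation); the group fielding the larger realized fighting size `S` wins.
#' Two readings of "more likely to win" are offered:
#' \describe{
#'   \item{`deterministic`}{winner is the group with the larger `S`; exact
#'     ties (including the no-contest case `S1 = S2 = 0`) are draws.}
#'   \item{`smooth`}{a Tullock contest success function
#'     `win_prob_1 = S1^beta / (S1^beta + S2^beta)`, with `win_prob_1 = 0.5`
#'     when both fighting sizes are 0. As `beta` grows this converges to the
#'     deterministic rule.}
#' }
#'
#' @param n1,n2 census sizes of the two groups (>= 1).
#' @param cost a [cost_profile()].
#' @param resource a [resource_profile()].
#' @param motivation a [motivation()].
#' @param rule `"deterministic"` or `"smooth"`.
#' @param beta Tullock decisiveness exponent for the smooth rule (default 1).
#' @return An object of class `contest_outcome`: list with `n1`, `n2`, `S1`,
#'   `S2`, `winner` (`"group1"`, `"group2"` or `"draw"`), and `win_prob_1`
#'   (`NA` under the deterministic rule).
#' @examples
#' resolve_contest(5, 10)    # larger group wins below patch capacity
#' resolve_contest(10, 40)   # the smaller group wins: no one joins for n = 40
#' resolve_contest(10, 40, rule = "smooth")
#' @export
resolve_contest <- function(n1, n2, cost = cost_profile(),
                            resource = resource_profile(),
                            motivation = bgcoord::motivation(),
                            rule = c("deterministic", "smooth"), beta = 1) {
  rule <- match.arg(rule)
  if (n1 < 1 || n2 < 1) stop("census sizes must be >= 1", call. = FALSE)
  S <- fighting_group_size(c(n1, n2), cost, resource, motivation)
  winner <- if (S[1] > S[2]) "group1" else if (S[2] > S[1]) "group2" else "draw"
  wp <- NA_real_
  if (rule == "smooth") {
    wp <- if (S[1] == 0 && S[2] == 0) 0.5 else S[1]^beta / (S[1]^beta + S[2]^beta)
  }
  structure(list(n1 = n1, n2 = n2, S1 = S[1], S2 = S[2], winner = winner,
                 win_prob_1 = wp, rule = rule, beta = beta),
            class = "contest_outcome")
}

#' @export
print.contest_outcome <- function(x, ...) {
  cat(sprintf("Contest: n1 = %g (S1 = %.4f) vs n2 = %g (S2 = %.4f)\n",
              x$n1, x$S1, x$n2, x$S2))
  cat("  winner:", x$winner,
      if (!is.na(x$win_prob_1))
        sprintf(" [P(group1 wins) = %.4f, smooth rule, beta = %g]",
                x$win_prob_1, x$beta) else "", "\n")
  invisible(x)
}

#' Satiation threshold
#'
#' The census size `v/s` at which the contested patch stops feeding every
#' group member to capacity (the "gray line"): below it per-capita gross
#' gains equal `s`; above it they decline as `v/n`.
#'
#' @param resource a [resource_profile()].
#' @return numeric, individuals.
#' @examples
#' satiation_threshold(resource_profile(s = 1, v = 10))  # 10
#' @export
satiation_threshold <- function(resource = resource_profile()) {
  resource <- as_resource_profile(resource)
  resource$v / resource$s
}

#' Upper viable group size
#'
#' The largest census size at which the expected individual net gain is still
#' positive (the "black arrow"): beyond it coordination costs exceed what the
#' patch can return, participation is 0 and contests no longer occur. The
#' zero crossing of the continuous net-gain function is located by a scan for
#' sign changes above the satiation threshold followed by bisection; the
#' result does not depend on `alpha`, which only scales positive gains.
#'
#' @param cost a [cost_profile()].
#' @param resource a [resource_profile()].
#' @param tol bisection tolerance (individuals), default `1e-6`.
#' @param n_max scan cap; default `10 * max(n_centers)`.
#' @return numeric, the largest root of the net gain on `(v/s, n_max]`, or
#'   `NA` (with a warning) when the net gain never turns negative on the
#'   scanned range ("no upper limit in range").
#' @examples
#' max_viable_group_size()   # 25 under default parameters
#' @export
max_viable_group_size <- function(cost = cost_profile(),
                                  resource = resource_profile(),
                                  tol = 1e-6,
                                  n_max = 10 * max(cost$n_centers)) {
  cost <- as_cost_profile(cost); resource <- as_resource_profile(resource)
  if (tol <= 0) stop("'tol' must be positive", call. = FALSE)
  # sign of the net gain g(n) matches sign of f(n) = min(s n, v) - c_g(n)
  f <- function(n) group_gain(n, resource) - group_coordination_cost(n, cost)
  lo <- satiation_threshold(resource)
  grid <- seq(lo, n_max, length.out = 4096L)
  fg <- f(grid)
  if (all(fg <= 0))
    stop("net gain is non-positive on the whole scanned range", call. = FALSE)
  # a crossing needs a strictly negative endpoint: near-total saturation of
  # the cost staircase can make f() exactly 0 in double precision without a
  # sign change
  flips <- which(fg[-length(fg)] > 0 & fg[-1L] < 0)
  if (length(flips) == 0L) {
    warning("no upper limit in range: net gain stays positive up to n_max = ",
            n_max)
    return(NA_real_)
  }
  i <- flips[length(flips)]  # largest root
  stats::uniroot(f, lower = grid[i], upper = grid[i + 1L], tol = tol)$root
}

#' Threshold report
#'
#' Convenience bundle of [satiation_threshold()] and
#' [max_viable_group_size()].
#'
#' @inheritParams max_viable_group_size
#' @return list with `satiation_threshold`, `max_viable_size`,
#'   `zero_crossing_tol`.
#' @export
threshold_report <- function(cost = cost_profile(),
                             resource = resource_profile(), tol = 1e-6) {
  list(satiation_threshold = satiation_threshold(resource),
       max_viable_size = max_viable_group_size(cost, resource, tol = tol),
       zero_crossing_tol = tol)
}

#' Phase diagram of contest winners over census-size pairs
#'
#' Resolves every pair `(n1, n2)` on integer grids under the deterministic
#' rule and reports the share of unequal pairs won by the smaller census
#' group — the model's "smaller groups can prevail" region.
#'
#' @param n1_grid,n2_grid integer census-size grids (>= 1).
#' @inheritParams resolve_contest
#' @return An object of class `phase_diagram`: list with `n1_grid`,
#'   `n2_grid`, `winner` (matrix coded 1 = group 1, 2 = group 2, 0 = draw;
#'   rows index `n1_grid`), and `smaller_wins_fraction`.
#' @examples
#' pd <- phase_diagram(1:9, 1:9)
#' pd$smaller_wins_fraction    # 0: below patch capacity the larger group wins
#' @export
phase_diagram <- function(n1_grid, n2_grid, cost = cost_profile(),
                          resource = resource_profile(),
                          motivation = bgcoord::motivation()) {
  n1_grid <- as.integer(n1_grid); n2_grid <- as.integer(n2_grid)
  if (any(n1_grid < 1L) || any(n2_grid < 1L))
    stop("grids must contain integers >= 1", call. = FALSE)
  S1 <- fighting_group_size(n1_grid, cost, resource, motivation)
  S2 <- fighting_group_size(n2_grid, cost, resource, motivation)
  d <- outer(S1, S2, "-")
  winner <- matrix(0L, nrow = length(n1_grid), ncol = length(n2_grid),
                   dimnames = list(n1 = n1_grid, n2 = n2_grid))
  winner[d > 0] <- 1L
  winner[d < 0] <- 2L
  nd <- outer(n1_grid, n2_grid, "-")  # >0 where group 1 is the larger group
  unequal <- nd != 0
  smaller_wins <- (winner == 1L & nd < 0) | (winner == 2L & nd > 0)
  frac <- if (any(unequal)) sum(smaller_wins[unequal]) / sum(unequal) else NA_real_
  structure(list(n1_grid = n1_grid, n2_grid = n2_grid, winner = winner,
                 smaller_wins_fraction = frac),
            class = "phase_diagram")
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat(sprintf("Phase diagram over %d x %d census-size pairs\n",
              length(x$n1_grid), length(x$n2_grid)))
  cat(sprintf("  smaller census group wins %.1f%% of unequal pairs\n",
              100 * x$smaller_wins_fraction))
  invisible(x)
}

#' Tabulate the model curves for several motivation levels
#'
#' Long-format table of every model quantity over an `n` grid for each value
#' of `alpha`, suitable for re-plotting the six model panels (cost staircase,
#' per-capita cost, gross/net individual gain, participation probability and
#' realized fighting size). The cost and gain columns are `alpha`-free; only
#' `p` and `S` differ across `alpha`.
#'
#' @param cost a [cost_profile()].
#' @param resource a [resource_profile()].
#' @param alphas numeric vector of motivation scalings in (0, 1].
#' @param n_grid census sizes (> 0).
#' @return data frame with columns `alpha`, `n`, `c_g`, `c_a`, `g_a`, `g`,
#'   `p`, `S`.
#' @examples
#' head(tabulate_model_curves(n_grid = 1:40))
#' @export
tabulate_model_curves <- function(cost = cost_profile(),
                                  resource = resource_profile(),
                                  alphas = c(0.4, 0.7, 1.0),
                                  n_grid = seq(1, 60, by = 0.5)) {
  if (length(alphas) < 1L) stop("'alphas' must be non-empty", call. = FALSE)
  out <- lapply(alphas, function(a) {
    ev <- evaluate_group(n_grid, cost, resource, motivation(a))
    cbind(alpha = a, ev[, c("n", "c_g", "c_a", "g_a", "g", "p", "S")])
  })
  do.call(rbind, out)
}
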