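# Mean-field model of a single group's readiness for a between-group contest:
# staircase coordination cost, capped group gain, individual net gain,
# participation probability and realized fighting-group size.

#' Group-level coordination cost
#'
#' The cost of assembling a group of census size `n` into a joint fighting
#' party, modelled as a sum of `m` sigmoid steps
#' \deqn{c_g(n) = \sum_{i=1}^{m} \frac{C_i}{1 + e^{-k_i (n - n_i)}}.}
#' Each step is the cost of recruiting the cluster of members feeding at one
#' food patch; the cost therefore rises in a staircase as group size (and
#' hence spatial spread over patches) grows. `c_g` is strictly increasing in
#' `n` and bounded above by `sum(C)`.
#'
#' @param n census group size(s), non-negative; vectorized.
#' @param cost a [cost_profile()].
#' @return numeric vector of group coordination costs (cost units).
#' @examples
#' group_coordination_cost(10, cost_profile())   # ~2.50023
#' group_coordination_cost(25, cost_profile())   # exactly 10 by symmetry
#' @export
group_coordination_cost <- function(n, cost = cost_profile()) {
  cost <- as_cost_profile(cost)
  n <- as.numeric(n)
  if (anyNA(n) || any(n < 0)) stop("'n' must be non-negative", call. = FALSE)
  # stats::plogis is the numerically stable logistic (no overflow for large
  # |k (n - n_i)|)
  x <- outer(n, seq_len(cost$m),
             function(nn, i) stats::plogis(cost$k[i] * (nn - cost$n_centers[i])))
  drop(x %*% cost$C)
}

#' Expected per-capita coordination cost
#'
#' `c_a(n) = c_g(n) / n`, the average cost per group member of mobilising the
#' group. Individuals nearer the contested patch pay less and distant ones
#' more; the model collapses this spatial heterogeneity into its mean.
#'
#' @inheritParams group_coordination_cost
#' @param n census group size(s), strictly positive; vectorized.
#' @return numeric vector of per-capita costs (cost units).
#' @examples
#' per_capita_cost(20, cost_profile())   # 0.375
#' @export
per_capita_cost <- function(n, cost = cost_profile()) {
  n <- as.numeric(n)
  if (anyNA(n) || any(n <= 0))
    stop("per-capita cost requires n > 0", call. = FALSE)
  group_coordination_cost(n, cost) / n
}

#' Expected group gain from a won contest
#'
#' The food obtained by the winning group, capped by the patch value:
#' `g_g(n) = min(s n, v)`. Below the satiation threshold `v/s` every member
#' can eat to capacity; above it the patch no longer feeds everyone.
#'
#' @param n census group size(s), non-negative; vectorized.
#' @param resource a [resource_profile()].
#' @return numeric vector of group gains (food units).
#' @examples
#' group_gain(5, resource_profile())    # 5
#' group_gain(40, resource_profile())   # 10 (capped)
#' @export
group_gain <- function(n, resource = resource_profile()) {
  resource <- as_resource_profile(resource)
  n <- as.numeric(n)
  if (anyNA(n) || any(n < 0)) stop("'n' must be non-negative", call. = FALSE)
  pmin(resource$s * n, resource$v)
}

#' Expected individual net gain
#'
#' Gross individual gain `g_a = min(s n, v)/n` (equal sharing among all
#' members, participants or not) minus the per-capita coordination cost:
#' `g = g_a - c_a`. Negative values mean joining a contest costs more than it
#' can return.
#'
#' @inheritParams group_gain
#' @param n census group size(s), strictly positive; vectorized.
#' @param cost a [cost_profile()].
#' @return numeric vector of net gains (food units); may be negative.
#' @examples
#' individual_net_gain(5, cost_profile(), resource_profile())    # ~0.9933
#' individual_net_gain(40, cost_profile(), resource_profile())   # ~-0.1875
#' @export
individual_net_gain <- function(n, cost = cost_profile(),
                                resource = resource_profile()) {
  n <- as.numeric(n)
  if (anyNA(n) || any(n <= 0))
    stop("individual net gain requires n > 0", call. = FALSE)
  group_gain(n, resource) / n - per_capita_cost(n, cost)
}

#' Probability of joining a contest
#'
#' Participation is proportional to the expected net gain when positive:
#' `p = alpha * g` clamped to `[0, 1]`, and exactly 0 whenever `g <= 0`.
#' (With the default parameters `g <= s = 1` and `alpha <= 1`, so the upper
#' clamp never binds; it is kept so `p` is a probability for any
#' parameterization.)
#'
#' @inheritParams individual_net_gain
#' @param motivation a [motivation()].
#' @return numeric vector of participation probabilities in `[0, 1]`.
#' @examples
#' participation_probability(10, motivation = motivation(0.7))  # ~0.525
#' @export
participation_probability <- function(n, cost = cost_profile(),
                                      resource = resource_profile(),
                                      motivation = bgcoord::motivation()) {
  motivation <- as_motivation(motivation)
  g <- individual_net_gain(n, cost, resource)
  pmin(1, pmax(0, motivation$alpha * g))
}

#' Realized fighting-group size
#'
#' `S = n p`: the expected number of members that actually turn up to fight.
#' Contest success is assumed to depend on `S`, not on census size itself.
#' `S` first rises with `n`, then declines once the group outgrows the patch,
#' and hits 0 at the upper viable group size.
#'
#' @inheritParams participation_probability
#' @param n census group size(s), non-negative; vectorized (`S(0) = 0`).
#' @return numeric vector of expected participant numbers, `0 <= S <= n`.
#' @examples
#' fighting_group_size(10)   # ~5.25 with defaults (alpha = 0.7)
#' fighting_group_size(40)   # 0: net gain is negative
#' @export
fighting_group_size <- function(n, cost = cost_profile(),
                                resource = resource_profile(),
                                motivation = bgcoord::motivation()) {
  n <- as.numeric(n)
  if (anyNA(n) || any(n < 0)) stop("'n' must be non-negative", call. = FALSE)
  S <- numeric(length(n))
  pos <- n > 0
  if (any(pos))
    S[pos] <- n[pos] * participation_probability(n[pos], cost, resource,
                                                 motivation)
  S
}

#' Evaluate all model quantities for a grid of group sizes
#'
#' Bundles the full chain — group cost `c_g`, per-capita cost `c_a`, group
#' gain `g_g`, gross individual gain `g_a`, net gain `g`, participation
#' probability `p` and realized fighting size `S` — into one data frame, one
#' row per census size.
#'
#' @inheritParams participation_probability
#' @param n census group size(s), strictly positive; vectorized.
#' @return A data frame with columns `n`, `c_g`, `c_a`, `g_g`, `g_a`, `g`,
#'   `p`, `S`.
#' @examples
#' evaluate_group(c(5, 10, 25, 40))
#' @export
evaluate_group <- function(n, cost = cost_profile(),
                           resource = resource_profile(),
                           motivation = bgcoord::motivation()) {
  n <- as.numeric(n)
  if (anyNA(n) || any(n <= 0))
    stop("evaluate_group requires n > 0", call. = FALSE)
  motivation <- as_motivation(motivation)
  c_g <- group_coordination_cost(n, cost)
  c_a <- c_g / n
  g_g <- group_gain(n, resource)
  g_a <- g_g / n
  g <- g_a - c_a
  p <- pmin(1, pmax(0, motivation$alpha * g))
  data.frame(n = n, c_g = c_g, c_a = c_a, g_g = g_g, g_a = g_a,
             g = g, p = p, S = n * p)
}
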