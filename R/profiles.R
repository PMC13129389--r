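#' Coordination-cost profile
#'
#' Bundles the parameters of the multi-phase sigmoid coordination-cost
#' function: `m` steps, each with a magnitude `C[i]`, a steepness `k[i]` and a
#' transition center `n_centers[i]`. Each step corresponds to one cluster of
#' group members occupying one food patch (e.g. a fruit tree), so `m` is the
#' number of patches over which a fully spread group is distributed, and
#' `C[i]` the cost of recruiting the members of patch `i` into a joint fight.
#'
#' @param C numeric vector of step magnitudes (cost units), all positive.
#' @param k numeric vector of step steepnesses (per individual), all positive.
#' @param n_centers numeric vector of transition centers (individuals),
#'   positive and strictly increasing.
#' @return An object of class `cost_profile`: a list with elements `m`, `C`,
#'   `k`, `n_centers`.
#' @examples
#' cost_profile()            # the default four-tree staircase
#' cost_profile(C = c(5, 5), k = c(1, 2), n_centers = c(10, 20))
#' @seealso [group_coordination_cost()], [resource_profile()], [motivation()]
#' @export
cost_profile <- function(C = c(5, 5, 5, 5), k = c(1, 1, 1, 1),
                         n_centers = c(10, 20, 30, 40)) {
  C <- as.numeric(C); k <- as.numeric(k); n_centers <- as.numeric(n_centers)
  m <- length(C)
  if (m < 1L || length(k) != m || length(n_centers) != m)
    stop("'C', 'k' and 'n_centers' must be non-empty vectors of equal length",
         call. = FALSE)
  if (anyNA(c(C, k, n_centers)))
    stop("cost profile parameters must not contain NA", call. = FALSE)
  if (any(C <= 0) || any(k <= 0) || any(n_centers <= 0))
    stop("all cost profile entries must be strictly positive", call. = FALSE)
  if (m > 1L && any(diff(n_centers) <= 0))
    stop("'n_centers' must be strictly increasing", call. = FALSE)
  structure(list(m = m, C = C, k = k, n_centers = n_centers),
            class = "cost_profile")
}

#' Resource profile of the contested patch
#'
#' @param s mean per-individual consumption capacity (food units), positive.
#' @param v value of the contested resource patch (food units), positive.
#' @return An object of class `resource_profile`.
#' @examples
#' resource_profile()         # s = 1, v = 10
#' @export
resource_profile <- function(s = 1, v = 10) {
  s <- as.numeric(s); v <- as.numeric(v)
  if (length(s) != 1L || length(v) != 1L || is.na(s) || is.na(v) ||
      s <= 0 || v <= 0)
    stop("'s' and 'v' must be single positive numbers", call. = FALSE)
  structure(list(s = s, v = v), class = "resource_profile")
}

#' Motivation scaling
#'
#' `alpha` scales the willingness of an individual to join a fight given a
#' positive expected net gain; it can be read as a species characteristic.
#' Values on (0, 1] are accepted (1 makes participation probability equal the
#' net gain when gains are below 1).
#'
#' @param alpha dimensionless scaling in (0, 1].
#' @return An object of class `motivation`.
#' @examples
#' motivation(0.7)
#' @export
motivation <- function(alpha = 0.7) {
  alpha <- as.numeric(alpha)
  if (length(alpha) != 1L || is.na(alpha) || alpha <= 0 || alpha > 1)
    stop("'alpha' must be a single number in (0, 1]", call. = FALSE)
  structure(list(alpha = alpha), class = "motivation")
}

#' Default model parameter set
#'
#' The parameter set used throughout the package documentation and tests:
#' four equal cost steps (`C = 5`, `k = 1`, centers 10, 20, 30, 40), unit
#' consumption capacity, patch value 10 and `alpha = 0.7`.
#'
#' @return A list with elements `cost`, `resource`, `motivation`.
#' @examples
#' p <- default_params()
#' fighting_group_size(10, p$cost, p$resource, p$motivation)
#' @export
default_params <- function() {
  list(cost = cost_profile(), resource = resource_profile(),
       motivation = motivation())
}

#' Read model parameters from a YAML config file
#'
#' Recognized keys: `cost.C`, `cost.k`, `cost.n_centers`, `resource.s`,
#' `resource.v`, `motivation.alpha`. Missing keys fall back to the defaults
#' of [default_params()].
#'
#' @param path path to a YAML file.
#' @return A list with elements `cost`, `resource`, `motivation`.
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  dft <- default_params()
  cost <- cost_profile(
    C = cfg$cost$C %||% dft$cost$C,
    k = cfg$cost$k %||% dft$cost$k,
    n_centers = cfg$cost$n_centers %||% dft$cost$n_centers)
  res <- resource_profile(s = cfg$resource$s %||% dft$resource$s,
                          v = cfg$resource$v %||% dft$resource$v)
  mot <- motivation(alpha = cfg$motivation$alpha %||% dft$motivation$alpha)
  list(cost = cost, resource = res, motivation = mot)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cost_profile <- function(x, ...) {
  cat("Coordination-cost profile (", x$m, " sigmoid steps)\n", sep = "")
  print(data.frame(step = seq_len(x$m), C = x$C, k = x$k,
                   center = x$n_centers), row.names = FALSE)
  invisible(x)
}

#' @export
print.resource_profile <- function(x, ...) {
  cat("Resource profile: s =", x$s, "(consumption capacity), v =", x$v,
      "(patch value); satiation threshold v/s =", x$v / x$s, "\n")
  invisible(x)
}

#' @export
print.motivation <- function(x, ...) {
  cat("Motivation scaling: alpha =", x$alpha, "\n")
  invisible(x)
}

as_cost_profile <- function(x) {
  if (inherits(x, "cost_profile")) return(x)
  stop("expected a 'cost_profile' object; see cost_profile()", call. = FALSE)
}
as_resource_profile <- function(x) {
  if (inherits(x, "resource_profile")) return(x)
  stop("expected a 'resource_profile' object; see resource_profile()",
       call. = FALSE)
}
as_motivation <- function(x) {
  if (inherits(x, "motivation")) return(x)
  stop("expected a 'motivation' object; see motivation()", call. = FALSE)
}
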