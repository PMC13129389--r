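# Independent brute-force oracles: deliberately naive, scalar, loop-based
# implementations used to cross-check the package's vectorized / optimized
# code paths. They share no code with R/.

# naive staircase cost: plain 1/(1+exp(-x)) term-by-term sum at one n
naive_cost <- function(n, C = c(5, 5, 5, 5), k = c(1, 1, 1, 1),
                       centers = c(10, 20, 30, 40)) {
  total <- 0
  for (i in seq_along(C))
    total <- total + C[i] / (1 + exp(-k[i] * (n - centers[i])))
  total
}

# naive chain at one n: returns all model quantities as a list
naive_eval <- function(n, C = c(5, 5, 5, 5), k = c(1, 1, 1, 1),
                       centers = c(10, 20, 30, 40), s = 1, v = 10,
                       alpha = 0.7) {
  c_g <- naive_cost(n, C, k, centers)
  c_a <- c_g / n
  g_g <- min(s * n, v)
  g_a <- g_g / n
  g <- g_a - c_a
  p <- min(1, max(0, alpha * g))
  list(c_g = c_g, c_a = c_a, g_g = g_g, g_a = g_a, g = g, p = p, S = n * p)
}

# random valid cost profile for property tests
random_cost_profile <- function() {
  m <- sample(1:5, 1)
  cost_profile(C = runif(m, 0.5, 10), k = runif(m, 0.2, 3),
               n_centers = sort(runif(m, 2, 80)) + seq(0, m - 1) * 0.5)
}

# closed-form cumulative-logit category probabilities at one covariate row
ordinal_cell_probs <- function(eta, theta) {
  cum <- c(1 / (1 + exp(-(theta - eta))), 1)
  diff(c(0, cum))
}

expect_rel_equal <- function(object, expected, rel_tol = 1e-9) {
  expect_true(abs(object - expected) <= rel_tol * max(1, abs(expected)),
              label = sprintf("|%.12g - %.12g| <= %g rel", object, expected,
                              rel_tol))
}
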