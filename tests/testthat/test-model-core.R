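# Mean-field model: staircase cost, capped gain, net gain, participation and
# realized fighting size, all checked against naive scalar oracles.

test_that("staircase cost matches the naive per-term oracle on a grid", {
  cost <- cost_profile()
  for (n in c(0, 0.5, 5, 9, 10, 20, 25, 33.3, 40, 100, 1000)) {
    expect_equal(group_coordination_cost(n, cost), naive_cost(n),
                 tolerance = 1e-12)
  }
  # frozen values forced by the default parameterization
  expect_rel_equal(group_coordination_cost(10, cost), 2.5002269996497, 1e-9)
  expect_rel_equal(group_coordination_cost(5, cost), 0.0334657842020, 1e-9)
  # paired-sigmoid symmetry: steps (1,4) and (2,3) sum to C at the midpoint
  expect_equal(group_coordination_cost(25, cost), 10, tolerance = 1e-12)
  # saturation at the total step mass
  expect_equal(group_coordination_cost(1000, cost), 20, tolerance = 1e-9)
})

test_that("cost is strictly increasing and bounded for random profiles", {
  set.seed(7)
  for (rep in 1:20) {
    cp <- random_cost_profile()
    # weak monotonicity and bounds hold everywhere, including deep
    # saturation where double precision pins each sigmoid at its ceiling
    n_wide <- sort(runif(50, 0, 3 * max(cp$n_centers)))
    cg_wide <- group_coordination_cost(n_wide, cp)
    expect_true(all(diff(cg_wide) >= 0))
    expect_true(all(cg_wide > 0) && all(cg_wide <= sum(cp$C)))
    # strict monotonicity and the open upper bound are testable wherever
    # the steepest exponent stays within floating-point resolution
    n_live <- sort(runif(50, 0, max(cp$n_centers) + 25 / max(cp$k)))
    cg_live <- group_coordination_cost(n_live, cp)
    expect_true(all(diff(cg_live) > 0))
    expect_true(all(cg_live < sum(cp$C)))
  }
})

test_that("cost profile validation rejects malformed inputs", {
  expect_error(cost_profile(C = c(5, 5), k = 1, n_centers = c(10, 20)),
               "equal length")
  expect_error(cost_profile(C = c(5, -1), k = c(1, 1), n_centers = c(10, 20)),
               "positive")
  expect_error(cost_profile(C = c(5, 5), k = c(1, 1), n_centers = c(20, 10)),
               "increasing")
  expect_error(group_coordination_cost(-1), "non-negative")
  expect_error(per_capita_cost(0), "n > 0")
})

test_that("per-capita cost, gain and net gain agree with the naive chain", {
  for (n in c(0.5, 5, 10, 20, 24.9, 25, 40, 77)) {
    o <- naive_eval(n)
    expect_equal(per_capita_cost(n), o$c_a, tolerance = 1e-12)
    expect_equal(group_gain(n), o$g_g, tolerance = 1e-12)
    expect_equal(individual_net_gain(n), o$g, tolerance = 1e-12)
    expect_equal(participation_probability(n), o$p, tolerance = 1e-12)
    expect_equal(fighting_group_size(n), o$S, tolerance = 1e-12)
  }
  # frozen: c_a(20) = 0.375 exactly up to the far sigmoid tails
  expect_rel_equal(per_capita_cost(20), 0.375, 1e-8)
  expect_rel_equal(per_capita_cost(5), 0.0066931568404, 1e-9)
  expect_rel_equal(individual_net_gain(5), 0.9933068431596, 1e-9)
  expect_rel_equal(individual_net_gain(40), -0.1874943250088, 1e-9)
  # zero crossing by symmetry: g_a(25) = c_a(25) = 0.4
  expect_equal(individual_net_gain(25), 0, tolerance = 1e-12)
})

test_that("gross gain is flat at s below v/s and strictly declining above", {
  res <- resource_profile(s = 1.5, v = 12)
  kink <- satiation_threshold(res)           # 8
  below <- seq(0.5, kink, by = 0.5)
  expect_true(all(abs(group_gain(below, res) / below - res$s) < 1e-12))
  above <- seq(kink + 0.5, 60, by = 0.5)
  ga <- group_gain(above, res) / above
  expect_true(all(diff(ga) < 0))
})

test_that("participation probability is clamped and scales with alpha", {
  expect_equal(participation_probability(40), 0)
  expect_rel_equal(participation_probability(10, motivation = motivation(0.7)),
                   0.5249841100245, 1e-9)
  expect_rel_equal(participation_probability(5, motivation = motivation(1)),
                   individual_net_gain(5), 1e-12)
  # clamp at 1 for parameterizations with large per-capita gains
  rich <- resource_profile(s = 5, v = 50)
  expect_equal(participation_probability(5, resource = rich,
                                         motivation = motivation(1)), 1)
  p <- participation_probability(c(2, 10, 20, 30, 40, 60))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("fighting size rises then falls and vanishes past the limit", {
  S <- fighting_group_size(c(0, 5, 10, 20, 40))
  expect_equal(S[1], 0)
  expect_rel_equal(S[3], 5.2498411002452, 1e-9)          # S(10), alpha = 0.7
  expect_equal(S[4], 1.75, tolerance = 1e-8)        # S(20) = 20 * 0.0875
  expect_equal(S[5], 0)                             # past the viable limit
  expect_gt(S[3], S[2])                             # S(10) > S(5)
  expect_lt(S[4], S[3])                             # S(20) < S(10)
  n <- seq(1, 60, by = 0.25)
  expect_true(all(fighting_group_size(n) <= n))
})

test_that("evaluate_group is internally consistent and matches elementwise", {
  n <- c(0.5, 3, 10, 19.5, 25, 40, 55)
  ev <- evaluate_group(n)
  expect_equal(ev$c_a * ev$n, ev$c_g, tolerance = 1e-12)
  expect_equal(ev$g, ev$g_a - ev$c_a, tolerance = 1e-12)
  expect_equal(ev$S, ev$n * ev$p, tolerance = 1e-12)
  expect_true(all(ev$p[ev$g <= 0] == 0))
  for (i in seq_along(n)) {
    o <- naive_eval(n[i])
    expect_equal(unlist(ev[i, -1]), unlist(o), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  # a lone individual facing huge assembly costs never fights
  huge <- cost_profile(C = rep(1000, 4), k = rep(1, 4),
                       n_centers = c(0.5, 1, 2, 3))
  ev1 <- evaluate_group(1, cost = huge)
  expect_equal(ev1$p, 0)
  expect_equal(ev1$S, 0)
})
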