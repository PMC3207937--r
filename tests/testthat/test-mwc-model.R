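test_that("equilibrium activity matches its closed-form anchors", {
  # half-maximal basal activity at K = 1, any c and n
  expect_equal(equilibrium_activity(sensor_params(1, 0.01, 4), 0), 0.5)
  expect_equal(equilibrium_activity(sensor_params(1, 0.5, 1), 0), 0.5)
  # weak-basal monomer
  expect_equal(equilibrium_activity(sensor_params(100, 0.01, 1), 0), 1 / 101)
  # saturation limit 1/(1 + K c^n): K*c = 1 gives one half for a monomer
  p <- sensor_params(100, 0.01, 1)
  expect_equal(equilibrium_activity(p, 1e12), 0.5, tolerance = 1e-9)
  expect_error(equilibrium_activity(p, -1), "nonnegative")
})

test_that("activity is monotone in input and pinned at its endpoints", {
  set.seed(101)
  for (i in 1:25) {
    p <- random_params()
    bs <- basal_saturation(p)
    expect_equal(equilibrium_activity(p, 0), bs[["basal"]])
    x0 <- threshold_input(p)
    xs <- 10^seq(log10(x0) - 3, log10(x0) + 3, length.out = 60)
    a <- equilibrium_activity(p, xs)
    # nondecreasing everywhere (the saturated tail flattens in double
    # precision), strictly increasing through the response region
    expect_true(all(diff(a) >= 0))
    expect_gt(equilibrium_activity(p, x0 * 2), equilibrium_activity(p, x0))
    # saturation approached far beyond the threshold
    expect_equal(equilibrium_activity(p, 1e9 * x0), bs[["saturation"]],
                 tolerance = 1e-6)
  }
  # c = 1 gives a flat response at the basal level
  pf <- sensor_params(100, 1, 4)
  expect_equal(basal_saturation(pf)[["saturation"]],
               basal_saturation(pf)[["basal"]])
  expect_equal(equilibrium_activity(pf, 17), 1 / 101)
})

test_that("parameter validation rejects unsupported regimes", {
  expect_error(sensor_params(-1, 0.5, 1), "K")
  expect_error(sensor_params(1, 1.5, 1), "inverted")
  expect_error(sensor_params(1, 0, 1), "inverted")
  expect_error(sensor_params(1, 0.5, 0), "n")
})

test_that("basal and saturation levels take their closed forms", {
  expect_equal(basal_saturation(sensor_params(100, 0.01, 1)),
               c(basal = 1 / 101, saturation = 0.5))
  bs4 <- basal_saturation(sensor_params(100, 0.01, 4))
  expect_equal(bs4[["basal"]], 0.00990099, tolerance = 1e-6)
  expect_equal(bs4[["saturation"]], 1 / (1 + 1e-6), tolerance = 1e-9)
})

test_that("threshold input solves the midpoint condition exactly", {
  # strong-binding limits with closed-form thresholds
  expect_equal(threshold_input(sensor_params(2, 1e-14, 1)), 3,
               tolerance = 1e-9)
  expect_equal(threshold_input(sensor_params(2, 1e-14, 2)), 1,
               tolerance = 1e-9)
  expect_error(threshold_input(sensor_params(2, 1, 2)), "degenerate")
  set.seed(202)
  for (i in 1:40) {
    p <- random_params()
    x0 <- threshold_input(p)
    bs <- basal_saturation(p)
    expect_equal(equilibrium_activity(p, x0),
                 (bs[["basal"]] + bs[["saturation"]]) / 2,
                 tolerance = 1e-10)
    # agrees with an independent bracketed root search
    expect_equal(x0, threshold_oracle(p), tolerance = 1e-8)
  }
})

test_that("kinetic rates encode the biases and enforce cycle closure", {
  kr <- kinetic_rates(f_R = 0.01, b_R = 1, f_T = 0.01, b_T = 100,
                      f_L = 10, b_L = 0.1)
  expect_equal(rate_biases(kr), c(K = 100, c = 0.01))
  expect_error(kinetic_rates(1, 1, 1, 1, 1, 1, f_L_i = 2, b_L_i = NULL),
               "pair")
  # per-occupancy rates must satisfy f_L_i / b_L_i = K * c^i
  expect_error(kinetic_rates(0.01, 1, 0.01, 100, 10, 0.1,
                             f_L_i = c(1, 1), b_L_i = c(1, 1)),
               "cycle closure")
  ok <- kinetic_rates(0.01, 1, 0.01, 100, 10, 0.1,
                      f_L_i = 100 * c(0.01, 0.01^2) * c(2, 3),
                      b_L_i = c(2, 3))
  expect_s3_class(ok, "kinetic_rates")
})

test_that("rate-matrix stationary activity reproduces the equilibrium law", {
  # zero input: two-conformation equilibrium 1/(1+K)
  kr <- rates_small_pool()
  Q0 <- build_rate_matrix(kr, 1, 0)
  expect_equal(single_sensor_active_probability(Q0), 1 / 101,
               tolerance = 1e-12)
  expect_true(all(abs(rowSums(Q0)) < 1e-12))
  # the printed high-basal tetramer set at an arbitrary input
  p <- sensor_params(2, 0.1, 4)
  Q <- build_rate_matrix(rates_high_basal(), 4, 0.7)
  expect_equal(single_sensor_active_probability(Q),
               equilibrium_activity(p, 0.7), tolerance = 1e-10)
  # property: agreement over random parameter sets and both topologies
  set.seed(303)
  for (i in 1:150) {
    n <- sample(c(1L, 2L, 4L, 8L), 1L)
    K <- 10^runif(1, 0, 6); c_ <- 10^runif(1, -6, 0)
    topo <- sample(c("L_only", "all_transitions"), 1L)
    kr_i <- complete_rates(K, c_, n, topology = topo)
    x <- 10^runif(1, -2, 2)
    Qx <- build_rate_matrix(kr_i, n, x, topo)
    pref <- 1 / (1 + exp(log(K) + n * log1p(c_ * x) - n * log1p(x)))
    expect_equal(single_sensor_active_probability(Qx), pref,
                 tolerance = 1e-8)
  }
})

test_that("stationary activity is invariant to the transition topology", {
  set.seed(404)
  for (i in 1:20) {
    n <- sample(c(2L, 4L, 8L), 1L)
    K <- 10^runif(1, 0, 4); c_ <- 10^runif(1, -4, 0)
    kr_all <- complete_rates(K, c_, n, topology = "all_transitions")
    kr_L <- kinetic_rates(kr_all$f_R, kr_all$b_R, kr_all$f_T, kr_all$b_T,
                          kr_all$f_L, kr_all$b_L)
    x <- 10^runif(1, -1, 1)
    pa <- single_sensor_active_probability(
      build_rate_matrix(kr_all, n, x, "all_transitions"))
    pl <- single_sensor_active_probability(build_rate_matrix(kr_L, n, x))
    expect_equal(pa, pl, tolerance = 1e-9)
    # scaling a conformational pair by a common factor keeps ratios, hence p
    kr_s <- kr_all
    kr_s$f_L_i <- kr_all$f_L_i * 7.3
    kr_s$b_L_i <- kr_all$b_L_i * 7.3
    ps <- single_sensor_active_probability(
      build_rate_matrix(kr_s, n, x, "all_transitions"))
    expect_equal(ps, pa, tolerance = 1e-9)
  }
})

test_that("all-transitions topology requires per-occupancy rates", {
  expect_error(build_rate_matrix(rates_small_pool(), 4, 1, "all_transitions"),
               "per-occupancy")
})
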