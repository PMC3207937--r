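test_that("dynamic range takes its closed-form values", {
  expect_equal(dynamic_range(sensor_params(100, 0.01, 1)), 0.4901, tolerance = 1e-4)
  expect_equal(dynamic_range(sensor_params(100, 0.01, 4)), 0.9901, tolerance = 1e-4)
  expect_equal(dynamic_range(sensor_params(7, 1, 8)), 0)
  expect_equal(dynamic_range(sensor_params(50, 1e-3, 2)),
               1 / (1 + 50 * 1e-6) - 1 / 51)
})

test_that("the Hill number is the logit slope at half-saturation", {
  # exactly one for monomers, any biases
  expect_identical(hill_number(sensor_params(3, 0.2, 1)), 1)
  expect_identical(hill_number(sensor_params(1e6, 1e-6, 1)), 1)
  # frozen value for a strongly sigmoidal tetramer (finite-difference oracle)
  expect_equal(hill_number(sensor_params(1e6, 1e-6, 4)), 3.873394,
               tolerance = 1e-6)
  # approach to the maximum n as K grows with K c^n still small
  h_seq <- sapply(10^c(6, 8, 10, 12), function(K)
    hill_number(sensor_params(K, 1e-13, 4)))
  expect_true(all(diff(h_seq) > 0))
  expect_lt(abs(h_seq[4] - 4), 0.005)
  # agreement with the centred finite-difference logit slope
  set.seed(505)
  for (i in 1:30) {
    p <- random_params(n = sample(c(2L, 4L, 8L), 1L))
    expect_equal(hill_number(p), hill_oracle(p), tolerance = 1e-5)
  }
  expect_equal(hill_number(sensor_params(2, 0.1, 4)),
               hill_oracle(sensor_params(2, 0.1, 4)), tolerance = 1e-6)
})

test_that("Hill numbers stay within [1, n] across the sampled ranges", {
  set.seed(606)
  for (i in 1:200) {
    p <- random_params()
    h <- hill_number(p)
    expect_gte(h, 1 - 1e-9)
    expect_lte(h, p$n + 1e-9)
  }
})

test_that("intrinsic noise follows the binomial coefficient of variation", {
  # activity one half with 100 sensors: eta = sqrt(0.5 / 50) = 0.1
  p <- sensor_params(1, 0.5, 1, N = 100)   # basal activity exactly 0.5
  expect_equal(intrinsic_noise(p, 0), 0.1)
  # vanishes as the population saturates fully active
  p2 <- sensor_params(100, 1e-4, 4, N = 100)
  expect_lt(intrinsic_noise(p2, 1e8), 1e-3)
  # doubling N halves eta^2 at fixed activity
  p4 <- sensor_params(2, 0.1, 4, N = 100)
  p8 <- sensor_params(2, 0.1, 4, N = 200)
  expect_equal(intrinsic_noise(p4, 1)^2 / intrinsic_noise(p8, 1)^2, 2)
  # monotone decrease with input for the high-basal tetramer
  eta <- intrinsic_noise(p4, seq(0.05, 5, length.out = 40))
  expect_true(all(diff(eta) < 0))
})

test_that("active-count variance peaks at half activity, not the threshold", {
  p <- sensor_params(2, 0.1, 4, N = 100)
  expect_equal(activity_variance(sensor_params(1, 0.5, 1, 100), 0), 25)
  x_half <- allosense:::activity_inverse(p, 0.5)
  x0 <- threshold_input(p)
  expect_gt(activity_variance(p, x_half), activity_variance(p, x0))
  expect_gt(x0, x_half)  # threshold lies above the variance maximiser here
  xs <- seq(0.01, 3, length.out = 400)
  expect_equal(xs[which.max(activity_variance(p, xs))], x_half,
               tolerance = 0.02)
})

test_that("capacity matches the quadrature oracle and orders sensibly", {
  quad_capacity <- function(p) {
    x0 <- threshold_input(p)
    xg <- 10^seq(log10(x0) - 8, log10(x0) + 8, length.out = 20001)
    a <- equilibrium_activity(p, xg)
    f <- static_gain(p, xg) * sqrt(p$N / (a * (1 - a)))
    Z <- sum(diff(xg) * (head(f, -1) + tail(f, -1))) / 2
    log2(Z / sqrt(2 * pi * exp(1)))
  }
  for (pars in list(sensor_params(100, 0.01, 4, 100),
                    sensor_params(100, 0.01, 1, 100),
                    sensor_params(2, 0.1, 4, 100),
                    sensor_params(1e4, 1e-3, 2, 100))) {
    expect_equal(capacity(pars)$bits, quad_capacity(pars), tolerance = 1e-6)
  }
  # near-ideal response with N = 100: log2(10 pi / sqrt(2 pi e)) bits
  p_ideal <- sensor_params(1e9, 1e-9, 2, 100)
  expect_equal(capacity(p_ideal)$bits, log2(10 * pi / sqrt(2 * pi * exp(1))),
               tolerance = 1e-3)
  # monotone: capacity grows with saturation (lower K c^n at fixed basal
  # would need K fixed), falls with basal at fixed saturation (K c fixed)
  expect_gt(capacity(sensor_params(100, 0.001, 1, 100))$bits,
            capacity(sensor_params(100, 0.01, 1, 100))$bits)
  expect_gt(capacity(sensor_params(1000, 0.001, 1, 100))$bits,
            capacity(sensor_params(100, 0.01, 1, 100))$bits)
  expect_error(capacity(sensor_params(10, 1, 1)), "degenerate")
  # tiny dynamic range: approximation invalid
  expect_false(capacity(sensor_params(1.5, 0.9, 1, 100))$valid)
  expect_true(capacity(sensor_params(100, 0.01, 4, 100))$valid)
})

test_that("optimal distributions normalize and shape as the theory says", {
  trapz <- allosense:::trapz
  # wide-range tetramer: bimodal output density peaking at both edges
  od4 <- optimal_distributions(sensor_params(100, 0.01, 4, 100))
  expect_equal(trapz(od4$input$x, od4$input$density), 1, tolerance = 1e-6)
  expect_equal(trapz(od4$output$activity, od4$output$density), 1,
               tolerance = 1e-6)
  dens <- od4$output$density
  expect_gt(dens[1], min(dens))
  expect_gt(dens[length(dens)], min(dens))
  imin <- which.min(dens)
  expect_true(imin > 1 && imin < length(dens))  # interior minimum => 2 peaks
  # output density proportional to 1 / sqrt(a (1 - a)) on its support
  shape <- 1 / sqrt(od4$output$activity * (1 - od4$output$activity))
  expect_equal(dens, shape / trapz(od4$output$activity, shape),
               tolerance = 1e-10)
  # monomer saturating at one half: at most one (edge) peak
  od1 <- optimal_distributions(sensor_params(100, 0.01, 1, 100))
  d1 <- od1$output$density
  expect_true(all(diff(d1) < 0))   # strictly decreasing: single left-edge peak
  expect_error(optimal_distributions(sensor_params(100, 0.01, 4, 100),
                                     x_grid = c(1, 2)), "cover")
})

test_that("static gain matches its closed form and the slope oracle", {
  # monomer, K = 1, strong binding: activity (1+x)/(2+x), slope 1/(2+x)^2
  p <- sensor_params(1, 1e-14, 1)
  expect_equal(threshold_input(p), 2, tolerance = 1e-9)
  expect_equal(static_gain(p, 2), 1 / 16, tolerance = 1e-10)
  expect_equal(static_gain(sensor_params(5, 1, 3), 1.3), 0)
  set.seed(707)
  for (i in 1:25) {
    pr <- random_params()
    x <- 10^runif(1, -1, 1) * threshold_input(pr)
    h <- x * 1e-6
    fd <- (equilibrium_activity(pr, x + h) -
             equilibrium_activity(pr, x - h)) / (2 * h)
    expect_equal(static_gain(pr, x), fd, tolerance = 1e-5)
  }
})

test_that("the linearized state space is stable and has the right DC gain", {
  set.seed(808)
  for (i in 1:30) {
    n <- sample(c(1L, 2L, 4L, 8L), 1L)
    K <- 10^runif(1, 0, 5); c_ <- 10^runif(1, -5, -0.1)
    kr <- complete_rates(K, c_, n)
    p <- sensor_params(K, c_, n)
    x0 <- threshold_input(p)
    ss <- build_state_space(kr, n, x0)
    expect_equal(nrow(ss$A), 2L * (n + 1L) - 1L)
    ev <- eigen(ss$A, only.values = TRUE)$values
    expect_true(all(Re(ev) < 0))
    dc <- as.numeric(ss$C %*% solve(-ss$A, ss$B))
    expect_equal(dc, static_gain(p, x0), tolerance = 1e-8)
  }
})

test_that("the sensor is a low-pass filter of relative degree two", {
  set.seed(909)
  for (n in c(1L, 2L, 4L, 8L)) {
    K <- 10^runif(1, 0.5, 4); c_ <- 10^runif(1, -4, -0.5)
    kr <- complete_rates(K, c_, n)
    x0 <- threshold_input(sensor_params(K, c_, n))
    fr <- frequency_response(build_state_space(kr, n, x0))
    expect_equal(fr$relative_degree, 2L)
    expect_equal(length(fr$poles) - length(fr$zeros), 2L)
    expect_true(all(Re(fr$poles) < 0))
    expect_equal(fr$cutoff, min(Mod(fr$poles)))
    # no gain above DC anywhere, decay beyond the cutoff
    expect_true(all(fr$gain <= fr$dc_gain * (1 + 1e-6)))
    expect_lt(fr$gain[length(fr$gain)], 0.05 * fr$dc_gain)
    # omega^-2 tail: gain * omega^2 approaches the asymptote constant
    w_hi <- c(30, 100, 300) * max(Mod(fr$poles))
    g_hi <- frequency_response(build_state_space(kr, n, x0), omega = w_hi)$gain
    expect_equal(g_hi * w_hi^2 / fr$hf_asymptote, rep(1, 3), tolerance = 0.01)
  }
})

test_that("response time is deterministic, scale-covariant and ODE-exact", {
  kr <- rates_high_basal()
  p <- sensor_params(2, 0.1, 4)
  x0 <- threshold_input(p)
  tau <- response_time(kr, 4, x0)
  expect_identical(tau, response_time(kr, 4, x0))  # bit-for-bit
  expect_gt(tau, 0)
  # time-rescaling: multiplying every rate by lambda divides tau by lambda
  lam <- 37.5
  kr_s <- kinetic_rates(kr$f_R * lam, kr$b_R * lam, kr$f_T * lam,
                        kr$b_T * lam, kr$f_L * lam, kr$b_L * lam)
  expect_equal(response_time(kr_s, 4, x0), tau / lam, tolerance = 1e-9)
  # independent ODE-integrator oracle (deSolve), both topologies
  skip_if_not_installed("deSolve")
  check_ode <- function(rates, n, x_step, topology) {
    tau_pkg <- response_time(rates, n, x_step, topology)
    Q <- build_rate_matrix(rates, n, x_step, topology)
    M <- t(Q)
    y0 <- stationary_distribution(build_rate_matrix(rates, n, 0, topology))
    a_inf <- sum(stationary_distribution(Q)[seq_len(n + 1)])
    a0 <- sum(y0[seq_len(n + 1)])
    out <- deSolve::ode(y0, seq(0, 3 * tau_pkg, length.out = 4000),
                        function(t, y, pp) list(as.numeric(M %*% y)), NULL)
    act <- rowSums(out[, 1 + seq_len(n + 1), drop = FALSE])
    t_cross <- unname(out[min(which(act >= (a0 + a_inf) / 2)), 1])
    expect_equal(tau_pkg, t_cross, tolerance = 2e-3)
  }
  check_ode(kr, 4, x0, "L_only")
  kr_all <- complete_rates(200, 0.02, n = 4, topology = "all_transitions",
                           seed = 99)
  x0a <- threshold_input(sensor_params(200, 0.02, 4))
  check_ode(kr_all, 4, x0a, "all_transitions")
})

test_that("characterize bundles the six calculators consistently", {
  p <- sensor_params(100, 0.01, 4, 100)
  kr <- rates_small_pool()
  rec <- characterize(p, kr)
  expect_equal(rec$r, dynamic_range(p))
  expect_equal(rec$h, hill_number(p))
  expect_equal(rec$x0, threshold_input(p))
  expect_equal(rec$eta_thr, intrinsic_noise(p, rec$x0))
  expect_equal(rec$G0_thr, static_gain(p, rec$x0))
  expect_equal(rec$capacity_bits, capacity(p)$bits)
  expect_true(rec$capacity_valid)
  expect_equal(rec$tau_norm, response_time(kr, 4, rec$x0))
  expect_equal(rec$r, 0.990098, tolerance = 1e-5)
  expect_lte(rec$h, 4)
  expect_error(characterize(sensor_params(5, 1, 2)), "degenerate")
  expect_error(characterize(p, rates_high_basal()), "inconsistent")
  # without rates the response time is absent, the rest unchanged
  rec2 <- characterize(p)
  expect_true(is.na(rec2$tau_norm))
  expect_equal(rec2$h, rec$h)
})
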