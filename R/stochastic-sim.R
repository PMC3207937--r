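#' Configuration for an exact stochastic simulation
#'
#' Describes a finite population of `N_sensors` MWC sensors sharing a
#' finite pool of `L_molecules` input molecules. Free-ligand depletion is
#' simulated exactly; the analytic binomial noise model assumes excess
#' input, so agreement should be judged at the self-consistent free-input
#' level (see [effective_free_input()]).
#'
#' @param rates a [kinetic_rates()] object.
#' @param n number of subunits per sensor.
#' @param N_sensors number of sensors.
#' @param L_molecules initial number of free input molecules.
#' @param t_max simulated time (seconds).
#' @param burn_in discarded initial time (seconds); default is ten times
#'   the slowest relaxation time of the zero-input single-sensor chain.
#' @param topology `"L_only"` or `"all_transitions"`.
#' @param seed RNG seed used by [gillespie_run()].
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(rates, n, N_sensors, L_molecules, t_max,
                              burn_in = NULL,
                              topology = c("L_only", "all_transitions"),
                              seed = 1L) {
  topology <- match.arg(topology)
  stopifnot(inherits(rates, "kinetic_rates"),
            n >= 1, N_sensors >= 1, L_molecules >= 0, t_max > 0)
  if (is.null(burn_in)) {
    Q0 <- build_rate_matrix(rates, n, 0, topology)
    lam <- Re(eigen(Q0, only.values = TRUE)$values)
    lam_slow <- min(abs(lam[abs(lam) > 1e-12 * max(abs(lam))]))
    burn_in <- min(10 / lam_slow, t_max / 2)
  }
  stopifnot(burn_in >= 0, t_max > burn_in)
  structure(list(rates = rates, n = as.integer(n),
                 N_sensors = as.integer(N_sensors),
                 L_molecules = as.integer(L_molecules),
                 t_max = t_max, burn_in = burn_in,
                 topology = topology, seed = as.integer(seed)),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  b <- rate_biases(x$rates)
  cat(sprintf(paste0("simulation: %d sensors (n = %d), %d input molecules, ",
                     "t_max = %g s (burn-in %.3g s), topology %s, seed %d\n"),
              x$N_sensors, x$n, x$L_molecules, x$t_max, x$burn_in,
              x$topology, x$seed))
  cat(sprintf("  biases: K = %g, c = %g\n", b[["K"]], b[["c"]]))
  invisible(x)
}

#' Mass-action reaction network of a sensor population
#'
#' Enumerates the reactions of the finite-pool model over the species
#' `R0..Rn, T0..Tn, L`: binding consumes one free `L` with propensity
#' `(n-i) f_R R_i L` (T analogue `f_T`), unbinding releases it with
#' propensity `(i+1) b_R R_{i+1}`, and conformational switching follows
#' the configured topology. Statistical site-counting factors are folded
#' into the rate constants.
#'
#' @param config a [simulation_config()].
#' @return A list with `species` (names), `reactions` (data frame with
#'   `name`, `k`, `reactant1`, `reactant2`) and `stoich` (species x
#'   reactions stoichiometry matrix).
#' @export
build_reaction_network <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n
  rates <- config$rates
  if (config$topology == "all_transitions" &&
      (is.null(rates$f_L_i) || length(rates$f_L_i) < n))
    stop("topology 'all_transitions' requires per-occupancy rates for 1..n")
  species <- c(state_labels(n), "L")
  iR <- function(i) i + 1L
  iT <- function(i) n + 2L + i
  iL <- 2L * (n + 1L) + 1L
  rx <- list()
  push <- function(name, kk, s1, s2, changes) {
    v <- integer(length(species))
    for (ch in changes) v[ch[1L]] <- v[ch[1L]] + ch[2L]
    rx[[length(rx) + 1L]] <<- list(name = name, k = kk, r1 = s1,
                                   r2 = if (is.null(s2)) -1L else s2,
                                   v = v)
  }
  for (i in 0:(n - 1L)) {
    push(sprintf("bind_R%d", i), (n - i) * rates$f_R, iR(i), iL,
         list(c(iR(i), -1L), c(iR(i + 1L), 1L), c(iL, -1L)))
    push(sprintf("unbind_R%d", i + 1L), (i + 1L) * rates$b_R, iR(i + 1L), NULL,
         list(c(iR(i + 1L), -1L), c(iR(i), 1L), c(iL, 1L)))
    push(sprintf("bind_T%d", i), (n - i) * rates$f_T, iT(i), iL,
         list(c(iT(i), -1L), c(iT(i + 1L), 1L), c(iL, -1L)))
    push(sprintf("unbind_T%d", i + 1L), (i + 1L) * rates$b_T, iT(i + 1L), NULL,
         list(c(iT(i + 1L), -1L), c(iT(i), 1L), c(iL, 1L)))
  }
  push("conf_R0_T0", rates$f_L, iR(0L), NULL,
       list(c(iR(0L), -1L), c(iT(0L), 1L)))
  push("conf_T0_R0", rates$b_L, iT(0L), NULL,
       list(c(iT(0L), -1L), c(iR(0L), 1L)))
  if (config$topology == "all_transitions") {
    for (i in seq_len(n)) {
      push(sprintf("conf_R%d_T%d", i, i), rates$f_L_i[i], iR(i), NULL,
           list(c(iR(i), -1L), c(iT(i), 1L)))
      push(sprintf("conf_T%d_R%d", i, i), rates$b_L_i[i], iT(i), NULL,
           list(c(iT(i), -1L), c(iR(i), 1L)))
    }
  }
  stoich <- vapply(rx, function(r) r$v, integer(length(species)))
  rownames(stoich) <- species
  colnames(stoich) <- vapply(rx, function(r) r$name, character(1))
  list(species = species,
       reactions = data.frame(
         name = colnames(stoich),
         k = vapply(rx, function(r) r$k, numeric(1)),
         reactant1 = vapply(rx, function(r) r$r1, integer(1)),
         reactant2 = vapply(rx, function(r) r$r2, integer(1))),
       stoich = stoich)
}

#' Exact stochastic simulation of a sensor population
#'
#' Runs the Gillespie direct method (compiled core, statistically exact
#' sampling of the chemical master equation) for the finite-pool MWC
#' model. All sensors start unbound and inactive (`T0`), all input free.
#' Identical seeds give identical trajectories.
#'
#' @param config a [simulation_config()].
#' @param keep_trajectory record event times and species counts (bounded
#'   by `max_record` events) for inspection; off by default because long
#'   runs generate millions of events.
#' @param max_record maximum recorded events when `keep_trajectory` is on.
#' @param n_batches number of equal-time batches used for batch-means
#'   standard errors.
#' @return Object of class `gillespie_run`: the config, the time-weighted
#'   occupancy of active-sensor counts after burn-in, batch summaries, the
#'   event count, the final state and (optionally) the trajectory.
#' @export
gillespie_run <- function(config, keep_trajectory = FALSE,
                          max_record = 100000L, n_batches = 50L) {
  stopifnot(inherits(config, "simulation_config"))
  net <- build_reaction_network(config)
  n <- config$n
  init <- integer(length(net$species))
  init[n + 2L] <- config$N_sensors            # all sensors start in T0
  init[length(init)] <- config$L_molecules    # free input pool
  active <- seq_len(n + 1L) - 1L              # 0-based indices of R states
  set.seed(config$seed)
  core <- gillespie_core(net$reactions$k,
                         as.integer(net$reactions$reactant1 - 1L),
                         as.integer(ifelse(net$reactions$reactant2 < 0, -1L,
                                           net$reactions$reactant2 - 1L)),
                         net$stoich, init,
                         config$t_max, config$burn_in,
                         as.integer(active), config$N_sensors,
                         if (keep_trajectory) as.integer(max_record) else 0L,
                         as.integer(n_batches))
  out <- list(config = config, network = net,
              occupancy = core$occupancy,
              batch_weight = core$batch_weight,
              batch_mean_m = core$batch_mean_m / core$batch_weight,
              batch_mean_m2 = core$batch_mean_m2 / core$batch_weight,
              n_events = core$n_events,
              final_state = setNames(core$final_state, net$species))
  if (keep_trajectory) {
    colnames(core$states) <- net$species
    out$trajectory <- list(times = core$times, states = core$states)
  }
  class(out) <- "gillespie_run"
  out
}

#' @export
print.gillespie_run <- function(x, ...) {
  cat(sprintf("Gillespie run: %.0f events over %g s (burn-in %.3g s)\n",
              x$n_events, x$config$t_max, x$config$burn_in))
  mom <- activity_moments(x)
  cat(sprintf("  stationary active count: mean %.3f (se %.3f), var %.3f\n",
              mom$mean, mom$mean_se, mom$var))
  invisible(x)
}

#' Stationary distribution of the active-sensor count
#'
#' Time-weighted occupancy of the number of active sensors over the
#' post-burn-in window of a run, as a probability mass function over
#' `m = 0..N`. If a recorded trajectory and an explicit `burn_in` are
#' supplied the distribution is recomputed from the trajectory instead.
#'
#' @param run a [gillespie_run()] result.
#' @param burn_in optional burn-in (seconds) for recomputation from a
#'   recorded trajectory.
#' @return Object of class `activity_distribution`: data frame with
#'   columns `m` and `prob`, plus attributes `source` and `N`.
#' @export
stationary_activity_distribution <- function(run, burn_in = NULL) {
  stopifnot(inherits(run, "gillespie_run"))
  N <- run$config$N_sensors
  if (!is.null(burn_in)) {
    if (is.null(run$trajectory))
      stop("recomputation from trajectory requires keep_trajectory = TRUE")
    tr <- run$trajectory
    tt <- c(tr$times, run$config$t_max)
    if (burn_in >= max(tt)) stop("empty post-burn-in window")
    m_series <- rowSums(tr$states[, seq_len(run$config$n + 1L), drop = FALSE])
    w <- pmax(pmin(tt[-1L], run$config$t_max) - pmax(tt[-length(tt)], burn_in), 0)
    occ <- vapply(0:N, function(m) sum(w[m_series == m]), numeric(1))
  } else {
    occ <- run$occupancy
  }
  if (sum(occ) <= 0) stop("empty post-burn-in window")
  structure(data.frame(m = 0:N, prob = occ / sum(occ)),
            class = c("activity_distribution", "data.frame"),
            source = "empirical", N = N)
}

#' Binomial activity distribution of the analytic noise model
#'
#' Probability that `m` of `N` independent sensors are active when each is
#' active with probability `p` (the equilibrium activity at the free-input
#' level).
#'
#' @param N number of sensors.
#' @param p single-sensor active probability.
#' @return `activity_distribution` data frame over `m = 0..N`.
#' @export
binomial_activity_distribution <- function(N, p) {
  structure(data.frame(m = 0:N, prob = stats::dbinom(0:N, N, p)),
            class = c("activity_distribution", "data.frame"),
            source = "binomial-model", N = N)
}

#' Total-variation distance between two activity distributions
#'
#' @param p,q `activity_distribution` objects (or numeric mass vectors)
#'   over the same support.
#' @return TV distance in `[0, 1]`.
#' @export
total_variation <- function(p, q) {
  pv <- if (is.data.frame(p)) p$prob else p
  qv <- if (is.data.frame(q)) q$prob else q
  stopifnot(length(pv) == length(qv))
  sum(abs(pv - qv)) / 2
}

#' Stationary mean and variance of the active-sensor count
#'
#' Point estimates from the time-weighted occupancy plus batch-means
#' standard errors (the batches are equal post-burn-in time windows, so
#' the standard errors account for autocorrelation).
#'
#' @param run a [gillespie_run()] result.
#' @return List with `mean`, `var`, `mean_se`, `var_se`.
#' @export
activity_moments <- function(run) {
  stopifnot(inherits(run, "gillespie_run"))
  p <- run$occupancy / sum(run$occupancy)
  m <- seq_along(p) - 1
  mu <- sum(p * m)
  v <- sum(p * m^2) - mu^2
  bm <- run$batch_mean_m
  bv <- run$batch_mean_m2 - run$batch_mean_m^2
  ok <- is.finite(bm) & is.finite(bv)
  list(mean = mu, var = v,
       mean_se = sd(bm[ok]) / sqrt(sum(ok)),
       var_se = sd(bv[ok]) / sqrt(sum(ok)))
}

#' Self-consistent mean free input of a finite pool
#'
#' The analytic binomial model takes the *free* input as given, but a
#' finite pool is depleted by binding. This solves the mean-field balance
#' `L_total = x * b_R/f_R + N * bound_per_sensor(x)` for the normalized
#' free input `x` at stationarity.
#'
#' @param config a [simulation_config()].
#' @return List with `x` (normalized free input), `L_free` (molecules) and
#'   `p` (the equilibrium activity at `x`).
#' @export
effective_free_input <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  b <- rate_biases(config$rates)
  params <- sensor_params(K = b[["K"]], c = b[["c"]], n = config$n,
                          N = config$N_sensors)
  conv <- config$rates$b_R / config$rates$f_R   # molecules per unit x
  L_tot <- config$L_molecules
  f <- function(x) x * conv +
    config$N_sensors * mean_bound_per_sensor(params, x) - L_tot
  if (L_tot == 0) return(list(x = 0, L_free = 0,
                              p = equilibrium_activity(params, 0)))
  x <- uniroot(f, lower = 0, upper = L_tot / conv, tol = 1e-12)$root
  list(x = x, L_free = x * conv, p = equilibrium_activity(params, x))
}

# mean number of bound input molecules per sensor at normalized input x
mean_bound_per_sensor <- function(params, x) {
  K <- params$K; c_ <- params$c; n <- params$n
  num <- n * (x * (1 + x)^(n - 1) + K * c_ * x * (1 + c_ * x)^(n - 1))
  num / ((1 + x)^n + K * (1 + c_ * x)^n)
}

#' Empirical intrinsic-noise curve over an input ladder
#'
#' Runs one simulation per target normalized input and reports the
#' empirical coefficient of variation of the active-sensor count. The
#' input pool for each run is sized so that the self-consistent mean free
#' input matches the target (`L = x b_R/f_R + expected bound`), keeping
#' the runs in the regime of the analytic model.
#'
#' Each run is sized adaptively: the burn-in is 20 relaxation times and the
#' sampled window `corr_times` relaxation times of the single-sensor chain
#' at that operating point (the unbind-to-switch pathway makes relaxation
#' much slower near saturation, so fixed-length runs would under-sample the
#' high-input points).
#'
#' @param config a template [simulation_config()]; its `L_molecules`,
#'   `t_max` and `burn_in` are overridden per ladder point and its seed is
#'   offset per point.
#' @param x_targets increasing normalized free-input levels.
#' @param corr_times sampled window length in units of the local
#'   relaxation time.
#' @return Data frame with columns `x`, `L`, `mean_activity`, `mean_se`,
#'   `var_m`, `var_se`, `eta` and `eta_se` (the `_se` columns are
#'   batch-means standard errors on the count scale).
#' @export
noise_curve <- function(config, x_targets, corr_times = 2000) {
  stopifnot(inherits(config, "simulation_config"), all(x_targets > 0))
  b <- rate_biases(config$rates)
  params <- sensor_params(b[["K"]], b[["c"]], config$n, config$N_sensors)
  conv <- config$rates$b_R / config$rates$f_R
  rows <- lapply(seq_along(x_targets), function(i) {
    x <- x_targets[i]
    L <- round(x * conv +
                 config$N_sensors * mean_bound_per_sensor(params, x))
    Qx <- build_rate_matrix(config$rates, config$n, x, config$topology)
    lam <- Re(eigen(Qx, only.values = TRUE)$values)
    t_relax <- 1 / min(abs(lam[abs(lam) > 1e-9 * max(abs(lam))]))
    cfg <- config
    cfg$L_molecules <- as.integer(L)
    cfg$burn_in <- 20 * t_relax
    cfg$t_max <- cfg$burn_in + corr_times * t_relax
    cfg$seed <- config$seed + i
    run <- gillespie_run(cfg)
    mom <- activity_moments(run)
    eta <- sqrt(mom$var) / mom$mean
    # delta-method SE from the mean/variance batch errors
    eta_se <- eta * sqrt((mom$var_se / (2 * mom$var))^2 +
                           (mom$mean_se / mom$mean)^2)
    data.frame(x = x, L = L, mean_activity = mom$mean / config$N_sensors,
               mean_se = mom$mean_se, var_m = mom$var, var_se = mom$var_se,
               eta = eta, eta_se = eta_se)
  })
  do.call(rbind, rows)
}
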