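#' Parameters of a population of MWC sensors
#'
#' Bundles the macroscopic parameters of a two-state concerted allosteric
#' sensor: the allosteric constant `K` (equilibrium bias toward the inactive
#' T state in the absence of input), the dissociation-constant ratio `c`
#' (R-state over T-state; `c < 1` means the input prefers the active state),
#' the number of identical allosteric subunits `n`, and the population size
#' `N` used for the stochastic quantities.
#'
#' The free input `x` used throughout is measured in units of the R-state
#' dissociation constant, i.e. `x = L * f_R / b_R` for a free-input molecule
#' count `L`.
#'
#' @param K allosteric constant, > 0.
#' @param c dissociation-constant ratio, 0 < c <= 1.
#' @param n number of allosteric subunits (positive integer).
#' @param N number of sensors in the population (positive integer).
#' @return An object of class `sensor_params`.
#' @examples
#' p <- sensor_params(K = 100, c = 0.01, n = 4, N = 100)
#' equilibrium_activity(p, 2.24)
#' @export
sensor_params <- function(K, c, n, N = 100L) {
  stopifnot(is.numeric(K), length(K) == 1L, is.finite(K), K > 0)
  stopifnot(is.numeric(c), length(c) == 1L, is.finite(c))
  if (c <= 0 || c > 1)
    stop("'c' must lie in (0, 1]: inverted responses (c > 1) are unsupported")
  stopifnot(length(n) == 1L, n >= 1, n == as.integer(n))
  stopifnot(length(N) == 1L, N >= 1, N == as.integer(N))
  structure(list(K = K, c = c, n = as.integer(n), N = as.integer(N)),
            class = "sensor_params")
}

#' @export
print.sensor_params <- function(x, ...) {
  cat(sprintf("MWC sensor population: K = %g, c = %g, n = %d, N = %d\n",
              x$K, x$c, x$n, x$N))
  bs <- basal_saturation(x)
  cat(sprintf("  basal activity %.4g, saturation %.4g\n",
              bs[["basal"]], bs[["saturation"]]))
  invisible(x)
}

#' Equilibrium activity of an MWC sensor population
#'
#' Mean fraction of sensors in the active R state at a normalized free-input
#' level `x`:
#' \deqn{\bar a(x) = \frac{(1+x)^n}{(1+x)^n + K(1+cx)^n}.}
#' The response is monotone nondecreasing in `x` for `c <= 1`.
#'
#' @param params a [sensor_params()] object.
#' @param x normalized free input (vectorized), >= 0, in units of the R-state
#'   dissociation constant.
#' @return Mean activity in (0, 1), same length as `x`.
#' @export
equilibrium_activity <- function(params, x) {
  stopifnot(inherits(params, "sensor_params"), is.numeric(x))
  if (any(x < 0)) stop("normalized input 'x' must be nonnegative")
  # work in logs: (1+x)^n overflows for large K-driven thresholds
  lu <- params$n * log1p(x)
  lv <- params$n * log1p(params$c * x)
  1 / (1 + exp(log(params$K) + lv - lu))
}

#' Basal and saturation activity levels
#'
#' The two endpoints of the mean response: `basal = 1/(1+K)` at zero input
#' and `saturation = 1/(1+K c^n)` at infinite input.
#'
#' @inheritParams equilibrium_activity
#' @return Named numeric vector `c(basal = , saturation = )`.
#' @export
basal_saturation <- function(params) {
  stopifnot(inherits(params, "sensor_params"))
  c(basal = 1 / (1 + params$K),
    saturation = 1 / (1 + params$K * params$c^params$n))
}

#' Threshold input of the mean response
#'
#' The normalized input `x0` at which the activity is midway between its
#' basal and saturation levels. Obtained by exact inversion of the activity
#' function: for a target level `m`, \eqn{((1+x)/(1+cx))^n = mK/(1-m)}, so
#' \eqn{x_0 = (\rho - 1)/(1 - \rho c)} with \eqn{\rho = (mK/(1-m))^{1/n}}
#' (well defined because `m` < saturation implies \eqn{\rho c < 1}).
#'
#' @inheritParams equilibrium_activity
#' @return Threshold input `x0 >= 0`.
#' @export
threshold_input <- function(params) {
  stopifnot(inherits(params, "sensor_params"))
  if (params$c == 1)
    stop("degenerate response: c = 1 gives a flat activity curve")
  bs <- basal_saturation(params)
  m <- (bs[["basal"]] + bs[["saturation"]]) / 2
  activity_inverse(params, m)
}

# exact inverse of equilibrium_activity for a level strictly between the
# basal and saturation activities
activity_inverse <- function(params, m) {
  stopifnot(m > 0, m < 1)
  rho <- (m * params$K / (1 - m))^(1 / params$n)
  x <- (rho - 1) / (1 - rho * params$c)
  max(x, 0)
}

#' Kinetic rates of the MWC reaction scheme
#'
#' Per-site binding/unbinding rates in each conformation plus the
#' conformational switching rates of the unbound sensor. The macroscopic
#' biases are determined by the rates: `K = f_L / b_L` (R0 -> T0 over
#' T0 -> R0) and `c = (b_R/f_R) / (b_T/f_T)`. When transitions at every
#' ligand-occupancy level are modelled, per-occupancy conformational rates
#' `f_L_i`, `b_L_i` (i = 1..n) must satisfy the thermodynamic cycle-closure
#' constraint `f_L_i / b_L_i = K * c^i`.
#'
#' @param f_R,b_R per-site binding (per molecule per second) and unbinding
#'   (per second) rates in the active R state.
#' @param f_T,b_T same for the inactive T state.
#' @param f_L,b_L conformational rates R0 -> T0 and T0 -> R0 (per second).
#' @param f_L_i,b_L_i optional numeric vectors of length `n` with the
#'   conformational rates at occupancies 1..n (per second).
#' @return An object of class `kinetic_rates`.
#' @examples
#' kr <- kinetic_rates(f_R = 0.01, b_R = 1, f_T = 0.01, b_T = 100,
#'                     f_L = 10, b_L = 0.1)
#' rate_biases(kr)  # K = 100, c = 0.01
#' @export
kinetic_rates <- function(f_R, b_R, f_T, b_T, f_L, b_L,
                          f_L_i = NULL, b_L_i = NULL) {
  vals <- c(f_R = f_R, b_R = b_R, f_T = f_T, b_T = b_T, f_L = f_L, b_L = b_L)
  stopifnot(all(is.finite(vals)), all(vals > 0))
  if (xor(is.null(f_L_i), is.null(b_L_i)))
    stop("per-occupancy rates must be given as a pair (f_L_i, b_L_i)")
  if (!is.null(f_L_i)) {
    stopifnot(length(f_L_i) == length(b_L_i),
              all(f_L_i > 0), all(b_L_i > 0))
    K <- f_L / b_L
    c_ <- (b_R / f_R) / (b_T / f_T)
    target <- K * c_^seq_along(f_L_i)
    if (any(abs(f_L_i / b_L_i - target) > 1e-8 * target))
      stop("per-occupancy rates violate cycle closure f_L_i/b_L_i = K*c^i")
  }
  structure(list(f_R = f_R, b_R = b_R, f_T = f_T, b_T = b_T,
                 f_L = f_L, b_L = b_L, f_L_i = f_L_i, b_L_i = b_L_i),
            class = "kinetic_rates")
}

#' @export
print.kinetic_rates <- function(x, ...) {
  b <- rate_biases(x)
  cat(sprintf(paste0("kinetic rates (s^-1): f_R=%g b_R=%g f_T=%g b_T=%g ",
                     "f_L=%g b_L=%g\n"),
              x$f_R, x$b_R, x$f_T, x$b_T, x$f_L, x$b_L))
  cat(sprintf("  implied biases: K = %g, c = %g%s\n", b[["K"]], b[["c"]],
              if (!is.null(x$f_L_i))
                sprintf("; per-occupancy rates for i = 1..%d",
                        length(x$f_L_i)) else ""))
  invisible(x)
}

#' Macroscopic biases implied by a set of kinetic rates
#'
#' @param rates a [kinetic_rates()] object.
#' @return Named vector `c(K = f_L/b_L, c = (b_R/f_R)/(b_T/f_T))`.
#' @export
rate_biases <- function(rates) {
  stopifnot(inherits(rates, "kinetic_rates"))
  c(K = rates$f_L / rates$b_L,
    c = (rates$b_R / rates$f_R) / (rates$b_T / rates$f_T))
}

state_labels <- function(n) {
  c(paste0("R", 0:n), paste0("T", 0:n))
}

#' Single-sensor transition-rate matrix
#'
#' Builds the generator of the continuous-time Markov chain of one sensor
#' over the `2(n+1)` states `R0..Rn, T0..Tn` at a fixed normalized free
#' input `x`. Binding `R_i -> R_{i+1}` carries the statistical factor
#' `(n-i)` times the per-site binding propensity `b_R * x` (since
#' `f_R * L = b_R * x`); unbinding `R_{i+1} -> R_i` carries `(i+1) * b_R`
#' (T analogues use `f_T * L = (f_T b_R / f_R) x` and `b_T`).
#' Conformational transitions connect `R0 <-> T0` only (`topology =
#' "L_only"`) or every occupancy level (`"all_transitions"`, which requires
#' per-occupancy rates obeying cycle closure).
#'
#' Orientation: rows index the *from* state, so rows sum to zero and the
#' stationary distribution solves `t(Q) %*% pi = 0`.
#'
#' @param rates a [kinetic_rates()] object.
#' @param n number of subunits.
#' @param x normalized free input (>= 0).
#' @param topology `"L_only"` or `"all_transitions"`.
#' @return A `2(n+1) x 2(n+1)` generator matrix with an attribute
#'   `"topology"` and dimnames giving the state labels.
#' @export
build_rate_matrix <- function(rates, n, x,
                              topology = c("L_only", "all_transitions")) {
  stopifnot(inherits(rates, "kinetic_rates"), n >= 1, x >= 0)
  topology <- match.arg(topology)
  n <- as.integer(n)
  if (topology == "all_transitions" && is.null(rates$f_L_i))
    stop("topology 'all_transitions' requires per-occupancy rates")
  d <- 2L * (n + 1L)
  Q <- matrix(0, d, d, dimnames = list(state_labels(n), state_labels(n)))
  iR <- function(i) i + 1L          # R_i
  iT <- function(i) n + 2L + i      # T_i
  kT_bind <- rates$f_T * rates$b_R / rates$f_R  # f_T * L with L = x b_R/f_R
  for (i in 0:(n - 1L)) {
    Q[iR(i), iR(i + 1L)] <- (n - i) * rates$b_R * x
    Q[iR(i + 1L), iR(i)] <- (i + 1L) * rates$b_R
    Q[iT(i), iT(i + 1L)] <- (n - i) * kT_bind * x
    Q[iT(i + 1L), iT(i)] <- (i + 1L) * rates$b_T
  }
  Q[iR(0L), iT(0L)] <- rates$f_L
  Q[iT(0L), iR(0L)] <- rates$b_L
  if (topology == "all_transitions") {
    if (length(rates$f_L_i) < n)
      stop("need per-occupancy rates for every occupancy 1..n")
    for (i in seq_len(n)) {
      Q[iR(i), iT(i)] <- rates$f_L_i[i]
      Q[iT(i), iR(i)] <- rates$b_L_i[i]
    }
  }
  diag(Q) <- -rowSums(Q)
  attr(Q, "topology") <- topology
  attr(Q, "n") <- n
  Q
}

#' Stationary distribution of a generator matrix
#'
#' Solves `t(Q) %*% pi = 0`, `sum(pi) = 1` by replacing one balance
#' equation with the normalization constraint, followed by one step of
#' iterative refinement for accuracy on badly scaled generators.
#'
#' @param Q generator with rows summing to zero (rows = from-state).
#' @return Stationary probability vector.
#' @export
stationary_distribution <- function(Q) {
  d <- nrow(Q)
  A <- t(Q)
  A[d, ] <- 1
  b <- c(rep(0, d - 1L), 1)
  pi_hat <- tryCatch(solve(A, b),
                     error = function(e) stop("singular or reducible generator"))
  r <- b - A %*% pi_hat                       # one refinement step
  pi_hat <- pi_hat + tryCatch(solve(A, r), error = function(e) 0)
  pi_hat <- as.numeric(pi_hat)
  if (any(pi_hat < -1e-9)) stop("generator is not irreducible")
  pi_hat[pi_hat < 0] <- 0
  pi_hat / sum(pi_hat)
}

#' Probability that a single sensor is active
#'
#' Sum of the stationary probabilities of the R states of a single-sensor
#' generator built by [build_rate_matrix()]. For consistent parameters it
#' equals [equilibrium_activity()] at the same input.
#'
#' @param Q a generator from [build_rate_matrix()].
#' @return Active-state probability in (0, 1).
#' @export
single_sensor_active_probability <- function(Q) {
  n <- attr(Q, "n")
  if (is.null(n)) n <- nrow(Q) / 2L - 1L
  p <- stationary_distribution(Q)
  sum(p[seq_len(n + 1L)])
}
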