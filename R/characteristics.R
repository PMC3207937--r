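#' Dynamic range of the mean response
#'
#' Difference between the saturation and basal activity levels,
#' \eqn{r = 1/(1 + K c^n) - 1/(1 + K)}, in `[0, 1)`.
#'
#' @inheritParams equilibrium_activity
#' @return Dynamic range `r`.
#' @export
dynamic_range <- function(params) {
  bs <- basal_saturation(params)
  unname(bs[["saturation"]] - bs[["basal"]])
}

#' Static gain of the mean response
#'
#' Derivative of the equilibrium activity with respect to the normalized
#' input, in closed form:
#' \deqn{G_0(x) = \frac{K n (1-c) (1+x)^{n-1} (1+cx)^{n-1}}
#'                     {\left[(1+x)^n + K(1+cx)^n\right]^2}.}
#' Equals the zero-frequency gain of the linearized transfer function.
#'
#' @inheritParams equilibrium_activity
#' @param x normalized input (vectorized), >= 0.
#' @return Gain in activity per unit normalized input; 0 when `c = 1`.
#' @export
static_gain <- function(params, x) {
  stopifnot(inherits(params, "sensor_params"), all(x >= 0))
  K <- params$K; c_ <- params$c; n <- params$n
  # log-space evaluation to survive extreme K and x
  llu <- (n - 1) * log1p(x)
  llv <- (n - 1) * log1p(c_ * x)
  lden <- 2 * log_sum_exp(n * log1p(x), log(K) + n * log1p(c_ * x))
  exp(log(K) + log(n) + log1p(-c_) + llu + llv - lden)
}

log_sum_exp <- function(a, b) {
  m <- pmax(a, b)
  m + log1p(exp(pmin(a, b) - m))
}

#' Hill number of the normalized response
#'
#' Logit-slope of the normalized activity at half-saturation: with
#' `g(x) = (a(x) - a_basal) / r`, the Hill number is
#' `h = d log(g/(1-g)) / d log(x)` evaluated at the threshold input `x0`
#' where `g = 1/2`. In closed form `h = 4 x0 G0(x0) / r`. For `n = 1` the
#' normalized response is an exact Moebius function of `x`, so the slope
#' simplifies algebraically to 1 and the function returns exactly 1.
#'
#' @inheritParams equilibrium_activity
#' @return Hill number in `[1, n]`.
#' @export
hill_number <- function(params) {
  stopifnot(inherits(params, "sensor_params"))
  if (params$c == 1) stop("degenerate response: c = 1")
  if (params$n == 1L) return(1)
  x0 <- threshold_input(params)
  4 * x0 * static_gain(params, x0) / dynamic_range(params)
}

#' Intrinsic noise of the active-sensor count
#'
#' Coefficient of variation of the number of active sensors under the
#' binomial model: `eta = sqrt((1 - a) / (N a))` with
#' `a = equilibrium_activity(params, x)`.
#'
#' @inheritParams static_gain
#' @return Intrinsic noise (dimensionless), strictly decreasing in activity.
#' @export
intrinsic_noise <- function(params, x) {
  a <- equilibrium_activity(params, x)
  sqrt((1 - a) / (params$N * a))
}

#' Variance of the active-sensor count
#'
#' Binomial variance `N a (1 - a)`; maximal where the activity crosses 1/2,
#' which need not coincide with the threshold input.
#'
#' @inheritParams static_gain
#' @return Variance of the number of active sensors.
#' @export
activity_variance <- function(params, x) {
  a <- equilibrium_activity(params, x)
  params$N * a * (1 - a)
}

#' Information-transfer capacity under small Gaussian noise
#'
#' Channel capacity (bits) of the input-to-activity map when the binomial
#' intrinsic noise is approximated by a small Gaussian:
#' \deqn{I_{opt} = \log_2\!\Big(\sqrt{N/(2\pi e)}\,
#'   \big[\arcsin(2 a_{sat} - 1) - \arcsin(2 a_{basal} - 1)\big]\Big),}
#' which depends only on the basal and saturation activities and `N`.
#' `2^I` bounds the number of distinguishable input bands.
#'
#' The validity flag is `FALSE` when the capacity is nonpositive or when
#' the Gaussian noise scale `sigma(a) = sqrt(a(1-a)/N)` exceeds half the
#' dynamic range anywhere on the response (the small-noise approximation
#' then breaks down).
#'
#' @inheritParams equilibrium_activity
#' @return List with elements `bits` and `valid`.
#' @export
capacity <- function(params) {
  stopifnot(inherits(params, "sensor_params"))
  if (params$c == 1) stop("degenerate response: c = 1")
  bs <- basal_saturation(params)
  Z <- sqrt(params$N) *
    (asin(2 * bs[["saturation"]] - 1) - asin(2 * bs[["basal"]] - 1))
  bits <- log2(Z / sqrt(2 * pi * exp(1)))
  a_star <- min(max(0.5, bs[["basal"]]), bs[["saturation"]])
  sigma_max <- sqrt(a_star * (1 - a_star) / params$N)
  r <- bs[["saturation"]] - bs[["basal"]]
  list(bits = unname(bits),
       valid = is.finite(bits) && bits > 0 && sigma_max <= r / 2)
}

#' Optimal input and output distributions for information transfer
#'
#' Under the small-Gaussian-noise model, information transfer is maximized
#' by the input density `P*(x) = (1/Z) (da/dx) sqrt(N / (a(1-a)))` and the
#' matching output density `P*(a)` proportional to `1 / sqrt(a(1-a))` on
#' `[a_basal, a_sat]`. The output density is bimodal with peaks at the two
#' support edges when the support brackets activity 1/2, and has at most
#' one edge peak otherwise.
#'
#' @inheritParams equilibrium_activity
#' @param x_grid increasing grid of normalized inputs covering the response
#'   region; defaults to 2001 log-spaced points spanning
#'   `x0 * 10^(-4)` to `x0 * 10^4`.
#' @return List with data frames `input` (`x`, `density`) and `output`
#'   (`activity`, `density`), and the normalization constant `Z`.
#' @export
optimal_distributions <- function(params, x_grid = NULL) {
  stopifnot(inherits(params, "sensor_params"))
  if (params$c == 1) stop("degenerate response: c = 1")
  x0 <- threshold_input(params)
  if (is.null(x_grid))
    x_grid <- 10^seq(log10(x0) - 4, log10(x0) + 4, length.out = 2001L)
  stopifnot(!is.unsorted(x_grid), all(x_grid >= 0))
  bs <- basal_saturation(params)
  a <- equilibrium_activity(params, x_grid)
  if (a[1] > bs[["basal"]] + 0.05 * dynamic_range(params) ||
      a[length(a)] < bs[["saturation"]] - 0.05 * dynamic_range(params))
    stop("x_grid does not cover the basal-to-saturation response region")
  g <- static_gain(params, x_grid)
  dens_in <- g * sqrt(params$N / (a * (1 - a)))
  Z <- trapz(x_grid, dens_in)
  a_grid <- seq(bs[["basal"]], bs[["saturation"]], length.out = 2001L)
  dens_out <- 1 / sqrt(a_grid * (1 - a_grid))
  dens_out <- dens_out / trapz(a_grid, dens_out)
  list(input = data.frame(x = x_grid, density = dens_in / Z),
       output = data.frame(activity = a_grid, density = dens_out),
       Z = Z)
}

trapz <- function(x, y) {
  sum(diff(x) * (head(y, -1) + tail(y, -1))) / 2
}

#' Linearized state-space model at an operating point
#'
#' Linearizes the deterministic rate equations of the single-sensor state
#' fractions around their equilibrium at normalized input `x`. One species
#' (`T_n`) is eliminated through sensor-number conservation, giving a
#' nonsingular reduced Jacobian `A`; `B` is the sensitivity of the rate
#' equations to a perturbation of the normalized input; `C` reads out the
#' active fraction.
#'
#' @inheritParams build_rate_matrix
#' @return List with `A`, `B`, `C`, the operating point `x`, the
#'   equilibrium state fractions `y`, and the full generator `Q`.
#' @export
build_state_space <- function(rates, n, x,
                              topology = c("L_only", "all_transitions")) {
  topology <- match.arg(topology)
  n <- as.integer(n)
  Q <- build_rate_matrix(rates, n, x, topology)
  y <- stationary_distribution(Q)
  d <- nrow(Q)
  # dy/dt = M y with M = t(Q) = M0 + x * M1 (binding terms linear in x)
  M <- t(Q)
  Q1 <- build_rate_matrix(rates, n, 1, topology)
  Q0 <- build_rate_matrix(rates, n, 0, topology)
  M1 <- t(Q1 - Q0)
  keep <- seq_len(d - 1L)              # drop T_n (an inactive state)
  A <- M[keep, keep, drop = FALSE] -
    M[keep, d, drop = FALSE] %*% matrix(1, 1L, d - 1L)
  B <- (M1 %*% y)[keep, , drop = FALSE]
  C <- matrix(c(rep(1, n + 1L), rep(0, n)), nrow = 1L)
  if (abs(det(A)) == 0) stop("singular reduced Jacobian (conservation bug)")
  list(A = A, B = B, C = C, x = x, y = y, Q = Q)
}

#' Frequency response of the linearized sensor
#'
#' Gain magnitude `|C (i w I - A)^{-1} B|` of the input-to-activity transfer
#' function on an angular-frequency grid, together with its poles
#' (eigenvalues of `A`), zeros (roots of the numerator polynomial obtained
#' by the Faddeev-LeVerrier adjugate recursion), the cutoff frequency (the
#' pole of smallest magnitude) and the relative degree. The system is a
#' low-pass filter whose gain falls as `w^-2` beyond the cutoff: the pole
#' count always exceeds the zero count by two.
#'
#' @param ss a state-space model from [build_state_space()] (or a list with
#'   `A`, `B`, `C`).
#' @param omega angular-frequency grid (rad/s); defaults to 400 log-spaced
#'   points spanning `1e-3` to `1e3` times the cutoff estimate.
#' @return List of class `frequency_response` with `omega`, `gain`,
#'   `poles`, `zeros`, `cutoff`, `relative_degree`, `dc_gain`, the
#'   `numerator` coefficients (highest degree first) and `hf_asymptote`,
#'   the high-frequency limit of `gain * omega^relative_degree`.
#' @export
frequency_response <- function(ss, omega = NULL) {
  A <- ss$A; B <- ss$B; C <- ss$C
  d <- nrow(A)
  poles <- eigen(A, only.values = TRUE)$values
  if (any(Re(poles) >= 0)) stop("unstable linearization: check the rates")
  cutoff <- min(Mod(poles))
  if (is.null(omega))
    omega <- 10^seq(log10(cutoff) - 3, log10(cutoff) + 3, length.out = 400L)
  num <- numerator_coefficients(A, B, C)
  zeros <- if (length(num) > 1L) polyroot(rev(num)) else complex(0)
  # below ~3x the fastest pole the resolvent solve is accurate; beyond it
  # the numerator/pole product form avoids catastrophic cancellation
  w_switch <- 3 * max(Mod(poles))
  powers <- rev(seq_along(num)) - 1L
  gain <- vapply(omega, function(w) {
    if (w <= w_switch)
      return(Mod((C %*% solve((1i * w) * diag(d) - A, B))[1, 1]))
    s <- 1i * w
    Mod(sum(num * s^powers) / prod(s - poles))
  }, numeric(1))
  list_out <- list(omega = omega, gain = gain, poles = poles, zeros = zeros,
                   cutoff = cutoff, relative_degree = d - length(zeros),
                   dc_gain = as.numeric(C %*% solve(-A, B)),
                   numerator = num,
                   hf_asymptote = abs(num[1]))
  class(list_out) <- "frequency_response"
  list_out
}

#' @export
print.frequency_response <- function(x, ...) {
  cat(sprintf(paste0("linearized frequency response: %d poles, %d zeros ",
                     "(relative degree %d)\n"),
              length(x$poles), length(x$zeros), x$relative_degree))
  cat(sprintf("  DC gain %.4g, cutoff %.4g rad/s\n", x$dc_gain, x$cutoff))
  invisible(x)
}

# Numerator polynomial of the SISO transfer function C (sI - A)^-1 B,
# coefficients from highest degree down, via the Faddeev-LeVerrier
# adjugate recursion. Time is rescaled by the infinity norm of A for
# conditioning; near-zero leading coefficients (the relative degree) are
# trimmed at a relative tolerance.
numerator_coefficients <- function(A, B, C, tol = 1e-7) {
  d <- nrow(A)
  alpha <- max(rowSums(abs(A)))
  As <- A / alpha
  Mk <- diag(d)
  coefs <- numeric(d)               # coef of s^(d-1) ... s^0 (scaled s)
  for (k in seq_len(d)) {
    coefs[k] <- as.numeric(C %*% Mk %*% B)
    ak <- -sum(diag(As %*% Mk)) / k
    Mk <- As %*% Mk + ak * diag(d)
  }
  # trim near-zero leading coefficients on the balanced (sigma) scale, then
  # undo the time scaling: adj(sI - A) = alpha^(d-1) adj(sigma I - As) with
  # sigma = s/alpha, so the s^(d-k) coefficient is alpha^(k-1) * coefs[k]
  lead <- which(abs(coefs) > tol * max(abs(coefs)))[1]
  ks <- lead:d
  coefs[ks] * alpha^(ks - 1)
}

#' Response time after a step in the input
#'
#' Deterministic time for the mean activity to reach the level midway
#' between the basal activity and the new equilibrium after the input steps
#' from zero to `x_step`, with the system initialized at the zero-input
#' equilibrium. Computed by eigendecomposition of the (fixed-input, linear)
#' rate equations and a bracketed search for the first crossing; the result
#' is normalized by 1 s and is bit-for-bit reproducible.
#'
#' @inheritParams build_rate_matrix
#' @param x_step normalized input level after the step (> 0).
#' @return Response time (dimensionless, seconds / 1 s).
#' @export
response_time <- function(rates, n, x_step,
                          topology = c("L_only", "all_transitions")) {
  topology <- match.arg(topology)
  stopifnot(x_step > 0)
  n <- as.integer(n)
  Q0 <- build_rate_matrix(rates, n, 0, topology)
  y0 <- stationary_distribution(Q0)
  Q <- build_rate_matrix(rates, n, x_step, topology)
  M <- t(Q)
  eg <- eigen(M)
  # detailed balance => real spectrum; discard numerical imaginary dust
  lam <- Re(eg$values)
  V <- Re(eg$vectors)
  coef <- tryCatch(solve(V, y0), error = function(e) qr.solve(V, y0))
  act_sel <- c(rep(1, n + 1L), rep(0, n + 1L))
  w <- as.numeric((act_sel %*% V) * coef)    # a(t) = sum w_j exp(lam_j t)
  izero <- which.max(lam)                    # stationary mode, lam ~ 0
  decay <- seq_along(lam)[-izero]
  a_inf <- sum(stationary_distribution(Q)[seq_len(n + 1L)])
  a0 <- sum(y0[seq_len(n + 1L)])
  target <- (a0 + a_inf) / 2
  a_of_t <- function(t) a_inf + sum(w[decay] * exp(lam[decay] * t))
  s0 <- sign(a0 - target)
  rate_scale <- max(abs(lam[decay]))
  t_lo <- 1e-12 / rate_scale
  grid <- 10^seq(log10(t_lo), log10(1e4 / min(abs(lam[decay]))),
                 length.out = 600L)
  vals <- vapply(grid, a_of_t, numeric(1)) - target
  cross <- which(sign(vals) != s0 & is.finite(vals))[1]
  if (is.na(cross))
    stop("response-time crossing search did not converge (pathological rates)")
  if (cross == 1L) return(grid[1])
  root <- uniroot(function(t) a_of_t(t) - target,
                  lower = grid[cross - 1L], upper = grid[cross],
                  tol = 1e-12 * grid[cross])$root
  root
}

#' Compute all six sensing characteristics for one parameter set
#'
#' Bundles the six calculators at their standard evaluation points:
#' intrinsic noise and static gain at the threshold input, capacity from
#' the basal and saturation activities, and the response time for a step
#' from zero input to the threshold.
#'
#' @inheritParams equilibrium_activity
#' @param rates a [kinetic_rates()] object consistent with `params`
#'   (needed for the response time); pass `NULL` to skip the response time.
#' @param topology transition topology for the response time.
#' @param x_step input level for the response-time step; defaults to the
#'   threshold input.
#' @return One-row data frame with columns `K, c, n, N, r, h, eta_thr,
#'   capacity_bits, capacity_valid, G0_thr, tau_norm, x0`.
#' @examples
#' p <- sensor_params(K = 100, c = 0.01, n = 4, N = 100)
#' characterize(p)
#' @export
characterize <- function(params, rates = NULL,
                         topology = c("L_only", "all_transitions"),
                         x_step = NULL) {
  topology <- match.arg(topology)
  stopifnot(inherits(params, "sensor_params"))
  if (params$c == 1) stop("degenerate response: c = 1")
  x0 <- threshold_input(params)
  cap <- capacity(params)
  tau <- NA_real_
  if (!is.null(rates)) {
    b <- rate_biases(rates)
    if (abs(b[["K"]] - params$K) > 1e-8 * params$K ||
        abs(b[["c"]] - params$c) > 1e-8 * params$c)
      stop("kinetic rates are inconsistent with the sensor parameters")
    if (is.null(x_step)) x_step <- x0
    tau <- response_time(rates, params$n, x_step, topology)
  }
  data.frame(K = params$K, c = params$c, n = params$n, N = params$N,
             r = dynamic_range(params),
             h = hill_number(params),
             eta_thr = intrinsic_noise(params, x0),
             capacity_bits = cap$bits,
             capacity_valid = cap$valid,
             G0_thr = static_gain(params, x0),
             tau_norm = tau,
             x0 = x0)
}
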