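#' Compute sensing characteristics for every row of an ensemble
#'
#' Maps [characterize()] over an [generate_ensemble()] table. Rows with a
#' degenerate response (`c` at the `c = 1` edge) or a failing calculator
#' are flagged, never dropped, and never abort the batch.
#'
#' @param ensemble an `ensemble_table` from [generate_ensemble()].
#' @param response_time compute the response time column (the only
#'   characteristic that needs the kinetic rates); disable for speed when
#'   only the five bias-determined characteristics are needed.
#' @return The ensemble joined with columns `r, h, eta_thr, capacity_bits,
#'   capacity_valid, G0_thr, tau_norm, x0, degenerate, failed`.
#' @export
characteristics_table <- function(ensemble, response_time = TRUE) {
  stopifnot(is.data.frame(ensemble))
  need <- c("n", "N", "K", "c", "topology")
  if (!all(need %in% names(ensemble)))
    stop("ensemble lacks required columns: ",
         paste(setdiff(need, names(ensemble)), collapse = ", "))
  m <- nrow(ensemble)
  out <- matrix(NA_real_, m, 8L,
                dimnames = list(NULL, c("r", "h", "eta_thr", "capacity_bits",
                                        "capacity_valid", "G0_thr",
                                        "tau_norm", "x0")))
  degenerate <- ensemble$c >= 1
  failed <- logical(m)
  for (j in seq_len(m)) {
    if (degenerate[j]) next
    rec <- tryCatch({
      p <- sensor_params(ensemble$K[j], ensemble$c[j], ensemble$n[j],
                         ensemble$N[j])
      kr <- if (response_time) ensemble_row_rates(ensemble[j, ]) else NULL
      characterize(p, kr, topology = ensemble$topology[j])
    }, error = function(e) NULL)
    if (is.null(rec)) { failed[j] <- TRUE; next }
    out[j, ] <- c(rec$r, rec$h, rec$eta_thr, rec$capacity_bits,
                  as.numeric(rec$capacity_valid), rec$G0_thr, rec$tau_norm,
                  rec$x0)
  }
  base <- as.data.frame(ensemble)
  base <- base[setdiff(names(base),
                       c(colnames(out), "degenerate", "failed"))]
  res <- cbind(base, as.data.frame(out))
  res$capacity_valid <- res$capacity_valid == 1
  res$degenerate <- degenerate
  res$failed <- failed
  res
}

characteristic_columns <- c("r", "h", "eta_thr", "capacity_bits",
                            "G0_thr", "tau_norm")

# per-characteristic bin index on an equal-width grid over the observed
# range (optionally log10 for the response time); constant columns collapse
# to bin 1 and are flagged degenerate
bin_characteristics <- function(table, bins_per_axis,
                                cols = characteristic_columns,
                                log_tau = FALSE) {
  idx <- matrix(1L, nrow(table), length(cols),
                dimnames = list(NULL, cols))
  edges <- vector("list", length(cols)); names(edges) <- cols
  degenerate_axes <- character(0)
  for (cc in cols) {
    v <- table[[cc]]
    if (cc == "tau_norm" && log_tau) v <- log10(v)
    if (length(unique(v)) < bins_per_axis) {
      degenerate_axes <- c(degenerate_axes, cc)
      edges[[cc]] <- range(v)
      next
    }
    e <- seq(min(v), max(v), length.out = bins_per_axis + 1L)
    idx[, cc] <- pmin(pmax(findInterval(v, e, rightmost.closed = TRUE), 1L),
                      bins_per_axis)
    edges[[cc]] <- e
  }
  list(index = idx, edges = edges, degenerate_axes = degenerate_axes)
}

#' Occupancy of the six-dimensional space of characteristics
#'
#' Bins each of the six characteristics into `bins_per_axis` equal-width
#' levels over its observed raw range, giving `bins_per_axis^6` hypercubes
#' (729 for the default three levels: low, medium, high), and counts the
#' sampled systems per cube. Binning the raw response time (rather than its
#' log) is what reproduces the reported occupancy bounds; set
#' `log_tau = TRUE` to bin the response time on a log10 scale instead.
#' Reports
#' the densest-first cumulative coverage curve and two headline fractions:
#' the fraction of cubes needed to contain 90% of the samples and the
#' fraction of non-empty cubes. Degenerate and failed rows are excluded;
#' by default rows whose capacity flag marks the small-noise approximation
#' as invalid still participate (all sampled systems count), but
#' `exclude_invalid = TRUE` restricts to capacity-valid rows.
#'
#' @param table a [characteristics_table()] restricted to one subunit
#'   number (mixing `n` values is refused).
#' @param bins_per_axis levels per characteristic (default 3).
#' @param exclude_invalid drop capacity-invalid rows before binning.
#' @param log_tau bin the response time on a log10 scale.
#' @return Object of class `occupancy_stats`.
#' @export
occupancy_stats <- function(table, bins_per_axis = 3L,
                            exclude_invalid = FALSE, log_tau = FALSE) {
  stopifnot(is.data.frame(table),
            all(characteristic_columns %in% names(table)))
  if (length(unique(table$n)) != 1L)
    stop("occupancy is computed per subunit number; filter the table first")
  keep <- !table$degenerate & !table$failed &
    stats::complete.cases(table[characteristic_columns])
  if (exclude_invalid) keep <- keep & table$capacity_valid
  excluded <- sum(!keep)
  tab <- table[keep, , drop = FALSE]
  if (nrow(tab) == 0L) stop("no usable rows after exclusions")
  b <- bin_characteristics(tab, bins_per_axis, log_tau = log_tau)
  key <- apply(b$index - 1L, 1L, function(z)
    sum(z * bins_per_axis^(seq_along(z) - 1L))) + 1L
  counts <- table(key)
  total_cubes <- bins_per_axis^length(characteristic_columns)
  sorted <- sort(as.integer(counts), decreasing = TRUE)
  coverage <- cumsum(sorted) / nrow(tab)
  n90 <- which(coverage >= 0.9)[1]
  structure(list(
    total_cubes = total_cubes,
    occupied_cubes = length(sorted),
    cube_counts = sorted,
    coverage_curve = coverage,
    frac_cubes_for_90pct = n90 / total_cubes,
    frac_nonempty = length(sorted) / total_cubes,
    n_samples = nrow(tab),
    n_excluded = excluded,
    bins_per_axis = bins_per_axis,
    edges = b$edges,
    degenerate_axes = b$degenerate_axes,
    n = unique(tab$n)), class = "occupancy_stats")
}

#' @export
print.occupancy_stats <- function(x, ...) {
  cat(sprintf("characteristic-space occupancy (n = %d, %d samples, %d excluded)\n",
              x$n, x$n_samples, x$n_excluded))
  cat(sprintf("  %d of %d hypercubes occupied (%.2f%%)\n",
              x$occupied_cubes, x$total_cubes, 100 * x$frac_nonempty))
  cat(sprintf("  90%% of samples inside %.2f%% of the cubes\n",
              100 * x$frac_cubes_for_90pct))
  if (length(x$degenerate_axes))
    cat("  degenerate axes:", paste(x$degenerate_axes, collapse = ", "), "\n")
  invisible(x)
}

# plug-in (histogram) mutual information and entropies, natural log
plugin_mi <- function(xi, xj, bins) {
  cut_idx <- function(v) {
    if (length(unique(v)) < 2L) return(rep(1L, length(v)))
    e <- seq(min(v), max(v), length.out = bins + 1L)
    pmin(pmax(findInterval(v, e, rightmost.closed = TRUE), 1L), bins)
  }
  bi <- cut_idx(xi); bj <- cut_idx(xj)
  pij <- table(bi, bj) / length(xi)
  pi_ <- rowSums(pij); pj_ <- colSums(pij)
  H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  I <- H(pi_) + H(pj_) - H(as.numeric(pij))
  list(I = max(I, 0), Hi = H(pi_), Hj = H(pj_))
}

#' Normalized mutual information between all characteristic pairs
#'
#' Histogram (plug-in) estimates of the mutual information between every
#' pair of the six characteristics, normalized by the entropy of the row
#' characteristic: `NMI(i, j) = I(Xi; Xj) / H(Xi)`. The matrix is
#' asymmetric in general; a characteristic with zero entropy (e.g. the
#' Hill number for monomers, which is identically 1) gets a zero row by
#' convention. Degenerate and failed rows are excluded; capacity-invalid
#' rows participate unless `exclude_invalid = TRUE`. The response time
#' enters on a log10 scale.
#'
#' @param table a [characteristics_table()] restricted to one subunit
#'   number.
#' @param bins histogram bins per characteristic (default 30).
#' @param exclude_invalid drop capacity-invalid rows first.
#' @return Object of class `nmi_matrix`: the 6 x 6 matrix plus per-row
#'   entropies (nats) and metadata.
#' @export
nmi_matrix <- function(table, bins = 30L, exclude_invalid = FALSE) {
  stopifnot(is.data.frame(table),
            all(characteristic_columns %in% names(table)))
  if (length(unique(table$n)) != 1L)
    stop("NMI is computed per subunit number; filter the table first")
  keep <- !table$degenerate & !table$failed &
    stats::complete.cases(table[characteristic_columns])
  if (exclude_invalid) keep <- keep & table$capacity_valid
  tab <- table[keep, , drop = FALSE]
  cols <- characteristic_columns
  vals <- lapply(cols, function(cc) {
    v <- tab[[cc]]
    if (cc == "tau_norm") log10(v) else v
  })
  names(vals) <- cols
  k <- length(cols)
  M <- matrix(0, k, k, dimnames = list(cols, cols))
  H <- numeric(k); names(H) <- cols
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      est <- plugin_mi(vals[[i]], vals[[j]], bins)
      if (j == 1L) H[i] <- est$Hi
      M[i, j] <- if (est$Hi > 0) est$I / est$Hi else 0
    }
  }
  structure(list(nmi = M, entropy = H, bins = bins,
                 n_samples = nrow(tab), n_excluded = sum(!keep),
                 n = unique(tab$n)), class = "nmi_matrix")
}

#' @export
print.nmi_matrix <- function(x, ...) {
  cat(sprintf("normalized mutual information (n = %d, %d samples, %d bins)\n",
              x$n, x$n_samples, x$bins))
  print(round(x$nmi, 3))
  invisible(x)
}

#' Analytic lower boundary of the Hill-number/dynamic-range region
#'
#' In the strong-binding limit (`c -> 0`) the characteristics collapse to
#' a one-parameter family in `K`: the dynamic range is \eqn{r = K/(1+K)} and
#' the threshold obeys `(1+x0)^n = 2+K`, giving the Hill number
#' `h = n x0 (2+K) / ((1+x0)(1+K))`. This parametric curve bounds the
#' sampled `(h, r)` scatter from below: no parameter set can fall beneath
#' it.
#'
#' @param n subunit number.
#' @param K_grid grid of allosteric constants tracing the curve; default
#'   600 log-spaced points over `[1e-4, 1e8]`.
#' @return Data frame with columns `K`, `h`, `r`, sorted by `h`.
#' @export
hr_boundary <- function(n, K_grid = 10^seq(-4, 8, length.out = 600L)) {
  stopifnot(n >= 1, all(K_grid > 0))
  x0 <- (2 + K_grid)^(1 / n) - 1
  h <- n * x0 * (2 + K_grid) / ((1 + x0) * (1 + K_grid))
  r <- K_grid / (1 + K_grid)
  out <- data.frame(K = K_grid, h = h, r = r)
  out[order(out$h), ]
}

#' Signed clearance of ensemble points above the h-r boundary
#'
#' For each row of a characteristics table, the vertical distance
#' \eqn{r - r_{boundary}(h)} to the analytic forbidden-region boundary of
#' its subunit number (linear interpolation in `h`; points with `h` below
#' the curve's minimum are compared against zero dynamic range). Nonnegative
#' (up to numerical tolerance) means no point enters the forbidden region.
#'
#' @param table a [characteristics_table()].
#' @return Numeric vector of clearances (NA for degenerate/failed rows).
#' @export
boundary_clearance <- function(table) {
  stopifnot(all(c("n", "h", "r") %in% names(table)))
  out <- rep(NA_real_, nrow(table))
  for (nn in unique(table$n)) {
    sel <- which(table$n == nn & !table$degenerate & !table$failed)
    if (!length(sel)) next
    if (nn == 1) {
      # monomers: the boundary degenerates to the vertical segment h = 1,
      # every point sits on it and no forbidden region exists
      out[sel] <- 0
      next
    }
    bd <- hr_boundary(nn)
    rb <- approx(bd$h, bd$r, xout = table$h[sel], rule = 1)$y
    rb[table$h[sel] < min(bd$h)] <- 0
    rb[table$h[sel] > max(bd$h)] <- max(bd$r)
    out[sel] <- table$r[sel] - rb
  }
  out
}

#' Mean response-time ratio between transition topologies
#'
#' Compares the model with conformational transitions only between the
#' unbound states (`L_only`) against the model with transitions at every
#' occupancy level (`all_transitions`) on matched bias samples: each
#' sampled `(K, c)` pair is completed into rates for both topologies from
#' the same substream seed, so the free rates coincide and only the extra
#' per-occupancy pathways differ. Reports the ratio of mean response times
#' (L_only over all_transitions) with a bootstrap confidence interval;
#' the extra pathways shorten the response by roughly two orders of
#' magnitude for large sensors.
#'
#' @param n subunit number (the effect is largest for octamers, n = 8).
#' @param count matched samples (>= 1000 recommended for stable means).
#' @param seed master seed.
#' @param ranges a [sampling_ranges()] object.
#' @param bounded bounded-rate mode for the extra per-occupancy rates.
#' @param n_boot bootstrap replicates for the CI.
#' @return List with `ratio`, `ci` (2.5/97.5% bootstrap), per-topology
#'   mean response times and the per-sample times.
#' @export
topology_response_comparison <- function(n = 8L, count = 1000L, seed = 1L,
                                         ranges = sampling_ranges(),
                                         bounded = FALSE, n_boot = 1000L) {
  stopifnot(count >= 1)
  set.seed(seed)
  row_seeds <- sample.int(.Machine$integer.max - 1L, count)
  tau_L <- tau_all <- h_val <- rep(NA_real_, count)
  for (j in seq_len(count)) {
    set.seed(row_seeds[j])
    bias <- sample_biases(ranges, 1L)
    if (bias$c >= 1) next
    kr_all <- complete_rates(bias$K, bias$c, n, ranges, "all_transitions",
                             bounded = bounded)
    if (is.null(kr_all)) next           # bounded mode: set rejected
    kr_L <- kinetic_rates(f_R = kr_all$f_R, b_R = kr_all$b_R,
                          f_T = kr_all$f_T, b_T = kr_all$b_T,
                          f_L = kr_all$f_L, b_L = kr_all$b_L)
    p <- sensor_params(bias$K, bias$c, n, ranges$N)
    x0 <- threshold_input(p)
    tau_L[j] <- tryCatch(response_time(kr_L, n, x0, "L_only"),
                         error = function(e) NA_real_)
    tau_all[j] <- tryCatch(response_time(kr_all, n, x0, "all_transitions"),
                           error = function(e) NA_real_)
    h_val[j] <- hill_number(p)
  }
  ok <- is.finite(tau_L) & is.finite(tau_all)
  ratio <- mean(tau_L[ok]) / mean(tau_all[ok])
  boots <- replicate(n_boot, {
    i <- sample(which(ok), sum(ok), replace = TRUE)
    mean(tau_L[i]) / mean(tau_all[i])
  })
  list(ratio = ratio,
       ci = unname(quantile(boots, c(0.025, 0.975))),
       mean_L_only = mean(tau_L[ok]),
       mean_all_transitions = mean(tau_all[ok]),
       tau_L_only = tau_L, tau_all_transitions = tau_all,
       hill = h_val, n_used = sum(ok))
}
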