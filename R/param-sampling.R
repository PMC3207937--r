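#' Sampling ranges for random sensor ensembles
#'
#' Defines the log-uniform sampling windows used to generate random sensor
#' parameter sets: the allosteric constant `K` and the dissociation-constant
#' ratio `c` each span six decades (`K` in `[1, 1e6]`, `c` in `[1e-6, 1]`),
#' and the freely sampled kinetic rates span `[1e-3, 1e3]` per second -
#' bounds motivated by diffusion-limited association at typical bacterial
#' volumes. Subunit numbers default to 1, 2, 4 and 8 with 10,000 parameter
#' sets each.
#'
#' @param log10K,log10c,log10rate length-2 numeric vectors of log10 bounds.
#' @param n_set integer vector of subunit numbers.
#' @param samples_per_n parameter sets per subunit number.
#' @param N sensor population size attached to every sampled set.
#' @return An object of class `sampling_ranges`.
#' @export
sampling_ranges <- function(log10K = c(0, 6), log10c = c(-6, 0),
                            log10rate = c(-3, 3),
                            n_set = c(1L, 2L, 4L, 8L),
                            samples_per_n = 10000L, N = 100L) {
  chk <- function(v, nm) {
    if (length(v) != 2L || !all(is.finite(v)) || v[1] >= v[2])
      stop(sprintf("'%s' must be a finite increasing pair of log10 bounds", nm))
  }
  chk(log10K, "log10K"); chk(log10c, "log10c"); chk(log10rate, "log10rate")
  stopifnot(all(n_set >= 1), samples_per_n >= 1, N >= 1)
  structure(list(log10K = log10K, log10c = log10c, log10rate = log10rate,
                 n_set = as.integer(n_set),
                 samples_per_n = as.integer(samples_per_n), N = as.integer(N)),
            class = "sampling_ranges")
}

#' Sample bias pairs log-uniformly
#'
#' Draws `count` independent pairs with `log10(K)` uniform over its window
#' and `log10(c)` uniform over its window.
#'
#' @param ranges a [sampling_ranges()] object.
#' @param count number of pairs.
#' @param seed optional seed applied before drawing.
#' @return Data frame with columns `K` and `c`.
#' @export
sample_biases <- function(ranges, count, seed = NULL) {
  stopifnot(inherits(ranges, "sampling_ranges"), count >= 1)
  if (!is.null(seed)) set.seed(seed)
  data.frame(K = 10^runif(count, ranges$log10K[1], ranges$log10K[2]),
             c = 10^runif(count, ranges$log10c[1], ranges$log10c[2]))
}

#' Complete a bias pair into a full set of kinetic rates
#'
#' Draws the free rates `b_L`, `f_R`, `b_R`, `f_T` log-uniformly over the
#' rate window, then derives `f_L = K * b_L` and `b_T = b_R * f_T /(c f_R)`
#' so that the sampled biases are preserved exactly. Derived rates may fall
#' outside the window; with `bounded = TRUE` a set whose *extra*
#' per-occupancy conformational rates `f_L_i` leave the window is rejected:
#' the function returns `NULL` and the caller drops that sample (for strong
#' biases no draw can ever satisfy the window, so bounded mode is a filter
#' on sampled sets, not a resampling loop). For
#' `topology = "all_transitions"` the per-occupancy backward rates `b_L_i`
#' are drawn log-uniformly and `f_L_i = K * c^i * b_L_i` closes the
#' thermodynamic cycles.
#'
#' @param K,c the bias pair.
#' @param n subunit number (needed for per-occupancy rates).
#' @param ranges a [sampling_ranges()] object.
#' @param topology `"L_only"` or `"all_transitions"`.
#' @param bounded reject (return `NULL` for) sets whose extra per-occupancy
#'   rates leave the rate window (only meaningful for `all_transitions`).
#' @param seed optional seed applied before drawing.
#' @return A [kinetic_rates()] object, or `NULL` when a bounded draw is
#'   rejected.
#' @export
complete_rates <- function(K, c, n = 1L, ranges = sampling_ranges(),
                           topology = c("L_only", "all_transitions"),
                           bounded = FALSE, seed = NULL) {
  topology <- match.arg(topology)
  stopifnot(K > 0, c > 0)
  if (!is.null(seed)) set.seed(seed)
  lo <- ranges$log10rate[1]; hi <- ranges$log10rate[2]
  draw <- function(m) 10^runif(m, lo, hi)
  inside <- function(v) all(log10(v) >= lo - 1e-12 & log10(v) <= hi + 1e-12)
  free <- draw(4L)
  b_L <- free[1]; f_R <- free[2]; b_R <- free[3]; f_T <- free[4]
  f_L <- K * b_L
  b_T <- b_R * f_T / (c * f_R)
  f_L_i <- b_L_i <- NULL
  if (topology == "all_transitions") {
    b_L_i <- draw(n)
    f_L_i <- K * c^seq_len(n) * b_L_i
  }
  if (bounded && !is.null(f_L_i) && !inside(f_L_i)) return(NULL)
  kinetic_rates(f_R = f_R, b_R = b_R, f_T = f_T, b_T = b_T,
                f_L = f_L, b_L = b_L, f_L_i = f_L_i, b_L_i = b_L_i)
}

#' Generate a random ensemble of sensor parameter sets
#'
#' The synthetic-data generator: for every subunit number in the ranges it
#' draws `samples_per_n` bias pairs log-uniformly and completes each into a
#' full kinetic-rate set with [complete_rates()]. Every row records its own
#' substream seed (drawn from the master seed), so any single row can be
#' regenerated in isolation with `complete_rates(K, c, ..., seed = row_seed)`
#' after redrawing its biases from the same seed.
#'
#' @param ranges a [sampling_ranges()] object.
#' @param seed master seed (integer).
#' @param topology transition topology passed to [complete_rates()].
#' @param bounded bounded-rate rejection mode (see [complete_rates()]).
#' @return Data frame of class `ensemble_table`, one row per parameter set,
#'   with columns `id, n, N, seed, K, c, f_R, b_R, f_T, b_T, f_L, b_L,
#'   topology` plus `b_L_i.*`/`f_L_i.*` columns under `all_transitions`.
#' @export
generate_ensemble <- function(ranges = sampling_ranges(), seed = 1L,
                              topology = c("L_only", "all_transitions"),
                              bounded = FALSE) {
  topology <- match.arg(topology)
  stopifnot(inherits(ranges, "sampling_ranges"))
  total <- length(ranges$n_set) * ranges$samples_per_n
  set.seed(seed)
  row_seeds <- sample.int(.Machine$integer.max - 1L, total)
  n_max <- max(ranges$n_set)
  n_col <- rep(ranges$n_set, each = ranges$samples_per_n)
  num <- matrix(NA_real_, total, 8L,
                dimnames = list(NULL, c("K", "c", "f_R", "b_R", "f_T",
                                        "b_T", "f_L", "b_L")))
  occ <- if (topology == "all_transitions")
    matrix(NA_real_, total, 2L * n_max,
           dimnames = list(NULL, c(paste0("b_L_i.", seq_len(n_max)),
                                   paste0("f_L_i.", seq_len(n_max)))))
  for (j in seq_len(total)) {
    set.seed(row_seeds[j])
    bias <- sample_biases(ranges, 1L)
    kr <- complete_rates(bias$K, bias$c, n_col[j], ranges, topology,
                         bounded = bounded)
    if (is.null(kr)) next               # bounded mode: set rejected
    num[j, ] <- c(bias$K, bias$c, kr$f_R, kr$b_R, kr$f_T, kr$b_T,
                  kr$f_L, kr$b_L)
    if (topology == "all_transitions") {
      occ[j, seq_len(n_col[j])] <- kr$b_L_i
      occ[j, n_max + seq_len(n_col[j])] <- kr$f_L_i
    }
  }
  out <- data.frame(id = seq_len(total), n = n_col, N = ranges$N,
                    seed = row_seeds, num, topology = topology)
  if (topology == "all_transitions") out <- cbind(out, as.data.frame(occ))
  if (bounded) out <- out[is.finite(out$K), , drop = FALSE]
  attr(out, "ranges") <- ranges
  attr(out, "master_seed") <- seed
  class(out) <- c("ensemble_table", "data.frame")
  out
}

# rebuild the kinetic_rates object stored in one ensemble row
ensemble_row_rates <- function(row) {
  f_L_i <- b_L_i <- NULL
  if (identical(row$topology, "all_transitions")) {
    bcols <- grep("^b_L_i\\.", names(row), value = TRUE)
    fcols <- grep("^f_L_i\\.", names(row), value = TRUE)
    b_L_i <- as.numeric(row[bcols])[seq_len(row$n)]
    f_L_i <- as.numeric(row[fcols])[seq_len(row$n)]
  }
  kinetic_rates(f_R = row$f_R, b_R = row$b_R, f_T = row$f_T, b_T = row$b_T,
                f_L = row$f_L, b_L = row$b_L,
                f_L_i = f_L_i, b_L_i = b_L_i)
}
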