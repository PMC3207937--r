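# allosense

Trade-offs and constraints in allosteric sensing, computed.

Many microbial sensing systems are nothing more than a population of
allosteric transcription factors: two-conformation
(Monod–Wyman–Changeux) oligomers whose activity shifts when they bind the
molecule they sense. `allosense` asks how well such a sensor population
can perform, for whom the answer matters — systems and synthetic
biologists choosing or engineering a sensor — and makes the trade-offs
quantitative.

For a population of `N` sensors with `n` subunits, allosteric constant `K`
(bias toward the inactive T state) and dissociation-constant ratio
`c ≤ 1` (how much the input prefers the active R state), the mean activity
at normalized free input `x` is

    ā(x) = (1+x)^n / [ (1+x)^n + K (1+cx)^n ].

From this single response law and its binomial fluctuation model the
package computes six sensing characteristics per parameter set:

| characteristic | definition |
|---|---|
| dynamic range `r` | `1/(1+Kc^n) − 1/(1+K)` |
| Hill number `h` | logit slope of the normalized response at the threshold input `x0` |
| intrinsic noise `η` | `sqrt((1−ā)/(N ā))` at `x0` |
| capacity `I_opt` | `log2( sqrt(N/2πe) · [asin(2a_sat−1) − asin(2a_basal−1)] )` bits |
| static gain `G0` | `dā/dx` at `x0` |
| response time `τ` | time to the midpoint of the activity step response, / 1 s |

Around that core the package provides: an exact Gillespie simulator
(compiled, finite input pool) that validates the binomial noise model; the
information-optimal input/output distributions; the linearized frequency
response (poles, zeros, low-pass `ω⁻²` tail); log-uniform parameter
ensembles matching the study conditions (`K ∈ [1, 10⁶]`, `c ∈ [10⁻⁶, 1]`,
rates `∈ [10⁻³, 10³] s⁻¹`, 10,000 sets per `n ∈ {1,2,4,8}`); and
ensemble analytics — characteristic-space occupancy over 729 hypercubes,
pairwise normalized mutual information, and the analytic forbidden-region
boundary in Hill-number/dynamic-range space.

## Worked example

A tetrameric sensor population with strong biases (`K = 100`, `c = 0.01`,
`N = 100`), with kinetic rates consistent with those biases:

```r
library(allosense)
p  <- sensor_params(K = 100, c = 0.01, n = 4, N = 100)
kr <- kinetic_rates(f_R = 0.01, b_R = 1, f_T = 0.01, b_T = 100,
                    f_L = 10, b_L = 0.1)
characterize(p, kr)
```

prints (columns transposed):

```
r                0.9901
h                2.7076
eta_thr          0.0990
capacity_bits    2.8308
capacity_valid   TRUE
G0_thr           0.2979
tau_norm         8.7692
x0               2.2495
```

Read: the response spans almost the full activity range (`r ≈ 0.99`), is
moderately cooperative (`h ≈ 2.7` of a possible 4), fluctuates by ~10% at
threshold, and transmits ~2.83 bits — `2^2.83 ≈ 7` distinguishable input
bands — with a threshold at `x0 ≈ 2.25` R-state dissociation constants and
a step response midpoint reached after ~8.8 s for these rates. An exact
stochastic check of the noise model for a finite pool:

```r
cfg <- read_sim_config(system.file("extdata", "sensor_small_pool.yaml",
                                   package = "allosense"))
run <- gillespie_run(cfg)                       # ~4.6M events, seconds
eff <- effective_free_input(cfg)                # depletion-corrected input
total_variation(stationary_activity_distribution(run),
                binomial_activity_distribution(20, eff$p))
#> 0.037   (binomial law holds to TV < 0.05)
```

A command-line front end (`characterize`, `sample`, `simulate`, `respond`,
`analyze`, `fixtures`) wraps the same functions; see
`inst/scripts/allosense`.

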