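---
title: "Sensing characteristics of allosteric MWC sensors: models and methods"
author: "allosense"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sensing characteristics of allosteric MWC sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`allosense` analyses populations of two-state concerted allosteric sensors
in the Monod-Wyman-Changeux (MWC) tradition — the standard model for
bacterial allosteric transcription factors, which transduce the detection
of a small molecule directly into changes in gene regulation. A sensor is
an oligomer of $n$ identical subunits, each carrying one binding site for
the input molecule. The whole oligomer switches concertedly between an
active (R) and an inactive (T) conformation; the unbound sensor is biased
toward T by the allosteric constant $K$, and the input binds the R state
more tightly by the factor $c \le 1$ (the ratio of R-state to T-state
dissociation constants). With the free input $x$ measured in units of the
R-state dissociation constant ($x = L f_R/b_R$ for a molecule count $L$),
the mean activity — the fraction of the $N$ sensors in the R state — is

$$\bar a(x) = \frac{(1+x)^n}{(1+x)^n + K(1+cx)^n},$$

rising monotonically from the basal level $1/(1+K)$ to the saturation
level $1/(1+Kc^n)$.

Kinetically the single sensor is a continuous-time Markov chain on the
$2(n+1)$ states $R_0 \dots R_n, T_0 \dots T_n$: binding with statistical
factor $(n-i)$, unbinding with factor $(i+1)$, and conformational
switching either only between the unbound states $R_0 \leftrightarrow T_0$
(topology `L_only`, with $f_L/b_L = K$) or at every occupancy level
(`all_transitions`, where thermodynamic cycle closure forces
$f_{L,i}/b_{L,i} = K c^i$). Cycle closure is why the extra transitions
change the kinetics but not the equilibrium: `build_rate_matrix()` plus
`stationary_distribution()` reproduce $\bar a(x)$ for either topology, and
the test suite asserts this to $10^{-8}$ over random parameter sets.

## The six sensing characteristics

`characterize()` evaluates, per parameter set:

* **dynamic range** $r = 1/(1+Kc^n) - 1/(1+K)$;
* **Hill number** $h$, the logit slope of the normalized response at the
  threshold input $x_0$ (the input giving activity midway between basal
  and saturation). In closed form $h = 4 x_0 G_0(x_0)/r$; it is exactly 1
  for monomers and approaches $n$ in the strongly sigmoidal limit
  ($K \to \infty$, $K c^n \to 0$) — slowly, as $x_0/(1+x_0)$ with
  $x_0 \sim K^{1/n}$, so e.g. $K = 10^6, c = 10^{-6}, n = 4$ gives
  $h = 3.873$, not yet 4;
* **intrinsic noise** $\eta = \sqrt{(1-\bar a)/(N \bar a)}$, the
  coefficient of variation of the active-sensor count under the binomial
  model, reported at $x_0$;
* **capacity** $I_{opt} = \log_2\!\big(\sqrt{N/2\pi e}\,
  [\arcsin(2 a_{sat}-1) - \arcsin(2 a_{basal}-1)]\big)$ bits, the maximal
  mutual information between input and activity under a small-Gaussian
  approximation of the binomial noise; $2^{I_{opt}}$ bounds the number of
  distinguishable input bands;
* **static gain** $G_0 = d\bar a/dx$ at $x_0$;
* **response time** $\tau$, the first time the deterministic activity
  crosses the midpoint between its basal level and its new equilibrium
  after a step from zero input (default step target: $x_0$), normalized
  by 1 s.

Evaluation points follow the convention that noise and gain are measured
at the threshold; the step size for the response time is recorded in the
output. The threshold itself is obtained by exact algebraic inversion of
the activity law — for a level $m$, $((1+x)/(1+cx))^n = mK/(1-m)$ gives
$x_0 = (\rho-1)/(1-\rho c)$ with $\rho = (mK/(1-m))^{1/n}$ — rather than
by iterative root finding; the midpoint identity then holds to machine
precision, and a bracketed `uniroot()` search survives only as an
independent oracle in the tests.

### Capacity validity

The small-noise capacity formula degrades when the Gaussian width
$\sigma(\bar a) = \sqrt{\bar a(1-\bar a)/N}$ is not small against the
response: the `capacity_valid` flag is false when $I_{opt} \le 0$ or when
$\max_a \sigma$ exceeds half the dynamic range. Invalid rows are kept and
flagged, never dropped.

### Optimal input and output distributions

`optimal_distributions()` returns the information-maximizing input density
$P^*(x) \propto (d\bar a/dx)\sqrt{N/(\bar a(1-\bar a))}$ and the matching
output density $\propto 1/\sqrt{\bar a(1-\bar a)}$ on
$[a_{basal}, a_{sat}]$. When the support brackets activity $1/2$ the
output density is bimodal with peaks at both edges; a sensor saturating at
or below $1/2$ can have at most one peak.

## Linearized frequency response

`build_state_space()` linearizes the deterministic rate equations around
the operating point, eliminating one species ($T_n$) through sensor-number
conservation so the reduced Jacobian $A$ is stable and nonsingular; the
input matrix $B$ is the sensitivity of the rate terms to the normalized
input and $C$ reads out the active fraction. `frequency_response()`
evaluates $|C(i\omega I - A)^{-1}B|$, the poles (eigenvalues of $A$), the
zeros (roots of the numerator polynomial from the Faddeev–LeVerrier
adjugate recursion, computed on an infinity-norm-rescaled copy of $A$ for
conditioning), the cutoff (smallest pole magnitude) and the relative
degree. The DC gain equals $d\bar a/dx$ analytically, and the tests assert
the equality to $10^{-8}$.

Two numerical points deserve note. First, for $\omega$ far above every
pole the resolvent solve suffers catastrophic cancellation (the leading
Markov parameter $CB$ is exactly zero), so the gain is evaluated from the
numerator/pole-product form beyond three times the fastest pole; in the
overlap band both forms agree to $\sim 10^{-8}$. Second, the generic
relative degree is two — the gain falls as $\omega^{-2}$ — but rate sets
with $f_R = f_T$ (as in the worked simulation parameter sets) are
degenerate: there the T-state binding coefficient equals $b_R$ and the
second Markov parameter $CAB$ also vanishes identically, giving relative
degree three. The low-pass property tests therefore use generic random
rates.

The response time is computed by eigendecomposition of the fixed-input
generator (detailed balance makes the spectrum real) plus a bracketed
search for the midpoint crossing — deterministic, seed-free, and validated
against `deSolve` integrations to $2\times 10^{-3}$ relative.

## Exact stochastic simulation

`gillespie_run()` implements the direct-method stochastic simulation
algorithm in compiled code over the species $R_0..R_n, T_0..T_n, L$ with a
finite input pool: binding consumes free molecules, so ligand depletion is
simulated exactly. The direct method samples the same master equation as
the Gibson–Bruck variant; the choice is a performance detail, not a
semantic one. Runs are bitwise reproducible from the configured seed
(R's RNG drives the core), and the default burn-in is ten relaxation times
of the zero-input chain.

The analytic noise model treats sensors as independent, which holds when
free input greatly exceeds the total number of binding sites. The package
therefore distinguishes two validation regimes:

* **Distribution shape at a scarce pool.** The packaged
  `sensor_small_pool.yaml` population (20 tetramers = 80 sites sharing 224
  molecules) binds about 10% of its pool at stationarity, so the binomial
  comparison is centred at the self-consistent mean-field free input from
  `effective_free_input()` (the analytic $p$ is the activity at the *free*
  input). There the empirical activity histogram matches the binomial law
  to total-variation distance well under 0.05, and the mean to a few
  standard errors — but the *variance* sits systematically ~10% below
  $N\bar a(1-\bar a)$ because pool sharing anticorrelates the sensors.
  That suppression is a real feature of the exact model, documented here
  and asserted one-sidedly in the tests, not an error to be averaged away.
* **Moments at excess input.** With at least a tenfold excess of free
  molecules over sites, the mean and variance agree with the binomial
  forms within batch-means standard errors; `noise_curve()` sizes each
  run adaptively (20 relaxation times of burn-in, 2000 for sampling) and
  compensates the pool so the mean free input hits each target. Near
  saturation the `L_only` topology relaxes slowly — switching requires
  complete unbinding, a pathway suppressed by $(1+x)^{-n}$ — which is why
  fixed-length runs would silently under-sample the high-input points.

The high-basal population (`sensor_high_basal.yaml`, $K = 2$, $c = 0.1$,
$n = 4$, $N = 100$) illustrates that the active-count variance peaks where
activity crosses one half (at $x \approx 0.215$), below the threshold
input ($x_0 \approx 0.482$), while the intrinsic noise falls monotonically
with input. The conformational rates in both fixtures are synthetic: only
their ratio is fixed by $K$, and they are placed geometrically
($f_L = \sqrt K$, $b_L = 1/\sqrt K$ s$^{-1}$); all comparisons made with
them are stationary-distribution checks insensitive to that placement.

## The parameter ensembles

`generate_ensemble()` is the synthetic-data generator and encodes the
study conditions directly: $\log_{10} K$ uniform on $[0, 6]$ and
$\log_{10} c$ uniform on $[-6, 0]$ (six decades each; the lower bound
$K \ge 1$ keeps basal activity at or below 50%, and $c \le 1$ keeps
responses non-inverted), free kinetic rates $b_L, f_R, b_R, f_T$
log-uniform on $[10^{-3}, 10^3]$ s$^{-1}$ (diffusion-limited association
at bacterial volumes), derived rates $f_L = K b_L$ and
$b_T = b_R f_T/(c f_R)$ left unclipped, subunit numbers
$n \in \{1, 2, 4, 8\}$ with 10,000 parameter sets each, and $N = 100$
sensors. Which four rates are "free" is a documented, configurable choice.
Every row records a substream seed so it can be regenerated in isolation.
The bounded mode used for one sub-analysis filters out sets whose *extra*
per-occupancy conformational rates leave the window — a single-draw filter,
because strong biases make the window unreachable for any draw.

## Ensemble analytics

`occupancy_stats()` bins the six characteristics into three equal-width
levels each over their observed ranges ($3^6 = 729$ hypercubes) and
reports the fraction of cubes (densest first) holding 90% of the samples
and the fraction of non-empty cubes. Two protocol details were genuinely
open and were fixed as follows. *Scale:* equal-width bins are taken on the
raw values, including the response time — binning $\log_{10}\tau$ instead
(available via `log_tau = TRUE`) spreads the tau axis over its ~11-decade
tail and inflates both headline fractions by roughly a factor of two; only
the raw-value reading reproduces the reported occupancy bounds for every
subunit number, so it is taken as the study protocol. *Inclusion:* all
non-degenerate rows participate, including capacity-invalid ones — the
occupancy claims are about all sampled systems; `exclude_invalid = TRUE`
restores the masked variant.

`nmi_matrix()` estimates pairwise mutual information by plug-in histograms
with 30 bins per characteristic (response time on $\log_{10}$ scale, where
30 bins otherwise collapse) and normalizes by the row characteristic's
entropy, so the matrix is asymmetric; a zero-entropy characteristic (the
monomer Hill number) yields a zero row by convention, reproducing the dark
row seen for $n = 1$. The plug-in estimator is biased upward at finite
samples (~0.01–0.02 NMI for independent columns at 10,000 samples), which
is why diagnostic "independence" checks use that scale rather than exact
zero, and the qualitative structure is stable from 20 to 40 bins.

`hr_boundary()` traces the strong-binding limit $c \to 0$, where the
characteristics collapse onto the one-parameter family
$r = K/(1+K)$, $(1+x_0)^n = 2+K$,
$h = n x_0 (2+K) / ((1+x_0)(1+K))$: the lower edge of the accessible
region in (Hill number, dynamic range) space. Sampled points never fall
below it (`boundary_clearance()` is nonnegative up to $10^{-6}$); for
monomers the curve degenerates to the vertical segment $h = 1$ and no
forbidden region exists.

`topology_response_comparison()` evaluates matched bias samples under both
topologies (shared substream seeds, so the base rates coincide) and
reports the ratio of mean response times with a bootstrap CI. A caveat
worth stating plainly: the `L_only` response-time distribution spans some
eleven decades, so the ratio of arithmetic means is dominated by the
slowest few samples — it is large (routinely $10^3$–$10^4$ at 1,000
samples) but unstable, while the geometric-mean ratio is a stable
$\sim 10$. Readers comparing against coarser "orders of magnitude"
statements should be aware that this statistic depends strongly on how the
slow tail is treated (any finite integration horizon truncates it).

## Problem sizes and numerical defaults

The test suite exercises the closed-form layer exhaustively; stochastic
checks use the fixture run lengths (up to $2\times 10^4$ s of simulated
time, a few million events, a few seconds of CPU each), and the ensemble
acceptance checks run the full 10,000 parameter sets per subunit number
(about two and a half minutes, dominated by the eigendecomposition-based
response times). Key tolerances: stationary-versus-analytic activity
$10^{-8}$; capacity closed form versus quadrature $10^{-6}$; DC gain
versus response slope $10^{-8}$; distribution normalizations $10^{-6}$.
Degenerate inputs ($c = 1$ flat responses) raise errors in the
characteristic calculators and are flagged, not propagated, by the batch
pipeline.

## Known limitations

* The intrinsic-noise and capacity layer assumes the excess-input
  (independent-sensor) regime; the exact simulator quantifies when that
  fails (scarce pools suppress the variance), but no corrected analytic
  noise model is provided.
* The capacity is the small-Gaussian-noise closed form, not an exact
  Blahut–Arimoto computation.
* Only the two-conformation concerted model is implemented — no
  sequential (KNF) schemes, extra conformations, or heterotropic ligands.
* Extrinsic input fluctuations are treated only through the linearized
  frequency response; simulations keep the input pool closed.
* The synthetic ensembles are log-uniform by construction: they emulate
  the study's parameter-plausibility assumptions, not any measured
  distribution of real transcription-factor parameters, so passing
  ensemble tests demonstrates internal consistency of the analysis, not
  agreement with biological data.
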