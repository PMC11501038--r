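---
title: "Modelling floor-plate formation and Shh gradient dynamics in a growing neural tube"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling floor-plate formation and Shh gradient dynamics in a growing neural tube}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shhfp)
```

## The model

`shhfp` simulates the formation of the floor plate (FP) — the ventral-most
Shh-producing domain of the neural tube — as the outcome of a small gene
network coupled to morphogen transport on a growing one-dimensional
dorsoventral (DV) axis. Three species interact:

* **F**, a non-diffusible floor-plate fate determinant;
* **N**, a non-diffusible neural-progenitor determinant;
* **Shh**, the diffusible morphogen.

F and N repress each other through cooperative (cubic by default)
repression terms, both are activated by Shh and by uniform basal inputs,
and the floor plate itself produces Shh with saturating kinetics:

$$
\partial_t F = \alpha_F\,
  \frac{\kappa_F (1 + c_{S\to F} S)}
       {(1 + K_{N\to F} N)^{m} + \kappa_F (1 + c_{S\to F} S)} - \gamma_F F,
$$

with the mirror-image equation for $N$ (parameters $\kappa_N$,
$c_{S\to N}$, $K_{F\to N}$), and

$$
\partial_t S = D_S \partial_x^2 S +
  \alpha_S \frac{\kappa_{F\to S} F}{1 + \kappa_{F\to S} F} - \gamma_S S .
$$

The F domain is defined by $F > N$; the FP size $\ell_{FP}$ is the length
of the contiguous ventral run of such bins. Notochord-derived Shh enters
either as a transient pulse (100 a.u. in the ventral-most bin at $t=0$)
or as a constant flux through the ventral boundary.

### Units

All rates are stored per hour. The defaults are $\gamma = 0.72\,
\mathrm{h}^{-1}$ ($= 2\times10^{-4}\,\mathrm{s}^{-1}$, a ~1 h half-life),
$D_S = 396\,\mu\mathrm{m}^2\mathrm{h}^{-1}$
($= 0.11\,\mu\mathrm{m}^2\mathrm{s}^{-1}$) and production rates
$\alpha = 360$ a.u. h$^{-1}$ ($= 0.1$ a.u. s$^{-1}$). The production
scale is the one consistent with the system's own behaviour: the
saturation concentration $\alpha/\gamma = 500$ a.u. produces Shh
amplitudes in the observed 100–500 a.u. range, makes the 2 a.u. dorsal
Shh bound of the screen a live constraint, and places the amplitude
saturation with FP size at $\ell_{FP} \gtrsim 2\text{–}3\lambda \approx
60\,\mu$m. A reading of $\alpha = 0.1$ a.u. h$^{-1}$ caps every species
at 0.14 a.u. and produces no two-domain patterns at all.

### Growth and mapped coordinates

The tissue grows uniformly from $L_0 = 100\,\mu$m, by default linearly at
$k_p = 5\,\mu$m/h to $400\,\mu$m at $t_{end} = 60$ h (an exponential mode
with $\tau = 43.3$ h is available). The equations are solved on the fixed
unit interval in the mapped variable $\bar{x} = x/L(t)$, which adds a
dilution term $-c\,\dot{L}/L$ to every concentration and rescales the
diffusion coefficient to $D_S/L^2$. The domain is divided into 100 bins
mimicking the cellular structure; absolute positions are recovered as
$x = \bar{x} L(t)$.

## Numerics

* **Scheme.** Explicit Heun (second-order predictor–corrector) stepping of
  all three fields; the diffusion operator is the standard three-point
  second difference on the bin grid.
* **Time step.** By default the step adapts to the explicit diffusive
  stability limit evaluated at the current length,
  $\Delta t = 0.4\,(\Delta\bar{x}\,L)^2 / (2 D_S)$ — about 1.8 s at
  $L_0$, relaxing as the bins widen with growth. A user-supplied `dt` is
  used as a fixed step instead; trajectories under the two policies agree
  to ~$10^{-12}$ relative. Steps are clipped to land exactly on the
  recording grid (10-min cadence by default).
* **Boundary closures.** Reflective boundaries are imposed by ghost bins
  mirroring the edge value. A boundary flux $j_{Shh}$ (printed units
  a.u./s) is imposed through a mirrored centered-difference ghost bin,
  giving a net influx of $2 \times 3600\, j_{Shh}$ a.u. µm/h through the
  ventral face. This calibration is fixed by two requirements: the
  simulated steady state must match the closed-form flux-fed gradient
  $A = \Phi\lambda/D \cdot \coth(L/\lambda)$ (verified in the test
  suite), and the resulting amplitude–flux relation must reproduce the
  relative flux contributions at high and low flux that motivated the
  flux experiments in the first place. The published $j$ values are used
  as printed.
* **Degenerate inputs.** Concentrations are clamped at zero after every
  update (only relevant with noise); zero rates are allowed for
  degenerate test systems (pure dilution, linear decay), in which case an
  explicit `dt` must be supplied.
* **Failure handling.** Non-finite fields abort the run with the failure
  time; during a screen such runs are recorded as failed visits.

### Expression noise

Stochastic effects of cell division are mimicked by an
Ornstein–Uhlenbeck process added to F and N, using the exact
discretization
$\eta' = \eta e^{-\Delta t/\tau_\eta} + \sigma_\eta
\sqrt{(1 - e^{-2\Delta t/\tau_\eta})/\tau_\eta}\, z$, $z \sim N(0,1)$,
applied only in bins whose expression exceeds 1 a.u. The defaults
$\sigma_\eta = \tau_\eta = 1$ give a stationary noise SD of 1 a.u.,
i.e. order-10% fluctuations relative to the initial N level of 10 a.u.
(the magnitude is not prescribed by the biology; both knobs are
exposed). Noise uses R's RNG, so `set.seed()` makes runs reproducible.

## The computational screen

Seven interaction parameters are explored over six orders of magnitude
($c_{S\to F}, c_{S\to N}, K_{N\to F}, K_{F\to N}, \kappa_{F\to S} \in
[0.005, 5000]$; $\kappa_F, \kappa_N \in [5\times10^{-6}, 5]$), under the
default pulse source, linear growth, and no noise. A parameter set
*succeeds* if, at $t_{end}$ (criteria evaluated on the recorded
trajectory):

1. the pattern has two domains, with the F domain contiguous from the
   ventral end and a non-empty N domain;
2. Shh decays monotonically — operationally, $S$ at the dorsal-most bin
   is at most 2% of $S_{init}$;
3. Shh and F concentrations are within an order of magnitude of each
   other ($0.1 \le \max S / \max F \le 10$);
4. the FP occupies 5–25% of the tissue (20–100 µm at defaults);
5. the FP is established (first ventral $F > N$) between 2.5 h and 20 h.

The search is a random walk in log-parameter space: uniform draws until
the first success, then log-normal proposals (SD 0.2) from the most
recent successful set, clipped to the ranges; failed proposals leave the
walk anchored at the last success. Every evaluated set counts as a
visit.

### Scaled-down screen design

The full published screen (10 chains × 40 000 visits) is cluster-scale.
The package's reference screen uses **4 chains × 2 500 visits** with a
pinned seed (~10 min on one CPU). Two empirical facts shaped this
choice, both computed with the package: the probability that a uniform
draw succeeds is only ~2–5 × 10⁻⁴, so a chain needs a few thousand
visits to complete its search phase at all; and the walk is strongly
autocorrelated (it camps for hundreds of visits in one region of
parameter space), so ensemble statistics need several independent
chains, and uncertainty on screen-derived fractions is assessed with
chain-cluster-robust intervals rather than per-visit binomial ones.
After the search phase roughly 45–50% of walk visits succeed, matching
the overall success fraction implied by the published screen size.

### Sensitivity classes

Each successful network is re-simulated with $\kappa_{F\to S} = 0$ (no
FP-derived Shh) and classified by $\Delta \ell_{FP} = \ell_{FP} -
\ell_{FP}^{\kappa_{F\to S}=0}$: *sensitive* (FP lost entirely),
*insensitive* ($|\Delta \ell_{FP}| \le$ one bin), *increased*
($\Delta \ell_{FP} <$ −one bin), *partial* (otherwise). Both
$\Delta \ell_{FP}$ and the class label are stored so alternative cuts
(e.g. any $\Delta \ell_{FP} < 0$) can be recomputed; size increases of
any magnitude occur in well under 1% of solutions.

## Derived metrics

* **Establishment time $T_{est}$** — first recorded time with $F > N$ in
  the ventral-most bin (the F domain is anchored ventrally, so the
  ventral bin is the natural probe).
* **Formation time $T_{FP}$** — earliest recorded time after which the
  relative FP size stays within a tolerance (default 0.01, one bin) of
  its final value; undefined if no FP exists at the end. With the
  one-bin tolerance this lands 1–2 h after $T_{est}$ for typical
  screened networks, i.e. around 4–7 h: the bin-quantized relative size
  locks in quickly once the boundary stops moving. Sub-bin boundary
  creep is invisible to this metric by construction; a stricter
  tolerance (exact final bin count) shifts individual values upward by a
  few hours and makes the metric fragile to late single-bin
  adjustments. Under perturbations that weaken N (e.g. doubling
  $\gamma_N$) many networks no longer reach a stationary pattern within
  the simulated window — the FP boundary keeps creeping dorsally — and
  $T_{FP}$ then reflects the end of the creep rather than a formation
  time; interpreting it requires checking that the perturbed pattern is
  still a plausibly sized floor plate.
* **Gradient amplitude $A_{Shh}$** — the Shh concentration in the
  ventral-most bin (the model analogue of measuring the experimental
  profile at its peak).
* **Decay length $\lambda_{Shh}$** — from a least-squares fit of
  $A e^{-x/\lambda}$ to the Shh profile over the N domain on the
  concentration scale (bins with $S < 10^{-8}$ a.u. excluded; at least
  5 bins required). Fitting on the concentration scale weights the
  proximal quasi-steady part of the gradient. This matters on a growing
  domain: the dorsal tail equilibrates on the time scale $x^2/D_S$,
  which exceeds the 60 h of a default run beyond $x \approx 150\,\mu$m,
  so the tail is systematically shallower than $\sqrt{D_S/\gamma_S}$ and
  an unweighted log-linear fit overestimates $\lambda$ by ~2 µm. The
  steady-state prediction itself is
  $\lambda = \sqrt{D_S/\gamma_S} = 23.45\,\mu$m, slightly reduced by the
  dilution contribution to the effective degradation rate
  ($\gamma + \dot L/L$).

## Downstream analyses

`sensitivity_scan()` rescales one parameter at a time over 40
log-equispaced multipliers in [0.1, 10] and records the relative FP size
or the amplitude at $t_{end}$, averaged over a network subset (the
reference subsets are drawn with `select_subset()` at a target relative
FP size, mirroring the published 20% subsets). `growth_sweep()` varies
$k_p$ (and exponential growth), `source_sweep()` varies pulse sizes,
fluxes and flux-removal times, `tfp_vs_degradation()` scales $\gamma_N$,
and `amplitude_fp_relation()` bins amplitude against FP size and fits a
continuous linear-then-plateau summary with a free breakpoint (the
breakpoint search is descriptive — the underlying saturation scale is
set by $\lambda$).

For the timing analyses the package uses cohorts of $n = 10$ networks
per condition, drawn from the insensitive class (the class supported by
the biology); the replicate convention and seed are exposed so any other
cohort can be replayed.

## Fluorescence-profile processing

`process_profile()` reproduces the standard immunostaining
quantification: background, defined as the minimum intensity within
10–90% of the DV length, is subtracted (clamped at zero) and the profile
is smoothed with a 5-µm centred moving average (window shrinking at the
edges; background subtraction precedes smoothing). `mean_profile()`
averages processed profiles per group with a pointwise 95% t-interval,
subtracts the mean profile's own background, shifts the origin to the
control mean-profile peak (the global maximum within the ventral 30% of
DV length — the anatomical "dorsal edge of the floor plate" cannot be
evaluated on synthetic data) and normalizes to the control group's mean
maximum. `fp_length_from_area()` converts an immunostained FP area to a
length via the 17 µm apicobasal monolayer thickness.

One property of the min-based background rule is worth knowing: with
noise of SD $\sigma$, the subtracted minimum sits ~2.9$\sigma$ below the
true background over a few hundred samples, leaving a small positive
offset in the processed profile. Decay-length estimates from processed
noisy profiles should therefore fit an explicit offset (as the test
suite does); log-linear fits without one are biased upward.

## Synthetic data

`generate_profiles()` emulates quantified Shh immunostaining profiles as
exponential decay plus flat background plus Gaussian noise on a 400-µm
DV axis sampled every micron (decay length 23.45 µm, the model's own
steady-state value; background 10 a.u. and noise SD 2 a.u. at a 100 a.u.
amplitude — typical signal-to-background for confocal sections). What
these profiles do *not* emulate: spatially correlated noise, the
FP-interior plateau of real sections, section-to-section DV-length
variation, or segmentation artefacts — so passing recovery tests shows
the processing chain is correct, not that it is robust to every
real-data pathology.

`reference_networks()` serves classified networks from a cache shipped
with the package (150 networks from the pinned-seed reference screen),
so examples and tests have deterministic inputs without re-running the
screen; `build_network_cache()` regenerates it. `make_criteria_fixture()`
builds hand-constructed trajectories with known metric values for
testing the metrics and criteria in isolation.

## Known limitations

* The model is 1-D with spatially uniform growth; non-uniform
  proliferation (the FP proliferates more slowly than the rest of the
  neural tube in vivo) and 2-D/3-D geometry are out of scope.
* Formation-time statistics are sensitive to the boundary-creep issue
  described above; comparisons across degradation-rate conditions are
  only meaningful on networks whose perturbed pattern remains
  stationary and plausibly sized.
* The flux boundary calibration (mirrored ghost bin) is a discretization
  convention; amplitudes under flux sources scale linearly with it, and
  FP sizes — which respond logarithmically to the Shh input — are
  nearly insensitive to it.
* The walk-based screen explores; it is not an inference engine, and
  screen-derived fractions carry chain-level, not visit-level,
  uncertainty.

## A worked example

```{r example, eval = FALSE}
library(shhfp)
library(dplyr)

# a curated Shh^FP-insensitive network from the shipped cache
net <- reference_networks("insensitive", 1)
p <- as_fp_params(net[1, 1:7])

traj <- simulate_tissue(p)      # pulse source, linear growth, 60 h
glance(traj)                    # FP size, amplitude, decay length, timing
autoplot(traj)

# how the FP size responds to the strength of FP Shh production
sens <- sensitivity_scan(list(p), "kappa_F_to_S", n_steps = 9)
autoplot(sens)
```
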