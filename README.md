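# shhfp

Floor-plate formation and Sonic hedgehog (Shh) gradient dynamics in a
growing neural tube.

## What this package is for

During spinal cord development, the Shh morphogen gradient that patterns
the dorsoventral (DV) axis is produced by two sources: the notochord,
which sits beneath the neural tube, and the floor plate (FP), a small
group of ventral midline cells that is itself specified by Shh. How a
morphogen *source* forms inside a growing target tissue — and how source
specification and tissue growth each shape the resulting gradient — is a
quantitative question this package lets you explore.

`shhfp` implements a three-species reaction–diffusion model on a
uniformly growing 1-D domain: non-diffusible fate determinants F (floor
plate) and N (neural progenitor) repress each other cooperatively and
are activated by diffusible Shh and by uniform basal inputs, while the
FP produces Shh with saturating kinetics,

```
dF/dt = a_F * k_F(1 + c_SF*S) / [(1 + K_NF*N)^m + k_F(1 + c_SF*S)] - g_F*F
dN/dt = a_N * k_N(1 + c_SN*S) / [(1 + K_FN*F)^m + k_N(1 + c_SN*S)] - g_N*N
dS/dt = D_S d2S/dx2 + a_S * k_FS*F / (1 + k_FS*F) - g_S*S
```

solved in mapped coordinates with a growth-dilution term, with notochord
Shh supplied as an initial ventral pulse or a boundary flux. On top of
the simulator the package provides:

* a **random-walk computational screen** over the seven interaction
  parameters with data-constrained success criteria, and classification
  of successful networks by their sensitivity to FP-derived Shh;
* **gradient quantification** (amplitude, exponential decay length) and
  floor-plate metrics (size, establishment time T_est, formation time
  T_FP);
* **sensitivity scans, growth/source sweeps** and the amplitude–FP-size
  relation;
* **fluorescence-intensity profile processing** (background subtraction,
  smoothing, group means with confidence bands) plus a synthetic profile
  generator, so the whole quantification chain is testable without
  imaging data.

Everything returns tibbles, composes with dplyr/ggplot2 (`autoplot()`
methods for each result type), and fitted/simulated objects have
broom-style `tidy()`/`glance()` methods. The integrator core is C++
(Rcpp); a 60 h default simulation takes ~0.1 s.

## A worked example

```r
library(shhfp)

# a curated Shh^FP-insensitive network from the shipped cache
net <- reference_networks("insensitive", 1)
p <- as_fp_params(net[1, 1:7])
p
#> <fp_params>
#>   screened: c_S_to_F=13.84, c_S_to_N=0.6788, kappa_F=5.815e-05, kappa_N=2.233,
#>             K_N_to_F=0.07865, K_F_to_N=1180, kappa_F_to_S=0.03274
#>   fixed:    alpha=360/360/360 a.u./h, gamma=0.72/0.72/0.72 /h
#>             D_S=396 um^2/h, m=3/3

traj <- simulate_tissue(p)   # pulse source, linear growth to 60 h
glance(traj)
#> # A tibble: 1 x 8
#>   t_end L_end  l_fp rel_fp a_shh lambda_shh t_est  t_fp
#>   <dbl> <dbl> <dbl>  <dbl> <dbl>      <dbl> <dbl> <dbl>
#> 1    60   400    84   0.21  373.       23.6     4  6.67
```

The network forms an 84 µm floor plate (21% of the 400 µm tissue) that
is established at 4 h and reaches its final relative size before 7 h;
afterwards it simply scales with growth. The Shh gradient it produces
has an amplitude of ~370 a.u. and a decay length of 23.6 µm — close to
the steady-state prediction `decay_length(0.11, 2e-4)` = 23.45 µm set by
diffusion and turnover alone. Removing FP-derived Shh shows this
network's floor plate barely depends on it (the size changes by a single
4 µm bin):

```r
classify_sensitivity(p, base_l_fp = 84)
#> # A tibble: 1 x 3
#>   l_fp_perturbed delta_l_fp sens_class
#>            <dbl>      <dbl> <chr>
#> 1             80          4 insensitive
```

whereas the Shh *amplitude* collapses without the FP source — run
`trajectory_metrics()` under `kappa_F_to_S = 0` to watch the pulse-fed
gradient decay away. A scaled-down screen is one call:

```r
scr <- run_screen(n_chains = 4, n_visits = 2500, seed = 42)  # ~10 min
autoplot(scr)   # half-normal-like distribution of floor-plate sizes
```

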