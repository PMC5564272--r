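# dropevolve

Simulation and analysis toolkit for **recursive droplet evolution**:
populations of water-in-oil microdroplets that grow or shrink by osmotic
exchange through the oil phase, carry an internal polymerisation
chemistry, and are put through iterated cycles of incubation,
size-threshold selection, replenishment with fresh feedstock, and
splitting. It is written for origin-of-life / artificial-chemistry
researchers who want a tested *in silico* counterpart of droplet
microfluidic evolution platforms: a place to explore which permeabilities,
rate constants, thresholds, and noise levels let selection on droplet size
couple to heritable chemical composition — before (or instead of) building
the hardware.

## The model in brief

Each droplet `i` has radius `r_i` (µm) and per-species amounts `n_ik`
(mol). Osmotically active solutes set the osmolarity
`Π_i = Σ_k n_ik / V_i` (mol/L), and droplets exchange with an
area-weighted mean-field bath:

    dV_i/dt = k_w · A_i · (Π_i − Π̄)                      (water)
    dn_ik/dt = k_s · (mw_ref/MW_k) · A_i · (c̄_k − c_ik)   (solutes, 1/MW law)

Trapped (non-exchangeable) species never transfer. Inside each droplet,
mass-action reactions — by default a condensation network `10 M → P` with
autocatalysis by the trapped decamer P — convert a mobile monomer into
trapped polymer, giving faster-polymerising droplets a net osmolarity
advantage and therefore growth. A diameter threshold `f` then decides which
droplets are recirculated: survivors are fused with fresh feedstock, split
in two (with compositional partition noise, the heritable-variation
source), and the loop repeats. Each generation is scored with the Price
decomposition

    w̄ · Δz̄ = Cov(w, z) + E(w · Δz)

(`w` = realised offspring count, `z` = end-of-incubation diameter; the
environment change Δe is reported alongside the transmission term), and
coarsening is tracked with the polydispersity ratio `s/d` — from the
simulated radii directly, or from synthetic micrographs through the
bundled ring detector. See the vignette in `vignettes/droplet-evolution.Rmd`
for the full model, the parameter table, and the design rationale.

## Worked example

The model experiment behind the package: a mixed, monodisperse population
of 50 mM glycylglycine droplets and pure-water droplets, co-incubated for
125 min. The solute droplets grow at the expense of their neighbours and
the polydispersity rises from zero:

```r
library(dropevolve)

pop <- glygly_population(n = 100)        # 50/50 mix, 30 um, monodisperse
run <- incubate(pop, duration = 7500, dt = 10, sample_every = 1500)
run$summary
#> # A tibble: 6 x 5
#>   time_s n_droplets mean_radius_um sd_radius_um s_over_d
#>    <dbl>      <int>          <dbl>        <dbl>    <dbl>
#> 1      0        100           30          0       0
#> 2   1500        100           30.0        0.370   0.0123
#> 3   3000        100           30.0        0.728   0.0243
#> 4   4500        100           30.0        1.07    0.0358
#> 5   6000        100           29.9        1.41    0.0471
#> 6   7500        100           29.9        1.74    0.0580
```

`s_over_d` climbs monotonically (0 → 0.058) as water moves into the
glycylglycine class; an unmixed control (`mix = "glycylglycine"`) stays at
exactly zero. `autoplot(run)` plots the series.

The full evolution loop — default autocatalytic chemistry, threshold
f = 60 µm, 10 generations of 100 droplets:

```r
res <- run_recursion(platform_config(seed = 0))
tidy(res)[1:4, c("generation", "n_survivors", "z_bar_um", "w_bar",
                 "cov_term", "transmission_term", "s_over_d")]
#> # A tibble: 4 x 7
#>   generation n_survivors z_bar_um w_bar cov_term transmission_term s_over_d
#>        <int>       <int>    <dbl> <dbl>    <dbl>             <dbl>    <dbl>
#> 1          0          48     60.0  0.96    0.842            -0.540   0.0176
#> 2          1          63     60.3  1       0.626            -0.389   0.0177
#> 3          2          69     60.5  1       0.569            -0.572   0.0169
#> 4          3          75     60.5  1       0.384            -0.384   0.0149

glance(res)
#> # A tibble: 1 x 6
#>   n_generations z_bar_first_um z_bar_final_um kendall_tau frac_increases
#> 1            10           60.0           60.5       0.556          0.556
```

The positive `cov_term` is selection on size each generation; the negative
transmission term is the dilution from splitting; the mean trait `z̄`
drifts upward across generations (positive Kendall τ) as the catalytic
polymer load ratchets up through the surviving lineages. A neutral control
(no chemistry, no partition noise, monodisperse input) shows no trend.

Scenario YAMLs live in `inst/extdata/`, and a thin command-line front end
in `inst/cli/dropevolve.R` exposes `coarsen`, `evolve`, `detect`, and
`demo` subcommands over the same functions, writing CSVs (and TIFF frames)
stamped with the seed and config hash.

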