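---
title: "Simulating recursive droplet evolution: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating recursive droplet evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropevolve)
```

## The system being modelled

Water-in-oil microdroplets co-incubated in a chamber exchange material
through the continuous oil phase. Water crosses quickly; solutes cross at a
rate inversely proportional to their molecular weight, and sufficiently
large species are effectively trapped. A droplet whose osmolarity exceeds
that of its neighbours therefore draws water from them and grows. When each
droplet also hosts a polymerisation network that converts a small, mobile
monomer into a large, trapped polymer, droplet growth becomes a readout of
the droplet's chemistry, and size-threshold sorting turns that readout into
a selection pressure. Iterating incubation, sorting, replenishment with
fresh feedstock, and splitting yields a serial-transfer evolution
experiment on purely chemical "individuals".

`dropevolve` implements this loop as composable simulation operators plus
the two observables used to monitor it: a Price decomposition of
per-generation trait change, and the polydispersity ratio *s/d* (standard
deviation of droplet radius over mean radius) obtained either directly from
simulated radii or from an image-analysis pipeline run on synthetic
micrographs.

## Physical model

All geometry is in µm (volume `V = 4/3 π r³` µm³, area `A = 4 π r²` µm²),
amounts in mol, osmolarity in mol/L (1 µm³ = 1e-15 L), and time in
seconds.

**Osmolarity.** `Π_i = Σ_k n_ik / V_i` over osmotically active species.

**Water exchange (mean-field).** The chamber is treated as a well-mixed
bath: every droplet exchanges with the area-weighted population mean rather
than with explicit neighbours,

```
dV_i/dt = k_w · A_i · (Π_i − Π̄),   Π̄ = Σ_j A_j Π_j / Σ_j A_j.
```

The area weighting makes the fluxes sum to zero identically, so total
dispersed volume is conserved by construction — the property we care most
about over long integrations. A spatially resolved pairwise model would
change transients but not the qualitative coarsening behaviour; it is out
of scope here.

**Solute exchange.** For exchangeable species `k`,

```
dn_ik/dt = k_s · (mw_ref / MW_k) · A_i · (c̄_k − c_ik),
```

with concentrations held internally in mol/µm³ and `c̄_k` again
area-weighted. The `1/MW` factor is the stated transport law; `mw_ref`
(100 g/mol) only fixes the scale of `k_s`. Non-exchangeable species have
identically zero flux.

**Chemistry.** Reactions run independently inside each droplet with
mass-action kinetics, `rate = k · Π c^order · c_catalyst`. Stoichiometric
counts and kinetic orders are separate fields because condensation
chemistry consumes many monomers per chain while following a low-order
empirical rate law. Every reaction must balance monomer-equivalent mass
(checked to 1e-9 relative when attached to a population), which makes total
monomer-equivalent mass a conserved quantity under reaction.

**Integration.** Explicit Euler with operator splitting: reactions first,
then exchange, per step. The step is validated against the stability bound
`dt ≤ 0.1 · min_i V_i / (k_w A_i Π_max)` — no droplet may exchange more
than a tenth of its volume per step under the worst osmolarity difference.
Amounts that would go negative are clipped at zero and the clipped
monomer-equivalent mass is logged on the population; droplets whose radius
falls below the 0.5 µm extinction floor are removed and logged, never left
with negative volume. Two floating-point conventions keep degenerate cases
exact: populations with uniform osmolarity or uniform concentration get
*identically* zero exchange rates (the unmixed control stays bit-stable
forever), and radii are recomputed from volume only for droplets whose
volume actually changed (a zero-rate population is an exact fixed point of
the stepper).

## Default constants and why

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `k_w` | 0.01 | µm·L·mol⁻¹·s⁻¹ | With 50 mM against water this gives radial drift ~2.5e-4 µm/s, so a mixed monodisperse population coarsens visibly within 1e3–1e4 s, matching the observed timescale of the model experiment. |
| `k_s` | 0.001 | µm/s at `mw_ref` | Monomer re-equilibration time `τ_M = r MW /(3 k_s mw_ref)` ≈ 1.3e4 s for 30 µm droplets — slow relative to water, fast relative to a generation. |
| `mw_ref` | 100 | g/mol | Scale convention only. |
| monomer | MW 132, exchangeable | | Glycylglycine-like precursor. |
| polymer | MW 1320, trapped | | Decamer (`L = 10`); condensation `10 M → P`. |
| `k_init` | 1e-6 | L/mol/s | Second-order initiation; seeds ~1e-4 M polymer in one incubation. |
| `k_auto` | 1.3e-4 | L/mol/s | Autocatalytic growth, first order in monomer, catalysed by polymer. |
| `incubation_time_s` | 2e5 | s | See below. |
| `dt_s` | 40 | s | ~1/50 of the stability bound for the default scenario; halving it moves radius trajectories by far less than 1%. |
| `init_radius_um`, `init_radius_cv` | 30, 0.02 | µm, – | Microfluidic generators produce near-monodisperse emulsions (CV of a few percent). |
| `size_threshold_um` (f) | 60 | µm | Equal to the mean initial diameter, so about half of generation 0 survives. |
| `split_fraction`, `partition_noise_sd` | 0.5, 0.1 | – | Symmetric splitting; 10% relative partitioning noise is the heritable-variation source. |
| `n_droplets`, `n_generations` | 100, 10 | – | Population and horizon of the reference experiment. |

The chemistry constants deserve the longest note, because the obvious
choice (fast autocatalysis) silently breaks the selection mechanism.
Converting `L` monomers into one polymer *removes* `L − 1` osmolytes from
the droplet; the polymer only pays off once the monomer deficit has been
refilled from the bath. Integrated over an incubation, the osmotic benefit
of conversion `x(t)` behaves like `∫x dt − L·τ_M·x(T)`: positive only when
the conversion e-fold time exceeds `L·τ_M` ≈ 1.3e5 s. A chemistry faster
than this makes actively converting droplets *shrink*, anti-selecting the
very lineages the platform is meant to reward. At the same time the
per-generation polymer amplification must beat the two-fold dilution from
fuse-with-feedstock-then-split, `exp(k_auto·[M]·T) > 2`. Both constraints
together force a slow chemistry and a long incubation; the defaults
(`k_auto·[M]·T ≈ 1.3`, amplification ≈ 3.7 per generation) satisfy them
with margin, and the initiation constant is set so the polymer seed
(~1e-4 M after one incubation) needs most of the 10-generation horizon to
ratchet into the millimolar range where its osmotic signal dominates the 2%
initial size noise. This is a deliberate calibration of free parameters —
none of the rate constants, permeabilities or sizes are measured
quantities — made once and kept fixed; all of them are exposed in the
configuration file.

## The evolution loop

One generation of `run_generation()`:

1. **Incubate** for `incubation_time_s`; record each droplet's
   end-of-incubation diameter as its trait `z_i`.
2. **Sort** by the diameter threshold `f`: individual mode keeps droplets
   with `D ≥ f` (ties kept); sub-population mode bins droplets into
   equal-width diameter bins (default 4, emulating passive fractionation
   into groups) and keeps whole bins whose mean diameter reaches `f`.
3. **Replenish and reproduce**: each survivor is fused with one fresh
   feedstock droplet (drawn from the generation-0 size law, containing
   fresh monomer only), and the fused droplet is split once into two
   offspring with partition noise. We fix fuse-then-split rather than
   split-then-fuse; replenishment before reproduction is the natural
   reading of recirculation with fresh feedstock, and the alternative only
   relabels when dilution happens.
4. **Regulate population size**: offspring are uniformly subsampled (or
   the pool is topped up with fresh droplets) to restore `n_droplets`.
   Fitness `w_i` is the number of a parent's offspring present in the
   returned population — 0 for discarded droplets, at most 2 for
   survivors. If nothing passes the threshold the next generation starts
   from fresh feedstock with a warning; the population never empties.

Realised offspring count is the standard Price-compatible
operationalisation of threshold-gated reproduction, and partitioning noise
at splitting is the concrete mechanism standing in for unspecified
"errors in heritance": siblings differ slightly in composition, so a
lineage's catalytic polymer load is heritable but noisy.

## Metrics

**Price decomposition.** For each generation,

```
w̄ · Δz̄ = Cov(w, z) + E(w · Δz),
```

with population (÷n) moments throughout — the identity holds exactly only
under that convention, and `price_decomposition()` reports its own
residual, which is property-tested to stay below 1e-10 (relative) on
fuzzed records. `Δz_i` is the mean offspring trait minus the parent trait,
defined only for parents with offspring (the weighted term vanishes
otherwise). The covariance is computed in centred form so uniform fitness
gives a selection term of exactly zero. The environment change `Δe` is
carried through the generation record and reported *alongside* the
transmission term, not mixed into the algebra: the modified form in which
the environment enters that term is not specified anywhere we can
implement from, and inventing a formula silently would be worse than
annotating honestly.

**Trait choice.** `z` defaults to end-of-incubation diameter — the
quantity the sorter actually thresholds. Growth rate or growth increment
are reasonable alternatives and the decomposition is agnostic; they can be
computed from the exported per-droplet tables.

**Polydispersity.** `s/d` uses the sample (n−1) standard deviation by
default; the convention is configurable and documented because nothing
pins it down externally. `evolution_trend()` summarises a per-generation
series by the fraction of successive strict increases plus a Kendall rank
correlation with generation index, flagging "evolving" when the
correlation is positive and the fraction reaches the cutoff (default 0.6).

## Synthetic imaging

`render_frame()` emulates a brightfield micrograph of a droplet monolayer:
dark interface rings (width 3 px) with slightly brighter interiors on a
mid-grey background, additive Gaussian noise, seeded non-overlapping
dart-throw placement with a border cushion, and exact ground truth stored
with the frame. It does *not* emulate real optics — no defocus,
illumination gradients, partial overlap, or out-of-plane droplets — so
detector performance on these frames is an upper bound, and the pipeline
as a whole is a functional stand-in for the original real-time tracking
software, whose parameters are unpublished.

`detect_droplets()` smooths (Gaussian, σ = 1 px), thresholds globally by
between-class variance maximisation (Otsu) to isolate the dark rings,
fills enclosed regions, labels connected components, and discards
border-touching or sub-`min_area` components (border-touching areas
underestimate radius, hence the exclusion policy). The reported radius is
the mean of the outer equivalent radius `sqrt(filled_area/π)` and the
inner equivalent radius `sqrt((filled − ring)_area/π)`: for a symmetric
interface the two biases cancel, removing the half-ring-width
overestimate that the outer radius alone would carry, without using any
renderer parameter. Equivalent-circle radii from areas are robust for
near-circular monolayer droplets; a Hough-transform detector would handle
overlapping or partial circles better but is unnecessary for these
fixtures.

## What the tests do and do not show

The test suite exercises the model at deliberately modest sizes: 1e4 Euler
steps of a 100-droplet mixed population for the conservation suite, a
two-droplet analytic endpoint (complete water transfer) checked against a
ten-fold finer integration, a 100-droplet 125-minute coarsening emulation,
1000-record Price-identity fuzzing, the 10-generation × 100-droplet
recursion across ten seeds, and 50 noisy synthetic frames for the
detector. Passing them shows the implementation is conservative,
convergent, reproducible, and internally consistent between its
simulation-side and image-side readouts — under the mean-field,
well-stirred, optics-free assumptions above. It does not show that a
physical droplet platform will evolve: the free constants were chosen for
a clean demonstration regime, real chambers have spatial structure and
surfactant physics we exclude, and real micrographs are harder than our
renders.

## Known limitations

- Mean-field exchange: no droplet positions, packing, or
  nearest-neighbour effects (a pairwise mode would be the natural
  extension).
- No interfacial-tension (Laplace-pressure) term, so classical Ostwald
  ripening of a uniform emulsion is absent by design; all coarsening here
  is osmotically driven.
- Explicit Euler: robust at the enforced step bound but first-order;
  stiff chemistries need smaller `dt_s` than the default.
- The Price `Δe` term is an annotation, not algebra (see above).
- The detector assumes non-overlapping, fully interior, in-focus rings.
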