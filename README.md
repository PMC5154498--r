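# memscape

Spatial and kinetic analysis of coarse-grained membrane–receptor
trajectories.

`memscape` is an R toolkit for quantifying how lipid composition and
receptor conformation shape the lateral organization of G protein-coupled
receptors (GPCRs) in multi-component model plasma membranes. It is aimed
at computational biophysicists who run coarse-grained (Martini-style)
simulations of receptor arrays — inactive and/or active protomers in an
asymmetric bilayer with PC/PE/SM/CHOL/GM/PS/PI/PIP/PA/CER/DAG/LPC
headgroup classes — and need the downstream statistics: lipid order and
bilayer-thickness fields, receptor-centred lipid densities, residence
times, sterol flip-flop kinetics, and dimer interface statistics.

Because such trajectories are rarely deposited, the package ships a
synthetic coarse-grained trajectory generator with planted ground truth
(order fields, flip rates, dimer interfaces), so every analysis stage is
testable end to end without molecular dynamics input.

## What it computes

**Lipid order.** For each lipid tail the order metric is the folded angle
between the membrane normal and the linker-to-terminal-tail-bead vector,

χ = arccos(|v_z| / ‖v‖) ∈ [0, π/2],

with χ = 0 a tail parallel to the normal (ordered) and χ = π/2 a tail
lying flat. Cholesterol uses its ROH-to-final-bead vector and is analysed
per z-zone (upper head / 1.6 nm-thick middle / lower head). Order,
thickness (difference of mean leaflet linker-bead heights) and
receptor-centred lipid densities are accumulated on square grids
(0.175 nm bins for order/thickness; 50×50 bins of 0.2 nm for densities,
restricted to monomeric receptors by the 5 nm centre-of-mass rule).

**Pair profiles.** Membrane modulation between two protomers is resolved
as a function of the protomer separation r and the along-axis lipid
position d, for lipids within |n| < r₀ = 1.7 nm of the line of centres
and d ∈ [r₀, r − r₀], restricted to frames where both orientations fall
in angular windows Ω_α = [α₀ − π/6, α₀ + π/6] (α₀ = 0 for the TM1,2,H8
face, −3π/4 for TM5,6) and no third protein occludes the axis.

**Kinetics.** Residence times at each helix (1.2 nm sidechain-bead
cutoff), flip-flop event detection with three-zone hysteresis, rates as
events/(molecules × time), and a cholesterol kinetic network: k-means
microstates on ROH–backbone contact fingerprints, a detailed-balance
transition matrix, spectral lumping into 8 macrostates, and
committor/reactive-flux pathway decomposition between the two bulk
leaflet states.

**Interfaces.** Dimers are detected from binary backbone contact maps
(0.8 nm cutoff, ≥10 contact residues per protomer), named by the helices
with ≥3 contact residues per side (e.g. `TM1,2,H8/TM4`), clustered by
k-means under the mismatch-count metric Tr(DᵀD), and their relative
frequencies estimated with a Bayesian multinomial model via the Poisson
trick — X_j ~ Poisson(λ_j), p_j = λ_j/Σλ, Normal(0, 100) priors on
log λ_j — sampled by adaptive random-walk Metropolis with split-R̂
convergence checks. Interface RMSDs against reference dimers use Kabsch
superposition on the interface-helix backbone beads.

## Worked example

```r
library(memscape)

params <- membrane_params(n_frames = 50, seed = 1)   # 25 nm patch, 16 receptors
run  <- build_system(params) |> simulate_membrane()
traj <- run$trajectory
#> <cg_trajectory> 50 frames x 15598 beads, t = 0..49 ns (replica 1)

flip_rate(detect_flips(traj, "CHOL"), traj, "CHOL")
#> # A tibble: 1 × 6
#>       rate    se n_events rate_upper95 n_molecules     t_total
#> 1 6863732.    NA      150           NA         446 0.000000049
```

The estimated flip rate, 6.86×10⁶ s⁻¹ from 150 events, recovers the
planted default of 7.23×10⁶ s⁻¹ within one standard error of the Poisson
count. Sphingomyelin enrichment in ordered regions shows the planted
SM–order coupling while other species stay near 50/50:

```r
sm_order_enrichment(traj, frames = 10:50)
#> # A tibble: 14 × 4
#>    species p_high_order p_low_order     n
#>  7 PC             0.490       0.510 19106
#> 14 SM             0.643       0.357  9020
```

Interface frequencies with credible intervals from observed dimer counts:

```r
post <- interface_frequencies(
  c("TM1,2,H8/TM4" = 31, "TM1,2,H8/TM4,5" = 15,
    "TM1,2,H8/TM5" = 8, "TM5/TM5" = 8), seed = 1)
tidy(post)
#> # A tibble: 4 × 6
#>   interface      count estimate conf.low conf.high  rhat
#> 1 TM1,2,H8/TM4      31    0.503   0.380      0.630  1.00
#> 2 TM1,2,H8/TM4,5    15    0.241   0.142      0.354  1.00
#> 3 TM1,2,H8/TM5       8    0.130   0.0601     0.224  1.00
#> 4 TM5/TM5            8    0.126   0.0569     0.223  1.00
```

Each estimate is the posterior mean fraction of dimers at that interface;
the bounds are 95% equal-tailed credible intervals. `autoplot()` methods
exist for fields, pair profiles and posteriors, and `tidy()`/`glance()`
for the kinetic network and the posterior.

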