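---
title: "Methods: membrane–receptor trajectory analysis in memscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: membrane–receptor trajectory analysis in memscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memscape)
```

`memscape` analyses coarse-grained trajectories of receptor arrays in
multi-component bilayers. This vignette records the models and
conventions the package implements, the parameters that matter, what the
synthetic trajectory generator does and does not emulate, and the design
choices made where more than one reasonable convention exists.

## Coordinate and geometry conventions

All coordinates are in nanometres. The box is orthorhombic and periodic
in x and y only; z is never wrapped. The instantaneous bilayer midplane
is the mean z of all lipid reference beads — the sterol hydroxyl bead
(ROH) for cholesterol and the first linker bead (GL1 or AM1) for every
other species — and serves as z = 0 for all zone and thickness logic.
Martini beads are treated as equal mass, so every centre of mass is an
unweighted bead mean, computed minimum-image-consistently by unwrapping
the selection about its first bead. Protein COMs use backbone beads only
(configurable); the paper-style protein reference direction is the xy
projection of COM → TM1-COM, which anchors the orientation angle α, the
tilt azimuth φ, and the receptor-frame alignment of density maps.

## Lipid order

The per-tail order metric is the folded angle
`chi = acos(|v_z|/||v||)` between the membrane normal and the vector
from the linker bead to the last tail bead. Folding (taking `|v_z|`)
puts both leaflets on one scale with extremes 0 (parallel to the
normal, ordered) and π/2 (lying flat); this is deliberately not the
traditional P2 segmental order parameter, which is out of scope.
Cholesterol, which has no glycerol tail, uses ROH → final bead and is
classified into three z-zones; the middle zone is 1.6 nm thick
(half-width 0.8 nm), flanked by the two headgroup zones. Species that
flip between leaflets (CHOL, CER, DAG) are excluded from tail-order and
thickness fields.

Fields are accumulated on square grids of 0.175 nm bins (order,
thickness) with per-bin sums and counts; empty bins are *missing*, never
zero. Receptor-centred density maps use 50 × 50 bins of 0.2 nm,
restricted to frames where the receptor is monomeric (COM ≥ 5 nm from
every other receptor, inclusive), and are normalized to sum to 1. The
receptor-frame alignment (translate to COM, rotate reference direction
to +x) is a package choice declared in output metadata; a published
trajectory analysis may have used an unaligned convention for restrained
receptors, for which the alignment is a no-op up to noise.

The ordered/disordered occupancy statistic (`sm_order_enrichment()`)
scores each species' reference-bead samples by whether their grid bin's
mean χ lies below or above the field average. Because "more ordered"
means *smaller* χ, the ordered-enrichment of sphingomyelin appears on
the low-χ side; both fractions are reported rather than a single ratio,
since the sign convention in prose descriptions of such ratios is easy
to invert.

## Pair profiles

For a protomer pair at separation r (COM–COM), lipids are decomposed as
d·v_d + n·n_d with v_d the unit vector from protomer 1 to protomer 2, so
d grows toward protomer 2 from protomer 1's COM (the anchor is a package
decision; the origin is otherwise ambiguous). Orientations α (protomer
1, measured from v_d to its reference direction) and β (protomer 2,
measured from −v_d) must fall in windows of half-width π/6 about α₀ and
β₀; presets are α₀ = 0 for the TM1,2,H8 face and −3π/4 for the TM5,6
face. Frames with any third protein COM within r₀ = 1.7 nm (the average
protomer radius) of the COM–COM segment are discarded, and samples are
kept only for |n| < r₀ and d ∈ [r₀, r − r₀]. Default bins are 0.25 nm in
both r (over [3, 12] nm) and d. The "local thickness" attached to each
lipid is the gridded thickness field looked up at the lipid position —
recomputing a lipid-centred patch thickness would double-count the
field's own discretization noise for no testable benefit.

## Kinetics

Residence times are maximal runs of consecutive frames within 1.2 nm of
any sidechain bead of a helix; a single out-of-contact frame ends a
dwell (no gap tolerance — the plain reading of the definition), and
dwell time is run length × frame stride. Flip-flop detection uses the
three z-zones with hysteresis: an event is recorded the first time a
molecule enters the head zone opposite its last-committed head zone, so
middle-zone excursions that return never count. Rates are
events/(N_molecules × T) per replica with T in seconds of simulation
time; no coarse-grained time rescaling is applied (any speed-up factor
is the user's to apply). The per-molecule-time denominator is an
explicit choice: the alternative per-system-time normalization differs
only by N and is recoverable from the reported molecule count. With zero
events a one-sided 95% Poisson bound 3/(N·T) is reported.

The cholesterol kinetic network featurizes each CHOL-frame as a binary
residue-contact vector (ROH within 0.7 nm of a backbone bead)
concatenated with a one-hot z-zone. Microstates come from k-means
(default `n_micro = 100`, capped at the number of distinct
fingerprints; states visited < 10 times are merged into their nearest
centroid), counts use a sliding window at the chosen lag (default 5
frames), and the transition matrix is the maximum-likelihood reversible
estimate from symmetrized counts, restricted to the largest connected
set. Macrostates (default 8) come from k-means on the top right
eigenvectors of the π-symmetrized transition matrix — a spectral,
PCCA-style lumping. A hidden-Markov refinement was considered and not
shipped: its hyperparameters (output model, EM initialization) are
unconstrained by any requirement here, while the spectral lumping is
deterministic given the seed and passes the same kinetic checks.
Committors are solved linearly, the net reactive flux is
`f_ij = max(0, pi_i q⁻_i T_ij q⁺_j − pi_j q⁻_j T_ji q⁺_i)`, and pathways
are peeled off by iterative widest-path (bottleneck) decomposition.

Lag choice matters: the generator's flip transit gives the zone signal a
short memory, so implied timescales converge from above as the lag
exceeds the transit time. The kinetic-recovery checks use lag 25 frames
against a 2-frame transit; at that lag the slowest implied timescale
matches the planted two-state relaxation 1/(k↑ + k↓) within a few
percent.

## Interface statistics

Contacts are backbone-bead pairs within 0.8 nm (minimum image); a dimer
requires ≥ 10 contact residues on *each* protomer. Interface names list
the helices with ≥ 3 contact residues per side in TM1…TM7, H8 order,
sides joined by "/". Side order is canonicalized by the lowest-index
contacting helix (inactive protomer first as a tie-break in mixed
pairs); if no helix reaches 3 residues the side is named by its
largest-contact helix and flagged weak. Clustering uses k-means over
vectorized canonical maps; the dissimilarity Tr(ΔᵀΔ) is the mismatch
count for binary maps and is minimized over the protomer ordering, which
canonicalization makes consistent across the set. k is selected by mean
silhouette over k ∈ [2, 12] and clusters sharing a majority name are
merged for reporting. The ≥10-residue rule is applied per frame; which
frames enter the clustering (e.g. only a final window) is left to the
caller's frame selection.

Interface frequencies use the multinomial–Poisson equivalence:
X_j ~ Poisson(λ_j) with p_j = exp(γ_j)/Σ exp(γ) and Normal(0, sd 100)
priors on γ_j = log λ_j. The posterior factorizes over j, so the
adaptive random-walk Metropolis sampler updates each coordinate
independently across 4 chains; convergence is enforced with split-R̂ <
1.05 on every p_j, and failure is an error, not a warning. Intervals are
95% equal-tailed by default with the level configurable (some summary
tables in the literature print 97.5% limits; 95% equal-tailed is the
default here). The sampler's calibration is tested by coverage: over
200 simulated multinomial data sets the 95% intervals cover the true
fractions in 95% ± 4% of cases.

Interface RMSD performs a least-squares (Kabsch) superposition on the
backbone beads of the interface helices of the full dimer and reports
the RMSD over those beads in Å (nm × 10); CG backbone beads stand in for
Cα atoms when the reference is an atomistic structure.

## The synthetic trajectory generator

`build_system()` + `simulate_membrane()` produce trajectories with known
ground truth. The defaults are the study conditions of the target
system: 16 protomers on a regular grid with independent random z-axis
rotations, in a 25 × 25 nm patch (the high-receptor-density set-up; 50 nm
is the low-density one), upper-leaflet lipid count from the
1:200-per-protein rule at 50 nm scaled by area (3200/800 upper,
3000/750 lower), a 1 ns frame stride, and an asymmetric composition:
upper leaflet 5% GM, 30% CHOL, 0.7% CER, 1.0% LPC, 0.4% DAG; lower
leaflet 19% charged (PA 1.5%, PIP₁₋₃ 1.6%, PS 9%, PI 6.9%), 27.4% CHOL,
0.1% CER, 0.5% DAG. The PC/PE/SM split of the remainder is a package
choice set so the zwitterionic totals are 60% (upper) and 53% (lower):
0.33/0.08/0.219 upper and 0.27/0.20/0.06 lower. The default planted CHOL
flip rate is 7.23×10⁶ s⁻¹ with DAG at 6.34×10⁶ s⁻¹ and CER effectively
inert (10⁴ s⁻¹).

Mechanistically: lipids take Brownian xy steps (default D = 0.02 nm²/ns,
a realistic CG lateral diffusivity); each lipid carries a latent order
angle evolving as an Ornstein–Uhlenbeck process whose local mean is the
planted field — a baseline χ of 0.5 rad plus Gaussian bumps of
correlation length 1.5 nm at the biased helices (defaults: ordered near
TM1/TM5/TM6, disordered near TM4) — and the tail-bead geometry realizes
that angle exactly. Linker depth is coupled to cos χ so ordered regions
are thicker, giving the order–thickness correlation its expected
negative sign in χ. SM molecules drift down the gradient of the planted
mean-order field with strength `sm_coupling` (0 decouples them — the
null case used in tests). Flip-capable lipids switch leaflets as a
telegraph process at the planted rate, with the z-coordinate crossing
over a configurable transit (default 2 frames) so zone-crossing
detection is exercised rather than teleportation; ground-truth events
are logged at the frame the destination head zone is reached, making
detector counts exactly comparable. Protomers are rigid 8-helix
templates (7 TM + H8 backbone rods with sidechain beads, azimuths laid
out so TM5/TM6 face the −3π/4 sector and an active template with TM6
swung outward); they diffuse, rotate, and when a pair's relative pose
falls inside a planted interface's capture window they bind at the
planted on-rate, locking into the exact pose (which guarantees ≥10
mutual contacts at 0.8 nm), and unbind at the off-rate (0 by default —
formed interfaces persist).

What the generator does **not** emulate: excluded volume (lipids can
overlap each other and the protein footprint after initial placement),
membrane undulations and curvature, electrostatics, lipid-specific
binding sites, and any force field. Passing tests therefore demonstrate
that the *analysis* machinery recovers planted statistical structure —
rates, fields, poses, frequencies — not that the generator reproduces
membrane physics.

## Numerical choices and degenerate inputs

- Largest-remainder apportionment converts mole fractions to integer
  counts deterministically; fractions must sum to 1 within 1e-9.
- Flip-rate estimation carries a small dead time (no re-initiation
  during the ~3-frame transit), biasing the estimate low by roughly
  rate × transit; at the default rates this is ~1–2%, inside the 3-SE
  recovery margin used in the checks.
- `kmeans` is seeded by the caller; microstate clustering initializes
  from distinct fingerprints to avoid duplicate-centre failures.
- Degenerate cases error loudly: empty COM selections, zero observation
  time, zero requested frames, disconnected Markov chains (restricted
  with a warning), fewer than 3 beads for tilt or RMSD, correlation on
  fewer than 2 paired bins (NA with a warning), non-integer Bayesian
  counts, and failed split-R̂.
- GRO I/O is fixed-width with 3-decimal positions; the binary frame
  stack (JSON header + little-endian doubles) is the compact multi-frame
  store, written and read by the package; concatenated GRO is also read.

## Problem sizes in the test suite

The suite generates everything at run time: membranes of 150–500 lipids
with 1–4 protomers for field and interface tests, 200-cholesterol
protein-free membranes of 10³–10⁴ frames for kinetics (the flip-rate
recovery uses 200 CHOL × 10 μs), 60 planted contact maps for clustering,
and 200 multinomial replications for Bayesian coverage. These sizes give
each stochastic check a comfortable margin (3 SE for rate recovery, ARI
≥ 0.9 for clustering, ±4% for coverage) while keeping the full suite in
the low minutes on one CPU.

## Known limitations

- The idealized protomer template reproduces helix topology and
  geometry, not real crystal coordinates; interface names from the
  generator depend on the template's azimuthal layout.
- The tilt of the template is not exactly zero (H8 and the loop caps
  bias the principal axis), so absolute tilt angles of generated systems
  carry a small intrinsic offset; tilt analyses of real trajectories are
  unaffected.
- The MSM module targets the cholesterol network; CER/DAG get rates
  only.
- Bound protomer clusters translate but do not rotate, and cluster
  growth is limited to chains (no cluster–cluster fusion), which is
  sufficient for planting dimers and trimers but not large aggregates.
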