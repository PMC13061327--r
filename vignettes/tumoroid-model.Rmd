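---
title: "The pdtsim tumoroid model: assumptions, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The pdtsim tumoroid model: assumptions, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdtsim)
set.seed(1)
```

`pdtsim` couples three organisational scales: a stochastic
gene-regulatory network (GRN) inside every cell, a cellular life cycle
(growth, division, fate), and population-level mechanics and signaling
in a 3D domain.  This vignette is the package's account of the model:
what is assumed, which parameters matter, what the synthetic data
emulate, and where genuinely open design choices were resolved.

## The gene network as a bursty PDMP

Each cell carries mRNA and protein *amounts* `(M_i, P_i)` for CD133,
SYP and Cyclin E.  Between bursts the amounts follow linear kinetics
(`M' = -d0 M`, `P' = s1 M - d1 P`), solved with the exact closed form —
not an Euler step — so the deterministic part carries no discretisation
error at any `dt`.  Gene `i` bursts at rate
`k0 + (k1 - k0)/(1 + exp(-sigma_i))`, where `sigma_i` sums the gene's
basal activity, the protein-weighted interactions `theta[source,
target]`, and (for CD133 only) the signaling input.  A burst adds an
`Exp(mean = 50)` jump to the gene's mRNA.

Two conventions deserve emphasis:

* **Interaction orientation.** `theta[i, j]` is the influence of gene
  *i*'s protein on gene *j*'s burst frequency.  This is the only reading
  under which SYP (250) activates Cyclin E and CD133 (−2) inhibits it,
  which is what gives differentiated cells their proliferative
  advantage.
* **Amounts, not concentrations.**  Halving "the molecular content" at
  division is only well defined for amounts; volume plays no role in
  the GRN state.

Within a time step, burst clocks are drawn per gene (fixed order CD133,
SYP, CyclinE) from exponential distributions at the current rates;
after each burst all rates are recomputed and the clocks are redrawn.
Rates are held constant between events.  This is the standard
simulation scheme for a PDMP with state-dependent jump rates and makes
runs bit-reproducible for a given seed.

### Key GRN parameters

| parameter | default | unit | meaning |
|---|---|---|---|
| `d0` | 1 | h⁻¹ | mRNA degradation (all genes) |
| `d1` | 0.001 / 0.01 / 0.01 | h⁻¹ | protein degradation (CD133 / SYP / CycE) |
| `s1` | `0.01 * d1` | h⁻¹ | protein synthesis |
| `beta` | −3 / −5 / −5 | — | basal activity |
| `burst_mean` | 50 | molecules | mean burst size |
| `k0`, `k1` | 0, 1 | h⁻¹ | burst-frequency bounds |

`k0` and `k1` are *not* published for this model; 0 and 1 h⁻¹ are
order-of-magnitude choices consistent with the protein scale implied by
`s1 = 0.01 d1` and the fate thresholds (0.003–0.01).  Quantities that
count bursts per cell cycle — above all the de-differentiation
frequency — are directly proportional to the burst budget and therefore
sensitive to `k1` and to the growth rate; this sensitivity is inherited
by every number the package reports, and is the first place to look
when absolute rates differ from published ones while trends agree.

## Cell life cycle

Volume grows linearly (`growth_rate`, default 0.05 volume units/h,
i.e. ~20 h to double) and is capped at 2.2.  A cell divides when its
volume is ≥ 2 *and* its Cyclin E protein is ≥ 0.01.  Daughters receive
half the volume and half of each molecular amount, are placed
symmetrically at ± half a daughter radius along a random direction, and
their fate is assessed *only* at division: stem iff `P_CD133 ≥ Th`,
boundary-inclusive.  The inclusive boundary matters for the initial
condition: founder cells start at `P_CD133 = 2 Th`, so first-generation
daughters sit exactly at `Th` and remain stem.  There is no cell death.

A de-differentiation event — a differentiated mother producing two stem
daughters — requires the mother's CD133 protein to climb from below
`Th` (at her birth) to at least `2 Th` (at her division).  Cell types
are basins of a stochastic system, so such jumps are rare but expected.

## Mechanics and movement

Cells are visco-elastic spheres with a rigid core (core radius = 0.5 ×
external radius by default) in an 80-unit cube with reflexive
boundaries; 1 unit = 6.4 µm.  The force model is deliberately simple:
overlapping pairs repel along their centre line with a displacement
proportional to the overlap — a soft gain (0.05 per sweep) on
external-shell overlap and a ten-fold stiffer gain on core overlap —
applied in Jacobi sweeps (all displacements computed, then applied,
which keeps the update order-independent and deterministic).  Sweeps
repeat until the worst core overlap is below 10⁻³ units or 20 sweeps
are reached; shell overlap may persist across steps, which is what
makes the packing visco-elastic rather than hard-sphere.  A per-sweep
displacement cap (0.25 units) guards against overshoot in crowded
regions.  These gains were chosen for numerical stability, not fitted;
the emergent packing density — and hence the cell count of a
cross-section at a given population size — is downstream of this
choice.

In the default *mobile* mode cells move only through these relaxation
forces (growth and division push neighbours outward).  In *motile* mode
each cell self-propels at `speed × dt` along a persistent random
heading, re-drawn on contact events and boundary reflections; contact
speeds follow the class rules (stem with ≥ 1 stem neighbour → `v_SS`;
mixed contact → `v_SD`, applied to both partners of a
stem–differentiated pair; differentiated-only contact → `v_DD`), with
low speeds acting as an adhesion surrogate.

## Signaling

*Contact*: a stem cell in contact with another stem cell receives
`S = 1`, entering the CD133 sigmoid as `+gamma S`.  Emission and
perception of the contact signal are strictly stem properties.

*Diffusive*: stem cells emit a Gaussian kernel; the field perceived at
position `l` is the Gauss transform `sum_j q exp(-||l - h_j||² /
delta)` over stem-cell centres `h_j`.  `delta` (the reachable area) is
the squared diffusion length: the kernel is a Gaussian of standard
deviation `sqrt(delta/2)` — ~4.5 µm for `delta = 1`, ~6.4 µm (one cell
diameter) for `delta = 2`.  The autocrine self-term is included by
default (an isolated stem cell perceives exactly `q`).

**Who perceives the field?**  This is the one place where the model's
two plausible readings diverge measurably.  If only stem cells evaluate
the field, differentiated mothers are — by construction — blind to
signaling, and the de-differentiation channel cannot respond to it at
all (the contact signal never reaches differentiated cells either).
The documented behaviour of the model, in which enabling short-range
diffusion *raises* the de-differentiation frequency and thereby helps
stabilise stem-cell clusters, requires differentiated cells to sense
the field through their CD133 promoter.  The package therefore defaults
to all-cell perception with stem-only *emission*;
`diffusion_config(perception = "stem")` restores the restricted
variant for sensitivity analysis.

The field is recomputed every step from current positions and types (a
quasi-static approximation, consistent with the kernel formulation
replacing an explicit reaction–diffusion solve).  The fast evaluator
bins sources on a grid and, per target, anchors an adaptive truncation
radius at the nearest source, which yields a provable per-target
relative error ≤ `epsilon` (default 0.01) against direct summation at
near-linear cost.

## Simulation loop and scale

Each `dt = 0.1 h` tick: contacts → signaling terms (from start-of-step
state) → per-cell PDMP advance → growth → divisions (with fate
assignment and event logging) → movement, overlap relaxation and
boundary reflection.  This sub-step order is a documented convention;
nothing in the model pins it down, and reproducibility was preferred
over speculative fidelity.

Runs stop when the population exceeds `stop_count`.  The package
default is 10,000 cells — a desk-scale compromise at which the
central-section indices are already stable enough for scenario
comparisons — while the full-scale experiments use 50,000 (pass
`stop_count = 50000`).  At 10,000 cells a run covers roughly 1,300–
1,500 simulated hours in a few tens of seconds on one CPU; full-scale
runs take minutes.  Replicate counts follow the study conditions:
5 seeds per configuration for the expensive diffusive scans, 10
elsewhere if desired.

## Spatial statistics

Cross-sections keep every cell whose sphere intersects the cutting
plane and convert coordinates to µm.  On the resulting labelled table:

* **Moran's I** uses binary neighbourhood weights (≤ 15 µm), rows
  normalised to sum to one, `w_ii = 0`; isolated cells get zero rows
  and drop from the numerator.  Row normalisation follows the printed
  constraint `sum_j w_ij = 1`; an unnormalised-matrix variant cannot be
  ruled out for the experimental values, which is part of why the
  classification uses a broad min–max band rather than a point target.
* **Entropy** histograms all stem–stem pairwise distances into 64
  equal-width bins over the section diagonal (natural log).  The
  experimental band (0.05–0.21) was obtained under an unknown binning;
  with the package's default the index is comparable *between*
  simulated sections but not against that band, so entropy
  classification should be treated as calibration-sensitive.
* **Centrality** is the mean stem-to-centre distance over the mean
  differentiated-to-centre distance, with the centre taken as the
  centroid of all cells (robust to image framing; a bounding-box option
  exists).
* **aSS** counts same-type neighbours around each stem cell within
  radius `r` (focal cell excluded, boundary-inclusive, `0/0 := 1`).
  Under random labelling its average is 1 *provided neighbourhoods are
  non-empty*; on sparse geometries the `0/0` rule shifts the
  permutation mean above 1, which is visible in the package's tests.
  The analytic null variance is not available here, so the confidence
  band `[1 − q, 1 + q]`, `q = sqrt(var/alpha)`, uses the empirical
  variance over label permutations (default 1,000); by Chebyshev's
  inequality its coverage is at least `1 − alpha` regardless of the
  aSS distribution, i.e. the band is conservative.

```{r ass-demo}
tab <- gen_clustered(pattern_spec(n = 800, stem_fraction = 0.06,
                                  extent = 300, structure = "clustered",
                                  n_clusters = 2, cluster_sd = 20,
                                  seed = 7))
b <- a_ss_band(tab, r = 20, n_perm = 300)
c(a_ss = b$a_ss, upper = b$upper, reject = b$reject)
```

## What the synthetic patterns do and do not emulate

The generators produce labelled point patterns with the gross geometry
of a section — ~2,500 cells on a ~450 µm field, a few percent stem
labels, optionally a 4.5 µm hard core — and controlled label structure:
i.i.d. labels (`gen_random`), labels concentrated near Gaussian cluster
centres on a *fixed* point set (`gen_clustered`, isolating label
autocorrelation from density effects), or labels with a minimum
stem–stem separation (`gen_dispersed`).  They emulate none of the
imaging pipeline: no segmentation errors, no staining-intensity
thresholds, no tissue-boundary effects, no anisotropy.  Tests passing
on these patterns validate the *statistics*, not the model's biological
realism on real immunohistochemistry.

## Numerical choices and degenerate inputs

* Closed-form relaxation switches to the analytic `d0 = d1` limit when
  `|d0 - d1| < 1e-12`.
* Zero burst rates draw an infinite waiting time (no RNG consumed
  asymmetrically: one exponential variate per gene per iteration).
* Statistics that are undefined (single-label tables, no neighbour
  pairs, < 2 stem cells, zero divisions) return `NA` with a specific
  warning rather than an arbitrary number.
* Coincident cell centres in the relaxation kernel separate along a
  fixed axis, so the update stays deterministic.
* `classify()` is boundary-inclusive, matching how the min–max bands
  are used.

## Known limitations

No cell death, no explicit extracellular matrix or mechanical feedback
on fate, fate re-evaluation only at division, three genes only, and a
deliberately schematic force law.  Absolute event rates (notably the
de-differentiation percentage) inherit the uncertainty of the
unpublished burst-frequency bounds `k0`/`k1` and of the growth rate;
scenario *contrasts* (contact vs diffusive, small vs large `delta`) are
the robust outputs at desk scale.
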