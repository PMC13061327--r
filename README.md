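# pdtsim — multiscale simulation of stem-cell organisation in neuroblastoma tumoroids

`pdtsim` simulates the growth of neuroblastoma patient-derived tumoroids
(PDTs) as an off-lattice 3D agent-based model in which every cell carries
its own stochastic gene-regulatory network, and provides the
spatial-statistics layer needed to compare simulated cross-sections with
immunohistochemistry-derived cell tables.  It is aimed at computational
biologists studying how local rules — contact signaling, differential
adhesion, short-range diffusive signaling — shape the spatial clustering
of cancer stem cells.

## The model

**Gene network.** Each cell runs a bursty piecewise-deterministic Markov
process over three genes: CD133 (stemness), SYP (synaptophysin,
differentiation) and Cyclin E (proliferation).  Between bursts, mRNA and
protein amounts relax deterministically,

    M_i' = -d0_i M_i ,      P_i' = s1_i M_i - d1_i P_i ,

and gene *i* bursts (an exponential jump of mean 50 molecules in `M_i`)
at rate

    k_on,i = k0_i + (k1_i - k0_i) / (1 + exp(-sigma_i)) ,
    sigma_i = beta_i + sum_j theta[j, i] P_j  (+ signal, CD133 only).

CD133 and SYP form a toggle switch (self-activation 15, mutual repression
−40); SYP strongly activates Cyclin E (250) while CD133 weakly inhibits
it (−2), so differentiated cells cycle faster than stem cells.

**Cell level.** Cells are visco-elastic spheres with a rigid core in an
80-unit cube (1 unit = 6.4 µm).  Volume grows linearly from 1 to at most
2.2; a cell divides once its volume has doubled *and* its Cyclin E
protein reaches 0.01.  Daughters inherit half of the volume and of every
molecular amount, and their fate is re-assessed at division: stem iff
`P_CD133 >= Th`.  A division in which a differentiated mother yields two
stem daughters is a *de-differentiation* event.

**Signaling.** Either a binary stem–stem contact signal (`+gamma` on the
CD133 sigmoid) or a nonlocal diffusive signal: stem cells emit a Gaussian
kernel `q exp(-d²/delta)` (the "reachable area" `delta` is the squared
diffusion length) and the perceived field is the Gauss transform of all
stem-cell positions, evaluated with a fast truncated scheme whose
per-target relative error is provably ≤ 1 %.

**Statistics.** 2D cross-sections are reduced to labelled cell tables
(the schema of QuPath detection exports) and quantified by stem
percentage, Moran's I (15 µm neighbor radius, row-normalised weights),
the entropy of pairwise stem–stem distances, a centrality index, and the
aSS intra-coefficient with a permutation confidence band
`[1 − q, 1 + q]`, `q = sqrt(var(aSS)/alpha)`.

## Worked example

Grow a desk-scale tumoroid with short-range diffusive signaling
(`delta = 2`, `q = 0.3`, `Th = 0.004`), section it through the centre and
score the section:

```r
library(pdtsim)
cfg <- simulation_config(stop_count = 2000, scenario = "diffusive",
                         diffusion = diffusion_config(q = 0.3, delta = 2),
                         fate = fate_config(differentiation_threshold = 0.004))
res <- run_simulation(cfg, seed = 1)
print(res)
#> tumoroid simulation: 2001 cells after 1130.7 simulated hours ( 11307 steps, seed 1 )
#>   divisions: 1986  de-differentiation events: 76
#>   stem fraction: 10.44 %

section <- cross_section(res)          # 221 cells on the central plane
print(stats_report(section))
#> spatial indices:
#>   percentage    9.9548  [within]
#>   moran         0.1648  [within]
#>   entropy       3.4458  [above]
#>   centrality    0.9041  [within]
#> not all indices within experimental ranges

dedifferentiation_fraction(res)
#> [1] 3.82679
```

The stem percentage and Moran's I fall inside the experimentally observed
bands — short-range diffusive signaling produces genuine stem-cell
clustering — and ~3.8 % of divisions are de-differentiation events.  The
entropy index depends on the histogram calibration (here 64 bins over the
section diagonal) and its experimental band is not transferable across
binnings; see the methods vignette.

Synthetic labelled point patterns (random / clustered / dispersed) for
testing the statistics without any simulation:

```r
tab <- gen_clustered(pattern_spec(n = 2500, stem_fraction = 0.06,
                                  structure = "clustered", seed = 1))
a_ss_band(tab, r = 30)         # aSS with its 95 % permutation band
```

A thin command-line front end is installed with the package
(`system.file("scripts", "pdtsim", package = "pdtsim")`) with
`run`, `stats` and `make-pattern` subcommands, driven by a plain
key-value configuration file (`write_sim_config()` /
`read_sim_config()`).

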