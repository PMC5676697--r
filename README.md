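# epichrom

Simulation and analysis of **stretched, "recolourable" chromatin fibres**:
a coarse-grained model of the coupling between 3D chromatin folding and 1D
epigenetic dynamics, for biophysicists studying epigenetic mark spreading,
reader/writer feedback and chromatin topology in single-molecule settings.

A chromatin fibre is a bead-spring polymer whose beads carry a colour
`q ∈ {grey, red, blue}` (unmarked, or one of two competing histone marks,
e.g. H3K27me3 / H3K9me3).  The fibre is stretched by a force *f* applied to
two macroscopic terminal beads.  Reader proteins are modelled implicitly by
a colour-dependent truncated Lennard-Jones pair potential

    U_ab(x) = (4 ε_ab / N) [ (σ/x)^12 − (σ/x)^6 − (σ/x_c)^12 + (σ/x_c)^6 ],
    x_c = 1.8 σ      if q_a = q_b ≠ 0   (attractive, depth exactly −ε)
    x_c = 2^(1/6) σ  otherwise          (purely repulsive WCA)

and writers by a Metropolis recolouring process: every interval τ_R each
bead is on average attempted once to switch to one of the two other
colours, accepted with probability min(1, exp(−ΔU/k_B T_R)).  Bead motion
follows Langevin dynamics (BAOAB velocity Verlet, compiled engine) with
harmonic bonds (κ = 100 k_B T_L/σ², x₀ = 1.1 σ) and a Kratky–Porod
stiffness (l_p = 3 σ).  The feedback between folding and recolouring makes
the fibre a *magnetic polymer* with an abrupt transition between a
stretched-disordered (SD) and a compact-ordered (CO) state, and — when a
knot is tied into the fibre — localised "epigenetic knotted solitons".

The analysis suite computes the epigenetic magnetisation
m = |n_red − n_blue|/L, the radius of gyration, kymographs, epigenetic
domains (w ≥ 50 beads, > 90% one colour) and their boundaries, boundary
tracks with time-averaged MSD δ²x(t) and diffusion coefficients
D = lim δ²x/2t, and knot localisation on open chains via minimal-arc
closure and Alexander invariants |Δ(−1)|, |Δ(−2)|.

## Worked example

A scaled-down flooding experiment: a 100-bead fibre under moderate force,
flooded with readers/writers of affinity ε = 2 k_B T_L at t = 0.

```r
library(epichrom)

cfg <- simulation_config(L = 100, epsilon = 2, f = 1, tau_R = 10,
                         runtime = 3000, equilibration = 50,
                         save_interval = 30, seed = 3)
sim <- run_simulation(cfg)
sim
#> epichrom_sim: L = 100, epsilon = 2, f = 1, seed = 3
#>   101 frames; final m = 0.890, Rg = 2.54 sigma

tail(sim$observables, 3)
#>     time    m m_signed       rg
#> 99  2940 0.80    -0.80 2.587792
#> 100 2970 0.80    -0.80 2.584027
#> 101 3000 0.89    -0.89 2.537244
```

At this force the fibre collapses and one mark (here blue: signed
magnetisation −0.89) takes over, with R_g ≈ 2.5 σ on the globular L^(1/3)
scale.  At strong stretching the same fibre stays extended and disordered:

```r
cfg$f <- 8
sim2 <- run_simulation(cfg)
steady_state_averages(sim2$trajectory)[c("mean_m", "mean_rg")]
#> $mean_m
#> [1] 0.1309524
#>
#> $mean_rg
#> [1] 31.80427
```

(m ≈ 0.13 is the finite-size noise floor of a random colour field;
R_g ≈ 32 σ is the stretched L-scale.)  `plot(sim$kymograph)` shows the
nucleation and spreading of the winning mark; `find_domains()`,
`analyse_boundaries()` and `analyse_knot_trajectory()` operate on the
kymograph and trajectory, and `tie_knot()` prepares knotted initial
conditions for soliton studies.

A thin command-line interface wraps the same functions
(`inst/cli/epichrom`): `simulate`, `sweep`, `analyse-domains`,
`analyse-knots`, `kymograph`, reading/writing extended-XYZ or
LAMMPS-dump-style trajectories, kymograph TSVs and YAML configs.

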