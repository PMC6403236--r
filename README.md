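# mdrin

Post-simulation analysis of molecular-dynamics ensembles of
protein–nucleic-acid complexes, written for structural bioinformaticians
who have trajectories (e.g. of a Toll-like-receptor ectodomain dimer
bound to double-stranded RNA) and want the standard downstream numbers
without an MD engine in the loop:

* **Structure/trajectory I/O** — multi-model PDB read/write (Å↔nm), an
  atom-selection mini-language (`"chain A and backbone"`,
  `"resid 39 60 108"`, `"heavy"`), nonbonded parameter tables.
* **Geometry** — Kabsch-fitted RMSD(t) and RMSF profiles, radius of
  gyration, Shrake–Rupley SASA, centre-of-mass and minimum distances.
* **Hydrogen bonds** — geometric detection (donor–acceptor ≤ 0.35 nm,
  H–donor–acceptor ≤ 30°) and per-frame group counts.
* **Interaction energies** — per-frame Coulomb + Lennard-Jones
  decomposition over cross pairs, per-residue tables that sum exactly to
  the group total, block-averaged errors.
* **Essential dynamics** — coordinate covariance models, PC projections,
  free-energy landscapes `ΔG = −k_B T ln(P/P_max)`, representative
  frames, Hess covariance overlap, RMSIP, porcupine vectors.
* **Residue interaction networks** — contact graphs (heavy-atom cutoff
  0.7 nm) weighted by hydrogen-bond counts, Brandes betweenness
  centrality

  C_B(v) = [2/((N−2)(N−1))] · Σ_{s<t} σ_st(v)/σ_st,

  selection of central residues (C_B ≥ 0.1) and a reference-vs-variant
  differential (|ΔC_B| ≥ 0.05) with the common flagged-residue
  intersection across variants.
* **Synthetic data** — deterministic generators for toy receptor–ligand
  complexes with *planted* hydrogen bonds, low-rank Gaussian fluctuation
  trajectories with planted PCA modes, graph fixtures with known
  centralities, and parameter fixtures; every analysis stage is testable
  against exact planted truth.
* **Pipeline** — a config-driven driver (`run_pipeline`) reproducing the
  whole workflow per complex and run, writing a deterministic CSV/PDB
  report tree plus cross-complex overlap/RMSIP matrices and differential
  centrality tables.

## Worked example

```r
library(mdrin)

## a two-chain horseshoe complex around a duplex ligand, with planted
## hydrogen bonds at the N-terminal, C-terminal and dimer-interface sites
cx <- make_toy_complex(toy_complex_spec(seed = 1))
cx$traj
#> md_trajectory: 216 atoms, 1 frames, dt = 2 ps
#>   chains: A B C D

hbond_count_series(cx$traj, "chain A", "chain C or chain D")$mean
#> [1] 5            # exactly the five bonds planted for chain A

## three independent runs with a planted (0.9, 0.3, 0.1) nm^2 spectrum
sel <- select_atoms(cx$traj, "backbone")
modes <- make_planted_modes(3 * length(sel), 3, seed = 2)
runs <- lapply(1:3, function(r)
  make_gaussian_trajectory(cx$traj, 500, modes, c(0.9, 0.3, 0.1),
                           noise_sd = 0.01, selection = sel,
                           timestep_ps = 20, seed = 100 + r))

model <- build_covariance(runs, "backbone", window_ns = 8)
model
#> covariance_model: 168 atoms, 1200 frames
#>   trace: 1.25327 nm^2; top eigenvalues: 0.8258, 0.2706, 0.1075
round(cumulative_variance(model, 3), 3)
#> [1] 0.961        # the three planted modes carry 96% of the motion

proj <- project_trajectory(runs, model, k = 2, window_ns = 8)
grid <- fel(proj)                       # 32x32, 300 K
representative_frame(grid, proj)
#> [1] 474          # pooled frame nearest the free-energy minimum

## residue network and centrality on the complex
da  <- infer_donors_acceptors(cx$traj)
hb  <- detect_hbonds(cx$traj$coords[, , 1], da$donors, da$acceptors)
rin <- build_rin(cx$traj, hbonds = hb)
rin
#> residue_graph: 40 nodes, 71 edges (cutoff 0.7 nm)

tab <- betweenness_centrality(rin)
## compare against a perturbed variant of the same complex
mutant <- tab
mutant$cb[mutant$chain == "A"] <- 0.4 * mutant$cb[mutant$chain == "A"]
head(differential_centrality(tab, mutant, threshold = 0.05), 3)
#>   chain resid resname     cb_ref     cb_alt       delta  abs_delta
#> 1     A     5     ALA 0.09446694 0.03778677 -0.05668016 0.05668016
#> 2     A     7     ALA 0.09446694 0.03778677 -0.05668016 0.05668016
#> 3     A     8     ALA 0.08906883 0.03562753 -0.05344130 0.05344130
```

The mean hydrogen-bond count recovers the planted truth exactly; the
covariance model recovers the planted eigenvalue spectrum within a few
percent at this sampling depth; the differential table flags exactly the
residues whose centrality was perturbed by at least 0.05.

For the full workflow, assemble a `pipeline_config()` (or a YAML file via
`read_pipeline_config()`) with labelled complexes and runs and call
`run_pipeline(config, out_dir)`; see the methods vignette
(`vignettes/mdrin-methods.Rmd`) for the model assumptions, parameter
defaults and numerical choices behind every stage.

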