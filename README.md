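# allopath

Allosteric path analysis for molecular-dynamics trajectories, and
FRET-lifetime titration fitting — the two computational arms used to study
how ligand binding at one site of a membrane transporter (such as the
SR/ER Ca²⁺-ATPase, SERCA) is allosterically communicated to a distant
binding site, and how a regulatory micropeptide (such as phospholamban)
can interrupt that communication.

## Who this is for

Computational biophysicists who have Cα trajectories of a protein in
several liganded states and want a reproducible, tested route from raw
coordinates to an allosteric communication network and path; and
spectroscopists fitting time-correlated single-photon counting (TCSPC)
decays and Ca²⁺ titrations who want a global Hill analysis with a shared
cooperativity coefficient across conditions. All inputs can be emulated by
built-in synthetic generators with planted ground truth, so every stage is
testable offline.

## The method

**Structural arm.** A protein chain of *n* residues is decomposed into
*n* − 3 overlapping fragments of four consecutive Cα atoms (consecutive
fragments share three residues). Each fragment, in each frame, is assigned
a letter from a structural alphabet of canonical fragment conformations —
by minimum RMSD after local superposition, or by proximity in the internal
angle space (θ₁, θ₂, τ) of the fragment. The trajectory becomes a set of
aligned structural strings; the coupling between two fragment columns
*C_i*, *C_j* is the finite-size-corrected normalized mutual information

    I_LLn(C_i; C_j) = ( I(C_i; C_j) − ε(C_i; C_j) ) / H(C_i, C_j)

with plug-in estimators, ε = (B_ij − B_i − B_j + 1) / 2T the first-order
finite-size bias term (B = occupied histogram cells, T = frames), clamped
to [0, 1]. Fragments become nodes of an undirected network; a pair is
joined when their first-Cα distance is ≤ 30 Å and I_LLn is above a cutoff
(default: 33% of the maximum pairwise I_LLn). Edges carry the
communication cost w = 1 − I_LLn; the allosteric path between two ligand
sites is the minimum-total-weight (Dijkstra) path over all combinations of
site fragments. Eigenvector centrality (strength = I_LLn) ranks node
importance, and I_LGn scores each fragment's coupling to discretized
global collective-motion states (first principal component, equal-frequency
bins).

**Spectroscopy arm.** TCSPC histograms (16 ps bins) are tail-fit with one-
or two-exponential decays under Poisson weighting; the amplitude-weighted
lifetime τ_DA = Σaᵢτᵢ/Σaᵢ gives the FRET efficiency
E = 100·(1 − τ_DA/τ_D) against the donor-only lifetime τ_D (default
3.52 ns). FRET-vs-[Ca²⁺] titrations are fit with the Hill model

    y = START + (END − START) · xⁿ / (Kⁿ + xⁿ)

globally across conditions: one shared Hill coefficient *n*, independent
START/END/K_Ca per condition (K on a log₁₀ scale, multi-start least
squares). Replicate K_Ca values are compared by one-way ANOVA with
Šidák-adjusted pairwise tests.

## Worked example

Plant a seven-fragment coupled chain among sixteen fragments (copy
probability 0.9, 2000 frames), then recover it:

```r
library(allopath)

fix <- gen_coupled_state_chain(gamma = 0.9, n_frames = 2000, seed = 42)
M   <- illn_matrix(fix$alignment)
net <- build_network(M, fix$coords)      # d_cut = 30 A, mi_frac = 0.33
net
#> MI network: 16 nodes, 6 edges (d_cut 30 A, mi_cut 0.1899)

shortest_allosteric_path(net, site_a = "1", site_b = "7")
#> Allosteric path: f1 -> f2 -> f3 -> f4 -> f5 -> f6 -> f7
#>   total weight 2.6263 over 6 edges; per-edge I_LLn: 0.537, 0.573, 0.559, 0.573, 0.556, 0.576
```

Only the six consecutive-chain edges pass the information and distance
gates (the off-chain fragments are uncoupled noise), and the
minimum-weight path is exactly the planted chain. Each edge's I_LLn
(~0.55) is the fraction of the pair's joint entropy explained by their
coupling; the cutoff 0.1899 is 33% of the strongest observed pair.

Fit a four-condition Ca²⁺ titration generated at K_Ca values spanning an
activated-to-inhibited design (1.8 µM, 332 nM, 702 nM, 334 nM, shared
n = 1):

```r
pars <- data.frame(
  condition = c("apo", "nucleotide", "nucleotide_plb", "nucleotide_s16e"),
  start = c(13.6, 15.6, 13.6, 15.6), end = 18.0,
  n = 1, k = c(1.8e-6, 332e-9, 702e-9, 334e-9))
tt  <- gen_titration(pars, noise_sd = 0.5, seed = 42)
fit_hill_global(tt$data)
#> Global Hill fit: shared n = 0.990 +/- 0.095
#>   apo              START 13.53  END 18.03  K 1.625e-06 M (+/- 2.6e-07)
#>   nucleotide       START 15.35  END 17.91  K 2.102e-07 M (+/- 6.4e-08)
#>   nucleotide_plb   START 13.46  END 18.03  K 6.686e-07 M (+/- 1e-07)
#>   nucleotide_s16e  START 15.79  END 18.08  K 5.15e-07 M (+/- 1.6e-07)
#>   residual sum of squares 67.5
```

The shared cooperativity comes back at 0.99 (truth 1.0) and the fitted
K_Ca values reproduce the planted ordering: the unliganded condition binds
Ca²⁺ weakest (µM), the nucleotide-bound condition strongest (~0.2–0.3 µM),
and the inhibitor shifts affinity back toward µM. `run_path_analysis()`
and `run_fret_analysis()` wrap these stages with YAML configs, artifact
CSV/JSON writers and reproducibility manifests.

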