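---
title: "Methods: allosteric path analysis and FRET titration fitting"
author: "allopath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allosteric path analysis and FRET titration fitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allopath)
```

This vignette documents the models, estimators, numerical choices and
limitations behind the package, in the spirit of a methods section: what
is computed, under which assumptions, and what the built-in tests do and
do not demonstrate.

## 1. The structural arm

### Fragments and structural strings

A protein chain of $n$ residues is represented by $n-3$ overlapping
fragments of four consecutive C$\alpha$ atoms; consecutive fragments share
three residues, and fragments never span chain breaks (pseudo-angles
across a chain break are meaningless). Fragments are named by their first
residue using the author numbering of the input PDB verbatim — no
renumbering — so a fragment label maps directly onto a published residue
span. The shape of a four-point fragment is fully determined by three
internal angles: two pseudo-bond angles $\theta_1$ (atoms 1-2-3) and
$\theta_2$ (atoms 2-3-4), and the pseudo-torsion $\tau$ (atoms 1-2-3-4).
We use the IUPAC biomolecular dihedral convention, cis $=0$,
$\tau \in (-180, 180]$; the sign convention is pinned by tests against an
independent dihedral implementation, because an unstated mirror convention
is the classic silent error of this computation.

### The structural alphabet

Fragments are assigned letters from a pluggable alphabet of canonical
states. Two assignment rules are implemented and config-selectable,
because the literature phrase "RMSD using local fit approximation" is
ambiguous between them:

* `rmsd_local_fit` (default): the state minimizing RMSD after optimal
  proper rigid superposition of the canonical 4-point fragment onto the
  observed one (closed-form Kabsch/SVD; ties break to the lowest letter
  index).
* `descriptor_nearest`: nearest canonical state in
  $(\theta_1, \theta_2, \tau)$ space with a periodic metric on $\tau$.

Assignment is per frame, with no temporal smoothing, so encoding commutes
with trajectory concatenation — a property the tests exploit.

The package ships a **synthetic** 25-state alphabet (letters A–Y,
`inst/extdata/alphabet_synthetic25.json`), built deterministically from a
spread grid of internal-angle triples with a 3.8 Å pseudo-bond. It is
*not* a transcription of any published canonical alphabet; it is a
well-separated stand-in that makes the information machinery exercisable
and testable. Users reproducing a published analysis should supply their
alphabet of choice via `read_alphabet()`; every downstream quantity is
agnostic to the alphabet's provenance. Test correctness never depends on
specific canonical coordinates: small 2–8 state alphabets generated by the
same builder are used throughout the suite.

### Coupling: finite-size-corrected normalized mutual information

For fragment columns $C_i, C_j$ over $T$ frames, with plug-in (histogram)
entropies in nats,

$$ I_{LLn}(C_i;C_j) \;=\; \frac{I(C_i;C_j) - \varepsilon(C_i;C_j)}
   {H(C_i,C_j)} , \qquad
   \varepsilon = \frac{B_{ij} - B_i - B_j + 1}{2T}, $$

where $B_{ij}$, $B_i$, $B_j$ count occupied joint and marginal histogram
cells. $\varepsilon$ is the standard first-order bias of plug-in mutual
information at finite sample size; it is floored at 0, $(I-\varepsilon)$
is floored at 0, and the ratio is clamped to $[0,1]$. When the joint
entropy is zero (two constant columns) $I_{LLn}$ is defined as 0 — the
divide-by-zero case forces a convention, and "no variation, no
information exchange" is the scientifically coherent one. The ratio is
invariant to the logarithm base; everything is computed in nats
internally to avoid mixed-unit bugs. Diagonal entries of the pairwise
matrix are 1 for non-constant columns (self-information) and are excluded
from all cutoff statistics.

The correction matters: for independent 5-letter columns at $T = 200$ the
raw plug-in MI is positively biased by $\approx 0.04$ nats, and the
acceptance suite verifies that the corrected estimate is unbiased to
within Monte-Carlo error over 500 seeds.

### Network, path, centrality

Fragments are nodes with representative coordinates: the time-averaged
position of the fragment's first C$\alpha$ (a single-frame option
exists). A pair is joined by an edge iff their distance is at most
`d_cut` (default 30 Å) *and* $I_{LLn}$ is at least the information
cutoff, by default `mi_frac` $\times$ the maximum off-diagonal $I_{LLn}$
with `mi_frac` $= 0.33$; an absolute override `mi_abs` is available. Edge
weight is the communication *cost* $w = 1 - I_{LLn}$. An all-zero
coupling matrix yields a valid, flagged, empty network rather than an
error, because "no path" is a scientific result (it is exactly the
expected outcome for an uncoupled or inhibited system).

The allosteric path between two sites is the minimum-total-weight path
over all combinations of start/end fragments (Dijkstra, via igraph), with
deterministic tie-breaking: fewer edges first, then the lexicographically
smallest fragment sequence. Tie-breaking is purely for reproducibility —
tied paths are physically equivalent under this model.

Eigenvector centrality uses $I_{LLn}$ (not $w$) as edge strength, since
centrality should reward information exchange while Dijkstra penalizes its
absence. It is computed by power iteration (tolerance $10^{-10}$, max
10,000 iterations) on $A + I$: the unit diagonal shift leaves the
principal eigenvector unchanged but guarantees convergence on bipartite
graphs, where plain power iteration oscillates. Scores are normalized to
max $=1$; a helper flags the top 12% by default, the conventional
reporting band for path-interior fragments. Near-degenerate networks — a
few disconnected edges of almost equal strength — have an ill-defined
principal eigenvector; the pipeline reports that failure in the run
artifacts instead of aborting.

### Global motion states and I_LGn

Global collective-motion states are built by projecting each superposed
frame onto the first principal component of the C$\alpha$ coordinate
covariance and discretizing into `n_states` (default 25) equal-frequency
bins. The PC sign is fixed so frame 1 projects non-positive, making the
series deterministic. This is one defensible construction among several
(the choice of component count and binning is not canonical); it is
config-exposed and validated only against its own contract. $I_{LGn}$
then applies the identical $I_{LLn}$ estimator between each fragment
column and the global state series.

## 2. The geometry arm

Superposition is proper rigid-body least squares (Kabsch, determinant
$+1$), verified against both brute-force minimization over Euler angles
and an independent reference implementation. RMSF uses a two-pass
convention — superpose to frame 1, recompute the time-mean structure,
re-superpose to the mean — which is deterministic and removes the
dependence on the arbitrary first reference; for isotropic Gaussian
jitter of per-axis SD $\sigma$ it converges to $\sigma\sqrt{3}$, a closed
form the acceptance suite checks at $F = 10^4$ frames to 2%.

Residue-pair distances default to C$\alpha$ atoms with a named-atom
override, since published distance analyses often leave the atom choice
unstated; both the atom rule and the 2D histogram bin width (default
0.25 Å, fine enough to separate modes at 15 and 20 Å) are exposed rather
than hard-coded. 2D density maps report percent occupancy per cell
(summing to 100%) and render with the conventional saturation at 21%.

## 3. The spectroscopy arm

### Decay fitting

TCSPC histograms (default 16 ps bins) are tail-fit from the peak bin with
$\sum_k a_k e^{-t/\tau_k}$ ($k \le 2$), no instrument-response
deconvolution: with nanosecond lifetimes and 16 ps binning the IRF
contribution to the tail is negligible. Weighting is Poisson via
iteratively reweighted least squares: the first pass weights by observed
counts, subsequent passes by the fitted model. The model-based weights
matter — weighting by observed counts alone (Neyman $\chi^2$)
systematically underestimates the short lifetime by $\sim$9% at $10^6$
photons, while the IRLS scheme is unbiased (verified over repeated
seeds). Components are reported in descending lifetime; the
amplitude-weighted mean $\tau = \sum a_k\tau_k / \sum a_k$ feeds the FRET
efficiency $E = 100(1 - \tau_{DA}/\tau_D)$. Slightly negative
efficiencies (noise with $\tau_{DA} > \tau_D$) are reported as-is with a
warning, not clipped, so averaging across replicates stays unbiased.

### Global Hill fitting

All conditions are fit simultaneously with one shared Hill coefficient
$n$ and independent START/END/$K$ per condition. $K$ is parameterized as
$\log_{10} K$ (bounds 1 nM–1 mM; $n \in [0.3, 5]$), which makes the
least-squares problem well-scaled across three decades of affinity. Five
multi-starts with deterministic seeded jitter guard against local minima;
parameter standard errors come from the Jacobian curvature at the
optimum. All points enter with equal weight — replicate weighting schemes
are not identifiable from the data layout and the equal-weight choice is
the simplest deterministic one. By construction the shared-$n$ model
nests inside the free-$n$ model, so its loss can never be smaller; the
acceptance suite asserts this inequality on every seed as an optimizer
sanity check. Free Ca²⁺ concentrations are taken as given in the input
table; chelator speciation is out of scope.

Group comparison of replicate $K_{Ca}$ values uses one-way ANOVA followed
by all-pairs two-sample $t$ tests with Šidák adjustment
$p_{adj} = 1-(1-p)^m$ — "Dunn–Šidák" names the correction, not the base
test, and the choice of pairwise $t$ tests is recorded in the output
metadata. Per-replicate $K$ values are obtained by refitting each
replicate with $n$ fixed at the global estimate.

## 4. Synthetic data: what it emulates, and what it does not

The generators provide every input class with planted ground truth:

* **Planted-chain alignments** (`gen_coupled_state_chain`): a root
  fragment flips between two letters as a Markov chain (flip probability
  0.3/frame); each downstream chain fragment copies its upstream neighbor
  with probability $\gamma$, else draws uniformly; off-chain fragments
  are uniform noise. Geometry places consecutive chain nodes 20 Å apart
  (inside the 30 Å gate) and second neighbors 40 Å apart (outside it), so
  the graph cannot shortcut the chain; off-chain nodes sit on a parallel
  line 25 Å away, distance-eligible but information-gated. Defaults
  ($\gamma = 0.9$, $T = 2000$, 16 fragments, chain of 7) are the regime
  where recovery is expected but not trivial: at $\gamma = 0.9$ the
  planted chain is recovered in $\ge 90\%$ of seeds, at $\gamma = 0$ "no
  path" is returned in $\ge 95\%$.
* **Two-state polymer** (`gen_two_state_polymer`): a 100-residue zigzag
  C$\alpha$ chain whose distal arm hinges between two conformers solved
  (by root finding on the hinge angle) to put a probe residue pair at
  exactly 15 Å and 20 Å; Markov switching (default 0.1/0.1 per frame)
  plus isotropic jitter (0.3 Å). This emulates rapid interconversion of a
  binding pocket between closed and open geometries.
* **TCSPC decays** (`gen_decay`): per-bin Poisson counts around a
  multi-exponential mean, 16 ps bins, expected total $10^6$ photons.
* **Titrations** (`gen_titration`): Hill curves on a 12-point log grid
  from 10 nM to 100 µM with Gaussian noise (SD 0.5 FRET points) and six
  replicates per condition, matching the scale of an experimental design
  with six to seven independent preparations per condition.

These are *statistical* stand-ins. They do not emulate real protein
mechanics: no excluded volume, no secondary-structure statistics, no
correlated noise between fragments beyond the planted chain, no detector
afterpulsing or IRF in the decays, and no pipetting-correlated errors in
titrations. A passing suite therefore demonstrates that the estimators
and search are correct and unbiased under their stated models — not that
a particular biological system will yield a clean path or a clean fit.

## 5. Numerical choices and degenerate inputs

* Entropies: plug-in, nats; $0 \log 0 = 0$.
* Collinear fragment triples make the torsion undefined:
  `fragment_descriptors` errors; `rmsd_local_fit` is unaffected (SVD
  handles rank deficiency).
* Superposition requires $\ge 3$ non-collinear reference atoms; the
  rotation is always proper (reflection corrected via the SVD determinant
  sign).
* Ties in state assignment and path search break deterministically
  (lowest letter index; fewer edges then lexicographic).
* Constant fragment columns couple to nothing ($I_{LLn} = 0$) and carry a
  zero diagonal.
* All generators snapshot and restore the global RNG state, and take
  explicit seeds; pipeline runs write a manifest (config, input MD5
  hashes, package version) sufficient to reproduce outputs byte-for-byte.
  Stage timings go to the message stream, never into artifacts.

## 6. Problem sizes used by the test and acceptance runs

The suite exercises: 1000 random column pairs (alphabet ≤ 5, T ≤ 200)
against a brute-force histogram oracle; 500-seed bias Monte Carlo; 1000
random graphs (≤ 10 nodes) against exhaustive simple-path enumeration;
100 random weighted graphs against dense eigen-decomposition; 50-seed
end-to-end planted-chain recovery at $T = 2000$; 500 random fragments
against an exhaustive quaternion superposition oracle; $10^4$-frame RMSF
closed forms; $10^6$-photon decay recovery; and 50-seed global Hill
recovery at the four-condition design. These sizes were chosen as the
smallest that make each statistical claim sharp (e.g. 3-SE bias bounds,
binomial-error occupancy checks); all are fixed-seed and deterministic.

## 7. Known limitations

* The structural arm analyzes C$\alpha$ geometry only; side-chain
  rearrangements enter only through their effect on backbone fragments.
* Paths are graph geodesics: physically intermediate fragments that fail
  the information gate are simply absent, and the method reports the
  graph path without interpolation.
* No time-lagged or directed (transfer-entropy) coupling; the network is
  undirected and time-averaged.
* Decay fitting assumes a clean tail; heavily scattered or IRF-dominated
  data need external deconvolution first.
* XTC input is not supported; convert to DCD or multi-model PDB upstream.
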