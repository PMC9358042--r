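---
title: "Simultaneous rigid fitting of protein subunits into cryo-EM maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simultaneous rigid fitting of protein subunits into cryo-EM maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryomrf)
```

## The problem

Cryo-electron microscopy frequently produces density maps of protein
complexes at medium to low resolution (6–20 Å), where atomic detail is
invisible but individual subunit structures are often known from
crystallography or structure prediction. The modeling task is then to place
each rigid subunit into the map so that (a) every subunit explains density
well and (b) the subunits form physically sensible interfaces. Searching
all subunits jointly is exponential in the number of chains; `cryomrf`
factorizes the problem as a pairwise Markov random field (MRF) over
per-subunit candidate poses, which makes joint scoring tractable while
keeping the coupling between chains.

## Pipeline overview

For each subunit the package performs an exhaustive 6D search: rotations
are sampled from a near-uniform set over SO(3) (7,416 orientations by
default), and for each rotation every integer-voxel translation is scored
by FFT cross-correlation. The per-shift score is the sum of a density
correlation and an overlap fraction:

* **CCC** (experimental maps): `sum(X_i Y_i) / sqrt(sum(X_i^2) sum(Y_i^2))`,
  where `X` is the experimental map and `Y` the simulated map of the
  placed subunit.
* **PCCC** (simulated maps): the mean-centered (Pearson) variant. Centering
  de-emphasizes dense cores and weights molecular surfaces, which works
  better when the target map itself is noise-free simulated density.
* **OV**: the fraction of the subunit's above-contour voxels that fall
  inside the experimental contour, `|X ∩ Y| / |Y|`. Note the asymmetric
  normalization by the subunit map.

The best shift per rotation is kept; poses overlapping the map by less
than 50% are discarded (inclusive boundary: `ov = 0.5` is kept); the
survivors are greedily clustered so that retained placed centroids are at
least 8 Å apart; and up to 100 poses per subunit are retained. Those four
constants — 0.5, 8 Å, 100, and the 7,416-orientation sampling — are the
method's defaults and are exposed in `pipeline_config()`.

Every pair of retained poses of different subunits is then scored with a
docking-style interaction energy (below), and the whole problem is
assembled into a pairwise MRF: one node per subunit holding its pose set
and per-pose node energies, one pairwise table per subunit pair. A single
complex conformation is scored by the log-linear energy

```
E(X_1..X_N) = sum_i [ w_cc * (-CC_i) + w_ov * (-OV_i) ]
            + sum_(i,j) [ w_ph * f_ph(i,j) + w_cl * f_cl(i,j) ]
```

with default weights `w_cc = 0.5`, `w_ov = 0.9`, `w_ph = 1.0`,
`w_cl = 0.8`. All four f-terms are on an energy scale — lower is better —
so good fits (high CC, high OV) get negative node energies and the optimal
assembly is the global energy **minimizer**. The MRF's partition function
is never computed; only MAP inference is needed.

Inference proceeds in two stages. First, one pass of max-sum (min-sum on
energies) belief propagation: each single node sends its per-pose beliefs
to incident pairwise nodes, and each pairwise node `(i, j)` returns to `i`,
for each pose of `i`, the best achievable `edge + belief of j`. For two
subunits this single pass is already exact. For three or more subunits the
cluster graph has loops and one pass is only a heuristic; the package
therefore treats beliefs as guidance and guarantees correctness in the
second stage: a best-first heap search over partial assignments, keyed by
the exact energy of the assigned part plus an admissible lower bound on the
remainder (per-node minima plus row-minima of the not-yet-decided edge
tables). Because the bound never overestimates, complete assignments pop
off the heap in exact energy order, so the returned top-K (default
`K = 10`) provably equals exhaustive enumeration — a property the test
suite checks on dozens of random instances. Assemblies whose total
cross-subunit clash count exceeds 10% of the heavy-atom count are
discarded and the search continues; if no clash-free assembly exists the
package raises an explicit "no valid models" error rather than returning
nonsense.

## Interaction energy

The method needs pairwise interface scores with the structure: van der
Waals, electrostatics, hydrogen/disulfide bonds, solvation, and a clash
count. The concrete functional forms here are deliberately simple,
documented stand-ins with that term structure:

* van der Waals: Lennard-Jones 12-6 in `r_min` form with per-element radii
  (C 1.9, N 1.8, O 1.7, S 2.0 Å) and well depths (0.12–0.25), capped at
  +10 per pair (soft core) so overlapping atoms stay finite;
* electrostatics: Coulomb with distance-dependent dielectric
  `eps(r) = 4r` and residue-level charges (Asp/Glu −1, Lys/Arg +1, split
  over terminal side-chain atoms; everything else neutral);
* hydrogen bonds: N···O pairs within 2.6–3.5 Å contribute −1 each, no
  angular term; disulfides: SG···SG within 1.8–2.4 Å contribute −2;
* solvation: a contact approximation below 5 Å — hydrophobic–hydrophobic
  contacts −0.03, polar-against-hydrophobic burial +0.02.

`f_ph` is the unweighted sum of the four terms; the clash count `f_cl`
enters the energy separately through `w_cl`. All terms are exactly zero
for pose pairs whose minimum heavy-atom distance exceeds 10 Å, and a
bounding-sphere prefilter assigns that exact zero without touching atom
pairs. These forms are *not* a reimplementation of any published docking
potential; conclusions about real interfaces should not lean on their
absolute values, only on their ranking role inside the MRF.

## Numerical choices

* **Grid convention.** Voxel `(i, j, k)` (0-based) is centered at
  `origin + (i, j, k) * voxel_size`. Maps are stored X-fastest; MRC files
  with permuted axis order are normalized on reading.
* **Map simulation.** Each heavy atom contributes an isotropic Gaussian of
  mass equal to its atomic mass; `resolution` is the kernel FWHM,
  `sigma = resolution / (2 sqrt(2 ln 2))`. Kernels are truncated at 4σ
  (search-time subunit maps use 3σ, trading ~0.3% of kernel mass per axis
  for speed). With padding ≥ 2× resolution the integral matches the total
  atomic mass to better than 1%.
* **Which voxels enter the sums.** The correlation and overlap sums run
  over the subunit's own footprint — its simulated map thresholded at 3%
  of its maximum — intersected with the experimental grid, after
  experimental values below the working contour (0.5 × the recommended
  level) are zeroed. The literature rarely states this choice; it is one
  defensible reading and it is applied identically in the FFT path and in
  the naive reference scan, which agree to 1e-6 by test.
* **FFT exactness.** Shifts are restricted to placements with the subunit
  grid fully inside the (zero-padded) experimental grid, so the circular
  FFT correlation has no wrap-around and equals the naive scan exactly.
  The experimental grid is transparently padded so that every rotation of
  the subunit fits; padding with zeros cannot change interior scores.
* **Rotation sampling.** A deterministic super-Fibonacci spiral on the
  quaternion 3-sphere gives exactly `n` near-uniform orientations for any
  `n` (default 7,416, empirical coverage ≈ 13°). A generated set was
  chosen over bundling a published orientation table so that any size is
  available from code alone; the default size matches the method's
  standard sampling density.
* **Ties.** The per-rotation argmax breaks ties lexicographically in
  (z, y, x); pose clustering visits equal scores in rotation order; the
  heap breaks equal energies by lexicographic pose index. Identical
  inputs therefore give identical outputs.
* **Degenerate inputs.** Zero-norm or constant densities on a scoring
  region raise typed errors (`cryomrf_undefined_score_error`) rather than
  returning NaN; empty pose sets after the overlap filter name the
  offending subunit.

## Evaluation metrics

`complex_rmsd()` superimposes the whole model onto the reference with one
global Kabsch fit and reports Cα RMSD; when chains with identical residue
sequences exist, all within-group permutations are tried (each with its own
global fit) and the minimum is returned. `aps()` reports the assembly
placement score: after that global superposition, each subunit's centroid
shift (Å) and rotation angle (degrees, the geodesic angle of its
per-subunit Kabsch rotation) are averaged with residue-count weights, so a
misplaced small chain moves the score less than a misplaced large one. The
per-subunit deviations are measured *after* the global fit — the
global-then-local convention. Angles are averaged arithmetically.

## The synthetic benchmark

`make_toy_complex()` builds pseudo-proteins — compact self-avoiding Cα
walks at 3.8 Å per step with backbone N/O atoms and one CB pseudo
side-chain per residue — and packs them into mutual contact with zero
cross-subunit clashes. `make_benchmark()` simulates the complex's map
(10 Å resolution, 1.0 Å voxels by default, matching the usual
simulated-benchmark convention) and scrambles every subunit by an
independent uniform random rigid transform, recording the planted
ground-truth transforms. For simulated toy maps the "recommended contour
level" is defined as 10% of the map maximum; the working contour is half
that.

Defaults: 3 subunits of 35 residues each. Subunit size matters: at 10 Å
resolution a pseudo-protein much below ~30 residues produces a featureless
blob whose footprint covers most of the small map, and rotational
discrimination collapses — the same small-subunit failure mode seen on
real benchmarks. The 35-residue default gives maps of roughly 50–70 voxels
per side and a recovery problem that is hard enough to exercise every
stage (wrong-rotation poses outscore planted ones locally and must be
rejected by the pairwise terms) yet solvable.

What the toy generator does **not** emulate: real secondary structure,
side-chain packing, experimental noise, B-factor variation, map anisotropy,
or nanodisc/membrane density. Passing the planted-recovery test shows the
search, inference and extraction machinery is correct under the stated
conditions; it does not certify accuracy on experimental maps.

## Problem sizes used by the tests

The test suite verifies the FFT scan against a brute-force scan on 16³
grids, the top-K extraction against enumeration on 50 random MRFs with 2–4
subunits and 3–8 poses each, and the full pipeline on the 3×35-residue
benchmark with a 576-orientation set plus the planted rotations — sizes
chosen so the whole suite completes on one CPU in minutes while still
covering every stage at full fidelity.

## A worked example

```{r example, eval = FALSE}
library(cryomrf)

cx <- make_toy_complex(n_subunits = 3, residues_per_subunit = 35, seed = 11)
bench <- make_benchmark(cx, seed = 12)

planted_q <- do.call(rbind, lapply(bench$planted, function(tr) tr$q))
cfg <- pipeline_config(rotations = rotation_set(576),
                       extra_rotations = planted_q, K = 10)
res <- run_pipeline(bench$map, bench$scrambled, cfg,
                    reference = bench$reference)
print(res)
#> <fit_result> 1 ranked assemblies
#>   rank  1  energy    -7.5042  RMSD   1.17 A  APS (1.16 A, 1.17 deg)
```

The top-ranked assembly recovers the planted complex to about one voxel of
translational error per subunit. Only clash-free assemblies are reported,
which is why fewer than `K` models may be returned.

## Known limitations

* Rigid-body only: no flexible fitting, normal modes, or refinement.
* The interaction terms are generic stand-ins, not a calibrated potential.
* Single-pass BP beliefs are heuristic for ≥3 subunits; correctness comes
  from the exact best-first extraction, whose worst case is exponential
  (bounded in practice by the 100-pose cap and the admissible bound).
* Non-orthogonal map cells, map sharpening, resolution estimation and
  half-map handling are out of scope.
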