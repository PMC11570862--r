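---
title: "alloscan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{alloscan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Allosteric modulators bind protein surfaces away from the active site.
`alloscan` treats the identification of the residues lining such sites as a
per-residue binary classification: each polymer residue of a holo structure
is an allosteric site-forming residue (AFR) or a free residue (FR).  The
package implements the full path from structure files to evaluated
predictions, with a synthetic generator standing in for curated benchmark
structures so that every stage is testable offline.

The ground-truth rule is operational: a residue is an AFR iff its minimum
heavy-atom distance to the modulator group is at most 5 Å — the upper end
of meaningful non-bonded interaction ranges.  The burial signal
LASA = ASA(apo) − ASA(complex) is computed per residue and stored, but the
*label* uses distance: the two criteria disagree only for residues that
approach the modulator without losing surface (rare, and the distance rule
is the one that is unambiguous).  An optional flag additionally requires
LASA > 0 for AFR status (off by default).  When no experimental apo
structure exists, the apo form is the holo structure with the modulator
deleted — a rigid approximation that ignores binding-induced relaxation; it
makes LASA non-negative by construction (occlusion monotonicity).

## Accessible surface area

ASA uses Shrake–Rupley sphere sampling: for each heavy atom, `n_points`
quasi-uniform points on a sphere of radius r_vdw + probe are tested against
all neighbouring expanded spheres.  Two deliberate choices:

* **Deterministic point set** (golden spiral, no RNG): LASA is a difference
  of two ASA runs, and determinism makes it exactly reproducible —
  identical inputs give byte-identical label tables.
* **Defaults** probe 1.4 Å (water), `n_points` 960; the suite checks
  convergence (< 2 % change at 3840 points) and the analytic isolated-atom
  value 4π(r+probe)² within 2 %.

Van der Waals radii are a bundled Bondi-style table (C 1.70, N 1.55,
O 1.52, S 1.80, P 1.80; unknown elements fall back to 1.70 with a warning).
Relative accessibility divides by the Tien et al. theoretical maxima,
clipped to [0, 1.2].  In complexes the modulator occludes protein atoms but
its own area never enters protein per-residue sums.

## The descriptor panel

No authoritative formula set exists for the named nanoenvironment
descriptors, so each is given an explicit operationalization; every
constant is recorded in the table's provenance attribute.

| descriptor | operationalization | default |
|---|---|---|
| `rel_asa` | residue ASA / type maximum, complex-state | probe 1.4, 960 pts |
| `dist_cg` | residue centroid to chain heavy-atom centroid | — |
| `sponge` | void fraction of a grid ball around the residue centroid, outside all vdW spheres | radius 10 Å, grid 1 Å |
| `hydrophob_env` | mean Kyte–Doolittle index over residues within cutoff (self included) | 6.5 Å |
| `elec_pot` | Σ 332.0636·q/(ε(r)·r), formal charges on Lys NZ, Arg CZ (+1), Asp CG, Glu CD (−1), His CE1 (+0.5), termini ±1; ε(r) = 4r, r ≥ 2 Å | — |
| `donor_energy`, `acceptor_energy` | best Kabsch–Sander backbone H-bond energy E = 0.084·332·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN), H rebuilt from the preceding carbonyl, accepted if E < −0.5, floored at −9.9 kcal/mol | — |
| `eccentricity`, `bottleneck` | hop eccentricity and (n−1)(n−2)-normalised betweenness on the 5 Å heavy-atom residue contact graph | 5 Å |

Geometric descriptors are computed on the **complex** (hetero atoms
occlude), mirroring descriptor extraction from deposited holo structures.
LASA and the modulator distance are excluded from the feature set — they
encode the label.  Non-finite values become 0 with a companion
`<name>_missing` indicator column (tree models handle indicator encoding
well); the suite verifies all descriptors are finite and rigid-motion
invariant (grid-anchored sponge and the sampled ASA carry a 0.02
tolerance, the rest 1e-6).

## Selection

Order is correlation pruning first, distribution filtering second.
Pruning is the classical greedy heuristic: while any pair exceeds
|ρ| = 0.7, drop from the worst pair the column with the larger mean
absolute correlation (ties: the later column, for determinism).  The
Kolmogorov–Smirnov filter keeps a descriptor iff the two-sample AFR-vs-FR
p-value is below α = 0.05 — exact p when the smaller class has < 25 rows,
asymptotic otherwise.  No multiple-testing correction by default (the
method this follows used raw KS decisions); Benjamini–Hochberg is
available by flag.  Which member of a correlated pair to drop and the α
level are genuinely open choices; both are config fields and live in the
selection report.

## Models

One gradient-boosted tree classifier per standard residue type, because
descriptor distributions are type-conditional (a buried Trp is not a buried
Gly).  No boosting library is assumed: the package ships a deterministic
Newton-boosting core (Rcpp) — histogram splits on ≤ 64 quantile bins,
log-loss gradients/hessians, L2 leaf regularisation (λ = 3), no row or
column subsampling, first-found tie-breaks.  Class imbalance (about 1:21 in
real benchmark data) is handled by `scale_pos_weight`, defaulting to
n_FR/n_AFR per training subset.  Defaults — 200 iterations, depth 4,
learning rate 0.1 — are library-style defaults; the config validates the
conventional search bounds (depth 3–10, rate 0.001–0.5, iterations
100–1000) but performs no search, consistent with the finding that default
hyperparameters plus weighting suffice.  Types lacking positive rows are
skipped and listed; their rows predict FR with `NA` probability.

Feature attribution offers two routes: per-path split attribution
(Saabas-style contributions on the margin scale, reported as mean
|contribution|) and permutation importance (mean ROC-AUC drop over 10
shuffles).  Exact TreeSHAP was judged out of proportion; the two
implemented routes agree on planted-signal fixtures, which is what the
package's tests require.

Persistence is plain text: `manifest.json` plus one JSON tree dump per
type, with doubles serialised as `%.17g` strings — split thresholds are
data values, so the round trip must be bit-exact or boundary rows change
routing (a bug class the suite now guards against).

## Evaluation

* **Chain-centric split**: composite `PDBcode_chain` keys are shuffled by
  seed; validation/test sizes are `round(fraction·n)`, remainder to train.
  376 keys at (0.503, 0.255, 0.242) give 189/96/91.
* **DCC**: Euclidean distance between heavy-atom centroids of the
  predicted AFR set (all residues with probability ≥ threshold, one set
  per chain) and the true site; success iff ≤ 4 Å.  An empty prediction
  yields an undefined DCC; the success-rate denominator either excludes
  such chains (default, mirroring "N/A" reporting) or counts them as
  failures — both policies are exposed because published denominators are
  not always reconstructible.
* **Residue metrics**: standard confusion-matrix metrics plus rank-based
  ROC-AUC; MCC and AUC are `NA` when a class is absent.
* **Pocket coverage**: external pocket residue lists (neutral TSV) are
  audited for how many labelled AFRs fall outside every pocket.

Selection is fitted on training-split rows only and frozen — the
leakage-safe reading of a workflow description that is silent on the
point.

## The synthetic world

`make_helix_structure()` builds ideal α-helices (φ = −57°, ψ = −47°,
ω = 180°; N, CA, C, O, CB) — backbone-only fixtures are sufficient for
every descriptor above while keeping geometry code small.
`plant_modulator()` was specified as a rigid pre-shaped 8-atom cluster
placed by search; implementation proved that design wrong for sites of
more than three residues (a compact cluster cannot sit within ±0.3 Å of a
target gap to four residues wrapping a helix barrel), so the generator
instead *constructs* the 8-carbon ligand: one anchor atom per site residue,
placed at the gap distance along the residue's radial outward direction
(principal-axis projection), remaining atoms stacked 1.5 Å further out.
This is deterministic, satisfies the ≥ 6-heavy-atom modulator heuristic,
and achieves the gap band exactly; the returned ground-truth site is
re-derived with the 5 Å rule so generator and labeller cannot disagree.
Default fixtures are 32-residue helices with a 4-residue helical-face site
at gap 3.5 Å, sequences drawn from a 5-letter alphabet (A, L, S, K, E) so
per-type training subsets stay populated at desk scale.

`synth_feature_table()` plants a Gaussian mean shift δ on k informative
columns; the optimal score is their sum, so the Bayes ROC-AUC is
Φ(δ√k/√2) — used both to verify parameter recovery (held-out AUC within
0.05 of Bayes at n = 2000 positives, 1:21 imbalance) and as an upper bound
no model may beat by more than 0.03.

What a green suite does **not** establish: real binding sites are pockets
with side-chain chemistry, water structure and conformational change; the
fixtures have none of these.  The synthetic results validate the
*machinery* — labeling geometry, descriptor determinism, selection
behaviour, weighting, DCC arithmetic — not biological accuracy.

## Numerical choices and degenerate inputs

* Altlocs: highest occupancy wins, ties alphabetical; first NMR model only.
* Hydrogens ignored everywhere ("heavy" = element ∉ {H, D}).
* Zero-variance descriptor columns: kept by the pruner (correlation
  undefined), warned about, and left to the KS filter.
* Empty predicted sites: undefined DCC, never an error.
* All boosting tie-breaks are order-deterministic; two runs with equal
  seeds produce identical artifacts, asserted byte-for-byte in the suite.

## Known limitations

Single-conformer, single-model structures; no assembly expansion; the
electrostatics is a screened formal-charge sum, not Poisson–Boltzmann;
attribution is path-based, not exact Shapley; one DCC centroid per chain
(spatially split predictions are not clustered into multiple candidate
sites).
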