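# alloscan

Per-residue prediction of **allosteric site-forming residues (AFRs)** from
protein 3-D structures.

Allosteric modulators bind outside the active site and tune protein
activity; finding the residues that line such sites is a central problem in
structure-based drug design.  Pocket-detection pipelines miss flat or
cryptic sites, so `alloscan` works residue by residue instead: every polymer
residue of a holo structure is labelled AFR or FR (free residue), described
by its *internal nanoenvironment*, and classified by a weighted
gradient-boosted model specific to its amino-acid type.

## Method

1. **Labeling.** With a bound modulator group M, a residue *r* is an AFR iff
   its minimum heavy-atom distance to M is ≤ 5 Å.  The burial signal

   LASA(*r*) = ASA_apo(*r*) − ASA_complex(*r*)

   (loss of accessible surface area; Shrake–Rupley with probe 1.4 Å and a
   deterministic golden-spiral point set) is computed and stored alongside.
   When no experimental apo structure exists, the apo form is the holo
   structure with M deleted.
2. **Descriptors.** Per residue: relative accessibility, distance to the
   chain centre of geometry, void ("sponge") fraction, neighbourhood
   Kyte–Doolittle hydrophobicity, screened Coulomb electrostatic potential,
   Kabsch–Sander backbone H-bond donor/acceptor energies, and contact-graph
   eccentricity and betweenness (5 Å heavy-atom contact graph).
3. **Selection.** Greedy Pearson pruning to pairwise |ρ| ≤ 0.7, then a
   two-sample Kolmogorov–Smirnov filter (AFR vs FR, keep if p < α = 0.05).
4. **Models.** One gradient-boosted tree classifier per residue type
   (log-loss, Newton boosting, deterministic), with the positive class
   weighted by `scale_pos_weight = n_FR / n_AFR`.
5. **Evaluation.** Chain-centric train/validation/test splits
   (PDBcode_chain keys), residue-level metrics (F1, MCC, recall, precision,
   ROC-AUC), and site-level **DCC** — the Euclidean distance between the
   centroids of predicted and true site residues, a success being
   DCC ≤ 4 Å.

A synthetic generator (ideal α-helices with a planted 8-atom modulator, and
Gaussian-shift descriptor tables with known Bayes ROC-AUC) makes the whole
pipeline testable with no downloads.

## Worked example

```r
library(alloscan)
# 12 synthetic holo fixtures: helices with a planted 8-atom modulator
fixtures <- lapply(1:12, function(k) make_labelled_fixture(seed = k + 100))
cfg <- run_config(seed = 1, split_fractions = c(0.7, 0.3, 0))
run <- run_train(fixtures[1:9], cfg)
run$selection
#> <selection report> kept 2 descriptor(s); 3 dropped by |rho| > 0.70; 4 dropped by KS (alpha=0.05)
run$ensemble
#> <allo_ensemble> 5 residue-type model(s) [ALA, GLU, LEU, LYS, SER], 2 feature(s)
ev <- run_evaluate(run, fixtures[10:12])
ev$dcc_table
#>   chain_key n_true n_pred      dcc success
#> 1   fx110_A      4      4 0.000000    TRUE
#> 2   fx111_A      4      4 0.000000    TRUE
#> 3   fx112_A      4      3 1.094845    TRUE
ev$success_rate
#> [1] 100
ev$metrics_overall
#> <metrics> n=96  P=1.0000 R=0.9167 F1=0.9565 MCC=0.9518 AUC=0.9717
```

Reading: on three held-out fixtures the predicted AFR sets sit 0–1.1 Å from
the true planted sites (all under the 4 Å success cutoff); at residue level
the ensemble recovers 91.7 % of planted AFRs with no false positives.

Real structures enter through `read_structure()` (PDB or mmCIF),
`label_residues()` and the same `run_train()`/`run_evaluate()` calls; a thin
CLI (`inst/exec/alloscan`) exposes `simulate`, `label`, `train` and
`evaluate` subcommands.

## Scope

No pocket detection (external pocket residue lists are consumed as TSV), no
hyperparameter search, no Poisson–Boltzmann electrostatics, no multi-model
NMR handling (first model only), single-centroid DCC per chain.
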