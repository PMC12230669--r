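---
title: "Jury consensus scoring of protein complex models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Jury consensus scoring of protein complex models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dockjury)
```

## The problem

Modern structure predictors emit many alternative models of a protein
complex, and downstream users need to know which model to trust — ideally
without the native structure, which is exactly what is unknown. Estimation
of model accuracy (EMA/QA) addresses this. The consensus ("jury") idea this
package implements is simple and robust: if many independently generated
models agree on a structural feature, that feature is probably right.
Concretely, each model in a pool is scored *against every other model used
as if it were the reference*, with a panel of established assembly
similarity metrics, and the model's predicted quality is the aggregate of
those pairwise scores.

## The metric panel

Eight jury metrics are computed per ordered model pair (model *i* scored
with model *j* as reference):

* **lDDT** — superposition-free fraction of reference interatomic
  distances (heavy-atom pairs within 15 Å, in distinct residues, intra- and
  inter-chain) reproduced within tolerances {0.5, 1, 2, 4} Å. Global and
  per-residue forms. The pair set is taken from the reference: atoms the
  model is missing count as unpreserved, so lDDT is deliberately
  asymmetric.
* **TM-score** — superposition-based score
  $\mathrm{TM} = \max \frac{1}{L_{ref}} \sum_i \frac{1}{1+(d_i/d_0)^2}$
  with $d_0 = 1.24\,(L_{ref}-15)^{1/3} - 1.8$ clamped at 0.5 Å. For
  assemblies, all chains are concatenated under a single superposition with
  one normalization length (the total mapped length); this is the standard
  assembly-TM convention, chosen because the sources this package follows
  do not pin down a multimer normalization.
* **GDT_TS** — mean over cutoffs {1, 2, 4, 8} Å of the largest fraction of
  mapped CA atoms superposable within the cutoff.
* **CAD (proxy)** — agreement of residue–residue contact areas. Areas are
  approximated analytically as $A(i,j) = \sum \max(0,\, r_i + r_j + 1.4 -
  d)$ over heavy-atom pairs with standard van der Waals radii — a monotone,
  dependency-free stand-in for Voronoi contact areas, flagged `cad-proxy`
  in output. The per-pair difference is bounded by the reference area
  (a contact that grows cannot count for more than one that vanishes),
  matching the bounded form of the published contact-area difference.
* **QS-score** (global and best) — conservation of weighted inter-chain
  CB–CB contacts (CA for glycine): weight 1 up to 5 Å, Gaussian shoulder
  $\exp(-(d-5)^2/(2\cdot4.28^2))$ to 12 Å, ratio of shared (min) over
  union (max) weights. QS-best restricts to chain pairs interfacing in
  both structures, hence QS-best ≥ QS-global always.
* **DockQ / DockQ-wave** — per-interface composite
  $(\mathrm{fnat} + 1/(1+(\mathrm{iRMSD}/1.5)^2) +
  1/(1+(\mathrm{LRMSD}/8.5)^2))/3$ with the published constants (5 Å
  heavy-atom contacts for fnat, 10 Å backbone cutoff for interface
  residues). DockQ-wave aggregates interfaces by the reference contact
  count of each interface — "wave" is not formally defined in the
  literature this follows, so the contact-count weighting is this
  package's documented choice, exposed as configuration.
* **PatchQS / PatchDockQ** — per-residue interface accuracy. For each
  model interface residue, the patch is that residue plus its 19 nearest
  residues by CB distance (any chain; `patch_size` configurable). PatchQS
  is the QS ratio restricted to contacts inside the patch; PatchDockQ is a
  DockQ-style composite of patch-restricted fnat and backbone RMSD terms.
  The patch construction is this package's choice; the scores it emulates
  are named but not specified in the assessment literature, so parity with
  official values is approximate by design.

## Chain mapping

All metrics require a correspondence between model and reference chains.
Chains are first grouped by sequence identity (end-gap-free pairwise
alignment, identity = matches / shorter length, threshold 0.95 — tolerant
of modelling gaps while separating paralogs; chains under 3 residues match
exactly or not at all). Within groups, the assignment maximizing shared
inter-chain contacts is chosen; ties are resolved geometrically (smallest
total squared CA deviation after one rigid superposition), then by chain
id. Up to 720 candidate assignments (all homomers to hexamers) the search
is exhaustive; beyond that a greedy seed-and-refine search is used, seeded
on the largest chain. The test suite checks greedy = exhaustive on
homo-oligomers up to 4 copies.

## The jury and its variants

With pairwise matrices in hand (diagonal undefined), the jury score of
model *i* under a metric is the mean of its row (mean of the top-*k*
entries is available; plain mean is the default as the least-assumption
consensus). Undefined comparisons are excluded from means, never imputed
as zero — missing is not bad.

* **D2 (linear)**: global assembly score = equal-weight mean of the lDDT,
  TM, GDT and CAD juries; global interface score = equal-weight mean of
  the QS-best, DockQ-wave, PatchQS and PatchDockQ juries. Weights are
  configuration so fitted values can be dropped in.
* **D2R (ranking)**: the same inputs aggregated by mean reciprocal rank
  across metrics, rescaled to [0, 1]; it emphasizes agreement on the top
  model rather than calibrated values.
* **D2S (single model)**: one model against a supplied reference pool;
  the same machinery restricted to that model's row. Its local score is
  the direct mean of the four local tracks (lDDT, CAD, PatchQS,
  PatchDockQ) — the quantity a trained local-score regressor would
  target; no trained network ships with this package.

The combined local track is the unweighted mean of the four local jury
tracks. Ranking is by global interface score, ties by assembly score then
label.

## The decoy generator

Synthetic study conditions come from `make_reference()` and `make_pool()`:
ideal α-helical chains (rise 1.5 Å, 100°/residue; backbone N, CA, C, O and
CB except glycine) arranged with $C_n$ symmetry for homomers and lateral
offsets for heteromers so adjacent chains always share an interface, with
distinct per-group sequence patterns so grouping separates heteromeric
chains. A pool is the reference copy plus one decoy per ladder rung, each
rung perturbing the last chain by a rotation (about its centroid),
translation and Gaussian coordinate noise of increasing magnitude.

Two generator design points deserve explanation:

* **Perturbation directions.** `make_pool()` displaces rungs along
  deterministic outward ("undocking") directions tilted 45° off the
  interface normal with rung-specific azimuths, rather than i.i.d. random
  directions (which `perturb()` itself defaults to). With random
  directions, a lightly perturbed decoy lands closer than the reference
  copy to a mid-rung decoy in roughly a third of draws, and compressive
  displacements inflate the decoy's contact set, flipping the fnat
  asymmetry — either effect can invert the top of the consensus ranking
  for near-duplicate models. Progressive undocking along spread directions
  keeps the reference the strict medoid of its own pool, which is what a
  ground-truth-ordered benchmark requires.
* **Ladder spacing.** The default ladder (10°/3 Å/0.1 Å σ up to
  90°/30 Å/1.0 Å σ) is deliberately coarse: consensus scoring cannot
  distinguish models that differ by less than the jury's resolution, so
  rungs are separated by more than that resolution. Problem sizes used
  throughout the documentation and tests (dimers and trimers of 6–20
  residues per chain, pools of 5) keep every computation exact or
  near-exhaustive while exercising the full code path.

What the generator does *not* emulate: real side chains and packing,
clash relief, compositional errors (missing domains, wrong stoichiometry
in the pool), and the clustered model populations real predictors emit.
Passing tests therefore demonstrate correctness of the scoring machinery
and the consensus logic under controlled geometry, not server-grade
accuracy on real CASP targets.

## Assessor evaluation layer

`evaluate_predictions()` scores a predictor the way assessors score QA
methods: Pearson and Spearman correlations of predicted vs observed
global scores, ROC AUC of local scores (observed binarized at 0.5 by
default; configurable, since official per-metric thresholds vary), and
top-1 selection loss (observed best minus observed quality of the model
ranked first; predicted ties resolve to the first index, also
configurable). Composite totals combine terms per metric:

* local total over {PatchDockQ, PatchQS, CAD, lDDT}:
  0.5·Pearson + 0.5·Spearman + AUC each (maximum 8);
* interface (QSCORE) total over {DockQ-wave, QS}: 0.5·Pearson +
  0.5·Spearman + AUC + (1 − Loss) each (maximum 6);
* fold (SCORE) total over {GDT_TS, TM}: likewise (maximum 6).

When ROC AUC is computed across several targets, per-target ROC averaging
is the default rather than pooling residues across targets.

## Numerical choices and degenerate inputs

* The GDT/TM superposition search seeds from all contiguous fragments of
  lengths {3, L/4, L/2, L} with iterative inclusion refinement (≤6
  rounds); it is heuristic but deterministic (fixed seed schedule,
  first-found maxima). Self-comparisons short-circuit at the exact
  maximum.
* Kabsch superposition corrects reflections (det = +1) and rejects
  collinear point sets; sub-3-point fits fall back to direct RMSD where a
  fallback is well-defined.
* Structures with no inter-chain contacts yield unscored (`NA`) interface
  metrics, serialized as "X" in QMODE2 and 0.00 in B-factor annotation.
* PDB output carries 3-decimal coordinates; disk round-trips are exact at
  that precision and byte-stable from the second write onward.
* Stoichiometry voting ties break by smallest total subunit count, then
  lexicographic order — the voting source does not state a tie-break, so
  this is fixed here for determinism.

## Known limitations

* The CAD proxy is monotone with, but not numerically equal to,
  tessellation-based contact areas; exact parity is a non-goal.
* TM/GDT values can differ from other implementations by small amounts
  because every implementation's superposition search is heuristic.
* The consensus premise fails when a pool is dominated by correlated wrong
  models; the jury then confidently prefers the consensus error. This is
  intrinsic to consensus methods, not specific to this implementation.
* mmCIF, nucleic acids, ligands and hydrogens are out of scope; input is
  PDB-format polypeptide assemblies.

## A minimal worked run

```{r example, eval = FALSE}
pool <- make_pool(decoy_spec("A2", chain_length = 15, seed = 1))
qa <- jury_qa(pool, variant = "D2")
qa[order(qa$rank), c("model", "assembly_score", "interface_score", "rank")]
```

The ranking recovers the generator's ladder order, rung0 (the reference
copy) first. `scripts/acceptance.R` runs this end to end — fixed point,
rank recovery over seeds, correlation with observed quality, selection
losses, local AUCs and composite totals — and writes the numbers as JSON.
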