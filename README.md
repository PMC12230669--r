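# dockjury

Consensus ("jury") quality assessment of protein quaternary-structure
models, for structural bioinformaticians who have a pool of alternative
complex models — from any predictor — and need to know which one to trust
without the native structure.

## The idea

Estimation of model accuracy (EMA/QA) for complexes: each model in a pool
is scored against every other model *used as if it were the reference*,
with a panel of established assembly comparison metrics, and a model's
predicted quality is the aggregate of those pairwise comparisons. A model
that agrees with many alternatives on its fold and its interfaces is
probably right. The jury panel is

- **lDDT** — superposition-free preserved-distance fraction, global and
  per residue (tolerances 0.5/1/2/4 Å within 15 Å);
- **TM-score** — `max (1/L_ref) Σ 1/(1+(d_i/d0)²)`,
  `d0 = 1.24 (L_ref−15)^⅓ − 1.8`, single normalization over the whole
  assembly;
- **GDT_TS** — mean maximal fraction of CA atoms superposable within
  1/2/4/8 Å;
- **CAD** (analytic proxy) — residue contact-area agreement;
- **QS-score** (global/best) — conservation of weighted inter-chain
  CB contacts (weight 1 ≤ 5 Å, Gaussian shoulder to 12 Å);
- **DockQ / DockQ-wave** —
  `(fnat + 1/(1+(iRMSD/1.5)²) + 1/(1+(LRMSD/8.5)²))/3`, aggregated over
  interfaces weighted by reference contact counts;
- **PatchQS / PatchDockQ** — the same ideas evaluated on local patches
  around individual interface residues, giving per-residue interface
  accuracy.

Three combiners mirror the common server variants: `D2` (linear global
scores), `D2R` (rank-optimized) and `D2S` (a single model scored against
a reference pool). Around the core sit chain mapping for homo- and
hetero-oligomers, stoichiometry parsing/voting (`"A3"`, `"A1B1C1"`), CASP
QA (QMODE1/QMODE2) file I/O, B-factor annotation of PDB models with local
scores (×100, the plDDT convention), an assessor-style evaluation layer
(correlations, ROC AUC, top-1 loss, composite totals), and a seeded
synthetic decoy generator so everything is testable offline.

## Worked example

```r
library(dockjury)

pool <- make_pool(decoy_spec("A2", chain_length = 15, seed = 1))
qa <- jury_qa(pool, variant = "D2")
qa[order(qa$rank), c("model", "assembly_score", "interface_score", "rank")]
#>  model assembly_score interface_score rank
#>  rung0      0.6988064      0.52437143    1
#>  rung1      0.6854278      0.41860837    2
#>  rung2      0.6334228      0.16302373    3
#>  rung3      0.5896852      0.04139049    4
#>  rung4      0.5269034      0.02444995    5
```

`make_pool()` builds a homodimer reference plus four decoys of increasing
perturbation ("rungs": progressively undocked copies of one chain). The
jury — which never sees the generator's metadata — ranks the reference
copy first and orders the decoys exactly by their ground-truth rung. The
`assembly_score` column is the consensus of the fold metrics (lDDT, TM,
GDT, CAD), `interface_score` the consensus of the interface metrics
(QS-best, DockQ-wave, PatchQS, PatchDockQ); both in [0, 1], higher is
better, and `interface_score` decays faster because undocking destroys
interfaces before it destroys chain folds.

Reference-based scoring of one model against a native, and the other
entry points:

```r
res <- cmd_score("model.pdb", "native.pdb", out_dir = "out")   # metric table
cmd_qa("models_dir/", out_dir = "out", variant = "D2")          # pool QA -> QMODE2 + annotated PDBs
cmd_eval("predicted.tsv", "observed.tsv", out_dir = "out")      # assessor totals
```

A thin command-line wrapper over the same functions ships at
`inst/scripts/dockjury.R` (subcommands `score`, `qa`, `qa-single`,
`eval`, `make-decoys`).

## Scope notes

PDB-format polypeptide assemblies only (no mmCIF, ligands, nucleic acids
or hydrogens). The CAD score is an analytic overlap proxy, flagged
`cad-proxy` in output. See `vignettes/jury-consensus-methods.Rmd` for the
full model description, parameter defaults, generator design rationale
and known limitations.
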