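---
title: "Screening LC8 binding sites from structure-prediction confidence scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening LC8 binding sites from structure-prediction confidence scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lc8screen)
```

## The problem and the model

LC8 (DYNLL1) is a small homodimeric hub that binds 8–10-residue linear
motifs of disordered client proteins in two symmetric grooves: the client
folds as a β-strand that pairs with the LC8 β3 strand, and the most
conserved motif position (the *anchor*, often a glutamine flanked by
threonines — "TQT") sits against LC8 residue G63. Binding is cooperative:
the first client copy pays the entropic cost of rigidifying LC8, the second
binds more tightly, so almost no LC8 exists half-bound at equilibrium.

The package treats a general protein structure predictor as a noisy binding
assay. Each candidate client window is co-predicted with the LC8 dimer in
two regimes — one client copy (the half-bound transition state of the
cooperative reaction) and two copies (the final duplex) — and the
predictor's *self-assessment* of each model, not the model geometry itself,
is scored. Structures almost always show the client docked in the groove
even for nonbinders; it is the confidence metrics that separate the
classes.

Five scores are extracted per structure:

| score | definition | good direction |
|---|---|---|
| confidence | 0.2·pTM + 0.8·ipTM | high |
| interface pLDDT | mean pLDDT over the bound client region ∪ contacting β3 residues | high |
| LtoP PAE (Å) | mean PAE, β3 rows → bound-client columns | low |
| PtoL PAE (Å) | transpose direction | low |
| dimer PAE (Å) | mean PAE over inter-protomer contact pairs, both directions | low |

PAE is directional — entry (i, j) is the expected error at residue j when
aligned on residue i — and although LtoP and PtoL look definitionally
equal, they differ in practice (β3 is held by a folded protein, the client
by nothing) and are kept separate. LtoP ≤ PtoL is a tendency, not an
invariant, and the package never assumes it.

The best structure of each run is chosen by interface pLDDT rather than by
the predictor's own confidence ranking, which separates the classes less
well. The 1-client and 2-client best-structure scores of the same window
are linked into a ten-parameter vector; a window is called a binder when
**all ten** strict inequalities of a threshold set hold. Conjunction is the
only combination rule consistent with how an exclusive (low false-positive)
and an inclusive (low false-negative) cut set can coexist on the same
parameters; both published sets ship as `thresholds_exclusive()` and
`thresholds_inclusive()`.

## Tunable parameters

* **Window parsing** — length 16, overlap 8 (residues). Full proteins are
  tiled at stride `window − overlap`; a non-multiple length gets one final
  window anchored at the sequence end so every residue is covered. 16/8 is
  the whole-protein scan configuration; targeted runs may use 10–71-residue
  windows.
* **Contact cutoff** — 8 Å between Cα atoms, used for the bound region, the
  β3-contact set and the dimer interface. The qualitative definition is
  "contacting residues"; 8 Å on Cα is the conventional residue-contact
  radius and is a recorded config knob, not a fitted value.
* **β3 span** — LC8 residues 60–67 (1-based LC8 numbering), bracketing the
  G63 anchor landmark. Published structures delimit β3 slightly
  differently; the span is configurable everywhere it is consumed.
* **C-terminal exclusion** — 3 residues per protomer dropped from the dimer
  interface, since the flexible C-termini would dilute the dimer-quality
  control score.
* **GA defaults** — population 200, 300 generations, tournament size 3,
  5% elitism, per-gene mutation probability 0.25 with Gaussian scale 5% of
  each parameter's observed range. No published hyperparameters exist;
  these are ordinary GA settings, all exposed via `ga_config()` and logged
  in the returned object.
* **Affinity models** — TQT: Kd = (best 1-client dimer PAE − 0.89)/0.0035;
  other anchors: Kd = (mean-across-structures 1-client PtoL PAE −
  4.45)/0.135, both in µM. Candidate filtering keeps predicted Kd ≤ 40 µM
  (the calibration data contain almost nothing weaker, so beyond that is
  extrapolation) and drops anchors inside user-supplied structured-domain
  intervals (LC8 binds only disordered regions).
* **AMI binning** — affinities are binned on decade/half-decade edges
  (three presets over 0–100 µM); scores by geometric, linear or quantile
  edges, default 6 bins. The headline value for a metric is the maximum
  over the nine combinations, so it must be read as an upper envelope, not
  an unbiased estimate.

## Numerical and design choices

* **Coordinates** are 0-based half-open internally; 1-based residue
  numbers appear only in presentation. Structural operations use 1-based
  within-chain residue positions as in PDB files.
* **Strict inequalities** at every cut: a vector sitting exactly on a cut
  fails that conjunct. This matches the `>`/`<` semantics of the shipped
  sets and makes `classify` monotone under cut relaxation.
* **Ties**: best-structure selection breaks interface-pLDDT ties toward the
  better (lower) confidence rank; the anchor search breaks distance ties
  toward the lower client index.
* **Unbound predictions are scored, not dropped.** When no client residue
  contacts β3, interface pLDDT and the directional PAEs fall back to the
  full client span and the structure is flagged `unbound`. Nonbinders must
  keep their poor scores or classifier training would see only binders.
* **Two-client grooves are averaged** into a single value per score, since
  a prediction is reported as one row; per-groove values are available in
  the `interface_scores` object.
* **AUROC is the conservative lower-staircase area** Σ(xᵢ₊₁ − xᵢ)·yᵢ of
  the Pareto frontier. For the composite classifier the frontier is built
  from an archive of every cut set evaluated during training, so the area
  is an explicit lower bound on the attainable AUROC — exhaustive traversal
  of a ten-dimensional cut space is infeasible. The archive is pre-seeded
  with every point of each parameter's exhaustive single-parameter ROC
  (each such cut, combined with fully permissive cuts elsewhere, classifies
  identically to the single parameter alone), which *guarantees* the
  composite frontier AUROC is at least the best single-parameter AUROC.
  Seeding only each parameter's optimal cut would not give that guarantee,
  which is why the full sweeps are archived.
* **Affinity floor at 1 µM.** The linear inversions inevitably go negative
  for the best-scoring sites, and a negative Kd is meaningless; any raw
  prediction below 1 µM is reported as 1 µM. Flooring at 1 µM (rather than
  clamping only negative values) keeps the output scale honest: these
  rough models cannot resolve sub-micromolar differences.
* **Eq. for TQT uses the best-structure dimer PAE**, while the non-TQT
  model explicitly averages PtoL across all structures of the run; the
  pairing of "best" with the TQT predictor follows the stated provenance
  of the fitted relation. Both metrics are plain columns of
  `metric_table()`, so either convention is reproducible.
* **Kd is regressed on the linear µM scale**, matching the form of the
  shipped inversions, although log-scale would be the thermodynamic
  convention; `linear_fit` accepts any transformed input if a user prefers
  log-Kd.
* **AMI degenerate cases** (a variable collapsing into one bin) return 0
  with a warning; conventions differ between implementations and 0 is the
  only value that cannot fake a relationship. The expected MI is the exact
  hypergeometric sum over all feasible cell counts, not a Monte-Carlo
  estimate, so small sub-datasets are handled exactly.
* **Geometric score binning** shifts non-positive values before taking
  log-spaced edges; the shift is a documented transformation, and interior
  bins may legitimately be empty.
* **Pseudo-Kd** ((#unbound)²/#bound) is undefined at zero bound structures
  (`NA`); at fully-bound it is 0 by the formula.
* **LC8 ortholog**: the default sequence is human DYNLL1 (UniProt P63167);
  which ortholog was paired with each client is recorded in run metadata
  and configurable, since orthologs differ slightly in numbering-relevant
  positions.

## What the synthetic fixtures emulate — and what they do not

`gen_run_dir()` writes ColabFold-dialect run directories: per-structure
score JSON (uniform pLDDT, a block-structured PAE matrix whose interface
blocks carry configured means, pTM/ipTM consistent with the 0.2/0.8
confidence identity) and Cα-only PDBs of an *idealized* LC8 trace — a
straight 3.8 Å-spaced chain pair 4.9 Å apart, with the client seated 3 Å
out of the dimer plane across the β3 span, or displaced 50 Å for unbound
fixtures. Every geometric operator in the package consumes only pairwise
Cα distances and the β3/G63 landmarks, so this trace exercises identical
code paths to a real structure while keeping expected scores exactly equal
to the configured block means. These files are labeled synthetic in their
manifests and must not be mistaken for structural models.

`gen_score_dataset()` draws class-conditional Gaussian score vectors
truncated to physical ranges ([0,1] confidence, [0,100] pLDDT, [0,31.5] Å
PAE), with a `separation` multiplier on the class mean gap (1 = clearly
separated classes, matching the qualitative picture of real binder/
nonbinder screens; 0 = the null) and an optional bimodal 1-client binder
mode emulating weak binders whose half-bound predictions look like
nonbinders.

Passing tests on these fixtures demonstrates that the arithmetic is right
— scores equal hand-computable block means, the classifier and GA behave
as specified, parameter recovery works — not that the thresholds transfer
to real prediction output. Real score distributions are non-Gaussian,
correlated across the ten parameters, and drift between predictor
versions; retraining on one's own labeled runs is the supported route
(`train_composite`), and the shipped cut sets carry their training-data
provenance in their documentation.

## Null calibration of the trained ROC

Because the reported ROC is a frontier over every evaluated cut set, it is
upward-biased on its own training data — a multiple-testing effect that
grows with the number of evaluations and shrinks with dataset size. The
package's null-calibration check therefore uses 2000 vectors per class and
a small search budget (population 40, 25 generations): at that size the
per-point sampling error of an (FPR, TPR) estimate is ≈ 0.011, so the
frontier of a chance-level classifier stays close to the diagonal and its
area lands near 0.5. With small datasets and long searches the training
frontier of null data can drift well above 0.5; held-out evaluation
(`learning_curve`, or `evaluate_thresholds` on a test split) is the honest
measure of a trained set, and the learning-curve machinery reports exactly
that.

## Known limitations

* The scores assume the standard two-LC8 + client(s) chain layout; other
  stoichiometries are not modeled.
* Linking requires exact window identity between 1-client and 2-client
  runs; near-matches are reported as orphans rather than fuzzily joined.
* Affinity models are calibrated for 16-residue clients and interpolate
  poorly outside 1–40 µM; they are hypothesis-ranking tools, not
  measurements.
* The AMI grid maximum over nine binnings inflates small-sample values;
  compare only against thresholds derived under the same protocol.
* Structured-domain intervals must be supplied by the user; deriving them
  from predicted-structure databases is out of scope.

## A compact end-to-end run

```{r example, eval = FALSE}
vectors <- gen_score_dataset(60, 60, separation = 0.5, seed = 7)
fit <- train_composite(vectors, ga_config(population = 60, generations = 40,
                                          seed = 7))
evaluate_thresholds(vectors, fit$thresholds)

d <- tempfile()
gen_run_dir(fixture_config(n_structures = 5), d)
run <- parse_run_dir(d)
score_run(run)

ledger_report(example_evidence_ledger(),
              priors = c("Hn/Hs" = -45, "Hi/Hs" = -30))
```
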