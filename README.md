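# varvote

Consensus pathogenicity calling and neutral-variant benchmarking for
missense protein variants.

Sequencing programs screening for alpha-1 antitrypsin deficiency (and
similar Mendelian conditions) keep turning up rare missense variants of
SERPINA1 with no experimental characterization. A practical triage runs
several orthogonal computational predictors per variant and asks how many
of them call the substitution damaging. `varvote` implements that
workflow end to end for analysts working with such score tables:

* **Per-predictor calls.** An SVM pathogenicity probability *p*, a FoldX
  folding free-energy change ΔΔG (kcal/mol), and a PolyPhen-2 damage
  probability *s* are thresholded into deleterious/neutral calls:
  deleterious iff *p* ≥ 0.5, round₁(ΔΔG) ≥ 1.0, and *s* ≥ 0.5
  respectively (inclusive cuts; ΔΔG is rounded half-away-from-zero to one
  decimal before the comparison).
* **Consensus category.** With *k* deleterious votes among the available
  predictors: *k* = 3 probably deleterious, *k* = 2 possibly deleterious,
  *k* = 1 possibly neutral, *k* = 0 probably neutral. Missing scores
  shrink the denominator and flag the row as reduced evidence.
* **Ortholog-derived neutral benchmarks.** Candidate neutral variants are
  substitutions observed in close homologs, filtered by conserved flanks
  (±2 alignment columns identical), gap proximity (no gap within ±3
  columns), conserved 3D contacts (every residue with an atom < 5 Å of
  the variant residue aligned to an identical subject residue), and
  source identity (> 90%, computed over ungapped columns); each distinct
  substitution keeps its highest-identity source.
* **Benchmark statistics.** TPR = TP/(TP+FN), TNR = TN/(TN+FP),
  PPV = TP/(TP+FP), NPV = TN/(TN+FN), ACC = (TP+TN)/N,
  BACC = (TPR+TNR)/2, with pathogenic as the positive class and explicit
  NA markers for zero denominators.
* **Seeded synthetic generators** for every stage (homolog pairs with
  planted filter outcomes, toy structures with analytic contact maps,
  score tables with planted confusion matrices), so the whole pipeline is
  testable offline with ground truth known by construction.

The published score tables for SERPINA1 — 16 rare/novel missense SNVs and
a 57-variant benchmark (17 ClinVar pathogenic, 5 ClinVar benign, 35
primate-derived neutral variants) — ship as checksum-verified fixtures.

## Worked example

```r
library(varvote)

cls <- classify_table(aat_novel_scores())
category_counts(cls)
#> probably_deleterious possibly_deleterious     possibly_neutral
#>                    8                    2                    4
#>     probably_neutral
#>                    2

cls  # per-variant calls
#> varvote classification: 16 variant(s)
#>  variant    call_svm  call_foldx call_polyphen2 n_deleterious n_available
#>    P289S deleterious deleterious    deleterious             3           3
#>    ...
#>      I9N     neutral     missing    deleterious             1           2
#>    ...
```

Eight of the 16 novel SNVs draw deleterious votes from all three
predictors (probably deleterious), two from two predictors, four from
one, and two from none. I9N is decided on two predictors only — its
residue lies in the cleaved signal peptide, so no free-energy change can
be computed — and is flagged accordingly.

Benchmarking the 57-variant labelled set:

```r
rep <- benchmark_report(aat_benchmark_scores())
rep$per_predictor$svm$metrics
#> tp=17 fp=7 tn=33 fn=0
#>   tpr   tnr   ppv   npv   acc  bacc
#> 1.000 0.825 0.708 1.000 0.877 0.913
```

The SVM recovers every pathogenic variant (TPR 1.0, NPV 1.0) and calls
28/35 of the primate neutral set benign (TNR 0.825 overall; balanced
accuracy 0.913). `rep$foldx_stability` summarizes FoldX by the sign of
ΔΔG: 16/17 pathogenic variants are predicted destabilizing and 4/5
ClinVar-benign variants stabilizing.

A command-line surface wraps the same functions
(`exec/varvote classify --scores ...`, `benchmark-build`,
`benchmark-score`, `simulate`), with distinct exit codes for usage,
data-validation and I/O errors.

Neutral-set construction from your own data:

```r
query    <- read_fasta("query.fasta")
homologs <- lapply(seq_names, function(id) read_fasta("homologs.fasta", id))
struct   <- read_structure("structure.pdb")
ns <- build_neutral_set(query, homologs, structure = struct)
ns$accepted    # surviving candidates, one per substitution
ns$candidates  # every candidate with per-filter booleans and reasons
```

See `vignettes/consensus-pathogenicity.Rmd` for the model, the
threshold-boundary decisions, the filter semantics, and what the
synthetic generators do and do not emulate.

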