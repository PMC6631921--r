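---
title: "Consensus pathogenicity calling and ortholog-derived neutral benchmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus pathogenicity calling and ortholog-derived neutral benchmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varvote)
```

## The problem

Rare missense variants of SERPINA1, the gene encoding alpha-1 antitrypsin
(AAT), are found routinely by sequencing programs screening for AAT
deficiency, but most have no experimental characterization. A practical
triage combines several orthogonal computational predictors and asks how
many of them consider a substitution damaging. `varvote` implements that
triage — thresholding, voting, and benchmarking — as a reusable toolkit,
together with the construction of ortholog-derived neutral variant sets
used to benchmark the predictors.

The package works at the protein level throughout: a variant is a
reference residue, a 1-based position, and an alternate residue (or `X`
for a stop gain, which is representable but never scored). Two numbering
schemes coexist for secreted proteins: *mature* numbering (signal peptide
removed; the conventional clinical numbering for AAT) and *precursor*
numbering (including the 24-residue signal peptide). Conversion is an
exact `+24`/`-24` shift; a precursor position at or below 24 lies inside
the cleaved signal peptide, has no mature equivalent, and conversion
refuses it rather than guessing — the packaged I9N variant is the
motivating case.

## The consensus vote

Three predictor scores enter per variant:

* an SVM-derived probability that the change is pathogenic, in $[0, 1]$;
* a FoldX folding free-energy change $\Delta\Delta G$ in kcal/mol
  (positive destabilizes the folded protein);
* a PolyPhen-2 damage probability in $[0, 1]$.

Each is thresholded into a deleterious/neutral call:

$$
\text{SVM deleterious} \iff p \ge 0.5, \qquad
\text{FoldX deleterious} \iff \operatorname{round}_1(\Delta\Delta G) \ge 1.0, \qquad
\text{PolyPhen-2 deleterious} \iff s \ge 0.5 .
$$

All comparisons are inclusive ("0.5 and above"). The number of
deleterious votes among the available predictors maps onto four
categories: 3 votes = *probably deleterious*, 2 = *possibly deleterious*,
1 = *possibly neutral*, 0 = *probably neutral*. The label is a pure
function of the count: which predictor voted never matters.

Three calling decisions deserve explanation because the design was
genuinely open:

**FoldX boundary.** The conventional rule for a significant destabilizing
effect is $\Delta\Delta G > 1$ kcal/mol. Applied literally to scores
printed at two decimals this calls 0.99 neutral, which contradicts the
published per-variant calls the fixtures transcribe (D341V, at a printed
0.99, is called deleterious there, while 0.72 is neutral). The package
therefore rounds $\Delta\Delta G$ half-away-from-zero to one decimal
before the inclusive comparison — equivalently, deleterious at
$\Delta\Delta G \ge 0.95$ — which reproduces every printed call. The
rounding is configurable (`thresholds(foldx_digits = Inf)` gives the
strict unrounded rule). Base R's `round()` is not used at the boundary
because it rounds half to even.

**PolyPhen-2 boundary.** PolyPhen-2 is conventionally described by a
ternary coding (benign below 0.15, probably damaging above 0.85). The
printed binary calls in both fixture tables, however, are jointly
consistent only with a single cut at 0.5 (e.g. a score of 0.517 is called
damaging; 32/35 of the primate set is called benign). The vote therefore
uses $s \ge 0.5$; the ternary coding is retained purely descriptively via
`pp2_ternary_label()`.

**Missing predictors.** A score can be missing (the packaged I9N variant
has no $\Delta\Delta G$ because its residue has no structure
coordinates). Missing predictors shrink the vote denominator without
changing the count-to-label map: one deleterious vote out of two
available is still *possibly neutral*. Such rows carry a
`reduced_evidence` flag. No fixture case has two deleterious votes out of
two available; the map would yield *possibly deleterious* there, with the
flag raised.

## Ortholog-derived neutral benchmarks

Benign human variant sets are small, so neutral benchmark variants are
harvested from close ortholog sequences: a residue where a close homolog
differs from the query, in an otherwise identical sequence and structural
context, is very likely neutral. `build_neutral_set()` implements the
filter cascade on pairwise alignments:

1. **Substitution extraction** — one candidate per alignment column where
   both rows hold residues and they differ (indels are not
   substitutions); positions are reported in ungapped 1-based query
   coordinates.
2. **Conserved flank** — the 2 alignment columns on each side must all
   exist and hold identical residues in both rows. Interpreted on
   alignment columns; a gap in the window fails.
3. **Gap proximity** — no gap in either row within 3 columns.
4. **Contact conservation** — every residue with at least one atom
   strictly within 5 Å of the variant residue (in the query's structure)
   must be aligned to an identical subject residue; a contact aligned to
   a gap counts as different. Variant positions absent from the structure
   are recorded as not resolvable and rejected rather than guessed.
5. **Identity** — candidates from pairs at or below 90% identity
   (computed over ungapped columns) are dropped; the threshold is strict.
6. **Deduplication** — among candidates passing every filter, each
   distinct substitution keeps the record from the highest-identity pair,
   with ties broken toward the lexicographically smaller subject
   identifier. Filters are applied per alignment first and the closest
   surviving source is then selected; this ordering reflects the intent
   of preferring variants observed in the closest homologs.

The percent-identity denominator (ungapped aligned columns) is a
documented choice; no universal convention exists, and it is configurable
through `aligned_pair` inputs since pre-aligned rows are accepted as-is.
Unaligned homolog sequences are aligned internally with Needleman–Wunsch
global alignment (BLOSUM62, affine gaps, opening 10 / extension 0.5).
Alignment acquisition by iterative database search is deliberately out of
scope: the filters are defined on alignment columns, not on any
particular search tool.

Contact maps follow the strict-inequality definition above, computed over
all polymer atoms; sequence neighbours $i \pm 1$ are *not* excluded
(nothing in the filter definition excludes them), waters and hetero
ligands are excluded, the first model of multi-model files is used, one
chain is analysed (first polymer chain by default), and alternate
locations resolve to the highest-occupancy conformer. Query positions map
to structure residues by author numbering by default, with an optional
user-supplied mapping for renumbered structures.

## Benchmark statistics

With pathogenic as the positive truth class and deleterious as the
positive prediction,

$$
\mathrm{TPR} = \frac{TP}{TP+FN},\quad
\mathrm{TNR} = \frac{TN}{TN+FP},\quad
\mathrm{PPV} = \frac{TP}{TP+FP},\quad
\mathrm{NPV} = \frac{TN}{TN+FN},
$$
$$
\mathrm{ACC} = \frac{TP+TN}{TP+FP+TN+FN},\qquad
\mathrm{BACC} = \tfrac12(\mathrm{TPR}+\mathrm{TNR}).
$$

A statistic with a zero denominator is reported as `NA` (an explicit
undefined marker) rather than raising an error, because the small subsets
typical of these benchmarks make empty cells likely; only an all-zero
confusion matrix is an error. Values are carried at full precision;
display rounding is half-away-from-zero to three decimals.

`benchmark_report()` additionally summarizes FoldX by the *sign* of
$\Delta\Delta G$ (fraction of a subset with $\Delta\Delta G > 0$,
i.e. predicted destabilizing). This is deliberately distinct from the
classification vote cut: the published per-subset stability fractions the
fixtures reproduce (16/17 of the pathogenic set destabilizing; 4/5 of the
benign set stabilizing) are only obtainable under the sign criterion —
e.g. M358R at $\Delta\Delta G = 0.431$ counts as destabilizing although
it does not reach the 1 kcal/mol classification cut.

One known discrepancy: the published summary table accompanying the
57-variant benchmark prints SVM PPV = 0.720 and ACC = 0.879, and
PolyPhen-2 TPR = 0.944, PPV = 0.85, ACC = 0.931, BACC = 0.935, whereas
the confusion counts implied by the printed per-variant scores give
17/24 ≈ 0.708, 50/57 ≈ 0.877, 16/17 ≈ 0.941, 16/19 ≈ 0.842,
53/57 ≈ 0.930 and ≈ 0.933 respectively. The counting basis of those
summary cells is not recoverable from the printed data; `varvote` reports
its recomputed values and documents the difference here rather than
matching those cells.

## Synthetic data: what it emulates and what it does not

Full-scale neutral-set construction depends on an external iterative
database search against a primate sequence snapshot, which is neither
reproducible at desk scale nor version-stable. The package's test harness
therefore rests on seeded generators that plant ground truth by
construction:

* `gen_homolog_pair()` builds a query/homolog alignment in which every
  substitution's filter outcome is planted: passing sites are isolated
  with conserved flanks; flank failures are planted as *twin* adjacent
  substitutions (both candidates fail, and both are recorded in the
  truth table); gap failures place a subject gap exactly 3 columns away
  (inside the gap window but outside the flank window); contact failures
  place a subject gap at a sequence-distant 3D contact partner. All gaps
  are subject-side, keeping query coordinates equal to alignment columns.
  Isolated filler substitutions tune realized identity to the target
  within one percentage point (validated at generation; infeasible specs
  raise a generation error rather than silently degrading).
* `gen_toy_structure()` lays planted contact paths on well-separated
  lines at 4 Å consecutive spacing with bounded coordinate jitter
  (≤ 0.3 Å per coordinate), so the expected contact set at 5 Å is exactly
  the consecutive pairs of each path; a multi-atom mode exercises the
  min-over-atom-pairs rule. Amino-acid sampling is uniform over the 20
  standard residues, excluding the reference residue at substitution
  sites.
* `gen_score_table()` plants one confusion matrix realized identically by
  all three predictors, drawing scores from class-conditional ranges
  strictly clear of every decision boundary (SVM/PolyPhen-2 in
  [0.01, 0.45] vs [0.55, 0.99]; $\Delta\Delta G$ in [-2, 0.85] vs
  [1.05, 6]). A single matrix is planted for all predictors because one
  table row carries one truth label: per-predictor confusions with
  different truth margins cannot coexist in one table.

These generators emulate the *structural* properties the pipeline
assumes — alignment-column geometry, contact geometry, threshold-straddling
score classes — and nothing else. They do not simulate serpin evolution,
realistic indel processes, correlated predictor errors, or realistic
score distributions near the thresholds. Passing the planted-recovery
tests therefore demonstrates that the filters, contact computation and
metrics implement their definitions exactly; it says nothing about how
often real homolog alignments satisfy the filters.

## Numerical and degenerate-input choices

* Inclusive comparisons at every cut point; FoldX rounding
  half-away-from-zero as above.
* Identity is undefined (error) for alignments with zero ungapped
  columns; columns gapped in both rows are invalid.
* Contact maps require at least two residues with at least one atom;
  the cutoff comparison is strictly `<`.
* Malformed variant strings (frameshift, splice, nucleotide notation)
  raise a classed parse condition; table readers skip such rows with a
  line-numbered warning in lenient mode and abort in strict mode.
* All randomness is seeded and generator outputs are byte-deterministic
  functions of (spec, seed); RNG state of the caller is restored.

## Problem sizes used by the test suite

The property-based checks run 100 random homolog specifications
(query lengths 250–320, identities straddling the 90% threshold, up to
four planted sites), 100 random toy structures (up to 20 residues, 1–3
atoms each) against a brute-force all-pairs contact oracle, and 1000
random labelings (n ≤ 50) against an independently coded confusion
counter. These sizes give full coverage of the planted-outcome space
while keeping the default suite fast.

## Limitations

* The packaged benchmark is small (57 variants, 5 of them benign human
  variants); the statistics computed from it have wide implicit
  uncertainty, and the package deliberately computes no confidence
  intervals or ROC curves because the workflow it implements defines
  none.
* Only missense substitutions are classified; stop gains parse but carry
  no scores, and nucleotide-level notation is out of scope.
* The contact filter depends on the chain choice and on author residue
  numbering matching query numbering (or a user-supplied mapping);
  mismatches surface as not-resolvable candidates rather than silent
  misassignments.
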