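---
title: "Predicting ubiquinone-binding proteins from sequence: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting ubiquinone-binding proteins from sequence: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ubppred)
```

## The problem

Ubiquinone (coenzyme Q) is the lipid-soluble electron carrier of the
respiratory chain; the proteins that dock it — ubiquinone-binding proteins
(UBPs), most of them membrane proteins of complexes I and II — are annotated
slowly and expensively by biochemistry. `ubppred` implements a
sequence-only classifier for UBPs together with the downstream analyses a
study of the predicted class typically runs: term over-representation
(GO/KEGG-style) and extraction of binding-site windows for motif discovery.

The method is a conventional but carefully specified stack:

1. **Encoding.** Each protein becomes an 820-dimensional vector: 20 amino
   acid composition (AAC) frequencies, 400 dipeptide composition (DC)
   frequencies, and a 400-dimensional *PSSM composition* built from a
   PSI-BLAST evolutionary profile.
2. **Feature selection.** A random forest ranks features by mean Gini
   decrease; zero-importance features are dropped; incremental feature
   selection (IFS) scans nested prefixes of the ranking and keeps the one
   maximizing cross-validated MCC.
3. **Classification.** A gradient-boosted tree ensemble (XGBoost) with
   eight exposed hyperparameters.
4. **Tuning.** Multi-objective particle swarm optimization (MOPSO) over the
   8-dimensional hyperparameter box, with a Pareto archive of non-dominated
   configurations; the final model is the archive member with the best MCC.
5. **Evaluation.** Sen, Spe, Pre, ACC, F1 and MCC from the confusion
   matrix, under stratified k-fold cross-validation plus an independent
   test set.

## The encoding

For a protein of length $L$ over the 20 standard residues:

* $f^{AAC}_i = n_i / L$ — the frequency of residue $i$; sums to 1.
* $f^{DC}_{ij} = n_{ij} / (L-1)$ — the frequency of the adjacent pair
  $ij$; sums to 1 for $L \ge 2$.
* $f^{PSSM}_{t,c} = \sum_{p\,:\,R_p = t} S_{p,c}$ — the profile score of
  column $c$ summed over the positions occupied by residue $t$, where
  $S$ is the $L \times 20$ position-specific scoring matrix.

The PSSM-composition definition deserves a note: a literal reading of the
summation with the indicator $\delta(R_i = AA_j)$ collapses to 20 numbers,
which cannot produce a 400-dimensional block. The only reading consistent
with the stated dimensionality is the standard residue-grouped column sum
above, and that is what `compute_pssm_composition()` implements.

Two further choices were genuinely open:

* **Which PSSM block.** PSI-BLAST ASCII files carry a log-odds block
  (columns 1–20) and a weighted-percentage block (21–40). The default is
  the log-odds block — the one consumed by most PSSM-based predictors —
  and `read_pssm(block = "percent_frequency")` switches; `source_kind`
  records the choice in every downstream artifact.
* **Normalization.** The composition is a bare sum by default (no division
  by $L$), making it length-sensitive; `normalize = "by_length"` or
  `"by_residue_count"` are available for users who want scale invariance.

Column order in PSSM files is taken verbatim from the file header
(PSI-BLAST order, `A R N D C Q E G H I L K M F P S T W Y V`) and addressed
only through the recorded `column_order`; feature names use alphabetical
order. A mismatch between a profile's row residues and the FASTA sequence
is an error, never a silent repair. Sequences shorter than 50 residues
(likely peptides) or containing non-standard letters are filtered out by
`apply_dataset_filters()` — exactly 50 is kept — and every rejection
carries a machine-readable reason.

## Feature selection

`rank_features()` uses a 500-tree random forest (the forest size is not
critical; 500 gives stable Gini estimates at the dataset sizes involved).
Ties are broken by original column index so rankings are reproducible.
`incremental_feature_selection()` scans prefixes $k = 1, 2, \ldots$ (step
configurable for very wide matrices), scoring each by cross-validated MCC
with default hyperparameters; on ties the smallest prefix wins
(parsimony). Note the IFS score is a selection criterion computed on the
training data — after selection it is optimistically biased, which is why
the pipeline reports final performance on a held-out independent test set.

## Tuning

The search box follows the eight documented thresholds: learning rate
$[0, 0.5]$, trees $[100, 2000]$, depth $[1, 10]$, subsample and
column-subsample fractions up to 1, $\gamma \in [0,1]$,
$\alpha \in [0,1]$, $\lambda \in [0,2]$. Two numerical choices:

* the sampling fractions get a lower bound of 0.05 (a zero fraction is
  undefined for the booster); this is a subset of the documented box;
* integer parameters are relaxed to continuous values during the swarm's
  movement and rounded at evaluation time only, which avoids degenerate
  swarms on the integer axes.

The swarm uses the standard constriction coefficients ($w = 0.729$,
$c_1 = c_2 = 1.494$); positions are clipped to the box with the velocity
zeroed on clipped components. The optimized objectives default to
(sensitivity, specificity) — the two complementary error types of a binary
confusion matrix — and the final configuration is selected from the Pareto
archive by MCC. The archive holds up to 100 non-dominated entries, pruned
by crowding distance so the extremes of the front survive. Production
defaults are a swarm of 80 for 200 iterations; the package's own tests use
desk-scale swarms (10–20 particles, 20–50 iterations), which the analytic
surrogate shows is already enough to localize an interior optimum to well
under 5% of the box diagonal.

Personal bests are replaced when dominated and by a fair coin on
incomparable outcomes; the social leader is chosen by a binary tournament
on crowding distance, biasing exploration toward sparse regions of the
front. These are standard MOPSO conventions; none is performance-critical
at the scales involved.

## Evaluation protocol

`compute_metrics()` implements the six confusion-matrix metrics with the
usual zero conventions for degenerate denominators (a ratio with a zero
denominator is 0; an MCC whose radicand has a zero factor is 0).
`kfold_cv()` uses stratified folds (the benchmark design is balanced;
stratification preserves that within folds) and a `repeats` argument:
`k = 5, repeats = 2` yields the "ten submodels" variant of 5-fold CV.
`independent_test()` refuses id overlap between training and test sets
unless explicitly told the resubstitution is deliberate.

Determinism: training, fold assignment and the swarm all flow from
explicit seeds, and the booster is pinned to one thread by default —
multi-threaded histogram construction is not bit-reproducible across
machines, and a pipeline whose rerun does not reproduce its metrics is
harder to debug than a slightly slower one. Raise `nthread` explicitly for
large matrices if bit-identical reruns are not needed.

## Enrichment and motif preparation

`hypergeom_tail(N, M, n, m)` is the upper-tail probability
$P(\text{overlap} \ge m)$ under sampling without replacement — computed
through the hypergeometric distribution function, which works in log space
and is stable for genome-scale $N$. The significance cutoff is a raw
$P < 0.05$ by default, with an optional Benjamini–Hochberg flag; the
background universe is an explicit user input (results are meaningless
without knowing what $N$ was). Terms are flat sets; no ontology graph
structure is used.

`extract_windows()` slices the 21-residue fragment centered on each
annotated binding site (10 residues each side). Sites within 10 residues
of a terminus yield clipped fragments flagged `full_width = FALSE` rather
than being padded or dropped — the caller decides, and
`write_meme_input()` excludes fragments below a minimum width (default 8)
when writing the motif-discovery FASTA.

## The synthetic generator

Because real benchmarks require Swiss-Prot snapshots, CD-HIT clustering
and PSI-BLAST profiles, the test surface runs on synthetic data with
*planted* signal in composition space — precisely the space the features
measure, so recovery tests are direct. `synthetic_config()` fixes the
study conditions: balanced classes of 100, lengths uniform on 50–150,
and a mixture signal of strength `effect_size` (default 0.8, a strong but
not degenerate signal: under `aac_bias` on residue A the positive-class
A-frequency is about $0.8 + 0.2/20 \approx 0.81$). Profiles are integer
log-odds-like matrices with a +4 shift on the observed residue; under
`pssm_bias` the planted shift lives only in the profile columns, invisible
to AAC/DC. The ASCII serialization follows the modern BLAST+ layout so the
parser is exercised on realistic input.

What the generator does **not** emulate: real Swiss-Prot score
distributions, sequence homology and redundancy, class imbalance, or
motif-level (positional) signal. Passing the planted-signal tests
demonstrates that the pipeline recovers a compositional class difference
end-to-end; it says nothing about absolute performance on real UBP data,
which depends on the evolutionary profiles and the benchmark construction.

## Scale of the shipped checks

The test suite and the acceptance script run the pipeline at desk scale,
chosen once as the smallest sizes at which the planted effects are
unambiguous: planted project $n = 200$ at effect 0.8 (independent test of
30), IFS capped at the top 25 ranked features with 3-fold evaluators, and
tuning with a swarm of 10 for 20 iterations. The null control uses
$n = 400$ with half held out: a 30-sample test set has a null-MCC
standard deviation of about 0.18, far too coarse to verify "MCC near 0",
while 200 held-out samples bring it to about 0.07. The end-to-end null
check therefore tests the pipeline's honesty (no leakage through
selection or tuning) with usable statistical power.

## Known limitations

* PSSMs must be produced externally (`psiblast -num_iterations 3 -evalue
  0.01 -out_ascii_pssm ...`); the package parses but never runs PSI-BLAST.
* The IFS trace's CV-MCC values are selection scores, not unbiased
  performance estimates.
* No probability calibration and no ROC analysis; calls use a fixed 0.5
  threshold.
* Enrichment treats terms as flat sets and, by default, applies no
  multiple-testing correction — matching the raw-cutoff convention, but
  users screening thousands of terms should pass `bh = TRUE`.
* Motif discovery itself (MEME) is external; the package only prepares its
  input.
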