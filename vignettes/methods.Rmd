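---
title: "Predicting ion channels from sequence: model, selection protocol and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting ion channels from sequence: model, selection protocol and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionpred)
```

## The problem and the model

Ion channels are membrane proteins that conduct ions across the lipid
bilayer. Identifying them from sequence alone is hard because channels with
the same function can share little sequence identity, so plain similarity
search misses a substantial fraction. `ionpred` implements a hierarchical
predictor with three stages: channel vs. non-channel (ION), voltage- vs.
ligand-gated (VLG), and the four voltage-gated subtypes potassium, calcium,
sodium and anion (VGS).

Each stage is a hybrid of two routes:

1. **An RBF-kernel SVM** over an 878-dimensional representation of the
   sequence and its predicted structural annotations. Probabilities come
   from Platt sigmoid calibration (binary) or pairwise coupling over the
   one-against-one decomposition (the 4-class stage uses
   $k(k-1)/2 = 6$ pairwise machines); the reported class is the
   probability argmax.
2. **Annotation transfer from the best BLAST hit** against the labelled
   training set. A hit qualifies when its e-value is at most a
   stage-specific threshold $t$ tuned by cross-validation over the grid
   $10^{-6}, \dots, 10^{1}$; the transferred label carries the normalized
   score $t/(t + e)$, which is 1 for an exact match and 0.5 at the
   threshold.

Whenever a qualifying hit exists the BLAST label wins; otherwise the SVM
decides. This ordering reflects the empirical situation the method targets:
close homologs are best annotated by transfer, while the SVM covers the
twilight zone where BLAST abstains.

Two chaining modes are provided. `flat` (the default) runs all three stages
unconditionally, matching how each stage is evaluated on stage-specific
data; `cascade` gates the type stage on a positive channel prediction and
the subtype stage on a voltage-gated prediction, which is what a user
screening unknown sequences wants.

## The 878-feature representation

The blocks, in frozen order (names from `feature_names()`):

| block | size | content |
|---|---|---|
| `AA_*` | 20 | amino acid composition |
| `Dipeptide_*` | 400 | ordered adjacent-pair composition, divided by $L-1$ |
| `AAproperty_i_{avg,sd}` | 12 | mean and population SD of six physicochemical scales |
| SS segments | 13 | segment counts, min/max run length over $L$, state compositions |
| disorder segments | 9 | the same descriptors over disordered/structured runs |
| RSA | 24 | buried/exposed fractions at cutoffs 0.25 and 0.75; min/max window-average RSA for windows of 4–22 residues |
| `PSSM_A1_A2` | 400 | per residue-type column sums of the PSSM, divided by $L$ and squashed by $1/(1+e^{-x})$ |

Inputs are consumed, not computed: PSSMs in the PSI-BLAST ASCII dialect
(only the first, log-odds block is read), secondary structure as ss2 state
strings, disorder as per-residue probabilities (flagged at $\ge 0.5$) or
mark characters, RSA as relative values clamped to $[0,1]$ (or absolute
areas divided by a maximum-ASA reference table).

Numerical conventions worth knowing:

* **"Segments at least $W$ long"** is implemented as extrema of
  window-averages over windows of *exactly* $W$ residues. Any longer
  window's average is bracketed by the averages of its length-$W$
  sub-windows, so the exact-$W$ extrema bound the at-least-$W$ extrema,
  and the computation is $O(L)$ per window length.
* An absent secondary-structure state or disorder class contributes zeros
  to its count and length features rather than NAs, keeping vectors finite
  and comparable.
* The property-statistics SD uses the population convention (divide by
  $L$), which is stable for short chains; the six default scales
  (Hopp–Woods hydrophilicity, Kyte–Doolittle hydrophobicity, Grantham
  polarity, Bhaskaran–Ponnuswamy flexibility, Chou–Fasman beta-turn
  propensity, Janin transfer free energy) are a configurable table, since
  any published variant of these scales is a defensible choice.
* A residue type absent from the sequence leaves its 20 PSSM features at
  the logistic midpoint 0.5, the image of a zero sum.
* Min-max normalization maps each feature into $[-1,1]$ via
  $(2x - x_{\min} - x_{\max})/(x_{\max} - x_{\min})$, with parameters
  fitted on training data only, constant features mapped to 0, and test
  values clamped into the interval so kernel inputs stay bounded.

## Feature selection and model optimization

`run_selection_grid()` sweeps a five-step protocol:

1. stratified 5-fold split, fixed by `fold_seed`;
2. features ranked by $|r_{pb}|$ — the point-biserial correlation with the
   labels — averaged over the five training folds, and cut at each BCC
   cutoff in $\{0.1, 0.15, 0.2, 0.25, 0.3\}$ (absolute values are used
   because sign encodes direction, not strength; the four-class stage
   reduces one-vs-rest, keeping each feature's maximum over classes);
3. greedy redundancy removal in rank order at each Pearson cutoff in
   $\{0.7, \dots, 0.9\}$, giving the $5 \times 5$ grid of candidate sets;
4. wrapper backward elimination: sweeps run weakest-first and repeat until
   a full pass removes nothing, a removal being accepted only when the
   pooled cross-validated MCC *strictly* increases. The SVM parameters are
   held fixed during elimination at the cell's pre-elimination grid-search
   winner, then re-searched afterwards — the steps are otherwise mutually
   recursive and this ordering bounds cost deterministically;
5. RBF-SVM grid search over $C = 2^{-2}, \dots, 2^{4}$ and
   $\gamma = 2^{-11}, \dots, 2^{0}$, argmax by pooled CV MCC with ties to
   the smaller $C$ then $\gamma$.

A PCA branch replaces steps 2–4: the fewest leading components reaching
each cumulative-variance cutoff in $\{0.1, \dots, 0.9\}$, pruned by the
same one-at-a-time rule. The winning configuration across all cells takes
the highest MCC, then fewer features, then smaller $C$, then smaller
$\gamma$.

Inner selection loops score hard SVM labels (no probability model), which
is several-fold faster and leaves the selected sets unchanged in practice;
deployed models always carry the calibrated probability model. The
four-class MCC used wherever a single number is needed is the mean of the
per-class one-vs-rest coefficients.

**A caution on the wrapper's own score.** Because the wrapper greedily
maximizes the pooled CV MCC of one particular fold split, its final score
is optimistically biased — under label permutation with ~100 surviving
noise features it can report MCC well above 0.7, and even re-evaluating
the selected features on a fresh fold split is insufficient (the selected
subset memorizes the sample itself, not the split: measured MCC ~0.55 on
permuted labels at n = 200). The package therefore treats the wrapper's
number as an internal selection criterion only. Honest generalization
estimates require either genuinely held-out data or nested
cross-validation — selection re-run inside each outer training fold,
scored on the untouched outer fold — which is how the test suite
implements its permutation null.

## Evaluation machinery

`confusion_counts()`, `accuracy()`, `mcc()`, `f_measure()`, `q4()` and
`sensitivity_fpr()` implement the standard definitions; the Matthews
coefficient uses the usual square-root denominator with the convention
that a zero factor yields 0, keeping grid searches total. Q4 is the trace
fraction of the $4\times4$ confusion matrix and reduces to accuracy for
two classes. `subsample_ci()` reports mean ± SD of the metrics over ten
seeded 50% subsamples drawn without replacement, redrawing any subsample
that misses a class. `jackknife()` is leave-one-out with a freshly fitted
normalizer per held-out protein. Cross-validation always refits the
normalizer on each fold's training portion — normalizing once globally
would leak test information into the scaling, so per-fold refitting is
enforced even though it is the stricter reading of the protocol.

During BLAST threshold tuning, the searchable database is restricted to
the query's training-fold portion, self-hits are excluded, "better than
the threshold" is inclusive ($e \le t$), and queries with no qualifying
hit are counted as errors — penalizing abstention favours thresholds that
actually cover the data. Ties in e-value break to the larger bit score,
then the lexicographically smaller subject id, so results are
order-independent.

## The synthetic data generator

`simulate_dataset()` emulates the study conditions desk-side: balanced
classes, sequence lengths 60–120 by default (minimum 25 so every RSA
window exists), and class signal planted in a configurable subset of the
feature blocks. Composition signal tilts the sampling weights of five
class-specific residues by $e^{0.5s}$; dipeptide signal adds a
within-block Markov preference; secondary structure and disorder are
run-length processes with class-tilted state frequencies; RSA is clipped
AR(1) noise with a class-dependent mean; PSSMs are small-integer noise in
$[-8, 12]$ — the realistic log-odds range, which also keeps the logistic
transform in its responsive region — with a class bias on four columns.
The default plants signal in the composition and PSSM blocks, the profile
block being the strongest input in this problem domain. Physicochemical
properties inherit signal through composition, as in real sequences. One
master seed drives per-protein substreams keyed by (seed, class, index),
so a protein's data is invariant to the dataset size.

Hit tables assign same-class pairs log-uniform e-values in
$[10^{-30}, 10^{-8}]$, cross-class pairs $[10^{1}, 10^{4}]$, and every
query a self-hit at $e = 0$ that `best_hit()` must exclude; per-query
coverage below 1 creates the abstention regime in which the hybrid's
advantage over pure transfer is visible.

What passing tests on this generator do **not** show: real channels do not
separate by composition tilts of disjoint residue blocks, real PSSMs have
position-structured, phylogeny-driven correlations, and real BLAST
e-values depend on length and database size. The generator validates the
machinery — parsers, representation, selection, tuning, combination —
not biological accuracy; published-scale accuracies require the original
curated datasets and the external prediction tools whose outputs this
package consumes.

## Problem sizes used by the test suite

Unit tests run on datasets of 5–15 proteins per class. The pipeline
recovery test uses 100 proteins per class with signal strength 1.5 and a
reduced sweep (one BCC 0.3 / Pearson 0.7 cell, a $3\times3$ SVM grid, a
wrapper sweep cap of 2, no PCA branch) — sizes chosen so the whole
protocol is exercised end-to-end at desk scale. The permutation null runs
nested (selection inside each outer fold) with BCC cutoff 0.1, since
noise rarely clears the higher cutoffs. Oracle equivalence runs on 100
random proteins per feature block and 1000 random confusion tables.

## Known limitations

* The wrapper's internal MCC is optimistically biased (see above); report
  fresh-split estimates.
* `remove_redundant()` computes correlations against the full training
  matrix, not per fold, mirroring the single ranked list the protocol
  produces; a fully nested variant would re-rank within each fold at
  roughly five times the cost.
* The VGS stage is trained unweighted even though real subtype data is
  imbalanced (81/29/12/26); no class weighting is applied anywhere.
* External predictors (PSI-BLAST, secondary structure, disorder, RSA
  tools) are consumed as files, never invoked; a thin wrapper around a
  local `blastp` is deliberately out of scope so the test suite has no
  binary dependencies.
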