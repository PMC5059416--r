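---
title: "Statistical methods behind pickedfdr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind pickedfdr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pickedfdr)
```

## The problem

A shotgun proteomics search engine assigns a candidate peptide to each
fragmentation spectrum, producing peptide-spectrum matches (PSMs) with a
heuristic score. Two statistical problems follow. First, the raw score is a
weak discriminator: many auxiliary features (mass error, charge, enzymatic
termini, ...) carry information the score ignores, and a classifier trained
to combine them yields far more confident identifications. Second, users
ultimately want statements about *proteins*, and protein-level error rates
are notoriously easy to get wrong when peptides are shared between protein
entries. `pickedfdr` implements both pieces: semi-supervised rescoring of
PSMs, and protein inference with picked target-decoy false discovery rate
(FDR) control, together with a sample/entrapment benchmark that audits
whether the reported error rates can be trusted.

## Target-decoy confidence estimates

All confidence estimation rests on the target-decoy principle: spectra are
searched both against the real (target) database and against a reversed
(decoy) database, and decoy matches model the score distribution of
incorrect matches. For entities (PSMs, peptides or protein groups) ranked
by a score $s$, the FDR at threshold $t$ is estimated as

$$\widehat{\mathrm{FDR}}(t) = \frac{1 + \#\{\text{decoys} \ge t\}}
  {\#\{\text{targets} \ge t\}},$$

and the q-value of an entity is the minimum estimated FDR over all
thresholds at or below its score, capped at 1 (`td_qvalues()`). Design
choices worth stating:

* the **+1 pseudo-count** in the numerator is the standard conservative
  convention; it also keeps empirical p-values strictly positive. No
  $\pi_0$ correction is applied ($\pi_0 = 1$), again conservative.
* **ties** in score are accepted or rejected together (threshold semantics
  use $\ge$), removing any dependence on sort order.

Posterior error probabilities (`estimate_peps()`) use a deliberately simple
estimator: entities are sorted into equal-count score bins, the raw PEP of
a bin is $\min(1, \#\text{decoys}/\#\text{targets})$ within it, and
monotone non-increase in score is enforced by pool-adjacent-violators
regression (`stats::isoreg`). The default bin count is
$\max(20, n/500)$; below 20 targets or 20 decoys a single global bin is
used. This replaces the spline-based density-ratio machinery of the
established tool chain with an estimator that is monotone by construction
and directly testable; its PEPs are consistent with the q-values in the
sense that the average PEP of entities below a cutoff bounds the error
fraction (a property the test suite checks). The cost is resolution: PEPs
are piecewise constant over bins, so very sharp score transitions are
smoothed.

Empirical p-values (`empirical_pvalues()`) are
$(1 + \#\{\text{decoys} \ge s\})/(1 + \#\text{decoys})$, and Fisher's
combination (`fisher_combine()`) refers $-2\sum_i \log p_i$ to a
$\chi^2_{2k}$ survival function. The paper trail for the protein-level
benchmark does not define how peptide p-values should be constructed;
empirical decoy p-values are this package's declared substitute.

## Semi-supervised rescoring

`rescore()` implements the iterative semi-supervised scheme with
three-fold cross-validation. Spectra (not PSMs) are assigned to folds so a
target/decoy pair is never split. Per fold:

1. an initial scoring direction is chosen by evaluating every feature with
   both signs and keeping the one with most targets at
   $q \le q_{\text{train}}$ (default 0.01); ties break to the lowest
   feature index, positive sign;
2. for a fixed number of iterations (default 10) the training partition is
   scored, targets at $q \le q_{\text{train}}$ become positives, all
   decoys negatives, and a linear SVM is refit. An iteration with zero
   positives keeps the previous direction rather than aborting.

The SVM is an L2-regularized squared-hinge primal solved by Newton
iteration with Armijo backtracking — with tens of features and up to
hundreds of thousands of rows, each step costs $O(nd)$ plus a trivial
$d \times d$ solve. Class-specific misclassification costs default to
$C_{\text{pos}} = 10$, $C_{\text{neg}} = 30$; the production tool's nested
cross-validation grid search over these costs is intentionally out of
scope, and the costs are exposed in `train_config()`. Features are
standardized globally before training.

In cross-validation mode each PSM's final score comes from the classifier
whose *test* fold contained it. In **subset training** mode
(`subset_size`), whole spectra are sampled until the requested PSM count is
reached, the same three-fold procedure runs on the subset, and every PSM is
scored by the *average* of the three classifiers — accepting the
train/test overlap this implies for the subset members, which is harmless
precisely in the large-data regime where subsetting is useful. Scores from
different classifiers are made commensurable by standardizing each with its
training partition's decoy mean and standard deviation; the source
procedure is silent on score merging, so decoy standardization is this
package's choice (decoys are the one population guaranteed to be
error-distributed, making their location/scale a natural anchor).

## Protein grouping and inference

Protein-level FDR control fails when shared peptides are retained: a
single confidently identified shared peptide "identifies" every protein
containing it, and reversed decoys offer no counterpart for this
amplification, so decoy-based estimates become anti-conservative. The
package's default pipeline therefore:

1. digests every protein *in silico* (trypsin, cleavage after K/R
   suppressed before proline, no missed cleavages, peptide length 7–50 by
   default) and groups proteins by these **theoretical** peptide sets —
   identical sets merge, and a set that is a strict subset of exactly one
   maximal set merges into it. A set nested inside two or more non-nested
   maximal sets is left as its own group: deterministic and conservative,
   at the cost of leaving some truncated forms ungrouped. Grouping is done
   before observing any data, so no peptide-level threshold enters;
2. keeps only peptides unique to one protein group
   (`assign_unique_peptides()`);
3. scores each group from its peptide evidence by one of four methods
   (`score_protein_groups()`): best peptide score, the two-peptide rule
   (best score, but groups without two distinct peptides at
   $q \le 0.01$ removed), the product of peptide PEPs (unscaled by protein
   length), or Fisher's combination of peptide p-values. The two-peptide
   rule's ranking statistic is not defined by its common usage; ranking by
   best peptide keeps it comparable to the best-peptide method;
4. runs the **picked** competition (`picked_competition()`): each target
   group competes against the decoy group whose members are exactly the
   reversed counterparts, only the better-scoring of the pair survives,
   and exact ties remove both (keeping either side would bias the null).
   Unpaired groups survive — the conservative fallback when reversal
   changes the grouping topology;
5. estimates protein-level q-values over the survivors.

The observed-peptide grouping mode (`grouping = "observed"`) reproduces
the poorly calibrated alternative for benchmarking: proteins grouped by
their sets of inferred peptides at a peptide-level threshold, shared
peptides retained.

Peptides are matched to theoretical digests as exact strings after
stripping flanking residues and bracketed modification annotations;
peptides absent from the theoretical map are treated as shared and
discarded. Isoleucine/leucine are *not* collapsed.

## The sample/entrapment benchmark

`build_entrapment_db()` constructs, for each of `multiplier` (default 9)
copies of every sample protein, a shuffled twin: each tryptic fragment's
residues are permuted, except that all K, R and P positions are held
fixed. Holding K/R/P fixed is a deliberate strengthening of "shuffle the
peptides": it guarantees that entrapment proteins re-digest on exactly the
source boundaries, so the entrapment database reproduces the sample's
digestion statistics fragment for fragment (the test suite asserts equal
length multisets). A shuffle that reproduces its source or collides with
any sample peptide is redrawn up to ten times, then accepted and counted
in `n_flagged` (for random proteomes this is essentially never hit). A
globally selected set of $\lfloor 4\% \rfloor$ of the distinct sample
peptides is kept verbatim in every copy, creating controlled shared
peptides between sample and entrapment; selecting the set globally (rather
than per copy) makes "4% of the sample peptides are shared" a property of
the peptide set itself. Within a copy, shuffles are drawn independently of
other copies.

Matches to the sample database are treated as true, matches to the
entrapment database as false; the resulting **entrapment FDR** is an
external audit of the decoy-based q-values (`calibration_curve()` pairs
the two, and reports the maximal multiplicative deviation from the
identity over a stated interval). With a ninefold entrapment partition,
incorrect matches split 9:1 between entrapment and sample, so the
entrapment FDR undercounts false positives by $1/9 \approx 11\%$ at the
PSM level (`entrapment_undercount()`) — protein-level undercounting is
smaller because truly present proteins absorb sample-hitting incorrect
matches.

## What the synthetic generator emulates — and what it does not

`simulate_proteome()` draws random sequences with K/R frequency 0.1, so
mean tryptic fragment length is $\approx 1/(0.1 \times 0.95) \approx 10.5$
residues. `simulate_psms()` emits one target and one decoy PSM per
spectrum, mirroring separate target/decoy searches; PSM-level target-decoy
competition (`compete_psms(mode = "tdc")`) then keeps the best per
spectrum. Key defaults, chosen once as the package's model of a
well-behaved large-scale experiment:

* `prop_correct = 0.35`: fraction of spectra generated by a present
  peptide;
* `present_fraction = 0.7` of the sample proteins are present, roughly a
  mid-log culture against its organism database;
* present-protein abundances follow a Zipf law with exponent 1
  (`abundance_shape`), the canonical long-tailed abundance profile, so a
  realistic margin of sparsely covered proteins exists;
* correct-PSM features are shifted by `effect_size = c(4, 1.5, 1, 0.5, 0)`
  standard deviations with exchangeable feature correlation 0.2. The
  4-sigma primary feature models a search score that separates correct
  matches well; with much weaker separation, decoys that beat a correct
  target in the per-spectrum competition — a real but normally rare
  phenomenon — become a noticeable selected-high subpopulation of the
  decoy tail.

Decoy features and incorrect-target features are drawn from the same code
path, so the calibration assumption (exchangeability under the null) holds
by construction. That is the point: it isolates *method* error from
*generator* error. It is also the generator's main limitation — real data
contain incorrect matches that are correlated with true proteins
(chimeric spectra, modified peptides, homologs), which is exactly the
mechanism that makes aggregating methods (product of PEPs, Fisher) fall
behind the best-peptide method on very large real data sets. On this
generator those methods tie with best-peptide to within sampling noise at
the ~200K-PSM scale, so passing method-comparison tests here demonstrates
correct implementation of the scorers, not the real-data superiority of
one over another. Fragment spectra, retention times and quantification are
not modeled at all.

## Numerical and degenerate-input choices

* Degenerate digests (no peptide in the length window) produce flagged
  singleton groups; they can never be identified.
* Proteins containing non-standard residues (B, Z, U, X) are digested
  literally.
* Scores must be finite; q-values are capped at 1; PEPs clamped to
  $[0, 1]$.
* A decoy's reported q-value is the one at its own score threshold
  (reporting convenience only; decoys never count as discoveries).
* The SVM Newton solver stops on relative gradient or objective change
  below $10^{-8}$, with a fallback scaled-gradient step if the Hessian
  solve fails; the per-fold decoy standard deviation is floored at
  $10^{-12}$ to keep normalization defined on degenerate folds.
* All randomness flows through explicit integer seeds
  (`withr::with_seed`), so every pipeline is reproducible bit for bit
  given (data, seed); sampling never touches the global RNG state.

## Problem sizes used by the test suite

The packaged tests exercise the full pipelines at desk scale: calibration
runs use 1,000 sample proteins with a ninefold entrapment database and
50,000 spectra across five seeds; subset-training stability uses 200,000
PSMs with 20,000-PSM training subsets across ten seeds; the
method-comparison runs use 2,000 proteins and 200,000 PSMs. Property
tests check digestion against a brute-force cut-site oracle on sequences
up to 30 residues and q-values against an exhaustive-threshold oracle on a
thousand random instances of up to 200 entities.

## Known limitations

* The PEP estimator trades resolution for monotonicity and simplicity; it
  is not the nonparametric logistic estimator of the established tool
  chain.
* Group-level decoy pairing requires the decoy grouping to mirror the
  target grouping exactly; where reversal changes the topology, pairs
  survive unpaired (conservative).
* The two-peptide rule's ranking statistic and the Fisher benchmark's
  choice of peptide universe (observed peptides only) are this package's
  stated choices where common usage is underdetermined.
* The entrapment construction models shared peptides as uniformly placed;
  it does not attempt homology-aware placement, and it only emulates fully
  tryptic peptides without missed cleavages.
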