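---
title: "Classifying anticancer and antimicrobial peptides with gapped n-grams and stacked random forests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying anticancer and antimicrobial peptides with gapped n-grams and stacked random forests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepstack)
```

## The problem

Anticancer peptides (ACPs) are a subset of antimicrobial peptides (AMPs):
short (typically 5–50 residues), cationic, hydrophobic molecules that
permeabilize negatively charged membranes. ACPs additionally target the
plasma and mitochondrial membranes of cancer cells. Because the two groups
are compositionally similar — both are rich in lysine and hydrophobic
residues, with ACPs shifted further toward lysine, leucine, alanine and
phenylalanine and AMPs toward glycine and cysteine — binary ACP-vs-other
screens confuse them. `pepstack` therefore models the problem as a single
three-class decision: ACP, AMP, or background (non-ACP/non-AMP, labeled
`NEG`).

## The model

### Features: binarized gapped n-grams of 5-mers

Each peptide is decomposed into overlapping windows of 5 residues
(*5-mers*, stride 1; a peptide of length $L$ yields $L - 4$ mers). Five is
the shortest peptide the model accepts, so every valid input produces at
least one window.

From each 5-mer we consider every *n*-gram with $n \in \{1,2,3\}$:

* unigrams (20);
* bigrams with a fixed gap of 0–3 positions between the two residues
  ($4 \times 20^2 = 1600$), written `KL`, `K_L`, `K__L`, `K___L`;
* trigrams with a gap of 0 or 1 between first/second and second/third
  residue ($4 \times 20^3 = 32000$), written e.g. `K_A_L`.

A gap position matches any residue. The full vocabulary holds
$20 + 4\cdot20^2 + 4\cdot20^3 = 33{,}620$ descriptors in a fixed canonical
order (by gap pattern, then lexicographically). Occurrence is *binarized*:
the feature is 1 if the n-gram occurs anywhere in the 5-mer at least once,
0 otherwise; multiplicity and position within the window are discarded.
Position independence is a deliberate choice: with binary
presence/absence semantics a positional variant would multiply the feature
space fivefold without adding much signal at window size 5.

### Feature selection: an exact permutation test

For a binary feature $x$ and a binary class contrast $y$ with margins
$n_f = \sum x$ and $n_t = \sum y$ fixed, permuting the labels makes the
co-occurrence count $n_{11}$ hypergeometric. The exact permutation
p-value of any table statistic can therefore be computed in closed form as
the hypergeometric mass of all achievable counts whose statistic reaches
the observed one — the Quick Permutation Test (QuiPT). We rank tables by
information gain (mutual information in nats), accumulate the tail with a
relative tie tolerance of $10^{-12}$ so that symmetric tables ($c$ and its
mirror image) are both counted, and run the test for every descriptor on
each of the three pairwise contrasts (ACP/AMP, ACP/NEG, AMP/NEG),
restricting rows to the two classes involved. A descriptor is *informative*
if $p < 10^{-4}$ in at least one contrast (union rule). The criterion
statistic is pluggable and the union/intersection rule switchable; no
multiple-testing correction is applied beyond the fixed threshold.

Mathematically, dropping the all-zero columns of the 33,620-column universe
before testing cannot change the selection (a constant feature has zero
information gain and p-value 1), so the implementation only materializes
observed columns.

### The stacked forests

Layer 1 is a probability random forest (`ranger`) on the binarized
selected-descriptor matrix of the training 5-mers, each mer inheriting its
peptide's label; 2000 trees by default, `mtry` $= \lfloor\sqrt p\rfloor$.
Layer 2 classifies whole peptides from 22 summary statistics of the
ordered sequence of the peptide's mer probabilities: for each class, the
mean, median, min, max, variance, the fraction of mers with probability
above 0.5, and the longest consecutive run above 0.5 divided by the mer
count; plus the mer count itself (500 trees by default). The fraction
statistic captures how much of the peptide looks like a class; the run
statistic captures whether that evidence is contiguous, as a membrane-
active motif would be; the mer count lets the forest condition on length.

**Leakage control.** The layer-2 training features are built from the
layer-1 *out-of-bag* probabilities: each training mer is scored only by
trees whose bootstrap excluded it. In-sample probabilities of a large
forest are nearly degenerate (close to the one-hot label), which would both
starve layer 2 of information and leak the training labels into its
features. The null-safety test (below) verifies empirically that the stack
cannot manufacture skill on data with no signal.

**Decisions.** The predicted class is the probability argmax, with exact
ties broken toward NEG, then AMP, then ACP — the conservative ordering for
a screen whose worst failure mode is a false ACP call. For binary
benchmarking the three-class output is collapsed: ACP score =
$p_{\mathrm{ACP}}$, rest score = $p_{\mathrm{AMP}} + p_{\mathrm{NEG}}$,
with decision ACP iff $p_{\mathrm{ACP}} > 0.5$ (strictly, so the boundary
is deterministic).

### Cross-validation

Fivefold cross-validation stratifies by class and sequence length: within
each class, peptides are sorted by length (ties shuffled under the seed)
and dealt to folds in serpentine order (1…5, 5…1, …), which keeps both the
fold sizes (±1) and the fold length distributions balanced; plain
round-robin dealing in sorted order would systematically give the first
fold the shorter member of every length block. Both layers are evaluated
per fold: the mer layer on held-out mers, the peptide layer on held-out
peptides. The report gives per-fold values and mean, sd and se across
folds (sd and se both, since summaries of fold spread are reported
inconsistently across the literature).

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `k` | 5 | mer window length; also the minimum peptide length |
| bigram gaps | 0–3 | span of a bigram never exceeds `k` |
| trigram gaps | {0,1} × {0,1} | single optional gap at either junction |
| `alpha` | 1e-4 | QuiPT selection threshold per contrast |
| `trees_layer1` | 2000 | mer-level forest size |
| `trees_layer2` | 500 | peptide-level forest size |
| `mtry` | floor(sqrt(p)) | features per split, both layers |
| decision threshold (binary mode) | 0.5, strict | ACP-vs-rest collapse |

Net charge defaults to the counting rule $\#K + \#R - \#D - \#E$
(histidine excluded: mostly neutral at pH 7); an opt-in Henderson–
Hasselbalch mode with a configurable pKa table computes pH-dependent
partial charges including termini. Hydropathy is the mean Kyte–Doolittle
index. Both rules are declared package choices — simple, deterministic and
documented — rather than reconstructions of any particular reference
implementation.

## The synthetic generator

`generate_peptides()` draws lengths uniformly from a configured range
(default 5–50) and residues iid from per-class frequency profiles lying on
the 20-simplex. The default profiles multiply a uniform background by
boost factors (ACP-like: K×4, L×3, A×3, F×2; AMP-like: G×3.5, C×3, K×2;
negative = background) and renormalize, mirroring the qualitative
enrichment pattern that separates the real classes. A `separation`
scalar interpolates every class profile toward the background: at 0 the
three classes are identically distributed by construction, which is the
null condition used to probe for stacking leakage. Optional motifs (e.g.
`KLAK` for the ACP class) can be implanted at a random admissible offset
with a configured probability; the default probability is 0 so that the
null condition needs no special casing.

What the generator does *not* emulate: residue autocorrelation,
amphipathic helical periodicity, homology clusters, database biases, and
realistic class imbalance. Passing the synthetic-recovery tests therefore
demonstrates that the pipeline's machinery works and does not leak — not
that the trained synthetic model transfers to real peptides.

## Reference problem sizes

The recovery experiments train on 300 peptides/class (lengths 5–50,
roughly 21,000 training mers) and evaluate on an independently generated
150/class held-out set; at this size the package uses 200 trees in layer 1
(and the default 500 in layer 2). Forest performance saturates well below
the 2000-tree default at this feature count, and the smaller forest keeps
the full experiment in the minutes range on a single core. Under these
conditions the separated-profile run reaches held-out peptide-layer AU1U
≈ 0.93 and kappa ≈ 0.74 against a mer-layer AU1U ≈ 0.75 — reproducing the
expected ordering (aggregation across a peptide's mers beats single-mer
calls), and the null run sits at AU1U ≈ 0.5, kappa ≈ 0.

## Numerical and degenerate-input choices

* Exact p-value tie pooling uses a relative tolerance of $10^{-12}$ on the
  information gain, so floating-point noise cannot split the two tails of
  a symmetric table.
* A constant feature or target yields statistic 0 and p-value 1 rather
  than an error; an all-zero descriptor column can never be selected.
* AUC ties get 1/2 credit (Mann–Whitney convention), which matters for
  discrete forest probabilities.
* Cohen's kappa with degenerate marginals ($p_e = 1$) is defined as 1 for
  perfect agreement and 0 otherwise; MCC with a zero denominator factor is
  0; precision without predicted positives is reported missing.
* The variance statistic of a single-mer peptide is 0, and its run/fraction
  statistics coincide.
* Mer probabilities for rows never out-of-bag (possible only with very
  small forests) fall back to the mean OOB profile, keeping the statistics
  simplex-valued.
* One master seed is expanded into independent per-stage streams (fold
  shuffling, each forest), so changing one stage's consumption cannot
  silently shift another's.

## Known limitations

* Overlapping mers from one peptide share residues and labels, so the
  selection-stage tests are computed on dependent rows; on pure-noise data
  more descriptors pass the threshold than the nominal rate for
  independent rows would suggest (the test itself is exact and verified
  super-uniform under iid permutation). This is inherent to testing at the
  mer level; the null-safety experiment shows it does not translate into
  held-out skill.
* The model neither deduplicates homologous training sequences nor
  performs identity clustering; curating non-redundant inputs is the
  user's responsibility.
* Peptides longer than 50 residues are accepted with a warning flag, but
  the intended domain is 5–50 residues; the model is not meant for
  proteins.

## Reproducing a published-style benchmark (optional, external data)

The package supports the full external evaluation protocol for users with
access to curated ACP/AMP/negative FASTA sets (e.g. the AntiCP 2.0
training and validation splits): train with
`pepstack train --acp train_acp.fasta --amp train_amp.fasta --neg
train_neg.fasta --out model.rds`, predict the validation split, and
compute accuracy, AU1U and kappa with `multiclass_metrics()` (or MCC,
precision, sensitivity, specificity and AUC on the binarized output with
`binarize_predictions()` + `binary_metrics()`). These runs depend on
downloaded data and a freshly trained forest, so their values are not part
of the package's test suite.
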