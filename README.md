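# pepstack

Three-class peptide classification — anticancer peptide (ACP) vs
antimicrobial peptide (AMP) vs background (non-ACP/non-AMP) — from
sequence alone.

ACPs are the subset of antimicrobial peptides that also kill cancer
cells, and the two groups are compositionally so similar (short, cationic,
hydrophobic) that binary screens routinely confuse them. `pepstack`
treats the problem as a single three-way decision and provides the full
workflow: sequence I/O and validation, physicochemical profiling,
feature extraction, feature selection, model training, prediction,
cross-validation and evaluation — plus a synthetic data generator so the
entire pipeline is testable offline.

## The method

1. **5-mer decomposition.** Every peptide (length ≥ 5) is cut into
   overlapping windows of 5 residues; a peptide of length *L* yields
   *L* − 4 mers, each inheriting the peptide's class during training.
2. **Binarized gapped n-grams.** Each 5-mer is encoded by the
   presence/absence of every n-gram with n = 1–3: unigrams, bigrams with a
   gap of 0–3 positions (`K_L`, `K__L`, …), and trigrams with a 0/1 gap at
   either junction (`K_A_L`). The vocabulary holds
   20 + 4·20² + 4·20³ = 33,620 descriptors; a gap matches any residue and
   multiplicity is discarded.
3. **Exact permutation-test selection (QuiPT).** For each descriptor and
   each pairwise class contrast, the information gain of the 2×2 table is
   tested exactly: conditioning on the margins makes the co-occurrence
   count hypergeometric, so the permutation p-value is a closed-form tail
   sum. Descriptors with *p* < 10⁻⁴ in at least one contrast are kept.
4. **Stacked random forests.** A 2000-tree probability forest classifies
   5-mers from the selected descriptors; each peptide is then summarized
   by 22 statistics of its ordered mer probabilities (per class: mean,
   median, min, max, variance, fraction > 0.5, longest run > 0.5 / mer
   count; plus the mer count), and a 500-tree forest makes the final
   three-class call. Layer-2 training features come from layer-1
   *out-of-bag* probabilities, so the stack is leakage-free.

Evaluation uses accuracy, the Hand–Till AU1U (mean of all pairwise
one-vs-one AUCs), Cohen's kappa, and — after collapsing AMP+NEG into a
"rest" class — MCC, precision, sensitivity, specificity and AUC.

## Worked example

Train on synthetic data with the default separated class profiles, then
profile and classify a small set of lysine-rich membrane-active peptides
shipped with the package:

```r
library(pepstack)

sim <- generate_peptides(synth_config(n_per_class = 100,
                                      length_range = c(5, 30), seed = 42))
fit <- train_model(sim$peptides,
                   model_config(trees_layer1 = 150, trees_layer2 = 150,
                                seed = 1))
fit
#> Stacked mer/peptide random-forest classifier
#>   classes:         ACP, AMP, NEG
#>   selected n-grams: 266
#>   layer-1 trees:   150  layer-2 trees:  150
#>   training mers:   3972

peps <- read_fasta(system.file("extdata", "mito_acps.fasta",
                               package = "pepstack"))
head(peptide_properties(peps)[, 1:4], 4)
#>           id length net_charge  hydropathy
#>          A9K     10          1  1.23000000
#>      hCAP-18     32          7 -1.04062500
#>  HPRP-A1-TAT     24         14 -2.11666667
#>          KLA     14          6 -0.07142857

head(predict_peptides(fit, peps)[, 1:5], 4)
#>           id prob_ACP prob_AMP prob_NEG decision
#>          A9K    0.981  0.00817   0.0110      ACP
#>      hCAP-18    0.617  0.15563   0.2269      ACP
#>  HPRP-A1-TAT    1.000  0.00000   0.0000      ACP
#>          KLA    0.926  0.03811   0.0361      ACP
```

`net_charge` is the simple K + R − D − E count (an opt-in pH mode exists),
`hydropathy` the mean Kyte–Doolittle index, and the probabilities are the
layer-2 forest output — here from a model trained on synthetic ACP-like
(K/L/A/F-rich) vs AMP-like (G/C-rich) vs background profiles, which is why
these lysine/leucine-rich peptides all score as ACP-like. A model for real
screening should be trained on curated FASTA sets:

```sh
pepstack train --acp acp.fasta --amp amp.fasta --neg neg.fasta \
    --out model.rds --seed 1
pepstack predict --model model.rds --input candidates.fasta \
    --out predictions.tsv --binary
pepstack cv --acp acp.fasta --amp amp.fasta --neg neg.fasta \
    --out cv.tsv --seed 1
```

(`pepstack` is installed under the package's `exec/` directory;
equivalently call `pepstack::cli_main()`.)

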