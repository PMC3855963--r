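# ismvar — informational spectrum classification of amino acid substitutions

`ismvar` predicts whether a protein missense variant is a deleterious
mutation or a neutral polymorphism from sequence alone, with no multiple
alignment. It targets the case where conservation-based predictors
(SIFT, PolyPhen-2) are weakest: substitutions *outside* conserved
functional domains, whose positions carry little evolutionary signal even
when the variants are pathogenic.

## The method

Each residue of a protein is mapped to its electron–ion interaction
potential (EIIP, in Rydbergs), and the resulting numeric series
*x(m)*, *m = 1…N*, is Fourier transformed:

    X(n) = Σ_m x(m) · exp(−i 2π n (m−1)/N),   n = 1 … ⌊N/2⌋

The informational spectrum (IS) is the energy density *S(n) = |X(n)|²* on
the frequency grid *f = n/N* (Nyquist bound 0.5). Peaks correspond to
periodicities of the EIIP profile that track the protein's long-range
interactions. For one gene with labelled variants (MUT = somatic
disease-associated, SNP = neutral), each variant *i* is scored at every
frequency *j* by its amplitude deviation from wild type:

    S(i, j) = A(f_j)_var_i − A(f_j)_wt

Frequencies are visited in descending order of wild-type amplitude; at each,
a two-sided Mann–Whitney U test compares MUT vs SNP scores, and the first
frequency with p < α (default 0.05) becomes the classifier. The wild-type
amplitude there is the cutoff; an orientation sign (±1) records on which
side of the wild type the mutations fall, so that the oriented score
`orientation · S(i, j*)` is always higher for mutation-like variants.
Classifier frequencies and cutoffs are protein-specific; models are fitted
per gene.

## Worked example

Every stage runs on synthetic data with a known planted signal, so the whole
pipeline is verifiable without external downloads:

```r
library(ismvar)

d <- generate_planted_dataset(length = 300, planted_index = 143,
                              n_mut = 20, n_snp = 20, effect_size = 3,
                              seed = 42)
d
#> Synthetic ISM dataset: wild type of 300 residues, 20 MUT + 20 SNP variants
#>   planted bin 143 (f = 0.477), realized separation 9.26 SD (requested >= 3)
#>   seed: 42

fit <- ism_fit(d$wild_type, d$variants, gene = "SYNTH")
fit
#> ISM variant classifier for SYNTH
#>   wild type: N = 300 residues, 150 frequency bins
#>   training variants: 20 MUT, 20 SNP
#>   classifier frequency: F(0.477) (bin 143), p = 6.776e-08 after 1 test(s)
#>   cutoff amplitude: 11.3455, orientation: +1
```

The fit recovered the planted bin 143 on the first test: the planted
periodicity dominates the wild-type spectrum, so the descending-amplitude
scan reaches it first, and the Mann–Whitney p-value (6.8e-08) is far below
α. `fit$trace` holds every tested frequency with its amplitude and p-value.

```r
pred <- predict(fit)
head(pred, 4)
#>   substitution amplitude     score oriented_score class
#> 1        F105L  11.95380 0.6082553      0.6082553   MUT
#> 2        N255D  12.13121 0.7856655      0.7856655   MUT
#> 3        F105I  11.95380 0.6082553      0.6082553   MUT
#> 4        M130L  11.90023 0.5546811      0.5546811   MUT

evaluate_predictions(pred$oriented_score, pred$class, fit$labels)
#> Classification evaluation (n = 40)
#>   TP 20  FP 11  FN 0  TN 9
#>   accuracy     0.725
#>   precision    0.645
#>   sensitivity  1
#>   specificity  0.45
#>   npv          1
#>   auc          1
#>   fisher p     0.00123
```

Each variant's IS amplitude at F(0.477) is compared with the wild-type
cutoff 11.3455: above (orientation +1) is a MUT call, at or below is SNP.
The oriented scores separate the classes perfectly (AUC 1) while the
amplitude-vs-cutoff rule miscalls 11 SNPs whose tiny deviations fall just
above the cutoff — the cutoff rule and the rank separation are related but
distinct criteria. Five-fold cross-validation
(`ism_cv(d$wild_type, d$variants, k = 5, seed = 7)`) selects bin 143 in all
five folds.

Real data enter through `read_protein_fasta()`, `read_variant_table()`
(columns `gene`, `substitution`, `label`), and the packaged conserved-domain
intervals `cfd_domains()`; `classify_region()` splits variants into
CFD/nCFD, and `run_evaluate(..., subset = "nCFD")` restricts evaluation to
substitutions outside conserved domains. Third-party predictor scores are
ingested with `read_external_scores()`, `transform_sift_score()` and
`binarize_external()`.

A command-line wrapper ships at `inst/cli/ism.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "ism.R", package = "ismvar"))')" \
    simulate --out sim --length 300 --planted_index 143 --seed 42
Rscript .../ism.R fit --fasta sim/wildtype.fasta --variants sim/variants.tsv --out fitdir
Rscript .../ism.R classify --model fitdir/model.txt --variants sim/variants.tsv --out preds
```

with commands `encode`, `spectrum`, `fit`, `classify`, `cv`, `evaluate`,
`simulate`, and exit codes distinguishing usage errors, data errors and
"no classifier found".

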