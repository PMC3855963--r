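---
title: "Classifying amino acid substitutions with the informational spectrum method"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying amino acid substitutions with the informational spectrum method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ismvar)
```

## The problem and the model

Most variant-effect predictors score a missense substitution by the
evolutionary conservation of its position. That works well inside conserved
functional domains (CFDs) and poorly outside them, where disease-associated
substitutions are common — in cancer genes, often the majority — but the
positions are not conserved. `ismvar` implements an alignment-free
alternative: the informational spectrum method (ISM), which asks whether a
substitution disturbs the *periodic structure* of a physicochemical property
along the whole sequence rather than the identity of one residue.

The procedure has two transformations and one decision rule.

**Encoding.** Each residue is replaced by its electron–ion interaction
potential (EIIP, in Rydbergs), a per-amino-acid constant approximating the
energy of its valence electrons. The 20 values span 0 (Leu, Ile) to 0.1263
(Asp); Ser and Cys coincide at 0.0829. The scale ships as a packaged
constant (`eiip_scale()`) and as a two-column text fixture, and any
alternative residue scale can be plugged in through `read_eiip_scale()`.
Non-canonical residues (X, B, Z, U, gaps) are rejected by default with the
offending position named; an explicit `unknown = "mean"` option imputes the
sequence-mean EIIP instead, but silent imputation is never the default
because curated variant sets should not contain such residues.

**Spectrum.** The numeric series \(x(m)\), \(m = 1..N\), is Fourier
transformed,

\[ X(n) = \sum_{m=1}^{N} x(m)\, e^{-i 2\pi n (m-1)/N}, \qquad n = 1, \dots, \lfloor N/2 \rfloor, \]

and the informational spectrum is the energy density \(S(n) = |X(n)|^2\) on
the dimensionless frequency grid \(f_n = n/N\). Residue spacing is taken as
1, so the grid is bounded by the Nyquist frequency 0.5, attained exactly
when \(N\) is even; for odd \(N\) the upper index is the integer floor. The
DC bin is excluded — adding a constant to the series changes no \(S(n)\) —
and the spectrum is raw: no windowing, zero-padding, or normalisation. The
implementation uses `stats::fft`, but the contract is the direct sum above,
and the test suite holds the implementation to an \(O(N^2)\) direct-sum
oracle at `1e-9` relative tolerance, plus Parseval's identity and
shift/offset invariances.

**Scoring and the decision rule.** For one protein, every labelled variant
(`MUT` = somatic disease-associated substitution, `SNP` = neutral
polymorphism) is applied to the wild type, and its spectrum is scored by the
deviation matrix

\[ S(i, j) = A(f_j)_{\mathrm{var}_i} - A(f_j)_{\mathrm{wt}} . \]

Frequencies are then visited in strictly descending order of *wild-type*
amplitude (ties broken by ascending frequency, a deterministic choice) and
at each the MUT scores are compared with the SNP scores by a two-sided
Mann–Whitney U test. The first frequency with \(p < \alpha\) (default 0.05)
becomes the classifier frequency; the wild-type amplitude there is the
cutoff. An orientation sign records whether mutations sit above (+1) or
below (−1) the wild type at that frequency — which side they fall on cannot
be known before the scan finishes, and differs between proteins. A variant
is called `MUT` iff `orientation * (amplitude − cutoff) > 0`; an amplitude
exactly at the cutoff is called `SNP` (benign by default). The oriented
score `orientation * (A_var − A_wt)` is the continuous score used for ROC
analysis, so that higher always means more mutation-like across genes.

Models are strictly per gene: classifier frequencies and cutoffs are
protein-specific, and pooling variants across proteins is not supported.
Frequency selection uses all labelled variants of the gene; evaluation may
afterwards be restricted to the subset outside conserved domains
(`run_evaluate(..., subset = "nCFD")`), which is the in-sample reading of
the published comparison and the package default; refitting on a subset is
equally possible by filtering the input table.

## Parameters that matter

* `alpha` (default 0.05, valid in (0, 1]): the per-test significance level
  of the sequential scan. **No multiple-testing correction is applied across
  the sequence of tests** — this mirrors the published procedure. The
  consequence is quantified rather than hidden: `frequencies_tested` and the
  full selection `trace` (each visited frequency with its wild-type
  amplitude and p-value) are part of every fit, and the null simulation
  below shows the inflated family-wise discovery rate.
* `exact` (`"auto"`/`"exact"`/`"approx"`): the Mann–Whitney p-value is exact
  when both groups have ≤ 12 observations and the scores are tie-free,
  otherwise the normal approximation with tie and continuity corrections is
  used. The switch is configurable because deviation scores are continuous
  in exact arithmetic but can tie after floating-point rounding.
* Orientation ties (equal medians) default to +1.

## The synthetic-data generator

External curated variant sets cannot ship with the package, so every stage
is exercised on synthetic data with known ground truth.
`generate_planted_dataset(length, planted_index, n_mut, n_snp, effect_size,
seed)` builds:

* a wild type whose EIIP series tracks a sinusoid at the planted bin
  \(n^*\) (cosine amplitude ≈ 0.028 Ry on a 0.055 Ry baseline, residues
  drawn from the two nearest EIIP values at 80% of positions, uniformly
  otherwise). This makes \(S(n^*)\) the dominant wild-type peak, so the
  descending-amplitude scan meets the planted bin first — the planted
  analogue of a strong functional periodicity;
* `n_mut` substitutions chosen by seeded greedy search (candidate
  evaluations capped, default 5000 per variant) to shift \(S(n^*)\) strongly
  and in a consistent direction — a single substitution changes \(X(n)\) by
  a rank-one term, so each candidate costs O(1);
* `n_snp` substitutions drawn from the smallest decile of spectral
  disturbance over the planted bin ± 3 neighbours (the neighbourhood guard
  keeps recovery tests free of leakage from adjacent bins).

The realised standardized separation at \(n^*\) is recorded and must reach
`effect_size` (pooled-SD units) or generation fails with advice to increase
the length. With `effect_size = 0` the construction deliberately degenerates
to the null generator (`generate_null_dataset`): uniform substitutions and
an unplanted wild type, because a greedy-extremes construction would
separate the groups even when asked for zero effect. Identical arguments and
seed give byte-identical datasets.

What the generator does *not* emulate: real mutational spectra, codon
structure, transition/transversion bias, disease prevalence, or the
position–domain correlation of real variants. Passing recovery tests
therefore demonstrate that the algorithm finds a class-discriminating
spectral signal when one exists — not that such signals exist in any
particular protein.

Default study conditions used by the tests and the acceptance script:
wild-type length 300 (planted bin 143, f ≈ 0.477), 20 MUT + 20 SNP, effect
size ≥ 3 pooled SDs, 100 replicates for the recovery rate; null runs use
length 200 with 15 + 15 variants, 200 replicates. These sizes sit in the
range of the real proteins the method was developed on (hundreds to ~2000
residues, tens to ~170 variants per gene) while keeping a full simulation
run in tens of seconds.

```{r}
d <- generate_planted_dataset(length = 300, planted_index = 143,
                              n_mut = 20, n_snp = 20, effect_size = 3,
                              seed = 42)
d
fit <- ism_fit(d$wild_type, d$variants, gene = "SYNTH")
fit
head(predict(fit))
ism_cv(d$wild_type, d$variants, k = 5, seed = 7)
```

## Numerical and design choices

* **Frequency convention**: \(f = n/N\) with the DC bin excluded and odd
  \(N\) truncated at the floor — the literal reading of the defining sum.
* **Tie rules**: equal wild-type amplitudes are visited in ascending
  frequency order; amplitude exactly at the cutoff classifies as SNP; equal
  medians give orientation +1. All three are deterministic choices where the
  method description is silent.
* **"No classifier found"** is an explicit result (`found = FALSE`, with the
  complete trace), not an exception; the command-line wrapper maps it to its
  own exit code. Degenerate cross-validation splits (a training fold losing
  one class) are reported per fold as `"degenerate"`.
* **Undefined metrics** (zero denominators, e.g. precision with no positive
  calls) are reported as `NA`, never silently 0.
* **External score conventions**: original SIFT scores are reflected
  (`1 - s`) so high means deleterious; binarization calls a mutation for
  original SIFT < 0.05 (0.05 exactly is a SNP — the strict reading) and for
  PolyPhen-2 ≥ 0.5 (the boundary is inclusive on the mutation side; the
  source convention leaves equality open and the inclusive choice is
  documented here).
* **Duplicate and conflicting labels**: a substitution listed under several
  diseases is one variant; one listed as both SNP and MUT is excluded with a
  warning — the conservative resolution of an ambiguity the curation rules
  leave open.
* **Wild-type mismatches** between a variant's stated reference residue and
  the sequence (e.g. isoform/coordinate disagreements) raise a consistency
  error naming expected and found residues rather than guessing.

## What the null simulation shows

With 15 + 15 uniformly drawn substitutions on a 200-residue protein and no
class signal, the sequential scan over ~100 frequencies declares *some*
classifier in the large majority of runs (the acceptance script measures
this rate; it is typically well above 0.9), even though each individual
test holds its 5% level — the expected behaviour of an uncorrected
sequential search, inherited deliberately from the original procedure. Any
single prespecified bin is selected at roughly the per-test rate. Users who
need family-wise control should treat the selected frequency as exploratory
and validate it by cross-validation (`ism_cv`), which is also the stability
check used on real data.

## Known limitations

* Single-residue substitutions only; no indels, no nucleotide-level input.
* One classifier frequency per protein; multi-frequency rules are out of
  scope.
* The amplitude-vs-cutoff call and the Mann–Whitney separation are related
  but not identical criteria: a strong rank separation of deviation scores
  does not guarantee that the wild-type amplitude is the best threshold, so
  in-sample accuracy can be noticeably lower than the oriented-score AUC
  (visible in the worked example above).
* Reproducing the published gene-level results requires the four UniProt
  wild-type sequences and the curated variant table, which are third-party
  data not distributed with the package; the test suite documents the file
  locations it expects for that reproduction.
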