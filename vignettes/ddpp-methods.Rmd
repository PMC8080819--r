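---
title: "DDPP: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DDPP: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddpp)
```

## The problem

Cohorts of patients treated with the same targeted drug, for whom both
paired tumor/normal transcriptomes and clinical outcome are available, are
tiny — typically three to ten patients. Any method that estimates per-gene
coefficients (multiple linear regression, multiple Cox regression) is
practically guaranteed to overfit at that size. The Digital Display
Precision Predictor (DDPP) approach implemented here avoids coefficient
learning entirely: it ranks a small literature-curated gene panel by
univariate correlation with progression-free survival (PFS, months),
collapses nested prefix subsets with parameter-free summations, and only
at the very end fits the two parameters of a simple linear regression.

## The model

For gene $g$ in patient $i$, with tumor and normal intensities $T_{i,g}$
and $N_{i,g}$ (relative fluorescence units from a dual-color array, both
strictly positive), the feature is

$$F_{i,g} = \log_2\!\frac{T_{i,g}}{N_{i,g}} \cdot \log_{1.1} I_{i,g},$$

where the channel intensity $I$ is either the tumor or the normal RFU of
that gene — one channel is chosen per model. The log base 1.1 of the
intensity term is the field's convention for these arrays and is exposed
as the `base` argument (see "Known wrinkles" below). In the single-biopsy
ablation (`feature_mode = "tumor_only"`) the feature is
$\log_{1.1} T_{i,g}$ alone; this mode exists to quantify how much the
paired-biopsy design matters.

The pipeline per drug:

1. **Panel** — an ordered list of literature-curated key genes
   (`get_panel()` ships six: everolimus 17, axitinib 13, trametinib 13,
   afatinib 13, FGFR inhibitors 19, anti-PD-1 12).
2. **Channel and ranking** — per-gene Pearson $(r, p)$ of $F_g$ against
   PFS is computed under both channels; the channel containing the single
   most correlated gene wins and is then used for every gene. Genes are
   ranked by decreasing $|r|$.
3. **Step-in search** — for $K = 1..$ panel size, the ranking prefix of
   size $K$ is collapsed per patient by each of five parameter-free
   summations: sum, mean, median, product (`fold`), absolute product
   (`fold_abs`). Each scalar is correlated with PFS; the $(K,
   \text{method})$ cell with maximal $|r|$ defines the predictor.
4. **Regression** — ordinary least squares of PFS on the winning scalar
   $X$ gives the predictor $\hat Y = \beta_1 X + \beta_0$ (months).

Significance of the two-sided Pearson $p$ uses the exact $t$
transformation $t = r\sqrt{(n-2)/(1-r^2)}$ with $n-2$ degrees of freedom.
With $n \le 10$ this $p$ is only honest for the *univariate, pre-specified*
question; the step-in search maximizes over cells, which is why the
package ships the random-gene-set null scan (`random_null_scan()`) rather
than pretending the best cell's $p$ is a family-wise error rate.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `base` | 1.1 | log base of the intensity factor in $F$ |
| `feature_mode` | `"dual"` | paired feature vs tumor-only ablation |
| `methods` | all five | summation methods searched |
| `min_abs_r`, `max_p` | 0.9, 0.05 | generic null-scan significance screen |
| `iterations` | caller-set | null-scan draws (100,000 for headline scans) |
| cohort size | $\ge 3$ | hard minimum for any fit; leave-one-out needs $\ge 4$ |

Censored PFS ("60.0+") is stored de-censored — the value at censoring
time enters every computation and the flag is kept for annotation only.
This matches the source methodology; with one long censored survivor in a
cohort of six the de-censored value anchors the regression, and the
leave-one-out error against that patient is inflated accordingly
(documented, not corrected).

## Deterministic tie-breaks and numerical choices

* Ranking: decreasing $|r|$; ties by ascending $p$, then lexicographic
  gene symbol. For fixed $n$ the $|r|$ and $p$ orderings coincide, so
  $|r|$ is the primary key.
* Channel: tumor wins exact ties.
* Best cell: maximal $|r|$; ties prefer smaller $K$ (parsimony), then the
  canonical method order sum, mean, median, fold, fold_abs.
* `fold`/`fold_abs` are computed in double precision with a finiteness
  guard; an overflowing product is an error, not an `Inf` carried forward
  (panel sizes up to ~20 keep magnitudes well below overflow; the
  published everolimus-style scalars reach ~1e13–1e14).
* Zero-variance inputs raise classed degenerate errors; ranking and scan
  contexts map degenerate *genes/draws* to "not significant" (r = 0,
  ranked last, tallied) instead of aborting a 100,000-draw scan.
* At numerically perfect correlation the returned $p$ is 0; a $p$ of
  exactly 0 only arises in noise-free synthetic worlds.
* Negative predicted PFS is returned as-is with a warning (one published
  equation has a negative intercept; clamping would silently change
  reported errors).

## Leave-one-out validation

`loo_validate()` repeats the **entire** selection — channel, ranking,
prefix, method, regression — on each reduced cohort, then predicts the
held-out patient. Nothing from the held-out patient enters its fold's
model; the test suite asserts this by perturbing the held-out patient's
expression and requiring the fold's model to be bit-identical. Reported:
per-fold model summaries, Pearson concordance between predicted and
observed PFS, RMSE and MAE. Whether the headline RMSE/MAE should come
from leave-one-out predictions or full-fit residuals is ambiguous in the
source; the report computes both (`rmse`/`mae` vs `rmse_fullfit`/
`mae_fullfit`) and documents leave-one-out as the default reading.

## Null scans and specificity

`random_null_scan()` draws gene sets (distinct genes within a draw,
independent draws across iterations — the source is silent on this;
distinct-within-draw matches the phrase "random selections of n genes"),
applies a fixed summation, and counts draws beating a threshold. Two
presets: `generic` ($|r| \ge 0.9$, $p \le 0.05$) and `match-predictor`
($|r| \ge$ observed $|r|$, $p \le$ observed $p$ — applied to $|r|$, since
one published predictor is negative). Degenerate draws count as not
significant and stay in the denominator. All randomness flows through one
integer seed recorded in the result. `cross_drug_test()` applies a frozen
model to another drug's cohort with no refitting, probing predictive vs
merely prognostic value.

## The synthetic world

`generate_cohort()` emulates the data the pipeline consumes: strictly
positive log-normal intensities (`intensity_log_mean = 7`,
`intensity_log_sd = 1`, i.e. ~1100 RFU typical), 3–10 patients (default
6, the everolimus cohort size), a planted $k$-gene signature whose
summation scalar $X$ is linearly coupled to PFS
($Y = \beta_1 X + \beta_0 + \mathcal N(0, \sigma)$, defaults
$\beta_1 = 1.499\times 10^{-13}$, $\beta_0 = 3.134$, $\sigma = 1$ month),
PFS floored at 0.1 months (a generator artifact, documented), and
optional censoring of the longest PFS. Per-patient targets $\beta_1 X$
are drawn uniformly over ~0.5–50 months, the realistic PFS span of these
cohorts.

Three generator mechanics deserve explanation because the design was
genuinely open:

* **Shares.** Product-type signatures give gene $j$ a random exponent
  share $w_j$ ($\sum w_j = 1$), sum-type a random additive share, so the
  planted genes are not identical copies.
* **Cancelling jitter.** Each planted gene carries gene-level noise that
  cancels exactly in the full joint summation (log-scale for products,
  additive zero-sum for sums). Without it, every prefix of a product
  signature is $X^a$ for some $a$, all prefixes correlate ~0.99 with PFS,
  and the step-in argmax at $n = 6$ is a coin flip; with it the full set
  is the unique optimum. Measured recovery of the exact planted
  configuration: 192/200 noise-free seeds, 97/100 at $\sigma = 0.5$.
* **Driver gene.** The first planted gene is (nearly) jitter-free and its
  on-channel intensity is drawn dim and variable (log-mean 2, log-sd
  0.5). A dim probe makes the gene's fold change large and
  patient-dependent, which scrambles its feature in the *opposite*
  channel — so the channel rule, which keys on the single best gene,
  reliably identifies the planted channel. This mirrors real panels,
  where one dominant gene (the everolimus panel's AKT2) drives the
  channel decision.

What a green synthetic test does **not** establish: dye bias, spatial
artifacts, probe saturation, batch structure, and biological correlation
between panel genes are all absent; non-planted genes are pure noise with
fold changes centered at 1. Green tests certify the *algorithm* —
ranking, selection, regression, validation plumbing — not microarray
reality.

## Known wrinkles

* The tumor-only ablation is described with a log base 1.1 intensity axis
  in one place and log base 2 in another in the source material; the
  implementation defaults to 1.1 and exposes `base` rather than resolving
  the discrepancy.
* The FGFR panel's ligand list is truncated with "etc." in the source;
  the packaged 19-gene list (FGFR1–4, FGF1–FGF10, FGF13, FGF16,
  FGF17, FGF18, FGF19) is one defensible completion and includes all five
  genes of the published 5-gene FGFR predictor. It is recorded in the
  panel JSON, not hard-coded.
* Whether the published anti-PD-1 equation used the product or the sum is
  ambiguous from its phrasing ("the value of the fold of …"); the
  packaged model uses the product (`fold`), consistent with the other
  product-type equations.
* Published per-drug numbers (the printed slopes/intercepts, the 0.994%
  everolimus null fraction, LOO RMSE 16.82) can only be re-derived with
  the original trial's deposited expression data, which the package does
  not ship; the packaged published models carry the printed constants as
  fixtures, and all quantitative claims in the test suite are computed on
  synthetic worlds with known ground truth.

## Limitations

With $n \le 6$ the step-in predictor is unstable under resampling — the
leave-one-out folds routinely select different subsets, and this package
faithfully reproduces that behavior rather than hiding it. The null scans
show that random gene sets clear stringent thresholds at the percent
level, so a single small-cohort fit should be read as hypothesis
generation, not validation.
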