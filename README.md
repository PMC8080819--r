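# ddpp

Parameter-free transcriptomic prediction of progression-free survival
(PFS) from paired tumor / organ-matched normal expression profiles.

## Who this is for

Translational oncology groups with very small per-drug cohorts (3–10
patients) holding dual-biopsy transcriptomes (tumor + matched normal,
dual-color microarray RFU intensities) and clinical outcome, who want a
continuous predictor of PFS in months rather than a binary
responder/non-responder call — and who need every step reproducible,
seeded, and honestly nulled against random gene sets.

## The method

For gene *g* in patient *i* the feature is

    F[i,g] = log2(T[i,g] / N[i,g]) * log_1.1(I[i,g])

where `T`/`N` are tumor/normal intensities and the channel intensity `I`
is either of the two (chosen once per model). Genes of a drug-specific
literature panel are ranked by Pearson correlation of `F` with PFS; the
ranking prefixes of size K = 1..panel size are collapsed per patient by
five parameter-free summations (`sum`, `mean`, `median`, `fold` =
product, `fold_abs` = absolute product); the (K, method) cell with
maximal |r| defines the predictor; ordinary least squares then gives
`PFS = slope * X + intercept`. No per-gene coefficients are ever
estimated — that is the point, at n = 6 they would only memorize the
cohort. Leave-one-out validation refits the entire selection per fold;
random-gene-set scans calibrate how often chance clears the same bar.

## Worked example

A synthetic cohort with a planted 8-gene product signature
(`PFS = 1.499e-13 * X + 3.134` plus 1 month of noise — the scale of the
published everolimus predictor):

```r
library(ddpp)
sim   <- generate_cohort(generator_config(seed = 20, noise_sd = 1, n_genes = 200))
panel <- ddpp_panel("synthetic", sim$truth$genes)
model <- ddpp_fit(sim$cohort, panel)
model
#> <ddpp_model> drug=synthetic: PFS = 1.434e-13 * X + 4.771
#>   X = fold of 8 genes (SIG1, SIG8, SIG6, SIG3, SIG7, SIG2, SIG4, SIG5), channel=tumor, mode=dual, base=1.1
#>   training: r=0.999, p=1.418e-06, n=6

loo_validate(sim$cohort, panel)
#> <ddpp_validation> 6 folds (0 failed)
#>   concordance r=0.9971 (p=1.218e-05); LOO RMSE=0.9629, MAE=0.8556
#>   full-fit RMSE=0.5286, MAE=0.5052

fm <- build_feature_matrix(sim$cohort, channel = model$channel)
random_null_scan(sim$cohort, fm, panel_size = 8, iterations = 10000,
                 threshold = match_predictor_threshold(model),
                 method = model$method, seed = 7)
#> <ddpp_null_scan> 10000 x 8-gene draws (method=fold, seed=7)
#>   threshold |r|>=0.999, p<=1.42e-06 -> 0 significant (0%), 0 degenerate
```

Reading the output: the pipeline recovered the planted channel (tumor),
all 8 planted genes, a product-type summation, and a slope/intercept near
the planted 1.499e-13 / 3.134 (the offset reflects the 1-month PFS
noise at n = 6). Leave-one-out concordance r = 0.997 with errors ~1
month; none of 10,000 random 8-gene sets matched the predictor's
training correlation.

Packaged assets: `get_panel()` ships the six drug panels (everolimus,
axitinib, trametinib, afatinib, FGFR inhibitors, anti-PD-1) with alias
maps; `published_model()` returns the six published predictor equations
as frozen `ddpp_model` objects; `winther_clinical()` loads the packaged
per-patient PFS table. Applying a frozen model to new expression data:
`predict_pfs()`, `cross_drug_test()`.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "ddpp.R", package = "ddpp"))')
Rscript "$CLI" simulate --out sim/ --seed 5 --n-genes 200
Rscript "$CLI" fit  --drug synthetic --expr sim/expression.csv --clin sim/clinical.csv \
                    --panel panel.json --out model.json
Rscript "$CLI" loo  --drug synthetic --expr sim/expression.csv --clin sim/clinical.csv \
                    --panel panel.json --out validation.json
Rscript "$CLI" null --drug synthetic --expr sim/expression.csv --clin sim/clinical.csv \
                    --panel-size 8 --iterations 100000 --seed 7 --out null.json
```

Subcommands: `rank | fit | predict | loo | null | shuffle | scan |
simulate`. Exit codes: 0 ok, 1 validation failure (named cause), 2 usage
error. A JSON config can be passed with `--config`; explicit flags win.

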