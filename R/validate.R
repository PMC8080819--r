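#' Leave-one-out validation of the DDPP pipeline
#'
#' For each patient, refits the entire pipeline — channel choice, Pearson
#' ranking, step-in prefix/method selection, and linear regression — on the
#' remaining patients, then predicts the left-out patient with the fold's
#' model. The left-out patient's data never enters the fold's fit. Folds
#' whose reduced cohort is degenerate (e.g. constant PFS) are flagged and
#' excluded from the summary but counted.
#'
#' Concordance is the Pearson correlation between predicted and observed
#' PFS across successful folds. RMSE and MAE are reported both for the
#' leave-one-out predictions (the default headline numbers) and, separately,
#' for the residuals of the single full-cohort fit.
#'
#' @inheritParams stepin_select
#' @return A `ddpp_validation` object: list with `folds` (data.frame
#'   `left_out`, `predicted`, `observed`, `censored`, `channel`, `K`,
#'   `method`, `slope`, `intercept`, `ok`), `concordance_r`,
#'   `concordance_p`, `rmse`, `mae`, `rmse_fullfit`, `mae_fullfit`,
#'   `n_folds`, `n_failed`.
#' @export
loo_validate <- function(cohort, panel, feature_mode = c("dual", "tumor_only"),
                         methods = ddpp_methods(), base = 1.1) {
  assert_fit_cohort(cohort, min_n = 4L)
  feature_mode <- match.arg(feature_mode)
  ids <- cohort$patients$patient_id
  folds <- data.frame(
    left_out = ids, predicted = NA_real_,
    observed = cohort$patients$pfs_months,
    censored = cohort$patients$censored,
    channel = NA_character_, K = NA_integer_, method = NA_character_,
    slope = NA_real_, intercept = NA_real_, ok = FALSE,
    stringsAsFactors = FALSE
  )
  for (i in seq_along(ids)) {
    train <- cohort_subset(cohort, ids[-i])
    model <- tryCatch(
      ddpp_fit(
        train, panel,
        feature_mode = feature_mode, methods = methods, base = base
      ),
      ddpp_validation_error = function(e) NULL
    )
    if (is.null(model)) next
    pred <- suppressWarnings(predict_pfs(model, cohort, ids[i]))
    folds$predicted[i] <- unname(pred)
    folds$channel[i] <- model$channel
    folds$K[i] <- length(model$genes)
    folds$method[i] <- model$method
    folds$slope[i] <- model$slope
    folds$intercept[i] <- model$intercept
    folds$ok[i] <- TRUE
  }
  ok <- folds$ok
  if (sum(ok) < 3L) {
    ddpp_degenerate_error("fewer than 3 successful leave-one-out folds")
  }
  err <- folds$predicted[ok] - folds$observed[ok]
  conc <- tryCatch(
    pearson_with_p(folds$predicted[ok], folds$observed[ok]),
    ddpp_degenerate_error = function(e) list(r = NA_real_, p = NA_real_)
  )
  full <- ddpp_fit(
    cohort, panel,
    feature_mode = feature_mode, methods = methods, base = base
  )
  full_err <- suppressWarnings(predict_pfs(full, cohort)) -
    cohort$patients$pfs_months
  structure(
    list(
      folds = folds,
      concordance_r = conc$r, concordance_p = conc$p,
      rmse = sqrt(mean(err^2)), mae = mean(abs(err)),
      rmse_fullfit = sqrt(mean(full_err^2)), mae_fullfit = mean(abs(full_err)),
      n_folds = length(ids), n_failed = sum(!ok)
    ),
    class = "ddpp_validation"
  )
}

#' @export
print.ddpp_validation <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<ddpp_validation> %d folds (%d failed)\n",
      "  concordance r=%.4g (p=%.4g); LOO RMSE=%.4g, MAE=%.4g\n",
      "  full-fit RMSE=%.4g, MAE=%.4g\n"
    ),
    x$n_folds, x$n_failed, x$concordance_r, x$concordance_p,
    x$rmse, x$mae, x$rmse_fullfit, x$mae_fullfit
  ))
  invisible(x)
}

#' Export per-fold leave-one-out results as CSV
#'
#' @param report A `ddpp_validation`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fold_table <- function(report, path) {
  if (!inherits(report, "ddpp_validation")) {
    ddpp_validation_error("expected a ddpp_validation")
  }
  cols <- c(
    "left_out", "predicted", "observed", "channel", "K", "method",
    "slope", "intercept"
  )
  write.csv(report$folds[, cols], path, row.names = FALSE)
  invisible(path)
}
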