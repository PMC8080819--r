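#' Ordinary least squares of PFS on the summation scalar
#'
#' Closed-form simple linear regression: `slope = Sxy / Sxx`,
#' `intercept = mean(y) - slope * mean(x)`, with the Pearson `r` and
#' two-sided `p` of [pearson_with_p()].
#'
#' @param x Summation scalar per patient (non-constant, `n >= 3`).
#' @param y_pfs Observed PFS in months.
#' @return List with `slope`, `intercept`, `n`, `r`, `p`.
#' @export
fit_linear <- function(x, y_pfs) {
  if (!is.numeric(x) || !is.numeric(y_pfs) || length(x) != length(y_pfs)) {
    ddpp_validation_error("x and y_pfs must be numeric vectors of equal length")
  }
  if (length(x) < 3L) ddpp_validation_error("regression requires n >= 3")
  xc <- x - mean(x)
  if (sum(xc^2) == 0) {
    ddpp_degenerate_error("x is constant; regression undefined")
  }
  slope <- sum(xc * (y_pfs - mean(y_pfs))) / sum(xc^2)
  intercept <- mean(y_pfs) - slope * mean(x)
  ct <- pearson_with_p(x, y_pfs)
  list(slope = slope, intercept = intercept, n = length(x), r = ct$r, p = ct$p)
}

#' Construct a fitted DDPP model object
#'
#' Usually produced by [ddpp_fit()]; the constructor is exported so that
#' published or deserialized models can be rebuilt and applied to new
#' cohorts.
#'
#' @param drug Drug label.
#' @param channel `"tumor"` or `"normal"`.
#' @param feature_mode `"dual"` or `"tumor_only"`.
#' @param genes Ordered gene subset (the selected ranking prefix).
#' @param method One of [ddpp_methods()].
#' @param slope,intercept Linear predictor coefficients (PFS in months).
#' @param train_r,train_p Training correlation of the scalar with PFS.
#' @param n_train Number of training patients (>= 3).
#' @param base Intensity log base (default 1.1).
#' @return A `ddpp_model` object.
#' @export
ddpp_model <- function(drug, channel, feature_mode, genes, method,
                       slope, intercept, train_r = NA_real_,
                       train_p = NA_real_, n_train = NA_integer_,
                       base = 1.1) {
  channel <- match.arg(channel, ddpp_channels)
  feature_mode <- match.arg(feature_mode, ddpp_feature_modes)
  method <- match.arg(method, ddpp_methods_all)
  genes <- as.character(genes)
  if (!length(genes) || anyDuplicated(genes)) {
    ddpp_validation_error("model genes must be a non-empty unique list")
  }
  stopifnot_scalar_number(slope, "slope")
  stopifnot_scalar_number(intercept, "intercept")
  if (is.finite(train_r) && abs(train_r) > 1 + 1e-12) {
    ddpp_validation_error("|train_r| must be <= 1")
  }
  structure(
    list(
      drug = as.character(drug), channel = channel,
      feature_mode = feature_mode, genes = genes, method = method,
      slope = slope, intercept = intercept,
      train_r = train_r, train_p = train_p,
      n_train = as.integer(n_train), base = base
    ),
    class = "ddpp_model"
  )
}

#' @export
print.ddpp_model <- function(x, ...) {
  cat(sprintf(
    "<ddpp_model> drug=%s: PFS = %.4g * X + %.4g\n",
    x$drug, x$slope, x$intercept
  ))
  cat(sprintf(
    "  X = %s of %d genes (%s), channel=%s, mode=%s, base=%g\n",
    x$method, length(x$genes), paste(x$genes, collapse = ", "),
    x$channel, x$feature_mode, x$base
  ))
  if (is.finite(x$train_r)) {
    cat(sprintf(
      "  training: r=%.4g, p=%.4g, n=%d\n", x$train_r, x$train_p, x$n_train
    ))
  }
  invisible(x)
}

#' Fit the full DDPP pipeline on one cohort
#'
#' Runs [stepin_select()] (channel choice, Pearson ranking, prefix/method
#' search) and regresses observed PFS on the winning scalar with
#' [fit_linear()].
#'
#' @inheritParams stepin_select
#' @return A `ddpp_model` with attribute `"selection"` holding the full
#'   [stepin_select()] result.
#' @export
ddpp_fit <- function(cohort, panel, feature_mode = c("dual", "tumor_only"),
                     methods = ddpp_methods(), base = 1.1) {
  feature_mode <- match.arg(feature_mode)
  sel <- stepin_select(
    cohort, panel,
    feature_mode = feature_mode, methods = methods, base = base
  )
  genes <- sel$ranking$gene[seq_len(sel$best_k)]
  x <- model_scalar_for(
    cohort, genes, sel$channel, feature_mode, sel$best_method, base
  )
  fit <- fit_linear(x, cohort$patients$pfs_months)
  model <- ddpp_model(
    drug = cohort$drug, channel = sel$channel, feature_mode = feature_mode,
    genes = genes, method = sel$best_method,
    slope = fit$slope, intercept = fit$intercept,
    train_r = fit$r, train_p = fit$p, n_train = fit$n, base = base
  )
  attr(model, "selection") <- sel
  model
}

# Summation scalar X for each patient of a cohort under a fixed
# gene-set/channel/method configuration.
model_scalar_for <- function(cohort, genes, channel, feature_mode, method,
                             base) {
  fm <- build_feature_matrix(
    cohort, genes,
    channel = channel, feature_mode = feature_mode, base = base
  )
  x <- summate_rows(fm$values, method)
  if (any(!is.finite(x))) {
    ddpp_validation_error("summation scalar overflowed to non-finite")
  }
  names(x) <- rownames(fm$values)
  x
}

#' Summation scalar of a frozen model on a cohort
#'
#' @param model A `ddpp_model`.
#' @param cohort A [ddpp_cohort()] covering the model genes.
#' @return Named numeric vector of per-patient X values.
#' @export
model_scalar <- function(model, cohort) {
  assert_model(model)
  assert_cohort(cohort)
  model_scalar_for(
    cohort, model$genes, model$channel, model$feature_mode,
    model$method, model$base
  )
}

#' Predict PFS for new patients
#'
#' Recomputes the model's feature/summation scalar for each patient of
#' `cohort` and returns `slope * X + intercept` (months). Predictions can
#' be negative; they are returned as-is with a warning rather than clamped.
#'
#' @param model A `ddpp_model`.
#' @param cohort A [ddpp_cohort()] whose gene universe covers the model
#'   genes (any number of patients).
#' @param patient_id Optional single id to predict for.
#' @return Named numeric vector of predicted PFS in months.
#' @export
predict_pfs <- function(model, cohort, patient_id = NULL) {
  assert_model(model)
  assert_cohort(cohort)
  if (!is.null(patient_id)) cohort <- cohort_subset(cohort, patient_id)
  x <- model_scalar(model, cohort)
  pred <- model$slope * x + model$intercept
  if (any(pred < 0)) {
    warning(
      "negative predicted PFS for patient(s): ",
      paste(names(pred)[pred < 0], collapse = ", "),
      call. = FALSE
    )
  }
  pred
}

assert_model <- function(model) {
  if (!inherits(model, "ddpp_model")) {
    ddpp_validation_error("expected a ddpp_model object")
  }
  invisible(model)
}
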