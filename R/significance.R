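#' Significance threshold for null scans
#'
#' A draw counts as significant when `|r| >= min_abs_r` and `p <= max_p`.
#' Two presets are used in practice: the generic screen (`|r| >= 0.9`,
#' `p <= 0.05`) and a threshold matched to an observed predictor
#' ([match_predictor_threshold()]).
#'
#' @param min_abs_r Minimum absolute Pearson r, in `[0, 1]`.
#' @param max_p Maximum two-sided p, in `(0, 1]`.
#' @return A `ddpp_threshold` object.
#' @export
threshold_spec <- function(min_abs_r = 0.9, max_p = 0.05) {
  stopifnot_scalar_number(min_abs_r, "min_abs_r")
  stopifnot_scalar_number(max_p, "max_p")
  if (min_abs_r < 0 || min_abs_r > 1) {
    ddpp_validation_error("min_abs_r must be in [0, 1]")
  }
  if (max_p <= 0 || max_p > 1) {
    ddpp_validation_error("max_p must be in (0, 1]")
  }
  structure(
    list(min_abs_r = min_abs_r, max_p = max_p),
    class = "ddpp_threshold"
  )
}

#' Threshold matched to an observed predictor
#'
#' `|r| >= |train_r|` and `p <= train_p` of the reference model — the
#' "same value as observed" preset used when asking how often random gene
#' sets do at least as well as the reported predictor.
#'
#' @param model A fitted `ddpp_model`.
#' @return A `ddpp_threshold`.
#' @export
match_predictor_threshold <- function(model) {
  assert_model(model)
  threshold_spec(
    min_abs_r = abs(model$train_r),
    max_p = max(model$train_p, .Machine$double.xmin)
  )
}

#' Random-gene-set null scan
#'
#' Draws `iterations` random gene sets of size `panel_size` (genes distinct
#' within a draw, draws independent across iterations), collapses each
#' patient's features with `method`, correlates the scalar with PFS, and
#' counts draws passing the threshold. Degenerate draws (zero-variance
#' scalar) count as not significant and are tallied; the denominator stays
#' `iterations`. The whole scan is reproducible from `seed`, which is drawn
#' through R's default Mersenne-Twister generator.
#'
#' @param cohort A [ddpp_cohort()] supplying PFS (patients must match the
#'   feature matrix rows).
#' @param transcriptome A `ddpp_features` matrix over the scan gene
#'   universe, e.g. from [build_feature_matrix()] with `genes = NULL`.
#' @param panel_size Genes per draw (1 <= panel_size <= gene count).
#' @param iterations Number of random draws (>= 1).
#' @param threshold A [threshold_spec()].
#' @param method Summation method applied to each draw; defaults to the
#'   method of the predictor under scrutiny.
#' @param seed Integer seed recorded in the result.
#' @return A `ddpp_null_scan` object: `panel_size`, `iterations`, `seed`,
#'   `method`, `threshold`, `n_significant`, `n_degenerate`,
#'   `proportion_significant`.
#' @export
random_null_scan <- function(cohort, transcriptome, panel_size, iterations,
                             threshold = threshold_spec(),
                             method = ddpp_methods(), seed = 1L) {
  assert_fit_cohort(cohort)
  if (!inherits(transcriptome, "ddpp_features")) {
    ddpp_validation_error("transcriptome must be a ddpp_features object")
  }
  if (!inherits(threshold, "ddpp_threshold")) {
    ddpp_validation_error("threshold must be a threshold_spec()")
  }
  method <- match.arg(method)
  panel_size <- as.integer(panel_size)
  iterations <- as.integer(iterations)
  vals <- transcriptome$values
  if (panel_size < 1L || panel_size > ncol(vals)) {
    ddpp_validation_error("panel_size must be in 1..gene count")
  }
  if (iterations < 1L) ddpp_validation_error("iterations must be >= 1")
  ids <- cohort$patients$patient_id
  if (!setequal(rownames(vals), ids)) {
    ddpp_validation_error("feature matrix patients do not match the cohort")
  }
  pfs <- cohort$patients$pfs_months[match(rownames(vals), ids)]
  n <- length(pfs)
  yc <- pfs - mean(pfs)
  syy <- sum(yc^2)
  if (syy == 0) ddpp_degenerate_error("PFS is constant across the cohort")
  df <- n - 2L
  set.seed(as.integer(seed))
  n_sig <- 0L
  n_deg <- 0L
  for (it in seq_len(iterations)) {
    idx <- sample.int(ncol(vals), panel_size)
    x <- summate_rows(vals[, idx, drop = FALSE], method)
    xc <- x - mean(x)
    sxx <- sum(xc^2)
    if (!is.finite(sxx) || sxx == 0) {
      n_deg <- n_deg + 1L
      next
    }
    r <- sum(xc * yc) / sqrt(sxx * syy)
    r <- max(-1, min(1, r))
    p <- if (1 - r^2 <= .Machine$double.eps) {
      0
    } else {
      2 * pt(-abs(r * sqrt(df / (1 - r^2))), df)
    }
    if (abs(r) >= threshold$min_abs_r && p <= threshold$max_p) {
      n_sig <- n_sig + 1L
    }
  }
  structure(
    list(
      panel_size = panel_size, iterations = iterations,
      seed = as.integer(seed), method = method, threshold = threshold,
      n_significant = n_sig, n_degenerate = n_deg,
      proportion_significant = n_sig / iterations
    ),
    class = "ddpp_null_scan"
  )
}

#' @export
print.ddpp_null_scan <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<ddpp_null_scan> %d x %d-gene draws (method=%s, seed=%d)\n",
      "  threshold |r|>=%.3g, p<=%.3g -> %d significant (%.4g%%),",
      " %d degenerate\n"
    ),
    x$iterations, x$panel_size, x$method, x$seed,
    x$threshold$min_abs_r, x$threshold$max_p,
    x$n_significant, 100 * x$proportion_significant, x$n_degenerate
  ))
  invisible(x)
}

#' Cross-drug (shuffle) specificity test
#'
#' Applies a frozen model — its channel, gene subset, summation method and
#' intensity base, with no refitting — to another cohort and correlates the
#' resulting scalar with that cohort's PFS. A predictive (rather than
#' merely prognostic) signature should lose significance on cohorts treated
#' with a different drug.
#'
#' @param model A fitted `ddpp_model`.
#' @param other_cohort A [ddpp_cohort()] covering the model genes.
#' @return List with `r`, `p`, `n`.
#' @export
cross_drug_test <- function(model, other_cohort) {
  assert_model(model)
  assert_fit_cohort(other_cohort)
  x <- model_scalar(model, other_cohort)
  pearson_with_p(x, other_cohort$patients$pfs_months)
}

#' Whole-transcriptome single-gene discovery scan
#'
#' Univariate Pearson (r, p) of every gene's feature against PFS, ranked by
#' decreasing `|r|` (ties: smaller p, then symbol); degenerate genes are
#' listed last with r = 0. Restricted to the panel genes this reproduces
#' the ranking of [rank_genes()] under the same channel.
#'
#' @param cohort A [ddpp_cohort()].
#' @param transcriptome Optional precomputed `ddpp_features`; by default
#'   built from the cohort's full gene universe with the given channel and
#'   mode.
#' @param feature_mode `"dual"` or `"tumor_only"`.
#' @param channel `"tumor"` or `"normal"`.
#' @param base Intensity log base.
#' @return data.frame `rank`, `gene`, `r`, `p`, `channel`, `degenerate`.
#' @export
transcriptome_scan <- function(cohort, transcriptome = NULL,
                               feature_mode = c("dual", "tumor_only"),
                               channel = c("tumor", "normal"), base = 1.1) {
  assert_fit_cohort(cohort)
  feature_mode <- match.arg(feature_mode)
  channel <- match.arg(channel)
  if (is.null(transcriptome)) {
    transcriptome <- build_feature_matrix(
      cohort,
      channel = channel, feature_mode = feature_mode, base = base
    )
  } else if (!inherits(transcriptome, "ddpp_features")) {
    ddpp_validation_error("transcriptome must be a ddpp_features object")
  }
  ids <- cohort$patients$patient_id
  if (!setequal(rownames(transcriptome$values), ids)) {
    ddpp_validation_error("feature matrix patients do not match the cohort")
  }
  pfs <- cohort$patients$pfs_months[
    match(rownames(transcriptome$values), ids)
  ]
  tab <- order_correlations(gene_correlations(transcriptome, pfs))
  tab <- cbind(rank = seq_len(nrow(tab)), tab)
  rownames(tab) <- NULL
  tab
}
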