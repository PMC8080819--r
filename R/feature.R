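ddpp_channels <- c("tumor", "normal")
ddpp_feature_modes <- c("dual", "tumor_only")

#' Per-gene expression feature
#'
#' In `dual` mode the feature for one gene in one patient is
#' `log2(tumor / normal) * log_base(channel intensity)` where the channel
#' intensity is the tumor or the normal RFU of that gene, and the intensity
#' log base defaults to 1.1. In `tumor_only` mode (single-biopsy ablation)
#' the feature is `log_base(tumor)` alone and `normal`/`channel_intensity`
#' are ignored.
#'
#' @param tumor,normal Strictly positive RFU intensities.
#' @param channel_intensity Strictly positive RFU of the chosen channel
#'   (tumor or normal) that multiplies the log2 fold change in `dual` mode.
#' @param feature_mode `"dual"` or `"tumor_only"`.
#' @param base Log base applied to the intensity term (default 1.1).
#' @return Numeric feature value(s); vectorized over the intensity inputs.
#' @export
compute_feature <- function(tumor, normal = NULL, channel_intensity = NULL,
                            feature_mode = c("dual", "tumor_only"),
                            base = 1.1) {
  feature_mode <- match.arg(feature_mode)
  stopifnot_scalar_number(base, "base", positive = TRUE)
  check_pos <- function(x, name) {
    if (is.null(x) || !is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
      ddpp_validation_error(sprintf("%s intensities must be finite and > 0", name))
    }
  }
  check_pos(tumor, "tumor")
  if (feature_mode == "tumor_only") {
    return(log(tumor) / log(base))
  }
  check_pos(normal, "normal")
  check_pos(channel_intensity, "channel")
  log2(tumor / normal) * log(channel_intensity) / log(base)
}

#' Build the patient-by-gene feature matrix
#'
#' Applies [compute_feature()] to every (patient, gene) pair of a cohort,
#' for the requested subset of genes (a panel or, by default, the whole
#' gene universe).
#'
#' @param cohort A [ddpp_cohort()].
#' @param genes Character vector of gene symbols (already resolved to the
#'   cohort universe), or `NULL` for all genes.
#' @param channel `"tumor"` or `"normal"`: which intensity multiplies the
#'   log2 fold change in `dual` mode.
#' @param feature_mode `"dual"` or `"tumor_only"`.
#' @param base Intensity log base (default 1.1).
#' @return A `ddpp_features` object: list with `values` (patients x genes
#'   matrix), `channel`, `feature_mode`, `base`, `gene_order`,
#'   `patient_order`.
#' @export
build_feature_matrix <- function(cohort, genes = NULL,
                                 channel = c("tumor", "normal"),
                                 feature_mode = c("dual", "tumor_only"),
                                 base = 1.1) {
  assert_cohort(cohort)
  channel <- match.arg(channel)
  feature_mode <- match.arg(feature_mode)
  universe <- cohort_genes(cohort)
  if (is.null(genes)) genes <- universe
  missing <- setdiff(genes, universe)
  if (length(missing)) ddpp_missing_gene_error(missing, "cohort gene universe")
  tum <- cohort$tumor[genes, , drop = FALSE]
  if (feature_mode == "tumor_only") {
    vals <- log(tum) / log(base)
  } else {
    nor <- cohort$normal[genes, , drop = FALSE]
    inten <- if (channel == "tumor") tum else nor
    vals <- log2(tum / nor) * log(inten) / log(base)
  }
  if (any(!is.finite(vals))) {
    ddpp_validation_error("non-finite feature value; check input intensities")
  }
  ddpp_features(
    values = t(vals), channel = channel,
    feature_mode = feature_mode, base = base
  )
}

#' Feature matrix container
#'
#' Wraps a patients x genes matrix of feature values with the metadata
#' (channel, feature mode, intensity log base) needed to reproduce it.
#' Used directly by the null-scan and discovery-scan operations, which also
#' accept externally constructed matrices (e.g. a simulated null).
#'
#' @param values Numeric matrix, patients in rows, genes in columns, both
#'   dimnames set.
#' @param channel,feature_mode,base Feature metadata (see
#'   [build_feature_matrix()]).
#' @return A `ddpp_features` object.
#' @export
ddpp_features <- function(values, channel = "tumor", feature_mode = "dual",
                          base = 1.1) {
  if (!is.matrix(values) || !is.numeric(values) ||
    is.null(rownames(values)) || is.null(colnames(values))) {
    ddpp_validation_error(
      "values must be a numeric matrix with patient rownames and gene colnames"
    )
  }
  if (any(!is.finite(values))) {
    ddpp_validation_error("feature values must be finite")
  }
  channel <- match.arg(channel, ddpp_channels)
  feature_mode <- match.arg(feature_mode, ddpp_feature_modes)
  structure(
    list(
      values = values, channel = channel, feature_mode = feature_mode,
      base = base, gene_order = colnames(values),
      patient_order = rownames(values)
    ),
    class = "ddpp_features"
  )
}

#' @export
print.ddpp_features <- function(x, ...) {
  cat(sprintf(
    "<ddpp_features> %d patients x %d genes (channel=%s, mode=%s, base=%g)\n",
    nrow(x$values), ncol(x$values), x$channel, x$feature_mode, x$base
  ))
  invisible(x)
}
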