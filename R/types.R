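#' Construct a paired tumor/normal cohort
#'
#' A cohort bundles, for one drug, the clinical outcome (PFS in months, with
#' censoring flags) and the paired expression measurements of every patient.
#' Intensities are relative fluorescence units (RFU) from a dual-color array
#' and must be strictly positive so that the log-ratio and log-intensity
#' features are defined. Censored PFS values are stored de-censored (the
#' value at censoring time) with `censored = TRUE` retained for annotation;
#' all computations use the de-censored value.
#'
#' @param drug Drug label (single string).
#' @param clinical `data.frame` with columns `patient_id`, `pfs_months`
#'   (positive, de-censored) and optionally `censored` (logical, default
#'   `FALSE`).
#' @param expression Named list, one element per patient id, each a
#'   `data.frame` with columns `gene`, `tumor_intensity`, `normal_intensity`.
#'   All patients must share the same gene universe.
#' @return An object of class `ddpp_cohort` with elements `drug`, `patients`
#'   (clinical data.frame), `tumor` and `normal` (gene x patient intensity
#'   matrices).
#' @export
ddpp_cohort <- function(drug, clinical, expression) {
  if (!is.character(drug) || length(drug) != 1L || !nzchar(drug)) {
    ddpp_validation_error("drug must be a non-empty string")
  }
  req <- c("patient_id", "pfs_months")
  if (!is.data.frame(clinical) || !all(req %in% names(clinical))) {
    ddpp_validation_error(
      "clinical must be a data.frame with columns patient_id, pfs_months"
    )
  }
  clinical$patient_id <- as.character(clinical$patient_id)
  if (anyDuplicated(clinical$patient_id)) {
    ddpp_validation_error("duplicate patient_id in clinical table")
  }
  if (is.null(clinical$censored)) clinical$censored <- FALSE
  clinical$censored <- as.logical(clinical$censored)
  pfs <- clinical$pfs_months
  if (!is.numeric(pfs) || any(!is.finite(pfs)) || any(pfs <= 0)) {
    ddpp_validation_error("pfs_months must be finite and strictly positive")
  }
  ids <- clinical$patient_id
  if (!is.list(expression) || is.null(names(expression))) {
    ddpp_validation_error("expression must be a named list of data.frames")
  }
  missing_expr <- setdiff(ids, names(expression))
  if (length(missing_expr)) {
    ddpp_validation_error(paste(
      "no expression data for patient(s):",
      paste(missing_expr, collapse = ", ")
    ))
  }
  universe <- NULL
  for (id in ids) {
    ex <- expression[[id]]
    cols <- c("gene", "tumor_intensity", "normal_intensity")
    if (!is.data.frame(ex) || !all(cols %in% names(ex))) {
      ddpp_parse_error(sprintf(
        "expression for patient %s lacks columns %s",
        id, paste(cols, collapse = ", ")
      ))
    }
    if (anyDuplicated(ex$gene)) {
      ddpp_parse_error(sprintf(
        "duplicate gene(s) for patient %s: %s", id,
        paste(unique(ex$gene[duplicated(ex$gene)]), collapse = ", ")
      ))
    }
    bad <- !is.finite(ex$tumor_intensity) | ex$tumor_intensity <= 0 |
      !is.finite(ex$normal_intensity) | ex$normal_intensity <= 0
    if (any(bad)) {
      ddpp_validation_error(sprintf(
        "non-positive intensity for patient %s, gene(s): %s", id,
        paste(ex$gene[bad], collapse = ", ")
      ))
    }
    if (is.null(universe)) {
      universe <- ex$gene
    } else if (!setequal(universe, ex$gene)) {
      ddpp_validation_error(sprintf(
        "patient %s does not share the cohort gene universe", id
      ))
    }
  }
  tumor <- matrix(NA_real_, length(universe), length(ids),
    dimnames = list(universe, ids)
  )
  normal <- tumor
  for (id in ids) {
    ex <- expression[[id]]
    tumor[ex$gene, id] <- ex$tumor_intensity
    normal[ex$gene, id] <- ex$normal_intensity
  }
  structure(
    list(
      drug = drug,
      patients = clinical[, c("patient_id", "pfs_months", "censored")],
      tumor = tumor,
      normal = normal
    ),
    class = "ddpp_cohort"
  )
}

#' @export
print.ddpp_cohort <- function(x, ...) {
  cat(sprintf(
    "<ddpp_cohort> drug=%s, %d patients, %d genes\n",
    x$drug, nrow(x$patients), nrow(x$tumor)
  ))
  invisible(x)
}

n_patients <- function(cohort) nrow(cohort$patients)

cohort_genes <- function(cohort) rownames(cohort$tumor)

#' Subset a cohort by patient id
#'
#' @param cohort A `ddpp_cohort`.
#' @param ids Character vector of patient ids to keep (order preserved).
#' @return A `ddpp_cohort` restricted to `ids`.
#' @export
cohort_subset <- function(cohort, ids) {
  assert_cohort(cohort)
  ids <- as.character(ids)
  missing <- setdiff(ids, cohort$patients$patient_id)
  if (length(missing)) {
    ddpp_validation_error(paste(
      "unknown patient id(s):", paste(missing, collapse = ", ")
    ))
  }
  keep <- match(ids, cohort$patients$patient_id)
  out <- cohort
  out$patients <- cohort$patients[keep, , drop = FALSE]
  rownames(out$patients) <- NULL
  out$tumor <- cohort$tumor[, ids, drop = FALSE]
  out$normal <- cohort$normal[, ids, drop = FALSE]
  out
}

assert_cohort <- function(cohort) {
  if (!inherits(cohort, "ddpp_cohort")) {
    ddpp_validation_error("expected a ddpp_cohort object")
  }
  invisible(cohort)
}

# Model fitting requires at least three patients; enforced at analysis time,
# not construction, so prediction-only cohorts of any size remain valid.
assert_fit_cohort <- function(cohort, min_n = 3L) {
  assert_cohort(cohort)
  if (n_patients(cohort) < min_n) {
    ddpp_validation_error(sprintf(
      "model fitting requires at least %d patients; cohort has %d",
      min_n, n_patients(cohort)
    ))
  }
  invisible(cohort)
}

#' Construct a drug gene panel
#'
#' An ordered list of literature-derived key genes for one drug, with an
#' optional alias map resolving panel symbols (often protein names, e.g.
#' `FKB-12`) to the symbols used in the expression data (e.g. `FKBP1A`).
#' Alias resolution is exact-match only; no fuzzy matching is performed.
#'
#' @param drug Drug label.
#' @param genes Character vector of unique, non-empty gene symbols
#'   (case-sensitive).
#' @param aliases Named character vector mapping panel symbol -> data symbol.
#' @param source Free-text provenance note.
#' @return An object of class `ddpp_panel`.
#' @export
ddpp_panel <- function(drug, genes, aliases = character(), source = "") {
  genes <- as.character(genes)
  if (!length(genes) || any(!nzchar(genes)) || anyDuplicated(genes)) {
    ddpp_validation_error("panel genes must be unique non-empty symbols")
  }
  aliases <- unlist(aliases)
  if (length(aliases) && is.null(names(aliases))) {
    ddpp_validation_error("aliases must be a named character vector")
  }
  structure(
    list(
      drug = as.character(drug), genes = genes,
      aliases = aliases, source = as.character(source)
    ),
    class = "ddpp_panel"
  )
}

#' @export
print.ddpp_panel <- function(x, ...) {
  cat(sprintf(
    "<ddpp_panel> drug=%s, %d genes: %s\n", x$drug, length(x$genes),
    paste(utils::head(x$genes, 8L), collapse = ", ")
  ))
  invisible(x)
}

# Map panel symbols onto the cohort's gene universe, applying the alias map
# for symbols absent from the universe. Hard error listing anything still
# unresolved: with cohorts this small, silent imputation would dominate the
# result.
resolve_panel_genes <- function(genes, universe, aliases = character()) {
  resolved <- ifelse(
    genes %in% universe, genes,
    ifelse(
      genes %in% names(aliases) & unname(aliases[genes]) %in% universe,
      unname(aliases[genes]), NA_character_
    )
  )
  if (anyNA(resolved)) {
    ddpp_missing_gene_error(genes[is.na(resolved)], "cohort gene universe")
  }
  if (anyDuplicated(resolved)) {
    ddpp_validation_error("alias resolution produced duplicate gene symbols")
  }
  resolved
}
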