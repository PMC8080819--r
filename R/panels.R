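# Packaged drug panels and published predictor equations, shipped as JSON
# under inst/extdata and cached per session.

.ddpp_data_cache <- new.env(parent = emptyenv())

load_extdata_json <- function(file) {
  if (!exists(file, envir = .ddpp_data_cache)) {
    path <- system.file("extdata", file, package = "ddpp")
    if (!nzchar(path)) {
      # devtools::load_all() fallback
      path <- file.path("inst", "extdata", file)
    }
    assign(
      file, jsonlite::read_json(path, simplifyVector = TRUE),
      envir = .ddpp_data_cache
    )
  }
  get(file, envir = .ddpp_data_cache)
}

normalize_drug_key <- function(drug, keys) {
  d <- tolower(gsub("[^a-z0-9]+", "", tolower(drug)))
  k <- tolower(gsub("[^a-z0-9]+", "", tolower(keys)))
  synonyms <- c(
    "fgfrinhibitor" = "fgfr", "fgfrinhibitors" = "fgfr",
    "antipd1" = "antipd1", "antipdl1" = "antipd1", "io" = "antipd1",
    "pembrolizumab" = "antipd1", "nivolumab" = "antipd1",
    "atezolizumab" = "antipd1"
  )
  if (d %in% names(synonyms)) d <- unname(synonyms[d])
  hit <- match(d, k)
  if (is.na(hit)) {
    ddpp_validation_error(sprintf(
      "unknown drug '%s'; available: %s", drug, paste(keys, collapse = ", ")
    ))
  }
  keys[hit]
}

#' Available packaged drug keys
#'
#' @return Character vector of drug keys accepted by [get_panel()] and
#'   [published_model()].
#' @export
available_drugs <- function() names(load_extdata_json("panels.json"))

#' Packaged literature gene panel for a drug
#'
#' Returns the full literature-derived key-gene panel shipped with the
#' package: everolimus (17 mTOR-pathway genes), axitinib (13 angiogenesis
#' genes), trametinib (13 MAPK-cascade genes), afatinib (13 HER-family
#' receptors/ligands), fgfr (19 FGFR/FGF genes) and anti-PD-1 (12
#' immuno-oncology genes). Drug keys are matched case-insensitively and
#' common synonyms (e.g. "FGFR-inhibitor", "pembrolizumab") are accepted.
#'
#' @param drug One of [available_drugs()].
#' @return A [ddpp_panel()].
#' @export
get_panel <- function(drug) {
  panels <- load_extdata_json("panels.json")
  key <- normalize_drug_key(drug, names(panels))
  p <- panels[[key]]
  ddpp_panel(
    drug = p$drug, genes = p$genes,
    aliases = unlist(p$aliases), source = p$source
  )
}

#' Published predictor equation for a drug
#'
#' The six published linear predictors (slope, intercept, ordered gene
#' subset, summation method, channel) with constants exactly as printed.
#' The returned `ddpp_model` can be applied to new cohorts with
#' [predict_pfs()] or [cross_drug_test()]; its training statistics are not
#' part of the published constants and are `NA`.
#'
#' @param drug One of [available_drugs()].
#' @return A `ddpp_model`.
#' @export
published_model <- function(drug) {
  models <- load_extdata_json("published_models.json")
  key <- normalize_drug_key(drug, names(models))
  m <- models[[key]]
  ddpp_model(
    drug = m$drug, channel = m$channel, feature_mode = "dual",
    genes = m$genes, method = m$method,
    slope = m$slope, intercept = m$intercept
  )
}

#' Packaged clinical outcome fixture
#'
#' The per-patient clinical table (patient id, drug, PFS in months,
#' censoring flag) of the 23 trial patients packaged with the tool, parsed
#' with the same reader as user-supplied clinical files ("X+" PFS values
#' are stored de-censored with `censored = TRUE`).
#'
#' @param drug Optional drug key to filter on.
#' @return data.frame `patient_id`, `drug`, `pfs_months`, `censored`.
#' @export
winther_clinical <- function(drug = NULL) {
  path <- system.file("extdata", "winther_clinical.csv", package = "ddpp")
  if (!nzchar(path)) path <- file.path("inst", "extdata", "winther_clinical.csv")
  tab <- read_clinical_table(path)
  if (!is.null(drug)) {
    key <- normalize_drug_key(drug, available_drugs())
    tab <- tab[tab$drug == key, , drop = FALSE]
    rownames(tab) <- NULL
  }
  tab
}
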