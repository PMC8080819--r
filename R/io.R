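# Readers and writers for the plain-text interchange formats: expression
# CSV/TSV (long or wide), clinical CSV, panel JSON, model JSON, report JSON.
# Comma-separated UTF-8 with a header row; tab separation by .tsv extension.

table_sep <- function(path) {
  if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
}

read_delim_checked <- function(path) {
  if (!file.exists(path)) ddpp_parse_error(paste("file not found:", path))
  read.csv(
    path,
    sep = table_sep(path), check.names = FALSE,
    stringsAsFactors = FALSE, colClasses = "character"
  )
}

parse_numeric <- function(x, what) {
  out <- suppressWarnings(as.numeric(x))
  if (anyNA(out)) {
    ddpp_parse_error(sprintf(
      "non-numeric %s value(s): %s", what,
      paste(unique(x[is.na(out)]), collapse = ", ")
    ))
  }
  out
}

#' Read a paired expression table
#'
#' Accepts two dialects, auto-detected from the header:
#' * long: columns `patient_id, gene, tumor_intensity, normal_intensity`;
#' * wide: a `gene` column plus one `<patient>_tumor` / `<patient>_normal`
#'   column pair per patient.
#'
#' All intensities must parse as strictly positive reals and gene symbols
#' must be unique within each patient.
#'
#' @param path CSV (or `.tsv`) file with a header row.
#' @return Named list mapping patient id to a `data.frame` with columns
#'   `gene`, `tumor_intensity`, `normal_intensity`.
#' @export
read_expression_table <- function(path) {
  tab <- read_delim_checked(path)
  long_cols <- c("patient_id", "gene", "tumor_intensity", "normal_intensity")
  if (all(long_cols %in% names(tab))) {
    return(expression_from_long(tab))
  }
  if ("gene" %in% names(tab)) {
    other <- setdiff(names(tab), "gene")
    tum <- grep("_tumor$", other, value = TRUE)
    nor <- grep("_normal$", other, value = TRUE)
    ids <- sub("_tumor$", "", tum)
    if (length(ids) && setequal(ids, sub("_normal$", "", nor)) &&
      length(tum) + length(nor) == length(other)) {
      return(expression_from_wide(tab, ids))
    }
  }
  ddpp_parse_error(paste0(
    "unrecognized expression table header in ", path,
    "; expected long columns (patient_id, gene, tumor_intensity, ",
    "normal_intensity) or wide columns (gene, <id>_tumor, <id>_normal)"
  ))
}

expression_from_long <- function(tab) {
  tab$tumor_intensity <- parse_numeric(tab$tumor_intensity, "tumor intensity")
  tab$normal_intensity <- parse_numeric(
    tab$normal_intensity, "normal intensity"
  )
  out <- lapply(split(tab, tab$patient_id), function(d) {
    validate_patient_expression(
      data.frame(
        gene = d$gene, tumor_intensity = d$tumor_intensity,
        normal_intensity = d$normal_intensity, stringsAsFactors = FALSE
      ),
      d$patient_id[1L]
    )
  })
  out[unique(tab$patient_id)]
}

expression_from_wide <- function(tab, ids) {
  out <- lapply(ids, function(id) {
    validate_patient_expression(
      data.frame(
        gene = tab$gene,
        tumor_intensity = parse_numeric(
          tab[[paste0(id, "_tumor")]], "tumor intensity"
        ),
        normal_intensity = parse_numeric(
          tab[[paste0(id, "_normal")]], "normal intensity"
        ),
        stringsAsFactors = FALSE
      ),
      id
    )
  })
  names(out) <- ids
  out
}

validate_patient_expression <- function(d, patient_id) {
  if (anyDuplicated(d$gene)) {
    ddpp_parse_error(sprintf(
      "duplicate gene(s) for patient %s: %s", patient_id,
      paste(unique(d$gene[duplicated(d$gene)]), collapse = ", ")
    ))
  }
  bad <- d$tumor_intensity <= 0 | d$normal_intensity <= 0 |
    !is.finite(d$tumor_intensity) | !is.finite(d$normal_intensity)
  if (any(bad)) {
    ddpp_validation_error(sprintf(
      "non-positive intensity for patient %s, gene(s): %s", patient_id,
      paste(d$gene[bad], collapse = ", ")
    ))
  }
  rownames(d) <- NULL
  d
}

#' Write a cohort's expression in long format
#'
#' @param cohort A [ddpp_cohort()].
#' @param path Output CSV (or `.tsv`) path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(cohort, path) {
  assert_cohort(cohort)
  ids <- cohort$patients$patient_id
  genes <- cohort_genes(cohort)
  long <- data.frame(
    patient_id = rep(ids, each = length(genes)),
    gene = rep(genes, times = length(ids)),
    tumor_intensity = as.vector(cohort$tumor),
    normal_intensity = as.vector(cohort$normal),
    stringsAsFactors = FALSE
  )
  write.table(
    long, path,
    sep = table_sep(path), row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Read a clinical outcome table
#'
#' Requires columns `patient_id`, `drug`, `pfs_months`; a `censored`
#' column (logical or 0/1) is optional. A `pfs_months` value with a `+`
#' suffix (e.g. `"60.0+"`) is parsed as the value at censoring time with
#' `censored = TRUE` — censored PFS is stored de-censored for all
#' computations, with the flag retained for annotation.
#'
#' @param path CSV (or `.tsv`) file with a header row.
#' @return data.frame `patient_id`, `drug`, `pfs_months`, `censored`.
#' @export
read_clinical_table <- function(path) {
  tab <- read_delim_checked(path)
  req <- c("patient_id", "drug", "pfs_months")
  if (!all(req %in% names(tab))) {
    ddpp_parse_error(paste(
      "clinical table must have columns:", paste(req, collapse = ", ")
    ))
  }
  pfs_raw <- trimws(tab$pfs_months)
  plus <- grepl("\\+$", pfs_raw)
  pfs <- parse_numeric(sub("\\+$", "", pfs_raw), "pfs_months")
  censored <- plus
  if ("censored" %in% names(tab)) {
    censored <- censored | tab$censored %in% c("TRUE", "true", "1", "yes")
  }
  data.frame(
    patient_id = as.character(tab$patient_id),
    drug = as.character(tab$drug),
    pfs_months = pfs, censored = censored,
    stringsAsFactors = FALSE
  )
}

#' Write a clinical table
#'
#' Censored rows are written with the `+` suffix convention understood by
#' [read_clinical_table()].
#'
#' @param clinical data.frame `patient_id`, `drug`, `pfs_months`,
#'   `censored`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_clinical_table <- function(clinical, path) {
  num <- vapply(clinical$pfs_months, function(v) sprintf("%.17g", v), "")
  pfs <- ifelse(isTRUE_vec(clinical$censored), paste0(num, "+"), num)
  out <- data.frame(
    patient_id = clinical$patient_id, drug = clinical$drug,
    pfs_months = pfs, stringsAsFactors = FALSE
  )
  write.table(
    out, path,
    sep = table_sep(path), row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

isTRUE_vec <- function(x) !is.null(x) & as.logical(x) %in% TRUE

#' Assemble a one-drug cohort from expression and clinical files
#'
#' @param expression_path Expression table (see [read_expression_table()]).
#' @param clinical_path Clinical table (see [read_clinical_table()]).
#' @param drug Drug to select from the clinical table; every selected
#'   patient must be present in the expression table.
#' @return A [ddpp_cohort()].
#' @export
read_cohort <- function(expression_path, clinical_path, drug) {
  clin <- read_clinical_table(clinical_path)
  clin <- clin[clin$drug == drug, , drop = FALSE]
  if (!nrow(clin)) {
    ddpp_validation_error(sprintf("no patients with drug '%s'", drug))
  }
  expr <- read_expression_table(expression_path)
  ddpp_cohort(drug, clin, expr)
}

#' Read a gene panel from JSON
#'
#' Schema: `{"drug": str, "genes": [...], "aliases": {panel: data},
#' "source": str}`.
#'
#' @param path JSON file.
#' @return A [ddpp_panel()].
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) ddpp_parse_error(paste("file not found:", path))
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(p$drug) || is.null(p$genes)) {
    ddpp_parse_error("panel JSON must have fields 'drug' and 'genes'")
  }
  ddpp_panel(
    drug = p$drug, genes = p$genes,
    aliases = unlist(p$aliases),
    source = if (is.null(p$source)) "" else p$source
  )
}

#' Write a gene panel to JSON
#'
#' @param panel A [ddpp_panel()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  if (!inherits(panel, "ddpp_panel")) {
    ddpp_validation_error("expected a ddpp_panel")
  }
  jsonlite::write_json(
    list(
      drug = panel$drug, genes = panel$genes,
      aliases = as.list(panel$aliases), source = panel$source
    ),
    path,
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(path)
}

#' Serialize a fitted model to JSON
#'
#' @param model A `ddpp_model`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  assert_model(model)
  jsonlite::write_json(
    unclass(model)[c(
      "drug", "channel", "feature_mode", "genes", "method", "slope",
      "intercept", "train_r", "train_p", "n_train", "base"
    )],
    path,
    auto_unbox = TRUE, pretty = TRUE, digits = NA, na = "null"
  )
  invisible(path)
}

#' Read a fitted model from JSON
#'
#' @param path JSON file written by [write_model()].
#' @return A `ddpp_model`.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) ddpp_parse_error(paste("file not found:", path))
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  null2na <- function(x) if (is.null(x)) NA_real_ else x
  ddpp_model(
    drug = m$drug, channel = m$channel, feature_mode = m$feature_mode,
    genes = m$genes, method = m$method,
    slope = m$slope, intercept = m$intercept,
    train_r = null2na(m$train_r), train_p = null2na(m$train_p),
    n_train = null2na(m$n_train),
    base = if (is.null(m$base)) 1.1 else m$base
  )
}

#' Serialize a leave-one-out validation report to JSON
#'
#' @param report A `ddpp_validation`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  if (!inherits(report, "ddpp_validation")) {
    ddpp_validation_error("expected a ddpp_validation")
  }
  out <- unclass(report)
  jsonlite::write_json(
    out, path,
    auto_unbox = TRUE, pretty = TRUE, digits = NA, dataframe = "rows",
    na = "null"
  )
  invisible(path)
}

#' Serialize a null-scan result to JSON
#'
#' @param scan A `ddpp_null_scan`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_null_scan <- function(scan, path) {
  if (!inherits(scan, "ddpp_null_scan")) {
    ddpp_validation_error("expected a ddpp_null_scan")
  }
  jsonlite::write_json(
    list(
      panel_size = scan$panel_size, iterations = scan$iterations,
      seed = scan$seed, method = scan$method,
      threshold = list(
        min_abs_r = scan$threshold$min_abs_r, max_p = scan$threshold$max_p
      ),
      n_significant = scan$n_significant,
      n_degenerate = scan$n_degenerate,
      proportion = scan$proportion_significant
    ),
    path,
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(path)
}
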