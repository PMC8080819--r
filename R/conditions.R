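# Condition constructors. Every user-facing failure is a classed condition so
# callers (CLI, scans, leave-one-out folds) can react without string matching.

ddpp_error <- function(msg, class, ...) {
  stop(errorCondition(msg, class = c(class, "ddpp_error"), ...))
}

ddpp_parse_error <- function(msg, ...) ddpp_error(msg, "ddpp_parse_error", ...)

ddpp_validation_error <- function(msg, ...) {
  ddpp_error(msg, "ddpp_validation_error", ...)
}

# zero-variance vector, constant PFS, all-degenerate selection table, ...
ddpp_degenerate_error <- function(msg, ...) {
  ddpp_error(msg, c("ddpp_degenerate_error", "ddpp_validation_error"), ...)
}

ddpp_missing_gene_error <- function(genes, where) {
  ddpp_error(
    sprintf(
      "gene(s) not found in %s: %s", where,
      paste(genes, collapse = ", ")
    ),
    c("ddpp_missing_gene_error", "ddpp_validation_error"),
    genes = genes
  )
}

ddpp_usage_error <- function(msg, ...) ddpp_error(msg, "ddpp_usage_error", ...)

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    ddpp_validation_error(sprintf("%s must be a single finite number", name))
  }
  if (positive && x <= 0) {
    ddpp_validation_error(sprintf("%s must be strictly positive", name))
  }
  invisible(x)
}
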