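#' Step-in prefix selection of the optimal gene subset and summation method
#'
#' For K = 1..panel size, forms the prefix of the ranked gene list, collapses
#' each patient's K feature values with every requested summation method,
#' and correlates the resulting scalar with PFS. The best cell of the
#' K x method table is the one with maximal `|r|`; exact ties prefer the
#' smaller K (parsimony) and then the canonical method order
#' `sum, mean, median, fold, fold_abs`. Degenerate cells (zero-variance
#' scalar) are recorded with `NA` correlation and never selected; if every
#' cell is degenerate an error is raised.
#'
#' @inheritParams rank_genes
#' @param methods Subset of [ddpp_methods()] to consider.
#' @return A `ddpp_selection` object: list with `channel`, `ranking`,
#'   `table` (data.frame `K`, `method`, `r`, `p`, `degenerate`), `best_k`,
#'   `best_method`, `best_r`, `best_p`, `feature_mode`, `base`.
#' @export
stepin_select <- function(cohort, panel,
                          feature_mode = c("dual", "tumor_only"),
                          methods = ddpp_methods(), base = 1.1) {
  assert_fit_cohort(cohort)
  feature_mode <- match.arg(feature_mode)
  methods <- match.arg(methods, ddpp_methods_all, several.ok = TRUE)
  ranked <- rank_genes(cohort, panel, feature_mode = feature_mode, base = base)
  fm <- build_feature_matrix(
    cohort, ranked$ranking$gene,
    channel = ranked$channel, feature_mode = feature_mode, base = base
  )
  pfs <- cohort$patients$pfs_months
  ngene <- nrow(ranked$ranking)
  grid <- expand.grid(
    K = seq_len(ngene), method = methods,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  r <- rep(NA_real_, nrow(grid))
  p <- rep(NA_real_, nrow(grid))
  degenerate <- logical(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    vals <- fm$values[, seq_len(grid$K[i]), drop = FALSE]
    x <- summate_rows(vals, grid$method[i])
    if (any(!is.finite(x))) {
      ddpp_validation_error(sprintf(
        "summation '%s' overflowed at K=%d", grid$method[i], grid$K[i]
      ))
    }
    res <- tryCatch(
      pearson_with_p(x, pfs),
      ddpp_degenerate_error = function(e) NULL
    )
    if (is.null(res)) {
      degenerate[i] <- TRUE
    } else {
      r[i] <- res$r
      p[i] <- res$p
    }
  }
  tab <- data.frame(
    K = grid$K, method = grid$method, r = r, p = p,
    degenerate = degenerate, stringsAsFactors = FALSE
  )
  ok <- !tab$degenerate
  if (!any(ok)) {
    ddpp_degenerate_error("every K x method cell is degenerate")
  }
  cand <- tab[ok, , drop = FALSE]
  ord <- order(
    -abs(cand$r), cand$K, match(cand$method, ddpp_methods_all)
  )
  best <- cand[ord[1L], ]
  structure(
    list(
      channel = ranked$channel, ranking = ranked$ranking, table = tab,
      best_k = best$K, best_method = best$method,
      best_r = best$r, best_p = best$p,
      feature_mode = feature_mode, base = base
    ),
    class = "ddpp_selection"
  )
}

#' @export
print.ddpp_selection <- function(x, ...) {
  cat(sprintf(
    "<ddpp_selection> channel=%s, best: K=%d, method=%s, r=%.4g, p=%.4g\n",
    x$channel, x$best_k, x$best_method, x$best_r, x$best_p
  ))
  cat(
    "  prefix:",
    paste(x$ranking$gene[seq_len(x$best_k)], collapse = ", "), "\n"
  )
  invisible(x)
}

#' Export a selection table as CSV
#'
#' Writes the K x method grid (`K,method,r,p`) of a [stepin_select()]
#' result.
#'
#' @param selection A `ddpp_selection`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_selection_table <- function(selection, path) {
  if (!inherits(selection, "ddpp_selection")) {
    ddpp_validation_error("expected a ddpp_selection")
  }
  write.csv(
    selection$table[, c("K", "method", "r", "p")],
    path,
    row.names = FALSE
  )
  invisible(path)
}
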