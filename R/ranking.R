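# Per-gene Pearson (r, p) for every column of a feature matrix against PFS.
# Degenerate genes (zero feature variance) are recorded with r = 0, p = 1
# and flagged instead of raising, so scans over thousands of genes survive
# flat probes.
gene_correlations <- function(features, pfs) {
  vals <- features$values
  genes <- colnames(vals)
  r <- numeric(length(genes))
  p <- numeric(length(genes))
  degenerate <- logical(length(genes))
  for (j in seq_along(genes)) {
    res <- tryCatch(
      pearson_with_p(vals[, j], pfs),
      ddpp_degenerate_error = function(e) NULL
    )
    if (is.null(res)) {
      r[j] <- 0
      p[j] <- 1
      degenerate[j] <- TRUE
    } else {
      r[j] <- res$r
      p[j] <- res$p
    }
  }
  data.frame(
    gene = genes, r = r, p = p, channel = features$channel,
    degenerate = degenerate, stringsAsFactors = FALSE
  )
}

# Deterministic ranking: decreasing |r|, ties by ascending p then gene
# symbol; degenerate genes always last. For fixed n the |r| and p orderings
# coincide, so |r| serves as the primary key.
order_correlations <- function(tab) {
  ord <- order(tab$degenerate, -abs(tab$r), tab$p, tab$gene)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Rank panel genes by correlation with PFS and choose the channel
#'
#' Computes per-gene Pearson correlations between the feature and PFS under
#' both intensity channels (tumor and normal), picks the channel that
#' contains the single most correlated gene (max `|r|`, ties by smaller p,
#' then by channel order tumor before normal), and returns all panel genes
#' ranked under that channel by decreasing `|r|` (ties: smaller p, then
#' lexicographic symbol). In `tumor_only` mode only the tumor channel
#' exists. The channel decision is made once per drug model and then applied
#' to every gene.
#'
#' @param cohort A [ddpp_cohort()] with at least 3 patients.
#' @param panel A [ddpp_panel()] or character vector of gene symbols.
#' @param feature_mode `"dual"` or `"tumor_only"`.
#' @param base Intensity log base (default 1.1).
#' @return List with `channel` and `ranking` (data.frame `gene`, `r`, `p`,
#'   `channel`, `degenerate`, plus `panel_gene` holding the unresolved panel
#'   symbol).
#' @export
rank_genes <- function(cohort, panel, feature_mode = c("dual", "tumor_only"),
                       base = 1.1) {
  assert_fit_cohort(cohort)
  feature_mode <- match.arg(feature_mode)
  pg <- resolve_panel(cohort, panel)
  pfs <- cohort$patients$pfs_months
  if (length(unique(pfs)) == 1L) {
    ddpp_degenerate_error("PFS is constant across the cohort")
  }
  channels <- if (feature_mode == "tumor_only") "tumor" else ddpp_channels
  per_channel <- lapply(channels, function(ch) {
    fm <- build_feature_matrix(
      cohort, pg$resolved,
      channel = ch, feature_mode = feature_mode, base = base
    )
    order_correlations(gene_correlations(fm, pfs))
  })
  names(per_channel) <- channels
  # channel of the single best gene wins (tumor first on exact ties)
  best_per <- vapply(per_channel, function(tab) {
    c(abs(tab$r[1L]), tab$p[1L])
  }, numeric(2))
  pick <- order(-best_per[1L, ], best_per[2L, ])[1L]
  channel <- channels[pick]
  ranking <- per_channel[[channel]]
  ranking$panel_gene <- pg$panel[match(ranking$gene, pg$resolved)]
  list(channel = channel, ranking = ranking)
}

resolve_panel <- function(cohort, panel) {
  if (inherits(panel, "ddpp_panel")) {
    genes <- panel$genes
    aliases <- panel$aliases
  } else if (is.character(panel)) {
    genes <- panel
    aliases <- character()
  } else {
    ddpp_validation_error("panel must be a ddpp_panel or character vector")
  }
  if (!length(genes)) ddpp_validation_error("panel is empty")
  list(
    panel = genes,
    resolved = resolve_panel_genes(genes, cohort_genes(cohort), aliases)
  )
}
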