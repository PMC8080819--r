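# Build a small cohort directly from intensity matrices (genes x patients).
toy_cohort <- function(tumor, normal, pfs, drug = "toy", censored = NULL) {
  ids <- colnames(tumor)
  if (is.null(ids)) {
    ids <- paste0("P", seq_len(ncol(tumor)))
    colnames(tumor) <- colnames(normal) <- ids
  }
  genes <- rownames(tumor)
  expression <- lapply(stats::setNames(ids, ids), function(id) {
    data.frame(
      gene = genes, tumor_intensity = tumor[, id],
      normal_intensity = normal[, id], stringsAsFactors = FALSE
    )
  })
  ddpp_cohort(
    drug,
    data.frame(
      patient_id = ids, pfs_months = pfs,
      censored = if (is.null(censored)) FALSE else censored,
      stringsAsFactors = FALSE
    ),
    expression
  )
}

# random positive-intensity cohort with no planted structure
random_cohort <- function(n_genes = 12, n_patients = 6, seed = 1,
                          drug = "toy") {
  set.seed(seed)
  genes <- paste0("G", seq_len(n_genes))
  ids <- paste0("P", seq_len(n_patients))
  tumor <- matrix(
    exp(rnorm(n_genes * n_patients, 6, 1)), n_genes, n_patients,
    dimnames = list(genes, ids)
  )
  normal <- matrix(
    exp(rnorm(n_genes * n_patients, 6, 1)), n_genes, n_patients,
    dimnames = list(genes, ids)
  )
  toy_cohort(tumor, normal, pfs = runif(n_patients, 1, 40), drug = drug)
}
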