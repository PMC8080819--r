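test_that("rank_genes equals a brute-force per-gene Pearson sort", {
  co <- random_cohort(n_genes = 10, n_patients = 6, seed = 5)
  panel <- cohort_genes(co)
  ranked <- rank_genes(co, panel)
  pfs <- co$patients$pfs_months
  # brute force: both channels, channel of the single best gene wins
  brute <- lapply(c("tumor", "normal"), function(ch) {
    inten <- if (ch == "tumor") co$tumor else co$normal
    r <- vapply(panel, function(g) {
      oracle_pearson_r(
        log2(co$tumor[g, ] / co$normal[g, ]) * log(inten[g, ]) / log(1.1),
        pfs
      )
    }, 1.0)
    r
  })
  names(brute) <- c("tumor", "normal")
  best_ch <- names(which.max(vapply(brute, function(r) max(abs(r)), 1.0)))
  expect_identical(ranked$channel, best_ch)
  expect_identical(
    ranked$ranking$gene,
    names(sort(-abs(brute[[best_ch]])))
  )
  expect_equal(
    ranked$ranking$r,
    unname(brute[[best_ch]][ranked$ranking$gene]),
    tolerance = 1e-10
  )
})

test_that("a perfectly linear gene ranks first with |r| = 1", {
  pfs <- c(2, 5, 9, 14, 20)
  tum <- matrix(
    exp(rnorm(15, 6, 0.5)), 3, 5,
    dimnames = list(c("HIT", "N1", "N2"), paste0("P", 1:5))
  )
  nor <- tum # zero fold change everywhere...
  # ...except HIT, whose dual feature is made proportional to PFS
  nor["HIT", ] <- tum["HIT", ] / 2^(pfs / (log(tum["HIT", ]) / log(1.1)))
  nor["N1", ] <- nor["N1", ] * exp(rnorm(5, 0, 0.01))
  nor["N2", ] <- nor["N2", ] * exp(rnorm(5, 0, 0.01))
  co <- toy_cohort(tum, nor, pfs)
  ranked <- rank_genes(co, c("N1", "HIT", "N2"))
  expect_identical(ranked$ranking$gene[1], "HIT")
  expect_equal(abs(ranked$ranking$r[1]), 1, tolerance = 1e-9)
})

test_that("degenerate genes rank last with r = 0 and a flag", {
  pfs <- c(1, 4, 9, 12)
  tum <- matrix(
    exp(rnorm(8, 6, 0.5)), 2, 4,
    dimnames = list(c("FLAT", "OK"), paste0("P", 1:4))
  )
  nor <- tum
  nor["OK", ] <- tum["OK", ] * exp(rnorm(4, 0, 0.3))
  co <- toy_cohort(tum, nor, pfs) # FLAT has zero fold change -> F == 0
  ranked <- rank_genes(co, c("FLAT", "OK"))
  tail_row <- ranked$ranking[nrow(ranked$ranking), ]
  expect_identical(tail_row$gene, "FLAT")
  expect_true(tail_row$degenerate)
  expect_identical(tail_row$r, 0)
})

test_that("single-gene panels reduce step-in to the univariate correlation", {
  co <- random_cohort(n_genes = 5, n_patients = 6, seed = 9)
  sel <- stepin_select(co, "G3")
  ranked <- rank_genes(co, "G3")
  expect_identical(sel$best_k, 1L)
  fm <- build_feature_matrix(co, "G3", channel = sel$channel)
  f <- fm$values[, 1]
  pfs <- co$patients$pfs_months
  # every non-absolute method's K=1 scalar IS the feature, so its
  # correlation equals the univariate gene correlation exactly
  for (m in c("sum", "mean", "median", "fold")) {
    cell <- sel$table[sel$table$K == 1 & sel$table$method == m, ]
    expect_equal(cell$r, ranked$ranking$r[1], tolerance = 1e-10)
  }
  # fold_abs folds the sign into the feature first
  cell <- sel$table[sel$table$K == 1 & sel$table$method == "fold_abs", ]
  expect_equal(cell$r, oracle_pearson_r(abs(f), pfs), tolerance = 1e-10)
  expect_equal(
    abs(sel$best_r),
    max(abs(ranked$ranking$r[1]), abs(oracle_pearson_r(abs(f), pfs))),
    tolerance = 1e-10
  )
})

test_that("step-in selection table matches brute-force recomputation", {
  co <- random_cohort(n_genes = 6, n_patients = 6, seed = 13)
  panel <- cohort_genes(co)
  sel <- stepin_select(co, panel)
  fm <- build_feature_matrix(co, sel$ranking$gene, channel = sel$channel)
  pfs <- co$patients$pfs_months
  for (i in seq_len(nrow(sel$table))) {
    K <- sel$table$K[i]
    m <- sel$table$method[i]
    x <- apply(fm$values[, seq_len(K), drop = FALSE], 1, function(v) {
      switch(m,
        sum = sum(v), mean = mean(v), median = stats::median(v),
        fold = prod(v), fold_abs = prod(abs(v))
      )
    })
    expect_equal(sel$table$r[i], oracle_pearson_r(x, pfs), tolerance = 1e-10)
  }
  best <- sel$table[!sel$table$degenerate, ]
  expect_equal(abs(sel$best_r), max(abs(best$r)), tolerance = 1e-12)
  expect_lte(sel$best_k, length(panel))
})

test_that("step-in selection is invariant to patient and panel order", {
  co <- random_cohort(n_genes = 8, n_patients = 6, seed = 21)
  panel <- cohort_genes(co)
  sel <- stepin_select(co, panel)
  set.seed(1)
  co2 <- cohort_subset(co, sample(co$patients$patient_id))
  sel2 <- stepin_select(co2, sample(panel))
  expect_identical(sel2$channel, sel$channel)
  expect_identical(sel2$ranking$gene, sel$ranking$gene)
  expect_identical(sel2$best_k, sel$best_k)
  expect_identical(sel2$best_method, sel$best_method)
  expect_equal(sel2$best_r, sel$best_r, tolerance = 1e-12)
})

test_that("constant PFS raises instead of returning NaN", {
  co <- random_cohort(n_genes = 4, n_patients = 4, seed = 3)
  co$patients$pfs_months <- rep(5, 4)
  expect_error(
    stepin_select(co, cohort_genes(co)),
    class = "ddpp_degenerate_error"
  )
})

test_that("panel aliases resolve against the cohort universe", {
  co <- random_cohort(n_genes = 4, n_patients = 5, seed = 8)
  panel <- ddpp_panel("toy", c("ALPHA", "G2"), aliases = c(ALPHA = "G1"))
  ranked <- rank_genes(co, panel)
  expect_setequal(ranked$ranking$gene, c("G1", "G2"))
  expect_identical(
    ranked$ranking$panel_gene[ranked$ranking$gene == "G1"], "ALPHA"
  )
  bad <- ddpp_panel("toy", c("NOPE", "G2"))
  err <- expect_error(
    rank_genes(co, bad),
    class = "ddpp_missing_gene_error"
  )
  expect_match(conditionMessage(err), "NOPE")
})
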