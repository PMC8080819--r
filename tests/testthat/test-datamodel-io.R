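test_that("long-format expression tables parse and preserve counts", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "patient_id,gene,tumor_intensity,normal_intensity",
    "P1,A,10,20", "P1,B,5,5", "P1,C,1.5,3",
    "P2,A,8,2", "P2,B,4,4", "P2,C,9,1"
  ), path)
  expr <- read_expression_table(path)
  expect_named(expr, c("P1", "P2"))
  expect_equal(vapply(expr, nrow, 1L), c(P1 = 3L, P2 = 3L))
  expect_equal(expr$P2$tumor_intensity[expr$P2$gene == "C"], 9)
})

test_that("wide-format expression tables are auto-detected", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "gene,P1_tumor,P1_normal,P2_tumor,P2_normal",
    "A,10,20,8,2", "B,5,5,4,4"
  ), path)
  expr <- read_expression_table(path)
  expect_named(expr, c("P1", "P2"))
  expect_equal(expr$P1$normal_intensity, c(20, 5))
  expect_equal(expr$P2$tumor_intensity, c(8, 4))
})

test_that("expression parsing rejects bad input with named culprits", {
  zero <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "patient_id,gene,tumor_intensity,normal_intensity",
    "P1,A,0,20", "P1,B,5,5"
  ), zero)
  err <- expect_error(
    read_expression_table(zero),
    class = "ddpp_validation_error"
  )
  expect_match(conditionMessage(err), "A")
  expect_match(conditionMessage(err), "P1")

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "patient_id,gene,tumor_intensity,normal_intensity",
    "P1,A,1,2", "P1,A,3,4"
  ), dup)
  err <- expect_error(read_expression_table(dup), class = "ddpp_parse_error")
  expect_match(conditionMessage(err), "A")

  bad_header <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("foo,bar", "1,2"), bad_header)
  expect_error(read_expression_table(bad_header), class = "ddpp_parse_error")
})

test_that("expression round-trip reproduces values to 1e-12", {
  sim <- generate_cohort(generator_config(seed = 7, n_genes = 20))
  path <- withr::local_tempfile(fileext = ".csv")
  write_expression_table(sim$cohort, path)
  expr <- read_expression_table(path)
  for (id in sim$cohort$patients$patient_id) {
    got <- expr[[id]]
    expect_equal(
      got$tumor_intensity[match(cohort_genes(sim$cohort), got$gene)],
      unname(sim$cohort$tumor[, id]),
      tolerance = 1e-12
    )
    expect_equal(
      got$normal_intensity[match(cohort_genes(sim$cohort), got$gene)],
      unname(sim$cohort$normal[, id]),
      tolerance = 1e-12
    )
  }
})

test_that("clinical tables parse '+'-suffixed PFS as de-censored values", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "patient_id,drug,pfs_months",
    "203,everolimus,60.0+", "148,everolimus,11.6", "90,everolimus,1.3"
  ), path)
  clin <- read_clinical_table(path)
  expect_identical(clin$pfs_months, c(60.0, 11.6, 1.3))
  expect_identical(clin$censored, c(TRUE, FALSE, FALSE))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,drug,pfs_months", "1,x,abc"), bad)
  expect_error(read_clinical_table(bad), class = "ddpp_parse_error")
})

test_that("clinical round-trip preserves values and censoring exactly", {
  clin <- data.frame(
    patient_id = c("a", "b"), drug = "d",
    pfs_months = c(60, 2.5), censored = c(TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_clinical_table(clin, path)
  back <- read_clinical_table(path)
  expect_identical(back$pfs_months, clin$pfs_months)
  expect_identical(back$censored, clin$censored)
})

test_that("header-only clinical file yields an empty result, no error", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("patient_id,drug,pfs_months", path)
  clin <- read_clinical_table(path)
  expect_identical(nrow(clin), 0L)
})

test_that("cohort construction enforces the domain invariants", {
  expect_error(
    toy_cohort(
      matrix(1, 1, 3, dimnames = list("A", paste0("P", 1:3))),
      matrix(1, 1, 3, dimnames = list("A", paste0("P", 1:3))),
      pfs = c(1, -2, 3)
    ),
    class = "ddpp_validation_error"
  )
  # shared gene universe
  expr <- list(
    P1 = data.frame(gene = "A", tumor_intensity = 1, normal_intensity = 1),
    P2 = data.frame(gene = "B", tumor_intensity = 1, normal_intensity = 1)
  )
  expect_error(
    ddpp_cohort(
      "d",
      data.frame(patient_id = c("P1", "P2"), pfs_months = c(1, 2)), expr
    ),
    class = "ddpp_validation_error"
  )
})

test_that("cohorts below three patients are rejected before fitting", {
  co <- random_cohort(n_genes = 4, n_patients = 2)
  expect_error(
    rank_genes(co, c("G1", "G2")),
    class = "ddpp_validation_error"
  )
  expect_error(ddpp_fit(co, c("G1", "G2")), class = "ddpp_validation_error")
})

test_that("panel and model JSON round-trip", {
  panel <- ddpp_panel(
    "toy", c("A", "B"),
    aliases = c(ALPHA = "A"), source = "unit test"
  )
  p_path <- withr::local_tempfile(fileext = ".json")
  write_panel(panel, p_path)
  back <- read_panel(p_path)
  expect_identical(back$genes, panel$genes)
  expect_identical(back$aliases, panel$aliases)

  model <- ddpp_model(
    "toy", "normal", "dual", c("A", "B"), "sum",
    slope = 2.014e-2, intercept = 4.36,
    train_r = 0.99, train_p = 4.68e-4, n_train = 5L
  )
  m_path <- withr::local_tempfile(fileext = ".json")
  write_model(model, m_path)
  back <- read_model(m_path)
  expect_identical(back$genes, model$genes)
  expect_identical(back$slope, model$slope)
  expect_identical(back$intercept, model$intercept)
  expect_identical(back$method, model$method)
  expect_identical(back$channel, model$channel)
  expect_equal(back$train_r, model$train_r, tolerance = 1e-12)
})

test_that("read_cohort assembles a drug cohort from the two tables", {
  sim <- generate_cohort(generator_config(seed = 3, n_genes = 10))
  ep <- withr::local_tempfile(fileext = ".csv")
  cp <- withr::local_tempfile(fileext = ".csv")
  write_expression_table(sim$cohort, ep)
  clin <- sim$cohort$patients
  clin$drug <- "synthetic"
  write_clinical_table(clin, cp)
  co <- read_cohort(ep, cp, "synthetic")
  expect_equal(co$tumor, sim$cohort$tumor, tolerance = 1e-12)
  expect_identical(co$patients$pfs_months, sim$cohort$patients$pfs_months)
  expect_error(read_cohort(ep, cp, "nope"), class = "ddpp_validation_error")
})
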