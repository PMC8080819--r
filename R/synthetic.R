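#' Configuration for the synthetic cohort generator
#'
#' The generator emulates a small paired tumor/normal microarray cohort with
#' a planted gene signature whose summation scalar is linearly coupled to
#' PFS. Defaults mirror the everolimus-style setting the tool targets: six
#' patients, an eight-gene `fold_abs` signature read on the tumor channel,
#' predictor constants `PFS = 1.499e-13 * X + 3.134` months, log-normal
#' intensities around `exp(7) ~ 1100` RFU, and one month of Gaussian PFS
#' noise.
#'
#' @param n_patients Cohort size (>= 3; default 6).
#' @param n_genes Gene universe size including the planted genes
#'   (default 500).
#' @param planted_genes Ordered symbols of the planted signature (default
#'   `SIG1..SIG8`).
#' @param planted_method Summation method the signature is built for.
#' @param channel Channel whose intensity multiplies the log2 fold change.
#' @param slope,intercept Linear coupling of the planted scalar X to PFS
#'   (months).
#' @param noise_sd Gaussian noise added to PFS, months (>= 0; default 1).
#' @param intensity_log_mean,intensity_log_sd Natural-log mean/sd of the
#'   log-normal RFU intensities (defaults 7 and 1).
#' @param censor_longest Mark the longest PFS as censored (default FALSE).
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @param base Intensity log base of the feature (default 1.1).
#' @return A `ddpp_generator_config` list.
#' @export
generator_config <- function(n_patients = 6L, n_genes = 500L,
                             planted_genes = paste0("SIG", 1:8),
                             planted_method = "fold_abs",
                             channel = c("tumor", "normal"),
                             slope = 1.499e-13, intercept = 3.134,
                             noise_sd = 1, intensity_log_mean = 7,
                             intensity_log_sd = 1, censor_longest = FALSE,
                             seed = 1L, base = 1.1) {
  planted_method <- match.arg(planted_method, ddpp_methods_all)
  channel <- match.arg(channel)
  n_patients <- as.integer(n_patients)
  n_genes <- as.integer(n_genes)
  if (n_patients < 3L) ddpp_validation_error("n_patients must be >= 3")
  planted_genes <- as.character(planted_genes)
  if (!length(planted_genes) || anyDuplicated(planted_genes)) {
    ddpp_validation_error("planted_genes must be unique and non-empty")
  }
  if (n_genes < length(planted_genes)) {
    ddpp_validation_error("n_genes must be >= number of planted genes")
  }
  stopifnot_scalar_number(slope, "slope")
  if (slope == 0) ddpp_validation_error("slope must be nonzero")
  stopifnot_scalar_number(intercept, "intercept")
  stopifnot_scalar_number(noise_sd, "noise_sd")
  if (noise_sd < 0) ddpp_validation_error("noise_sd must be >= 0")
  if (slope < 0 && intercept <= 1) {
    ddpp_validation_error(
      "a negative slope needs intercept > 1 to keep synthetic PFS positive"
    )
  }
  structure(
    list(
      n_patients = n_patients, n_genes = n_genes,
      planted_genes = planted_genes, planted_method = planted_method,
      channel = channel, slope = slope, intercept = intercept,
      noise_sd = noise_sd, intensity_log_mean = intensity_log_mean,
      intensity_log_sd = intensity_log_sd,
      censor_longest = isTRUE(censor_longest),
      seed = as.integer(seed), base = base
    ),
    class = "ddpp_generator_config"
  )
}

#' Generate a synthetic paired cohort with a planted signature
#'
#' Draws strictly positive log-normal intensities for all genes. For the
#' planted genes, the tumor/normal ratio is adjusted so that the planted
#' summation scalar equals a target `X_i` per patient: targets are drawn
#' uniformly on the PFS scale (`slope * X` spanning about 0.5 to 50 months,
#' bounded so PFS stays positive for negative slopes) and the per-gene
#' features realize them exactly — for product-type methods each gene
#' carries a random positive share of the exponent, for `sum` a random
#' share of the total, for `mean`/`median` every gene carries `X_i`.
#' Non-planted genes get log2 fold changes centered at 0 (no signal in
#' expectation). PFS is `slope * X + intercept + N(0, noise_sd)`, floored
#' at 0.1 months (a documented generator artifact); optionally the longest
#' PFS is flagged censored.
#'
#' @param config A [generator_config()].
#' @return List with `cohort` (a [ddpp_cohort()]) and `truth` (list
#'   `drug`, `genes`, `method`, `channel`, `slope`, `intercept`, `base`,
#'   `scalar` = the planted per-patient X).
#' @export
generate_cohort <- function(config = generator_config()) {
  if (!inherits(config, "ddpp_generator_config")) {
    ddpp_validation_error("config must come from generator_config()")
  }
  set.seed(config$seed)
  n <- config$n_patients
  k <- length(config$planted_genes)
  ids <- sprintf("SYN%02d", seq_len(n))
  genes <- c(
    config$planted_genes,
    sprintf("G%05d", seq_len(config$n_genes - k))
  )

  # planted scalar targets, spread over the predictor's working range
  span_hi <- if (config$slope < 0) {
    max(1, config$intercept - 0.3)
  } else {
    50
  }
  q <- runif(n, 0.5, span_hi)
  x_target <- q / abs(config$slope)

  # Per-gene positive shares so the planted genes are not identical copies,
  # plus gene-level jitter that cancels in the full joint summation: the
  # signature is exact only as a whole, so partial prefixes are strictly
  # noisier and the step-in search has a genuine optimum at K = k.
  w <- runif(k, 0.8, 1.2)
  w <- w / sum(w)
  # Gene-level jitter cancels across the planted set, so the signature is
  # exact only as a whole and partial prefixes are strictly noisier. For
  # the product methods the first gene is a jitter-free "driver" (it
  # anchors the channel decision, like the top-ranked gene of a real
  # panel); for sum/mean the jitter spans all genes — a clean driver would
  # make the K = 1 cell exactly optimal too and the step-in K ambiguous.
  jitter_sd <- 0.2
  center_tail <- function(e) { # e[1] stays 0, e[2..k] sum to 0
    if (k > 1L) e[-1L] <- e[-1L] - mean(e[-1L])
    e
  }
  # driver gets a tenth of the jitter (so its K = 1 cell is strictly
  # suboptimal yet still anchors the ranking/channel); the rest absorb it
  additive_jitter <- function(scale) {
    d <- center_tail(c(0, rnorm(k - 1L, 0, scale)))
    if (k > 1L) {
      d1 <- rnorm(1L, 0, 0.1 * scale)
      d <- d + c(d1, rep(-d1 / (k - 1L), k - 1L))
    }
    d
  }
  feat <- matrix(NA_real_, k, n) # planted feature values, genes x patients
  for (i in seq_len(n)) {
    feat[, i] <- switch(config$planted_method,
      fold = ,
      fold_abs = x_target[i]^w *
        exp(center_tail(c(0, rnorm(k - 1L, 0, jitter_sd)))),
      sum = x_target[i] * w + additive_jitter(jitter_sd * x_target[i]),
      mean = x_target[i] + additive_jitter(jitter_sd * abs(x_target[i])),
      median = rep(x_target[i], k) # exact copies: median-stable
    )
  }

  logb <- function(v) log(v) / log(config$base)
  tumor <- matrix(
    exp(rnorm(
      length(genes) * n, config$intensity_log_mean, config$intensity_log_sd
    )),
    length(genes), n,
    dimnames = list(genes, ids)
  )
  # background: log2 fold changes centered at 0, sd 0.5
  fc <- matrix(rnorm(length(genes) * n, 0, 0.5), length(genes), n)
  normal <- tumor / 2^fc
  # Planted genes: solve the channel equation exactly.
  # channel tumor: F = log2(T/N) * log1.1(T)  =>  N = T / 2^(F / log1.1(T))
  # channel normal: F = log2(T/N) * log1.1(N) =>  T = N * 2^(F / log1.1(N))
  # The driver gene's on-channel intensity is drawn dim and variable
  # (log-mean 2, log-sd 0.5): its fold change is then large and patient-
  # dependent, which decorrelates the driver's feature in the opposite
  # channel and makes the planted channel identifiable, while the
  # on-channel feature stays exact by construction.
  for (j in seq_len(k)) {
    if (config$channel == "tumor") {
      tum <- if (j == 1L) exp(rnorm(n, 2, 0.5)) else tumor[j, ]
      tumor[j, ] <- tum
      normal[j, ] <- tum / 2^(feat[j, ] / logb(tum))
    } else {
      nor <- if (j == 1L) exp(rnorm(n, 2, 0.5)) else normal[j, ]
      normal[j, ] <- nor
      tumor[j, ] <- nor * 2^(feat[j, ] / logb(nor))
    }
  }
  if (any(!is.finite(tumor)) || any(tumor <= 0) ||
    any(!is.finite(normal)) || any(normal <= 0)) {
    ddpp_validation_error(
      "generator configuration produced non-positive intensities"
    )
  }

  pfs <- config$slope * x_target + config$intercept +
    rnorm(n, 0, config$noise_sd)
  pfs <- pmax(pfs, 0.1)
  censored <- rep(FALSE, n)
  if (config$censor_longest) censored[which.max(pfs)] <- TRUE

  expression <- lapply(setNames(ids, ids), function(id) {
    data.frame(
      gene = genes, tumor_intensity = tumor[, id],
      normal_intensity = normal[, id], stringsAsFactors = FALSE
    )
  })
  cohort <- ddpp_cohort(
    drug = "synthetic",
    clinical = data.frame(
      patient_id = ids, pfs_months = pfs, censored = censored,
      stringsAsFactors = FALSE
    ),
    expression = expression
  )
  truth <- list(
    drug = "synthetic", genes = config$planted_genes,
    method = config$planted_method, channel = config$channel,
    slope = config$slope, intercept = config$intercept,
    base = config$base, scalar = setNames(x_target, ids)
  )
  list(cohort = cohort, truth = truth)
}
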