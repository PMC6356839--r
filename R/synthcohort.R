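# Synthetic tumor/normal cohort generator with known prognostic ground truth.
#
# Expression is log2-scale Gaussian with block correlation; survival follows a
# Weibull proportional-hazards model on a sparse set of informative genes
# (optionally through non-linear terms); censoring is independent exponential
# calibrated to a target rate. Every downstream stage of the package can be
# exercised against the planted truth without any external data.

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate a single-platform glioblastoma expression study: a few
#' hundred tumors, a small normal-reference group, log2 intensities around 7
#' with unit variance, correlated gene blocks, twenty informative genes with
#' unit log-hazard effects (a fifth acting through a centered quadratic term),
#' a Weibull baseline whose median survival is near 14 months at zero risk,
#' and roughly 30% right censoring.
#'
#' @param n_tumor number of tumor samples.
#' @param n_normal number of normal reference samples.
#' @param n_genes number of genes.
#' @param n_informative number of genes that drive the hazard. Informative
#'   genes are mutually uncorrelated and independent of the background
#'   blocks, so the planted truth is identifiable.
#' @param block_size genes per correlated block.
#' @param block_rho within-block correlation, in `[0, 1)`.
#' @param effect_sizes log-hazard coefficients of the informative genes
#'   (length `n_informative`); default alternates +1/-1.
#' @param nonlinear_fraction fraction of informative genes whose effect enters
#'   the risk through a centered quadratic term instead of linearly.
#' @param baseline_shape,baseline_scale Weibull baseline-hazard parameters
#'   (scale in months).
#' @param censor_rate target fraction of censored samples, in `[0, 1)`.
#' @param de_shift mean log2 tumor-vs-normal shift of informative genes (and
#'   of the differentially expressed background genes, with random sign).
#' @param de_background_fraction fraction of non-informative genes that are
#'   differentially expressed tumor-vs-normal without being prognostic. Real
#'   tumor transcriptomes are dominated by such genes (roughly a third of
#'   the transcriptome survives a 2-fold differential-expression filter),
#'   and they are what a differential-expression pre-filter feeds into the
#'   survival model alongside the truly prognostic genes.
#' @param age_risk_cor correlation between age and the true linear predictor
#'   (all other clinical covariates are generated independently of expression).
#' @param seed integer seed; identical configurations reproduce bit-identical
#'   cohorts.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_tumor = 400, n_normal = 10, n_genes = 500,
                             n_informative = 20, block_size = 10,
                             block_rho = 0.6, effect_sizes = NULL,
                             nonlinear_fraction = 0.2,
                             baseline_shape = 1.2, baseline_scale = 20,
                             censor_rate = 0.3, de_shift = 1.5,
                             de_background_fraction = 0.3,
                             age_risk_cor = 0.3, seed = 1) {
  cfg <- list(
    n_tumor = check_count(n_tumor, "n_tumor"),
    n_normal = check_count(n_normal, "n_normal"),
    n_genes = check_count(n_genes, "n_genes"),
    n_informative = check_count(n_informative, "n_informative", min = 0),
    block_size = check_count(block_size, "block_size"),
    block_rho = check_fraction(block_rho, "block_rho", open_hi = TRUE),
    nonlinear_fraction = check_fraction(nonlinear_fraction, "nonlinear_fraction"),
    baseline_shape = baseline_shape,
    baseline_scale = baseline_scale,
    censor_rate = check_fraction(censor_rate, "censor_rate", open_hi = TRUE),
    de_shift = de_shift,
    de_background_fraction = check_fraction(de_background_fraction,
                                            "de_background_fraction"),
    age_risk_cor = check_fraction(age_risk_cor, "age_risk_cor", lo = -1),
    seed = check_count(seed, "seed", min = 0)
  )
  if (!is.numeric(baseline_shape) || baseline_shape <= 0)
    stop_config("field 'baseline_shape' must be positive")
  if (!is.numeric(baseline_scale) || baseline_scale <= 0)
    stop_config("field 'baseline_scale' must be positive")
  if (cfg$n_informative > cfg$n_genes)
    stop_config("field 'n_informative' exceeds 'n_genes'")
  if (is.null(effect_sizes))
    effect_sizes <- if (cfg$n_informative > 0)
      rep_len(c(1, -1), cfg$n_informative) else numeric(0)
  if (length(effect_sizes) != cfg$n_informative)
    stop_config("field 'effect_sizes' must have length n_informative (",
                cfg$n_informative, ")")
  cfg$effect_sizes <- as.numeric(effect_sizes)
  structure(cfg, class = "synthetic_config")
}

# Deterministic per-gene baseline log2 means and informative-gene placement,
# shared by the tumor and normal generators.
cohort_gene_layout <- function(config) {
  set.seed(derive_seed(config$seed, 1L))
  gene_ids <- sprintf("G%04d", seq_len(config$n_genes))
  mu <- stats::rnorm(config$n_genes, mean = 7, sd = 1)
  # informative genes are mutually uncorrelated singleton blocks so the
  # planted truth stays identifiable; the remaining background genes carry
  # the block correlation structure
  k <- config$n_informative
  informative_idx <- seq_len(k)
  n_nl <- round(config$nonlinear_fraction * k)
  nonlinear <- rep(FALSE, k)
  if (n_nl > 0) nonlinear[seq(k - n_nl + 1, k)] <- TRUE
  n_bg <- config$n_genes - k
  bg_blocks <- if (n_bg > 0)
    k + rep(seq_len(ceiling(n_bg / config$block_size)),
            each = config$block_size)[seq_len(n_bg)] else integer(0)
  # differentially expressed but non-prognostic background genes: shifted
  # tumor-vs-normal by +/- de_shift, with no effect on the hazard
  n_de_bg <- round(config$de_background_fraction * n_bg)
  de_bg_idx <- if (n_de_bg > 0) k + sort(sample.int(n_bg, n_de_bg)) else integer(0)
  de_bg_sign <- if (n_de_bg > 0) sample(c(-1, 1), n_de_bg, replace = TRUE) else numeric(0)
  list(gene_ids = gene_ids, mu = mu, informative_idx = informative_idx,
       nonlinear = nonlinear, block = c(seq_len(k), bg_blocks),
       de_bg_idx = de_bg_idx, de_bg_sign = de_bg_sign)
}

# Block-equicorrelated Gaussian expression: shared block factor plus
# idiosyncratic noise, unit marginal variance on the log2 scale.
draw_expression <- function(layout, n_samples, rho) {
  n_genes <- length(layout$mu)
  n_blocks <- max(layout$block)
  f <- matrix(stats::rnorm(n_blocks * n_samples), n_blocks, n_samples)
  e <- matrix(stats::rnorm(n_genes * n_samples), n_genes, n_samples)
  sqrt(rho) * f[layout$block, , drop = FALSE] + sqrt(1 - rho) * e + layout$mu
}

#' Generate a synthetic tumor cohort
#'
#' Draws block-correlated log2 expression, Weibull proportional-hazards event
#' times driven by the informative genes, exponential censoring calibrated to
#' the configured rate, and clinical covariates. Returns the expression matrix
#' (genes x samples), a survival table, a clinical table, and the ground
#' truth used for generation.
#'
#' @param config a [synthetic_config()].
#' @return a list of class `synthetic_cohort` with elements `expression`
#'   (numeric matrix, genes x samples), `survival` (data.frame with
#'   `sample_id`, `time`, `event`), `clinical` (data.frame of covariates) and
#'   `truth` (list with `informative_gene_ids`, `true_coefficients`,
#'   `nonlinear`, `true_linear_predictor`).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "synthetic_config"))
    stop_config("'config' must be created by synthetic_config()")
  layout <- cohort_gene_layout(config)

  set.seed(derive_seed(config$seed, 2L))
  X <- draw_expression(layout, config$n_tumor, config$block_rho)
  sample_ids <- sprintf("S%04d", seq_len(config$n_tumor))
  dimnames(X) <- list(layout$gene_ids, sample_ids)

  # true linear predictor on standardized informative expression; quadratic
  # terms are centered and scaled to unit variance so effect sizes stay
  # comparable between linear and non-linear genes
  lp <- numeric(config$n_tumor)
  if (config$n_informative > 0) {
    Z <- X[layout$informative_idx, , drop = FALSE] - layout$mu[layout$informative_idx]
    for (i in seq_len(config$n_informative)) {
      zi <- Z[i, ]
      term <- if (layout$nonlinear[i]) (zi^2 - 1) / sqrt(2) else zi
      lp <- lp + config$effect_sizes[i] * term
    }
  }

  # Weibull PH event times by inverse-transform sampling:
  # S(t) = exp(-(t/scale)^shape * exp(lp))
  u <- stats::runif(config$n_tumor)
  t_event <- config$baseline_scale * (-log(u) * exp(-lp))^(1 / config$baseline_shape)

  if (config$censor_rate > 0) {
    # P(censored) = E_T[1 - exp(-rate * T)]; solve for the exponential rate
    target <- function(log_rate)
      mean(1 - exp(-exp(log_rate) * t_event)) - config$censor_rate
    rate <- exp(stats::uniroot(target, c(-20, 20))$root)
    t_cens <- stats::rexp(config$n_tumor, rate)
  } else {
    t_cens <- rep(Inf, config$n_tumor)
  }
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)
  time <- pmax(time, .Machine$double.eps)

  surv <- data.frame(sample_id = sample_ids, time = time, event = event,
                     stringsAsFactors = FALSE)

  set.seed(derive_seed(config$seed, 3L))
  clinical <- draw_clinical(sample_ids, lp, config$age_risk_cor)

  truth <- list(
    informative_gene_ids = layout$gene_ids[layout$informative_idx],
    true_coefficients = config$effect_sizes,
    nonlinear = layout$nonlinear,
    true_linear_predictor = stats::setNames(lp, sample_ids)
  )
  structure(list(expression = X, survival = surv, clinical = clinical,
                 truth = truth, config = config),
            class = "synthetic_cohort")
}

draw_clinical <- function(sample_ids, lp, age_risk_cor) {
  n <- length(sample_ids)
  lp_std <- if (stats::sd(lp) > 0) (lp - mean(lp)) / stats::sd(lp) else rep(0, n)
  age <- round(57 + 10 * (age_risk_cor * lp_std +
                            sqrt(1 - age_risk_cor^2) * stats::rnorm(n)))
  data.frame(
    sample_id = sample_ids,
    age = as.numeric(pmax(age, 18)),
    gender = stats::rbinom(n, 1, 0.6),
    kps = sample(c(40, 60, 80, 100), n, replace = TRUE,
                 prob = c(0.10, 0.25, 0.40, 0.25)),
    therapy = sample(c("chemoradiation", "chemotherapy", "radiation", "none"),
                     n, replace = TRUE, prob = c(0.55, 0.10, 0.20, 0.15)),
    subtype = sample(c("proneural", "classical", "mesenchymal", "other"),
                     n, replace = TRUE, prob = c(0.30, 0.25, 0.30, 0.15)),
    mgmt = stats::rbinom(n, 1, 0.45),
    gcimp = stats::rbinom(n, 1, 0.08),
    idh_mutation = stats::rbinom(n, 1, 0.10),
    stringsAsFactors = FALSE
  )
}

#' Generate the matched normal reference expression matrix
#'
#' Normal samples share the tumor gene layout; informative genes are shifted
#' down by `de_shift` log2 units relative to the tumor mean, all other genes
#' keep the tumor baseline mean, so informative genes are the differentially
#' expressed ones by construction.
#'
#' @param config a [synthetic_config()].
#' @return numeric matrix (genes x `n_normal` samples) of log2 expression.
#' @export
generate_normal_reference <- function(config) {
  if (!inherits(config, "synthetic_config"))
    stop_config("'config' must be created by synthetic_config()")
  layout <- cohort_gene_layout(config)
  set.seed(derive_seed(config$seed, 4L))
  layout$mu[layout$informative_idx] <-
    layout$mu[layout$informative_idx] - config$de_shift
  layout$mu[layout$de_bg_idx] <-
    layout$mu[layout$de_bg_idx] - layout$de_bg_sign * config$de_shift
  X <- draw_expression(layout, config$n_normal, config$block_rho)
  dimnames(X) <- list(layout$gene_ids, sprintf("N%03d", seq_len(config$n_normal)))
  X
}
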