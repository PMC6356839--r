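# Classical survival machinery: Cox proportional-hazards fits with Wald
# tests and optional stratification, proportional-hazards checking, Harrell's
# concordance, prognostic index with median split, Kaplan-Meier curves and
# the log-rank test. Model fitting is delegated to the survival package
# (Breslow ties throughout, for consistency with the network loss).

#' Fit a Cox proportional-hazards model
#'
#' @param covariates data.frame (numeric and/or factor columns) aligned with
#'   `surv`; constant columns are rejected.
#' @param surv data.frame with `time` and `event`.
#' @param strata optional name of a `covariates` column to stratify on (the
#'   column then contributes no regression coefficient).
#' @return object of class `cox_model_result`: a list with `summary`
#'   (data.frame: `term`, `beta`, `hazard_ratio`, `ci95_low`, `ci95_high`,
#'   `wald_p`), `concordance` (Harrell's C of the fitted linear predictor),
#'   `overall_lr_p` (likelihood-ratio test of the whole model), `strata`,
#'   and the underlying `coxph` fit.
#' @export
fit_cox_ph <- function(covariates, surv, strata = NULL) {
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != nrow(surv))
    stop_data("covariates and survival table are not aligned")
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    if ((is.numeric(v) && stats::sd(v) == 0) ||
        (!is.numeric(v) && length(unique(v)) < 2))
      stop_data("constant covariate '", nm, "' makes the model degenerate")
  }
  dat <- cbind(surv[, c("time", "event")], covariates)
  rhs <- setdiff(names(covariates), strata)
  fml <- paste("survival::Surv(time, event) ~",
               paste(c(sprintf("`%s`", rhs),
                       if (!is.null(strata)) sprintf("survival::strata(`%s`)", strata)),
                     collapse = " + "))
  if (!is.null(strata)) {
    ev_by_stratum <- tapply(dat$event, covariates[[strata]], sum)
    if (any(ev_by_stratum < 1))
      stop_data("a stratum has no events; stratified fit undefined")
  } else if (sum(dat$event) < 1) {
    stop_data("no events; partial likelihood undefined")
  }
  fit <- tryCatch(
    survival::coxph(stats::as.formula(fml), data = dat, ties = "breslow"),
    error = function(e) stop("Cox fit failed: ", conditionMessage(e)),
    warning = function(w) {
      # refit, keeping the result but surfacing convergence problems
      f <- suppressWarnings(survival::coxph(stats::as.formula(fml), data = dat,
                                            ties = "breslow"))
      if (grepl("infinite|converge", conditionMessage(w)))
        stop("Cox fit failed: ", conditionMessage(w))
      f
    })
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  z975 <- stats::qnorm(0.975)
  summary_df <- data.frame(
    term = names(beta), beta = as.numeric(beta),
    hazard_ratio = exp(as.numeric(beta)),
    ci95_low = exp(as.numeric(beta) - z975 * se),
    ci95_high = exp(as.numeric(beta) + z975 * se),
    wald_p = 2 * stats::pnorm(-abs(as.numeric(beta) / se)),
    row.names = NULL, stringsAsFactors = FALSE)
  lr <- 2 * (fit$loglik[2] - fit$loglik[1])
  lp <- unname(fit$linear.predictors)
  structure(list(summary = summary_df,
                 concordance = concordance_index(lp, dat),
                 overall_lr_p = stats::pchisq(lr, df = length(beta),
                                              lower.tail = FALSE),
                 strata = strata, coxph = fit, data = dat),
            class = "cox_model_result")
}

#' Test the proportional-hazards assumption
#'
#' Grambsch-Therneau test: per-term chi-square from the correlation of scaled
#' Schoenfeld residuals with the event-time rank.
#'
#' @param fit a [fit_cox_ph()] result.
#' @return named numeric vector of per-term p-values (the global test is
#'   included under `"GLOBAL"`).
#' @export
ph_assumption_test <- function(fit) {
  if (!inherits(fit, "cox_model_result")) stop_data("'fit' must be a cox_model_result")
  if (sum(fit$data$event) < 3)
    stop_data("need at least 3 events to test proportional hazards")
  zp <- survival::cox.zph(fit$coxph, transform = "rank")
  stats::setNames(zp$table[, "p"], rownames(zp$table))
}

#' Harrell's concordance index
#'
#' Over usable pairs (the member with the strictly shorter time experienced
#' the event), the fraction in which the higher predicted risk had the
#' shorter time; risk ties count one half. Pairs with equal observed times
#' are not usable.
#'
#' @param risk numeric vector of predicted risks (higher = worse).
#' @param surv aligned survival table with `time`, `event`.
#' @return concordance in `[0, 1]`.
#' @export
concordance_index <- function(risk, surv) {
  if (length(risk) != nrow(surv)) stop_data("risk and survival table misaligned")
  time <- surv$time; event <- surv$event
  usable <- outer(time, time, "<") & (event == 1) # [i, j]: t_i < t_j, event_i
  n_usable <- sum(usable)
  if (n_usable == 0) stop_data("no comparable pairs; concordance undefined")
  concordant <- usable & outer(risk, risk, ">")
  tied <- usable & outer(risk, risk, "==")
  (sum(concordant) + 0.5 * sum(tied)) / n_usable
}

#' Prognostic index (Cox linear predictor)
#'
#' `PI = x'beta`, with no baseline-hazard or centering term. Accepts either a
#' fitted [fit_cox_ph()] model with new covariate data, or a bare coefficient
#' vector with a numeric covariate matrix whose columns match the
#' coefficient names.
#'
#' @param fit a `cox_model_result`, or a named (or unnamed) numeric
#'   coefficient vector.
#' @param covariates data.frame or matrix of covariate values.
#' @return numeric vector of per-sample prognostic indices.
#' @export
prognostic_index <- function(fit, covariates) {
  if (inherits(fit, "cox_model_result")) {
    pred <- tryCatch(
      stats::predict(fit$coxph, newdata = as.data.frame(covariates),
                     type = "lp", reference = "zero"),
      error = function(e) stop_data("covariates do not match model terms: ",
                                    conditionMessage(e)))
    return(as.numeric(pred))
  }
  beta <- as.numeric(fit)
  Xm <- as.matrix(covariates)
  if (!is.null(names(fit))) {
    if (!all(names(fit) %in% colnames(Xm)))
      stop_data("missing covariate column(s): ",
                paste(setdiff(names(fit), colnames(Xm)), collapse = ", "))
    Xm <- Xm[, names(fit), drop = FALSE]
  }
  if (ncol(Xm) != length(beta)) stop_data("covariates do not match coefficients")
  as.numeric(Xm %*% beta)
}

#' Split samples at the median prognostic index
#'
#' Samples strictly above the median are `"high_risk"`; samples at or below
#' the median are `"low_risk"` (ties go to the low-risk group).
#'
#' @param pi_values numeric prognostic indices, `n >= 2`.
#' @return factor with levels `low_risk`, `high_risk`.
#' @export
median_split <- function(pi_values) {
  if (length(pi_values) < 2) stop_data("need at least 2 samples to split")
  if (length(unique(pi_values)) == 1)
    stop_data("all prognostic indices identical; median split degenerate")
  med <- stats::median(pi_values)
  factor(ifelse(pi_values > med, "high_risk", "low_risk"),
         levels = c("low_risk", "high_risk"))
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator; censored times reduce the risk set without a
#' survival drop.
#'
#' @param surv survival table with `time`, `event`.
#' @return data.frame of class `km_curve` with `time` (ascending unique
#'   observed times), `survival`, `n_at_risk`, `n_event`.
#' @export
km_curve <- function(surv) {
  if (nrow(surv) < 1) stop_data("empty survival table")
  sf <- survival::survfit(survival::Surv(time, event) ~ 1,
                          data = surv[, c("time", "event")])
  structure(data.frame(time = sf$time, survival = sf$surv,
                       n_at_risk = sf$n.risk, n_event = sf$n.event),
            class = c("km_curve", "data.frame"))
}

#' Log-rank test for survival differences between groups
#'
#' @param surv survival table with `time`, `event`.
#' @param groups group labels aligned with `surv` (at least two groups).
#' @return list of class `logrank_result` with `chi_square`, `df`, `p_value`.
#' @export
logrank_test <- function(surv, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2)
    stop_config("log-rank test needs at least 2 groups")
  if (sum(surv$event) < 1) stop_data("no events; log-rank undefined")
  dat <- data.frame(time = surv$time, event = surv$event, g = groups)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ g, data = dat)
  df <- length(sd_$n) - 1L
  structure(list(chi_square = as.numeric(sd_$chisq), df = df,
                 p_value = stats::pchisq(as.numeric(sd_$chisq), df,
                                         lower.tail = FALSE)),
            class = "logrank_result")
}

#' Baseline clinical Cox model and its network-node augmentation
#'
#' Fits the clinical-covariate-only model and the model with the
#' last-hidden-layer node outputs appended, reporting both. A node output can
#' be dichotomized at a threshold and used as a stratification variable
#' (useful when a node violates proportional hazards). A near-singular
#' augmented design (e.g., a node duplicating a clinical covariate) raises a
#' collinearity warning with the design-matrix condition number.
#'
#' @param clinical clinical data.frame (a `sample_id` column, if present, is
#'   dropped).
#' @param node_outputs numeric matrix (samples x nodes) of hidden-node
#'   activations.
#' @param surv aligned survival table.
#' @param dichotomize optional list `list(node =, threshold =)` turning one
#'   node column into a binary `>= threshold` indicator used as a stratum.
#' @return list with `baseline` and `augmented` (`cox_model_result`s).
#' @export
augment_baseline_model <- function(clinical, node_outputs, surv,
                                   dichotomize = NULL) {
  clin <- as.data.frame(clinical)
  clin$sample_id <- NULL
  node_df <- as.data.frame(node_outputs)
  if (nrow(node_df) != nrow(clin)) stop_data("node outputs misaligned with clinical table")
  baseline <- fit_cox_ph(clin, surv)
  strata <- NULL
  if (!is.null(dichotomize)) {
    nd <- dichotomize$node
    if (!nd %in% names(node_df)) stop_data("node '", nd, "' not in node outputs")
    node_df[[nd]] <- factor(ifelse(node_df[[nd]] >= dichotomize$threshold,
                                   "high", "low"), levels = c("low", "high"))
    strata <- nd
  }
  aug <- cbind(clin, node_df)
  mm <- stats::model.matrix(~ ., data = aug[, setdiff(names(aug), strata)])
  kap <- kappa(mm, exact = FALSE)
  if (kap > 1e8)
    warning("augmented design is near-singular (condition number ",
            format(kap, digits = 3), "); collinear covariates suspected")
  augmented <- fit_cox_ph(aug, surv, strata = strata)
  list(baseline = baseline, augmented = augmented)
}
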