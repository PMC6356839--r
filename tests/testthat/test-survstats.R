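test_that("Cox fits respect symmetry, report exact hazard ratios, and reject degeneracy", {
  # perfectly mirrored event experience in the two arms
  dat <- data.frame(sample_id = paste0("s", 1:20),
                    time = rep(c(2, 4, 6, 8, 10), 4),
                    event = 1)
  grp <- data.frame(g = rep(c(0, 1), each = 10))
  fit <- fit_cox_ph(grp, dat)
  expect_lt(abs(fit$summary$beta), 1e-8)
  expect_equal(fit$summary$hazard_ratio, exp(fit$summary$beta))
  expect_true(fit$summary$ci95_low <= fit$summary$hazard_ratio &
                fit$summary$hazard_ratio <= fit$summary$ci95_high)
  expect_error(fit_cox_ph(data.frame(x = rep(1, 20)), dat), "constant")
})

test_that("Cox coefficients agree with a generic optimizer of the partial likelihood", {
  set.seed(50)
  n <- 30
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
  surv <- make_surv(n, seed = 51)
  fit <- fit_cox_ph(as.data.frame(X), surv)
  oracle <- optim(c(0, 0), function(b)
    neg_log_partial_likelihood(as.numeric(X %*% b), surv),
    method = "BFGS", control = list(reltol = 1e-14))
  expect_lt(max(abs(fit$summary$beta - oracle$par)), 1e-5)
})

test_that("stratified fits drop the stratum term and need events per stratum", {
  set.seed(52)
  n <- 80
  cov <- data.frame(x = rnorm(n), s = rep(c("u", "v"), each = n / 2))
  surv <- make_surv(n, seed = 53)
  fit <- fit_cox_ph(cov, surv, strata = "s")
  expect_identical(nrow(fit$summary), 1L)
  surv0 <- surv; surv0$event[cov$s == "v"] <- 0
  expect_error(fit_cox_ph(cov, surv0, strata = "s"), "stratum")
})

test_that("proportional-hazards test flags a built-in reversing effect", {
  # time-varying effect: log-hazard +0.9x before the typical event time
  # (the unit-baseline median log 2), -0.9x after; piecewise inverse
  # transform of the cumulative hazard
  sim_reversing <- function(n, seed, b = 0.9, m = log(2)) {
    set.seed(seed)
    x <- rnorm(n)
    e <- rexp(n)
    h1 <- exp(b * x)
    t <- ifelse(e < h1 * m, e / h1, m + (e - h1 * m) / exp(-b * x))
    data.frame(x = x, time = t, event = 1)
  }
  hits <- vapply(1:60, function(s) {
    d <- sim_reversing(150, s)
    fit <- fit_cox_ph(d["x"], d[c("time", "event")])
    unname(ph_assumption_test(fit)["x"] < 0.05)
  }, logical(1))
  expect_gt(mean(hits), 0.8)
  # too few events to test the assumption
  few <- data.frame(time = c(1, 2, 3, 4, 5, 6), event = c(1, 1, 0, 0, 0, 0))
  set.seed(66)
  fit_few <- fit_cox_ph(data.frame(x = rnorm(6, sd = 0.1)), few)
  expect_error(ph_assumption_test(fit_few), "3 events")
})

test_that("concordance matches brute-force enumeration and its symmetries", {
  surv <- make_surv(50, seed = 54, tie = TRUE)
  set.seed(55)
  risk <- round(rnorm(50), 1) # risk ties
  expect_identical(concordance_index(risk, surv), brute_concordance(risk, surv))
  # perfect ranking / all ties
  s2 <- data.frame(time = 1:10, event = 1)
  expect_equal(concordance_index(10:1, s2), 1)
  expect_equal(concordance_index(rep(0, 10), s2), 0.5)
  # complement symmetry for tie-free inputs
  surv3 <- make_surv(30, seed = 56)
  r3 <- rnorm(30)
  expect_equal(concordance_index(r3, surv3) + concordance_index(-r3, surv3), 1)
  expect_error(concordance_index(c(1, 2), data.frame(time = c(1, 1), event = c(1, 1))),
               "comparable")
})

test_that("prognostic index is the bare linear predictor", {
  expect_equal(prognostic_index(c(1, -1), matrix(c(2, 3), 1, 2)), -1)
  expect_equal(prognostic_index(rep(0, 3), matrix(rnorm(15), 5, 3)), rep(0, 5))
  set.seed(57)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  surv <- make_surv(20, seed = 58)
  fit <- fit_cox_ph(as.data.frame(X), surv)
  pi_fit <- prognostic_index(fit, as.data.frame(X))
  expect_equal(pi_fit, as.numeric(X %*% fit$summary$beta), tolerance = 1e-8)
  b <- c(a = 1, b = 2)
  expect_error(prognostic_index(b, matrix(0, 2, 1, dimnames = list(NULL, "a"))),
               "missing")
})

test_that("median split sends ties to the low-risk group", {
  s <- median_split(1:10)
  expect_identical(as.integer(table(s)), c(5L, 5L))
  s2 <- median_split(c(0, 0, 0, 1))
  expect_identical(as.integer(table(s2)), c(3L, 1L))
  set.seed(59)
  v <- rnorm(31)
  expect_identical(unname(median_split(v) == "high_risk"), v > median(v))
  expect_error(median_split(rep(2, 5)), "identical")
})

test_that("Kaplan-Meier estimates match hand computations", {
  km <- km_curve(data.frame(time = 1:4, event = 1))
  expect_equal(km$survival, c(0.75, 0.5, 0.25, 0))
  all_cens <- km_curve(data.frame(time = c(2, 5, 7), event = 0))
  expect_true(all(all_cens$survival == 1))
  # events at 1 and 3, censoring at 2: S = 2/3 after t=1, 0 after t=3
  km3 <- km_curve(data.frame(time = c(1, 2, 3), event = c(1, 0, 1)))
  expect_equal(km3$survival[km3$time == 1], 2 / 3)
  expect_equal(km3$survival[km3$time == 3], 0)
  expect_true(all(diff(km3$survival) <= 0))
})

test_that("log-rank agrees with the textbook observed-minus-expected formula", {
  surv <- make_surv(20, seed = 60, tie = TRUE)
  groups <- rep(c("a", "b"), each = 10)
  got <- logrank_test(surv, groups)
  # independent implementation over shared event times
  tms <- sort(unique(surv$time[surv$event == 1]))
  o_minus_e <- 0; v <- 0
  for (tt in tms) {
    at1 <- sum(surv$time >= tt & groups == "a")
    at2 <- sum(surv$time >= tt & groups == "b")
    d1 <- sum(surv$time == tt & surv$event == 1 & groups == "a")
    d2 <- sum(surv$time == tt & surv$event == 1 & groups == "b")
    n_t <- at1 + at2; d_t <- d1 + d2
    o_minus_e <- o_minus_e + d1 - d_t * at1 / n_t
    if (n_t > 1)
      v <- v + d_t * (at1 / n_t) * (at2 / n_t) * (n_t - d_t) / (n_t - 1)
  }
  expect_lt(abs(got$chi_square - o_minus_e^2 / v), 1e-10)
  expect_identical(got$df, 1L)
  # identical survival experience in both groups: statistic 0, p 1
  dup <- data.frame(time = rep(c(1, 3, 5, 7), 2), event = rep(c(1, 1, 0, 1), 2))
  same <- logrank_test(dup, rep(c("a", "b"), each = 4))
  expect_lt(same$chi_square, 1e-10)
  expect_equal(same$p_value, 1)
  # label swap invariance
  expect_equal(logrank_test(surv, groups)$chi_square,
               logrank_test(surv, rev(groups))$chi_square)
  expect_error(logrank_test(surv, rep("a", 20)), "2 groups")
})

test_that("strongly separated groups give a decisive log-rank result", {
  set.seed(61)
  n <- 200
  t1 <- rexp(n, 0.05); t2 <- rexp(n, 0.15) # hazard ratio 3
  surv <- data.frame(time = c(t1, t2), event = 1)
  lr <- logrank_test(surv, rep(c("lo", "hi"), each = n))
  expect_lt(lr$p_value, 0.001)
})

test_that("hazard-ratio confidence intervals achieve nominal coverage", {
  covered <- vapply(1:500, function(s) {
    set.seed(1000 + s)
    n <- 500
    x <- rnorm(n)
    t_ev <- rexp(n, exp(0.5 * x) * 0.1)
    cens <- rexp(n, 0.03)
    surv <- data.frame(time = pmin(t_ev, cens), event = as.integer(t_ev <= cens))
    fit <- fit_cox_ph(data.frame(x = x), surv)
    fit$summary$ci95_low <= exp(0.5) && exp(0.5) <= fit$summary$ci95_high
  }, logical(1))
  expect_gte(mean(covered), 0.92)
  expect_lte(mean(covered), 0.98)
})

test_that("node outputs augment the clinical baseline when and only when informative", {
  cfg0 <- synthetic_config(n_tumor = 300, n_genes = 40, n_informative = 10,
                           age_risk_cor = 0.3, seed = 62)
  coh <- generate_cohort(cfg0)
  lp <- coh$truth$true_linear_predictor
  set.seed(63)
  nodes_signal <- cbind(node_a = pmax(lp + rnorm(300, 0, 0.5), 0),
                        node_b = pmax(-lp + rnorm(300, 0, 0.5), 0))
  both <- augment_baseline_model(coh$clinical, nodes_signal, coh$survival)
  expect_gte(both$augmented$concordance, both$baseline$concordance)
  # pure-noise nodes change nothing material
  nodes_null <- matrix(abs(rnorm(600)), 300, 2,
                       dimnames = list(NULL, c("node_a", "node_b")))
  null_fit <- augment_baseline_model(coh$clinical, nodes_null, coh$survival)
  expect_lt(abs(null_fit$augmented$concordance - null_fit$baseline$concordance),
            0.03)
  # a node duplicating a clinical covariate triggers the collinearity warning
  dup <- cbind(node_a = coh$clinical$age)
  expect_warning(augment_baseline_model(coh$clinical, dup, coh$survival),
                 "near-singular")
})

test_that("a dichotomized node can be used as a stratification variable", {
  cfg0 <- synthetic_config(n_tumor = 200, n_genes = 20, n_informative = 5,
                           seed = 64)
  coh <- generate_cohort(cfg0)
  set.seed(65)
  nodes <- matrix(abs(rnorm(400)), 200, 2,
                  dimnames = list(NULL, c("node_1", "node_2")))
  res <- augment_baseline_model(coh$clinical, nodes, coh$survival,
                                dichotomize = list(node = "node_2",
                                                   threshold = 1.6))
  expect_identical(res$augmented$strata, "node_2")
  expect_false("node_2" %in% res$augmented$summary$term)
})
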