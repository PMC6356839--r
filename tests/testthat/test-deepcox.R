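test_that("partial-likelihood loss matches closed forms and is shift invariant", {
  # two events at distinct times, both risks zero: loss = ln 2
  expect_equal(neg_log_partial_likelihood(
    c(0, 0), data.frame(time = c(1, 2), event = c(1, 1))), log(2))
  # a single event has a singleton risk set: loss 0
  expect_equal(neg_log_partial_likelihood(
    0.5, data.frame(time = 3, event = 1)), 0)
  surv <- make_surv(30, seed = 1, tie = TRUE)
  risk <- rnorm(30)
  expect_lt(abs(neg_log_partial_likelihood(risk, surv) -
                  neg_log_partial_likelihood(risk + 7.3, surv)), 1e-8)
  expect_error(neg_log_partial_likelihood(
    c(0, 0), data.frame(time = 1:2, event = c(0, 0))), "event")
})

test_that("partial-likelihood value and gradient agree with coxph and finite differences", {
  surv <- make_surv(40, seed = 2, tie = TRUE)
  set.seed(3)
  risk <- rnorm(40)
  off <- survival::coxph(survival::Surv(time, event) ~ offset(risk),
                         data = cbind(surv, risk = risk), ties = "breslow")
  expect_equal(-neg_log_partial_likelihood(risk, surv), off$loglik[1])
  g <- neg_log_partial_likelihood_grad(risk, surv)
  expect_lt(max(abs(g - fd_risk_gradient(risk, surv))), 1e-6)
})

test_that("forward pass matches a hand-rolled matrix-arithmetic oracle", {
  cfg <- network_config(hidden_sizes = c(4, 3), seed = 5)
  X <- make_expr(6, 5, seed = 6)
  model <- deepcox_init(cfg, rownames(X))
  # perturb bn statistics away from the identity so the oracle is non-trivial
  for (l in 1:2) {
    model$bn[[l]]$running_mean <- rnorm(length(model$bn[[l]]$running_mean))
    model$bn[[l]]$running_var <- runif(length(model$bn[[l]]$running_var), 0.5, 2)
    model$bn[[l]]$gamma <- runif(length(model$bn[[l]]$gamma), 0.5, 1.5)
    model$bn[[l]]$beta <- rnorm(length(model$bn[[l]]$beta))
  }
  out <- deepcox_forward(model, X, mode = "eval")
  # independent reimplementation, written plainly
  Z <- X
  for (l in 1:2) {
    A <- model$layers[[l]]$W %*% Z + model$layers[[l]]$b
    bn <- model$bn[[l]]
    Ahat <- (A - bn$running_mean) / sqrt(bn$running_var + 1e-5)
    Z <- pmax(bn$gamma * Ahat + bn$beta, 0)
  }
  oracle <- as.numeric(model$layers[[3]]$W %*% Z + model$layers[[3]]$b)
  expect_lt(max(abs(out$risk - oracle)), 1e-6)
  expect_true(all(out$hidden_activations[[2]] >= 0))
  # eval mode is a pure function
  expect_identical(out, deepcox_forward(model, X, mode = "eval"))
})

test_that("degenerate and linear network configurations behave exactly", {
  X <- make_expr(3, 8, seed = 7)
  cfg <- network_config(hidden_sizes = c(4), seed = 8)
  model <- deepcox_init(cfg, rownames(X))
  for (l in seq_along(model$layers)) model$layers[[l]]$W[] <- 0
  model$layers[[2]]$b <- 0.7
  out <- deepcox_forward(model, X)
  expect_equal(out$risk, rep(0.7, 8))
  expect_equal(nrow(unique(t(out$hidden_activations[[1]]))), 1)

  # one gene, no hidden layer, unit weight: risk equals the gene values
  lin <- deepcox_init(network_config(hidden_sizes = integer(0), seed = 1), "g001")
  lin$layers[[1]]$W[] <- 1; lin$layers[[1]]$b <- 0
  X1 <- X[1, , drop = FALSE]
  expect_equal(deepcox_forward(lin, X1)$risk, unname(X1[1, ]))
  expect_error(deepcox_forward(lin, X), "gene ids")
})

test_that("training respects the penalty, the epoch budget and the seed", {
  cfg0 <- synthetic_config(n_tumor = 60, n_genes = 12, n_informative = 4,
                           seed = 9)
  coh <- generate_cohort(cfg0)
  Xtr <- coh$expression[, 1:40]; str_ <- coh$survival[1:40, ]
  Xva <- coh$expression[, 41:60]; sva <- coh$survival[41:60, ]
  # an overwhelming penalty drives the weights to zero (adaptive steps decay
  # them at roughly the learning rate per epoch, hence the small rate and
  # generous epoch budget)
  big <- deepcox_train(network_config(hidden_sizes = c(4), l2_coefficient = 1e6,
                                      learning_rate = 1e-3, max_epochs = 4000,
                                      seed = 2),
                       Xtr, str_, Xva, sva)
  expect_lt(sqrt(sum(vapply(big$final_model$layers, function(l) sum(l$W^2),
                            numeric(1)))), 1e-2)
  # zero epochs returns the (seeded, deterministic) initialization
  cfg <- network_config(hidden_sizes = c(4), max_epochs = 0, seed = 3)
  init1 <- deepcox_train(cfg, Xtr, str_, Xva, sva)
  init2 <- deepcox_train(cfg, Xtr, str_, Xva, sva)
  expect_identical(init1$model, init2$model)
  expect_equal(nrow(init1$history), 0)
  # identical seeds give identical trained models
  cfg2 <- network_config(hidden_sizes = c(4), max_epochs = 30, seed = 4)
  expect_identical(deepcox_train(cfg2, Xtr, str_, Xva, sva)$model,
                   deepcox_train(cfg2, Xtr, str_, Xva, sva)$model)
})

test_that("penalized training loss trends downward at a small learning rate", {
  cfg0 <- synthetic_config(n_tumor = 80, n_genes = 10, n_informative = 3,
                           seed = 10)
  coh <- generate_cohort(cfg0)
  fit <- deepcox_train(network_config(hidden_sizes = c(5), learning_rate = 1e-3,
                                      l2_coefficient = 0.01, max_epochs = 150,
                                      seed = 5),
                       coh$expression[, 1:60], coh$survival[1:60, ],
                       coh$expression[, 61:80], coh$survival[61:80, ])
  loss <- fit$history$train_loss
  # adaptive full-batch steps are not strictly monotone; require a dominant
  # downward trend and near-monotonicity
  expect_lt(loss[150], loss[1])
  expect_gt(mean(diff(loss) <= 1e-8), 0.95)
})

test_that("the network learns planted linear survival signal", {
  cfg0 <- synthetic_config(n_tumor = 400, n_genes = 500, n_informative = 20,
                           nonlinear_fraction = 0, seed = 11)
  coh <- generate_cohort(cfg0)
  part <- stratified_partition(coh$survival, k = 10, seed = 11)
  iv <- part$partition == 2
  itr <- !iv & part$partition != 1
  fit <- deepcox_train(network_config(hidden_sizes = c(82, 27), seed = 11),
                       coh$expression[, itr], coh$survival[itr, ],
                       coh$expression[, iv], coh$survival[iv, ])
  expect_gte(fit$best_valid_cindex, 0.70)
})

test_that("no survival signal survives outcome permutation (leakage guard)", {
  cfg0 <- synthetic_config(n_tumor = 200, n_genes = 40, n_informative = 10,
                           seed = 12)
  coh <- generate_cohort(cfg0)
  set.seed(13)
  perm <- sample(200)
  surv_p <- coh$survival[perm, ]
  surv_p$sample_id <- coh$survival$sample_id
  fit <- deepcox_train(network_config(hidden_sizes = c(8), max_epochs = 200,
                                      seed = 6),
                       coh$expression[, 1:150], surv_p[1:150, ],
                       coh$expression[, 151:200], surv_p[151:200, ])
  risk <- deepcox_forward(fit$model, coh$expression[, 151:200])$risk
  expect_lt(abs(concordance_index(risk, surv_p[151:200, ]) - 0.5), 0.1)
})

test_that("hyperparameter search ranks architectures by validation concordance", {
  single <- list(network_config(hidden_sizes = c(4), max_epochs = 20, seed = 1))
  cfg0 <- synthetic_config(n_tumor = 400, n_genes = 30, n_informative = 8,
                           nonlinear_fraction = 1, seed = 14)
  coh <- generate_cohort(cfg0)
  part <- stratified_partition(coh$survival, k = 5, seed = 14)
  got <- hyperparameter_search(single, coh$expression, coh$survival, part,
                               valid_index = 2, test_index = 1)
  expect_identical(got$best_index, 1L)
  expect_error(hyperparameter_search(list(), coh$expression, coh$survival,
                                     part, 2), "empty")
  # purely quadratic planted effects: a two-layer net should do at least as
  # well as the linear (no-hidden-layer) model
  grid <- list(linear = network_config(hidden_sizes = integer(0),
                                       max_epochs = 400, seed = 15),
               deep = network_config(hidden_sizes = c(16, 8),
                                     max_epochs = 400, seed = 15))
  res <- hyperparameter_search(grid, coh$expression, coh$survival, part,
                               valid_index = 2, test_index = 1)
  expect_gte(res$results$valid_cindex[2], res$results$valid_cindex[1])
})

test_that("validation rotation is stable across partitions", {
  cfg0 <- synthetic_config(n_tumor = 200, n_genes = 40, n_informative = 10,
                           seed = 16)
  coh <- generate_cohort(cfg0)
  part <- stratified_partition(coh$survival, k = 5, seed = 16)
  rot <- rotate_validation(network_config(hidden_sizes = c(8), max_epochs = 150,
                                          seed = 17),
                           coh$expression, coh$survival, part, test_index = 1)
  expect_length(rot$concordances, 4)
  expect_lt(rot$sd, 0.15)
})
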