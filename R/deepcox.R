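# Feed-forward survival network trained on the Cox partial likelihood.
#
# Architecture: input -> up to two dense hidden layers, each followed by
# batch normalization and ReLU -> single linear output node (the log risk).
# Training minimizes the negative log partial likelihood plus an L2 penalty
# on all weight matrices, by full-batch Adam, keeping the parameters of the
# epoch with the best validation concordance. Inference always uses stored
# batch-norm running statistics and is deterministic.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

#' Network training configuration
#'
#' @param hidden_sizes integer vector of 0 to 2 hidden-layer widths; the
#'   published operating point is `c(82, 27)`.
#' @param learning_rate Adam step size.
#' @param l2_coefficient L2 penalty on all weight matrices. The training
#'   loss is the unnormalized total negative log partial likelihood, so the
#'   penalty is on that scale; the default was selected by validation
#'   concordance on the default synthetic cohort.
#' @param max_epochs maximum training epochs (default 1000).
#' @param batch_mode currently `"full"` (full-batch gradients).
#' @param standardize z-score each input gene on the training data and freeze
#'   the transform for validation/test/importance passes.
#' @param seed integer seed for weight initialization.
#' @return object of class `network_config`.
#' @export
network_config <- function(hidden_sizes = c(82, 27), learning_rate = 0.01,
                           l2_coefficient = 1, max_epochs = 1000,
                           batch_mode = c("full"), standardize = TRUE,
                           seed = 1) {
  if (length(hidden_sizes) > 2)
    stop_config("at most two hidden layers are supported")
  if (length(hidden_sizes) > 0 &&
      (any(hidden_sizes < 1) || any(hidden_sizes != round(hidden_sizes))))
    stop_config("'hidden_sizes' must be positive integers")
  if (!is.numeric(learning_rate) || learning_rate <= 0)
    stop_config("'learning_rate' must be positive")
  if (!is.numeric(l2_coefficient) || l2_coefficient < 0)
    stop_config("'l2_coefficient' must be nonnegative")
  structure(list(hidden_sizes = as.integer(hidden_sizes),
                 learning_rate = learning_rate,
                 l2_coefficient = l2_coefficient,
                 max_epochs = check_count(max_epochs, "max_epochs", min = 0),
                 batch_mode = match.arg(batch_mode),
                 standardize = isTRUE(standardize),
                 seed = check_count(seed, "seed", min = 0)),
            class = "network_config")
}

#' Initialize a survival network
#'
#' He-style initialization for ReLU hidden layers, small output weights, unit
#' batch-norm scale, zero shifts and running means, unit running variances.
#'
#' @param config a [network_config()].
#' @param input_gene_ids character vector of input gene ids (fixes input
#'   dimension and order).
#' @param center,scale optional per-gene standardization parameters frozen
#'   into the model (default: identity transform).
#' @return object of class `deepcox_model`.
#' @export
deepcox_init <- function(config, input_gene_ids, center = NULL, scale = NULL) {
  p <- length(input_gene_ids)
  set.seed(derive_seed(config$seed, 11L))
  dims <- c(p, config$hidden_sizes, 1L)
  layers <- vector("list", length(dims) - 1)
  for (l in seq_along(layers)) {
    fan_in <- dims[l]
    sd0 <- if (l < length(layers)) sqrt(2 / fan_in) else 1 / sqrt(fan_in)
    layers[[l]] <- list(
      W = matrix(stats::rnorm(dims[l + 1] * fan_in, sd = sd0), dims[l + 1], fan_in),
      b = numeric(dims[l + 1]))
  }
  n_hidden <- length(config$hidden_sizes)
  bn <- if (n_hidden > 0) lapply(config$hidden_sizes, function(h)
    list(gamma = rep(1, h), beta = rep(0, h),
         running_mean = rep(0, h), running_var = rep(1, h))) else list()
  structure(list(config = config, input_gene_ids = input_gene_ids,
                 layers = layers, bn = bn,
                 center = center %||% rep(0, p),
                 scale = scale %||% rep(1, p)),
            class = "deepcox_model")
}

n_parameters <- function(model) {
  sum(vapply(model$layers, function(l) length(l$W) + length(l$b), numeric(1))) +
    sum(vapply(model$bn, function(b) length(b$gamma) + length(b$beta), numeric(1)))
}

align_input <- function(model, X) {
  if (is.null(rownames(X)) || !identical(rownames(X), model$input_gene_ids))
    stop_data("expression gene ids do not match the model's input genes ",
              "(same genes, same order, required)")
  (X - model$center) / model$scale
}

#' Forward pass of the survival network
#'
#' @param model a `deepcox_model`.
#' @param X expression matrix (genes x samples) whose rownames equal
#'   `model$input_gene_ids` in order.
#' @param mode `"eval"` (stored batch-norm running statistics; deterministic)
#'   or `"train"` (statistics of the current batch).
#' @return list of class `risk_output` with `sample_ids`, `risk` (log-risk
#'   per sample) and `hidden_activations` (list of per-layer nodes x samples
#'   matrices, nonnegative).
#' @export
deepcox_forward <- function(model, X, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  if (any(vapply(model$layers, function(l) anyNA(l$W) || anyNA(l$b), logical(1))))
    stop_data("model weights contain NaN; training diverged or model corrupted")
  Z <- align_input(model, X)
  fw <- forward_pass(model, Z, mode)
  structure(list(sample_ids = colnames(X), risk = fw$risk,
                 hidden_activations = fw$hidden),
            class = "risk_output")
}

# Internal forward over an already standardized input, keeping the caches
# required for backpropagation.
forward_pass <- function(model, Z, mode) {
  n_hidden <- length(model$bn)
  cache <- vector("list", n_hidden)
  hidden <- vector("list", n_hidden)
  for (l in seq_len(n_hidden)) {
    A <- model$layers[[l]]$W %*% Z + model$layers[[l]]$b
    bn <- model$bn[[l]]
    if (mode == "train") {
      mu <- rowMeans(A)
      va <- rowMeans((A - mu)^2)
    } else {
      mu <- bn$running_mean
      va <- bn$running_var
    }
    inv_sd <- 1 / sqrt(va + BN_EPS)
    Ahat <- (A - mu) * inv_sd
    H <- bn$gamma * Ahat + bn$beta
    Zl <- pmax(H, 0)
    cache[[l]] <- list(Z_in = Z, A = A, mu = mu, va = va, inv_sd = inv_sd,
                       Ahat = Ahat, H = H)
    hidden[[l]] <- Zl
    Z <- Zl
  }
  out <- model$layers[[n_hidden + 1]]
  risk <- as.numeric(out$W %*% Z + out$b)
  list(risk = risk, hidden = hidden, cache = cache, Z_last = Z)
}

# Backpropagation of d(loss)/d(risk) through the network (train-mode batch
# norm), returning per-layer weight/bias/bn-parameter gradients including the
# L2 penalty term on weights.
backward_pass <- function(model, fw, d_risk, l2) {
  n_hidden <- length(model$bn)
  grads <- list(layers = vector("list", n_hidden + 1),
                bn = vector("list", n_hidden))
  out <- model$layers[[n_hidden + 1]]
  d_risk <- matrix(d_risk, nrow = 1)
  grads$layers[[n_hidden + 1]] <- list(
    W = d_risk %*% t(fw$Z_last) + 2 * l2 * out$W,
    b = sum(d_risk))
  dZ <- t(out$W) %*% d_risk
  for (l in rev(seq_len(n_hidden))) {
    cc <- cache_l <- fw$cache[[l]]
    bn <- model$bn[[l]]
    relu_mask <- fw$hidden[[l]] > 0
    dH <- dZ * relu_mask
    dgamma <- rowSums(dH * cc$Ahat)
    dbeta <- rowSums(dH)
    dAhat <- dH * bn$gamma
    nb <- ncol(cc$A)
    # batch-norm backward (per node/row)
    dvar <- rowSums(dAhat * (cc$A - cc$mu)) * (-0.5) * cc$inv_sd^3
    dmu <- -rowSums(dAhat) * cc$inv_sd + dvar * rowMeans(-2 * (cc$A - cc$mu))
    dA <- dAhat * cc$inv_sd + dvar * 2 * (cc$A - cc$mu) / nb + dmu / nb
    grads$layers[[l]] <- list(
      W = dA %*% t(cc$Z_in) + 2 * l2 * model$layers[[l]]$W,
      b = rowSums(dA))
    grads$bn[[l]] <- list(gamma = dgamma, beta = dbeta)
    dZ <- t(model$layers[[l]]$W) %*% dA
  }
  grads
}

sum_sq_weights <- function(model)
  sum(vapply(model$layers, function(l) sum(l$W^2), numeric(1)))

#' Train the survival network
#'
#' Full-batch Adam on the penalized negative log partial likelihood
#' `loss + l2 * sum of squared weights`. After every epoch the batch-norm
#' running statistics are updated (exponential moving average) and the
#' validation concordance is evaluated in eval mode; the returned model is
#' the checkpoint of the epoch with the highest validation concordance.
#' Identical seeds give identical models.
#'
#' @param config a [network_config()].
#' @param X_train,X_valid expression matrices (genes x samples).
#' @param surv_train,surv_valid aligned survival tables with at least one
#'   event each.
#' @return list with `model` (best-epoch `deepcox_model`), `final_model`
#'   (the last epoch's parameters), `history` (data.frame with `epoch`,
#'   `train_loss`, `valid_cindex`), `best_epoch`, `best_valid_cindex`.
#' @export
deepcox_train <- function(config, X_train, surv_train, X_valid, surv_valid) {
  if (ncol(X_train) != nrow(surv_train) || ncol(X_valid) != nrow(surv_valid))
    stop_data("expression and survival tables are not aligned")
  if (sum(surv_train$event) < 1 || sum(surv_valid$event) < 1)
    stop_data("training and validation sets each need at least one event")
  center <- rowMeans(X_train)
  scl <- apply(X_train, 1, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  if (!config$standardize) { center <- rep(0, nrow(X_train)); scl <- rep(1, nrow(X_train)) }
  model <- deepcox_init(config, rownames(X_train), center = center, scale = scl)

  Z_train <- align_input(model, X_train)
  l2 <- config$l2_coefficient
  # Adam state mirrors the parameter tree
  zero_like <- function(m) {
    list(layers = lapply(m$layers, function(l) list(W = l$W * 0, b = l$b * 0)),
         bn = lapply(m$bn, function(b) list(gamma = b$gamma * 0, beta = b$beta * 0)))
  }
  mom <- zero_like(model); vel <- zero_like(model)
  b1 <- 0.9; b2 <- 0.999; aeps <- 1e-8
  best <- list(model = model, cindex = -Inf, epoch = 0L)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        valid_cindex = numeric(0))
  if (config$max_epochs == 0) {
    return(list(model = model, final_model = model, history = history))
  }
  for (epoch in seq_len(config$max_epochs)) {
    fw <- forward_pass(model, Z_train, "train")
    nll <- neg_log_partial_likelihood(fw$risk, surv_train)
    loss <- nll + l2 * sum_sq_weights(model)
    if (!is.finite(loss))
      stop("training diverged (non-finite loss) at epoch ", epoch)
    d_risk <- neg_log_partial_likelihood_grad(fw$risk, surv_train)
    grads <- backward_pass(model, fw, d_risk, l2)

    # Adam update over every parameter
    corr1 <- 1 - b1^epoch; corr2 <- 1 - b2^epoch
    step <- function(par, g, m, v) {
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g^2
      par <- par - config$learning_rate * (m / corr1) / (sqrt(v / corr2) + aeps)
      list(par = par, m = m, v = v)
    }
    for (l in seq_along(model$layers)) {
      for (nm in c("W", "b")) {
        s <- step(model$layers[[l]][[nm]], grads$layers[[l]][[nm]],
                  mom$layers[[l]][[nm]], vel$layers[[l]][[nm]])
        model$layers[[l]][[nm]] <- s$par
        mom$layers[[l]][[nm]] <- s$m; vel$layers[[l]][[nm]] <- s$v
      }
    }
    for (l in seq_along(model$bn)) {
      for (nm in c("gamma", "beta")) {
        s <- step(model$bn[[l]][[nm]], grads$bn[[l]][[nm]],
                  mom$bn[[l]][[nm]], vel$bn[[l]][[nm]])
        model$bn[[l]][[nm]] <- s$par
        mom$bn[[l]][[nm]] <- s$m; vel$bn[[l]][[nm]] <- s$v
      }
      model$bn[[l]]$running_mean <- BN_MOMENTUM * model$bn[[l]]$running_mean +
        (1 - BN_MOMENTUM) * fw$cache[[l]]$mu
      model$bn[[l]]$running_var <- BN_MOMENTUM * model$bn[[l]]$running_var +
        (1 - BN_MOMENTUM) * fw$cache[[l]]$va
    }

    valid_risk <- deepcox_forward(model, X_valid, "eval")$risk
    ci <- concordance_index(valid_risk, surv_valid)
    history <- rbind(history, data.frame(epoch = epoch, train_loss = loss,
                                         valid_cindex = ci))
    if (ci > best$cindex) best <- list(model = model, cindex = ci, epoch = epoch)
  }
  list(model = best$model, final_model = model, history = history,
       best_epoch = best$epoch, best_valid_cindex = best$cindex)
}

#' Exhaustive hyperparameter search by validation concordance
#'
#' Trains each candidate configuration on the training partitions and scores
#' it on the validation partition; the best configuration maximizes
#' validation concordance, with ties broken first by fewer parameters, then
#' by grid order.
#'
#' @param configs list of [network_config()] objects.
#' @param X expression matrix (genes x samples).
#' @param surv aligned survival table.
#' @param partition a [stratified_partition()] assignment.
#' @param valid_index partition used for validation.
#' @param test_index optional partition excluded from training (held-out
#'   test set).
#' @return list with `best_config`, `best_index` and `results` (data.frame
#'   of per-config validation concordance and parameter counts).
#' @export
hyperparameter_search <- function(configs, X, surv, partition, valid_index,
                                  test_index = NULL) {
  if (length(configs) == 0) stop_config("hyperparameter grid is empty")
  idx_valid <- partition$partition == valid_index
  idx_train <- !idx_valid
  if (!is.null(test_index)) idx_train <- idx_train & partition$partition != test_index
  res <- data.frame(config = seq_along(configs), valid_cindex = NA_real_,
                    n_params = NA_real_)
  fits <- vector("list", length(configs))
  for (i in seq_along(configs)) {
    fit <- deepcox_train(configs[[i]],
                         X[, idx_train, drop = FALSE], surv[idx_train, ],
                         X[, idx_valid, drop = FALSE], surv[idx_valid, ])
    res$valid_cindex[i] <- fit$best_valid_cindex %||% NA_real_
    res$n_params[i] <- n_parameters(fit$model)
    fits[[i]] <- fit
  }
  best <- order(-res$valid_cindex, res$n_params, res$config)[1]
  list(best_config = configs[[best]], best_index = best, results = res,
       best_fit = fits[[best]])
}

#' Validation-rotation stability of a configuration
#'
#' Rotates each non-test partition as the validation set (training on the
#' remaining non-test partitions) and reports the per-rotation validation
#' concordances with their mean and SD.
#'
#' @inheritParams hyperparameter_search
#' @param config a single [network_config()].
#' @return list with `concordances`, `mean`, `sd`.
#' @export
rotate_validation <- function(config, X, surv, partition, test_index = NULL) {
  parts <- sort(unique(partition$partition))
  if (!is.null(test_index)) parts <- setdiff(parts, test_index)
  ci <- vapply(parts, function(v) {
    idx_valid <- partition$partition == v
    idx_train <- !idx_valid
    if (!is.null(test_index)) idx_train <- idx_train & partition$partition != test_index
    fit <- deepcox_train(config, X[, idx_train, drop = FALSE], surv[idx_train, ],
                         X[, idx_valid, drop = FALSE], surv[idx_valid, ])
    fit$best_valid_cindex %||% NA_real_
  }, numeric(1))
  list(concordances = stats::setNames(ci, paste0("partition", parts)),
       mean = mean(ci), sd = stats::sd(ci))
}
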