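# End-to-end orchestration: filter -> partition -> train -> importance ->
# signature -> penalized comparators -> Cox evaluation -> median-split
# validation, with a JSON manifest recording every seed and threshold.

#' Pipeline configuration
#'
#' Bundles the synthetic-cohort settings (or paths to on-disk inputs), the
#' filtering thresholds, network configuration, importance settings, and
#' penalty specifications. A single global seed fans out to per-stage seed
#' streams so any stage can be rerun in isolation.
#'
#' @param synth a [synthetic_config()] describing the cohort to generate, or
#'   `NULL` when `expression_path`/`survival_path`/`clinical_path` are given.
#' @param expression_path,normal_path,survival_path,clinical_path optional
#'   tab-delimited input files used instead of the synthetic generator.
#' @param p_max,min_abs_log2fc differential-expression thresholds.
#' @param r_max correlation-pruning threshold.
#' @param min_genes if fewer genes pass the filter, the pipeline falls back
#'   to the `min_genes` smallest-p genes so downstream stages stay defined.
#' @param k_partitions number of survival-time-stratified partitions.
#' @param test_partition,valid_partition partition indices held out for
#'   testing and validation.
#' @param network a [network_config()] (its seed is overridden by the global
#'   seed stream).
#' @param n_repeats permutation repeats per gene.
#' @param ci_level flagging confidence level.
#' @param p_threshold occurrence-null tail probability.
#' @param penalties named list of [penalty_spec()]s to fit as comparators
#'   (adaptive-lasso weights are derived from the ridge fit automatically).
#' @param cv_folds cross-validation folds for the lambda path.
#' @param output_dir optional directory for tab-delimited stage outputs and
#'   the manifest.
#' @param seed global integer seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = synthetic_config(),
                            expression_path = NULL, normal_path = NULL,
                            survival_path = NULL, clinical_path = NULL,
                            p_max = 0.01, min_abs_log2fc = 1.0, r_max = 0.8,
                            min_genes = 10, k_partitions = 10,
                            test_partition = 1, valid_partition = 2,
                            network = network_config(),
                            n_repeats = 5, ci_level = 0.95,
                            p_threshold = 0.01,
                            penalties = list(
                              ridge = penalty_spec("ridge"),
                              adaptive_lasso = penalty_spec("adaptive_lasso"),
                              elastic_net = penalty_spec("elastic_net", alpha = 0.5)),
                            cv_folds = 9, output_dir = NULL, seed = 1) {
  structure(list(synth = synth, expression_path = expression_path,
                 normal_path = normal_path, survival_path = survival_path,
                 clinical_path = clinical_path,
                 p_max = p_max, min_abs_log2fc = min_abs_log2fc,
                 r_max = r_max, min_genes = min_genes,
                 k_partitions = check_count(k_partitions, "k_partitions", min = 2),
                 test_partition = test_partition,
                 valid_partition = valid_partition,
                 network = network, n_repeats = n_repeats,
                 ci_level = ci_level, p_threshold = p_threshold,
                 penalties = penalties, cv_folds = cv_folds,
                 output_dir = output_dir,
                 seed = check_count(seed, "seed", min = 0)),
            class = "pipeline_config")
}

#' Run the discovery pipeline end to end
#'
#' Stages: differential-expression filtering against the normal reference
#' (with the beta-uniform mixture FDR report), correlation pruning,
#' survival-time-stratified partitioning, network training with best-epoch
#' checkpointing, last-hidden-layer permutation importance, occurrence-based
#' signature extraction, penalized-Cox comparators at the cross-validated
#' minimum lambda, baseline/augmented Cox evaluation on the clinical
#' covariates, and a median-split log-rank validation of the signature on
#' the held-out test partition.
#'
#' @param config a [pipeline_config()].
#' @return result bundle (list) with per-stage outputs and a `manifest`
#'   recording every seed and threshold used.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    stop_config("'config' must be created by pipeline_config()")

  # ---- inputs -------------------------------------------------------------
  if (!is.null(config$expression_path)) {
    tumor <- read_expression(config$expression_path)
    normal <- read_expression(config$normal_path)
    surv <- read_survival(config$survival_path)
    clinical <- read_clinical(config$clinical_path)
    truth <- NULL
  } else {
    cohort <- generate_cohort(config$synth)
    tumor <- cohort$expression
    normal <- generate_normal_reference(config$synth)
    surv <- cohort$survival
    clinical <- cohort$clinical
    truth <- cohort$truth
  }

  # ---- differential-expression filter ------------------------------------
  de <- diff_expression(tumor, normal)
  bum <- tryCatch(fit_bum(pmin(pmax(de$p_value, 1e-300), 1)),
                  error = function(e) NULL)
  fdr_at_pmax <- if (!is.null(bum)) bum_fdr(bum, config$p_max) else NA_real_
  selected <- select_de_genes(de, config$p_max, config$min_abs_log2fc)
  fallback_used <- FALSE
  if (length(selected) < config$min_genes) {
    # too few genes pass (e.g., a null cohort): keep the smallest-p genes so
    # the downstream stages remain defined
    fallback_used <- TRUE
    selected <- de$gene_id[order(de$p_value)][seq_len(min(config$min_genes,
                                                          nrow(de)))]
  }
  pruned <- correlation_prune(tumor[selected, , drop = FALSE], config$r_max)
  X <- tumor[pruned, , drop = FALSE]

  # ---- partitions ---------------------------------------------------------
  part <- stratified_partition(surv, k = config$k_partitions,
                               seed = derive_seed(config$seed, 21L))
  idx_test <- part$partition == config$test_partition
  idx_valid <- part$partition == config$valid_partition
  idx_train <- !idx_test & !idx_valid

  # ---- network training ---------------------------------------------------
  net_cfg <- config$network
  net_cfg$seed <- derive_seed(config$seed, 22L)
  fit <- deepcox_train(net_cfg, X[, idx_train, drop = FALSE], surv[idx_train, ],
                       X[, idx_valid, drop = FALSE], surv[idx_valid, ])
  model <- fit$model
  test_risk <- deepcox_forward(model, X[, idx_test, drop = FALSE])$risk
  test_cindex <- concordance_index(test_risk, surv[idx_test, ])

  # ---- permutation importance & signature --------------------------------
  imp <- permutation_deltas(model, X, n_repeats = config$n_repeats,
                            seed = derive_seed(config$seed, 23L))
  flags <- flag_all_nodes(imp, config$ci_level)
  freq <- gene_frequency(flags)
  n_nodes <- ncol(flags)
  k_min <- occurrence_threshold(freq, n_nodes = n_nodes,
                                p_threshold = config$p_threshold)
  signature <- extract_signature(freq, k_min, config$p_threshold)

  # ---- penalized comparators ---------------------------------------------
  # features are standardized on the training partition for the penalized
  # fits (penalties are scale-sensitive); the frozen transform is reused on
  # the test partition
  Xp <- scale(t(X[, idx_train, drop = FALSE]))
  pen_center <- attr(Xp, "scaled:center"); pen_scale <- attr(Xp, "scaled:scale")
  pen_scale[pen_scale == 0 | !is.finite(pen_scale)] <- 1
  surv_train <- surv[idx_train, ]
  Xp_test <- scale(t(X[, idx_test, drop = FALSE]), center = pen_center,
                   scale = pen_scale)
  cv_seed <- derive_seed(config$seed, 24L)
  comparators <- list()
  ridge_fit <- NULL
  for (nm in names(config$penalties)) {
    pen <- config$penalties[[nm]]
    if (pen$kind == "adaptive_lasso" && is.null(pen$weights)) {
      if (is.null(ridge_fit)) next
      pen$weights <- unname(adaptive_weights(ridge_fit))
    }
    path <- cv_lambda_path(Xp, surv_train, pen, n_folds = config$cv_folds,
                           seed = cv_seed)
    pfit <- fit_penalized_cox(Xp, surv_train, pen, path$lambda_min)
    if (pen$kind == "ridge") ridge_fit <- pfit
    comparators[[nm]] <- list(
      fit = pfit, lambda_min = path$lambda_min,
      test_cindex = concordance_index(as.numeric(Xp_test %*% pfit$beta),
                                      surv[idx_test, ]),
      ranking = rank_by_coefficient(pfit))
  }

  # ---- clinical baseline vs node augmentation ----------------------------
  nodes_all <- deepcox_forward(model, X)$hidden_activations
  node_eval <- if (length(nodes_all) > 0) {
    t(nodes_all[[length(nodes_all)]])
  } else matrix(numeric(0), ncol(X), 0)
  colnames(node_eval) <- if (ncol(node_eval) > 0)
    paste0("node_", seq_len(ncol(node_eval)))
  clin_models <- tryCatch(
    augment_baseline_model(clinical, node_eval, surv),
    error = function(e) NULL)

  # ---- median-split validation on the held-out partition -----------------
  sig_genes <- signature$gene_ids
  validation <- NULL
  if (length(sig_genes) >= 1) {
    Xs_train <- t(X[sig_genes, idx_train, drop = FALSE])
    Xs_test <- t(X[sig_genes, idx_test, drop = FALSE])
    # ridge-stabilized coefficients when the signature is large relative to n
    sig_fit <- if (length(sig_genes) > nrow(Xs_train) / 10) {
      fit_penalized_cox(Xs_train, surv_train, penalty_spec("ridge"),
                        lambda = 1)$beta
    } else {
      b <- fit_cox_ph(as.data.frame(Xs_train), surv_train)$summary
      stats::setNames(b$beta, sig_genes)
    }
    pi_test <- prognostic_index(sig_fit, Xs_test)
    validation <- tryCatch({
      groups <- median_split(pi_test)
      list(groups = groups,
           logrank = logrank_test(surv[idx_test, ], groups),
           km = lapply(split(surv[idx_test, ], groups), km_curve),
           pi = pi_test)
    }, error = function(e) list(error = conditionMessage(e)))
  }

  manifest <- list(
    seed = config$seed,
    stage_seeds = list(partition = derive_seed(config$seed, 21L),
                       network = derive_seed(config$seed, 22L),
                       importance = derive_seed(config$seed, 23L),
                       cv = cv_seed),
    thresholds = list(p_max = config$p_max,
                      min_abs_log2fc = config$min_abs_log2fc,
                      r_max = config$r_max, ci_level = config$ci_level,
                      p_threshold = config$p_threshold, k_min = k_min),
    synth = if (is.null(config$expression_path)) unclass(config$synth),
    network = list(hidden_sizes = net_cfg$hidden_sizes,
                   learning_rate = net_cfg$learning_rate,
                   l2_coefficient = net_cfg$l2_coefficient,
                   max_epochs = net_cfg$max_epochs),
    n_genes_selected = length(selected), fallback_used = fallback_used,
    n_genes_pruned = length(pruned),
    bum = if (!is.null(bum)) list(lambda_mix = bum$lambda_mix,
                                  a_shape = bum$a_shape,
                                  fdr_at_p_max = fdr_at_pmax),
    best_epoch = fit$best_epoch %||% NA,
    valid_cindex = fit$best_valid_cindex %||% NA,
    test_cindex = test_cindex,
    signature = list(k_min = k_min, genes = signature$gene_ids))

  result <- list(de = de, bum = bum, selected_genes = selected,
                 pruned_genes = pruned, partition = part,
                 model = model, history = fit$history,
                 valid_cindex = fit$best_valid_cindex %||% NA,
                 test_cindex = test_cindex,
                 importance = imp, frequency = freq, k_min = k_min,
                 signature = signature, comparators = comparators,
                 clinical_models = clin_models, validation = validation,
                 truth = truth, manifest = manifest)

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    od <- config$output_dir
    utils::write.table(data.frame(gene_id = signature$gene_ids,
                                  frequency = signature$frequency),
                       file.path(od, "signature.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(freq, file.path(od, "gene_frequency.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(part, file.path(od, "partitions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}
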