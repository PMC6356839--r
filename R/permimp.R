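# Hidden-layer input-permutation importance, high-impact gene flagging,
# cross-node occurrence frequency, binomial occurrence null, and signature
# extraction.

#' Input-permutation importance at the last hidden layer and output
#'
#' Permutes one input gene at a time across samples (breaking its association
#' with the outcome), re-runs the network in eval mode, and records the mean
#' absolute change of each last-hidden-layer node activation and of the
#' output risk over samples, averaged over `n_repeats` seeded permutations.
#' Permutations are seeded per (gene id, repeat) by a counter scheme keyed on
#' a hash of the gene id, so results do not depend on gene iteration order.
#' The input matrix is never mutated.
#'
#' @param model a trained `deepcox_model`.
#' @param X expression matrix aligned with `model$input_gene_ids`.
#' @param n_repeats number of permutation repeats per gene (default 5).
#' @param seed base seed for the permutation streams.
#' @param statistic `"mean_abs"` (default; signed changes can cancel) or
#'   `"signed_mean"`.
#' @return matrix of class `importance_matrix` (genes x targets) whose
#'   columns are the last-hidden-layer nodes (`node_1`, ...) plus `"output"`;
#'   entries are nonnegative for `"mean_abs"`. Attribute `n_repeats` records
#'   the repeat count.
#' @export
permutation_deltas <- function(model, X, n_repeats = 5, seed = 1,
                               statistic = c("mean_abs", "signed_mean")) {
  statistic <- match.arg(statistic)
  if (n_repeats < 1) stop_config("'n_repeats' must be >= 1")
  Z <- align_input(model, X)
  n <- ncol(Z)
  n_hidden <- length(model$bn)
  fw0 <- forward_pass(model, Z, "eval")
  H0 <- if (n_hidden > 0) fw0$hidden[[n_hidden]] else matrix(numeric(0), 0, n)
  risk0 <- fw0$risk
  n_nodes <- nrow(H0)
  W1 <- model$layers[[1]]$W

  # forward from the (possibly rank-one-updated) first-layer pre-activation
  forward_from_A1 <- function(A1) {
    Zl <- A1
    for (l in seq_len(n_hidden)) {
      bn <- model$bn[[l]]
      if (l > 1) Zl <- model$layers[[l]]$W %*% Zl + model$layers[[l]]$b
      Ahat <- (Zl - bn$running_mean) / sqrt(bn$running_var + BN_EPS)
      Zl <- pmax(bn$gamma * Ahat + bn$beta, 0)
    }
    out <- model$layers[[n_hidden + 1]]
    list(H = Zl, risk = as.numeric(out$W %*% Zl + out$b))
  }
  A1_base <- model$layers[[1]]$W %*% Z + model$layers[[1]]$b

  agg <- if (statistic == "mean_abs") function(d) rowMeans(abs(d)) else rowMeans
  agg1 <- if (statistic == "mean_abs") function(d) mean(abs(d)) else mean

  gene_ids <- model$input_gene_ids
  hashes <- hash_id(gene_ids)
  delta <- matrix(0, length(gene_ids), n_nodes + 1,
                  dimnames = list(gene_ids,
                                  c(if (n_nodes > 0) paste0("node_", seq_len(n_nodes)),
                                    "output")))
  for (g in seq_along(gene_ids)) {
    acc <- numeric(n_nodes + 1)
    for (r in seq_len(n_repeats)) {
      set.seed(derive_seed(hashes[g] + seed, 100L + r))
      perm <- sample.int(n)
      dz <- Z[g, perm] - Z[g, ]
      if (n_hidden > 0) {
        A1 <- A1_base + W1[, g, drop = FALSE] %*% matrix(dz, nrow = 1)
        fwp <- forward_from_A1(A1)
        acc[seq_len(n_nodes)] <- acc[seq_len(n_nodes)] + agg(fwp$H - H0)
        acc[n_nodes + 1] <- acc[n_nodes + 1] + agg1(fwp$risk - risk0)
      } else {
        riskp <- risk0 + model$layers[[1]]$W[1, g] * dz
        acc[1] <- acc[1] + agg1(riskp - risk0)
      }
    }
    delta[g, ] <- acc / n_repeats
  }
  structure(delta, class = c("importance_matrix", class(delta)),
            n_repeats = n_repeats, statistic = statistic)
}

#' Flag high-impact genes at one network node
#'
#' A gene is flagged important at a node when its permutation delta exceeds
#' the across-gene mean by more than the normal 95%-interval half-width
#' (`mean + 1.96 * SD` at the default level): the outlier criterion applied
#' one-sidedly since deltas are nonnegative.
#'
#' @param imp an [permutation_deltas()] importance matrix.
#' @param node column name (e.g. `"node_3"` or `"output"`).
#' @param ci_level confidence level of the interval (default 0.95).
#' @return named logical vector over genes.
#' @export
flag_important_genes <- function(imp, node, ci_level = 0.95) {
  if (!node %in% colnames(imp)) stop_data("node '", node, "' not present")
  d <- imp[, node]
  if (length(d) < 10)
    stop_data("need at least 10 genes to form the across-gene interval")
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  d > mean(d) + z * stats::sd(d)
}

#' Flag matrix over every last-hidden-layer node
#'
#' @inheritParams flag_important_genes
#' @return logical matrix (genes x nodes), excluding the `"output"` column.
#' @export
flag_all_nodes <- function(imp, ci_level = 0.95) {
  nodes <- setdiff(colnames(imp), "output")
  flags <- vapply(nodes, function(nd) flag_important_genes(imp, nd, ci_level),
                  logical(nrow(imp)))
  dimnames(flags) <- list(rownames(imp), nodes)
  flags
}

#' Cross-node occurrence frequency of flagged genes
#'
#' @param flags logical matrix (genes x nodes) from [flag_all_nodes()], or a
#'   named list of per-node logical vectors over the same gene universe.
#' @return data.frame of class `gene_frequency_table` with `gene_id` and
#'   `frequency` (number of nodes flagging the gene), ordered by descending
#'   frequency then gene id.
#' @export
gene_frequency <- function(flags) {
  if (is.list(flags) && !is.data.frame(flags)) {
    universes <- lapply(flags, names)
    if (length(unique(universes)) != 1)
      stop_data("inconsistent gene universes across nodes")
    flags <- do.call(cbind, flags)
  }
  freq <- rowSums(flags)
  out <- data.frame(gene_id = rownames(flags), frequency = as.integer(freq),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$frequency, out$gene_id), ]
  rownames(out) <- NULL
  attr(out, "n_nodes") <- ncol(flags)
  class(out) <- c("gene_frequency_table", "data.frame")
  out
}

#' Occurrence threshold under an independent-Bernoulli binomial null
#'
#' Under the null that a gene is flagged independently at each node with the
#' pooled probability `q_hat` (mean fraction of genes flagged per node), the
#' number of nodes flagging a gene is Binomial(`n_nodes`, `q_hat`). Returns
#' the smallest occurrence count `k` whose upper-tail probability
#' `P(K >= k)` falls below `p_threshold`.
#'
#' @param freq a [gene_frequency()] table (used to estimate `q_hat` unless
#'   given explicitly).
#' @param n_nodes number of network nodes (default 27).
#' @param p_threshold tail-probability threshold (default 0.01).
#' @param q_hat optional explicit per-node flag probability.
#' @return integer `k_min`.
#' @export
occurrence_threshold <- function(freq, n_nodes = 27, p_threshold = 0.01,
                                 q_hat = NULL) {
  if (n_nodes < 1) stop_config("'n_nodes' must be >= 1")
  if (is.null(q_hat)) {
    if (!inherits(freq, "gene_frequency_table"))
      stop_data("'freq' must be a gene_frequency_table (or supply q_hat)")
    q_hat <- sum(freq$frequency) / (nrow(freq) * n_nodes)
  }
  if (q_hat <= 0) {
    warning("no genes flagged at any node; occurrence threshold defaults to 1")
    return(1L)
  }
  for (k in seq_len(n_nodes)) {
    tail_p <- 1 - stats::pbinom(k - 1, n_nodes, q_hat)
    if (tail_p < p_threshold) return(as.integer(k))
  }
  as.integer(n_nodes + 1)
}

#' Extract the gene signature at an occurrence threshold
#'
#' @param freq a [gene_frequency()] table.
#' @param k_min minimum occurrence count (inclusive).
#' @param p_threshold optional tail probability recorded alongside.
#' @return list of class `gene_signature` with `gene_ids` (descending
#'   frequency, then gene id), `k_min`, `p_threshold`.
#' @export
extract_signature <- function(freq, k_min, p_threshold = NA_real_) {
  if (k_min < 1) stop_config("'k_min' must be >= 1")
  sel <- freq[freq$frequency >= k_min, ]
  sel <- sel[order(-sel$frequency, sel$gene_id), ]
  structure(list(gene_ids = sel$gene_id, frequency = sel$frequency,
                 k_min = as.integer(k_min), p_threshold = p_threshold),
            class = "gene_signature")
}
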