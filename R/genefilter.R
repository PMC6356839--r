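# Differential-expression filtering, beta-uniform mixture p-value modelling,
# correlation pruning, and survival-time-stratified data partitioning.

#' Per-gene differential expression between tumor and normal groups
#'
#' Welch two-sample t-test on log2 expression, gene by gene. The fold change
#' is reported on the log2 scale (`mean(tumor) - mean(normal)`), so a 2-fold
#' biological change corresponds to `|log2_fold_change| >= 1`.
#'
#' @param tumor,normal numeric matrices (genes x samples) with identical
#'   rownames (gene ids) and at least two samples each.
#' @return data.frame of class `diff_expr_result` with columns `gene_id`,
#'   `log2_fold_change`, `t_stat`, `df`, `p_value`.
#' @export
diff_expression <- function(tumor, normal) {
  if (is.null(rownames(tumor)) || is.null(rownames(normal)) ||
      !identical(rownames(tumor), rownames(normal)))
    stop_data("tumor and normal matrices must share identical gene ids")
  n1 <- ncol(tumor); n2 <- ncol(normal)
  if (n1 < 2 || n2 < 2)
    stop_data("each group needs at least 2 samples (got ", n1, " and ", n2, ")")
  m1 <- rowMeans(tumor); m2 <- rowMeans(normal)
  v1 <- rowSums((tumor - m1)^2) / (n1 - 1)
  v2 <- rowSums((normal - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  lfc <- m1 - m2
  t_stat <- ifelse(se2 > 0, lfc / sqrt(se2), ifelse(lfc == 0, 0, sign(lfc) * Inf))
  # Welch-Satterthwaite degrees of freedom; degenerate zero-variance genes
  # fall back to the pooled df (their p-value is 0 or 1 regardless)
  df <- ifelse(se2 > 0,
               se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1))),
               n1 + n2 - 2)
  p <- 2 * stats::pt(-abs(t_stat), df)
  structure(data.frame(gene_id = rownames(tumor), log2_fold_change = lfc,
                       t_stat = t_stat, df = df, p_value = p,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("diff_expr_result", "data.frame"))
}

#' Fit a beta-uniform mixture (BUM) model to p-values
#'
#' Models the p-value density as `lambda + (1 - lambda) * a * p^(a - 1)`:
#' a uniform noise component of weight `lambda` plus a Beta(a, 1) signal
#' component with `a` in (0, 1). Fitted by bounded maximum likelihood from a
#' small grid of starting points, so the result is deterministic.
#'
#' @param p_values numeric vector of at least 100 p-values in (0, 1].
#' @return list of class `bum_fit` with `lambda_mix`, `a_shape`, `loglik`.
#' @export
fit_bum <- function(p_values) {
  p <- as.numeric(p_values)
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop_data("p-values must lie in (0, 1]")
  if (length(p) < 100)
    stop_data("need at least 100 p-values to fit the mixture (got ",
              length(p), ")")
  eps <- 1e-6
  negll <- function(par)
    -sum(log(par[1] + (1 - par[1]) * par[2] * p^(par[2] - 1)))
  starts <- expand.grid(l = c(0.2, 0.5, 0.8, 0.95), a = c(0.1, 0.3, 0.6, 0.9))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(c(starts$l[i], starts$a[i]), negll, method = "L-BFGS-B",
                   lower = c(eps, eps), upper = c(1 - eps, 1 - eps)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best))
    stop("beta-uniform mixture fit failed to converge from every start")
  structure(list(lambda_mix = best$par[1], a_shape = best$par[2],
                 loglik = -best$value, n = length(p)),
            class = "bum_fit")
}

#' Estimated false discovery rate at a p-value threshold under a BUM fit
#'
#' Uses the conservative upper bound on the uniform-component mass,
#' `pi_ub = lambda + (1 - lambda) * a`, giving
#' `FDR(tau) = pi_ub * tau / F(tau)` with
#' `F(tau) = lambda * tau + (1 - lambda) * tau^a`, capped to `[0, 1]`.
#'
#' @param fit a [fit_bum()] result.
#' @param tau significance threshold in (0, 1).
#' @return estimated FDR among genes with `p <= tau`.
#' @export
bum_fdr <- function(fit, tau) {
  if (!inherits(fit, "bum_fit")) stop_data("'fit' must be a bum_fit")
  if (!is.numeric(tau) || length(tau) != 1 || tau <= 0 || tau >= 1)
    stop_data("'tau' must lie in (0, 1)")
  l <- fit$lambda_mix; a <- fit$a_shape
  pi_ub <- l + (1 - l) * a
  Ftau <- l * tau + (1 - l) * tau^a
  min(max(pi_ub * tau / Ftau, 0), 1)
}

#' Select differentially expressed genes
#'
#' Keeps genes passing both arms of the filter: `p_value < p_max` and
#' `|log2_fold_change| >= min_abs_log2fc` (down-regulation counts), preserving
#' input order.
#'
#' @param de a [diff_expression()] result.
#' @param p_max p-value cutoff (exclusive).
#' @param min_abs_log2fc minimum absolute log2 fold change (inclusive);
#'   the default 1 corresponds to a 2-fold change.
#' @return character vector of selected gene ids.
#' @export
select_de_genes <- function(de, p_max = 0.01, min_abs_log2fc = 1.0) {
  if (p_max <= 0 || min_abs_log2fc < 0)
    stop_config("thresholds must be positive")
  de$gene_id[de$p_value < p_max & abs(de$log2_fold_change) >= min_abs_log2fc]
}

#' Prune highly correlated genes to one representative each
#'
#' Groups genes by greedy single linkage on absolute Pearson correlation
#' (`|r| > r_max` links two genes into the same group) and keeps, per group,
#' the gene with the highest variance (ties broken by lexicographically
#' smallest id). Correlations involving a constant gene are defined as 0, so
#' constant genes are always retained. Because linkage is transitive-closed,
#' no two retained genes are correlated beyond `r_max`.
#'
#' @param expr numeric matrix (genes x samples), `>= 2` samples.
#' @param r_max correlation threshold (exclusive).
#' @return character vector of retained gene ids, in input order.
#' @export
correlation_prune <- function(expr, r_max = 0.8) {
  if (ncol(expr) < 2) stop_data("need at least 2 samples to compute correlations")
  g <- nrow(expr)
  if (g == 1) return(rownames(expr))
  r <- suppressWarnings(stats::cor(t(expr)))
  r[is.na(r)] <- 0 # constant genes: correlation defined as 0
  # union-find single linkage over |r| > r_max
  parent <- seq_len(g)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  idx <- which(abs(r) > r_max & upper.tri(r), arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    a <- find(idx[k, 1]); b <- find(idx[k, 2])
    if (a != b) parent[b] <- a
  }
  comp <- vapply(seq_len(g), find, integer(1))
  vars <- apply(expr, 1, stats::var)
  ids <- rownames(expr)
  keep <- logical(g)
  for (cc in unique(comp)) {
    members <- which(comp == cc)
    best <- members[order(-vars[members], ids[members])][1]
    keep[best] <- TRUE
  }
  ids[keep]
}

#' Survival-time-stratified partitioning
#'
#' Sorts samples by survival time, forms consecutive rank blocks of size `k`,
#' and deals each block's samples one to each partition in seeded random
#' order. Every partition therefore receives one sample from each region of
#' the survival-time distribution, guaranteeing the partitions preserve that
#' distribution; sizes differ by at most 1.
#'
#' @param surv data.frame with `sample_id`, `time`, `event`.
#' @param k number of partitions.
#' @param seed integer seed controlling the within-block dealing order.
#' @return data.frame with `sample_id` and `partition` (integer in 1..k).
#' @export
stratified_partition <- function(surv, k = 10, seed = 1) {
  n <- nrow(surv)
  if (k > n) stop_config("'k' (", k, ") exceeds the number of samples (", n, ")")
  if (k < 1) stop_config("'k' must be >= 1")
  set.seed(derive_seed(seed, 5L))
  ord <- order(surv$time)
  part <- integer(n)
  pos <- 1
  while (pos <= n) {
    block <- ord[pos:min(pos + k - 1, n)]
    part[block] <- sample(k)[seq_along(block)]
    pos <- pos + k
  }
  data.frame(sample_id = surv$sample_id, partition = part,
             stringsAsFactors = FALSE)
}
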