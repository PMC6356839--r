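# Shared fixture builders: everything is generated in code at test time.

# small survival table with optional ties
make_surv <- function(n, seed = 1, event_p = 0.7, tie = FALSE) {
  set.seed(seed)
  time <- rexp(n, 0.1) + 0.05
  if (tie) time <- round(time, 0) + 0.5 # integer-ish times force ties
  data.frame(sample_id = sprintf("s%03d", seq_len(n)),
             time = time, event = rbinom(n, 1, event_p))
}

# small expression matrix, genes x samples
make_expr <- function(n_genes, n_samples, seed = 1, mean = 7) {
  set.seed(seed)
  matrix(rnorm(n_genes * n_samples, mean), n_genes, n_samples,
         dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                         sprintf("s%03d", seq_len(n_samples))))
}

# brute-force Harrell concordance by explicit pair enumeration
brute_concordance <- function(risk, surv) {
  num <- 0; den <- 0
  n <- length(risk)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (surv$time[i] < surv$time[j] && surv$event[i] == 1) {
      den <- den + 1
      if (risk[i] > risk[j]) num <- num + 1
      else if (risk[i] == risk[j]) num <- num + 0.5
    }
  }
  num / den
}

# central finite differences of the partial-likelihood loss in risk space
fd_risk_gradient <- function(risk, surv, h = 1e-6) {
  vapply(seq_along(risk), function(i) {
    up <- risk; dn <- risk
    up[i] <- up[i] + h; dn[i] <- dn[i] - h
    (neg_log_partial_likelihood(up, surv) -
       neg_log_partial_likelihood(dn, surv)) / (2 * h)
  }, numeric(1))
}

# penalized Cox objective used by the independent optimizer oracle; the l1
# term is smoothed by sqrt(b^2 + eps) so a quasi-Newton method applies
coxpen_objective <- function(X, surv, penalty, lambda, l1_eps = 0) {
  p <- ncol(X)
  w <- if (is.null(penalty$weights)) rep(1, p) else penalty$weights
  function(beta) {
    nll <- neg_log_partial_likelihood(as.numeric(X %*% beta), surv)
    pen <- switch(penalty$kind,
                  ridge = lambda * sum(beta^2),
                  adaptive_lasso = lambda * sum(w * sqrt(beta^2 + l1_eps)),
                  elastic_net = lambda * sum(penalty$alpha * sqrt(beta^2 + l1_eps) +
                                               (1 - penalty$alpha) * beta^2 / 2))
    nll + pen
  }
}
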