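# Cox partial likelihood with Breslow tie handling: the loss used both as the
# network training objective and as the smooth part of the penalized
# comparators. All computations use log-sum-exp stabilization.

# Internal workhorse: negative log partial likelihood and, optionally, its
# gradient with respect to the per-sample risk scores.
coxlik_core <- function(risk, time, event, gradient = FALSE) {
  n <- length(risk)
  ord <- order(time, decreasing = TRUE) # risk sets accumulate down this order
  r <- risk[ord]; tt <- time[ord]; ev <- event[ord]
  m <- max(r)
  er <- exp(r - m)
  cs <- cumsum(er)
  # ties (Breslow): every sample in a tied-time group shares the risk-set sum
  # taken at the group's last position
  grp <- cumsum(!duplicated(tt))
  lens <- rle(grp)$lengths
  ends <- cumsum(lens)                 # per-group last index
  starts <- ends - lens + 1            # per-group first index
  S <- cs[ends][grp]                   # risk-set sums (scaled by exp(-m))
  loglik_terms <- ev * ((r - m) - log(S))
  nll <- -sum(loglik_terms)
  if (!gradient) return(list(value = nll))
  # d(nll)/d(risk_j) = -(event_j - exp(risk_j) * sum_{events i: t_i <= t_j} 1/S_i)
  h <- ev / S
  rev_cum <- rev(cumsum(rev(h)))
  A <- rev_cum[starts][grp]
  g_ord <- -(ev - er * A)
  g <- numeric(n)
  g[ord] <- g_ord
  list(value = nll, gradient = g)
}

#' Negative Cox log partial likelihood of a risk score
#'
#' Computes `-sum over events i of (risk_i - log sum_{j in R_i} exp(risk_j))`
#' with risk set `R_i = {j : t_j >= t_i}` and Breslow handling of tied event
#' times. This is the training loss of the survival network and is invariant
#' to adding a constant to all risks.
#'
#' @param risk numeric vector of per-sample log-risk scores.
#' @param surv data.frame with `time` and `event` aligned with `risk`.
#' @return the loss (a nonnegative scalar; 0 when every risk set is a
#'   singleton).
#' @export
neg_log_partial_likelihood <- function(risk, surv) {
  if (length(risk) != nrow(surv))
    stop_data("risk vector and survival table have different lengths")
  if (any(!is.finite(risk))) stop_data("non-finite risk scores")
  if (sum(surv$event) < 1)
    stop_data("partial likelihood undefined without at least one event")
  coxlik_core(risk, surv$time, surv$event)$value
}

#' Gradient of the negative log partial likelihood with respect to risk
#'
#' @inheritParams neg_log_partial_likelihood
#' @return numeric vector, same length as `risk`.
#' @export
neg_log_partial_likelihood_grad <- function(risk, surv) {
  if (length(risk) != nrow(surv))
    stop_data("risk vector and survival table have different lengths")
  if (sum(surv$event) < 1)
    stop_data("partial likelihood undefined without at least one event")
  coxlik_core(risk, surv$time, surv$event, gradient = TRUE)$gradient
}
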