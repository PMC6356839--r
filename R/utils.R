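# Internal helpers: seed streams, argument checking, small numerics.

#' Derive a reproducible sub-seed from a base seed
#'
#' Stages of the pipeline draw from independent seed streams derived from one
#' global seed, so any stage can be rerun in isolation with identical results.
#' The derivation is a fixed affine step modulo a Mersenne prime, keeping the
#' result inside the 32-bit integer range R requires of `set.seed()`.
#'
#' @param seed integer base seed.
#' @param offset integer stream offset (stage or unit counter).
#' @return an integer seed in [1, 2^31 - 2].
#' @keywords internal
derive_seed <- function(seed, offset) {
  m <- 2147483647 # 2^31 - 1
  s <- (as.numeric(seed) %% m) * 48271 + as.numeric(offset) * 16807 + 1
  as.integer(s %% m + 1)
}

# Order-independent string hash used to seed per-gene permutations, so that
# importance results do not depend on gene iteration order.
hash_id <- function(x) {
  vapply(x, function(s) {
    v <- utf8ToInt(s)
    h <- 0
    for (ch in v) h <- (h * 131 + ch) %% 2147483647
    as.integer(h)
  }, integer(1), USE.NAMES = FALSE)
}

stop_config <- function(...) {
  stop(structure(class = c("deepcoxsig_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_data <- function(...) {
  stop(structure(class = c("deepcoxsig_data_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x != round(x) || x < min)
    stop_config("field '", name, "' must be an integer >= ", min)
  as.integer(x)
}

check_fraction <- function(x, name, lo = 0, hi = 1, open_hi = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lo ||
      (if (open_hi) x >= hi else x > hi))
    stop_config("field '", name, "' must lie in [", lo, ", ", hi,
                if (open_hi) ")" else "]")
  as.numeric(x)
}

# Numerically stable log(sum(exp(x))).
logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
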