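# Independent brute-force oracles and small fixture builders. The oracles scan
# explicit ECDF differences over every observed threshold and never touch the
# running-sum code path they check.

# N * one-sided two-sample KS D+ between class and rest, decreasing order:
# max over thresholds v of P(class >= v) - P(rest >= v).
oracle_up_score <- function(expr, labels, cl) {
  a <- expr[labels == cl]
  b <- expr[labels != cl]
  length(expr) * max(vapply(expr, function(v) mean(a >= v) - mean(b >= v),
                            numeric(1L)))
}

# Increasing-order counterpart: max over thresholds of P(class <= v) - P(rest <= v).
oracle_down_score <- function(expr, labels, cl) {
  a <- expr[labels == cl]
  b <- expr[labels != cl]
  length(expr) * max(vapply(expr, function(v) mean(a <= v) - mean(b <= v),
                            numeric(1L)))
}

# Random matrix with almost-surely distinct values plus random labels.
random_dataset <- function(G, N, K, seed) {
  set.seed(seed)
  X <- matrix(stats::rnorm(G * N, 8, 2), G, N,
              dimnames = list(sprintf("g%03d", seq_len(G)),
                              sprintf("s%03d", seq_len(N))))
  repeat {
    labels <- sample(paste0("C", seq_len(K)), N, replace = TRUE)
    tab <- table(factor(labels, levels = paste0("C", seq_len(K))))
    if (all(tab >= 1L) && all(tab < N)) break
  }
  list(X = X, Y = dks_labels(labels, classes = paste0("C", seq_len(K))))
}

# Hand-built two-class model over explicit gene lists (no training), used by
# the classification unit tests.
manual_model <- function(up, down = up, mode = "both", variant = "default",
                         rescale = NULL) {
  structure(list(variant = variant, mode = mode,
                 t = length(up[[1L]]), classes = names(up),
                 up = up, down = down, rescale = rescale, log_base = exp(1)),
            class = "dks_model")
}

# The published-style worked values shared by several tests.
worked_increments <- c(-8/5, 8/3, -8/5, 8/3, -8/5, 8/3, -8/5, -8/5)
worked_running_sum <- c(-8/5, 16/15, -8/15, 32/15, 8/15, 16/5, 8/5, 0)
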