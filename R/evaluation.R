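# Error estimation: 0.632+ bootstrap (Efron-Tibshirani) and the signature-size
# sweep. Both run through one engine so that every (t, variant) cell of a
# sweep is evaluated on the same bootstrap draws, and the score table of each
# bootstrap replicate is computed once and sliced into prefix signatures
# (the t-gene signature is a prefix of the (t+1)-gene one).

# Bootstrap index draws. Stratified: resample with replacement within each
# class (replicates can then never lose a class). Plain: resample the whole
# sample list; replicates missing a class are redrawn (counted), with a cap.
boot_draws <- function(Y, B, seed, stratified = TRUE, max_redraws = 100L * B) {
  set.seed(seed)
  N <- length(Y$labels)
  by_class <- lapply(Y$classes, function(cl) which(Y$labels == cl))
  redraws <- 0L
  draws <- vector("list", B)
  for (b in seq_len(B)) {
    if (stratified) {
      draws[[b]] <- unlist(lapply(by_class, function(ix)
        ix[sample.int(length(ix), length(ix), replace = TRUE)]))
    } else {
      repeat {
        cand <- sample.int(N, N, replace = TRUE)
        if (all(Y$classes %in% Y$labels[cand])) break
        redraws <- redraws + 1L
        if (redraws > max_redraws)
          dks_stop("exhausted ", max_redraws,
                   " redraws of bootstrap replicates missing a class; ",
                   "use stratified resampling")
      }
      draws[[b]] <- cand
    }
  }
  list(draws = draws, redraws = redraws)
}

# Prefix slice of a full selection order into a model.
model_from_order <- function(ord, t, mode, variant, classes, log_base) {
  structure(list(variant = variant, mode = mode, t = as.integer(t),
                 classes = classes,
                 up = lapply(ord$up, utils::head, t),
                 down = lapply(ord$down, utils::head, t),
                 rescale = NULL, log_base = log_base),
            class = "dks_model")
}

# Score tables (one per variant family) for a training set.
variant_scores <- function(X, Y, variants, log_base) {
  raw <- dks_score(X, Y)
  out <- list(default = raw, rescaled = raw)
  if ("weighted" %in% variants) {
    W <- dks_weights(class_mean_ranks(X, Y), nrow(X), log_base = log_base)
    out$weighted <- weighted_scores(raw, W)
  }
  out
}

est_632plus <- function(err_train, err1, gamma) {
  denom <- gamma - err_train
  R <- if (is.na(err1) || denom <= 0 || err1 <= err_train) 0
       else (err1 - err_train) / denom
  R <- min(max(R, 0), 1)
  w <- 0.632 / (1 - 0.368 * R)
  err1p <- min(err1, gamma)
  list(err_632plus = (1 - w) * err_train + w * err1p,
       err_train = err_train, err_loo_boot = err1, gamma = gamma, R = R)
}

boot_engine <- function(X, Y, grid, variants, mode, B, seed,
                        stratified = TRUE, log_base = exp(1)) {
  validate_expression(X)
  Y <- align_labels(X, Y)
  N <- ncol(X); G <- nrow(X)
  grid <- sort(unique(as.integer(grid)))
  if (!length(grid)) dks_stop("empty signature-size grid")
  if (any(grid < 1L) || any(grid > G))
    dks_stop("signature sizes must lie in 1..G (G = ", G, ")")
  variants <- match.arg(variants, c("default", "weighted", "rescaled"),
                        several.ok = TRUE)
  if (B < 1L) dks_stop("B must be >= 1")

  dr <- boot_draws(Y, B, seed, stratified = stratified)
  cells <- expand.grid(t = grid, variant = variants,
                       stringsAsFactors = FALSE)

  # Full-data models: resubstitution error and the no-information rate gamma
  # (gamma = sum_l p_l (1 - q_l), q_l = full-data call proportions).
  sc_full <- variant_scores(X, Y, variants, log_base)
  p <- Y$counts / N
  full <- lapply(seq_len(nrow(cells)), function(ci) {
    v <- cells$variant[ci]
    ord <- signature_order(sc_full[[v]])
    m <- model_from_order(ord, cells$t[ci], mode, v, Y$classes, log_base)
    if (v == "rescaled") m$rescale <- rescale_factors(m, X)
    calls <- dks_classify(X, m)$call
    q <- vapply(Y$classes, function(cl) mean(calls == cl), numeric(1L))
    list(err_train = mean(calls != Y$labels), gamma = sum(p * (1 - q)))
  })

  # Out-of-bag evaluation; per-sample error accumulators per cell. Gene
  # selection, weighting ranks and rescaling factors are all refit inside
  # every replicate - out-of-bag samples never touch the replicate's model.
  err_sum <- matrix(0, nrow(cells), N)
  err_cnt <- matrix(0L, nrow(cells), N)
  for (b in seq_len(B)) {
    idx <- dr$draws[[b]]
    oob <- setdiff(seq_len(N), unique(idx))
    if (!length(oob)) next
    Xb <- X[, idx, drop = FALSE]
    colnames(Xb) <- make.unique(colnames(Xb))
    Yb <- dks_labels(Y$labels[idx], classes = Y$classes)
    sc_b <- variant_scores(Xb, Yb, variants, log_base)
    ords <- lapply(sc_b, signature_order)
    Xoob <- X[, oob, drop = FALSE]
    truth <- Y$labels[oob]
    for (ci in seq_len(nrow(cells))) {
      v <- cells$variant[ci]
      m <- model_from_order(ords[[v]], cells$t[ci], mode, v, Y$classes,
                            log_base)
      if (v == "rescaled") m$rescale <- rescale_factors(m, Xb)
      wrong <- dks_classify(Xoob, m)$call != truth
      err_sum[ci, oob] <- err_sum[ci, oob] + wrong
      err_cnt[ci, oob] <- err_cnt[ci, oob] + 1L
    }
  }

  estimates <- lapply(seq_len(nrow(cells)), function(ci) {
    seen <- err_cnt[ci, ] > 0L
    err1 <- if (any(seen)) mean(err_sum[ci, seen] / err_cnt[ci, seen]) else NA_real_
    e <- est_632plus(full[[ci]]$err_train, err1, full[[ci]]$gamma)
    c(e, list(B = B, seed = seed, redraws = dr$redraws,
              t = cells$t[ci], variant = cells$variant[ci], mode = mode))
  })
  list(cells = cells, estimates = estimates)
}

#' 0.632+ bootstrap error estimate of a Dual-KS classifier
#'
#' Trains the full signature pipeline (scoring, selection, weighting and
#' rescaling as applicable) inside each of \code{B} bootstrap replicates and
#' evaluates each replicate's model on its out-of-bag samples. The 0.632+
#' estimator blends the resubstitution error with the leave-one-out bootstrap
#' error, weighted by the relative overfitting rate against the no-information
#' rate gamma.
#'
#' @inheritParams dks_train
#' @param B number of bootstrap replicates.
#' @param seed integer seed determining every bootstrap draw.
#' @param stratified resample within class (default; replicates then always
#'   contain every class) or plainly across all samples.
#' @return an object of class \code{dks_error632}: list with
#'   \code{err_632plus}, \code{err_train}, \code{err_loo_boot}, \code{gamma},
#'   \code{R}, \code{B}, \code{seed}, \code{redraws}, \code{t},
#'   \code{variant}, \code{mode}.
#' @examples
#' sim <- dks_simulate(G = 60, n_per_class = 8, seed = 3)
#' dks_bootstrap(sim$X, sim$Y, t = 5, B = 10, seed = 3)
#' @export
dks_bootstrap <- function(X, Y, t, variant = c("default", "weighted", "rescaled"),
                          mode = c("both", "up", "down"), B = 100L, seed = 1L,
                          stratified = TRUE, log_base = exp(1)) {
  variant <- match.arg(variant)
  mode <- match.arg(mode)
  eng <- boot_engine(X, Y, grid = t, variants = variant, mode = mode, B = B,
                     seed = seed, stratified = stratified, log_base = log_base)
  structure(eng$estimates[[1L]], class = "dks_error632")
}

#' @export
print.dks_error632 <- function(x, ...) {
  cat(sprintf(
    "0.632+ bootstrap (t = %d, variant = %s, mode = %s, B = %d, seed = %d)\n",
    x$t, x$variant, x$mode, x$B, x$seed))
  cat(sprintf("  err632+ = %.4f  (train %.4f, loo-boot %.4f, gamma %.4f, R %.3f)\n",
              x$err_632plus, x$err_train, x$err_loo_boot, x$gamma, x$R))
  invisible(x)
}

#' Sweep signature size (and variants) and pick the optimum
#'
#' Runs the 0.632+ bootstrap for every combination of signature size in
#' \code{grid} and scoring variant, on a common set of bootstrap draws so the
#' comparison is paired, and returns the combination with the lowest estimated
#' error. Ties go to the smallest \code{t} (parsimony), then to variant order
#' as requested.
#'
#' @inheritParams dks_bootstrap
#' @param grid integer vector of signature sizes to evaluate.
#' @param variants character vector of scoring variants to evaluate.
#' @return an object of class \code{dks_sweep}: list with a \code{table}
#'   data.frame (t, variant, err_train, err1, gamma, R, err632plus),
#'   \code{optimum_t}, \code{optimum_variant}, and the run settings.
#' @examples
#' sim <- dks_simulate(G = 60, n_per_class = 8, seed = 3)
#' sw <- dks_sweep(sim$X, sim$Y, grid = c(5, 10), B = 10, seed = 3)
#' sw$optimum_t
#' @export
dks_sweep <- function(X, Y, grid = seq(5L, 50L, 5L), variants = "default",
                      mode = c("both", "up", "down"), B = 100L, seed = 1L,
                      stratified = TRUE, log_base = exp(1)) {
  mode <- match.arg(mode)
  eng <- boot_engine(X, Y, grid = grid, variants = variants, mode = mode,
                     B = B, seed = seed, stratified = stratified,
                     log_base = log_base)
  tab <- data.frame(
    t = eng$cells$t,
    variant = eng$cells$variant,
    err_train = vapply(eng$estimates, `[[`, numeric(1L), "err_train"),
    err1 = vapply(eng$estimates, `[[`, numeric(1L), "err_loo_boot"),
    gamma = vapply(eng$estimates, `[[`, numeric(1L), "gamma"),
    R = vapply(eng$estimates, `[[`, numeric(1L), "R"),
    err632plus = vapply(eng$estimates, `[[`, numeric(1L), "err_632plus"),
    stringsAsFactors = FALSE)
  best <- order(tab$err632plus, tab$t, match(tab$variant, variants))[1L]
  structure(list(table = tab,
                 optimum_t = tab$t[best],
                 optimum_variant = tab$variant[best],
                 grid = sort(unique(as.integer(grid))), variants = variants,
                 mode = mode, B = B, seed = seed),
            class = "dks_sweep")
}

#' @export
print.dks_sweep <- function(x, ...) {
  cat("dks_sweep (mode =", x$mode, ", B =", x$B, ", seed =", x$seed, ")\n")
  print(x$table, row.names = FALSE, digits = 4)
  cat("optimum: t =", x$optimum_t, ", variant =", x$optimum_variant, "\n")
  invisible(x)
}
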