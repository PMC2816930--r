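# GSEA-style classification against a signature model.

test_that("a perfect prefix of class genes scores the pooled maximum n", {
  model <- manual_model(up = list(A = c("a1", "a2"), B = c("b1", "b2")),
                        mode = "up")
  x <- c(a1 = 10, a2 = 9, b1 = 2, b2 = 1)
  e <- dks_enrichment(x, model)
  expect_equal(e$up[["A"]], 4)  # running sum 2, 4, 2, 0
  expect_equal(e$up[["B"]], 0)
})

test_that("enrichment equals the brute-force KS oracle over pooled positions", {
  set.seed(31)
  for (rep in 1:20) {
    genes <- sprintf("g%02d", 1:12)
    picks <- matrix(sample(genes), nrow = 3)
    model <- manual_model(up = list(A = picks[1, ], B = picks[2, ],
                                    C = picks[3, ]),
                          mode = "up")
    x <- stats::setNames(stats::rnorm(12), genes)
    e <- dks_enrichment(x, model)
    pool <- unlist(model$up)
    src <- rep(names(model$up), each = 4)
    for (cl in names(model$up)) {
      # oracle over the pooled expression values, decreasing order
      expect_equal(e$up[[cl]], oracle_up_score(x[pool], src, cl),
                   tolerance = 1e-9)
    }
  }
})

test_that("classification depends only on ranks (monotone-transform invariance)", {
  sim <- dks_simulate(G = 50, n_per_class = 6, seed = 17)
  model <- dks_train(sim$X, sim$Y, t = 4)
  r1 <- dks_classify(sim$X, model)
  r2 <- dks_classify(2^sim$X, model)          # strictly increasing transform
  r3 <- dks_classify(sim$X * 3 - 100, model)
  expect_identical(r1[, -1], r2[, -1])
  expect_identical(r1[, -1], r3[, -1])
})

test_that("mode both equals the sum of mode up and mode down scores", {
  sim <- dks_simulate(G = 50, n_per_class = 6, seed = 18)
  mb <- dks_train(sim$X, sim$Y, t = 4, mode = "both")
  mu <- mb; mu$mode <- "up"
  md <- mb; md$mode <- "down"
  rb <- dks_classify(sim$X, mb)
  ru <- dks_classify(sim$X, mu)
  rd <- dks_classify(sim$X, md)
  for (cl in mb$classes) {
    col <- paste0("E_", cl)
    expect_equal(rb[[col]], ru[[col]] + rd[[col]], tolerance = 1e-12)
  }
})

test_that("each pooled running sum terminates at zero and 0 <= u' <= n", {
  sim <- dks_simulate(G = 50, n_per_class = 6, seed = 19)
  model <- dks_train(sim$X, sim$Y, t = 4)
  n <- model$t * length(model$classes)
  e <- dks_enrichment(stats::setNames(sim$X[, 1], rownames(sim$X)), model)
  expect_true(all(e$up >= 0 & e$up <= n))
  expect_true(all(e$down >= 0 & e$down <= n))
})

test_that("argmax, margin and tie flag behave as documented", {
  out <- dks_classify_sample(c(g1 = 4, g2 = 1, g3 = 3, g4 = 2),
                             manual_model(up = list(A = c("g1", "g2"),
                                                    B = c("g3", "g4")),
                                          mode = "up"),
                             sample_id = "s1")
  # alternating A/B genes give both classes identical scores: tie, first class
  expect_identical(out$call, "A")
  expect_true(out$tie)
  expect_equal(out$margin, 0)

  out2 <- dks_classify_sample(c(g1 = 4, g2 = 3, g3 = 2, g4 = 1),
                              manual_model(up = list(A = c("g1", "g2"),
                                                     B = c("g3", "g4")),
                                           mode = "up"))
  expect_identical(out2$call, "A")
  expect_false(out2$tie)
  expect_equal(out2$margin, 4 - 0)
})

test_that("missing signature genes error by default and drop symmetrically on request", {
  model <- manual_model(up = list(A = c("g1", "g2"), B = c("g3", "g4")),
                        down = list(A = c("g5", "g6"), B = c("g7", "g8")))
  X <- matrix(stats::rnorm(7 * 2), 7, 2,
              dimnames = list(paste0("g", c(1:3, 5:8)), c("s1", "s2")))
  expect_error(dks_classify(X, model), "g4")
  res <- dks_classify(X, model, allow_missing = TRUE)
  expect_identical(nrow(res), 2L)
  # symmetric drop: pooled up list is now g1,g2 (A) + g3 (B); n=3, n_A=2, n_B=1
  reduced <- manual_model(up = list(A = c("g1", "g2"), B = "g3"),
                          down = list(A = c("g5", "g6"), B = c("g7", "g8")))
  expect_equal(res[, -1], dks_classify(X, reduced)[, -1])
  # dropping a class's whole signature is refused
  X2 <- X[c("g1", "g2", "g5", "g6", "g7", "g8"), ]
  expect_error(dks_classify(X2, model, allow_missing = TRUE), "empty")
})

test_that("matrix classification preserves order, handles zero samples, is columnwise", {
  sim <- dks_simulate(G = 50, n_per_class = 6, seed = 20)
  model <- dks_train(sim$X, sim$Y, t = 4)
  res <- dks_classify(sim$X, model)
  expect_identical(res$sample_id, colnames(sim$X))
  expect_equal(mean(res$call == sim$Y$labels), 1)  # separable by construction

  perm <- sample(ncol(sim$X))
  res_p <- dks_classify(sim$X[, perm], model)
  expect_equal(res_p, res[perm, ], ignore_attr = TRUE)

  empty <- sim$X[, integer(0), drop = FALSE]
  res0 <- dks_classify(empty, model)
  expect_identical(nrow(res0), 0L)
  expect_true(all(c("sample_id", "call", "margin", "tie") %in% names(res0)))
})
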