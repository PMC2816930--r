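# Signature selection, rescaling factors and model interchange.

test_that("a single gene is forced into every signature", {
  X <- matrix(c(5, 4, 3, 2), 1, 4, dimnames = list("g1", paste0("s", 1:4)))
  y <- dks_labels(c("A", "A", "B", "B"))
  model <- select_signatures(dks_score(X, y), t = 1)
  expect_equal(model$up, list(A = "g1", B = "g1"))
  expect_equal(model$down, list(A = "g1", B = "g1"))
})

test_that("genes shifted up in one class only are exactly the selected up-signature", {
  set.seed(21)
  G <- 40; N <- 18
  X <- matrix(rnorm(G * N, 8, 1), G, N,
              dimnames = list(sprintf("g%02d", 1:G), sprintf("s%02d", 1:N)))
  y <- dks_labels(rep(c("A", "B", "C"), each = 6))
  X[1:5, y$labels == "A"] <- X[1:5, y$labels == "A"] + 5
  model <- select_signatures(dks_score(X, y), t = 5)
  expect_setequal(model$up$A, sprintf("g%02d", 1:5))
})

test_that("signatures nest: the t-gene list is a prefix of the (t+1)-gene list", {
  d <- random_dataset(G = 30, N = 12, K = 3, seed = 4)
  sc <- dks_score(d$X, d$Y)
  for (t in c(1, 3, 7)) {
    m1 <- select_signatures(sc, t)
    m2 <- select_signatures(sc, t + 1)
    for (cl in d$Y$classes) {
      expect_identical(m1$up[[cl]], m2$up[[cl]][1:t])
      expect_identical(m1$down[[cl]], m2$down[[cl]][1:t])
    }
  }
  # t = G returns all genes, ordered by score
  mG <- select_signatures(sc, 30)
  expect_setequal(mG$up$C1, rownames(d$X))
  expect_error(select_signatures(sc, 31), "1..G")
})

test_that("selection is deterministic across repeated runs", {
  d <- random_dataset(G = 25, N = 10, K = 2, seed = 6)
  m1 <- dks_train(d$X, d$Y, t = 4, variant = "weighted")
  m2 <- dks_train(d$X, d$Y, t = 4, variant = "weighted")
  expect_identical(m1, m2)
})

test_that("rescaling factors are the per-class training maxima and normalize to 1", {
  sim <- dks_simulate(G = 60, n_per_class = 8, seed = 11)
  model <- dks_train(sim$X, sim$Y, t = 5, variant = "rescaled")
  expect_true(all(model$rescale > 0))
  res <- dks_classify(sim$X, model)
  for (cl in model$classes) {
    expect_equal(max(res[[paste0("E_", cl)]]), 1, tolerance = 1e-12)
    expect_true(all(res[[paste0("E_", cl)]] <= 1 + 1e-12))
  }
})

test_that("equal rescaling factors leave the class calls unchanged", {
  sim <- dks_simulate(G = 60, n_per_class = 8, seed = 12)
  model <- dks_train(sim$X, sim$Y, t = 5)
  scaled <- model
  scaled$rescale <- stats::setNames(rep(2, 3), model$classes)
  expect_identical(dks_classify(sim$X, model)$call,
                   dks_classify(sim$X, scaled)$call)
})

test_that("non-positive rescaling factors are refused with advice", {
  # class A's up genes sit at the bottom of every training sample, so A's
  # running sum never rises above its terminal zero and r_A = 0
  X <- matrix(c(9, 8, 3, 2,
                9, 8, 3, 2), nrow = 4,
              dimnames = list(c("g1", "g2", "g3", "g4"), c("s1", "s2")))
  model <- manual_model(up = list(A = c("g3", "g4"), B = c("g1", "g2")),
                        mode = "up")
  expect_error(rescale_factors(model, X),
               "non-positive rescaling factor.*default variant")
})

test_that("models round-trip through GMT and JSON losslessly", {
  sim <- dks_simulate(G = 40, n_per_class = 6, seed = 14)
  model <- dks_train(sim$X, sim$Y, t = 4, variant = "rescaled")
  gmt <- tempfile(fileext = ".gmt")
  write_gmt(model, gmt)
  sets <- read_gmt(gmt)
  expect_identical(sets$C1_up, model$up$C1)
  expect_identical(sets$C3_down, model$down$C3)
  expect_match(attr(sets, "descriptions")[["C1_up"]], "variant=rescaled;t=4")

  js <- tempfile(fileext = ".json")
  write_dks_model(model, js)
  back <- read_dks_model(js)
  expect_identical(back$up, model$up)
  expect_identical(back$down, model$down)
  expect_equal(back$rescale, model$rescale)
  expect_identical(back$t, model$t)
  expect_identical(back$variant, model$variant)
  expect_identical(back$mode, model$mode)
  expect_identical(dks_classify(sim$X, back), dks_classify(sim$X, model))
})

test_that("external gene lists build a usable model (GMT import path)", {
  sim <- dks_simulate(G = 40, n_per_class = 6, seed = 15)
  trained <- dks_train(sim$X, sim$Y, t = 3)
  gmt <- tempfile(fileext = ".gmt")
  write_gmt(trained, gmt)
  sets <- read_gmt(gmt)
  cls <- trained$classes
  rebuilt <- dks_model(up = stats::setNames(sets[paste0(cls, "_up")], cls),
                       down = stats::setNames(sets[paste0(cls, "_down")], cls))
  expect_identical(dks_classify(sim$X, rebuilt), dks_classify(sim$X, trained))
  expect_error(dks_model(up = list(A = c("g1", "g2"), B = "g3")), "equal sizes")
  expect_error(dks_model(up = list(A = c("g1", "g1"), B = c("g2", "g3"))),
               "duplicated genes")
  expect_error(dks_model(up = list(A = "g1")), "at least 2 classes")
})
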