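ns <- asNamespace("sbipredict")

test_that("dense head gradients match finite differences", {
  set.seed(42)
  p <- ns$head_init(7, c(5, 4), 3)
  X <- matrix(rnorm(6 * 7), 6, 7)
  Y <- matrix(rbinom(18, 1, 0.4), 6, 3)
  loss <- function(p) ns$bce_loss(ns$head_forward(p, X, 2, 0, FALSE)$P, Y)
  cache <- ns$head_forward(p, X, 2, 0, FALSE)
  g <- ns$head_backward(p, cache, (cache$P - Y) / length(Y), 2, 0, FALSE)
  eps <- 1e-6
  base <- loss(p)
  worst <- 0
  for (nm in names(p)) for (i in seq_along(p[[nm]])) {
    p2 <- p; p2[[nm]][i] <- p2[[nm]][i] + eps
    worst <- max(worst, abs((loss(p2) - base) / eps - g[[nm]][i]))
  }
  expect_lt(worst, 1e-5)
})

test_that("CNN channel gradients match finite differences", {
  set.seed(43)
  ch <- ns$channel_init(5, 3, 2, 4)
  hd <- ns$head_init(6, c(5), 3)
  tok <- matrix(sample(0:5, 8 * 30, TRUE), 8, 30)
  Y <- matrix(rbinom(24, 1, 0.4), 8, 3)
  loss <- function(ch) {
    pool <- ns$channel_forward(ch, tok, 4)$pool
    ns$bce_loss(ns$head_forward(hd, pool, 1, 0, FALSE)$P, Y)
  }
  cc <- ns$channel_forward(ch, tok, 4)
  hc <- ns$head_forward(hd, cc$pool, 1, 0, FALSE)
  hg <- ns$head_backward(hd, hc, (hc$P - Y) / length(Y), 1, 0, FALSE)
  cg <- ns$channel_backward(ch, cc, hg$dX, 4)
  base <- loss(ch)
  eps <- 1e-6
  worst <- 0
  blocks <- list(
    list(\(c) c$c1$W, \(c, v) { c$c1$W <- array(v, dim(c$c1$W)); c }, cg$c1$W),
    list(\(c) c$c2$W, \(c, v) { c$c2$W <- array(v, dim(c$c2$W)); c }, cg$c2$W),
    list(\(c) c$c3$W, \(c, v) { c$c3$W <- array(v, dim(c$c3$W)); c }, cg$c3$W),
    list(\(c) c$c3$b, \(c, v) { c$c3$b <- v; c }, cg$c3$b))
  for (blk in blocks) {
    gv <- blk[[3]]
    for (i in seq_len(min(50, length(gv)))) {
      c2 <- blk[[2]](ch, { v <- blk[[1]](ch); v[i] <- v[i] + eps; v })
      worst <- max(worst, abs((loss(c2) - base) / eps - gv[i]))
    }
  }
  # embedding rows (skip the frozen padding row 1)
  for (i in seq_along(cg$E)) {
    if ((i - 1) %% nrow(ch$E) + 1 == 1) next
    c2 <- ch; v <- c2$E; v[i] <- v[i] + eps; c2$E <- matrix(v, nrow(ch$E))
    worst <- max(worst, abs((loss(c2) - base) / eps - cg$E[i]))
  }
  expect_lt(worst, 1e-5)
})

test_that("sub-model architectures have the documented dimensions", {
  cnn <- build_submodel("CNN", list(smd_vocab = 10, biod_vocab = 26), 49)
  expect_equal(nrow(cnn$params$head$W1), 2 * 3 * 64)  # 192 + 192 = 384
  expect_equal(dim(cnn$params$smd$c1$W), c(8, 128, 64))
  expect_equal(dim(cnn$params$smd$c3$W), c(8, 128, 192))
  expect_equal(ncol(cnn$params$head$W3), 49)
  dense <- build_submodel("FP_EMB", 1024 + 1280, 49)
  expect_equal(dim(dense$params$head$W1), c(2304, 512))
  expect_equal(dim(dense$params$head$W2), c(512, 256))
  expect_equal(dim(dense$params$head$W3), c(256, 49))
  expect_error(build_submodel("CNN", 100, 49), "smd_vocab")
})

test_that("early stopping obeys the patience arithmetic", {
  set.seed(1)
  X <- matrix(rnorm(40 * 6), 40, 6)
  Y <- matrix(rbinom(80, 1, 0.5), 40, 2)
  m <- build_submodel("FP_EMB", 6, 2, hidden = c(4, 3), dropout = 0, seed = 2)
  # lr = 0: no weight ever changes, so the validation loss is constant from
  # epoch 1 and training stops at epoch 1 + patience
  fit <- train_submodel(m, X, Y, X, Y,
                        train_config(lr = 0, max_epochs = 50, patience = 3,
                                     batch_size = 16, seed = 3))
  expect_equal(nrow(fit$history), 4)
  expect_equal(attr(fit$history, "best_epoch"), 1)
  # restored weights reproduce the best validation loss
  P <- predict(fit, X)
  expect_equal(ns$bce_loss(P, Y), min(fit$history$val_loss), tolerance = 1e-12)
  expect_error(train_config(max_epochs = 5, patience = 10), "patience")
})

test_that("training beats the class-prior entropy baseline on signal data", {
  set.seed(5)
  n <- 200
  X <- matrix(rnorm(n * 10), n, 10)
  z <- X[, 1] - X[, 2]
  Y <- cbind(as.numeric(z > 0), as.numeric(z <= 0), rbinom(n, 1, 0.2))
  # closed-form baseline: loss of the constant class-prior predictor
  pbar <- pmin(pmax(colMeans(Y), 1e-7), 1 - 1e-7)
  prior_loss <- -mean(t(t(Y) * log(pbar) + t(1 - Y) * log(1 - pbar)))
  m <- build_submodel("FP_EMB", 10, 3, hidden = c(16, 8), dropout = 0, seed = 6)
  fit <- train_submodel(m, X, Y, X, Y,
                        train_config(max_epochs = 40, patience = 10,
                                     batch_size = 64, seed = 7))
  expect_lt(min(fit$history$train_loss), prior_loss)
})

test_that("training is reproducible and outputs stay in (0,1)", {
  set.seed(8)
  X <- matrix(rnorm(60 * 8), 60, 8)
  Y <- matrix(rbinom(120, 1, 0.3), 60, 2)
  tc <- train_config(max_epochs = 5, patience = 2, batch_size = 32, seed = 9)
  f1 <- train_submodel(build_submodel("FP_EMB", 8, 2, hidden = c(6, 4), seed = 1),
                       X, Y, X, Y, tc)
  f2 <- train_submodel(build_submodel("FP_EMB", 8, 2, hidden = c(6, 4), seed = 1),
                       X, Y, X, Y, tc)
  expect_identical(f1$history, f2$history)
  P <- predict(f1, X)
  expect_true(all(P > 0 & P < 1))
})

test_that("ensemble is the unweighted mean, bounded by its members", {
  set.seed(10)
  X <- matrix(rnorm(30 * 5), 30, 5)
  Y <- matrix(rbinom(60, 1, 0.4), 30, 2)
  tc <- train_config(max_epochs = 3, patience = 1, batch_size = 16, seed = 2)
  mods <- list(
    FP_EMB = train_submodel(build_submodel("FP_EMB", 5, 2, hidden = c(4, 3),
                                           seed = 1), X, Y, X, Y, tc),
    SPI_BPI = train_submodel(build_submodel("SPI_BPI", 5, 2, hidden = c(4, 3),
                                            seed = 2), X, Y, X, Y, tc))
  xs <- list(FP_EMB = X, SPI_BPI = X)
  P <- predict_ensemble(mods, xs, allow_subset = TRUE)
  P1 <- predict(mods$FP_EMB, X); P2 <- predict(mods$SPI_BPI, X)
  expect_equal(P, (P1 + P2) / 2, tolerance = 1e-12)
  expect_true(all(P >= pmin(P1, P2) - 1e-12 & P <= pmax(P1, P2) + 1e-12))
  # identical sub-models: ensemble equals any single output
  P_same <- predict_ensemble(list(a = mods$FP_EMB, b = mods$FP_EMB),
                             list(a = X, b = X), allow_subset = TRUE)
  expect_equal(P_same, P1, tolerance = 1e-12)
  # missing modality errors unless the subset flag is set
  expect_error(predict_ensemble(mods, xs), "allow_subset")
})
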