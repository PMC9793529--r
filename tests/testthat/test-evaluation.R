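test_that("fold plans partition the pairs with balanced sizes", {
  plan <- make_folds(100, k = 5, seed = 3)
  expect_length(plan$test, 5)
  expect_equal(vapply(plan$test, length, numeric(1)), rep(20, 5),
               ignore_attr = TRUE)
  expect_setequal(unlist(plan$test), 1:100)
  expect_identical(plan, make_folds(100, k = 5, seed = 3))
  expect_false(identical(plan$test, make_folds(100, k = 5, seed = 4)$test))
  expect_error(make_folds(3, k = 5), "exceeds")
  # small strata are pooled rather than dropped
  plan2 <- make_folds(50, k = 5, seed = 1,
                      strata = c(rep("a", 47), "b", "b", "c"))
  expect_setequal(unlist(plan2$test), 1:50)
})

test_that("metrics reproduce hand-computed confusion arithmetic", {
  # TP=2 FP=1 FN=1 TN=6
  y <- c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0)
  s <- c(0.9, 0.8, 0.2, 0.7, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1)
  m <- compute_metrics(y, s)
  expect_equal(m$Pre, 2 / 3)
  expect_equal(m$Rec, 2 / 3)
  expect_equal(m$F1, 2 / 3)
  expect_equal(m$ACC, 0.8)
  # perfect separation scores 1 everywhere
  mp <- compute_metrics(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(unlist(mp[c("ACC", "AUC", "AUPR", "F1", "Pre", "Rec")]),
               rep(1, 6), ignore_attr = TRUE)
  # single-class truth: AUC undefined with warning
  expect_warning(m1 <- compute_metrics(c(1, 1), c(0.2, 0.7)), "undefined")
  expect_true(is.na(m1$AUC))
})

test_that("AUC and AUPR match the exhaustive threshold-sweep oracle", {
  set.seed(303)
  for (i in 1:100) {
    n <- sample(20:200, 1)
    y <- rbinom(n, 1, runif(1, 0.1, 0.9))
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    s <- round(runif(n), sample(c(1, 2, 6), 1))  # coarse rounding forces ties
    m <- compute_metrics(y, s)
    o <- oracle_sweep(y, s)
    for (nm in c("ACC", "AUC", "AUPR", "F1", "Pre", "Rec"))
      expect_equal(m[[nm]], o[[nm]], tolerance = 1e-10, info = nm)
  }
})

test_that("micro AUC agrees with an independent ROC implementation", {
  set.seed(17)
  y <- rbinom(500, 1, 0.3)
  s <- pmin(pmax(rnorm(500, 0.3 + 0.3 * y, 0.2), 0), 1)
  expect_equal(compute_metrics(y, s)$AUC,
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-10)
})

test_that("metrics are invariant under sample permutation", {
  set.seed(23)
  Y <- matrix(rbinom(300, 1, 0.3), 100, 3)
  S <- matrix(runif(300), 100, 3)
  perm <- sample(100)
  m1 <- compute_metrics(Y, S)
  m2 <- compute_metrics(Y[perm, ], S[perm, ])
  expect_equal(m1, m2, tolerance = 1e-12)
})

test_that("macro averaging neutralizes class-prior ranking", {
  # scores that only encode class priors: constant within class
  set.seed(31)
  n <- 400
  Y <- cbind(rbinom(n, 1, 0.5), rbinom(n, 1, 0.1), rbinom(n, 1, 0.05))
  S <- matrix(rep(colMeans(Y), each = n), n, 3)
  S <- pmin(pmax(S + matrix(rnorm(n * 3, 0, 1e-6), n, 3), 0), 1)  # break ties
  micro <- compute_metrics(Y, S)$AUC
  macro <- compute_metrics(Y, S, average = "macro")$AUC
  expect_gt(micro, 0.6)              # prior-only scores inflate micro AUC
  expect_lt(abs(macro - 0.5), 0.05)  # but carry no within-class information
})

test_that("cross-validation reports per-fold rows plus a mean row", {
  gen <- small_gen(101)
  feats <- build_features(gen$universe)
  sp <- candidate_pair_split(gen$universe)
  neg <- random_sample_negatives(sp$unl, nrow(sp$pos), seed = 2)
  tc <- train_config(max_epochs = 3, patience = 1, batch_size = 64, seed = 2)
  rep <- run_cv(gen$universe, feats, neg, list(fp = "FP_EMB"), tc,
                k = 5, seed = 2, hidden = c(16, 8))
  expect_equal(sum(!is.na(rep$fold)), 5)
  expect_equal(sum(is.na(rep$fold)), 1)
  mean_row <- rep[is.na(rep$fold), ]
  expect_equal(mean_row$AUPR, mean(rep$AUPR[!is.na(rep$fold)]))
  expect_true(all(unlist(rep[c("ACC", "AUC", "AUPR", "F1", "Pre", "Rec")]) >= 0))
  # negatives overlapping positives are rejected
  expect_error(run_cv(gen$universe, feats, sp$pos[1:5, ], list(fp = "FP_EMB"),
                      tc), "overlap")
})

test_that("cold split shares no drug between train and test", {
  gen <- small_gen(111)
  sp <- candidate_pair_split(gen$universe)
  pairs <- rbind(sp$pos, sp$unl[1:50, ])
  cs <- cold_split(pairs, seed = 5)
  expect_length(intersect(pairs$smd_id[cs$train], pairs$smd_id[cs$test]), 0)
  expect_length(intersect(pairs$biod_id[cs$train], pairs$biod_id[cs$test]), 0)
  expect_length(intersect(cs$train, cs$test), 0)
})

test_that("PR curve points integrate to the reported AUPR", {
  set.seed(41)
  y <- rbinom(150, 1, 0.3)
  s <- round(runif(150), 2)
  crv <- pr_curve(y, s)
  expect_true(all(diff(crv$threshold) < 0))
  expect_equal(sum(diff(c(0, crv$recall)) * crv$precision),
               compute_metrics(y, s)$AUPR, tolerance = 1e-12)
})
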