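# a hand-built feature bundle whose flat design is controlled exactly:
# fingerprint bit 1 carries the class, everything else is noise
stub_bundle <- function(smds, biods, smd_flag, seed = 1) {
  set.seed(seed)
  fp <- matrix(rbinom(length(smds) * 16, 1, 0.5), length(smds), 16,
               dimnames = list(smds, NULL))
  fp[, 1] <- as.numeric(smd_flag)
  emb <- matrix(rnorm(length(biods) * 8), length(biods), 8,
                dimnames = list(biods, NULL))
  topo_s <- matrix(0, length(smds), 2, dimnames = list(smds, NULL))
  topo_b <- matrix(0, length(biods), 2, dimnames = list(biods, NULL))
  structure(list(smd_ids = smds, biod_ids = biods,
                 fp = fp, emb = emb,
                 topo = list(spi = topo_s, ssi = topo_s,
                             bpi = topo_b, bbi = topo_b)),
            class = "feature_bundle")
}

test_that("a single stump separates a linearly separable fixture", {
  smds <- sprintf("s%02d", 1:40)
  biods <- sprintf("b%02d", 1:5)
  flag <- seq_along(smds) <= 11  # s01..s11 carry the positive-like feature
  feats <- stub_bundle(smds, biods, flag)
  P <- expand.grid(smd_id = smds[1:10], biod_id = biods,
                   stringsAsFactors = FALSE)
  hidden <- expand.grid(smd_id = smds[11], biod_id = biods,
                        stringsAsFactors = FALSE)
  planted <- expand.grid(smd_id = smds[12:40], biod_id = biods,
                         stringsAsFactors = FALSE)
  U <- rbind(hidden, planted)
  st <- score_unlabeled(P, U, feats,
                        pu_config(n_reps = 1, maxdepth = 1, seed = 3))
  hid_scores <- st$mean_score[seq_len(nrow(hidden))]
  neg_scores <- st$mean_score[nrow(hidden) + seq_len(nrow(planted))]
  expect_true(all(hid_scores > 0.9))
  expect_true(all(neg_scores < 0.1))
})

test_that("score table is deterministic with full bookkeeping", {
  gen <- small_gen(81)
  feats <- build_features(gen$universe)
  sp <- candidate_pair_split(gen$universe)
  cfg <- pu_config(n_reps = 5, seed = 7)
  s1 <- score_unlabeled(sp$pos, sp$unl, feats, cfg)
  s2 <- score_unlabeled(sp$pos, sp$unl, feats, cfg)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), nrow(sp$unl))
  expect_true(all(s1$mean_score >= 0 & s1$mean_score <= 1))
  expect_true(all(s1$n_evals == 5))
  expect_error(score_unlabeled(sp$unl, sp$pos, feats, cfg), ">=")
})

test_that("negative selection eliminates at theta and breaks ties by pair id", {
  st <- data.frame(smd_id = c("s1", "s2", "s3"), biod_id = "b1",
                   mean_score = c(0.9, 0.1, 1.0), n_evals = 5)
  sel <- select_negatives(st, 1, theta = 1)
  expect_equal(sel$smd_id, "s2")
  expect_error(select_negatives(st, 3, theta = 1), "theta")
  # ties: selection invariant under input shuffling
  st2 <- data.frame(smd_id = sprintf("s%02d", 1:10),
                    biod_id = rep(c("b1", "b2"), 5),
                    mean_score = 0.25, n_evals = 5)
  sel_a <- select_negatives(st2, 4)
  sel_b <- select_negatives(st2[sample(10), ], 4)
  expect_identical(sel_a, sel_b)
})

test_that("random sampling is seeded, disjoint from P, hypergeometric", {
  U <- expand.grid(smd_id = sprintf("s%d", 1:5), biod_id = sprintf("b%d", 1:4),
                   stringsAsFactors = FALSE)
  expect_identical(random_sample_negatives(U, 5, seed = 4),
                   random_sample_negatives(U, 5, seed = 4))
  expect_error(random_sample_negatives(U, 21, seed = 1), "exceeds")
  # inclusion frequency of one fixed pair over many seeded draws ~ n/|U|
  hits <- vapply(1:4000, function(s) {
    d <- random_sample_negatives(U, 5, seed = s)
    any(d$smd_id == "s1" & d$biod_id == "b1")
  }, logical(1))
  p_hat <- mean(hits)
  expect_lt(abs(p_hat - 5 / 20), 4 * sqrt(0.25 * 0.75 / 4000))
})

test_that("hidden positives outscore never-interacting pairs on signal data", {
  gen <- generate_universe(sim_config(seed = 91,
                                      hidden_positive_fraction = 0.15))
  feats <- build_features(gen$universe)
  sp <- candidate_pair_split(gen$universe)
  st <- score_unlabeled(sp$pos, sp$unl, feats, pu_config(n_reps = 15, seed = 5))
  hid_key <- paste(gen$hidden_positives$drug_a, gen$hidden_positives$drug_b)
  is_hidden <- paste(st$smd_id, st$biod_id) %in% hid_key
  expect_gt(sum(is_hidden), 0)
  w <- wilcox.test(st$mean_score[is_hidden], st$mean_score[!is_hidden],
                   alternative = "greater", exact = FALSE)
  expect_lt(w$p.value, 0.01)
})

test_that("tree walker reproduces predict.rpart probabilities", {
  set.seed(9)
  X <- matrix(rnorm(300 * 12), 300, 12); colnames(X) <- paste0("V", 1:12)
  y <- factor(as.integer(X[, 3] + 0.5 * X[, 7] + rnorm(300, 0, 0.5) > 0),
              levels = c("0", "1"))
  df <- data.frame(y = y); df$X <- X
  fit <- rpart::rpart(y ~ X, df, method = "class",
                      control = rpart::rpart.control(
                        maxdepth = 4, cp = 0.001, xval = 0,
                        maxcompete = 0, maxsurrogate = 0, minbucket = 5))
  Xn <- matrix(rnorm(400 * 12), 400, 12); colnames(Xn) <- colnames(X)
  dfn <- data.frame(row.names = seq_len(400)); dfn$X <- Xn
  ref <- predict(fit, newdata = dfn)[, "1"]
  got <- sbipredict:::rpart_prob_walk(fit, Xn)
  expect_equal(unname(got), unname(ref), tolerance = 1e-12)
})
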