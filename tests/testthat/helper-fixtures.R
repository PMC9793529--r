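# Shared fixtures and independent oracles, built in code at test time.

options(sbipredict.verbose = FALSE)

# small handmade universe: 3 SMDs, 2 BioDs, 3 proteins
tiny_universe <- function() {
  drugs <- data.frame(
    id = c("s1", "s2", "s3", "b1", "b2"),
    kind = c("SMD", "SMD", "SMD", "BioD", "BioD"),
    structure = c("CCO", "CCN", "c1ccccc1", "ACDEFGHIKL", "MNPQRSTVWY"),
    stringsAsFactors = FALSE)
  edges <- list(
    SSI = data.frame(from = "s1", to = "s2"),
    BBI = data.frame(from = "b1", to = "b2"),
    SPI = data.frame(from = c("s1", "s2"), to = c("p1", "p2")),
    BPI = data.frame(from = c("b1", "b2"), to = c("p2", "p3")))
  sbi <- data.frame(drug_a = c("s1", "s2"), drug_b = c("b1", "b1"),
                    mechanism = c("metabolism", "metabolism"),
                    action = c("increase", "decrease"),
                    stringsAsFactors = FALSE)
  drug_universe(drugs, c("p1", "p2", "p3"), edges, sbi, min_count = 0)
}

# fast generated universe for unit tests (acceptance uses the full defaults)
small_gen <- function(seed = 1, ...) {
  generate_universe(sim_config(n_smd = 30, n_biod = 10, n_protein = 20,
                               n_events = 3, seed = seed, ...))
}

# independent 32-bit FNV-1a + xor-fold, written as a plain byte loop
oracle_hash_bit <- function(s, nbits) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    lo <- bitwXor(h %% 65536, b)
    h <- (h %/% 65536) * 65536 + lo
    h1 <- h %/% 65536; h0 <- h %% 65536
    h <- (((h1 * 16777619) %% 65536) * 65536 + h0 * 16777619) %% 4294967296
  }
  bitwXor(h %/% 65536, h %% 65536) %% nbits + 1
}

# brute-force threshold-sweep metrics oracle (O(n * thresholds) loops)
oracle_sweep <- function(y, s) {
  ths <- sort(unique(s), decreasing = TRUE)
  tpr <- fpr <- pre <- rec <- numeric(length(ths))
  for (i in seq_along(ths)) {
    pred <- s >= ths[i]
    tp <- sum(pred & y == 1); fp <- sum(pred & y == 0)
    fn <- sum(!pred & y == 1); tn <- sum(!pred & y == 0)
    tpr[i] <- tp / (tp + fn); fpr[i] <- fp / (fp + tn)
    pre[i] <- if (tp + fp == 0) 1 else tp / (tp + fp)
    rec[i] <- tpr[i]
  }
  tpr <- c(0, tpr); fpr <- c(0, fpr)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  aupr <- sum(diff(c(0, rec)) * pre)
  pred <- s >= 0.5
  tp <- sum(pred & y == 1); fp <- sum(pred & y == 0)
  fn <- sum(!pred & y == 1); tn <- sum(!pred & y == 0)
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  list(ACC = (tp + tn) / length(y), AUC = auc, AUPR = aupr,
       F1 = if (p + r == 0) 0 else 2 * p * r / (p + r), Pre = p, Rec = r)
}

candidate_pair_split <- function(universe) {
  cand <- enumerate_candidate_pairs(universe)
  list(pos = cand[cand$label == "positive", c("smd_id", "biod_id")],
       unl = cand[cand$label == "unlabeled", c("smd_id", "biod_id")])
}
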