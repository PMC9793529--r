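# Stratified k-fold cross-validation and the six evaluation metrics (ACC,
# AUC, AUPR, F1, Pre, Rec), micro-averaged over all label classes: per-class
# TP/FP/TN/FN are pooled across classes before any ratio is taken.

#' Stratified k-fold plan over drug pairs
#'
#' Partitions the pair indices into `k` folds, balancing the strata (event
#' labels); strata with fewer than `k` members are pooled into one stratum
#' before assignment. Deterministic given the seed.
#'
#' @param n number of pairs (or a data.frame whose rows are pairs).
#' @param k number of folds (default 5).
#' @param seed RNG seed.
#' @param strata optional vector of length `n` to stratify by.
#' @return Object of class `fold_plan`: list with `k`, `test` (list of k
#'   disjoint index vectors covering `1..n`) and `seed`.
#' @export
make_folds <- function(n, k = 5, seed = 1, strata = NULL) {
  if (is.data.frame(n)) n <- nrow(n)
  if (k > n) stopf("k (%d) exceeds the number of pairs (%d)", k, n)
  strata <- if (is.null(strata)) rep(1L, n) else as.character(strata)
  tab <- table(strata)
  small <- names(tab)[tab < k]
  if (length(small)) strata[strata %in% small] <- ".pooled"
  fold_of <- integer(n)
  local_seed(seed, {
    for (s in unique(strata)) {
      idx <- sample(which(strata == s))
      fold_of[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  structure(list(k = k, test = split(seq_len(n), fold_of), seed = seed),
            class = "fold_plan")
}

# exact trapezoidal area under the micro ROC curve (ties grouped)
roc_auc <- function(y, s) {
  if (length(unique(y)) < 2) return(NA_real_)
  ord <- order(s, decreasing = TRUE)
  y <- y[ord]; s <- s[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- !duplicated(s, fromLast = TRUE)  # one operating point per threshold
  tpr <- c(0, tp[last] / sum(y))
  fpr <- c(0, fp[last] / sum(1 - y))
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# step-interpolated area under the micro precision-recall curve
pr_auc <- function(y, s) {
  if (sum(y) == 0) return(NA_real_)
  ord <- order(s, decreasing = TRUE)
  y <- y[ord]; s <- s[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- !duplicated(s, fromLast = TRUE)
  rec <- tp[last] / sum(y)
  pre <- tp[last] / (tp[last] + fp[last])
  sum(diff(c(0, rec)) * pre)
}

#' Multi-class classification metrics (micro or macro averaged)
#'
#' In the default micro mode, TP/FP/TN/FN are accumulated over all classes
#' (each class indicator of each sample is one pooled binary decision at
#' threshold 0.5): accuracy, precision, recall, F1, the trapezoidal area
#' under the pooled ROC curve and the step-interpolated area under the
#' pooled precision-recall curve. Micro AUC is dominated by the frequent
#' classes, so its no-information level sits well above 0.5 whenever the
#' model can learn the unequal class priors. Macro mode computes each
#' metric per class and averages over the classes where it is defined; a
#' prior-only predictor scores 0.5 macro AUC, making it the cleaner null
#' reference.
#'
#' @param y_true multi-hot label matrix (or binary vector).
#' @param y_score probability matrix (or vector) of the same shape.
#' @param threshold decision threshold for ACC/F1/Pre/Rec (default 0.5).
#' @param average `"micro"` (default) or `"macro"`.
#' @return Object of class `metric_report`: named list with `ACC`, `AUC`,
#'   `AUPR`, `F1`, `Pre`, `Rec`.
#' @export
compute_metrics <- function(y_true, y_score, threshold = 0.5,
                            average = c("micro", "macro")) {
  average <- match.arg(average)
  Y <- as.matrix(y_true)
  S <- as.matrix(y_score)
  if (length(Y) != length(S)) stopf("y_true and y_score differ in size")
  if (any(S < 0 | S > 1)) stopf("scores must lie in [0, 1]")
  one <- function(y, s) {
    pred <- as.numeric(s >= threshold)
    tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
    tn <- sum(pred == 0 & y == 0); fn <- sum(pred == 0 & y == 1)
    pre <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    list(ACC = (tp + tn) / length(y), AUC = roc_auc(y, s),
         AUPR = pr_auc(y, s),
         F1 = if (pre + rec == 0) 0 else 2 * pre * rec / (pre + rec),
         Pre = pre, Rec = rec)
  }
  out <- if (average == "micro") {
    one(as.numeric(Y), as.numeric(S))
  } else {
    per <- lapply(seq_len(ncol(Y)), function(j) one(Y[, j], S[, j]))
    lapply(stats::setNames(names(per[[1]]), names(per[[1]])), function(nm) {
      v <- vapply(per, function(p) p[[nm]] %||% NA_real_, numeric(1))
      mean(v, na.rm = TRUE)
    })
  }
  if (is.na(out$AUC)) warnf("AUC undefined: truth contains a single class")
  structure(out, class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("ACC %.4f | AUC %.4f | AUPR %.4f | F1 %.4f | Pre %.4f | Rec %.4f\n",
              x$ACC, x$AUC, x$AUPR, x$F1, x$Pre, x$Rec))
  invisible(x)
}

# primary stratification label of each pair: first active event id, else 0
primary_class <- function(Y) {
  ev <- apply(Y[, -1, drop = FALSE] > 0, 1, function(r) {
    w <- which(r)
    if (length(w)) w[1] else 0L
  })
  as.integer(ev)
}

# train the requested modality sub-models on one split
train_modalities <- function(features, pairs_tr, y_tr, pairs_val, y_val,
                             modalities, n_classes, config,
                             hidden = c(512, 256), dropout = 0.3,
                             f = 64, d_emb = 128) {
  models <- list()
  for (mod in modalities) {
    x_tr <- pair_design(features, pairs_tr, mod)
    x_val <- pair_design(features, pairs_val, mod)
    dims <- if (mod == "CNN") {
      list(smd_vocab = features$vocab$smiles$unknown,
           biod_vocab = features$vocab$aa$unknown)
    } else ncol(x_tr)
    m <- build_submodel(mod, dims, n_classes, hidden = hidden,
                        dropout = dropout, f = f, d_emb = d_emb,
                        seed = derive_seed(config$seed, mod))
    models[[mod]] <- train_submodel(m, x_tr, y_tr, x_val, y_val, config)
  }
  models
}

#' Cross-validated evaluation of modality recipes
#'
#' For each requested modality subset (recipe), trains the per-modality
#' sub-models on each fold's training pairs (with a stratified 10%
#' validation split for early stopping), fuses them by output averaging,
#' and reports the micro metrics on the fold's test pairs. The labeled
#' positives and the supplied negatives together form the evaluation pair
#' set; negatives carry the class-0 label.
#'
#' @param universe a `drug_universe`.
#' @param features a [build_features()] bundle.
#' @param negatives data.frame of negative pairs (`smd_id`, `biod_id`),
#'   disjoint from the positives.
#' @param recipes named list of modality subsets, e.g.
#'   `list(all = c("CNN","FP_EMB","SPI_BPI","SSI_BBI"), cnn = "CNN")`.
#' @param config a [train_config()].
#' @param k number of folds (default 5).
#' @param folds_to_run optional subset of fold indices (e.g. `1` for a
#'   single 80/20 split).
#' @param seed fold-assignment seed.
#' @param hidden,dropout,f,d_emb architecture settings forwarded to
#'   [build_submodel()].
#' @return data.frame: one row per (recipe, fold) plus a `mean` row per
#'   recipe, with the six metric columns.
#' @export
run_cv <- function(universe, features, negatives, recipes, config = train_config(),
                   k = 5, folds_to_run = NULL, seed = 1,
                   hidden = c(512, 256), dropout = 0.3, f = 64, d_emb = 128) {
  positives <- unique(universe$sbi[c("drug_a", "drug_b")])
  names(positives) <- c("smd_id", "biod_id")
  pos_key <- paste(positives$smd_id, positives$biod_id)
  neg_key <- paste(negatives$smd_id, negatives$biod_id)
  if (any(neg_key %in% pos_key))
    stopf("negatives overlap the positive set (%d pair(s))",
          sum(neg_key %in% pos_key))
  pairs <- rbind(positives, negatives[c("smd_id", "biod_id")])
  rownames(pairs) <- NULL
  Y <- pair_label_matrix(universe, pairs)
  n_classes <- ncol(Y)
  strata <- primary_class(Y)
  plan <- make_folds(nrow(pairs), k = k, seed = seed, strata = strata)
  folds_to_run <- folds_to_run %||% seq_len(k)

  bad <- setdiff(unique(unlist(recipes)), .modalities)
  if (length(bad)) stopf("unknown modalities in recipes: %s", paste(bad, collapse = ", "))

  rows <- list()
  for (fi in folds_to_run) {
    test_idx <- plan$test[[fi]]
    tr_idx <- setdiff(seq_len(nrow(pairs)), test_idx)
    # stratified 10% of the training fold held out for early stopping
    val_plan <- make_folds(length(tr_idx), k = 10,
                           seed = derive_seed(seed, paste0("val", fi)),
                           strata = strata[tr_idx])
    val_idx <- tr_idx[val_plan$test[[1]]]
    fit_idx <- setdiff(tr_idx, val_idx)

    all_mods <- unique(unlist(recipes))
    models <- train_modalities(features, pairs[fit_idx, ], Y[fit_idx, , drop = FALSE],
                               pairs[val_idx, ], Y[val_idx, , drop = FALSE],
                               all_mods, n_classes, config,
                               hidden = hidden, dropout = dropout,
                               f = f, d_emb = d_emb)
    x_test <- lapply(stats::setNames(all_mods, all_mods), function(mod)
      pair_design(features, pairs[test_idx, ], mod))
    for (rn in names(recipes)) {
      mods <- recipes[[rn]]
      P <- predict_ensemble(models[mods], x_test[mods], allow_subset = TRUE)
      m <- compute_metrics(Y[test_idx, , drop = FALSE], P)
      rows[[length(rows) + 1]] <- data.frame(recipe = rn, fold = fi,
                                             ACC = m$ACC, AUC = m$AUC,
                                             AUPR = m$AUPR, F1 = m$F1,
                                             Pre = m$Pre, Rec = m$Rec)
    }
  }
  out <- do.call(rbind, rows)
  means <- do.call(rbind, lapply(split(out, out$recipe), function(d) {
    data.frame(recipe = d$recipe[1], fold = NA_integer_,
               ACC = mean(d$ACC), AUC = mean(d$AUC), AUPR = mean(d$AUPR),
               F1 = mean(d$F1), Pre = mean(d$Pre), Rec = mean(d$Rec))
  }))
  rownames(means) <- NULL
  rbind(out, means)
}

#' Sampling-strategy comparison on synthetic universes
#'
#' For each seed, generates a universe with hidden (true-but-unlabeled)
#' positives, selects one negative set by PU undersampling and one by
#' uniform random sampling, counts the hidden positives contaminating each,
#' and (optionally) trains a downstream sub-model on each negative set to
#' compare test AUPR. This reproduces the experiment design behind the
#' PU-versus-random sampling comparison, at desk scale.
#'
#' @param seeds integer vector; one universe and comparison per seed.
#' @param sim_args [sim_config()] overrides (the seed is set per run).
#' @param pu_args [pu_config()] overrides.
#' @param train_args [train_config()] overrides.
#' @param downstream logical: also train/evaluate the downstream model.
#' @param modality modality of the downstream sub-model (default
#'   `"FP_EMB"`).
#' @param f,d_emb CNN settings forwarded when `modality = "CNN"`.
#' @return data.frame, one row per seed: hidden-positive counts in each
#'   negative set and (if requested) the downstream AUPRs.
#' @export
sampling_comparison <- function(seeds = 1:10, sim_args = list(),
                                pu_args = list(), train_args = list(),
                                downstream = TRUE, modality = "FP_EMB",
                                f = 16, d_emb = 16) {
  rows <- lapply(seeds, function(s) {
    gen <- generate_universe(do.call(sim_config,
                                     utils::modifyList(sim_args, list(seed = s))))
    u <- gen$universe
    feats <- build_features(u)
    cand <- enumerate_candidate_pairs(u)
    pos <- cand[cand$label == "positive", c("smd_id", "biod_id")]
    unl <- cand[cand$label == "unlabeled", c("smd_id", "biod_id")]
    pu <- do.call(pu_config, utils::modifyList(pu_args, list(seed = s)))
    scores <- score_unlabeled(pos, unl, feats, pu)
    neg_pu <- select_negatives(scores, nrow(pos), theta = pu$theta)
    neg_rd <- random_sample_negatives(unl, nrow(pos), seed = s)
    hid_key <- paste(gen$hidden_positives$drug_a, gen$hidden_positives$drug_b)
    row <- data.frame(
      seed = s, n_pos = nrow(pos), n_hidden = length(unique(hid_key)),
      hidden_in_pu = sum(paste(neg_pu$smd_id, neg_pu$biod_id) %in% hid_key),
      hidden_in_random = sum(paste(neg_rd$smd_id, neg_rd$biod_id) %in% hid_key))
    if (downstream) {
      tc <- do.call(train_config,
                    utils::modifyList(list(max_epochs = 20, patience = 5),
                                      utils::modifyList(train_args, list(seed = s))))
      rec <- stats::setNames(list(modality), "m")
      r_pu <- run_cv(u, feats, neg_pu[c("smd_id", "biod_id")], rec, tc,
                     k = 5, folds_to_run = 1, seed = s, f = f, d_emb = d_emb)
      r_rd <- run_cv(u, feats, neg_rd, rec, tc,
                     k = 5, folds_to_run = 1, seed = s, f = f, d_emb = d_emb)
      row$aupr_pu <- r_pu$AUPR[1]
      row$aupr_random <- r_rd$AUPR[1]
    }
    row
  })
  do.call(rbind, rows)
}

#' Modality ablation study on synthetic universes
#'
#' Trains the four per-modality sub-models once per seed on a signal-bearing
#' synthetic universe (PU-selected negatives) and evaluates every requested
#' modality subset on the held-out fold — the experiment design behind the
#' feature-combination comparison.
#'
#' @param seeds integer vector of universe/training seeds.
#' @param recipes named list of modality subsets; defaults to the four
#'   singletons plus the full four-modality ensemble.
#' @param sim_args,pu_args,train_args configuration overrides.
#' @param f,d_emb CNN filter base and embedding width.
#' @return data.frame of per-seed fold metrics, one row per (seed, recipe).
#' @export
ablation_study <- function(seeds = 1:5, recipes = NULL, sim_args = list(),
                           pu_args = list(), train_args = list(),
                           f = 16, d_emb = 16) {
  recipes <- recipes %||% c(
    stats::setNames(as.list(.modalities), .modalities),
    list(ensemble = .modalities))
  rows <- lapply(seeds, function(s) {
    gen <- generate_universe(do.call(sim_config,
                                     utils::modifyList(sim_args, list(seed = s))))
    u <- gen$universe
    feats <- build_features(u)
    cand <- enumerate_candidate_pairs(u)
    pos <- cand[cand$label == "positive", c("smd_id", "biod_id")]
    unl <- cand[cand$label == "unlabeled", c("smd_id", "biod_id")]
    pu <- do.call(pu_config, utils::modifyList(pu_args, list(seed = s)))
    neg <- select_negatives(score_unlabeled(pos, unl, feats, pu),
                            nrow(pos), theta = pu$theta)
    tc <- do.call(train_config,
                  utils::modifyList(list(max_epochs = 20, patience = 5),
                                    utils::modifyList(train_args, list(seed = s))))
    rep <- run_cv(u, feats, neg[c("smd_id", "biod_id")], recipes, tc,
                  k = 5, folds_to_run = 1, seed = s, f = f, d_emb = d_emb)
    cbind(seed = s, rep[!is.na(rep$fold), ])
  })
  do.call(rbind, rows)
}

#' Null calibration: micro AUC under zero signal
#'
#' Generates signal-free universes (`signal_strength = 0`), trains a
#' sub-model, and reports the held-out micro AUC, which should fluctuate
#' around 0.5: the labels carry no information about any feature.
#'
#' The split is drug-disjoint ([cold_split()]), not pair-level. With shared
#' drugs and a balanced evaluation set, a model can memorize each drug's
#' realized positive frequency from its identity — a real transductive
#' correlation that inflates pair-level AUC above 0.5 even on label-free
#' features. The cold split removes that channel, so the remaining AUC
#' isolates feature-borne signal.
#'
#' @param seeds integer vector.
#' @param modality sub-model used (default `"FP_EMB"`).
#' @param sim_args,train_args configuration overrides
#'   (`signal_strength = 0` is enforced).
#' @return data.frame with one held-out micro AUC per seed.
#' @export
null_calibration <- function(seeds = 1:5, modality = "FP_EMB",
                             sim_args = list(), train_args = list()) {
  rows <- lapply(seeds, function(s) {
    gen <- generate_universe(do.call(sim_config,
      utils::modifyList(sim_args, list(seed = s, signal_strength = 0))))
    u <- gen$universe
    feats <- build_features(u)
    cand <- enumerate_candidate_pairs(u)
    pos <- cand[cand$label == "positive", c("smd_id", "biod_id")]
    unl <- cand[cand$label == "unlabeled", c("smd_id", "biod_id")]
    neg <- random_sample_negatives(unl, nrow(pos), seed = s)
    pairs <- rbind(pos, neg)
    rownames(pairs) <- NULL
    Y <- pair_label_matrix(u, pairs)
    sp <- cold_split(pairs, seed = s)
    strata <- primary_class(Y)[sp$train]
    vplan <- make_folds(length(sp$train), k = 10,
                        seed = derive_seed(s, "nullval"), strata = strata)
    val_idx <- sp$train[vplan$test[[1]]]
    fit_idx <- setdiff(sp$train, val_idx)
    tc <- do.call(train_config,
                  utils::modifyList(list(max_epochs = 15, patience = 5),
                                    utils::modifyList(train_args, list(seed = s))))
    models <- train_modalities(feats, pairs[fit_idx, ], Y[fit_idx, , drop = FALSE],
                               pairs[val_idx, ], Y[val_idx, , drop = FALSE],
                               modality, ncol(Y), tc)
    P <- predict(models[[modality]], pair_design(feats, pairs[sp$test, ], modality))
    Yt <- Y[sp$test, , drop = FALSE]
    micro <- compute_metrics(Yt, P)$AUC
    # no-information reference: same scores against permuted pair labels
    Yp <- Yt[local_seed(derive_seed(s, "perm"), sample(nrow(Yt))), , drop = FALSE]
    micro_perm <- compute_metrics(Yp, P)$AUC
    macro <- compute_metrics(Yt, P, average = "macro")$AUC
    data.frame(seed = s, micro_auc = micro, micro_auc_permuted = micro_perm,
               macro_auc = macro, n_test = length(sp$test))
  })
  do.call(rbind, rows)
}

#' Drug-disjoint (cold) train/test split of a pair set
#'
#' Holds out a fraction of SMDs and of BioDs; test pairs are those whose
#' drugs are BOTH held out, training pairs those whose drugs are both
#' retained (pairs mixing the two groups are discarded). No drug is shared
#' between training and test, which removes the drug-identity
#' memorization channel that pair-level splits admit.
#'
#' @param pairs data.frame with `smd_id`, `biod_id`.
#' @param smd_frac,biod_frac held-out fractions (defaults 0.4).
#' @param seed RNG seed.
#' @return List with `train` and `test` row-index vectors into `pairs`.
#' @export
cold_split <- function(pairs, smd_frac = 0.4, biod_frac = 0.4, seed = 1) {
  smds <- unique(pairs$smd_id); biods <- unique(pairs$biod_id)
  local_seed(seed, {
    s_test <- sample(smds, max(1, round(smd_frac * length(smds))))
    b_test <- sample(biods, max(1, round(biod_frac * length(biods))))
  })
  in_s <- pairs$smd_id %in% s_test
  in_b <- pairs$biod_id %in% b_test
  list(train = which(!in_s & !in_b), test = which(in_s & in_b))
}

#' Micro precision-recall curve points
#'
#' One operating point per distinct score threshold, ready for export or
#' plotting; the step-interpolated area under these points equals the AUPR
#' reported by [compute_metrics()].
#'
#' @param y_true multi-hot label matrix (or binary vector).
#' @param y_score probability matrix (or vector) of the same shape.
#' @return data.frame with `threshold`, `recall`, `precision`, ordered by
#'   decreasing threshold.
#' @export
pr_curve <- function(y_true, y_score) {
  y <- as.numeric(as.matrix(y_true))
  s <- as.numeric(as.matrix(y_score))
  ord <- order(s, decreasing = TRUE)
  y <- y[ord]; s <- s[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- !duplicated(s, fromLast = TRUE)
  data.frame(threshold = s[last],
             recall = tp[last] / sum(y),
             precision = tp[last] / (tp[last] + fp[last]))
}
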