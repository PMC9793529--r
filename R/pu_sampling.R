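# Positive-unlabeled undersampling: repeatedly train a decision tree on the
# positives versus a balanced random draw from the unlabeled set, average the
# trees' positive-class probabilities over all unlabeled pairs, eliminate
# suspected positives at a score threshold, and keep the lowest-scoring
# pairs as high-confidence negatives.

#' PU-sampling configuration
#'
#' @param n_reps number of balanced tree repetitions (T). Score variance
#'   decays as 1/T; the default 50 stabilizes ranks at desk scale.
#' @param maxdepth,min_leaf decision-tree settings ("simple" trees).
#' @param theta elimination threshold in (0, 1]: unlabeled pairs whose mean
#'   score is >= theta are removed before negative selection. The default
#'   1.0 eliminates only unanimously positive-scored pairs.
#' @param seed RNG seed for the balanced draws.
#' @return Object of class `pu_config`.
#' @export
pu_config <- function(n_reps = 50, maxdepth = 4, min_leaf = 5,
                      theta = 1.0, seed = 1) {
  if (n_reps < 1) stopf("n_reps must be >= 1")
  if (theta <= 0 || theta > 1) stopf("theta must lie in (0, 1]")
  structure(list(n_reps = as.integer(n_reps), maxdepth = as.integer(maxdepth),
                 min_leaf = as.integer(min_leaf), theta = as.numeric(theta),
                 seed = as.integer(seed)),
            class = "pu_config")
}

# Vectorized class-probability prediction by walking a fitted rpart tree.
# Requires a tree grown with maxcompete = 0, maxsurrogate = 0 on complete
# data (one splits row per internal node). Verified against predict.rpart
# in the unit tests.
rpart_prob_walk <- function(fit, X, positive = "1") {
  frame <- fit$frame
  ylev <- attr(fit, "ylevels")
  k <- length(ylev)
  pos_col <- 1 + k + match(positive, ylev)
  prob <- frame$yval2[, pos_col]
  if (nrow(frame) == 1) return(rep(prob[1], nrow(X)))
  nn <- as.integer(rownames(frame))
  is_leaf <- frame$var == "<leaf>"
  split_row <- integer(nrow(frame))
  split_row[!is_leaf] <- seq_len(sum(!is_leaf))
  sp <- fit$splits
  var_col <- match(sub("^X", "", rownames(sp)), colnames(X))
  out <- numeric(nrow(X))
  rec <- function(fr, idx) {
    if (!length(idx)) return()
    if (is_leaf[fr]) { out[idx] <<- prob[fr]; return() }
    srow <- split_row[fr]
    xv <- X[idx, var_col[srow]]
    cut <- sp[srow, "index"]
    go_left <- if (sp[srow, "ncat"] < 0) xv < cut else xv >= cut
    left_fr <- match(2L * nn[fr], nn)
    right_fr <- match(2L * nn[fr] + 1L, nn)
    rec(left_fr, idx[go_left])
    rec(right_fr, idx[!go_left])
  }
  rec(1L, seq_len(nrow(X)))
  out
}

fit_pu_tree <- function(Xtrain, y, config) {
  df <- data.frame(y = factor(y, levels = c("0", "1")))
  df$X <- Xtrain
  rpart::rpart(y ~ X, data = df, method = "class",
               control = rpart::rpart.control(
                 maxdepth = config$maxdepth, minbucket = config$min_leaf,
                 cp = 0.001, xval = 0, maxcompete = 0, maxsurrogate = 0))
}

#' Score all unlabeled pairs by repeated balanced tree training
#'
#' For each of `n_reps` repetitions, `|P|` unlabeled pairs are drawn
#' uniformly without replacement as temporary negatives, a decision tree is
#' trained on the positives (label 1) versus the draw (label 0) using the
#' concatenated pair features, and every unlabeled pair is scored with the
#' tree's positive-class probability. The final score of a pair is the mean
#' over the repetitions: its confidence of being a hidden positive.
#'
#' @param positives,unlabeled data.frames with `smd_id`, `biod_id`.
#' @param features a [build_features()] bundle.
#' @param config a [pu_config()].
#' @return Object of class `score_table`: data.frame (`smd_id`, `biod_id`,
#'   `mean_score`, `n_evals`).
#' @export
score_unlabeled <- function(positives, unlabeled, features, config = pu_config()) {
  nP <- nrow(positives); nU <- nrow(unlabeled)
  if (nP < 2) stopf("need at least 2 positive pairs, got %d", nP)
  if (nU < nP) stopf("|U| (%d) must be >= |P| (%d)", nU, nP)
  XP <- pair_design_flat(features, positives)
  XU <- pair_design_flat(features, unlabeled)
  colnames(XP) <- colnames(XU) <- paste0("V", seq_len(ncol(XP)))
  if (all(apply(rbind(XP, XU), 2, function(v) length(unique(v))) == 1))
    stopf("degenerate features: all columns constant")
  y <- c(rep("1", nP), rep("0", nP))
  acc <- numeric(nU)
  local_seed(config$seed, {
    for (t in seq_len(config$n_reps)) {
      draw <- sample.int(nU, nP)
      fit <- fit_pu_tree(rbind(XP, XU[draw, , drop = FALSE]), y, config)
      acc <- acc + rpart_prob_walk(fit, XU)
    }
  })
  out <- data.frame(smd_id = unlabeled$smd_id, biod_id = unlabeled$biod_id,
                    mean_score = acc / config$n_reps,
                    n_evals = config$n_reps,
                    stringsAsFactors = FALSE)
  class(out) <- c("score_table", class(out))
  out
}

#' Select high-confidence negatives from a score table
#'
#' Pairs with mean score >= `theta` are eliminated as suspected positives;
#' the remainder are sorted by ascending score (ties broken by lexicographic
#' pair id) and the first `n` are returned — the pairs the trees most
#' consistently judged unlike the labeled positives.
#'
#' @param scores a [score_unlabeled()] table.
#' @param n number of negatives to select (typically `|P|`, for a 1:1
#'   balanced training set).
#' @param theta elimination threshold (default 1.0).
#' @return data.frame of `n` selected pairs with their scores.
#' @export
select_negatives <- function(scores, n, theta = 1.0) {
  keep <- scores[scores$mean_score < theta, , drop = FALSE]
  if (nrow(keep) < n)
    stopf("only %d pairs score below theta = %g; %d more needed for n = %d",
          nrow(keep), theta, n - nrow(keep), n)
  ord <- order(keep$mean_score, keep$smd_id, keep$biod_id)
  sel <- keep[ord[seq_len(n)], , drop = FALSE]
  rownames(sel) <- NULL
  sbi_log(sprintf("select_negatives: eliminated %d pair(s) at theta = %g; kept %d of %d",
                  nrow(scores) - nrow(keep), theta, n, nrow(keep)))
  sel
}

#' Uniform random negative sampling (baseline)
#'
#' Draws `n` unlabeled pairs uniformly without replacement — the sampling
#' strategy PU-sampling is compared against.
#'
#' @param unlabeled data.frame with `smd_id`, `biod_id`.
#' @param n number of pairs to draw.
#' @param seed RNG seed.
#' @return data.frame of `n` drawn pairs.
#' @export
random_sample_negatives <- function(unlabeled, n, seed = 1) {
  if (n > nrow(unlabeled))
    stopf("n (%d) exceeds the unlabeled pool (%d)", n, nrow(unlabeled))
  idx <- local_seed(seed, sample.int(nrow(unlabeled), n))
  out <- unlabeled[idx, c("smd_id", "biod_id"), drop = FALSE]
  rownames(out) <- NULL
  out
}
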