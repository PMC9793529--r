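# Four per-modality sub-models — one with two CNN sequence encoders, three
# on precomputed dense vectors — each ending in the same three-layer dense
# classifier (hidden 512 and 256 units, sigmoid output per class), fused by
# unweighted output averaging.

#' Training schedule configuration
#'
#' Adam, up to `max_epochs` epochs, early stopping when the validation loss
#' has not decreased for `patience` epochs, restoring the best-validation
#' weights. The loss is mean per-class binary cross-entropy (the targets are
#' multi-hot: several event neurons may be active for one pair).
#'
#' @param lr learning rate (default 1e-3).
#' @param max_epochs maximum epochs (default 100).
#' @param patience early-stopping patience in epochs (default 10; must be
#'   smaller than `max_epochs`).
#' @param batch_size minibatch size (default 256).
#' @param seed RNG seed for initialization shuffling and dropout.
#' @return Object of class `train_config`.
#' @export
train_config <- function(lr = 1e-3, max_epochs = 100, patience = 10,
                         batch_size = 256, seed = 1) {
  if (patience >= max_epochs) stopf("patience must be < max_epochs")
  structure(list(lr = lr, max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "train_config")
}

#' Build a per-modality sub-model
#'
#' Dense modalities (`FP_EMB`, `SPI_BPI`, `SSI_BBI`) feed the concatenated
#' pair vector straight into the classifier head. The `CNN` modality first
#' encodes the two token channels (SMILES and amino acids) with independent
#' three-layer 1D convolutions (kernel length `kernel`, filter counts `f`,
#' `2f`, `3f`) followed by global max pooling; the two pooled outputs
#' (length `3f` each) are concatenated and fed to the head.
#'
#' @param modality one of `"CNN"`, `"FP_EMB"`, `"SPI_BPI"`, `"SSI_BBI"`.
#' @param dims for dense modalities, the input dimension (integer); for
#'   `"CNN"`, a list with `smd_vocab` and `biod_vocab` (vocabulary sizes,
#'   unknown index included).
#' @param n_classes number of output neurons (classes incl. class 0).
#' @param hidden hidden-layer widths (default `c(512, 256)`).
#' @param dropout dropout rate on hidden units (default 0.3).
#' @param f CNN base filter count (default 64 for filters 64/128/192).
#' @param d_emb token-embedding width (default 128).
#' @param kernel convolution kernel length (default 8).
#' @param seed initialization seed.
#' @return Object of class `sbi_submodel`.
#' @export
build_submodel <- function(modality, dims, n_classes,
                           hidden = c(512, 256), dropout = 0.3,
                           f = 64, d_emb = 128, kernel = 8, seed = 1) {
  modality <- match.arg(modality, .modalities)
  params <- local_seed(seed, {
    if (modality == "CNN") {
      if (!is.list(dims) || is.null(dims$smd_vocab) || is.null(dims$biod_vocab))
        stopf("CNN dims must be list(smd_vocab =, biod_vocab =)")
      list(smd = channel_init(dims$smd_vocab, d_emb, f, kernel),
           biod = channel_init(dims$biod_vocab, d_emb, f, kernel),
           head = head_init(2 * 3 * f, hidden, n_classes))
    } else {
      if (!is.numeric(dims) || length(dims) != 1 || dims < 1)
        stopf("dense dims must be a single positive input dimension")
      list(head = head_init(as.integer(dims), hidden, n_classes))
    }
  })
  structure(list(modality = modality, dims = dims, n_classes = n_classes,
                 hidden = hidden, dropout = dropout, f = f, d_emb = d_emb,
                 kernel = kernel, seed = seed, params = params,
                 fitted = FALSE, history = NULL),
            class = "sbi_submodel")
}

#' @export
print.sbi_submodel <- function(x, ...) {
  cat(sprintf("sbi_submodel [%s]: head %s -> %d outputs; %s\n", x$modality,
              paste(x$hidden, collapse = "/"), x$n_classes,
              if (x$fitted) sprintf("fitted (best epoch %d)",
                                    attr(x$history, "best_epoch"))
              else "untrained"))
  invisible(x)
}

submodel_module <- function(model) {
  nh <- length(model$hidden)
  if (model$modality == "CNN") {
    list(
      forward = function(p, x, training) {
        cs <- channel_forward(p$smd, x$smd, model$kernel)
        cb <- channel_forward(p$biod, x$biod, model$kernel)
        hc <- head_forward(p$head, cbind(cs$pool, cb$pool), nh,
                           model$dropout, training)
        c(hc, list(cs = cs, cb = cb))
      },
      backward = function(p, cache, dZout, training) {
        hg <- head_backward(p$head, cache, dZout, nh, model$dropout, training)
        f3 <- 3 * model$f
        gs <- channel_backward(p$smd, cache$cs,
                               hg$dX[, seq_len(f3), drop = FALSE], model$kernel)
        gb <- channel_backward(p$biod, cache$cb,
                               hg$dX[, f3 + seq_len(f3), drop = FALSE],
                               model$kernel)
        hg$dX <- NULL
        list(smd = gs, biod = gb, head = hg)
      },
      slice = function(x, idx) list(smd = x$smd[idx, , drop = FALSE],
                                    biod = x$biod[idx, , drop = FALSE]),
      n = function(x) nrow(x$smd))
  } else {
    list(
      forward = function(p, x, training)
        head_forward(p$head, x, nh, model$dropout, training),
      backward = function(p, cache, dZout, training) {
        hg <- head_backward(p$head, cache, dZout, nh, model$dropout, training)
        hg$dX <- NULL
        list(head = hg)
      },
      slice = function(x, idx) x[idx, , drop = FALSE],
      n = function(x) nrow(x))
  }
}

#' Train a sub-model with early stopping
#'
#' @param model an [build_submodel()] object.
#' @param x_train,x_val modality inputs from [pair_design()] (dense matrix,
#'   or token list for the CNN modality).
#' @param y_train,y_val multi-hot label matrices from [pair_label_matrix()].
#' @param config a [train_config()].
#' @return The fitted model; `$history` holds per-epoch train/validation
#'   losses with attribute `best_epoch`.
#' @export
train_submodel <- function(model, x_train, y_train, x_val, y_val,
                           config = train_config()) {
  stopifnot(inherits(model, "sbi_submodel"))
  module <- submodel_module(model)
  if (module$n(x_train) == 0 || module$n(x_val) == 0)
    stopf("empty training or validation split")
  fit <- train_nn(module, model$params, x_train, y_train, x_val, y_val, config)
  model$params <- fit$params
  model$history <- fit$history
  attr(model$history, "best_epoch") <- fit$best_epoch
  model$fitted <- TRUE
  model
}

#' Predict class probabilities with a sub-model
#'
#' @param object fitted `sbi_submodel`.
#' @param x modality input as in [train_submodel()].
#' @param ... unused.
#' @return Matrix `n x n_classes` of sigmoid probabilities in (0, 1).
#' @export
predict.sbi_submodel <- function(object, x, ...) {
  module <- submodel_module(object)
  module$forward(object$params, x, training = FALSE)$P
}

#' Average the outputs of per-modality sub-models
#'
#' The fused prediction is the unweighted arithmetic mean of the sub-models'
#' 49-dimensional (generally `n_classes`-dimensional) sigmoid outputs. By
#' default all four modalities must be present; pass `allow_subset = TRUE`
#' for ablation runs on fewer modalities.
#'
#' @param models named list of fitted sub-models (names = modalities).
#' @param x named list of modality inputs matching `models`.
#' @param allow_subset allow fewer than the four modalities.
#' @return Probability matrix `n x n_classes`.
#' @export
predict_ensemble <- function(models, x, allow_subset = FALSE) {
  if (!allow_subset && !all(.modalities %in% names(models)))
    stopf("ensemble requires all modalities (%s); missing: %s. Use allow_subset = TRUE for ablations.",
          paste(.modalities, collapse = ", "),
          paste(setdiff(.modalities, names(models)), collapse = ", "))
  ks <- vapply(models, function(m) m$n_classes, numeric(1))
  if (length(unique(ks)) != 1)
    stopf("sub-models disagree on the label space: %s", paste(ks, collapse = ", "))
  preds <- lapply(names(models), function(nm) predict(models[[nm]], x[[nm]]))
  Reduce(`+`, preds) / length(preds)
}
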