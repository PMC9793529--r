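# Per-drug feature stores for the four modalities, and the per-pair design
# matrices assembled from them.

.modalities <- c("CNN", "FP_EMB", "SPI_BPI", "SSI_BBI")

#' Compute all per-drug features of a universe
#'
#' Builds the four modality stores: tokenized sequences (CNN channel),
#' fingerprint/embedding vectors, SPI/BPI topology rows, and SSI/BBI
#' topology rows. All matrices are indexed by sorted drug id.
#'
#' @param universe a `drug_universe`.
#' @param smd_max_len,biod_max_len token-vector lengths (defaults 1000/100).
#' @param pca_k PCA target dimension for SMD topology rows (default 512).
#' @param fp_bits fingerprint width (default 1024).
#' @param embed_dims protein-embedding width (default 1280).
#' @param embed_backend,external_fn passed to [protein_embedding()].
#' @return Object of class `feature_bundle`.
#' @export
build_features <- function(universe, smd_max_len = 1000, biod_max_len = 100,
                           pca_k = 512, fp_bits = 1024, embed_dims = 1280,
                           embed_backend = "fallback", external_fn = NULL) {
  smds <- sort(smd_ids(universe))
  biods <- sort(biod_ids(universe))
  struct <- stats::setNames(universe$drugs$structure, universe$drugs$id)

  vocab_smiles <- build_vocabulary(struct[smds], "SMILES")
  vocab_aa <- build_vocabulary(struct[biods], "AA")
  tok_smd <- tokenize(struct[smds], vocab_smiles, smd_max_len)
  tok_biod <- tokenize(struct[biods], vocab_aa, biod_max_len)
  rownames(tok_smd) <- smds
  rownames(tok_biod) <- biods

  fp <- fingerprint(struct[smds], nbits = fp_bits)
  emb <- protein_embedding(struct[biods], dims = embed_dims,
                           backend = embed_backend, external_fn = external_fn)
  topo <- topology_features(universe, k = pca_k)

  structure(list(smd_ids = smds, biod_ids = biods,
                 vocab = list(smiles = vocab_smiles, aa = vocab_aa),
                 tokens = list(smd = tok_smd, biod = tok_biod),
                 fp = fp, emb = emb, topo = topo),
            class = "feature_bundle")
}

#' @export
print.feature_bundle <- function(x, ...) {
  cat(sprintf("feature_bundle: %d SMDs, %d BioDs\n",
              length(x$smd_ids), length(x$biod_ids)))
  cat(sprintf("  tokens: SMD %d, BioD %d | fp: %d bits | embedding: %d dims\n",
              ncol(x$tokens$smd), ncol(x$tokens$biod), ncol(x$fp), ncol(x$emb)))
  cat(sprintf("  topology: SPI %d, SSI %d (PCA), BPI %d, BBI %d dims\n",
              ncol(x$topo$spi), ncol(x$topo$ssi),
              ncol(x$topo$bpi), ncol(x$topo$bbi)))
  invisible(x)
}

#' Per-pair design for one modality
#'
#' Concatenates the SMD-side and BioD-side feature vectors of each pair.
#' For the CNN modality the result is the pair of token matrices (one per
#' channel) rather than a single dense matrix.
#'
#' @param features a [build_features()] bundle.
#' @param pairs data.frame with `smd_id`, `biod_id`.
#' @param modality one of `"CNN"`, `"FP_EMB"`, `"SPI_BPI"`, `"SSI_BBI"`.
#' @return Dense matrix, or for `"CNN"` a list with `smd` and `biod` token
#'   matrices.
#' @export
pair_design <- function(features, pairs, modality) {
  modality <- match.arg(modality, .modalities)
  si <- match(pairs$smd_id, features$smd_ids)
  bi <- match(pairs$biod_id, features$biod_ids)
  if (anyNA(si) || anyNA(bi))
    stopf("pairs reference drugs absent from the feature bundle")
  switch(modality,
    CNN = list(smd = features$tokens$smd[si, , drop = FALSE],
               biod = features$tokens$biod[bi, , drop = FALSE]),
    FP_EMB = cbind(features$fp[si, , drop = FALSE],
                   features$emb[bi, , drop = FALSE]),
    SPI_BPI = cbind(features$topo$spi[si, , drop = FALSE],
                    features$topo$bpi[bi, , drop = FALSE]),
    SSI_BBI = cbind(features$topo$ssi[si, , drop = FALSE],
                    features$topo$bbi[bi, , drop = FALSE]))
}

# Classifier-ready flat representation: every modality except tokens,
# concatenated. Used by the PU-sampling decision trees.
pair_design_flat <- function(features, pairs) {
  cbind(pair_design(features, pairs, "FP_EMB"),
        pair_design(features, pairs, "SPI_BPI"),
        pair_design(features, pairs, "SSI_BBI"))
}
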