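# Network topology modality: one-hot interaction profiles over each
# network's partner-node universe, Jaccard similarity between same-type
# drugs, and PCA compression of the SMD similarity rows.

#' One-hot interaction profile of a drug in one network
#'
#' Bit `i` is 1 iff the drug shares an edge with `partner_universe[i]`.
#' Drugs absent from the network get the all-zero profile.
#'
#' @param drug drug id.
#' @param network edge data.frame (`from`, `to`); intra-type networks are
#'   treated as undirected.
#' @param partner_universe ordered character vector of partner node ids
#'   defining the profile dimension.
#' @return Binary vector of length `length(partner_universe)`.
#' @export
onehot_profile <- function(drug, network, partner_universe) {
  partners <- c(network$to[network$from == drug],
                network$from[network$to == drug])
  as.numeric(partner_universe %in% partners)
}

# Profiles for many drugs at once: drugs x partner_universe binary matrix.
onehot_profiles <- function(drugs, network, partner_universe) {
  m <- matrix(0, length(drugs), length(partner_universe),
              dimnames = list(drugs, partner_universe))
  if (nrow(network)) {
    e <- rbind(network[c("from", "to")],
               stats::setNames(network[c("to", "from")], c("from", "to")))
    e <- e[e$from %in% drugs & e$to %in% partner_universe, ]
    if (nrow(e)) m[cbind(e$from, e$to)] <- 1
  }
  m
}

#' Jaccard similarity of two binary profiles
#'
#' `|A intersect B| / (|A| + |B| - |A intersect B|)` over the supports of
#' the two bit vectors. Two empty supports give 0 by convention (isolated
#' drugs share no evidence).
#'
#' @param a,b binary vectors of equal length.
#' @return Similarity in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  if (length(a) != length(b)) stopf("profile dimension mismatch: %d vs %d",
                                    length(a), length(b))
  inter <- sum(a > 0 & b > 0)
  union <- sum(a > 0) + sum(b > 0) - inter
  if (union == 0) 0 else inter / union
}

#' Pairwise Jaccard similarity matrix over drug profiles
#'
#' Row `i` is drug `i`'s topology feature vector: its Jaccard similarity to
#' every same-type drug. Computed from bit-matrix products, so it is exact
#' set arithmetic.
#'
#' @param profiles binary matrix (drugs x partners), e.g. from one network's
#'   one-hot profiles.
#' @return Symmetric matrix with unit diagonal for non-empty profiles.
#' @export
similarity_matrix <- function(profiles) {
  profiles <- (profiles > 0) * 1
  inter <- tcrossprod(profiles)
  sizes <- rowSums(profiles)
  union <- outer(sizes, sizes, "+") - inter
  sim <- ifelse(union == 0, 0, inter / union)
  dimnames(sim) <- list(rownames(profiles), rownames(profiles))
  sim
}

#' PCA compression of similarity rows
#'
#' Centers the rows-as-features matrix and keeps the top `k` principal
#' components by explained variance. The fitted transform (centers +
#' rotation) is returned so unseen drugs' similarity rows can be projected
#' consistently. Component signs follow a fixed convention: the
#' largest-magnitude loading of each component is positive.
#'
#' @param x numeric matrix (drugs x features), typically a similarity
#'   matrix's rows.
#' @param k target dimension (default 512); silently capped at the matrix
#'   rank with a warning.
#' @param seed kept for interface symmetry; the eigendecomposition is
#'   deterministic.
#' @return Object of class `pca_transform`: list with `rotation`, `center`,
#'   `sdev`, `k`, and `scores` (the projected training rows).
#' @export
reduce_pca <- function(x, k = 512, seed = NULL) {
  x <- as.matrix(x)
  if (k > nrow(x)) stopf("k (%d) exceeds the number of drugs (%d)", k, nrow(x))
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  rank <- sum(p$sdev > max(p$sdev) * 1e-9)
  if (k > rank) {
    warnf("requested k = %d exceeds rank %d; keeping %d components", k, rank, rank)
    k <- rank
  }
  rot <- p$rotation[, seq_len(k), drop = FALSE]
  # sign convention: largest |loading| positive
  for (j in seq_len(k)) {
    m <- which.max(abs(rot[, j]))
    if (rot[m, j] < 0) rot[, j] <- -rot[, j]
  }
  scores <- sweep(x, 2, p$center) %*% rot
  structure(list(rotation = rot, center = p$center,
                 sdev = p$sdev[seq_len(k)], k = k, scores = scores),
            class = "pca_transform")
}

#' Project new rows through a fitted PCA transform
#'
#' @param transform a [reduce_pca()] result.
#' @param x matrix of rows in the original feature space.
#' @return Matrix of `k`-dimensional projections.
#' @export
project_pca <- function(transform, x) {
  stopifnot(inherits(transform, "pca_transform"))
  sweep(as.matrix(x), 2, transform$center) %*% transform$rotation
}

#' All four topology feature blocks of a universe
#'
#' For each network, one-hot profiles are computed over the sorted union of
#' partner nodes observed in that network, then converted to same-type
#' Jaccard similarity rows. SMD rows (dimension `|SMD|`) are PCA-compressed
#' to `min(k, |SMD|)` dimensions; BioD rows (dimension `|BioD|`) are kept
#' raw. SPI/BPI-derived and SSI/BBI-derived blocks are separate modalities.
#'
#' @param universe a `drug_universe`.
#' @param k PCA target dimension for SMD rows (default 512).
#' @return List with matrices `spi` (SMD), `bpi` (BioD), `ssi` (SMD),
#'   `bbi` (BioD), the fitted `pca` transforms for the two SMD blocks, and
#'   the partner universes used.
#' @export
topology_features <- function(universe, k = 512) {
  smds <- sort(smd_ids(universe))
  biods <- sort(biod_ids(universe))
  partner_universe <- function(net) sort(unique(c(net$from, net$to)))
  partners <- list(
    SSI = partner_universe(universe$edges$SSI),
    BBI = partner_universe(universe$edges$BBI),
    SPI = sort(unique(universe$edges$SPI$to)),
    BPI = sort(unique(universe$edges$BPI$to)))

  sim <- function(drugs, net, univ) {
    if (length(univ) == 0)
      return(matrix(0, length(drugs), length(drugs),
                    dimnames = list(drugs, drugs)))
    similarity_matrix(onehot_profiles(drugs, net, univ))
  }
  ssi_sim <- sim(smds, universe$edges$SSI, partners$SSI)
  spi_sim <- sim(smds, universe$edges$SPI, partners$SPI)
  bbi_sim <- sim(biods, universe$edges$BBI, partners$BBI)
  bpi_sim <- sim(biods, universe$edges$BPI, partners$BPI)

  k_eff <- min(k, length(smds))
  # the rank cap is expected here (centered n x n rows have rank < n)
  pca_spi <- suppressWarnings(reduce_pca(spi_sim, k = k_eff))
  pca_ssi <- suppressWarnings(reduce_pca(ssi_sim, k = k_eff))
  list(spi = pca_spi$scores, ssi = pca_ssi$scores,
       bpi = bpi_sim, bbi = bbi_sim,
       pca = list(spi = pca_spi, ssi = pca_ssi),
       partners = partners)
}
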