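# Seeded synthetic drug universes with planted, learnable signal.
#
# Each drug carries a low-dimensional Gaussian latent factor. Structures
# (SMILES fragments, residue composition) and network neighborhoods are
# drawn conditionally on the factor, and interaction events are drawn from a
# multinomial whose logits combine latent-factor affinity with shared-protein
# counts — so the structure and the topology modalities both carry signal.
# With signal_strength = 0 the labels are independent of every feature (a
# null model for calibration tests).

# chain-safe SMILES fragments: each keeps <= 2 open valences, so arbitrary
# concatenations remain valid molecules over the C/c/N/O/S/=/()/1 alphabet
.default_grammar <- c("C", "CC", "CCC", "C(C)C", "C(C)(C)", "C(=O)O",
                      "C(=O)N", "O", "N", "S", "c1ccccc1", "CO", "CN",
                      "C=C", "OCC")

#' Configuration for the synthetic drug-universe generator
#'
#' Defaults are desk scale: 120 SMDs x 30 BioDs (3600 candidate pairs),
#' 80 proteins and 6 event types — large enough for stratified 5-fold
#' cross-validation, small enough for minutes-scale runs.
#'
#' @param n_smd,n_biod,n_protein entity counts (all >= 1).
#' @param n_events number of planted interaction event types.
#' @param smiles_grammar character vector of chain-safe SMILES fragments
#'   from which SMD structures are assembled.
#' @param seq_length_range integer (min, max) BioD sequence length.
#' @param densities named list of edge probabilities for `ssi`, `bbi`,
#'   `spi`, `bpi`.
#' @param positive_rate expected fraction of candidate pairs that interact.
#' @param hidden_positive_fraction fraction of true positives withheld from
#'   the labeled set (returned separately as hidden positives).
#' @param signal_strength >= 0; scales the dependence of interaction labels
#'   on latent factors and shared-protein counts. 0 = null model.
#' @param latent_dim dimension of the per-drug Gaussian latent factor.
#' @param min_count rare-event threshold for the generated catalog.
#' @param seed integer RNG seed; identical configs generate identical
#'   universes.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_smd = 120, n_biod = 30, n_protein = 80, n_events = 6,
                       smiles_grammar = .default_grammar,
                       seq_length_range = c(60, 100),
                       densities = list(ssi = 0.05, bbi = 0.10,
                                        spi = 0.08, bpi = 0.15),
                       positive_rate = 0.10,
                       hidden_positive_fraction = 0.10,
                       signal_strength = 2,
                       latent_dim = 4,
                       min_count = 10,
                       seed = 1) {
  cfg <- list(n_smd = as.integer(n_smd), n_biod = as.integer(n_biod),
              n_protein = as.integer(n_protein), n_events = as.integer(n_events),
              smiles_grammar = as.character(smiles_grammar),
              seq_length_range = as.integer(seq_length_range),
              densities = lapply(densities, as.numeric),
              positive_rate = as.numeric(positive_rate),
              hidden_positive_fraction = as.numeric(hidden_positive_fraction),
              signal_strength = as.numeric(signal_strength),
              latent_dim = as.integer(latent_dim),
              min_count = as.integer(min_count),
              seed = as.integer(seed))
  with(cfg, {
    if (any(c(n_smd, n_biod, n_protein, n_events, latent_dim) < 1))
      stopf("all counts must be >= 1")
    if (length(seq_length_range) != 2 || seq_length_range[1] < 3 ||
        seq_length_range[2] < seq_length_range[1])
      stopf("seq_length_range must be (min, max) with min >= 3")
    dens <- unlist(densities[c("ssi", "bbi", "spi", "bpi")])
    if (length(dens) != 4 || any(dens < 0 | dens > 1))
      stopf("densities must provide ssi/bbi/spi/bpi probabilities in [0,1]")
    if (positive_rate < 0 || positive_rate > 1 ||
        hidden_positive_fraction < 0 || hidden_positive_fraction > 1)
      stopf("rates/fractions must lie in [0,1]")
    if (signal_strength < 0) stopf("signal_strength must be >= 0")
    if (round(positive_rate * n_smd * n_biod) < n_events)
      stopf("infeasible config: expected positives (%d) < n_events (%d)",
            round(positive_rate * n_smd * n_biod), n_events)
  })
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: %d SMD x %d BioD, %d proteins, %d events, signal %.2g, seed %d\n",
              x$n_smd, x$n_biod, x$n_protein, x$n_events,
              x$signal_strength, x$seed))
  invisible(x)
}

.mechanism_pool <- c("metabolism", "serum concentration",
                     "therapeutic efficacy", "adverse effects",
                     "hypoglycemic activity", "anticoagulant activity",
                     "qtc prolongation", "immunosuppressive activity")

#' Generate a seeded synthetic drug universe
#'
#' @param config a [sim_config()].
#' @return List with elements `universe` (a validated [drug_universe()]
#'   whose labeled positives exclude the hidden set), `hidden_positives`
#'   (quaternary data.frame of true-but-unlabeled positives) and `latent`
#'   (the per-drug and per-protein factors plus the event projections).
#' @export
generate_universe <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  local_seed(config$seed, {
    d <- config$latent_dim
    smd_id <- sprintf("SMD%04d", seq_len(config$n_smd))
    biod_id <- sprintf("BIO%04d", seq_len(config$n_biod))
    prot_id <- sprintf("PRT%04d", seq_len(config$n_protein))

    Zs <- matrix(stats::rnorm(config$n_smd * d), config$n_smd, d,
                 dimnames = list(smd_id, NULL))
    Zb <- matrix(stats::rnorm(config$n_biod * d), config$n_biod, d,
                 dimnames = list(biod_id, NULL))
    Wp <- matrix(stats::rnorm(config$n_protein * d), config$n_protein, d,
                 dimnames = list(prot_id, NULL))

    # SMD structures: fragment choice biased by the latent factor
    nf <- length(config$smiles_grammar)
    Gf <- matrix(stats::rnorm(nf * d), nf, d)
    frag_prob <- softmax_rows(Zs %*% t(Gf))  # n_smd x nf
    n_frag <- sample(3:8, config$n_smd, replace = TRUE)
    smiles <- vapply(seq_len(config$n_smd), function(i) {
      paste(sample(config$smiles_grammar, n_frag[i], replace = TRUE,
                   prob = frag_prob[i, ]), collapse = "")
    }, character(1))

    # BioD sequences: residue composition biased by the latent factor
    alpha <- aa_alphabet()
    Ma <- matrix(stats::rnorm(length(alpha) * d), length(alpha), d)
    res_prob <- softmax_rows(Zb %*% t(Ma))   # n_biod x 25
    seq_len_b <- sample(config$seq_length_range[1]:config$seq_length_range[2],
                        config$n_biod, replace = TRUE)
    seqs <- vapply(seq_len(config$n_biod), function(i) {
      paste(sample(alpha, seq_len_b[i], replace = TRUE, prob = res_prob[i, ]),
            collapse = "")
    }, character(1))

    draw_bipartite <- function(Z, W, density, from_ids, to_ids) {
      logit <- stats::qlogis(max(density, 1e-6)) + Z %*% t(W) / sqrt(d)
      p <- stats::plogis(logit)
      hit <- matrix(stats::runif(length(p)) < p, nrow(p), ncol(p))
      idx <- which(hit, arr.ind = TRUE)
      data.frame(from = from_ids[idx[, 1]], to = to_ids[idx[, 2]],
                 stringsAsFactors = FALSE)
    }
    draw_intra <- function(Z, density, ids) {
      n <- nrow(Z)
      if (n < 2) return(data.frame(from = character(), to = character()))
      pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
      logit <- stats::qlogis(max(density, 1e-6)) +
        rowSums(Z[pairs[, 1], , drop = FALSE] * Z[pairs[, 2], , drop = FALSE]) / sqrt(d)
      hit <- stats::runif(nrow(pairs)) < stats::plogis(logit)
      data.frame(from = ids[pairs[hit, 1]], to = ids[pairs[hit, 2]],
                 stringsAsFactors = FALSE)
    }
    spi <- draw_bipartite(Zs, Wp, config$densities$spi, smd_id, prot_id)
    bpi <- draw_bipartite(Zb, Wp, config$densities$bpi, biod_id, prot_id)
    ssi <- draw_intra(Zs, config$densities$ssi, smd_id)
    bbi <- draw_intra(Zb, config$densities$bbi, biod_id)

    # shared-protein counts between every (SMD, BioD) pair
    As <- matrix(0, config$n_smd, config$n_protein, dimnames = list(smd_id, prot_id))
    if (nrow(spi)) As[cbind(spi$from, spi$to)] <- 1
    Ab <- matrix(0, config$n_biod, config$n_protein, dimnames = list(biod_id, prot_id))
    if (nrow(bpi)) Ab[cbind(bpi$from, bpi$to)] <- 1
    shared <- As %*% t(Ab)
    shared_std <- as.vector(scale(as.vector(shared)))
    if (anyNA(shared_std)) shared_std <- rep(0, length(shared))

    affinity <- as.vector(Zs %*% t(Zb)) / sqrt(d)
    aff_std <- as.vector(scale(affinity))
    if (anyNA(aff_std)) aff_std <- rep(0, length(affinity))

    # interaction propensity combines both signal sources; the intercept is
    # calibrated so the expected positive fraction equals positive_rate
    s <- config$signal_strength * (aff_std + shared_std) / 2
    target <- min(max(config$positive_rate, 1e-6), 1 - 1e-6)
    base <- stats::uniroot(function(b) mean(stats::plogis(b + s)) - target,
                           c(-40, 40), tol = 1e-10)$root
    p_pos <- stats::plogis(base + s)
    is_pos <- stats::runif(length(p_pos)) < p_pos
    pair_idx <- which(matrix(is_pos, config$n_smd, config$n_biod), arr.ind = TRUE)
    if (nrow(pair_idx) < config$n_events)
      stopf("degenerate draw: fewer positives (%d) than events (%d); use a larger universe",
            nrow(pair_idx), config$n_events)

    # event assignment: multinomial with latent-driven logits
    K <- config$n_events
    Uk <- matrix(stats::rnorm(K * d), K, d) / sqrt(d)
    Vk <- matrix(stats::rnorm(K * d), K, d) / sqrt(d)
    wk <- stats::rnorm(K)
    bk <- stats::rnorm(K, sd = 0.7)  # baseline imbalance across events
    si <- pair_idx[, 1]; bi <- pair_idx[, 2]
    flat <- (bi - 1L) * config$n_smd + si
    logits <- Zs[si, , drop = FALSE] %*% t(Uk) +
      Zb[bi, , drop = FALSE] %*% t(Vk) +
      outer(shared_std[flat], wk)
    logits <- config$signal_strength * logits +
      matrix(bk, nrow(logits), K, byrow = TRUE)
    probs <- softmax_rows(logits)
    ev <- vapply(seq_len(nrow(probs)),
                 function(i) sample.int(K, 1, prob = probs[i, ]), integer(1))

    mech <- rep(.mechanism_pool, length.out = max(1, ceiling(K / 2)))
    mechanism <- mech[ceiling(ev / 2)]
    action <- ifelse(ev %% 2 == 1, "increase", "decrease")
    quats <- data.frame(drug_a = smd_id[si], drug_b = biod_id[bi],
                        mechanism = mechanism, action = action,
                        stringsAsFactors = FALSE)

    n_hidden <- floor(config$hidden_positive_fraction * nrow(quats))
    hidden_rows <- if (n_hidden > 0) sort(sample.int(nrow(quats), n_hidden)) else integer(0)
    hidden <- quats[hidden_rows, , drop = FALSE]
    labeled <- quats[setdiff(seq_len(nrow(quats)), hidden_rows), , drop = FALSE]
    rownames(hidden) <- rownames(labeled) <- NULL

    drugs <- rbind(
      data.frame(id = smd_id, kind = "SMD", structure = smiles,
                 stringsAsFactors = FALSE),
      data.frame(id = biod_id, kind = "BioD", structure = seqs,
                 stringsAsFactors = FALSE))
    universe <- drug_universe(drugs, prot_id,
                              list(SSI = ssi, BBI = bbi, SPI = spi, BPI = bpi),
                              labeled, min_count = config$min_count)
    list(universe = universe,
         hidden_positives = hidden,
         latent = list(smd = Zs, biod = Zb, protein = Wp,
                       event_u = Uk, event_v = Vk, event_w = wk, event_b = bk))
  })
}
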