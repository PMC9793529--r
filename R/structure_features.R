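# Structure modalities: (a) integer token sequences feeding the CNN channel,
# (b) fixed-length vectors — hashed path fingerprint for SMDs (1024 bits),
# hashed 3-mer embedding for BioDs (1280 dims).

#' Build a character vocabulary from a structure corpus
#'
#' One positive integer index per distinct character. Indices are assigned in
#' first-occurrence order over the sorted input strings, so the mapping is a
#' deterministic function of the corpus content. Index 0 is reserved for
#' padding and never assigned.
#'
#' @param structures character vector (SMILES or amino-acid sequences).
#' @param kind `"SMILES"` or `"AA"`.
#' @return Object of class `sbi_vocabulary`: list with `index` (named
#'   integer map), `kind`, and `unknown` (= size + 1, the reserved index for
#'   characters unseen at build time).
#' @export
build_vocabulary <- function(structures, kind = c("SMILES", "AA")) {
  kind <- match.arg(kind)
  if (length(structures) == 0) stopf("empty structure corpus")
  chars <- unlist(strsplit(sort(as.character(structures)), ""), use.names = FALSE)
  uniq <- unique(chars)
  index <- stats::setNames(seq_along(uniq), uniq)
  structure(list(index = index, kind = kind, size = length(uniq),
                 unknown = length(uniq) + 1L),
            class = "sbi_vocabulary")
}

#' @export
print.sbi_vocabulary <- function(x, ...) {
  cat(sprintf("sbi_vocabulary (%s): %d characters (+0 pad, +%d unknown)\n",
              x$kind, x$size, x$unknown))
  invisible(x)
}

#' Tokenize structures to fixed-length integer vectors
#'
#' The first `max_len` characters are mapped through the vocabulary; shorter
#' inputs are right-padded with 0, longer inputs truncated. Characters absent
#' from the vocabulary map to its reserved unknown index with a warning.
#'
#' @param structures character vector.
#' @param vocab an [build_vocabulary()] result.
#' @param max_len output length (SMD convention: 1000; BioD: 100).
#' @return Integer matrix `length(structures) x max_len`; attribute
#'   `lengths` holds the pre-padding lengths (capped at `max_len`).
#' @export
tokenize <- function(structures, vocab, max_len) {
  stopifnot(inherits(vocab, "sbi_vocabulary"), max_len >= 1)
  structures <- as.character(structures)
  out <- matrix(0L, length(structures), max_len)
  n_unknown <- 0L
  lens <- integer(length(structures))
  for (i in seq_along(structures)) {
    ch <- strsplit(structures[i], "")[[1]]
    if (length(ch) > max_len) ch <- ch[seq_len(max_len)]
    lens[i] <- length(ch)
    if (!length(ch)) next
    ix <- vocab$index[ch]
    unk <- is.na(ix)
    n_unknown <- n_unknown + sum(unk)
    ix[unk] <- vocab$unknown
    out[i, seq_along(ix)] <- as.integer(ix)
  }
  if (n_unknown > 0)
    warnf("%d character(s) outside the vocabulary mapped to the unknown index %d",
          n_unknown, vocab$unknown)
  attr(out, "lengths") <- lens
  out
}

# --- hashed linear-path fingerprint ----------------------------------------

.bond_symbol <- c("1" = "-", "2" = "=", "3" = "#")

# Parse SMILES through OpenBabel (via ChemmineR) into an atom-labeled graph.
parse_smiles_graph <- function(smiles) {
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, seq_along(smiles))))
  valid <- ChemmineR::validSDF(sdf)
  lapply(seq_along(smiles), function(i) {
    if (!valid[i]) {
      # the SDF container cannot hold bondless molecules; accept lone atoms
      # (optionally bracketed, e.g. "O" or "[Li+]") directly
      if (grepl("^(\\[[A-Za-z][a-z]?[^]]*\\]|[A-Za-z][a-z]?)$", smiles[i])) {
        el <- sub("^\\[?([A-Za-z][a-z]?).*$", "\\1", smiles[i])
        substr(el, 1, 1) <- toupper(substr(el, 1, 1))
        return(list(elements = el, bonds = matrix(numeric(0), 0, 3)))
      }
      return(NULL)
    }
    mol <- sdf[[i]]
    ab <- ChemmineR::atomblock(mol)
    bb <- ChemmineR::bondblock(mol)
    elements <- sub("_.*$", "", rownames(ab))
    if (length(elements) == 0) return(NULL)
    bonds <- if (is.null(dim(bb)) || nrow(bb) == 0) {
      matrix(numeric(0), 0, 3)
    } else unname(as.matrix(bb[, 1:3, drop = FALSE]))
    list(elements = elements, bonds = bonds)
  })
}

# All simple linear paths of 1..max_atoms atoms, as canonical strings
# (lexicographic min of the two read directions).
enumerate_paths <- function(graph, max_atoms = 8) {
  n <- length(graph$elements)
  adj <- vector("list", n)
  nb_order <- vector("list", n)
  if (nrow(graph$bonds)) {
    for (r in seq_len(nrow(graph$bonds))) {
      a <- graph$bonds[r, 1]; b <- graph$bonds[r, 2]; o <- graph$bonds[r, 3]
      adj[[a]] <- c(adj[[a]], b); nb_order[[a]] <- c(nb_order[[a]], o)
      adj[[b]] <- c(adj[[b]], a); nb_order[[b]] <- c(nb_order[[b]], o)
    }
  }
  bond_sym <- function(o) {
    s <- .bond_symbol[as.character(o)]
    ifelse(is.na(s), ":", s)  # ":" covers aromatic/other orders
  }
  paths <- character(0)
  visited <- logical(n)
  dfs <- function(atom, tokens) {
    fwd <- paste(tokens, collapse = "")
    rev_ <- paste(rev(tokens), collapse = "")
    paths[[length(paths) + 1L]] <<- if (fwd <= rev_) fwd else rev_
    if ((length(tokens) + 1) / 2 >= max_atoms) return()
    visited[atom] <<- TRUE
    nbs <- adj[[atom]]
    for (j in seq_along(nbs)) {
      nb <- nbs[j]
      if (!visited[nb])
        dfs(nb, c(tokens, bond_sym(nb_order[[atom]][j]), graph$elements[nb]))
    }
    visited[atom] <<- FALSE
  }
  for (a in seq_len(n)) dfs(a, graph$elements[a])
  unique(paths)
}

#' Hashed linear-path molecular fingerprint
#'
#' A daylight-style topological fingerprint: all simple atom-bond paths of up
#' to `max_path` bonds are enumerated on the molecular graph (parsed from
#' SMILES by OpenBabel), written as canonical element/bond-order strings, and
#' hashed (32-bit FNV-1a) onto `nbits` binary bits. Because enumeration runs
#' on the parsed graph, SMILES aliases of one molecule (e.g. `"CCO"` and
#' `"OCC"`) produce identical fingerprints.
#'
#' @param smiles character vector of SMILES; names (if set) are used as drug
#'   ids in error messages.
#' @param nbits fingerprint width (default 1024).
#' @param max_path maximum path length in bonds (default 7).
#' @return Binary matrix `length(smiles) x nbits` with attribute
#'   `featurizer` = `"hashed-path/1"`.
#' @export
fingerprint <- function(smiles, nbits = 1024, max_path = 7) {
  ids <- names(smiles) %||% as.character(seq_along(smiles))
  graphs <- parse_smiles_graph(as.character(smiles))
  bad <- vapply(graphs, is.null, logical(1))
  if (any(bad))
    stopf("unparseable SMILES for drug(s): %s", paste(ids[bad], collapse = ", "))
  fp <- matrix(0, length(smiles), nbits, dimnames = list(ids, NULL))
  for (i in seq_along(graphs)) {
    paths <- enumerate_paths(graphs[[i]], max_atoms = max_path + 1)
    fp[i, unique(hash_to_bit(paths, nbits))] <- 1
  }
  attr(fp, "featurizer") <- "hashed-path/1"
  fp
}

# --- hashed k-mer protein embedding ----------------------------------------

.embed_cache <- new.env(parent = emptyenv())
.EMBED_BINS <- 2048L
.EMBED_SEED <- 760211L  # fixed: the projection is part of the featurizer

embed_projection <- function(dims) {
  key <- paste0("proj", dims)
  if (is.null(.embed_cache[[key]])) {
    .embed_cache[[key]] <- local_seed(.EMBED_SEED, {
      matrix(stats::rnorm(.EMBED_BINS * dims), .EMBED_BINS, dims) / sqrt(dims)
    })
  }
  .embed_cache[[key]]
}

#' Overlapping k-mer counts of a sequence
#'
#' The pre-hash count stage of the fallback protein embedding, exposed for
#' inspection and testing.
#'
#' @param sequence amino-acid string.
#' @param k k-mer length (default 3).
#' @return Named integer vector of k-mer counts (empty if the sequence is
#'   shorter than `k`).
#' @export
protein_kmer_counts <- function(sequence, k = 3) {
  n <- nchar(sequence)
  if (n < k) return(stats::setNames(integer(0), character(0)))
  kmers <- substring(sequence, 1:(n - k + 1), k:n)
  tab <- table(kmers)
  stats::setNames(as.integer(tab), names(tab))
}

#' Fixed-length protein embedding for biotech drugs
#'
#' Sequences are truncated to their first 1024 residues. The default
#' (`backend = "fallback"`) embedding is deterministic and self-contained:
#' overlapping 3-mer counts are hashed into 2048 bins, L2-normalized, and
#' projected to `dims` dimensions by a fixed seeded Gaussian random
#' projection. `backend = "external"` is an adapter contract for a
#' pretrained protein language model: supply `external_fn`, a function
#' mapping a character vector of (already truncated) sequences to a
#' `length(sequences) x dims` matrix.
#'
#' @param sequences character vector; names (if set) are used as drug ids.
#' @param dims embedding width (default 1280).
#' @param backend `"fallback"` or `"external"`.
#' @param external_fn embedding function for the external backend.
#' @param k k-mer length of the fallback featurizer.
#' @return Matrix `length(sequences) x dims` with attribute `featurizer`.
#' @export
protein_embedding <- function(sequences, dims = 1280,
                              backend = c("fallback", "external"),
                              external_fn = NULL, k = 3) {
  backend <- match.arg(backend)
  ids <- names(sequences) %||% as.character(seq_along(sequences))
  sequences <- as.character(sequences)
  if (any(!nzchar(sequences)))
    stopf("empty sequence for drug(s): %s",
          paste(ids[!nzchar(sequences)], collapse = ", "))
  sequences <- substr(sequences, 1, 1024)  # first 1024 residues only
  if (backend == "external") {
    if (!is.function(external_fn))
      stopf("backend 'external' requires external_fn(sequences) -> matrix")
    out <- external_fn(sequences)
    if (!is.matrix(out) || nrow(out) != length(sequences) || ncol(out) != dims)
      stopf("external_fn must return a %d x %d matrix", length(sequences), dims)
    dimnames(out) <- list(ids, NULL)
    attr(out, "featurizer") <- "external"
    return(out)
  }
  counts <- matrix(0, length(sequences), .EMBED_BINS)
  for (i in seq_along(sequences)) {
    km <- protein_kmer_counts(sequences[i], k = k)
    if (!length(km)) next
    bins <- hash_to_bit(names(km), .EMBED_BINS)
    for (j in seq_along(bins))
      counts[i, bins[j]] <- counts[i, bins[j]] + km[j]
    nrm <- sqrt(sum(counts[i, ]^2))
    if (nrm > 0) counts[i, ] <- counts[i, ] / nrm
  }
  out <- counts %*% embed_projection(dims)
  dimnames(out) <- list(ids, NULL)
  attr(out, "featurizer") <- sprintf("hashed-%dmer-proj/1", k)
  out
}
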