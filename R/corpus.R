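#' The 25-letter amino-acid alphabet accepted for biotech-drug sequences
#'
#' The 20 standard residues plus the ambiguity/rare codes B, Z, X, U and O.
#'
#' @return Character vector of 25 single letters.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P", "Q",
    "R", "S", "T", "V", "W", "Y", "B", "Z", "X", "U", "O")
}

.network_names <- c("SSI", "BBI", "SPI", "BPI")

#' Assemble and validate a drug universe
#'
#' A drug universe bundles the two drug populations (small-molecule drugs,
#' SMDs, carrying SMILES strings; biotech drugs, BioDs, carrying amino-acid
#' sequences), a protein set, the four prior-knowledge interaction networks
#' (SSI: SMD-SMD, BBI: BioD-BioD, SPI: SMD-protein, BPI: BioD-protein) and
#' the labeled positive SMD-BioD interaction (SBI) set, expressed as
#' quaternaries `(drug_a, drug_b, mechanism, action)`.
#'
#' Validation enforces: unique drug ids, non-empty structures, BioD sequences
#' over the 25-letter alphabet, no self-loops, edge endpoints of the declared
#' types, and quaternaries with an SMD as `drug_a` and a BioD as `drug_b`.
#' Duplicate edges and duplicate quaternary rows are dropped with a warning.
#'
#' @param drugs data.frame with columns `id`, `kind` ("SMD"/"BioD"),
#'   `structure`.
#' @param proteins character vector of protein ids.
#' @param edges named list of data.frames (`SSI`, `BBI`, `SPI`, `BPI`), each
#'   with columns `from`, `to`.
#' @param sbi data.frame of positive quaternaries with columns `drug_a`,
#'   `drug_b`, `mechanism`, `action` ("increase"/"decrease").
#' @param min_count rare-event threshold passed to [build_event_catalog()].
#' @return An object of class `drug_universe`.
#' @export
drug_universe <- function(drugs, proteins, edges, sbi, min_count = 10) {
  drugs <- as.data.frame(drugs, stringsAsFactors = FALSE)
  needed <- c("id", "kind", "structure")
  if (!all(needed %in% names(drugs)))
    stopf("drugs table must have columns: %s", paste(needed, collapse = ", "))
  drugs <- drugs[needed]
  drugs[] <- lapply(drugs, as.character)
  if (anyDuplicated(drugs$id))
    stopf("duplicate drug id(s): %s",
          paste(unique(drugs$id[duplicated(drugs$id)]), collapse = ", "))
  if (!all(drugs$kind %in% c("SMD", "BioD")))
    stopf("drug kind must be 'SMD' or 'BioD'")
  if (any(!nzchar(drugs$structure)))
    stopf("empty structure for drug(s): %s",
          paste(drugs$id[!nzchar(drugs$structure)], collapse = ", "))
  biod <- drugs[drugs$kind == "BioD", ]
  if (nrow(biod)) {
    chars <- strsplit(biod$structure, "")
    bad <- vapply(chars, function(x) any(!x %in% aa_alphabet()), logical(1))
    if (any(bad))
      stopf("BioD sequence outside the 25-letter alphabet for: %s",
            paste(biod$id[bad], collapse = ", "))
  }
  proteins <- as.character(proteins)
  if (anyDuplicated(proteins)) proteins <- unique(proteins)

  if (!all(.network_names %in% names(edges)))
    stopf("edges must be a named list with elements %s",
          paste(.network_names, collapse = ", "))
  kind_of <- stats::setNames(drugs$kind, drugs$id)
  edges <- lapply(.network_names, function(net) {
    e <- as.data.frame(edges[[net]], stringsAsFactors = FALSE)
    if (nrow(e) == 0) return(data.frame(from = character(), to = character(),
                                        stringsAsFactors = FALSE))
    names(e)[1:2] <- c("from", "to")
    e <- data.frame(from = as.character(e$from), to = as.character(e$to),
                    stringsAsFactors = FALSE)
    if (any(e$from == e$to))
      stopf("%s edge list contains self-loop(s) at row(s) %s", net,
            paste(which(e$from == e$to), collapse = ", "))
    if (net %in% c("SSI", "BBI")) {
      want <- if (net == "SSI") "SMD" else "BioD"
      # canonical unordered orientation for intra-type edges
      swap <- e$from > e$to
      tmp <- e$from[swap]; e$from[swap] <- e$to[swap]; e$to[swap] <- tmp
      bad <- is.na(kind_of[e$from]) | is.na(kind_of[e$to]) |
        kind_of[e$from] != want | kind_of[e$to] != want
      if (any(bad))
        stopf("%s edge endpoints must be known %s drugs; offending row(s): %s",
              net, want, paste(which(bad), collapse = ", "))
    } else {
      want <- if (net == "SPI") "SMD" else "BioD"
      bad <- is.na(kind_of[e$from]) | kind_of[e$from] != want |
        !(e$to %in% proteins)
      if (any(bad))
        stopf("%s edges must link a known %s to a known protein; offending row(s): %s",
              net, want, paste(which(bad), collapse = ", "))
    }
    key <- paste(e$from, e$to, sep = "\r")
    if (anyDuplicated(key)) {
      warnf("%s: %d duplicate edge(s) dropped", net, sum(duplicated(key)))
      e <- e[!duplicated(key), ]
    }
    rownames(e) <- NULL
    e
  })
  names(edges) <- .network_names

  sbi <- as.data.frame(sbi, stringsAsFactors = FALSE)
  needed <- c("drug_a", "drug_b", "mechanism", "action")
  if (!all(needed %in% names(sbi)))
    stopf("sbi table must have columns: %s", paste(needed, collapse = ", "))
  sbi <- sbi[needed]
  sbi[] <- lapply(sbi, as.character)
  if (nrow(sbi)) {
    bad <- is.na(kind_of[sbi$drug_a]) | kind_of[sbi$drug_a] != "SMD"
    if (any(bad))
      stopf("sbi drug_a must be a known SMD; offending row(s): %s",
            paste(which(bad), collapse = ", "))
    bad <- is.na(kind_of[sbi$drug_b]) | kind_of[sbi$drug_b] != "BioD"
    if (any(bad))
      stopf("sbi drug_b must be a known BioD; offending row(s): %s",
            paste(which(bad), collapse = ", "))
    if (!all(sbi$action %in% c("increase", "decrease")))
      stopf("sbi action must be 'increase' or 'decrease'")
    key <- do.call(paste, c(sbi, sep = "\r"))
    if (anyDuplicated(key)) {
      warnf("sbi: %d duplicate quaternary row(s) dropped", sum(duplicated(key)))
      sbi <- sbi[!duplicated(key), ]
      rownames(sbi) <- NULL
    }
  }

  catalog <- if (nrow(sbi)) build_event_catalog(sbi, min_count = min_count) else NULL
  structure(list(drugs = drugs, proteins = proteins, edges = edges,
                 sbi = sbi, catalog = catalog),
            class = "drug_universe")
}

#' @export
print.drug_universe <- function(x, ...) {
  cat("drug_universe:",
      sum(x$drugs$kind == "SMD"), "SMDs,",
      sum(x$drugs$kind == "BioD"), "BioDs,",
      length(x$proteins), "proteins\n")
  for (net in .network_names)
    cat(sprintf("  %s edges: %d\n", net, nrow(x$edges[[net]])))
  cat("  positive SBI quaternaries:", nrow(x$sbi), "\n")
  if (!is.null(x$catalog))
    cat("  event classes (incl. class 0):", x$catalog$n_classes, "\n")
  invisible(x)
}

smd_ids <- function(universe) universe$drugs$id[universe$drugs$kind == "SMD"]
biod_ids <- function(universe) universe$drugs$id[universe$drugs$kind == "BioD"]

#' Build the interaction-event catalog with rare-event merging
#'
#' Events are the distinct `(mechanism, action)` combinations of the positive
#' quaternary set. Events observed more than `min_count` times receive ids
#' `1..F` ordered by descending count (ties broken lexicographically by
#' mechanism then action); all events observed `min_count` times or fewer are
#' merged into a single rare bucket placed last. Event id 0 is reserved for
#' the no-interaction class, so the total number of label classes is
#' `F + (1 if any rare) + 1`.
#'
#' @param quaternaries data.frame with columns `mechanism`, `action`.
#' @param min_count events with count <= `min_count` go to the rare bucket.
#' @return Object of class `event_catalog`: a list with `events` (data.frame
#'   mapping mechanism/action to `event_id`), `rare_id` (NA if no rare
#'   bucket), `n_events` (ids 1..K) and `n_classes` (= K + 1, with class 0).
#' @export
build_event_catalog <- function(quaternaries, min_count = 10) {
  q <- as.data.frame(quaternaries, stringsAsFactors = FALSE)
  if (nrow(q) == 0) stopf("cannot build an event catalog from zero quaternaries")
  counts <- stats::aggregate(list(count = rep(1L, nrow(q))),
                             by = list(mechanism = as.character(q$mechanism),
                                       action = as.character(q$action)),
                             FUN = sum)
  counts <- counts[order(-counts$count, counts$mechanism, counts$action), ]
  rownames(counts) <- NULL
  frequent <- counts$count > min_count
  counts$rare <- !frequent
  counts$event_id <- NA_integer_
  counts$event_id[frequent] <- seq_len(sum(frequent))
  rare_id <- if (any(!frequent)) sum(frequent) + 1L else NA_integer_
  counts$event_id[!frequent] <- rare_id
  n_events <- sum(frequent) + as.integer(any(!frequent))
  structure(list(events = counts, rare_id = rare_id, n_events = n_events,
                 n_classes = n_events + 1L, min_count = min_count),
            class = "event_catalog")
}

#' @export
print.event_catalog <- function(x, ...) {
  cat("event_catalog:", x$n_events, "event ids (+ class 0);",
      if (is.na(x$rare_id)) "no rare bucket"
      else sprintf("rare bucket = id %d", x$rare_id),
      sprintf("(min_count = %d)\n", x$min_count))
  invisible(x)
}

#' Map quaternaries to event ids under a catalog
#'
#' @param catalog an `event_catalog`.
#' @param mechanism,action character vectors.
#' @return Integer event ids in `1..n_events`.
#' @export
event_id <- function(catalog, mechanism, action) {
  key <- paste(mechanism, action, sep = "\r")
  tab <- stats::setNames(catalog$events$event_id,
                         paste(catalog$events$mechanism, catalog$events$action,
                               sep = "\r"))
  out <- tab[key]
  if (anyNA(out))
    stopf("unknown event(s): %s", paste(unique(key[is.na(out)]), collapse = "; "))
  unname(out)
}

#' Enumerate the candidate SMD-BioD pair space
#'
#' Every ordered (SMD, BioD) combination is a candidate pair; pairs present
#' in the positive quaternary set are labeled `positive`, all remaining pairs
#' `unlabeled`. The candidate count is exactly `|SMD| * |BioD|`.
#'
#' @param universe a `drug_universe`.
#' @return data.frame with columns `smd_id`, `biod_id`, `label`; attribute
#'   `counts` holds the partition sizes.
#' @export
enumerate_candidate_pairs <- function(universe) {
  smds <- sort(smd_ids(universe))
  biods <- sort(biod_ids(universe))
  pairs <- expand.grid(smd_id = smds, biod_id = biods,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pos_key <- unique(paste(universe$sbi$drug_a, universe$sbi$drug_b, sep = "\r"))
  key <- paste(pairs$smd_id, pairs$biod_id, sep = "\r")
  pairs$label <- ifelse(key %in% pos_key, "positive", "unlabeled")
  counts <- c(candidates = nrow(pairs),
              positive = sum(pairs$label == "positive"),
              unlabeled = sum(pairs$label == "unlabeled"))
  sbi_log(sprintf("candidate space: %d pairs = %d SMD x %d BioD (%d positive, %d unlabeled)",
                  counts[["candidates"]], length(smds), length(biods),
                  counts[["positive"]], counts[["unlabeled"]]))
  attr(pairs, "counts") <- counts
  pairs
}

#' Multi-hot event label matrix for drug pairs
#'
#' Builds the per-pair target vector over `n_classes` outputs: column 1 is
#' the no-interaction class (bit set only for pairs absent from the positive
#' set), columns `2..n_classes` are event ids `1..K`. A pair with several
#' quaternaries gets several event bits set.
#'
#' @param universe a `drug_universe` (with a catalog).
#' @param pairs data.frame with `smd_id`, `biod_id`.
#' @return numeric matrix `nrow(pairs) x n_classes`.
#' @export
pair_label_matrix <- function(universe, pairs) {
  catalog <- universe$catalog
  if (is.null(catalog)) stopf("universe has no event catalog")
  K <- catalog$n_classes
  Y <- matrix(0, nrow(pairs), K)
  sbi <- universe$sbi
  ev <- event_id(catalog, sbi$mechanism, sbi$action)
  pkey <- paste(pairs$smd_id, pairs$biod_id, sep = "\r")
  skey <- paste(sbi$drug_a, sbi$drug_b, sep = "\r")
  idx <- match(skey, pkey)
  keep <- !is.na(idx)
  if (any(keep)) Y[cbind(idx[keep], ev[keep] + 1L)] <- 1
  no_int <- rowSums(Y[, -1, drop = FALSE]) == 0
  Y[no_int, 1] <- 1
  colnames(Y) <- c("class0", paste0("event", seq_len(K - 1L)))
  Y
}
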