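test_that("vocabulary assigns one contiguous index per distinct character", {
  v <- build_vocabulary(c("CCO", "CN"), "SMILES")
  expect_equal(v$size, 3)
  expect_setequal(names(v$index), c("C", "O", "N"))
  expect_equal(sort(unname(v$index)), 1:3)
  expect_equal(v$unknown, 4)
  # empty strings contribute nothing
  v2 <- build_vocabulary(c("", "CCO", "CN"), "SMILES")
  expect_equal(v2$size, 3)
  # full residue coverage gives the 25-letter alphabet
  va <- build_vocabulary(paste(aa_alphabet(), collapse = ""), "AA")
  expect_equal(va$size, 25)
})

test_that("tokenize pads, truncates and maps unknowns to the reserved index", {
  v <- build_vocabulary("CCO", "SMILES")  # C -> 1, O -> 2
  tok <- tokenize("CCO", v, 5)
  expect_equal(as.integer(tok[1, ]), c(1L, 1L, 2L, 0L, 0L))
  expect_equal(attr(tok, "lengths"), 3L)
  # truncation keeps the first max_len characters
  long <- paste(rep("C", 1500), collapse = "")
  tok2 <- tokenize(long, v, 1000)
  expect_equal(ncol(tok2), 1000)
  expect_true(all(tok2[1, ] == 1L))
  # unknown character -> reserved index, with a warning
  expect_warning(tok3 <- tokenize("CX", v, 4), "unknown")
  expect_equal(as.integer(tok3[1, ]), c(1L, v$unknown, 0L, 0L))
  # padding mass equals max(0, max_len - length)
  strs <- c("C", "CCO", "CCOCCO")
  tk <- tokenize(strs, v, 4)
  expect_equal(rowSums(tk == 0), pmax(0, 4 - nchar(strs)) * 1.0)
})

test_that("fingerprint is 1024-bit, canonical over SMILES aliases", {
  fp <- fingerprint(c(a = "CCO", b = "OCC", tol1 = "Cc1ccccc1",
                      tol2 = "c1ccccc1C"))
  expect_equal(ncol(fp), 1024)
  expect_true(all(fp %in% c(0, 1)))
  expect_identical(fp["a", ], fp["b", ])
  expect_identical(fp["tol1", ], fp["tol2", ])
  # Tanimoto of a molecule with itself is 1
  expect_equal(jaccard(fp["a", ], fp["a", ]), 1)
  # unparseable SMILES names the drug
  expect_error(fingerprint(c(bad = "C(((")), "bad")
  # bondless molecules still fingerprint (one atom path each)
  expect_equal(unname(rowSums(fingerprint(c("C", "[Li+]")))), c(1, 1))
})

test_that("benzene bit population matches an exhaustive path-enumeration oracle", {
  # independent oracle: enumerate all simple paths on a hand-built kekulized
  # 6-ring (alternating single/double bonds), canonicalize, hash
  adj <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 6), c(6, 1))
  bond <- c("-", "=", "-", "=", "-", "=")
  nbrs <- lapply(1:6, function(a) {
    hits <- which(adj[, 1] == a | adj[, 2] == a)
    data.frame(to = ifelse(adj[hits, 1] == a, adj[hits, 2], adj[hits, 1]),
               sym = bond[hits])
  })
  paths <- character(0)
  grow <- function(atom, visited, tokens) {
    fwd <- paste(tokens, collapse = "")
    bwd <- paste(rev(tokens), collapse = "")
    paths <<- c(paths, min(fwd, bwd))
    if ((length(tokens) + 1) / 2 >= 8) return()
    nb <- nbrs[[atom]]
    for (r in seq_len(nrow(nb)))
      if (!(nb$to[r] %in% visited))
        grow(nb$to[r], c(visited, nb$to[r]), c(tokens, nb$sym[r], "C"))
  }
  for (a in 1:6) grow(a, a, "C")
  oracle_bits <- sort(unique(vapply(unique(paths),
                                    function(p) oracle_hash_bit(p, 1024),
                                    numeric(1))))
  fp <- fingerprint(c(bz = "c1ccccc1"))
  expect_identical(which(fp[1, ] == 1), as.integer(oracle_bits))
})

test_that("protein embedding is 1280-dim, deterministic, truncated at 1024", {
  e1 <- protein_embedding(c(x = "ACDEFGHIKLMNPQRSTVWY"))
  expect_equal(dim(e1), c(1L, 1280L))
  e2 <- protein_embedding(c(x = "ACDEFGHIKLMNPQRSTVWY"))
  expect_identical(e1, e2)
  # sequences identical in the first 1024 residues embed identically
  base <- paste(sample(aa_alphabet()[1:20], 1024, TRUE), collapse = "")
  s1 <- paste0(base, "AAAA"); s2 <- paste0(base, "WWWW")
  expect_identical(unname(protein_embedding(s1)), unname(protein_embedding(s2)))
  expect_error(protein_embedding(c(bad = "")), "bad")
})

test_that("3-mer counts match the hand-enumerated k-mer multiset", {
  expect_identical(protein_kmer_counts("ACD"), c(ACD = 1L))
  km <- protein_kmer_counts("ACDCACD")
  # windows: ACD CDC DCA CAC ACD
  expect_identical(km[order(names(km))],
                   c(ACD = 2L, CAC = 1L, CDC = 1L, DCA = 1L))
  expect_length(protein_kmer_counts("AC"), 0)
})

test_that("external embedding backend enforces the adapter contract", {
  fn_ok <- function(seqs) matrix(1, length(seqs), 1280)
  e <- protein_embedding(c(a = "ACD"), backend = "external", external_fn = fn_ok)
  expect_equal(dim(e), c(1L, 1280L))
  fn_bad <- function(seqs) matrix(1, length(seqs), 64)
  expect_error(protein_embedding(c(a = "ACD"), backend = "external",
                                 external_fn = fn_bad), "1280")
})
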