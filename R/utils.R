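# internal helpers shared across modules

#' @keywords internal
"_PACKAGE"

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards so library code never clobbers user seeds.
local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic sub-stream seed derivation; result always in [0, 2^31).
derive_seed <- function(seed, tag) {
  base <- ((as.numeric(seed) %% 65011) + 1) * 33013
  as.integer((base + fnv1a(tag)) %% 2147483647)
}

# Vectorized 32-bit FNV-1a string hash. Multiplication mod 2^32 is done in
# 16-bit halves so everything stays inside exact double arithmetic.
fnv1a <- function(strings) {
  strings <- as.character(strings)
  n <- length(strings)
  if (n == 0L) return(numeric(0))
  bytes <- lapply(strings, utf8ToInt)
  lens <- lengths(bytes)
  maxlen <- max(lens, 1L)
  h <- rep(2166136261, n)
  prime <- 16777619
  for (i in seq_len(maxlen)) {
    active <- lens >= i
    if (!any(active)) break
    b <- vapply(bytes[active], function(x) x[[i]], numeric(1))
    hv <- h[active]
    # xor via 16-bit halves (bitwXor needs ints < 2^31)
    lo <- bitwXor(hv %% 65536, b)
    hi <- hv %/% 65536
    hv <- hi * 65536 + lo
    # hv * prime mod 2^32
    h1 <- hv %/% 65536
    h0 <- hv %% 65536
    hv <- (((h1 * prime) %% 65536) * 65536 + h0 * prime) %% 4294967296
    h[active] <- hv
  }
  h
}

# Hash strings to bit positions 1..nbits. The 32-bit hash is XOR-folded to
# 16 bits first: FNV-1a's low bits alone mix poorly for short similar keys.
hash_to_bit <- function(strings, nbits) {
  h <- fnv1a(strings)
  (bitwXor(h %/% 65536, h %% 65536) %% nbits) + 1
}

sbi_log <- function(...) {
  if (isTRUE(getOption("sbipredict.verbose", TRUE))) message(...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

softmax_rows <- function(x) {
  x <- x - apply(x, 1, max)
  e <- exp(x)
  e / rowSums(e)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
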