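#' @keywords internal
"_PACKAGE"

# Derive a per-unit RNG seed from a master seed so permutation streams are
# independent of iteration order. Kept below 2^31 - 1.
stream_seed <- function(seed, i) {
  s <- (as.numeric(seed) %% 2147483647) * 1000003 + as.numeric(i) * 7919
  as.integer(s %% 2147483647)
}

# Evaluate expr with a temporary RNG state seeded by `seed`; restores the
# caller's stream afterwards so seeded helpers do not perturb global RNG.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# FNV-1a 32-bit hash of a character scalar, as 8 hex digits. Used for the
# run manifest's config fingerprint; not cryptographic.
fnv1a_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(x)
  # 32-bit arithmetic via doubles (R ints overflow at 2^31)
  h <- 2166136261
  for (b in bytes) {
    h <- xor32(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# xor of a double-held 32-bit value with a small int
xor32 <- function(a, b) {
  ab <- as.integer(a %% 65536)
  at <- as.integer(a %/% 65536)
  bb <- as.integer(b %% 65536)
  bt <- as.integer(b %/% 65536)
  as.numeric(bitwXor(at, bt)) * 65536 + as.numeric(bitwXor(ab, bb))
}

# significance stars matching the usual *, **, *** convention
p_stars <- function(p) {
  out <- character(length(p))
  out[!is.na(p) & p < 0.05]  <- "*"
  out[!is.na(p) & p < 0.01]  <- "**"
  out[!is.na(p) & p < 0.001] <- "***"
  out[is.na(p)] <- NA_character_
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

flood_log <- function(fmt, ..., verbose = TRUE) {
  if (isTRUE(verbose)) message(sprintf(fmt, ...))
  invisible(NULL)
}
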