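# 32-bit unsigned arithmetic on doubles (exact below 2^53)

.mod32 <- function(x) x %% 4294967296

.mul32 <- function(a, b) {
  a_lo <- a %% 65536
  a_hi <- (a - a_lo) / 65536
  b_lo <- b %% 65536
  b_hi <- (b - b_lo) / 65536
  mid <- (a_lo * b_hi + a_hi * b_lo) %% 65536
  (a_lo * b_lo + mid * 65536) %% 4294967296
}

.xor32 <- function(a, b) {
  a_lo <- a %% 65536
  b_lo <- b %% 65536
  hi <- bitwXor(as.integer((a - a_lo) / 65536), as.integer((b - b_lo) / 65536))
  hi * 65536 + bitwXor(as.integer(a_lo), as.integer(b_lo))
}

.shr32 <- function(a, n) floor(a / 2^n)

# splitmix32 finaliser: avalanches a 32-bit word
.scramble32 <- function(z) {
  z <- .xor32(z, .shr32(z, 16))
  z <- .mul32(z, 569420461)   # 0x21f0aaad
  z <- .xor32(z, .shr32(z, 15))
  z <- .mul32(z, 1935289751)  # 0x735a2d97
  .xor32(z, .shr32(z, 15))
}

#' Derive a reproducible child seed from a sequence of integer keys
#'
#' Counter-based seed derivation: hashes an arbitrary sequence of integer
#' keys (for example master seed, cell id, individual id, replication id)
#' into a positive seed below 2^31 suitable for [set.seed()]. Distinct key
#' sequences map to effectively independent seeds, and the mapping is a
#' pure function, so any stream in a hierarchical simulation can be
#' reconstructed without storing generator state.
#'
#' @param ... integer-like scalar keys (coerced with `as.numeric`).
#' @return A single integer in `[1, 2^31 - 1]`.
#' @export
#' @examples
#' mix_seed(42, 3, 17, 1)
mix_seed <- function(...) {
  keys <- vapply(list(...), as.numeric, numeric(1))
  if (any(!is.finite(keys))) stop("mix_seed(): keys must be finite numbers")
  h <- 2166136261
  for (k in keys) {
    h <- .scramble32(.xor32(h, .mod32(abs(k))))
    h <- .scramble32(.xor32(h, 2654435769))  # golden-ratio separator
  }
  as.integer(h %% 2147483646) + 1L
}

# FNV-1a over a string; short hex digest for provenance records
.digest_string <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\x1f")))
  h <- 2166136261
  for (b in bytes) h <- .mul32(.xor32(h, b), 16777619)
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

# Display rounding: half away from zero (sprintf/round use half-even)
.round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's
# RNG state afterwards (no-op wrapper when seed is NULL).
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
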