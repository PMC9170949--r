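# Shared internal helpers: rounding conventions, stable hashing, codon
# translation, and seed scoping.

#' Round half away from zero
#'
#' Commercial rounding (0.5 always rounds up), the convention used for every
#' reported percentage in this package. Base R's `round()` rounds half to
#' even, which disagrees on values such as 21.875.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5 + 1e-9) / f
}

# percentage of num/den, rounded half-up to one decimal
pct1 <- function(num, den) round_half_up(100 * num / den, 1)

# Stable 32-bit FNV-1a hash of strings, returned as 8-char hex. Used for
# reproducible clone identifiers; must not depend on R's serialization.
fnv1a_hex <- function(x) {
  vapply(x, function(s) {
    bytes <- utf8ToInt(s)
    # split the 32-bit state into two 16-bit halves so xor/multiply stay exact
    hi <- 0x8421L; lo <- 0x2325L  # 2166136261 = 0x84212325
    for (b in bytes) {
      lo <- bitwXor(lo, b)
      # multiply (hi,lo) by FNV prime 16777619 = 0x01000193
      p_lo <- 0x0193; p_hi <- 0x0100
      new_lo <- lo * p_lo
      new_hi <- hi * p_lo + lo * p_hi + new_lo %/% 65536
      lo <- new_lo %% 65536
      hi <- new_hi %% 65536
    }
    sprintf("%04x%04x", hi, lo)
  }, character(1), USE.NAMES = FALSE)
}

# Vectorized nucleotide -> amino acid translation (standard code, "*" = stop).
translate_cdr3 <- function(nt) {
  gc_tab <- Biostrings::GENETIC_CODE
  n <- nchar(nt)
  stopifnot(all(n %% 3 == 0))
  nc <- n %/% 3
  idx <- rep(seq_along(nt), nc)
  starts <- unlist(lapply(nc, function(k) seq(1, by = 3, length.out = k)),
                   use.names = FALSE)
  codons <- substring(nt[idx], starts, starts + 2)
  aas <- unname(gc_tab[codons])
  aas[is.na(aas)] <- "X"
  out <- vapply(split(aas, factor(idx, levels = seq_along(nt))),
                paste, character(1), collapse = "")
  unname(out)
}

# Evaluate `expr` under a temporary seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a child seed from a master seed and a stream label; keeps all
# randomness attributable to one master seed. Stays below 2^31.
derive_seed <- function(seed, stream) {
  h <- strtoi(substr(fnv1a_hex(paste0("s", seed, ":", stream)), 2, 8), 16L)
  (h + seed) %% 2147483647L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
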