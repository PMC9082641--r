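#' Derive a reproducible sub-seed from a master seed and a stream label
#'
#' All stochastic stages draw from named streams derived from one master
#' integer seed, so that partial reruns (e.g. regenerating only the mission
#' stream) are reproducible. The derivation is a small deterministic hash of
#' the label folded into the master seed, reduced modulo 2^31 - 1.
#'
#' @param master integer master seed.
#' @param label character stream label, e.g. `"region"`, `"missions/rep3"`.
#' @return an integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @export
#' @examples
#' derive_seed(1, "region")
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1, is.character(label))
  h <- 0
  for (cc in utf8ToInt(label)) h <- (h * 131 + cc) %% 2147483647
  s <- (abs(as.numeric(master)) %% 2147483647) * 48271 %% 2147483647
  out <- (s + h * 69621) %% 2147483646 + 1
  as.integer(out)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG state is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# 32-bit FNV-1a hash of a character string, as hex; used for provenance
# headers on output files. Arithmetic kept in doubles (exact below 2^53);
# the per-byte xor only touches the low 8 bits.
fnv1a32 <- function(x) {
  h <- 2166136261
  for (b in as.integer(charToRaw(enc2utf8(x)))) {
    h <- h - (h %% 256) + bitwXor(as.integer(h %% 256), b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", h)
}
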