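#' @keywords internal
"_PACKAGE"

#' @importFrom stats rbinom runif setNames
#' @importFrom utils read.table write.table
NULL

# Seed streams: one master seed, fixed offsets per component so that the
# reference, array and variant simulations can be regenerated independently.
.seed_offsets <- c(reference = 101L, array = 202L, variants = 303L)

.component_seed <- function(seed, component) {
  off <- .seed_offsets[[component]]
  (as.integer(seed) + off) %% .Machine$integer.max
}

# Uniform random DNA as a character scalar; raw-byte path keeps 10 Mb
# contigs cheap enough to regenerate per seed.
random_dna <- function(n) {
  rawToChar(as.raw(sample(c(65L, 67L, 71L, 84L), n, replace = TRUE)))
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Half-up rounding to `digits` decimals (base round() is round-half-even).
round_half_up <- function(x, digits = 1) {
  floor(x * 10^digits + 0.5) / 10^digits
}

`%||%` <- function(a, b) if (is.null(a)) b else a
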