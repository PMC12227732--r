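# Internal helpers shared across modules.

# Bitmask encoding of observed alleles: A=1, C=2, G=4, T=8.
# A position's allele set is the set bits; two allele sets are disjoint
# iff bitwAnd() of their masks is zero.
BASE_MASK <- c(A = 1L, C = 2L, G = 4L, T = 8L)
BASES <- c("A", "C", "G", "T")

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_if <- function(cond, ...) {
  if (cond) stop(..., call. = FALSE)
}

# Evaluate `code` under a fixed RNG seed, restoring caller RNG state.
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

# Derive a stream-specific child seed below 2^31 from a base seed.
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 1009 + as.numeric(stream) * 7919) %% 2147483647
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == floor(x)
}

# Collapse a character vector into a single comma-separated token
# (used for list-like columns in TSV reports).
collapse_ids <- function(x) paste(x, collapse = ",")
split_ids <- function(x) if (!nzchar(x)) character(0) else strsplit(x, ",", fixed = TRUE)[[1]]
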