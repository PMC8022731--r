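# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
.assert <- function(cond, ..., call. = FALSE) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = call.)
}

# Reverse complement of a plain character motif (ACGT only).
.revcomp <- function(x) {
  chartr("ACGTacgt", "TGCAtgca",
         vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
                character(1), USE.NAMES = FALSE))
}

# Random DNA string of length n from the current RNG stream.
.random_dna <- function(n, gc = 0.42) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# A string of `n` bases taken from the tandem repeat of `motif`, ending on a
# complete motif copy (used for telomere tails read 5'->3' into the chromosome).
.repeat_tail <- function(motif, n) {
  m <- nchar(motif)
  full <- strrep(motif, ceiling(n / m) + 1L)
  substr(full, nchar(full) - n + 1L, nchar(full))
}

# Apply uniform substitutions at `rate` to a DNA string.
.mutate_dna <- function(s, rate) {
  if (rate <= 0) return(s)
  n <- nchar(s)
  hit <- which(runif(n) < rate)
  if (!length(hit)) return(s)
  ch <- strsplit(s, "")[[1]]
  alt <- c("A", "C", "G", "T")
  for (i in hit) {
    ch[i] <- sample(setdiff(alt, ch[i]), 1L)
  }
  paste(ch, collapse = "")
}

# Deterministic integer sub-seed derived from a base seed and an offset,
# kept within the 32-bit integer range.
.sub_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + as.numeric(offset)) %% 2147483647)
}
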