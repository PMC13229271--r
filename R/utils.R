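# Shared constants and small internal helpers.

#' The twenty canonical amino-acid letters
#'
#' One-letter codes in alphabetical order. This ordering fixes the column
#' order of all composition vectors and of the composition embedder.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Kyte-Doolittle hydropathy scale
#'
#' Named numeric vector over [AA_ALPHABET]. Residues with positive values are
#' treated as hydrophobic throughout the synthetic generators and the parity
#' controls.
#'
#' @format Named numeric vector of length 20.
#' @export
KD_HYDROPATHY <- c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8,
                   G = -0.4, H = -3.2, I = 4.5, K = -3.9, L = 3.8,
                   M = 1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
                   S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)

#' Hydrophobic amino acids (Kyte-Doolittle > 0)
#'
#' @format Character vector.
#' @export
HYDROPHOBIC_AA <- names(KD_HYDROPATHY)[KD_HYDROPATHY > 0]

# Split a sequence string into single characters.
seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

# Integer codes (1..20) into AA_ALPHABET; NA for non-canonical letters.
seq_codes <- function(seq) match(seq_chars(seq), AA_ALPHABET)

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. Used by every seeded operation so generators stay pure
# functions of their arguments.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derive a stream of sub-seeds from one user-facing seed (kept < 2^31).
spawn_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
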