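# Composition-preserving permutation and scramble controls: tools that
# separate sequence-patterning effects from amino-acid composition.

#' All distinct permutations of a short sequence
#'
#' Enumerates the distinct multiset permutations (count
#' `L! / prod(multiplicities!)`). Guarded to short sequences; lift the guard
#' explicitly for longer ones.
#'
#' @param seq Sequence string.
#' @param max_len Factorial guard (default 8).
#' @return Character vector of distinct sequences.
#' @export
exhaustive_permutations <- function(seq, max_len = 8L) {
  stopifnot(is_string(seq), nzchar(seq))
  chars <- seq_chars(seq)
  if (length(chars) > max_len) {
    stop("sequence longer than the factorial guard (", max_len,
         "); pass a larger max_len to override")
  }
  rec <- function(chars) {
    if (length(chars) <= 1L) return(paste(chars, collapse = ""))
    out <- character(0)
    for (a in unique(chars)) {
      rest <- chars[-match(a, chars)]
      out <- c(out, paste0(a, rec(rest)))
    }
    out
  }
  rec(sort(chars))
}

#' Seeded composition-preserving scrambles
#'
#' Draws `n` uniform random permutations of the sequence (with replacement
#' across draws); every scramble has exactly the letter counts of the
#' input.
#'
#' @param seq Sequence string.
#' @param n Number of scrambles (>= 1).
#' @param seed Seed; the scramble list is reproducible from it.
#' @return Character vector of length `n`.
#' @export
sampled_scrambles <- function(seq, n, seed = 1L) {
  stopifnot(is_string(seq), nzchar(seq), n >= 1L)
  chars <- seq_chars(seq)
  with_seed(seed, vapply(seq_len(n), function(i)
    paste(sample(chars), collapse = ""), character(1)))
}

#' Positional-parity subclass of marked residues
#'
#' Classifies an arrangement of marked residues (e.g. the hydrophilic Q and
#' K of a hexapeptide) by position: `adjacent_center` when the marked
#' positions are mutually consecutive and lie wholly within the central
#' third of the sequence (positions `ceiling(L/3) .. ceiling(2L/3)`),
#' otherwise `same_parity` when all marked 1-based positions share parity,
#' otherwise `mixed`.
#'
#' @param seq Sequence string.
#' @param marked_residues Character vector of marked letters; each must
#'   occur in `seq`.
#' @return One of `"adjacent_center"`, `"same_parity"`, `"mixed"`.
#' @export
parity_subclass <- function(seq, marked_residues) {
  chars <- seq_chars(seq)
  missing_marks <- setdiff(marked_residues, chars)
  if (length(missing_marks) > 0L) {
    stop("marked letter(s) absent from sequence: ",
         paste(missing_marks, collapse = ", "))
  }
  pos <- which(chars %in% marked_residues)
  L <- length(chars)
  lo <- ceiling(L / 3); hi <- ceiling(2 * L / 3)
  consecutive <- length(pos) >= 2L && all(diff(pos) == 1L)
  if (consecutive && all(pos >= lo & pos <= hi)) return("adjacent_center")
  if (length(unique(pos %% 2L)) == 1L) return("same_parity")
  "mixed"
}

#' Whole-sequence probability scorer from a classifier and backend
#'
#' Returns a function mapping a sequence to the classifier probability of
#' its mean-pooled embedding — the scorer used by the scramble controls.
#'
#' @param model A `phase_classifier`.
#' @param backend An `embedder_backend`.
#' @param type `"prob"` (default) or `"logit"`.
#' @return Function `seq -> numeric`.
#' @export
sequence_scorer <- function(model, backend, type = "prob") {
  force(model); force(backend); force(type)
  function(seq) {
    pooled <- matrix(mean_pool(backend$embed(seq)), nrow = 1L)
    predict(model, pooled, type = type)
  }
}

#' Score change under composition-preserving scrambling
#'
#' Scores the original sequence and `n` seeded scrambles, and summarizes the
#' decrease `original - scramble`. Under a composition-only scorer the
#' decrease is identically zero; a positive mean decrease on high-scoring
#' sequences indicates the scorer rewards the original residue arrangement
#' beyond its composition.
#'
#' @param scorer Function `seq -> numeric` (see [sequence_scorer()]).
#' @param seq Sequence string.
#' @param n Number of scrambles (>= 1).
#' @param seed Seed for the scrambles.
#' @return Object of class `scramble_delta`: list with `original_score`,
#'   `scramble_scores`, `mean_decrease` and decrease `quantiles`.
#' @export
scramble_delta <- function(scorer, seq, n = 100L, seed = 1L) {
  stopifnot(is.function(scorer), n >= 1L)
  original <- scorer(seq)
  scrambles <- sampled_scrambles(seq, n, seed)
  scores <- vapply(scrambles, scorer, numeric(1), USE.NAMES = FALSE)
  dec <- original - scores
  structure(list(original_score = original, scramble_scores = scores,
                 mean_decrease = mean(dec),
                 quantiles = stats::quantile(dec, c(0.05, 0.25, 0.5,
                                                    0.75, 0.95))),
            class = "scramble_delta")
}

#' @export
print.scramble_delta <- function(x, ...) {
  cat(sprintf(
    "<scramble_delta> original %.4f, %d scrambles, mean decrease %.4f\n",
    x$original_score, length(x$scramble_scores), x$mean_decrease))
  invisible(x)
}
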