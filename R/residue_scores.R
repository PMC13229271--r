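# Multi-window per-residue scoring: tile a sequence into overlapping
# fragments, score fragments with a classifier, average the scores of all
# fragments covering each residue, then average across probe lengths.

#' Tile a sequence into overlapping fragments
#'
#' Stride-1 windows of length `w`; for sequences shorter than `w` the whole
#' sequence is returned as a single fragment flagged `short`.
#'
#' @param seq Sequence string (non-empty).
#' @param w Window (probe) length, >= 1.
#' @return Data frame with columns `start` (1-based), `fragment`, `short`.
#' @export
tile_fragments <- function(seq, w) {
  stopifnot(is_string(seq), nzchar(seq), w >= 1L)
  L <- nchar(seq)
  if (L < w) {
    return(data.frame(start = 1L, fragment = seq, short = TRUE,
                      stringsAsFactors = FALSE))
  }
  starts <- 1L:(L - w + 1L)
  data.frame(start = starts, fragment = substring(seq, starts, starts + w - 1L),
             short = FALSE, stringsAsFactors = FALSE)
}

#' Per-residue scores from fragment scores (covering mean)
#'
#' Residue i's score is the mean of `frag_scores[s]` over all window starts
#' `s` in `[max(1, i - w + 1), min(i, L - w + 1)]`, i.e. over every fragment
#' covering residue i. `NA` fragment scores (e.g. masked fragments) are
#' excluded from the mean; residues covered by no defined fragment are `NA`.
#'
#' @param L Sequence length.
#' @param w Window length (w <= L).
#' @param frag_scores Numeric vector of length `L - w + 1`.
#' @return Numeric vector of length L.
#' @export
per_residue_from_fragments <- function(L, w, frag_scores) {
  L <- as.integer(L); w <- as.integer(w)
  stopifnot(w >= 1L, L >= w)
  if (length(frag_scores) != L - w + 1L) {
    stop("expected ", L - w + 1L, " fragment scores, got ", length(frag_scores))
  }
  ok <- !is.na(frag_scores)
  cs <- c(0, cumsum(ifelse(ok, frag_scores, 0)))
  cn <- c(0, cumsum(as.numeric(ok)))
  i <- seq_len(L)
  lo <- pmax(1L, i - w + 1L)
  hi <- pmin(i, L - w + 1L)
  tot <- cs[hi + 1L] - cs[lo]
  cnt <- cn[hi + 1L] - cn[lo]
  out <- tot / cnt
  out[cnt == 0] <- NA_real_
  out
}

# Fragment probabilities for one probe length, masking fragments that
# contain X. Returns the length-(L - w + 1) score vector (NA where masked),
# or a single flagged value for short sequences.
fragment_probs <- function(seq, w, model, backend) {
  L <- nchar(seq)
  chars <- seq_chars(seq)
  has_x <- chars == "X"
  if (L < w) {
    if (any(has_x)) return(NA_real_)
    pooled <- matrix(mean_pool(backend$embed(seq)), nrow = 1L)
    return(predict(model, pooled))
  }
  n_win <- L - w + 1L
  cx <- c(0L, cumsum(as.integer(has_x)))
  valid <- which((cx[(w + 1L):(L + 1L)] - cx[1L:n_win]) == 0L)
  scores <- rep(NA_real_, n_win)
  if (length(valid) == 0L) return(scores)
  if (!any(has_x) && !is.null(backend$pool_windows)) {
    pooled <- pool_windows(backend, seq, w)
  } else {
    frags <- substring(seq, valid, valid + w - 1L)
    pooled <- embed_sequences(frags, backend)
  }
  scores[valid] <- predict(model, pooled)
  scores
}

#' Per-residue propensity profile of one sequence
#'
#' For every probe length the sequence is tiled into overlapping fragments,
#' each fragment is embedded and scored by the corresponding classifier
#' (probability scale), and fragment scores are turned into residue scores
#' with [per_residue_from_fragments()]. The combined profile is the
#' unweighted mean over the probes defined at each residue. Fragments
#' containing masked (`X`) residues are skipped; residues covered by no
#' surviving fragment are undefined.
#'
#' @param seq Sequence string (canonical letters plus optional `X`).
#' @param models A single `phase_classifier` applied at every probe, or a
#'   named list mapping probe length (as character) to a classifier.
#' @param backend An `embedder_backend` matching the classifiers' feature
#'   space.
#' @param probes Integer vector of window lengths, e.g. `c(6, 10, 15)` for
#'   amyloid and `c(15, 25, 40)` for LLPS scoring.
#' @param short One of `"whole"` (default: a probe longer than the sequence
#'   scores the whole sequence once and assigns that value to every residue,
#'   flagged low-confidence) or `"omit"` (that probe contributes nothing).
#' @return An object of class `residue_profile`: list with `sequence`,
#'   `probes`, `scores` (probe x residue matrix), `combined`,
#'   `short_probes`, `backend`.
#' @export
profile_sequence <- function(seq, models, backend, probes = c(6L, 10L, 15L),
                             short = c("whole", "omit")) {
  short <- match.arg(short)
  stopifnot(is_string(seq), nzchar(seq), length(probes) >= 1L)
  probes <- as.integer(probes)
  L <- nchar(seq)
  model_for <- function(w) {
    if (inherits(models, "phase_classifier")) return(models)
    m <- models[[as.character(w)]]
    if (is.null(m)) stop("no classifier supplied for probe length ", w)
    m
  }
  scores <- matrix(NA_real_, nrow = length(probes), ncol = L,
                   dimnames = list(as.character(probes), NULL))
  short_probes <- integer(0)
  for (pi in seq_along(probes)) {
    w <- probes[pi]
    model <- model_for(w)
    if (L < w) {
      short_probes <- c(short_probes, w)
      if (short == "omit") next
      val <- fragment_probs(seq, w, model, backend)
      scores[pi, ] <- rep(val, L)
    } else {
      fs <- fragment_probs(seq, w, model, backend)
      scores[pi, ] <- per_residue_from_fragments(L, w, fs)
    }
  }
  combined <- colMeans(scores, na.rm = TRUE)
  combined[!is.finite(combined)] <- NA_real_
  structure(list(sequence = seq, probes = probes, scores = scores,
                 combined = combined, short_probes = short_probes,
                 backend = backend$name),
            class = "residue_profile")
}

#' @export
print.residue_profile <- function(x, ...) {
  cat("<residue_profile> L =", length(x$combined), "probes =",
      paste(x$probes, collapse = "/"), "\n")
  def <- x$combined[!is.na(x$combined)]
  if (length(def) > 0L) {
    cat(sprintf("  combined score: min %.3f, median %.3f, max %.3f\n",
                min(def), stats::median(def), max(def)))
  }
  invisible(x)
}

#' @export
as.data.frame.residue_profile <- function(x, ...) {
  out <- data.frame(residue = seq_along(x$combined),
                    aa = seq_chars(x$sequence))
  for (w in rownames(x$scores)) out[[paste0("probe_", w)]] <- x$scores[w, ]
  out$combined <- x$combined
  out
}

#' Plot a per-residue profile
#'
#' @param x A `residue_profile`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.residue_profile <- function(x, ...) {
  graphics::plot(seq_along(x$combined), x$combined, type = "l",
                 ylim = c(0, 1), xlab = "residue", ylab = "combined score",
                 ...)
  graphics::matlines(t(x$scores), lty = 3L,
                     col = grDevices::grey(0.6))
  invisible(x)
}

#' Fraction of residues above a score threshold
#'
#' Strict inequality: a residue counts as high-propensity when its combined
#' score is `> threshold`. Undefined residues are excluded from the
#' denominator.
#'
#' @param profile A `residue_profile`.
#' @param threshold Score threshold (default 0.5); vectorized.
#' @return Numeric fraction(s) in `[0, 1]`, named by threshold when several
#'   are given.
#' @export
high_fraction <- function(profile, threshold = 0.5) {
  sc <- profile$combined[!is.na(profile$combined)]
  if (length(sc) == 0L) stop("profile has no defined residues")
  out <- vapply(threshold, function(t) mean(sc > t), numeric(1))
  if (length(threshold) > 1L) names(out) <- as.character(threshold)
  out
}

#' Write per-residue profiles as a long-format TSV
#'
#' One row per (sequence, residue) with per-probe columns and the combined
#' score, suitable for track-style viewers.
#'
#' @param profiles Named list of `residue_profile` objects.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_profiles_tsv <- function(profiles, path) {
  stopifnot(length(profiles) > 0L)
  ids <- names(profiles) %||% as.character(seq_along(profiles))
  tabs <- lapply(seq_along(profiles), function(i) {
    d <- as.data.frame(profiles[[i]])
    cbind(data.frame(id = ids[i]), d)
  })
  utils::write.table(do.call(rbind, tabs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
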