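# Shared helpers for building fixtures in code.

rand_seq <- function(L) paste(sample(AA_ALPHABET, L, TRUE), collapse = "")

# Wrap a backend so that raw embed calls are counted (for cache contracts).
counting_backend <- function(backend) {
  calls <- new.env(parent = emptyenv())
  calls$n <- 0L
  wrapped <- embedder_backend(
    backend$name, backend$dim,
    embed = function(seq) {
      calls$n <- calls$n + 1L
      backend$embed(seq)
    },
    pool_windows = backend$pool_windows)
  list(backend = wrapped, calls = calls)
}

# Classifier that predicts a constant probability regardless of input.
const_classifier <- function(p, dim) {
  structure(list(weights = rep(0, dim), intercept = stats::qlogis(p),
                 selected_features = seq_len(dim),
                 scaler = structure(list(mean = rep(0, dim),
                                         sd = rep(1, dim),
                                         keep = seq_len(dim),
                                         dropped = integer(0),
                                         dim_in = dim),
                                    class = "scaler_params"),
                 penalty = "l2", C = 1, iterations = 0L, meta = list()),
            class = "phase_classifier")
}

# Hand-made residue_profile with a given combined score vector.
manual_profile <- function(combined, seq = NULL) {
  L <- length(combined)
  if (is.null(seq)) seq <- strrep("A", L)
  structure(list(sequence = seq, probes = 1L,
                 scores = matrix(combined, nrow = 1L,
                                 dimnames = list("1", NULL)),
                 combined = combined, short_probes = integer(0),
                 backend = "manual"),
            class = "residue_profile")
}

# Independent covering-set oracle for per-residue scores: O(L * w) loop.
per_residue_oracle <- function(L, w, frag_scores) {
  out <- numeric(L)
  for (i in seq_len(L)) {
    starts <- max(1L, i - w + 1L):min(i, L - w + 1L)
    v <- frag_scores[starts]
    v <- v[!is.na(v)]
    out[i] <- if (length(v) == 0L) NA_real_ else mean(v)
  }
  out
}

# O(n^2) pairwise ROC-AUC oracle with half credit for ties.
roc_auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}
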