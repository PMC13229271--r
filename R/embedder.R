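# Pluggable sequence embedders: a backend contract, mean pooling, two
# deterministic toy backends, and an on-disk embedding cache.
#
# A backend is any object that maps a sequence to a per-residue numeric
# matrix (rows = residues, columns = embedding dimensions) and declares its
# dimension. Real protein-language-model backends plug in through the same
# contract; the test suite only ever needs the toy backends.

#' Construct an embedder backend
#'
#' @param name Backend identifier (used for cache keys and provenance).
#' @param dim Embedding dimension D declared by the backend.
#' @param embed Function `seq -> matrix` returning an L x D per-residue
#'   matrix for a canonical sequence of length L.
#' @param pool_windows Optional fast path: function `(seq, w) -> matrix`
#'   returning the (L - w + 1) x D matrix of mean-pooled embeddings of all
#'   stride-1 windows of length `w`, exactly equal to embedding each window
#'   and mean-pooling it. When absent, a generic per-fragment fallback is
#'   used.
#' @param context_free Logical; `TRUE` when a residue's row is independent
#'   of sequence context outside its k-mer, so batching cannot change
#'   results.
#' @return An object of class `embedder_backend`.
#' @export
embedder_backend <- function(name, dim, embed, pool_windows = NULL,
                             context_free = TRUE) {
  stopifnot(is_string(name), is.function(embed), dim >= 1)
  structure(list(name = name, dim = as.integer(dim), embed = embed,
                 pool_windows = pool_windows, context_free = context_free),
            class = "embedder_backend")
}

#' @export
print.embedder_backend <- function(x, ...) {
  cat("<embedder_backend>", x$name, " D =", x$dim, "\n")
  invisible(x)
}

#' Mean-pool a per-residue embedding matrix
#'
#' Column means over residue rows only; special tokens of real backends must
#' be removed upstream.
#'
#' @param matrix Numeric L x D matrix with L >= 1.
#' @return Numeric vector of length D.
#' @export
mean_pool <- function(matrix) {
  if (!is.matrix(matrix) || nrow(matrix) < 1L) {
    stop("mean_pool needs a matrix with at least one residue row")
  }
  colMeans(matrix)
}

# One-hot matrix (L x 20) for a canonical sequence; errors on other letters.
one_hot_matrix <- function(seq) {
  codes <- seq_codes(seq)
  if (length(codes) == 0L) stop("empty sequence")
  if (anyNA(codes)) {
    stop("non-canonical residue at position ", which(is.na(codes))[1L])
  }
  M <- matrix(0, nrow = length(codes), ncol = 20L,
              dimnames = list(NULL, AA_ALPHABET))
  M[cbind(seq_along(codes), codes)] <- 1
  M
}

#' Composition toy backend
#'
#' Row i is the 20-dimensional one-hot encoding of residue i, so the pooled
#' embedding of any sequence is its amino-acid frequency vector and is
#' exactly invariant to residue permutation. This backend is the package's
#' falsifiable control for claims about sequence patterning: any score
#' computed through it can only depend on composition.
#'
#' @return An `embedder_backend` with D = 20.
#' @export
composition_backend <- function() {
  pool_win <- function(seq, w) {
    M <- one_hot_matrix(seq)
    L <- nrow(M)
    stopifnot(w >= 1L, L >= w)
    cs <- rbind(0, apply(M, 2L, cumsum))
    # Window sums are integer counts, so the fast path is bit-identical to
    # pooling each fragment separately.
    (cs[(w + 1L):(L + 1L), , drop = FALSE] -
       cs[1L:(L - w + 1L), , drop = FALSE]) / w
  }
  embedder_backend("composition", 20L, embed = one_hot_matrix,
                   pool_windows = pool_win)
}

#' Patterned toy backend (order-sensitive random k-mer features)
#'
#' Row i is a fixed, seeded random-feature encoding of the k-mer starting at
#' residue i (cyclic padding at the sequence end). Each feature dimension
#' applies a fixed random projection to the concatenated one-hot encodings
#' of the k residues and squashes the result with `tanh`; the projection
#' weights are structured so that every dimension reads a random mixture of
#' a physicochemical letter scale (Kyte-Doolittle hydropathy) and an
#' idiosyncratic random letter scale, with independent coefficients per
#' k-mer offset. This emulates how pooled protein-language-model embeddings
#' behave: individual axes respond to local biophysical patterning (e.g.
#' hydrophobic/polar contrast between neighbours), and the saturating
#' nonlinearity makes the pooled vector depend on residue order for
#' k >= 2. For k = 1 each row is an elementwise map of the residue identity,
#' so the pooled embedding is a function of composition alone and is
#' permutation-invariant.
#'
#' @param k K-mer length (>= 1, default 2).
#' @param dim Number of random features (default 128).
#' @param seed Seed for the fixed projection.
#' @param scale Gain inside `tanh`; larger values saturate harder and
#'   strengthen order (interaction) sensitivity.
#' @param property_weight Fraction (in `[0, 1]`) of each dimension's letter
#'   scale drawn from the hydropathy axis rather than an idiosyncratic
#'   random axis (default 0.7).
#' @return An `embedder_backend`.
#' @export
patterned_backend <- function(k = 2L, dim = 128L, seed = 0L, scale = 1.2,
                              property_weight = 0.7) {
  stopifnot(k >= 1L, dim >= 1L, property_weight >= 0, property_weight <= 1)
  k <- as.integer(k); dim <- as.integer(dim)
  kdn <- unname(KD_HYDROPATHY[AA_ALPHABET])
  kdn <- kdn / stats::sd(kdn)
  par <- with_seed(seed, {
    g <- stats::rnorm(dim)
    U <- sqrt(property_weight) * outer(kdn, g) +
      sqrt(1 - property_weight) * matrix(stats::rnorm(20L * dim), nrow = 20L)
    list(U = U, A = matrix(stats::rnorm(k * dim), nrow = k),
         b = stats::rnorm(dim, sd = 0.5))
  })
  embed <- function(seq) {
    codes <- seq_codes(seq)
    if (length(codes) == 0L) stop("empty sequence")
    if (anyNA(codes)) {
      stop("non-canonical residue at position ", which(is.na(codes))[1L])
    }
    L <- length(codes)
    acc <- matrix(rep(par$b, each = L), nrow = L)
    for (j in seq_len(k)) {
      rows <- codes[((seq_len(L) + j - 2L) %% L) + 1L]
      acc <- acc + par$U[rows, , drop = FALSE] *
        matrix(rep(par$A[j, ], each = L), nrow = L)
    }
    tanh(scale * acc)
  }
  pool_win <- NULL
  if (k == 2L) {
    # A window's rows equal the full-sequence "linear" rows except for the
    # final row, whose cyclic successor wraps to the window start. Window
    # sums therefore come from one cumulative sum over linear rows plus a
    # vectorized wrap row (equal to per-fragment pooling up to float
    # round-off of the summation order).
    pool_win <- function(seq, w) {
      codes <- seq_codes(seq)
      if (anyNA(codes)) {
        stop("non-canonical residue at position ", which(is.na(codes))[1L])
      }
      L <- length(codes)
      stopifnot(w >= 1L, L >= w)
      n_win <- L - w + 1L
      bmat <- function(n) matrix(rep(par$b, each = n), nrow = n)
      a1 <- matrix(rep(par$A[1L, ], each = n_win), nrow = n_win)
      a2 <- matrix(rep(par$A[2L, ], each = n_win), nrow = n_win)
      wrap <- tanh(scale * (bmat(n_win) +
                              par$U[codes[w:L], , drop = FALSE] * a1 +
                              par$U[codes[1L:n_win], , drop = FALSE] * a2))
      if (w == 1L) return(wrap)
      l1 <- matrix(rep(par$A[1L, ], each = L - 1L), nrow = L - 1L)
      l2 <- matrix(rep(par$A[2L, ], each = L - 1L), nrow = L - 1L)
      lin <- tanh(scale * (bmat(L - 1L) +
                             par$U[codes[1L:(L - 1L)], , drop = FALSE] * l1 +
                             par$U[codes[2L:L], , drop = FALSE] * l2))
      cs <- rbind(0, apply(lin, 2L, cumsum))
      sums <- cs[(w - 1L) + seq_len(n_win), , drop = FALSE] -
        cs[seq_len(n_win), , drop = FALSE]
      (sums + wrap) / w
    }
  }
  embedder_backend(sprintf("patterned_k%d_d%d_s%d", k, dim, seed),
                   dim, embed = embed, pool_windows = pool_win)
}

#' Mean-pooled embeddings of all stride-1 windows of a sequence
#'
#' Uses the backend's fast path when it declares one, otherwise embeds each
#' fragment separately. Both routes give identical results by the backend
#' contract.
#'
#' @param backend An `embedder_backend`.
#' @param seq Canonical sequence of length L >= w.
#' @param w Window length.
#' @return (L - w + 1) x D matrix of pooled window embeddings.
#' @export
pool_windows <- function(backend, seq, w) {
  L <- nchar(seq)
  stopifnot(w >= 1L, L >= w)
  if (!is.null(backend$pool_windows)) return(backend$pool_windows(seq, w))
  starts <- 1L:(L - w + 1L)
  frags <- substring(seq, starts, starts + w - 1L)
  t(vapply(frags, function(f) mean_pool(backend$embed(f)),
           numeric(backend$dim), USE.NAMES = FALSE))
}

#' Create an in-memory embedding cache
#'
#' Pooled embeddings are keyed by `(backend name, sequence)`; the cache can
#' be persisted with [save_embedding_cache()] and reloaded with
#' [load_embedding_cache()].
#'
#' @param backend The backend the cache belongs to.
#' @return An object of class `embedding_cache`.
#' @export
embedding_cache <- function(backend) {
  structure(list(env = new.env(parent = emptyenv()),
                 backend = backend$name, dim = backend$dim),
            class = "embedding_cache")
}

#' @export
print.embedding_cache <- function(x, ...) {
  cat("<embedding_cache>", x$backend, "D =", x$dim, "entries =",
      length(ls(x$env)), "\n")
  invisible(x)
}

#' Persist an embedding cache as a delimited store plus a JSON manifest
#'
#' @param cache An `embedding_cache`.
#' @param dir Directory to write `embeddings.tsv` and `manifest.json` into.
#' @return `dir`, invisibly.
#' @export
save_embedding_cache <- function(cache, dir) {
  stopifnot(inherits(cache, "embedding_cache"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  keys <- sort(ls(cache$env))
  mat <- do.call(rbind, lapply(keys, function(k) cache$env[[k]]))
  tab <- data.frame(sequence = keys, stringsAsFactors = FALSE)
  if (length(keys) > 0L) tab <- cbind(tab, as.data.frame(mat))
  utils::write.table(tab, file.path(dir, "embeddings.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(backend = cache$backend, dim = cache$dim,
                            n_entries = length(keys)),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Load a persisted embedding cache
#'
#' @param dir Directory written by [save_embedding_cache()].
#' @return An `embedding_cache`.
#' @export
load_embedding_cache <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  cache <- structure(list(env = new.env(parent = emptyenv()),
                          backend = man$backend, dim = as.integer(man$dim)),
                     class = "embedding_cache")
  tab <- utils::read.table(file.path(dir, "embeddings.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  if (nrow(tab) > 0L) {
    for (i in seq_len(nrow(tab))) {
      cache$env[[tab$sequence[i]]] <- as.numeric(tab[i, -1L])
    }
  }
  cache
}

#' Embed sequences into mean-pooled feature vectors
#'
#' Sequences are processed in batches (batching cannot change the result for
#' context-free backends) and cached by sequence so repeated sequences cost
#' one backend call.
#'
#' @param seqs Character vector of canonical sequences; names, when present,
#'   become row names of the result.
#' @param backend An `embedder_backend`.
#' @param batch_size Number of sequences per batch (default 32).
#' @param cache Optional `embedding_cache` created for the same backend;
#'   warm entries skip the backend entirely.
#' @return n x D numeric matrix of pooled embeddings with attributes
#'   `backend` and `dim`.
#' @export
embed_sequences <- function(seqs, backend, batch_size = 32L, cache = NULL) {
  stopifnot(inherits(backend, "embedder_backend"), batch_size >= 1L)
  if (!is.null(cache)) {
    stopifnot(inherits(cache, "embedding_cache"))
    if (cache$backend != backend$name) {
      stop("cache belongs to backend '", cache$backend, "', not '",
           backend$name, "'")
    }
  }
  n <- length(seqs)
  out <- matrix(NA_real_, nrow = n, ncol = backend$dim)
  batches <- split(seq_len(n), ceiling(seq_len(n) / batch_size))
  for (idx in batches) {
    for (i in idx) {
      s <- seqs[[i]]
      hit <- if (!is.null(cache)) cache$env[[s]] else NULL
      if (is.null(hit)) {
        hit <- tryCatch(mean_pool(backend$embed(s)), error = function(e) {
          stop("embedding failed for sequence '",
               names(seqs)[i] %||% paste0("#", i), "': ",
               conditionMessage(e), call. = FALSE)
        })
        if (!all(is.finite(hit))) {
          stop("non-finite embedding for sequence #", i)
        }
        if (!is.null(cache)) cache$env[[s]] <- hit
      }
      out[i, ] <- hit
    }
  }
  rownames(out) <- names(seqs)
  attr(out, "backend") <- backend$name
  attr(out, "embedding_dim") <- backend$dim
  out
}
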