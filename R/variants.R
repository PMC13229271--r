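# Single-substitution variant analysis: local score shifts around a variant
# site, Fisher tail enrichment of |delta| values, and bootstrap odds-ratio
# intervals.

#' Apply a single-residue substitution
#'
#' @param seq Wild-type sequence.
#' @param position 1-based position within `seq`.
#' @param ref_aa Expected wild-type residue at `position` (checked).
#' @param alt_aa Substituted residue.
#' @return The mutant sequence (same length).
#' @export
apply_variant <- function(seq, position, ref_aa, alt_aa) {
  stopifnot(is_string(seq), position >= 1L, position <= nchar(seq))
  found <- substring(seq, position, position)
  if (found != ref_aa) {
    stop("reference mismatch at position ", position, ": expected '",
         ref_aa, "', found '", found, "'")
  }
  if (alt_aa == ref_aa) {
    warning("alt equals ref at position ", position, "; sequence unchanged")
    return(seq)
  }
  paste0(substring(seq, 1L, position - 1L), alt_aa,
         substring(seq, position + 1L, nchar(seq)))
}

#' Local score shift induced by a variant
#'
#' Difference in mean combined per-residue score over the window of
#' `halfwidth` residues either side of the variant position (clipped at the
#' IDR boundaries), mutant minus wild type.
#'
#' @param wt_profile,mut_profile `residue_profile` objects computed on the
#'   wild-type and mutant sequence with the same probes and backend.
#' @param position 1-based variant position within the IDR.
#' @param halfwidth Window half-width in residues (default 14).
#' @return Signed delta score.
#' @export
delta_aggregation <- function(wt_profile, mut_profile, position,
                              halfwidth = 14L) {
  L <- length(wt_profile$combined)
  stopifnot(length(mut_profile$combined) == L, position >= 1L, position <= L)
  win <- max(1L, position - halfwidth):min(L, position + halfwidth)
  wt <- wt_profile$combined[win]
  mt <- mut_profile$combined[win]
  ok <- !is.na(wt) & !is.na(mt)
  if (!any(ok)) stop("empty window: no defined residues around position ",
                     position)
  mean(mt[ok]) - mean(wt[ok])
}

#' Score shift for one SNP from sequence
#'
#' Convenience wrapper: profiles the wild-type and mutant IDR with the same
#' models/backend/probes and returns the local delta.
#'
#' @param seq Wild-type IDR sequence.
#' @param position 1-based variant position within the IDR.
#' @param ref_aa,alt_aa Reference and substituted residues.
#' @param models,backend,probes Passed to [profile_sequence()].
#' @param halfwidth Window half-width (default 14).
#' @return Signed delta score.
#' @export
snp_delta <- function(seq, position, ref_aa, alt_aa, models, backend,
                      probes = c(6L, 10L, 15L), halfwidth = 14L) {
  mut <- apply_variant(seq, position, ref_aa, alt_aa)
  wt_p <- profile_sequence(seq, models, backend, probes)
  mut_p <- profile_sequence(mut, models, backend, probes)
  delta_aggregation(wt_p, mut_p, position, halfwidth)
}

#' Fisher's exact test on a 2x2 table, with the sample odds ratio
#'
#' Two-sided conditional p-value (sum of hypergeometric probabilities of
#' tables at most as probable as the observed one, via
#' [stats::fisher.test()]) together with the sample odds ratio
#' `(a d) / (b c)`; the Haldane-Anscombe +0.5 correction is applied to the
#' odds ratio (never to the exact p) when any cell is zero. A zero margin
#' gives `p = 1` and an undefined-OR flag.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return List with `odds_ratio`, `p_value`, `or_defined`.
#' @export
fisher_exact <- function(table) {
  tab <- as.matrix(table)
  stopifnot(all(dim(tab) == c(2L, 2L)), all(tab >= 0), all(tab == round(tab)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(odds_ratio = NA_real_, p_value = 1, or_defined = FALSE))
  }
  p <- stats::fisher.test(tab)$p.value
  if (any(tab == 0)) {
    or <- (tab[1, 1] + 0.5) * (tab[2, 2] + 0.5) /
      ((tab[1, 2] + 0.5) * (tab[2, 1] + 0.5))
  } else {
    or <- tab[1, 1] * tab[2, 2] / (tab[1, 2] * tab[2, 1])
  }
  list(odds_ratio = or, p_value = min(1, p), or_defined = TRUE)
}

# Sample odds ratio with Haldane correction for one bootstrap table.
sample_or <- function(a, b, c_, d) {
  z <- a == 0 | b == 0 | c_ == 0 | d == 0
  out <- a * d / (b * c_)
  out[z] <- ((a[z] + 0.5) * (d[z] + 0.5)) / ((b[z] + 0.5) * (c_[z] + 0.5))
  out
}

#' Tail enrichment of variant score shifts by clinical class
#'
#' For each threshold t, variants are classified by `|delta| > t` and the
#' resulting 2x2 table (pathogenic/benign x above/below) is tested with
#' Fisher's exact test; the sample odds ratio gets a seeded stratified
#' bootstrap percentile confidence interval (variants resampled within
#' class).
#'
#' @param deltas_pathogenic,deltas_benign Signed delta scores per class
#'   (nonempty).
#' @param thresholds Thresholds on `|delta|`; default the 75th/90th/95th
#'   percentiles of the pooled `|delta|` distribution.
#' @param n_boot Bootstrap replicates (default 2000).
#' @param conf_level Confidence level (default 0.95).
#' @param seed Seed for the bootstrap.
#' @return Data frame of class `tail_enrichment`, one row per threshold:
#'   cell counts, `odds_ratio`, `p_value`, `ci_lo`, `ci_hi`, `degenerate`.
#' @export
tail_enrichment <- function(deltas_pathogenic, deltas_benign,
                            thresholds = NULL, n_boot = 2000L,
                            conf_level = 0.95, seed = 1L) {
  dp <- abs(as.numeric(deltas_pathogenic))
  db <- abs(as.numeric(deltas_benign))
  stopifnot(length(dp) >= 1L, length(db) >= 1L, n_boot >= 1L)
  if (is.null(thresholds)) {
    thresholds <- unname(stats::quantile(c(dp, db), c(0.75, 0.90, 0.95)))
  }
  th_seeds <- spawn_seeds(seed, length(thresholds))
  alpha <- (1 - conf_level) / 2
  rows <- lapply(seq_along(thresholds), function(i) {
    t <- thresholds[i]
    a <- sum(dp > t); b <- length(dp) - a
    c_ <- sum(db > t); d <- length(db) - c_
    fe <- fisher_exact(matrix(c(a, b, c_, d), nrow = 2L, byrow = TRUE))
    or_boot <- with_seed(th_seeds[i], {
      bp <- matrix(sample(dp, length(dp) * n_boot, replace = TRUE),
                   ncol = n_boot)
      bb <- matrix(sample(db, length(db) * n_boot, replace = TRUE),
                   ncol = n_boot)
      ab <- colSums(bp > t)
      cb <- colSums(bb > t)
      sample_or(ab, length(dp) - ab, cb, length(db) - cb)
    })
    ci <- stats::quantile(or_boot, c(alpha, 1 - alpha), names = FALSE)
    data.frame(threshold = t, n_path_above = a, n_path_below = b,
               n_benign_above = c_, n_benign_below = d,
               odds_ratio = if (a + c_ == 0) NA_real_ else
                 sample_or(a, b, c_, d),
               p_value = fe$p_value, ci_lo = ci[1], ci_hi = ci[2],
               degenerate = (a + c_ == 0L) || (b + d == 0L))
  })
  out <- do.call(rbind, rows)
  attr(out, "n_boot") <- n_boot
  attr(out, "conf_level") <- conf_level
  attr(out, "seed") <- seed
  class(out) <- c("tail_enrichment", "data.frame")
  out
}
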