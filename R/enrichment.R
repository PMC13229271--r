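# Category-level annotation statistics over per-residue profiles:
# high-score fractions, Brunner-Munzel rank tests with BH FDR control, and
# the composition-averaged baseline separating composition from patterning.

# Per-IDR high-score bookkeeping at one threshold.
per_idr_high_stats <- function(profiles, threshold = 0.5) {
  ids <- names(profiles) %||% as.character(seq_along(profiles))
  n_def <- vapply(profiles, function(p) sum(!is.na(p$combined)), integer(1))
  n_high <- vapply(profiles, function(p)
    sum(p$combined > threshold, na.rm = TRUE), integer(1))
  data.frame(id = ids, n_defined = n_def, n_high = n_high,
             fraction = ifelse(n_def > 0L, n_high / n_def, NA_real_),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Residue-weighted high-score fraction of a set of profiles
#'
#' Count of residues with combined score strictly above `threshold` across
#' all profiles, divided by the total number of defined residues — i.e. the
#' length-weighted mean of the per-IDR fractions.
#'
#' @param profiles List of `residue_profile` objects (nonempty).
#' @param threshold Score threshold (default 0.5).
#' @return Fraction in `[0, 1]`.
#' @export
residue_weighted_fraction <- function(profiles, threshold = 0.5) {
  stopifnot(length(profiles) > 0L)
  st <- per_idr_high_stats(profiles, threshold)
  if (sum(st$n_defined) == 0L) stop("no defined residues in category")
  sum(st$n_high) / sum(st$n_defined)
}

#' Brunner-Munzel two-sample rank test
#'
#' Heteroscedastic rank test of the stochastic-dominance functional
#' `P(X < Y) + 0.5 P(X = Y)` with the Welch-type t degrees-of-freedom
#' approximation; two-sided by default. When the midrank variances are both
#' degenerate the test reports `p = 1` with a warning if the groups are
#' centred identically, and `p = 0` otherwise (complete separation).
#'
#' @param x,y Numeric samples (each of size >= 2).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return List with `statistic`, `df`, `p_value` and `estimate` (the
#'   dominance probability that Y exceeds X).
#' @export
brunner_munzel <- function(x, y, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 2L, n2 >= 2L, !anyNA(x), !anyNA(y))
  N <- n1 + n2
  r <- rank(c(x, y))
  r1 <- r[seq_len(n1)]; r2 <- r[n1 + seq_len(n2)]
  m1 <- mean(r1); m2 <- mean(r2)
  p_hat <- (m2 - (n2 + 1) / 2) / n1
  v1 <- sum((r1 - rank(x) - m1 + (n1 + 1) / 2)^2) / (n1 - 1)
  v2 <- sum((r2 - rank(y) - m2 + (n2 + 1) / 2)^2) / (n2 - 1)
  vsum <- n1 * v1 + n2 * v2
  if (vsum <= 0) {
    if (isTRUE(all.equal(m1, m2))) {
      warning("degenerate midrank variance; reporting p = 1")
      return(list(statistic = 0, df = NA_real_, p_value = 1,
                  estimate = p_hat))
    }
    warning("degenerate midrank variance with separated groups")
    return(list(statistic = sign(m2 - m1) * Inf, df = NA_real_,
                p_value = 0, estimate = p_hat))
  }
  stat <- n1 * n2 * (m2 - m1) / (N * sqrt(vsum))
  df <- vsum^2 / ((n1 * v1)^2 / (n1 - 1) + (n2 * v2)^2 / (n2 - 1))
  p <- switch(alternative,
              two.sided = 2 * stats::pt(-abs(stat), df),
              greater = stats::pt(stat, df, lower.tail = FALSE),
              less = stats::pt(stat, df))
  list(statistic = stat, df = df, p_value = min(1, p), estimate = p_hat)
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param p_values Numeric p-values in `[0, 1]`.
#' @return q-values of the same length.
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Category enrichment of high-propensity residues
#'
#' For every category (e.g. GO term) with at least `min_category_size`
#' member profiles, the distribution of per-IDR high-score fractions inside
#' the category is compared with all remaining profiles using the
#' Brunner-Munzel test; p-values are BH-corrected across the categories
#' tested at each threshold (callers should correct ontology branches
#' separately by calling once per branch). Categories are not made mutually
#' exclusive: a profile may belong to many terms, and members of one term
#' stay in the complement of every other.
#'
#' @param profiles Named list of `residue_profile` objects; names are
#'   profile ids.
#' @param term_map Data frame with columns `term` and `id` mapping
#'   categories to profile ids.
#' @param thresholds Numeric vector of score thresholds (default 0.5); one
#'   result row per (term, threshold).
#' @param min_category_size Minimum member count for a term to be tested
#'   (default 20).
#' @return Data frame with one row per (term, threshold): member counts,
#'   residue-weighted fraction, mean per-IDR fraction, Brunner-Munzel
#'   statistic, `p_value` and `q_value`.
#' @export
category_enrichment <- function(profiles, term_map, thresholds = 0.5,
                                min_category_size = 20L) {
  ids <- names(profiles)
  if (is.null(ids)) stop("profiles must be a named list")
  stopifnot(all(c("term", "id") %in% names(term_map)))
  term_map <- term_map[term_map$id %in% ids, , drop = FALSE]
  members <- split(term_map$id, term_map$term)
  members <- members[vapply(members, function(m)
    length(unique(m)) >= min_category_size, logical(1))]
  if (length(members) == 0L) stop("no category reaches min_category_size")
  out <- list()
  for (th in thresholds) {
    st <- per_idr_high_stats(profiles, th)
    fr <- stats::setNames(st$fraction, st$id)
    nh <- stats::setNames(st$n_high, st$id)
    nd <- stats::setNames(st$n_defined, st$id)
    rows <- lapply(names(members), function(tm) {
      inside <- unique(members[[tm]])
      outside <- setdiff(ids, inside)
      if (length(outside) == 0L) {
        stop("category '", tm, "' contains every profile (empty complement)")
      }
      bm <- brunner_munzel(fr[outside], fr[inside])
      data.frame(term = tm, threshold = th,
                 n_idrs = length(inside),
                 n_residues = sum(nd[inside]),
                 rw_fraction = sum(nh[inside]) / sum(nd[inside]),
                 mean_fraction = mean(fr[inside]),
                 bm_statistic = bm$statistic,
                 p_value = bm$p_value,
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    tab$q_value <- bh_fdr(tab$p_value)
    out[[as.character(th)]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Composition-averaged score
#'
#' Dot product of a category's amino-acid frequency vector with the
#' proteome-wide per-amino-acid mean scores: the score the category would
#' get if composition alone mattered.
#'
#' @param aa_frequencies Numeric 20-vector over [AA_ALPHABET] summing to 1
#'   (tolerance 1e-6).
#' @param per_aa_mean_scores Numeric 20-vector of mean residue scores per
#'   amino acid.
#' @return Scalar composition-averaged score.
#' @export
composition_average_score <- function(aa_frequencies, per_aa_mean_scores) {
  stopifnot(length(aa_frequencies) == 20L, length(per_aa_mean_scores) == 20L)
  if (abs(sum(aa_frequencies) - 1) > 1e-6) {
    stop("amino-acid frequencies must sum to 1")
  }
  sum(aa_frequencies * per_aa_mean_scores)
}

#' Squared Pearson correlation
#'
#' @param x,y Paired numeric vectors of length >= 3.
#' @return R^2 in `[0, 1]`.
#' @export
r_squared <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in one of the vectors")
  }
  stats::cor(x, y)^2
}

#' Per-amino-acid score distribution summary
#'
#' Pools combined residue scores across profiles, partitions them by
#' amino-acid identity and summarizes each distribution (median and the
#' letter-value quantiles used in boxen-style plots).
#'
#' @param profiles List of `residue_profile` objects.
#' @return Data frame with one row per amino acid: `n`, `mean`, `median`,
#'   `q25`, `q75`, `q87.5`, `q93.75`.
#' @export
aa_score_summary <- function(profiles) {
  aa <- unlist(lapply(profiles, function(p) seq_chars(p$sequence)))
  sc <- unlist(lapply(profiles, function(p) p$combined))
  ok <- !is.na(sc) & aa %in% AA_ALPHABET
  aa <- aa[ok]; sc <- sc[ok]
  rows <- lapply(AA_ALPHABET, function(a) {
    s <- sc[aa == a]
    if (length(s) == 0L) {
      return(data.frame(aa = a, n = 0L, mean = NA_real_, median = NA_real_,
                        q25 = NA_real_, q75 = NA_real_, q87.5 = NA_real_,
                        q93.75 = NA_real_))
    }
    q <- stats::quantile(s, c(0.25, 0.5, 0.75, 0.875, 0.9375), names = FALSE)
    data.frame(aa = a, n = length(s), mean = mean(s), median = q[2],
               q25 = q[1], q75 = q[3], q87.5 = q[4], q93.75 = q[5])
  })
  do.call(rbind, rows)
}

#' Composition baseline versus observed category fractions
#'
#' Computes, per category, the observed residue-weighted high-score fraction
#' and the composition-averaged score (category amino-acid frequencies times
#' the proteome-wide per-amino-acid mean scores), and the R^2 between them.
#' A low R^2 indicates that the scorer responds to sequence patterning that
#' composition cannot explain.
#'
#' @param profiles Named list of `residue_profile` objects.
#' @param term_map Data frame with columns `term` and `id`.
#' @param threshold Score threshold for the observed fraction (default 0.5).
#' @param min_category_size Minimum members per term (default 5).
#' @return Data frame (`term`, `n_idrs`, `observed_fraction`,
#'   `composition_average`) with attribute `r_squared`.
#' @export
composition_baseline <- function(profiles, term_map, threshold = 0.5,
                                 min_category_size = 5L) {
  ids <- names(profiles)
  summ <- aa_score_summary(profiles)
  per_aa <- stats::setNames(summ$mean, summ$aa)
  per_aa[is.na(per_aa)] <- mean(per_aa, na.rm = TRUE)
  members <- split(term_map$id, term_map$term)
  members <- members[vapply(members, function(m)
    length(unique(intersect(m, ids))) >= min_category_size, logical(1))]
  rows <- lapply(names(members), function(tm) {
    sub <- profiles[unique(intersect(members[[tm]], ids))]
    aa <- unlist(lapply(sub, function(p) seq_chars(p$sequence)))
    aa <- aa[aa %in% AA_ALPHABET]
    freq <- tabulate(match(aa, AA_ALPHABET), 20L)
    freq <- freq / sum(freq)
    data.frame(term = tm, n_idrs = length(sub),
               observed_fraction = residue_weighted_fraction(sub, threshold),
               composition_average = composition_average_score(freq, per_aa))
  })
  out <- do.call(rbind, rows)
  if (nrow(out) >= 3L) {
    attr(out, "r_squared") <- r_squared(out$composition_average,
                                        out$observed_fraction)
  }
  out
}
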