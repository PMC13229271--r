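# Seeded synthetic-data generators. These emulate the statistical structure
# the analyses assume — short fixed-length labelled peptides with an
# order-sensitive signal, a disordered "proteome" of variable-length IDRs
# with annotation terms and a rare driver class, and paired benign /
# pathogenic single substitutions — so that every module is testable without
# external downloads. Each generator is a pure function of its arguments and
# seed.

#' Disorder-like background residue frequencies
#'
#' A fixed composition with the hallmarks of disordered regions (elevated
#' P, S, G, Q/E, depleted aromatics and aliphatics), used as the default
#' background of all generators. Normalized to sum to 1 over
#' [AA_ALPHABET].
#'
#' @return Named numeric 20-vector.
#' @export
idr_background_freqs <- function() {
  f <- c(A = 0.063, C = 0.010, D = 0.052, E = 0.075, F = 0.018,
         G = 0.077, H = 0.021, I = 0.028, K = 0.058, L = 0.055,
         M = 0.018, N = 0.040, P = 0.089, Q = 0.060, R = 0.052,
         S = 0.100, T = 0.052, V = 0.040, W = 0.005, Y = 0.020)
  f[AA_ALPHABET] / sum(f)
}

# Random background sequences as an n x L integer code matrix.
random_code_matrix <- function(n, L, background) {
  matrix(sample.int(20L, n * L, replace = TRUE, prob = background),
         nrow = n)
}

codes_to_strings <- function(codes) {
  apply(codes, 1L, function(cd) paste(AA_ALPHABET[cd], collapse = ""))
}

# Order-sensitive patterning statistic: mean Kyte-Doolittle contrast over
# cyclically adjacent residue pairs, scaled to [0, 1]. Depends on residue
# arrangement, not only on composition.
hydropathy_contrast <- function(codes) {
  kd <- unname(KD_HYDROPATHY[AA_ALPHABET])
  v <- matrix(kd[codes], nrow = nrow(codes))
  nxt <- cbind(v[, -1L, drop = FALSE], v[, 1L, drop = FALSE])
  rowMeans(abs(v - nxt)) / 9
}

# Composition statistic: mean hydropathy scaled to roughly [-1, 1].
mean_hydropathy <- function(codes) {
  kd <- unname(KD_HYDROPATHY[AA_ALPHABET])
  rowMeans(matrix(kd[codes], nrow = nrow(codes))) / 4.5
}

#' Generate a labelled synthetic peptide dataset
#'
#' Sequences are drawn from a disorder-like background composition. A
#' ground-truth propensity statistic is computed per peptide — an
#' order-sensitive hydrophobic/polar contrast for `signal = "patterned"`, a
#' purely compositional mean hydropathy for `signal = "composition"`, or a
#' constant for `signal = "null"` — and labels are drawn through a logistic
#' link with slope `effect_size` on the centred statistic, offset to the
#' requested class balance.
#'
#' @param n Number of peptides.
#' @param length Peptide length (>= 2; default 6, the hexapeptide setting).
#' @param signal `"patterned"` (default), `"composition"` or `"null"`.
#' @param effect_size Logistic slope on the standardized ground-truth
#'   statistic (default 25; large values make labels nearly deterministic in
#'   the planted statistic).
#' @param class_balance Target positive fraction in `(0, 1)`.
#' @param seed Seed; the dataset is a pure function of the arguments.
#' @param background Background residue frequencies over [AA_ALPHABET].
#' @return A peptide table (see [peptide_records()]) with extra columns
#'   `truth_score` (the planted statistic) and `truth_prob`.
#' @export
gen_peptide_dataset <- function(n, length = 6L,
                                signal = c("patterned", "composition", "null"),
                                effect_size = 25, class_balance = 0.5,
                                seed = 1L,
                                background = idr_background_freqs()) {
  signal <- match.arg(signal)
  stopifnot(n >= 2L, length >= 2L,
            class_balance > 0, class_balance < 1)
  with_seed(seed, {
    codes <- random_code_matrix(n, length, background)
    s <- switch(signal,
                patterned = hydropathy_contrast(codes),
                composition = mean_hydropathy(codes),
                null = rep(0, n))
    if (signal == "null") {
      prob <- rep(class_balance, n)
    } else {
      z <- (s - mean(s)) / max(stats::sd(s), 1e-12)
      prob <- stats::plogis(effect_size * z + stats::qlogis(class_balance))
    }
    y <- stats::rbinom(n, 1L, prob)
    tag <- if (length %in% c(6L, 10L, 15L, 20L)) {
      sprintf("%daa", length)
    } else "custom"
    out <- peptide_records(id = sprintf("pep%05d", seq_len(n)),
                           sequence = codes_to_strings(codes),
                           label = y, dataset_tag = tag)
    out$truth_score <- s
    out$truth_prob <- prob
    out
  })
}

# Draw one alternating hydrophobic/polar stretch of the given length,
# sampling letters within each hydropathy class from the background.
alternating_stretch <- function(len, background, phase = 1L) {
  hyd <- which(AA_ALPHABET %in% HYDROPHOBIC_AA)
  pol <- setdiff(seq_len(20L), hyd)
  codes <- integer(len)
  for (i in seq_len(len)) {
    pool <- if ((i + phase) %% 2L == 0L) hyd else pol
    codes[i] <- sample(pool, 1L, prob = background[pool])
  }
  codes
}

#' Generate a synthetic disordered proteome (IDRome) with annotations
#'
#' IDR lengths are uniform in `length_range`; sequences come from the
#' background composition. Each IDR receives one to three molecular-function
#' terms and one cellular-component term. IDRs annotated with the planted
#' term have a contiguous fraction `planted_effect` of their residues
#' replaced by an alternating hydrophobic/polar stretch, which raises their
#' per-IDR high-score fractions under any scorer that rewards hydrophobic
#' content or hydrophobic/polar patterning. LLPS drivers are sampled as
#' whole proteins (every IDR of a driver is positive).
#'
#' @param n_idrs Number of IDRs.
#' @param length_range Integer range of IDR lengths.
#' @param n_terms Number of molecular-function terms.
#' @param planted_term Index (1-based) of the planted term, or `NULL` for a
#'   fully null proteome.
#' @param planted_effect Fraction of residues of planted-term IDRs replaced
#'   by the planted stretch (0 disables planting).
#' @param driver_fraction Fraction of proteins flagged as LLPS drivers
#'   (rare-positive regime; must be < 0.5).
#' @param seed Seed.
#' @param background Background residue frequencies.
#' @return List with `idrs` (an IDR table, see [idr_records()]), `term_map`
#'   (`term`, `id`, `ontology`), `drivers` (accessions) and `planted_term`
#'   (term id or `NA`).
#' @export
gen_idrome <- function(n_idrs = 500L, length_range = c(40L, 70L),
                       n_terms = 20L, planted_term = 1L,
                       planted_effect = 0.25, driver_fraction = 0.02,
                       seed = 1L, background = idr_background_freqs()) {
  stopifnot(n_idrs >= 2L, n_terms >= 2L, driver_fraction < 0.5,
            planted_effect >= 0, planted_effect <= 1)
  if (!is.null(planted_term) && planted_term > n_terms) {
    stop("planted_term exceeds n_terms")
  }
  with_seed(seed, {
    n_prot <- max(2L, ceiling(n_idrs / 1.5))
    prot_of <- sort(sample.int(n_prot, n_idrs, replace = TRUE))
    acc <- sprintf("P%05d", prot_of)
    lens <- sample(length_range[1L]:length_range[2L], n_idrs, replace = TRUE)
    mf_terms <- sprintf("MF%02d", seq_len(n_terms))
    cc_terms <- sprintf("CC%02d", seq_len(max(4L, n_terms %/% 2L)))
    go_mf <- lapply(seq_len(n_idrs), function(i)
      sample(mf_terms, sample(1:3, 1L)))
    go_cc <- lapply(seq_len(n_idrs), function(i) sample(cc_terms, 1L))
    planted_id <- if (!is.null(planted_term)) mf_terms[planted_term] else NA
    seqs <- character(n_idrs)
    for (i in seq_len(n_idrs)) {
      cd <- sample.int(20L, lens[i], replace = TRUE, prob = background)
      if (!is.na(planted_id) && planted_effect > 0 &&
            planted_id %in% go_mf[[i]]) {
        k <- max(2L, round(planted_effect * lens[i]))
        at <- sample.int(lens[i] - k + 1L, 1L)
        cd[at:(at + k - 1L)] <- alternating_stretch(k, background)
      }
      seqs[i] <- paste(AA_ALPHABET[cd], collapse = "")
    }
    present <- unique(prot_of)
    drivers <- sprintf("P%05d",
                       sample(present, max(1L, round(driver_fraction *
                                                       length(present)))))
    idrs <- idr_records(accession = acc, idr_start = 1L, idr_end = lens,
                        sequence = seqs, go_mf = go_mf, go_cc = go_cc,
                        is_driver = acc %in% drivers)
    term_map <- rbind(
      data.frame(term = unlist(go_mf),
                 id = rep(idrs$idr_id, lengths(go_mf)),
                 ontology = "MF", stringsAsFactors = FALSE),
      data.frame(term = unlist(go_cc),
                 id = rep(idrs$idr_id, lengths(go_cc)),
                 ontology = "CC", stringsAsFactors = FALSE))
    list(idrs = idrs, term_map = term_map, drivers = unique(drivers),
         planted_term = planted_id)
  })
}

#' Generate a synthetic SNP set with a planted pathogenic tail effect
#'
#' Wild-type IDR sequences come from the background composition. Benign
#' variants substitute a residue within its own hydropathy class
#' (conservative, small expected score shift). Pathogenic variants make a
#' strong cross-class substitution (polar to strongly hydrophobic or vice
#' versa) with probability `1 - 1/planted_or`, and a benign-like
#' substitution otherwise, so larger `planted_or` inflates the pathogenic
#' `|delta|` tail.
#'
#' @param n_per_class Variants per clinical class (>= 10).
#' @param planted_or Planted tail-odds parameter (>= 1; 1 means no class
#'   difference).
#' @param idr_length Length of each wild-type IDR.
#' @param seed Seed.
#' @param background Background residue frequencies.
#' @return Data frame with one row per variant: `accession`, `sequence`
#'   (wild type), `position`, `ref_aa`, `alt_aa`, `clinical_class`, and the
#'   ground-truth flag `strong_substitution`.
#' @export
gen_snp_set <- function(n_per_class = 200L, planted_or = 3, idr_length = 60L,
                        seed = 1L, background = idr_background_freqs()) {
  stopifnot(n_per_class >= 10L, planted_or >= 1, idr_length >= 30L)
  hyd <- which(AA_ALPHABET %in% HYDROPHOBIC_AA)
  pol <- setdiff(seq_len(20L), hyd)
  strong_hyd <- which(AA_ALPHABET %in% c("V", "I", "L", "F", "W"))
  strong_pol <- which(AA_ALPHABET %in% c("D", "E", "K", "R", "P"))
  with_seed(seed, {
    n <- 2L * n_per_class
    codes <- random_code_matrix(n, idr_length, background)
    cls <- rep(c("pathogenic", "benign"), each = n_per_class)
    pos <- sample.int(idr_length, n, replace = TRUE)
    p_strong <- 1 - 1 / planted_or
    rows <- lapply(seq_len(n), function(i) {
      ref <- codes[i, pos[i]]
      same_class <- if (ref %in% hyd) hyd else pol
      benign_pool <- setdiff(same_class, ref)
      strong <- cls[i] == "pathogenic" && stats::runif(1) < p_strong
      alt <- if (strong) {
        pool <- if (ref %in% hyd) strong_pol else strong_hyd
        sample(pool, 1L)
      } else {
        sample(benign_pool, 1L)
      }
      data.frame(accession = sprintf("S%05d", i),
                 sequence = paste(AA_ALPHABET[codes[i, ]], collapse = ""),
                 position = pos[i], ref_aa = AA_ALPHABET[ref],
                 alt_aa = AA_ALPHABET[alt], clinical_class = cls[i],
                 strong_substitution = strong, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
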