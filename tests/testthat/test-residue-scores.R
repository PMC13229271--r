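# Multi-window tiling and per-residue score profiles.

test_that("tiling produces stride-1 windows and flags short sequences", {
  t1 <- tile_fragments("VQIVYK", 6L)
  expect_equal(nrow(t1), 1L)
  expect_equal(t1$start, 1L)
  t2 <- tile_fragments(strrep("A", 10L), 6L)
  expect_equal(t2$start, 1:5)
  expect_equal(nchar(t2$fragment), rep(6L, 5L))
  t3 <- tile_fragments("VQIV", 6L)
  expect_true(t3$short)
  expect_equal(t3$fragment, "VQIV")
  expect_error(tile_fragments("", 6L), "nzchar")
})

test_that("per-residue covering means match hand-derived values", {
  expect_equal(per_residue_from_fragments(6L, 6L, 0.7), rep(0.7, 6L))
  expect_equal(per_residue_from_fragments(10L, 4L, rep(0.3, 7L)),
               rep(0.3, 10L))
  # covering-set enumeration for L=8, w=6, scores (0, 0.3, 0.9):
  # residue 1 <- {1}; residue 3 <- {1,2,3}; residue 7 <- {2,3}; residue 8 <- {3}
  got <- per_residue_from_fragments(8L, 6L, c(0, 0.3, 0.9))
  expect_equal(got[c(1L, 3L, 7L, 8L)], c(0, 0.4, 0.6, 0.9))
  expect_error(per_residue_from_fragments(8L, 6L, c(0, 0.3)), "expected 3")
})

test_that("per-residue scores equal the covering-set oracle on random inputs", {
  set.seed(30)
  for (i in 1:500) {
    w <- sample(c(6L, 10L, 15L, 25L, 40L), 1L)
    L <- sample(w:200L, 1L)
    fs <- runif(L - w + 1L)
    expect_identical(per_residue_from_fragments(L, w, fs) -
                       per_residue_oracle(L, w, fs),
                     rep(0, L))
  }
})

test_that("coverage counts and score bounds hold for random cases", {
  set.seed(32)
  for (i in 1:50) {
    w <- sample(2:20, 1L)
    L <- w + sample(0:40, 1L)
    fs <- runif(L - w + 1L)
    res <- per_residue_from_fragments(L, w, fs)
    cover <- vapply(seq_len(L), function(ii)
      length(max(1L, ii - w + 1L):min(ii, L - w + 1L)), integer(1))
    expect_equal(sum(cover), w * (L - w + 1L))
    expect_true(all(res >= min(fs) - 1e-12 & res <= max(fs) + 1e-12))
  }
})

test_that("NA fragment scores are excluded and uncovered residues are NA", {
  fs <- c(NA, 0.5, NA)
  res <- per_residue_from_fragments(8L, 6L, fs)
  expect_equal(res, per_residue_oracle(8L, 6L, fs))
  expect_true(is.na(per_residue_from_fragments(6L, 6L, NA_real_)[1L]))
})

test_that("a constant model yields a flat profile; single probe equals its row", {
  cm <- const_classifier(0.5, 20L)
  prof <- profile_sequence(strrep("ASGP", 5L), cm, composition_backend(),
                           probes = c(6L, 10L, 15L))
  expect_equal(unname(prof$combined), rep(0.5, 20L))
  expect_equal(high_fraction(prof, 0.5), 0) # strict boundary
  one <- profile_sequence(strrep("ASGP", 5L), cm, composition_backend(),
                          probes = 10L)
  expect_equal(unname(one$combined), unname(one$scores["10", ]))
})

test_that("profiles localize a planted high-signal stretch", {
  # hydrophobic/polar alternating stretch in a polar background, scored by a
  # patterned classifier trained on the same kind of signal
  set.seed(33)
  dat <- gen_peptide_dataset(300L, length = 6L, seed = 33)
  pb <- patterned_backend()
  model <- train_logistic(embed_sequences(dat$sequence, pb), dat$label, C = 1)
  core <- "VSVSVS"
  seq <- paste0(strrep("Q", 20L), core, strrep("Q", 20L))
  prof <- profile_sequence(seq, model, pb, probes = 6L)
  span <- 21:26
  expect_gt(min(prof$combined[span]), max(prof$combined[c(1:12, 35:46)]))
  # brute-force argmax: the best-scoring residue lies in the planted span
  expect_true(which.max(prof$combined) %in% 15:32)
})

test_that("combined profiles are invariant to probe processing order", {
  set.seed(34)
  cm <- const_classifier(0.8, 20L)
  dat <- gen_peptide_dataset(120L, length = 6L, seed = 35)
  pb <- composition_backend()
  model <- train_logistic(embed_sequences(dat$sequence, pb), dat$label, C = 1)
  s <- rand_seq(30L)
  p1 <- profile_sequence(s, model, pb, probes = c(6L, 10L, 15L))
  p2 <- profile_sequence(s, model, pb, probes = c(15L, 6L, 10L))
  expect_equal(p1$combined, p2$combined)
})

test_that("short-sequence probes follow the whole/omit policy", {
  cm <- const_classifier(0.9, 20L)
  s <- strrep("A", 8L)
  whole <- profile_sequence(s, cm, composition_backend(),
                            probes = c(6L, 15L), short = "whole")
  expect_equal(whole$short_probes, 15L)
  expect_equal(unname(whole$scores["15", ]), rep(0.9, 8L))
  omit <- profile_sequence(s, cm, composition_backend(),
                           probes = c(6L, 15L), short = "omit")
  expect_true(all(is.na(omit$scores["15", ])))
  expect_equal(unname(omit$combined), rep(0.9, 8L))
})

test_that("masked residues void covering fragments and high-fraction denominators", {
  cm <- const_classifier(0.9, 20L)
  s <- paste0(strrep("A", 10L), "X", strrep("A", 10L))
  prof <- profile_sequence(s, cm, composition_backend(), probes = 6L)
  expect_true(is.na(prof$combined[11L]))
  # neighbours of X covered only by X-containing fragments are NA too
  expect_true(all(!is.na(prof$combined[c(1:5, 17:21)])))
  expect_equal(high_fraction(prof, 0.5), 1.0)
  all_x <- profile_sequence("XXXXXXX", cm, composition_backend(), probes = 6L)
  expect_error(high_fraction(all_x), "no defined")
})

test_that("high_fraction counts strictly and sweeps thresholds", {
  prof <- manual_profile(c(0.2, 0.6, 0.6, 0.4))
  expect_equal(high_fraction(prof, 0.5), 0.5)
  sw <- high_fraction(prof, c(0.4, 0.5, 0.6))
  expect_equal(unname(sw), c(0.5, 0.5, 0)) # 0.4 is not > 0.4 (strict)
  flat <- manual_profile(rep(0.9, 10L))
  expect_equal(high_fraction(flat), 1.0)
})

test_that("profile export writes one row per residue", {
  cm <- const_classifier(0.4, 20L)
  profs <- list(a = profile_sequence(strrep("A", 12L), cm,
                                     composition_backend(), probes = 6L))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_profiles_tsv(profs, f)
  tab <- utils::read.table(f, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), 12L)
  expect_true(all(c("id", "residue", "aa", "combined") %in% names(tab)))
})
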