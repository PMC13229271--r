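# Sequence dataset reading, validation and labelling.

test_that("read_fasta preserves order, joins wrapped lines, uppercases", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "VQIVYK", ">b desc", "vqiv", "yk", ">c", "PPPP"), f)
  fa <- read_fasta(f)
  expect_equal(fa$id, c("a", "b desc", "c"))
  expect_equal(fa$sequence, c("VQIVYK", "VQIVYK", "PPPP"))

  # order matches an independent line-by-line parse on a generated fixture
  set.seed(11)
  ids <- sprintf("seq%02d", 1:12)
  seqs <- vapply(rep(25L, 12L), rand_seq, "")
  g <- withr::local_tempfile(fileext = ".fasta")
  writeLines(unlist(Map(function(i, s)
    c(paste0(">", i), substring(s, 1, 10), substring(s, 11, 25)),
    ids, seqs)), g)
  naive <- local({
    lines <- readLines(g)
    hdr <- grepl("^>", lines)
    grp <- cumsum(hdr)
    data.frame(id = sub("^>", "", lines[hdr]),
               sequence = vapply(split(lines[!hdr], grp[!hdr]), paste,
                                 "", collapse = ""),
               row.names = NULL)
  })
  got <- read_fasta(g)
  expect_equal(got$id, naive$id)
  expect_equal(got$sequence, naive$sequence)
})

test_that("read_fasta rejects empty records, naming them", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">ok", "VQIVYK", ">empty_one", ">tail", "AAA"), f)
  expect_error(read_fasta(f), "empty_one")
  expect_error(read_fasta(withr::local_tempfile()), "not found")
})

test_that("write_fasta / read_fasta round-trips sequences byte-identically", {
  set.seed(3)
  seqs <- stats::setNames(vapply(c(5L, 61L, 120L, 1L), rand_seq, ""),
                          c("w", "x", "y", "z"))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seqs, f)
  back <- read_fasta(f)
  expect_identical(back$sequence, unname(seqs))
  expect_identical(back$id, names(seqs))
})

test_that("validate_sequence folds case and enforces the alphabet", {
  expect_identical(validate_sequence("vqivyk"), "VQIVYK")
  expect_error(validate_sequence("VQIBYK"), "position 4")
  expect_warning(out <- validate_sequence("VQIBYK", policy = "mask"),
                 "masked")
  expect_identical(out, "VQIXYK")
  expect_error(validate_sequence(""), "nzchar")
})

test_that("fluorescence labelling is strict at the 1.5x boundary and monotone", {
  expect_identical(label_by_fluorescence(2.0, 0.9), 1L)
  expect_identical(label_by_fluorescence(1.0, 1.0), 0L)
  expect_identical(label_by_fluorescence(1.5, 1.5), 0L)
  expect_identical(label_by_fluorescence(NA, 1.6), 1L)
  expect_error(label_by_fluorescence(NA_real_, NA_real_), "missing")
  # monotone nondecreasing in each ratio
  set.seed(1)
  for (i in 1:50) {
    t1 <- runif(1, 0, 3); p1 <- runif(1, 0, 3)
    bump <- runif(1, 0, 1)
    expect_gte(label_by_fluorescence(t1 + bump, p1),
               label_by_fluorescence(t1, p1))
    expect_gte(label_by_fluorescence(t1, p1 + bump),
               label_by_fluorescence(t1, p1))
  }
})

test_that("peptide records enforce tag lengths and labels", {
  ok <- peptide_records("a", "VQIVYK", 1L, "6aa")
  expect_equal(nchar(ok$sequence), 6L)
  expect_error(peptide_records("a", "VQIVY", 1L, "6aa"), "length")
  expect_error(peptide_records("a", "VQIVYK", 2L, "6aa"), "labels")
  expect_error(peptide_records("a", "VQIVYK", 1L, "7aa"), "dataset_tag")
})

test_that("read_peptide_table maps heterogeneous layouts via a schema", {
  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(
    data.frame(name = c("p1", "p2"), pep = c("VQIVYK", "AAAAAA"),
               amyloid = c(1L, 0L)),
    f, sep = "\t", quote = FALSE, row.names = FALSE)
  tab <- read_peptide_table(f, schema = list(id = "name", sequence = "pep",
                                             label = "amyloid"),
                            dataset_tag = "6aa")
  expect_equal(tab$label, c(1L, 0L))
  expect_equal(tab$dataset_tag, c("6aa", "6aa"))
  expect_error(
    read_peptide_table(f, schema = list(id = "nope", sequence = "pep")),
    "nope")
})

test_that("driver labelling marks every IDR of a driver protein", {
  idrs <- idr_records(accession = rep(sprintf("P%d", 1:5), each = 2L),
                      idr_start = 1L, idr_end = 8L,
                      sequence = replicate(10L, strrep("A", 8L)))
  # drivers P1 (2 IDRs) and P2 but with one of its IDRs replaced: rebuild a
  # table where P2 has a single IDR so drivers contribute 3 IDRs total
  idrs <- idrs[-4L, ]
  lab <- build_llps_labels(idrs, c("P1", "P2"))
  expect_equal(attr(lab, "n_positive"), 3L)
  expect_equal(attr(lab, "n_positive_accessions"), 2L)
  expect_equal(sum(lab$label), 3L)
  # positives count equals the sum over driver proteins of their IDR counts
  expect_equal(sum(lab$label), sum(table(idrs$accession)[c("P1", "P2")]))

  none <- build_llps_labels(idrs, character())
  expect_equal(attr(none, "n_positive"), 0L)

  expect_warning(miss <- build_llps_labels(idrs, c("P1", "P2", "PX")),
                 "PX")
  expect_equal(attr(miss, "n_positive"), 3L)
  expect_equal(attr(miss, "unmatched"), "PX")
})

test_that("IDR records enforce the span/length invariant", {
  expect_error(idr_records("P1", 1L, 9L, strrep("A", 8L)), "span")
  expect_error(idr_records("P1", 0L, 7L, strrep("A", 8L)), ">= 1")
  rec <- idr_records("P1", 10L, 17L, "ACDEFGHI")
  expect_equal(rec$idr_id, "P1_10-17")
})
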