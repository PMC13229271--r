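# Reading, validating and labelling sequence datasets: peptide tables,
# FASTA files, IDR metadata and LLPS-driver lists.

#' Read a FASTA file
#'
#' Thin wrapper around [Biostrings::readAAStringSet()] that returns a plain
#' data frame, preserves record order, joins wrapped lines and uppercases
#' sequences. Empty records are an error naming the offending header.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `id` and `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  ids <- names(set)
  if (is.null(ids) || anyNA(ids) || any(ids == "")) {
    stop("malformed FASTA '", path, "': record with empty header")
  }
  widths <- Biostrings::width(set)
  if (any(widths == 0L)) {
    stop("empty sequence for FASTA record '", ids[which(widths == 0L)[1L]], "'")
  }
  data.frame(id = ids, sequence = toupper(as.character(set)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write sequences to a FASTA file
#'
#' @param x Data frame with columns `id` and `sequence` (as returned by
#'   [read_fasta()]), or a named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  if (is.character(x)) {
    x <- data.frame(id = names(x) %||% as.character(seq_along(x)),
                    sequence = unname(x), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("id", "sequence") %in% names(x)))
  set <- Biostrings::AAStringSet(x$sequence)
  names(set) <- x$id
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Validate and canonicalize an amino-acid sequence
#'
#' Uppercases the sequence and enforces the 20-letter canonical alphabet.
#' Under `policy = "strict"` any other letter is an error naming its
#' position; under `policy = "mask"` non-canonical letters are replaced by
#' `X` with a warning. Masked positions receive no per-residue score
#' downstream (see [profile_sequence()]).
#'
#' @param seq A single sequence string.
#' @param policy `"strict"` (default) or `"mask"`.
#' @return The canonical sequence string.
#' @export
validate_sequence <- function(seq, policy = c("strict", "mask")) {
  policy <- match.arg(policy)
  stopifnot(is_string(seq), nzchar(seq))
  up <- toupper(seq)
  chars <- seq_chars(up)
  bad <- which(!(chars %in% AA_ALPHABET))
  if (length(bad) == 0L) return(up)
  if (policy == "strict") {
    stop("non-canonical residue '", chars[bad[1L]], "' at position ", bad[1L])
  }
  chars[bad] <- "X"
  warning(length(bad), " non-canonical residue(s) masked to X")
  paste(chars, collapse = "")
}

#' Label peptides from dye-fluorescence ratios
#'
#' A peptide is labelled amyloid-positive when either the ThT or the pFTAA
#' fluorescence signal exceeds its control by more than 50%, i.e. when the
#' largest available signal/control ratio is strictly greater than `cutoff`.
#' Boundary equality is negative ("exceeded" is read strictly).
#'
#' @param tht_ratio,pftaa_ratio Nonnegative signal/control ratios; either may
#'   be `NA`, but not both. Vectorized.
#' @param cutoff Ratio above which a peptide is positive (default 1.5).
#' @return Integer vector of 0/1 labels.
#' @export
label_by_fluorescence <- function(tht_ratio, pftaa_ratio = NA_real_,
                                  cutoff = 1.5) {
  n <- max(length(tht_ratio), length(pftaa_ratio))
  tht <- rep_len(as.numeric(tht_ratio), n)
  pft <- rep_len(as.numeric(pftaa_ratio), n)
  if (any(is.na(tht) & is.na(pft))) {
    stop("both fluorescence ratios missing for some peptide(s)")
  }
  if (any(c(tht, pft) < 0, na.rm = TRUE)) stop("fluorescence ratios must be nonnegative")
  as.integer(pmax(tht, pft, na.rm = TRUE) > cutoff)
}

#' Construct a validated peptide table
#'
#' Builds the canonical peptide record layout used by the model-training
#' functions: one row per peptide with an id, a canonical sequence, a 0/1
#' label (or `NA` for unlabelled peptides) and a dataset tag. When the tag is
#' one of the fixed-length tags (`"6aa"`, `"10aa"`, `"15aa"`, `"20aa"`) every
#' sequence must have that length.
#'
#' @param id Character ids.
#' @param sequence Sequences (validated strictly).
#' @param label 0/1 labels, `NA` allowed.
#' @param dataset_tag One of `"6aa"`, `"10aa"`, `"15aa"`, `"20aa"`,
#'   `"custom"`; recycled.
#' @param tht_ratio,pftaa_ratio Optional fluorescence ratios.
#' @return A data frame of peptide records.
#' @export
peptide_records <- function(id, sequence, label = NA_integer_,
                            dataset_tag = "custom",
                            tht_ratio = NA_real_, pftaa_ratio = NA_real_) {
  n <- length(sequence)
  tag <- rep_len(as.character(dataset_tag), n)
  ok_tags <- c("6aa", "10aa", "15aa", "20aa", "custom")
  if (!all(tag %in% ok_tags)) {
    stop("dataset_tag must be one of ", paste(ok_tags, collapse = ", "))
  }
  sequence <- vapply(sequence, validate_sequence, "", policy = "strict",
                     USE.NAMES = FALSE)
  fixed <- tag != "custom"
  if (any(fixed)) {
    want <- as.integer(sub("aa$", "", tag[fixed]))
    got <- nchar(sequence[fixed])
    if (any(want != got)) {
      i <- which(want != got)[1L]
      stop("sequence length ", got[i], " does not match dataset_tag '",
           tag[fixed][i], "'")
    }
  }
  label <- rep_len(as.integer(label), n)
  if (!all(label %in% c(0L, 1L, NA_integer_))) stop("labels must be 0, 1 or NA")
  data.frame(id = rep_len(as.character(id), n), sequence = sequence,
             label = label, dataset_tag = tag,
             tht_ratio = rep_len(as.numeric(tht_ratio), n),
             pftaa_ratio = rep_len(as.numeric(pftaa_ratio), n),
             stringsAsFactors = FALSE)
}

#' Read a delimited peptide table with a declared column schema
#'
#' Source peptide datasets use heterogeneous layouts, so the mapping from
#' file columns to record fields is declared explicitly rather than guessed.
#'
#' @param path Path to a delimited text file with a header row.
#' @param schema Named list mapping record fields (`id`, `sequence`, `label`,
#'   `dataset_tag`, `tht_ratio`, `pftaa_ratio`) to column names in the file.
#'   `id` and `sequence` are required.
#' @param sep Field separator (default tab).
#' @param dataset_tag Tag applied to all rows when the schema has no
#'   `dataset_tag` entry.
#' @return A validated peptide table (see [peptide_records()]).
#' @export
read_peptide_table <- function(path, schema = list(id = "id", sequence = "sequence",
                                                   label = "label"),
                               sep = "\t", dataset_tag = "custom") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- unlist(schema, use.names = FALSE)
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0L) {
    stop("columns missing from '", path, "': ",
         paste(missing_cols, collapse = ", "))
  }
  grab <- function(field, default) {
    if (!is.null(schema[[field]])) tab[[schema[[field]]]] else default
  }
  if (is.null(schema$id) || is.null(schema$sequence)) {
    stop("schema must map at least 'id' and 'sequence'")
  }
  peptide_records(id = tab[[schema$id]],
                  sequence = tab[[schema$sequence]],
                  label = grab("label", NA_integer_),
                  dataset_tag = grab("dataset_tag", dataset_tag),
                  tht_ratio = grab("tht_ratio", NA_real_),
                  pftaa_ratio = grab("pftaa_ratio", NA_real_))
}

#' Construct a validated IDR table
#'
#' One row per intrinsically disordered region. Coordinates are 1-based
#' inclusive residue indices in the parent protein, and the span length must
#' equal the sequence length.
#'
#' @param accession Parent-protein accessions.
#' @param idr_start,idr_end 1-based inclusive residue coordinates.
#' @param sequence IDR sequences (masking of non-canonical letters allowed).
#' @param go_mf,go_cc Lists of character vectors of GO molecular-function /
#'   cellular-component term ids (optional).
#' @param is_driver Logical LLPS-driver flag (optional, default `FALSE`).
#' @return A data frame of IDR records; `go_mf`/`go_cc` are list columns.
#' @export
idr_records <- function(accession, idr_start, idr_end, sequence,
                        go_mf = NULL, go_cc = NULL, is_driver = FALSE) {
  n <- length(sequence)
  sequence <- vapply(sequence, function(s)
    suppressWarnings(validate_sequence(s, policy = "mask")), "",
    USE.NAMES = FALSE)
  idr_start <- rep_len(as.integer(idr_start), n)
  idr_end <- rep_len(as.integer(idr_end), n)
  if (any(idr_start < 1L)) stop("idr_start must be >= 1")
  if (any(idr_end - idr_start + 1L != nchar(sequence))) {
    stop("IDR span length must equal sequence length")
  }
  out <- data.frame(accession = rep_len(as.character(accession), n),
                    idr_start = idr_start, idr_end = idr_end,
                    sequence = sequence,
                    is_driver = rep_len(as.logical(is_driver), n),
                    stringsAsFactors = FALSE)
  out$go_mf <- if (is.null(go_mf)) rep(list(character()), n) else go_mf
  out$go_cc <- if (is.null(go_cc)) rep(list(character()), n) else go_cc
  out$idr_id <- paste0(out$accession, "_", out$idr_start, "-", out$idr_end)
  out
}

#' Label IDRs by membership of an LLPS-driver list
#'
#' Every IDR whose parent accession appears in `driver_accessions` is
#' labelled positive (the source databases do not say which IDR of a driver
#' protein is responsible, so all of its IDRs count). Driver accessions that
#' match no IDR are reported as warnings, not failures.
#'
#' @param idrs IDR table from [idr_records()] (or any data frame with an
#'   `accession` column).
#' @param driver_accessions Character vector of driver protein accessions.
#' @return `idrs` with an integer `label` column added; attributes
#'   `n_positive`, `n_positive_accessions` and `unmatched` carry the counts
#'   and the unmatched driver accessions.
#' @export
build_llps_labels <- function(idrs, driver_accessions) {
  driver_accessions <- unique(as.character(driver_accessions))
  hit <- idrs$accession %in% driver_accessions
  unmatched <- setdiff(driver_accessions, idrs$accession)
  if (length(unmatched) > 0L) {
    warning(length(unmatched), " driver accession(s) match no IDR: ",
            paste(utils::head(unmatched, 5L), collapse = ", "))
  }
  idrs$label <- as.integer(hit)
  attr(idrs, "n_positive") <- sum(hit)
  attr(idrs, "n_positive_accessions") <- length(unique(idrs$accession[hit]))
  attr(idrs, "unmatched") <- unmatched
  idrs
}
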