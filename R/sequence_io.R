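# Sequence, alignment and annotation-table I/O.
#
# Sequences travel as a tibble with one row per record (id, description,
# residues, habitat); alignments as an `aar_msa` object (named character
# vector of equal-length gapped rows). All residue positions reported
# downstream use reference numbering: 1-based coordinates in the ungapped
# sequence of a designated reference row (initiator Met = 1).

new_sequence_records <- function(id, description = "", residues,
                                 habitat = "unknown") {
  records <- tibble::tibble(
    id = as.character(id),
    description = as.character(description),
    residues = toupper(as.character(residues)),
    habitat = as.character(habitat)
  )
  validate_sequence_records(records)
}

validate_sequence_records <- function(records) {
  if (anyDuplicated(records$id)) {
    abort_argument(paste0(
      "duplicate sequence ids: ",
      paste(unique(records$id[duplicated(records$id)]), collapse = ", ")
    ))
  }
  if (any(!nzchar(records$residues))) {
    abort_format("empty residue string")
  }
  bad <- !records$habitat %in% habitat_levels()
  if (any(bad)) {
    abort_argument(paste0(
      "invalid habitat label(s): ",
      paste(unique(records$habitat[bad]), collapse = ", ")
    ))
  }
  for (i in seq_len(nrow(records))) {
    check_residue_alphabet(records$residues[i], records$id[i])
  }
  records
}

check_residue_alphabet <- function(residues, id, allow_gap = FALSE) {
  allowed <- aa_alphabet()
  if (allow_gap) allowed <- c(allowed, "-")
  letters_seen <- unique(strsplit(residues, "", fixed = TRUE)[[1]])
  bad <- setdiff(letters_seen, allowed)
  if (length(bad) > 0) {
    abort_format(sprintf(
      "sequence '%s' contains non-amino-acid character(s): %s",
      id, paste(bad, collapse = " ")
    ))
  }
  invisible(residues)
}

# Locate the first line of a FASTA body containing a disallowed character,
# for error messages; Biostrings does not report line numbers.
find_offending_line <- function(path, allow_gap = FALSE) {
  allowed <- aa_alphabet()
  if (allow_gap) allowed <- c(allowed, "-", ".")
  lines <- readLines(path, warn = FALSE)
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (startsWith(line, ">") || !nzchar(line)) next
    letters_seen <- unique(strsplit(toupper(line), "", fixed = TRUE)[[1]])
    if (length(setdiff(letters_seen, allowed)) > 0) return(ln)
  }
  NA_integer_
}

#' Read protein sequences from a FASTA file
#'
#' Parses a plain (unaligned) protein FASTA file. Multi-line sequence bodies
#' are concatenated; record order is preserved. The first whitespace-delimited
#' token of each header is the record id, the remainder its description.
#' Residues must be drawn from the 20 canonical amino acids plus `X`.
#'
#' @param path Path to a FASTA file.
#' @param habitat Optional habitat table (see [read_habitat_table()]) used to
#'   tag records; ids absent from the table are tagged `"unknown"`.
#' @return A tibble with columns `id`, `description`, `residues`, `habitat`.
#' @export
read_fasta <- function(path, habitat = NULL) {
  if (!file.exists(path)) abort_format(paste0("file not found: ", path))
  # validate the raw lines first: Biostrings silently drops invalid codes
  ln <- find_offending_line(path)
  if (!is.na(ln)) {
    abort_format(sprintf(
      "non-amino-acid character on line %d of %s", ln, path
    ))
  }
  set <- tryCatch(
    suppressWarnings(Biostrings::readAAStringSet(path)),
    error = function(e) abort_format(paste0("not a valid FASTA file: ", path))
  )
  if (length(set) == 0) abort_format(paste0("empty FASTA file: ", path))
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  descriptions <- ifelse(grepl("\\s", headers),
                         sub("^\\S+\\s+", "", headers), "")
  residues <- toupper(as.character(set))
  records <- new_sequence_records(ids, descriptions, residues)
  if (!is.null(habitat)) {
    records$habitat <- unname(habitat[records$id])
    records$habitat[is.na(records$habitat)] <- "unknown"
  }
  records
}

#' Write protein sequences to a FASTA file
#'
#' @param records Sequence tibble as returned by [read_fasta()].
#' @param path Output path.
#' @param width Line-wrap width for sequence bodies (default 60 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60) {
  set <- Biostrings::AAStringSet(records$residues)
  names(set) <- ifelse(nzchar(records$description),
                       paste(records$id, records$description),
                       records$id)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Construct a multiple sequence alignment object
#'
#' @param aligned Named character vector of gapped rows (names are ids), or an
#'   unnamed vector plus `ids`.
#' @param ids Optional id vector when `aligned` is unnamed.
#' @return An `aar_msa` object.
#' @export
new_msa <- function(aligned, ids = names(aligned)) {
  if (is.null(ids)) abort_argument("alignment rows must be named")
  aligned <- toupper(as.character(aligned))
  aligned <- gsub(".", "-", aligned, fixed = TRUE)
  names(aligned) <- as.character(ids)
  if (anyDuplicated(ids)) abort_argument("duplicate ids in alignment")
  widths <- nchar(aligned)
  if (length(unique(widths)) > 1) {
    abort_format(sprintf(
      "ragged alignment: row widths %s",
      paste(sort(unique(widths)), collapse = ", ")
    ))
  }
  for (i in seq_along(aligned)) {
    check_residue_alphabet(aligned[i], names(aligned)[i], allow_gap = TRUE)
    if (!nzchar(gsub("-", "", aligned[i], fixed = TRUE))) {
      abort_format(sprintf("row '%s' is all gaps", names(aligned)[i]))
    }
  }
  structure(aligned, class = "aar_msa")
}

#' @export
print.aar_msa <- function(x, ...) {
  cat(sprintf("<aar_msa> %d rows x %d columns\n", length(x), msa_width(x)))
  shown <- utils::head(seq_along(x), 10)
  for (i in shown) {
    row <- unclass(x)[i]
    seq_show <- if (nchar(row) > 60) paste0(substr(row, 1, 57), "...") else row
    cat(sprintf("  %-12s %s\n", names(x)[i], seq_show))
  }
  if (length(x) > 10) cat(sprintf("  ... and %d more rows\n", length(x) - 10))
  invisible(x)
}

#' @export
#' @rdname new_msa
msa_width <- function(aligned) nchar(unclass(aligned)[[1]])

#' Character matrix view of an alignment (rows = sequences, columns = sites)
#' @param msa An `aar_msa`.
#' @return Character matrix with rownames = ids.
#' @export
msa_matrix <- function(msa) {
  m <- do.call(rbind, strsplit(unclass(msa), "", fixed = TRUE))
  rownames(m) <- names(msa)
  m
}

#' Drop gaps from one alignment row
#' @param msa An `aar_msa`.
#' @param id Row id.
#' @return Ungapped residue string.
#' @export
ungap_row <- function(msa, id) {
  if (!id %in% names(msa)) abort_lookup(paste0("id not in alignment: ", id))
  gsub("-", "", unclass(msa)[[id]], fixed = TRUE)
}

#' Read a protein multiple sequence alignment
#'
#' Supports aligned FASTA and Clustal (`.aln`) formats. Clustal block
#' structure is reassembled into one gapped row per id; `.` gap characters
#' are normalized to `-`.
#'
#' @param path Path to the alignment file.
#' @param format `"fasta"` (aligned FASTA) or `"clustal"`.
#' @return An `aar_msa` object with rows in file order.
#' @export
read_alignment <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort_format(paste0("file not found: ", path))
  if (format == "fasta") {
    set <- tryCatch(
      Biostrings::readAAStringSet(path),
      error = function(e) abort_format(paste0("not a valid FASTA file: ", path))
    )
    if (length(set) == 0) abort_format(paste0("empty alignment file: ", path))
    aligned <- as.character(set)
    names(aligned) <- sub("\\s.*$", "", names(set))
  } else {
    aln <- tryCatch(
      suppressWarnings(seqinr::read.alignment(path, format = "clustal")),
      error = function(e) abort_format(paste0("not a valid Clustal file: ", path))
    )
    aligned <- unlist(aln$seq)
    names(aligned) <- aln$nam
    if (anyNA(aln$nam) || any(is.na(aligned)) || any(aligned == "na")) {
      abort_format(paste0("not a valid Clustal file: ", path))
    }
  }
  new_msa(aligned)
}

#' Write an alignment as aligned FASTA
#' @param msa An `aar_msa`.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(msa, path, width = 60) {
  set <- Biostrings::AAStringSet(unclass(msa))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Map alignment columns to reference residue numbers
#'
#' Builds the column-to-residue map that underlies all residue reports:
#' non-gap columns of the reference row are numbered 1..L in order (initiator
#' Met = 1 in the native deposited sequence), gap columns are `NA`.
#'
#' @param msa An `aar_msa`.
#' @param reference_id Id of the numbering reference row.
#' @return An `aar_refmap`: list with `reference_id` and integer vector
#'   `column_to_residue` (length = alignment width, `NA` at reference gaps).
#' @export
build_reference_map <- function(msa, reference_id) {
  if (!reference_id %in% names(msa)) {
    abort_lookup(paste0("reference id not in alignment: ", reference_id))
  }
  ref_chars <- strsplit(unclass(msa)[[reference_id]], "", fixed = TRUE)[[1]]
  non_gap <- ref_chars != "-"
  col_map <- rep(NA_integer_, length(ref_chars))
  col_map[non_gap] <- seq_len(sum(non_gap))
  structure(
    list(reference_id = reference_id, column_to_residue = col_map),
    class = "aar_refmap"
  )
}

#' Read a habitat annotation table
#'
#' Two-column TSV (`id`, `habitat`) mapping strain ids to one of
#' `marine`, `freshwater`, `both`, `unknown`.
#'
#' @param path Path to the TSV file.
#' @return Named character vector: habitat label per id.
#' @export
read_habitat_table <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!all(c("id", "habitat") %in% names(tab))) {
    abort_format("habitat table must have columns 'id' and 'habitat'")
  }
  bad <- !tab$habitat %in% habitat_levels()
  if (any(bad)) {
    abort_format(paste0(
      "invalid habitat label(s): ",
      paste(unique(tab$habitat[bad]), collapse = ", ")
    ))
  }
  stats::setNames(tab$habitat, tab$id)
}

#' Write a habitat annotation table
#' @param habitat Named character vector (id -> habitat).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_habitat_table <- function(habitat, path) {
  readr::write_tsv(
    tibble::tibble(id = names(habitat), habitat = unname(habitat)), path
  )
  invisible(path)
}
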