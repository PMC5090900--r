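# Pairwise global alignment and percent-identity matrices.
#
# Identity convention used throughout: 100 * matches / columns where neither
# sequence has a gap. `X` never counts as a match. Alignments are global
# (end gaps penalized) affine-gap Needleman-Wunsch under BLOSUM62 with
# BLAST protein default penalties (open 11, extend 1), the scheme the
# identity statistics feeding the tree are computed under.

#' Alignment scoring scheme
#'
#' @param matrix Substitution matrix name (one shipped with Biostrings,
#'   default `"BLOSUM62"`) or a numeric substitution matrix.
#' @param gap_open Positive gap-opening penalty (default 11).
#' @param gap_extend Positive gap-extension penalty per residue (default 1).
#' @return A `scoring_scheme` list.
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1) {
  if (gap_open <= 0 || gap_extend <= 0) {
    abort_argument("gap penalties must be positive")
  }
  sub_mat <- if (is.matrix(matrix)) {
    matrix
  } else {
    get(data(list = matrix, package = "Biostrings", envir = environment()))
  }
  if (!isSymmetric(unname(sub_mat))) {
    abort_argument("substitution matrix must be symmetric")
  }
  structure(
    list(matrix = sub_mat, gap_open = gap_open, gap_extend = gap_extend),
    class = "scoring_scheme"
  )
}

as_residue_string <- function(x) {
  if (is.character(x) && length(x) == 1) return(toupper(x))
  if (is.data.frame(x) && "residues" %in% names(x)) {
    if (nrow(x) != 1) abort_argument("expected a single sequence record")
    return(x$residues)
  }
  abort_argument("expected a residue string or one-row sequence record")
}

#' Global pairwise alignment of two protein sequences
#'
#' Affine-gap Needleman-Wunsch with end gaps penalized. The score is the
#' maximum over all alignments under the scheme; ungapping either output
#' string recovers the corresponding input.
#'
#' @param a,b Residue strings or one-row sequence tibbles.
#' @param scheme A [scoring_scheme()].
#' @return List with gapped strings `a` and `b` and the alignment `score`.
#' @export
global_align <- function(a, b, scheme = scoring_scheme()) {
  a <- as_residue_string(a)
  b <- as_residue_string(b)
  if (!nzchar(a) || !nzchar(b)) abort_argument("sequences must be non-empty")
  fit <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "global",
    substitutionMatrix = scheme$matrix,
    gapOpening = scheme$gap_open,
    gapExtension = scheme$gap_extend
  )
  list(
    a = as.character(Biostrings::alignedPattern(fit)),
    b = as.character(Biostrings::alignedSubject(fit)),
    score = Biostrings::score(fit)
  )
}

#' Percent identity of an aligned sequence pair
#'
#' 100 x (columns where both letters are equal and neither is a gap) /
#' (columns where neither is a gap). `X` never counts as a match.
#'
#' @param a Either the list returned by [global_align()], or the first gapped
#'   string.
#' @param b The second gapped string (ignored when `a` is an alignment list).
#' @return Percent identity in `[0, 100]`.
#' @export
percent_identity <- function(a, b = NULL) {
  if (is.list(a) && !is.data.frame(a)) {
    b <- a$b
    a <- a$a
  }
  if (nchar(a) != nchar(b)) {
    abort_argument("aligned strings must have equal length")
  }
  ca <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  cb <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  overlap <- ca != "-" & cb != "-"
  if (!any(overlap)) {
    abort_undefined("percent identity undefined: no co-aligned columns")
  }
  matches <- overlap & ca == cb & ca != "X"
  100 * sum(matches) / sum(overlap)
}

#' Pairwise percent-identity matrix from unaligned sequences
#'
#' Aligns every unordered pair globally under `scheme` and scores identity on
#' the pairwise alignment.
#'
#' @param records Sequence tibble (>= 2 rows, unique ids).
#' @param scheme A [scoring_scheme()].
#' @return Symmetric numeric matrix (diagonal 100) with ids as dimnames.
#' @export
identity_matrix <- function(records, scheme = scoring_scheme()) {
  if (nrow(records) < 2) abort_argument("need at least 2 sequences")
  if (anyDuplicated(records$id)) abort_argument("duplicate sequence ids")
  n <- nrow(records)
  ids <- records$id
  m <- diag(100, n)
  dimnames(m) <- list(ids, ids)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      aln <- global_align(records$residues[i], records$residues[j], scheme)
      m[i, j] <- m[j, i] <- percent_identity(aln)
    }
  }
  validate_identity_matrix(m)
}

#' Pairwise percent-identity matrix computed on MSA columns
#'
#' Identity per pair over the alignment's columns, with the same
#' neither-gap denominator convention as [percent_identity()].
#'
#' @param msa An `aar_msa` with >= 2 rows.
#' @return Symmetric numeric matrix with ids as dimnames.
#' @export
msa_identity_matrix <- function(msa) {
  if (length(msa) < 2) abort_argument("need at least 2 alignment rows")
  chars <- msa_matrix(msa)
  n <- nrow(chars)
  m <- diag(100, n)
  dimnames(m) <- list(rownames(chars), rownames(chars))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      ca <- chars[i, ]
      cb <- chars[j, ]
      overlap <- ca != "-" & cb != "-"
      if (!any(overlap)) {
        abort_undefined(sprintf(
          "no co-aligned columns between '%s' and '%s'",
          rownames(chars)[i], rownames(chars)[j]
        ))
      }
      matches <- overlap & ca == cb & ca != "X"
      m[i, j] <- m[j, i] <- 100 * sum(matches) / sum(overlap)
    }
  }
  validate_identity_matrix(m)
}

validate_identity_matrix <- function(m) {
  stopifnot(isSymmetric(unname(m)), all(m >= 0 & m <= 100),
            all(abs(diag(m) - 100) < 1e-12))
  m
}

#' Write an identity (or distance) matrix as TSV with id header row/column
#' @param m Numeric matrix with id dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_identity_tsv <- function(m, path) {
  tab <- tibble::as_tibble(m, rownames = "id")
  readr::write_tsv(tab, path)
  invisible(path)
}

#' Read an identity/distance matrix written by [write_identity_tsv()]
#' @param path Path to the TSV file.
#' @return Numeric matrix with id dimnames.
#' @export
read_identity_tsv <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    id = "c", .default = "d"
  ), progress = FALSE)
  m <- as.matrix(tab[, -1])
  rownames(m) <- tab$id
  m
}

#' Write a square PHYLIP distance matrix
#' @param d Symmetric numeric matrix with id dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylip_dist <- function(d, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  for (i in seq_len(nrow(d))) {
    writeLines(paste0(
      formatC(substr(rownames(d)[i], 1, 10), width = -10),
      " ",
      paste(formatC(d[i, ], format = "f", digits = 6), collapse = " ")
    ), con)
  }
  invisible(path)
}
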