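# Alignment-column scan for group-discriminating residues, and mutation
# proposals in wild-type + reference-position + consensus style (e.g. Q15R).
#
# Two criteria are implemented:
#   strict     - every in-group row carries one identical non-gap residue and
#                at most `max_outgroup_matches` out-group rows carry it
#                (candidate activity determinants);
#   similarity - all in-group residues fall within a single similarity class
#                while the out-group residues do not all fall in that class
#                (candidate specificity determinants).
# Gaps in any in-group row disqualify a column; out-group gaps count as
# non-matching. `X` never matches anything, including itself.

#' Clustal "strong group" amino-acid similarity classes
#'
#' The conservative substitution classes marked `:` in Clustal output,
#' used as the default similarity partition for the residue scan.
#'
#' @return Named list of character vectors of one-letter codes.
#' @export
clustal_strong_groups <- function() {
  groups <- c("STA", "NEQK", "NHQK", "NDEQ", "QHRK", "MILV", "MILF", "HY",
              "FYW")
  stats::setNames(lapply(groups, function(g) strsplit(g, "")[[1]]), groups)
}

#' Group specification for the residue scan
#'
#' @param ingroup_ids Ids of the in-group rows (non-empty, proper subset of
#'   the alignment's ids).
#' @param mode `"strict"` or `"similarity"`.
#' @param max_outgroup_matches Strict mode: maximum number of out-group rows
#'   allowed to carry the in-group residue (default 0).
#' @param similarity_classes Similarity mode: list of residue classes
#'   (default [clustal_strong_groups()]).
#' @param name Optional label.
#' @return A `group_spec` list.
#' @export
group_spec <- function(ingroup_ids, mode = c("strict", "similarity"),
                       max_outgroup_matches = 0,
                       similarity_classes = clustal_strong_groups(),
                       name = NULL) {
  mode <- match.arg(mode)
  if (length(ingroup_ids) == 0) abort_argument("in-group must be non-empty")
  if (max_outgroup_matches < 0) {
    abort_argument("max_outgroup_matches must be >= 0")
  }
  structure(
    list(name = name %||% mode, ingroup_ids = ingroup_ids, mode = mode,
         max_outgroup_matches = max_outgroup_matches,
         similarity_classes = similarity_classes),
    class = "group_spec"
  )
}

check_group_spec <- function(msa, spec) {
  missing <- setdiff(spec$ingroup_ids, names(msa))
  if (length(missing) > 0) {
    abort_argument(paste0("in-group id(s) not in alignment: ",
                          paste(missing, collapse = ", ")))
  }
  if (length(spec$ingroup_ids) >= length(msa)) {
    abort_argument("in-group must be a proper subset of the alignment rows")
  }
  invisible(spec)
}

scan_result_row <- function(column, refpos, criterion, ingroup, outgroup) {
  tibble::tibble(
    ref_position = refpos,
    column = column,
    criterion = criterion,
    ingroup_residues = paste(sort(unique(ingroup)), collapse = ""),
    outgroup_residues = paste(sort(unique(outgroup)), collapse = ""),
    numberable = !is.na(refpos)
  )
}

empty_scan_result <- function() {
  tibble::tibble(
    ref_position = integer(), column = integer(), criterion = character(),
    ingroup_residues = character(), outgroup_residues = character(),
    numberable = logical()
  )
}

finish_scan <- function(rows) {
  if (length(rows) == 0) return(empty_scan_result())
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, !.data$numberable, .data$ref_position, .data$column)
}

#' Scan for strictly conserved in-group residues absent from the out-group
#'
#' Reports every alignment column where (i) all in-group rows share one
#' identical non-gap residue, and (ii) at most `max_outgroup_matches`
#' out-group rows carry that residue. Columns that are gaps in the numbering
#' reference are reported with alignment-column coordinates only and flagged
#' `numberable = FALSE`.
#'
#' @param msa An `aar_msa`.
#' @param spec A [group_spec()] with `mode = "strict"`.
#' @param refmap Reference map built on the same alignment
#'   ([build_reference_map()]).
#' @return Tibble with columns `ref_position`, `column`, `criterion`,
#'   `ingroup_residues`, `outgroup_residues`, `numberable`, sorted by
#'   reference position.
#' @export
scan_strict <- function(msa, spec, refmap) {
  if (spec$mode != "strict") abort_argument("spec mode must be 'strict'")
  check_group_spec(msa, spec)
  chars <- msa_matrix(msa)
  in_rows <- chars[spec$ingroup_ids, , drop = FALSE]
  out_rows <- chars[setdiff(rownames(chars), spec$ingroup_ids), ,
                    drop = FALSE]
  rows <- list()
  for (col in seq_len(ncol(chars))) {
    ing <- in_rows[, col]
    if (any(ing == "-") || any(ing == "X")) next
    if (length(unique(ing)) != 1) next
    r <- ing[[1]]
    outg <- out_rows[, col]
    if (sum(outg == r) > spec$max_outgroup_matches) next
    rows[[length(rows) + 1]] <- scan_result_row(
      col, refmap$column_to_residue[col], "strict", ing, outg
    )
  }
  finish_scan(rows)
}

# residues sharing at least one similarity class ('X' shares none)
shared_classes <- function(residues, classes) {
  residues <- unique(residues)
  if (any(residues == "-") || any(residues == "X")) return(character(0))
  names(Filter(function(cl) all(residues %in% cl), classes))
}

#' Scan for in-group-similar residues not shared by the out-group
#'
#' Reports every column where all in-group residues fall within a single
#' similarity class (default: Clustal strong groups) and the out-group
#' residues do not all fall within that class. Identical in-group residues
#' count as similar only if the residue belongs to some class.
#'
#' @inheritParams scan_strict
#' @param spec A [group_spec()] with `mode = "similarity"`.
#' @return Tibble as for [scan_strict()] with `criterion = "similarity"`.
#' @export
scan_similarity <- function(msa, spec, refmap) {
  if (spec$mode != "similarity") abort_argument("spec mode must be 'similarity'")
  check_group_spec(msa, spec)
  chars <- msa_matrix(msa)
  in_rows <- chars[spec$ingroup_ids, , drop = FALSE]
  out_rows <- chars[setdiff(rownames(chars), spec$ingroup_ids), ,
                    drop = FALSE]
  classes <- spec$similarity_classes
  rows <- list()
  for (col in seq_len(ncol(chars))) {
    ing <- in_rows[, col]
    cls <- shared_classes(ing, classes)
    if (length(cls) == 0) next
    outg <- out_rows[, col]
    # out-group "also similar" if all its residues fit one in-group class
    out_similar <- any(vapply(
      cls, function(cl) all(outg %in% classes[[cl]]), logical(1)
    ))
    if (out_similar) next
    rows[[length(rows) + 1]] <- scan_result_row(
      col, refmap$column_to_residue[col], "similarity", ing, outg
    )
  }
  finish_scan(rows)
}

#' Run the scan configured by a group spec
#' @inheritParams scan_strict
#' @return Scan result tibble.
#' @export
scan_positions <- function(msa, spec, refmap) {
  switch(spec$mode,
    strict = scan_strict(msa, spec, refmap),
    similarity = scan_similarity(msa, spec, refmap)
  )
}

#' Propose single-residue substitutions toward the in-group consensus
#'
#' For each discriminating position, proposes replacing the target's residue
#' with the in-group consensus at that column, labeled wild-type letter +
#' reference position + proposed letter (e.g. `Q15R`). Positions where the
#' target already matches the consensus are skipped; positions where the
#' target has a gap are skipped with a warning record (`skipped = TRUE`).
#'
#' @param positions Scan result tibble.
#' @param target_id Id of the target row (must be outside the in-group).
#' @param msa An `aar_msa`.
#' @param spec The [group_spec()] used for the scan.
#' @return Tibble with columns `target_id`, `label`, `ref_position`,
#'   `column`, `wild_type`, `proposed`, `skipped`, `variant_id`.
#' @export
propose_mutations <- function(positions, target_id, msa, spec) {
  if (target_id %in% spec$ingroup_ids) {
    abort_argument("target must be outside the in-group")
  }
  if (!target_id %in% names(msa)) {
    abort_lookup(paste0("target id not in alignment: ", target_id))
  }
  chars <- msa_matrix(msa)
  in_rows <- chars[spec$ingroup_ids, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(positions))) {
    col <- positions$column[i]
    refpos <- positions$ref_position[i]
    if (is.na(refpos)) next   # unnumberable positions yield no labels
    ing <- in_rows[, col]
    # consensus: most frequent in-group residue, ties to the earlier row
    consensus <- names(which.max(table(factor(ing, levels = unique(ing)))))
    wt <- chars[target_id, col]
    if (wt == "-") {
      rows[[length(rows) + 1]] <- tibble::tibble(
        target_id = target_id, label = NA_character_,
        ref_position = refpos, column = col,
        wild_type = "-", proposed = consensus, skipped = TRUE
      )
      warning(sprintf(
        "target '%s' has a gap at reference position %d; no proposal",
        target_id, refpos
      ))
      next
    }
    if (wt == consensus) next
    rows[[length(rows) + 1]] <- tibble::tibble(
      target_id = target_id,
      label = sprintf("%s%d%s", wt, refpos, consensus),
      ref_position = refpos, column = col,
      wild_type = wt, proposed = consensus, skipped = FALSE
    )
  }
  if (length(rows) == 0) {
    out <- tibble::tibble(
      target_id = character(), label = character(), ref_position = integer(),
      column = integer(), wild_type = character(), proposed = character(),
      skipped = logical()
    )
  } else {
    out <- dplyr::bind_rows(rows)
  }
  out$variant_id <- ifelse(out$skipped, NA_character_,
                           paste0(out$target_id, "_", out$label))
  out
}

#' Write scan results as TSV
#' @param positions Scan result tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scan_tsv <- function(positions, path) {
  readr::write_tsv(positions, path)
  invisible(path)
}
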