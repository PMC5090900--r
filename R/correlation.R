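# Property-versus-sequence-identity correlations with a leave-one-out
# robustness check: a correlation driven by one high-leverage point (e.g.
# the reference enzyme itself) disappears when that point is dropped,
# arguing against overall-similarity explanations of the property.

#' Pearson product-moment correlation
#'
#' Thin validated wrapper over [stats::cor()]: requires n >= 3 complete pairs
#' and nonzero variance in both variables.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) abort_argument("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort_argument("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort_undefined("correlation undefined: zero variance")
  }
  stats::cor(x, y)
}

#' Build a property-versus-identity table
#'
#' Pairs one scalar property per variant with its percent identity to a named
#' reference sequence. The reference's self-identity point (100%) is excluded
#' by default, since its inclusion is exactly what the leave-one-out check
#' probes.
#'
#' @param profiles Profile tibble ([assemble_profiles()]) or any tibble with a
#'   `variant_id` column.
#' @param property Name of the property column.
#' @param identity Percent-identity matrix with variant ids as dimnames.
#' @param reference_id Column of `identity` to take identities from.
#' @param include_reference Keep the reference's own point? Default `FALSE`.
#' @return Tibble with columns `id`, `identity`, `property` (complete rows
#'   only).
#' @export
property_identity_table <- function(profiles, property, identity,
                                    reference_id,
                                    include_reference = FALSE) {
  if (!property %in% names(profiles)) {
    abort_lookup(paste0("no such property column: ", property))
  }
  if (!reference_id %in% colnames(identity)) {
    abort_lookup(paste0("reference id not in identity matrix: ", reference_id))
  }
  ids <- intersect(profiles$variant_id, rownames(identity))
  out <- tibble::tibble(
    id = ids,
    identity = unname(identity[ids, reference_id]),
    property = profiles[[property]][match(ids, profiles$variant_id)]
  )
  if (!include_reference) out <- out[out$id != reference_id, ]
  out[stats::complete.cases(out$identity, out$property), ]
}

#' Correlation with and without one data point
#'
#' @param pv Tibble with columns `id`, `identity`, `property`.
#' @param drop_id Id of the point to drop.
#' @param n_perm Optional number of permutations for a two-sided permutation
#'   p-value on the full correlation (0 = none; the shuffles are seeded by the
#'   caller's RNG state).
#' @return List with `r_full`, `r_dropped`, `n_full`, `n_dropped`, and
#'   `p_perm` when requested.
#' @export
leave_one_out <- function(pv, drop_id, n_perm = 0) {
  if (!drop_id %in% pv$id) abort_lookup(paste0("no such id: ", drop_id))
  r_full <- pearson(pv$identity, pv$property)
  kept <- pv[pv$id != drop_id, ]
  if (nrow(kept) < 3) abort_argument("dropping leaves fewer than 3 points")
  r_dropped <- pearson(kept$identity, kept$property)
  out <- list(r_full = r_full, r_dropped = r_dropped,
              n_full = nrow(pv), n_dropped = nrow(kept))
  if (n_perm > 0) {
    perm <- vapply(seq_len(n_perm), function(i) {
      stats::cor(pv$identity, sample(pv$property))
    }, numeric(1))
    out$p_perm <- (1 + sum(abs(perm) >= abs(r_full))) / (n_perm + 1)
  }
  out
}
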