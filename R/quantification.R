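# Derived enzyme-property quantities from hydrocarbon (GC-MS) and
# western-blot densitometry tables.
#
# The activity index of a variant is its mean total hydrocarbon amount
# divided by its mean soluble band volume, expressed relative to a reference
# variant; the index is unit-free (invariant to global rescaling of either
# table). Replicate aggregation forms ratios of means, not means of ratios;
# standard errors come from first-order relative-error propagation.
#
# Input table contracts (TSV headers):
#   hydro: variant_id, replicate, amount_c15, amount_c17_1, amount_c17_0
#          (+ optional extra analyte columns named amount_*)
#   blot:  variant_id, replicate, soluble_volume, insoluble_volume,
#          soluble_detected, insoluble_detected (+ optional ado_soluble)

analyte_cols <- function(hydro) {
  grep("^amount_", names(hydro), value = TRUE)
}

validate_hydro_table <- function(hydro) {
  need <- c("variant_id", "replicate", "amount_c15", "amount_c17_1",
            "amount_c17_0")
  missing <- setdiff(need, names(hydro))
  if (length(missing) > 0) {
    abort_format(paste0("hydrocarbon table missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  amounts <- as.matrix(hydro[analyte_cols(hydro)])
  if (any(amounts < 0, na.rm = TRUE)) abort_format("negative hydrocarbon amount")
  dup <- duplicated(hydro[c("variant_id", "replicate")])
  if (any(dup)) abort_format("duplicate (variant_id, replicate) in hydrocarbon table")
  hydro
}

validate_blot_table <- function(blot) {
  need <- c("variant_id", "replicate", "soluble_volume", "insoluble_volume")
  missing <- setdiff(need, names(blot))
  if (length(missing) > 0) {
    abort_format(paste0("blot table missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  if (!"soluble_detected" %in% names(blot)) blot$soluble_detected <- TRUE
  if (!"insoluble_detected" %in% names(blot)) blot$insoluble_detected <- TRUE
  vols <- c(blot$soluble_volume, blot$insoluble_volume)
  if (any(vols < 0, na.rm = TRUE)) abort_format("negative band volume")
  dup <- duplicated(blot[c("variant_id", "replicate")])
  if (any(dup)) abort_format("duplicate (variant_id, replicate) in blot table")
  # a non-detected band is missing, whatever volume was recorded
  blot$soluble_volume[!blot$soluble_detected] <- NA_real_
  blot$insoluble_volume[!blot$insoluble_detected] <- NA_real_
  blot
}

#' Read the hydrocarbon measurement table (TSV)
#' @param path Path to a TSV with columns `variant_id`, `replicate`,
#'   `amount_c15`, `amount_c17_1`, `amount_c17_0`.
#' @return Validated tibble.
#' @export
read_hydro_table <- function(path) {
  tab <- suppressWarnings(readr::read_tsv(path, col_types = readr::cols(
    variant_id = "c", replicate = "i", .default = "d"
  ), progress = FALSE))
  validate_hydro_table(tab)
}

#' Read the western-blot densitometry table (TSV)
#' @param path Path to a TSV with columns `variant_id`, `replicate`,
#'   `soluble_volume`, `insoluble_volume`, `soluble_detected`,
#'   `insoluble_detected`.
#' @return Validated tibble.
#' @export
read_blot_table <- function(path) {
  tab <- suppressWarnings(readr::read_tsv(path, col_types = readr::cols(
    variant_id = "c", replicate = "i",
    soluble_detected = "l", insoluble_detected = "l", .default = "d"
  ), progress = FALSE))
  validate_blot_table(tab)
}

#' Product-spectrum specificity fractions
#'
#' Each analyte amount divided by the total over all analytes; the fractions
#' sum to 1 and proxy the enzyme's substrate chain-length preference.
#'
#' @param amounts Non-negative named numeric vector of aggregated amounts.
#' @return Numeric vector of fractions summing to 1.
#' @export
specificity_fractions <- function(amounts) {
  if (any(amounts < 0)) abort_argument("amounts must be non-negative")
  total <- sum(amounts)
  if (total <= 0) abort_undefined("fractions undefined: all amounts are zero")
  amounts / total
}

#' Percent solubility from band volumes
#'
#' 100 * S / (S + P), the soluble share of the expressed protein.
#'
#' @param soluble,insoluble Band volumes (S and P fractions).
#' @return Percent in `[0, 100]`; `NA` when either band is `NA` (non-detect).
#' @export
solubility <- function(soluble, insoluble) {
  if (any(is.na(soluble) | is.na(insoluble))) return(NA_real_)
  total <- soluble + insoluble
  if (any(total <= 0)) abort_undefined("solubility undefined: S + P = 0")
  100 * soluble / total
}

#' Bundle one variant's measurements
#' @param hydro,blot Validated measurement tables.
#' @param variant_id Variant to extract.
#' @return A `measurement_set` list with that variant's rows of both tables.
#' @export
measurement_set <- function(hydro, blot, variant_id) {
  structure(
    list(
      variant_id = variant_id,
      hydro = dplyr::filter(validate_hydro_table(hydro),
                            .data$variant_id == !!variant_id),
      blot = dplyr::filter(validate_blot_table(blot),
                           .data$variant_id == !!variant_id)
    ),
    class = "measurement_set"
  )
}

# mean and standard error of the mean over replicates (SE = 0 for n = 1)
mean_se <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0) return(c(mean = NA_real_, se = NA_real_, n = 0))
  se <- if (n > 1) stats::sd(x) / sqrt(n) else 0
  c(mean = mean(x), se = se, n = n)
}

# activity index of one variant: mean total hydrocarbons / mean soluble
# volume, with first-order relative-error SE; NA when soluble non-detected
activity_index <- function(ms) {
  amounts <- as.matrix(ms$hydro[analyte_cols(ms$hydro)])
  tot <- mean_se(rowSums(amounts))
  sol <- mean_se(ms$blot$soluble_volume)
  if (nrow(ms$blot) == 0 || any(!ms$blot$soluble_detected) ||
      is.na(sol["mean"]) || sol["mean"] <= 0 || is.na(tot["mean"])) {
    return(c(value = NA_real_, rel_se = NA_real_))
  }
  value <- tot[["mean"]] / sol[["mean"]]
  rel_se <- sqrt((tot[["se"]] / tot[["mean"]])^2 + (sol[["se"]] / sol[["mean"]])^2)
  c(value = value, rel_se = rel_se)
}

expression_index <- function(ms) {
  tot <- mean_se(ms$blot$soluble_volume + ms$blot$insoluble_volume)
  if (is.na(tot[["mean"]]) || tot[["mean"]] <= 0) {
    return(c(value = NA_real_, rel_se = NA_real_))
  }
  c(value = tot[["mean"]], rel_se = tot[["se"]] / tot[["mean"]])
}

ratio_to_reference <- function(variant_idx, reference_idx, is_reference) {
  if (is_reference) return(c(value = 1, se = 0))
  if (is.na(variant_idx[["value"]]) || is.na(reference_idx[["value"]])) {
    return(c(value = NA_real_, se = NA_real_))
  }
  value <- variant_idx[["value"]] / reference_idx[["value"]]
  rel <- sqrt(variant_idx[["rel_se"]]^2 + reference_idx[["rel_se"]]^2)
  c(value = value, se = value * rel)
}

#' Aldehyde-producing activity relative to a reference variant
#'
#' The variant's activity index (mean total hydrocarbons over mean soluble
#' band volume) divided by the reference's. "Not determined" (`NA`) when the
#' soluble band of the variant is below detection.
#'
#' @param variant,reference `measurement_set` objects.
#' @return Named vector `value`, `se`.
#' @export
relative_activity <- function(variant, reference) {
  ratio_to_reference(activity_index(variant), activity_index(reference),
                     identical(variant$variant_id, reference$variant_id))
}

#' Expression level relative to a reference variant
#'
#' Total (soluble + insoluble) band volume of the variant over that of the
#' reference.
#'
#' @inheritParams relative_activity
#' @return Named vector `value`, `se`.
#' @export
relative_expression <- function(variant, reference) {
  ratio_to_reference(expression_index(variant), expression_index(reference),
                     identical(variant$variant_id, reference$variant_id))
}

#' Specificity relative to a reference variant
#'
#' Elementwise ratio of product fractions; analytes where the reference
#' fraction is zero are reported as `NA` (undefined).
#'
#' @param variant_fractions,reference_fractions Fraction vectors
#'   (see [specificity_fractions()]).
#' @return Numeric vector of per-analyte ratios.
#' @export
relative_specificity <- function(variant_fractions, reference_fractions) {
  out <- ifelse(reference_fractions > 0,
                variant_fractions / reference_fractions, NA_real_)
  names(out) <- names(variant_fractions)
  out
}

#' Assemble per-variant activity profiles
#'
#' Computes, for every variant present in either table: relative activity and
#' expression (to `reference_id`), percent solubility, product-spectrum
#' fractions with replicate-scatter SEs, relative total hydrocarbons, and
#' replicate counts. Variants whose soluble band is not detected get
#' `NA` ("not determined") activity and solubility.
#'
#' If the blot table carries an `ado_soluble` column it is checked for
#' near-constancy across variants (warning when its coefficient of variation
#' exceeds `ado_cv_warn`); it is never used in normalization.
#'
#' @param hydro Hydrocarbon table (see [read_hydro_table()]).
#' @param blot Blot table (see [read_blot_table()]).
#' @param reference_id Reference variant (must be present and fully detected).
#' @param ado_cv_warn CV threshold for the ADO constancy warning (default 0.25).
#' @return Tibble with one row per variant.
#' @export
assemble_profiles <- function(hydro, blot, reference_id, ado_cv_warn = 0.25) {
  hydro <- validate_hydro_table(hydro)
  blot <- validate_blot_table(blot)
  if (!reference_id %in% blot$variant_id ||
      !reference_id %in% hydro$variant_id) {
    abort_config(paste0("reference variant not in both tables: ", reference_id))
  }
  ref <- measurement_set(hydro, blot, reference_id)
  if (any(!ref$blot$soluble_detected)) {
    abort_config("reference variant has non-detected soluble band")
  }
  if ("ado_soluble" %in% names(blot)) {
    ado <- blot$ado_soluble[!is.na(blot$ado_soluble)]
    if (length(ado) > 1 && mean(ado) > 0) {
      cv <- stats::sd(ado) / mean(ado)
      if (cv > ado_cv_warn) {
        warning(sprintf(
          "soluble ADO varies across cultures (CV %.2f > %.2f); activity normalization assumes it is constant",
          cv, ado_cv_warn
        ))
      }
    }
  }

  variants <- unique(c(hydro$variant_id, blot$variant_id))
  analytes <- analyte_cols(hydro)
  frac_names <- sub("^amount_", "f_", analytes)
  ref_idx <- activity_index(ref)
  ref_expr <- expression_index(ref)
  ref_tot <- mean_se(rowSums(as.matrix(ref$hydro[analytes])))

  rows <- lapply(variants, function(v) {
    ms <- measurement_set(hydro, blot, v)
    is_ref <- identical(v, reference_id)
    act <- ratio_to_reference(activity_index(ms), ref_idx, is_ref)
    expr <- ratio_to_reference(expression_index(ms), ref_expr, is_ref)
    tot <- mean_se(rowSums(as.matrix(ms$hydro[analytes])))
    tot_rel <- ratio_to_reference(
      c(value = tot[["mean"]], rel_se = if (!is.na(tot[["mean"]]) && tot[["mean"]] > 0)
        tot[["se"]] / tot[["mean"]] else NA_real_),
      c(value = ref_tot[["mean"]], rel_se = if (ref_tot[["mean"]] > 0)
        ref_tot[["se"]] / ref_tot[["mean"]] else NA_real_),
      is_ref
    )

    # solubility: ratio of replicate means, NA on any non-detect
    sol_pct <- if (nrow(ms$blot) == 0 ||
                   any(!ms$blot$soluble_detected | !ms$blot$insoluble_detected)) {
      NA_real_
    } else {
      s <- mean(ms$blot$soluble_volume)
      p <- mean(ms$blot$insoluble_volume)
      if (s + p > 0) 100 * s / (s + p) else NA_real_
    }
    sol_se <- if (is.na(sol_pct) || nrow(ms$blot) < 2) {
      if (is.na(sol_pct)) NA_real_ else 0
    } else {
      per_rep <- 100 * ms$blot$soluble_volume /
        (ms$blot$soluble_volume + ms$blot$insoluble_volume)
      stats::sd(per_rep) / sqrt(length(per_rep))
    }

    # fractions: ratios of replicate-mean amounts (sum to 1); SE from
    # per-replicate fraction scatter
    amounts <- as.matrix(ms$hydro[analytes])
    if (nrow(amounts) > 0 && sum(colMeans(amounts)) > 0) {
      fr <- colMeans(amounts) / sum(colMeans(amounts))
      rep_tot <- rowSums(amounts)
      ok <- rep_tot > 0
      fr_se <- if (sum(ok) > 1) {
        apply(amounts[ok, , drop = FALSE] / rep_tot[ok], 2, stats::sd) /
          sqrt(sum(ok))
      } else {
        rep(0, length(analytes))
      }
    } else {
      fr <- fr_se <- rep(NA_real_, length(analytes))
    }

    out <- tibble::tibble(
      variant_id = v,
      relative_activity = act[["value"]], relative_activity_se = act[["se"]],
      solubility_pct = sol_pct, solubility_se = sol_se,
      relative_expression = expr[["value"]],
      relative_expression_se = expr[["se"]],
      total_relative = tot_rel[["value"]], total_relative_se = tot_rel[["se"]],
      n_replicates = nrow(ms$hydro)
    )
    for (a in seq_along(analytes)) {
      out[[frac_names[a]]] <- unname(fr[a])
      out[[paste0(frac_names[a], "_se")]] <- unname(fr_se[a])
    }
    out
  })
  dplyr::bind_rows(rows)
}

#' Write activity profiles as TSV and JSON
#' @param profiles Tibble from [assemble_profiles()].
#' @param path Output path without extension; writes `<path>.tsv` and
#'   `<path>.json`.
#' @return Paths written, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  tsv <- paste0(path, ".tsv")
  json <- paste0(path, ".json")
  readr::write_tsv(profiles, tsv)
  jsonlite::write_json(profiles, json, dataframe = "rows", digits = NA,
                       na = "null", pretty = TRUE)
  invisible(c(tsv, json))
}
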