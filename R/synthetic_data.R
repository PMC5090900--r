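# Synthetic protein families and measurement tables with known ground truth.
#
# The family generator plants group-diagnostic residues into an otherwise
# shared background sequence: every in-group row carries one designated
# residue at each planted position while out-group rows draw from a disjoint
# residue set, so the strict scan must recover exactly the planted positions
# when the background substitution rate is zero. The measurement generator
# emulates replicate scatter of band volumes and GC-MS amounts with
# multiplicative lognormal noise (both are positive intensity measurements)
# and habitat-dependent product-fraction means drawn from a Dirichlet.

#' Configuration for the synthetic family generator
#'
#' Defaults emulate an AAR-like family: length 341, a 2-member in-group
#' (marine-like, high-activity analog) against a 6-member out-group
#' (freshwater-like), and 11 planted diagnostic positions.
#'
#' @param length Sequence length L (default 341).
#' @param n_ingroup,n_outgroup Group sizes (defaults 2 and 6).
#' @param n_planted Number of planted positions generated when `planted` is
#'   `NULL` (default 11).
#' @param planted Optional tibble with columns `position`,
#'   `ingroup_residue`, `outgroup_residues` (string of allowed out-group
#'   letters, disjoint from `ingroup_residue`).
#' @param background Per-site, per-sequence background substitution
#'   probability (default 0.05).
#' @param gap_rate Optional per-site gap-injection probability applied to
#'   non-planted positions of non-reference rows, to exercise gap handling
#'   (default 0).
#' @param seed Integer seed; identical seeds give identical families.
#' @return A `family_config` list.
#' @export
family_config <- function(length = 341, n_ingroup = 2, n_outgroup = 6,
                          n_planted = 11, planted = NULL, background = 0.05,
                          gap_rate = 0, seed = 1) {
  if (background < 0 || background > 1 || gap_rate < 0 || gap_rate > 1) {
    abort_config("probabilities must be in [0, 1]")
  }
  if (!is.null(planted)) {
    if (anyDuplicated(planted$position) ||
        any(planted$position < 1 | planted$position > length)) {
      abort_config("planted positions must be distinct and within 1..L")
    }
    for (i in seq_len(nrow(planted))) {
      outs <- strsplit(planted$outgroup_residues[i], "")[[1]]
      if (planted$ingroup_residue[i] %in% outs) {
        abort_config(sprintf(
          "planted in-group residue '%s' at position %d also in out-group set",
          planted$ingroup_residue[i], planted$position[i]
        ))
      }
    }
  }
  structure(
    list(length = length, n_ingroup = n_ingroup, n_outgroup = n_outgroup,
         n_planted = n_planted, planted = planted, background = background,
         gap_rate = gap_rate, seed = seed),
    class = "family_config"
  )
}

aa20 <- function() setdiff(aa_alphabet(), "X")

#' Generate a synthetic protein family with planted diagnostic residues
#'
#' A root sequence is drawn uniformly over the 20 canonical letters; each
#' group member is derived by independent background substitutions, after
#' which planted positions are overwritten with the designated in-group /
#' out-group residues. The returned alignment is gapless (all rows equal
#' length) unless `gap_rate > 0`.
#'
#' @param cfg A [family_config()].
#' @return List with `records` (sequence tibble; in-group rows are tagged
#'   habitat `"marine"`, out-group rows `"freshwater"`), `msa`, and `truth`
#'   (planted-position tibble, in-group ids, root sequence).
#' @export
generate_family <- function(cfg) {
  set.seed(cfg$seed)
  alphabet <- aa20()
  planted <- cfg$planted
  if (is.null(planted)) {
    pos <- sort(sample.int(cfg$length, cfg$n_planted))
    planted <- tibble::tibble(
      position = pos,
      ingroup_residue = sample(alphabet, cfg$n_planted, replace = TRUE),
      outgroup_residues = vapply(seq_len(cfg$n_planted), function(i) {
        paste(sample(setdiff(alphabet, sample(alphabet, 1)), 2), collapse = "")
      }, character(1))
    )
    # regenerate any out-group set that collides with its in-group residue
    for (i in seq_len(nrow(planted))) {
      outs <- strsplit(planted$outgroup_residues[i], "")[[1]]
      outs <- setdiff(outs, planted$ingroup_residue[i])
      if (length(outs) == 0) {
        outs <- sample(setdiff(alphabet, planted$ingroup_residue[i]), 2)
      }
      planted$outgroup_residues[i] <- paste(outs, collapse = "")
    }
  }
  root <- sample(alphabet, cfg$length, replace = TRUE)
  ids <- c(paste0("marine", seq_len(cfg$n_ingroup)),
           paste0("fresh", seq_len(cfg$n_outgroup)))
  ingroup_ids <- ids[seq_len(cfg$n_ingroup)]
  habitat <- c(rep("marine", cfg$n_ingroup), rep("freshwater", cfg$n_outgroup))

  seqs <- vapply(seq_along(ids), function(i) {
    s <- root
    mutate_site <- stats::runif(cfg$length) < cfg$background
    if (any(mutate_site)) {
      s[mutate_site] <- vapply(s[mutate_site], function(old) {
        sample(setdiff(alphabet, old), 1)
      }, character(1))
    }
    for (p in seq_len(nrow(planted))) {
      at <- planted$position[p]
      if (i <= cfg$n_ingroup) {
        s[at] <- planted$ingroup_residue[p]
      } else {
        outs <- strsplit(planted$outgroup_residues[p], "")[[1]]
        s[at] <- if (length(outs) == 1) outs else sample(outs, 1)
      }
    }
    paste(s, collapse = "")
  }, character(1))

  aligned <- seqs
  if (cfg$gap_rate > 0) {
    for (i in seq_along(aligned)[-1]) {
      s <- strsplit(aligned[i], "")[[1]]
      gap_site <- stats::runif(cfg$length) < cfg$gap_rate
      gap_site[planted$position] <- FALSE
      s[gap_site] <- "-"
      aligned[i] <- paste(s, collapse = "")
    }
  }
  names(aligned) <- ids
  msa <- new_msa(aligned)
  records <- new_sequence_records(
    id = ids, description = "synthetic AAR-like sequence",
    residues = vapply(ids, function(id) ungap_row(msa, id), character(1)),
    habitat = habitat
  )
  list(
    records = records,
    msa = msa,
    truth = list(planted = planted, ingroup_ids = ingroup_ids,
                 root = paste(root, collapse = ""))
  )
}

#' Habitat-dependent product-fraction means
#'
#' Defaults: marine-like enzymes centered at (0.75, 0.20, 0.05) for
#' (C15:0, C17:1, C17:0) — a predominantly 16-carbon-substrate profile —
#' and freshwater-like at (0.15, 0.77, 0.08), where pentadecane is ~20% of
#' heptadecene.
#'
#' @return Named list of fraction triples summing to 1.
#' @export
default_fraction_means <- function() {
  list(
    marine = c(amount_c15 = 0.75, amount_c17_1 = 0.20, amount_c17_0 = 0.05),
    freshwater = c(amount_c15 = 0.15, amount_c17_1 = 0.77, amount_c17_0 = 0.08)
  )
}

#' Random per-variant ground truth for the measurement generator
#'
#' Activities and expression levels are lognormally dispersed around the
#' reference; solubility is uniform on 5-50% (aggregation-prone enzymes).
#'
#' @param n_variants Number of non-reference variants.
#' @param reference_id Id of the reference variant (true values all 1, except
#'   solubility 0.4).
#' @param p_marine Probability a variant is marine-like.
#' @param sdlog_activity,sdlog_expression Lognormal sdlog of true activity
#'   and expression ratios.
#' @param seed Integer seed.
#' @return Tibble with columns `variant_id`, `habitat`, `true_activity`,
#'   `true_expression`, `true_solubility`, `detected`.
#' @export
random_variant_truth <- function(n_variants, reference_id = "ref",
                                 p_marine = 0.5, sdlog_activity = 1,
                                 sdlog_expression = 0.5, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    variant_id = c(reference_id, paste0("v", seq_len(n_variants))),
    habitat = c("freshwater",
                ifelse(stats::runif(n_variants) < p_marine,
                       "marine", "freshwater")),
    true_activity = c(1, stats::rlnorm(n_variants, 0, sdlog_activity)),
    true_expression = c(1, stats::rlnorm(n_variants, 0, sdlog_expression)),
    true_solubility = c(0.4, stats::runif(n_variants, 0.05, 0.5)),
    detected = TRUE
  )
}

#' Configuration for the synthetic measurement generator
#'
#' @param variants Per-variant truth tibble ([random_variant_truth()] or
#'   hand-built), columns `variant_id`, `habitat`, `true_activity`,
#'   `true_expression`, `true_solubility`, `detected`.
#' @param reference_id Which variant is the normalization reference.
#' @param fraction_means Habitat-indexed fraction triples
#'   ([default_fraction_means()]).
#' @param dirichlet_conc Dirichlet concentration for replicate fraction draws
#'   (default 100; `Inf` = no fraction noise).
#' @param cv Lognormal coefficient of variation of band volumes and amounts
#'   (default 0.1; 0 = noise-free).
#' @param n_replicates Replicates per variant (default 3).
#' @param seed Integer seed.
#' @return A `measurement_config` list.
#' @export
measurement_config <- function(variants, reference_id = variants$variant_id[1],
                               fraction_means = default_fraction_means(),
                               dirichlet_conc = 100, cv = 0.1,
                               n_replicates = 3, seed = 1) {
  if (cv < 0) abort_config("cv must be >= 0")
  if (n_replicates < 1) abort_config("need at least 1 replicate")
  if (!reference_id %in% variants$variant_id) {
    abort_config("reference_id must be among the variants")
  }
  sums <- vapply(fraction_means, sum, numeric(1))
  if (any(abs(sums - 1) > 1e-9)) {
    abort_config("fraction means must each sum to 1")
  }
  if (any(!variants$habitat %in% names(fraction_means))) {
    abort_config("every variant habitat needs an entry in fraction_means")
  }
  structure(
    list(variants = variants, reference_id = reference_id,
         fraction_means = fraction_means, dirichlet_conc = dirichlet_conc,
         cv = cv, n_replicates = n_replicates, seed = seed),
    class = "measurement_config"
  )
}

# unit-mean lognormal multiplicative noise with the given CV
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Dirichlet draw around `mean` with concentration `conc` (gamma construction);
# conc = Inf returns the mean exactly
rdirichlet_mean <- function(mean, conc) {
  if (!is.finite(conc)) return(mean)
  g <- stats::rgamma(length(mean), shape = mean * conc, rate = 1)
  if (sum(g) == 0) return(mean)
  stats::setNames(g / sum(g), names(mean))
}

#' Generate synthetic hydrocarbon and blot tables
#'
#' Per replicate: soluble volume = expression x solubility x lognormal(CV);
#' insoluble volume = expression x (1 - solubility) x lognormal(CV);
#' total hydrocarbons = activity x expression x solubility x lognormal(CV),
#' split across analytes by a Dirichlet draw around the variant's habitat
#' fraction mean. Variants flagged `detected = FALSE` emit
#' `soluble_detected = FALSE` rows (below the blot detection limit).
#'
#' @param cfg A [measurement_config()].
#' @return List with `hydro` and `blot` tables (ready for
#'   [assemble_profiles()]) and `truth` (the variants tibble plus each
#'   variant's true fraction triple).
#' @export
generate_measurements <- function(cfg) {
  set.seed(cfg$seed)
  v <- cfg$variants
  hydro_rows <- list()
  blot_rows <- list()
  true_fracs <- list()
  for (i in seq_len(nrow(v))) {
    mean_frac <- cfg$fraction_means[[v$habitat[i]]]
    true_fracs[[i]] <- mean_frac
    for (rep_i in seq_len(cfg$n_replicates)) {
      sol_truth <- v$true_expression[i] * v$true_solubility[i]
      soluble <- sol_truth * rlnorm_cv(1, cfg$cv)
      insoluble <- v$true_expression[i] * (1 - v$true_solubility[i]) *
        rlnorm_cv(1, cfg$cv)
      total <- v$true_activity[i] * sol_truth * rlnorm_cv(1, cfg$cv)
      fr <- rdirichlet_mean(mean_frac, cfg$dirichlet_conc)
      amounts <- total * fr
      hydro_rows[[length(hydro_rows) + 1]] <- tibble::tibble(
        variant_id = v$variant_id[i], replicate = rep_i,
        amount_c15 = amounts[["amount_c15"]],
        amount_c17_1 = amounts[["amount_c17_1"]],
        amount_c17_0 = amounts[["amount_c17_0"]]
      )
      blot_rows[[length(blot_rows) + 1]] <- tibble::tibble(
        variant_id = v$variant_id[i], replicate = rep_i,
        soluble_volume = if (v$detected[i]) soluble else NA_real_,
        insoluble_volume = insoluble,
        soluble_detected = v$detected[i],
        insoluble_detected = TRUE
      )
    }
  }
  truth <- v
  truth$true_fractions <- true_fracs
  list(
    hydro = validate_hydro_table(dplyr::bind_rows(hydro_rows)),
    blot = validate_blot_table(dplyr::bind_rows(blot_rows)),
    truth = truth
  )
}

#' Deterministic high-leverage correlation fixture
#'
#' Ten base points whose property is an exactly symmetric function of
#' identity (sample correlation exactly 0 by construction) plus one
#' high-leverage point at `leverage_identity`, so the full-data correlation
#' is strong while dropping the leverage point leaves none.
#'
#' @param leverage_identity,leverage_property Coordinates of the leverage
#'   point (defaults 100, 10).
#' @return Tibble with columns `id`, `identity`, `property`; the leverage
#'   point has id `"leverage"`.
#' @export
leverage_fixture <- function(leverage_identity = 100, leverage_property = 10) {
  identity <- seq(55, 73, by = 2)   # ortholog-like identity spread
  property <- ((identity - mean(identity)) / 20)^2
  tibble::tibble(
    id = c(paste0("base", seq_along(identity)), "leverage"),
    identity = c(identity, leverage_identity),
    property = c(property, leverage_property)
  )
}

#' Write a synthetic dataset to disk in the pipeline's input dialects
#'
#' @param family Output of [generate_family()].
#' @param measurements Output of [generate_measurements()].
#' @param dir Output directory (created if needed).
#' @return Named vector of written paths, invisibly.
#' @export
write_synthetic_dataset <- function(family, measurements, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    fasta = file.path(dir, "sequences.fasta"),
    msa = file.path(dir, "alignment.fasta"),
    habitat = file.path(dir, "habitat.tsv"),
    hydro = file.path(dir, "hydrocarbons.tsv"),
    blot = file.path(dir, "blot.tsv"),
    truth = file.path(dir, "ground_truth.json")
  )
  write_fasta(family$records, paths[["fasta"]])
  write_alignment(family$msa, paths[["msa"]])
  write_habitat_table(
    stats::setNames(family$records$habitat, family$records$id),
    paths[["habitat"]]
  )
  readr::write_tsv(measurements$hydro, paths[["hydro"]])
  readr::write_tsv(measurements$blot, paths[["blot"]])
  truth <- list(
    planted = family$truth$planted,
    ingroup_ids = family$truth$ingroup_ids,
    variants = measurements$truth[
      setdiff(names(measurements$truth), "true_fractions")
    ]
  )
  jsonlite::write_json(truth, paths[["truth"]], dataframe = "rows",
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
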