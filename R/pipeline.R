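# End-to-end orchestration: one YAML config drives every stage in
# dependency order, writing plain-text reports into an output directory.
# All floating-point report values are written with 6 significant digits.

#' Read and validate a pipeline configuration
#'
#' The config is a YAML mapping with (all optional unless a stage needs
#' them): `sequences`, `msa`, `msa_format`, `habitat`, `hydro`, `blot` input
#' paths; `reference_id`; `scoring: {matrix, gap_open, gap_extend}`;
#' `tree: {k, correction}`; `scan: {ingroup, mode, max_outgroup_matches,
#' target}`; `correlate: {property, drop_id}`; `simulate:` (arguments of
#' [family_config()], [random_variant_truth()] and [measurement_config()]);
#' `output_dir`; `seed`.
#'
#' @param path Path to a YAML file, or a list with the same structure.
#' @return Validated config list.
#' @export
read_pipeline_config <- function(path) {
  config <- if (is.list(path)) path else yaml::read_yaml(path)
  config$output_dir <- config$output_dir %||% "aartools-output"
  config$seed <- config$seed %||% 1L
  for (field in c("sequences", "msa", "habitat", "hydro", "blot")) {
    p <- config[[field]]
    if (!is.null(p) && !file.exists(p)) {
      abort_config(sprintf("config field '%s': file not found: %s", field, p))
    }
  }
  config
}

require_field <- function(config, field) {
  value <- config[[field]]
  if (is.null(value)) {
    abort_config(paste0("config field required for this stage: ", field))
  }
  value
}

pipeline_log <- function(config, stage, message) {
  line <- sprintf("[aartools %s] %s: %s",
                  as.character(utils::packageVersion("aartools")),
                  stage, message)
  message(line)
  log_path <- file.path(config$output_dir, "pipeline.log")
  if (dir.exists(config$output_dir)) {
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
  }
  invisible(line)
}

init_stage <- function(config, stage) {
  config <- read_pipeline_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  pipeline_log(config, stage, sprintf("seed %d", config$seed))
  config
}

config_scheme <- function(config) {
  s <- config$scoring %||% list()
  scoring_scheme(
    matrix = s$matrix %||% "BLOSUM62",
    gap_open = s$gap_open %||% 11,
    gap_extend = s$gap_extend %||% 1
  )
}

fmt6 <- function(x) signif(x, 6)

load_config_identity <- function(config) {
  if (!is.null(config$sequences)) {
    identity_matrix(read_fasta(config$sequences), config_scheme(config))
  } else if (!is.null(config$msa)) {
    msa_identity_matrix(
      read_alignment(config$msa, config$msa_format %||% "fasta")
    )
  } else {
    abort_config("config needs 'sequences' or 'msa' for identity analysis")
  }
}

#' Run the identity stage: percent-identity matrix and distances
#' @param config Config path or list (see [read_pipeline_config()]).
#' @return Identity matrix, invisibly; writes `identity.tsv` and
#'   `distance.phylip`.
#' @export
run_identity <- function(config) {
  config <- init_stage(config, "identity")
  m <- load_config_identity(config)
  write_identity_tsv(fmt6(m), file.path(config$output_dir, "identity.tsv"))
  d <- to_distance(m, (config$tree %||% list())$correction %||% "none")
  write_phylip_dist(d, file.path(config$output_dir, "distance.phylip"))
  pipeline_log(config, "identity",
               sprintf("%d sequences, off-diagonal identity %.1f-%.1f%%",
                       nrow(m), min(m[upper.tri(m)]), max(m[upper.tri(m)])))
  invisible(m)
}

#' Run the tree stage: NJ tree, clade groups, habitat summary
#' @param config Config path or list.
#' @return The `phylo` tree, invisibly; writes `tree.nwk`, `groups.tsv`,
#'   `habitat_summary.tsv`.
#' @export
run_tree <- function(config) {
  config <- init_stage(config, "tree")
  m <- load_config_identity(config)
  tree_cfg <- config$tree %||% list()
  d <- to_distance(m, tree_cfg$correction %||% "none")
  tree <- neighbor_joining(d)
  writeLines(write_newick(tree), file.path(config$output_dir, "tree.nwk"))
  k <- tree_cfg$k %||% 3
  groups <- clade_groups(tree, k = min(k, length(tree$tip.label)))
  readr::write_tsv(groups, file.path(config$output_dir, "groups.tsv"))
  habitat <- if (!is.null(config$habitat)) {
    read_habitat_table(config$habitat)
  } else {
    stats::setNames(rep("unknown", nrow(groups)), groups$id)
  }
  hs <- habitat_summary(groups, habitat)
  hs$fraction <- fmt6(hs$fraction)
  readr::write_tsv(hs, file.path(config$output_dir, "habitat_summary.tsv"))
  pipeline_log(config, "tree", sprintf("%d leaves cut into %d groups",
                                       length(tree$tip.label), k))
  invisible(tree)
}

#' Run the quantification stage: per-variant activity profiles
#' @param config Config path or list.
#' @return Profile tibble, invisibly; writes `profiles.tsv` / `profiles.json`.
#' @export
run_quantify <- function(config) {
  config <- init_stage(config, "quantify")
  hydro <- read_hydro_table(require_field(config, "hydro"))
  blot <- read_blot_table(require_field(config, "blot"))
  profiles <- assemble_profiles(hydro, blot,
                                require_field(config, "reference_id"))
  out <- dplyr::mutate(profiles,
                       dplyr::across(dplyr::where(is.numeric), fmt6))
  write_profiles(out, file.path(config$output_dir, "profiles"))
  pipeline_log(config, "quantify",
               sprintf("%d variants quantified", nrow(profiles)))
  invisible(profiles)
}

#' Run the residue-scan stage: discriminating positions and proposals
#' @param config Config path or list.
#' @return Scan tibble, invisibly; writes `scan.tsv` and `mutations.tsv`.
#' @export
run_scan <- function(config) {
  config <- init_stage(config, "scan")
  msa <- read_alignment(require_field(config, "msa"),
                        config$msa_format %||% "fasta")
  scan_cfg <- config$scan %||% list()
  ingroup <- scan_cfg$ingroup
  if (is.null(ingroup)) abort_config("config field required: scan.ingroup")
  spec <- group_spec(
    ingroup_ids = ingroup,
    mode = scan_cfg$mode %||% "strict",
    max_outgroup_matches = scan_cfg$max_outgroup_matches %||% 0
  )
  refmap <- build_reference_map(msa, require_field(config, "reference_id"))
  positions <- scan_positions(msa, spec, refmap)
  write_scan_tsv(positions, file.path(config$output_dir, "scan.tsv"))
  target <- scan_cfg$target
  if (!is.null(target)) {
    proposals <- propose_mutations(positions, target, msa, spec)
    readr::write_tsv(proposals, file.path(config$output_dir, "mutations.tsv"))
  }
  pipeline_log(config, "scan",
               sprintf("%d discriminating positions (%s mode)",
                       nrow(positions), spec$mode))
  invisible(positions)
}

#' Run the correlation stage: property vs identity with leave-one-out
#' @param config Config path or list.
#' @return Result list, invisibly; writes `correlation.tsv` and
#'   `correlation_points.tsv`.
#' @export
run_correlate <- function(config) {
  config <- init_stage(config, "correlate")
  hydro <- read_hydro_table(require_field(config, "hydro"))
  blot <- read_blot_table(require_field(config, "blot"))
  reference_id <- require_field(config, "reference_id")
  profiles <- assemble_profiles(hydro, blot, reference_id)
  m <- load_config_identity(config)
  cor_cfg <- config$correlate %||% list()
  property <- cor_cfg$property %||% "relative_activity"
  pv <- property_identity_table(profiles, property, m, reference_id)
  drop_id <- cor_cfg$drop_id %||% pv$id[which.max(pv$identity)]
  res <- leave_one_out(pv, drop_id, n_perm = cor_cfg$n_perm %||% 0)
  readr::write_tsv(dplyr::mutate(pv, identity = fmt6(.data$identity),
                                 property = fmt6(.data$property)),
                   file.path(config$output_dir, "correlation_points.tsv"))
  summary <- tibble::tibble(
    property = property, reference_id = reference_id, drop_id = drop_id,
    r_full = fmt6(res$r_full), r_dropped = fmt6(res$r_dropped),
    n_full = res$n_full, n_dropped = res$n_dropped
  )
  if (!is.null(res$p_perm)) summary$p_perm <- fmt6(res$p_perm)
  readr::write_tsv(summary, file.path(config$output_dir, "correlation.tsv"))
  pipeline_log(config, "correlate",
               sprintf("%s: r_full %.3f, r without %s %.3f",
                       property, res$r_full, drop_id, res$r_dropped))
  invisible(res)
}

#' Run the simulation stage: synthetic dataset with ground truth
#' @param config Config path or list; `simulate:` subfields override
#'   generator defaults.
#' @return Written paths, invisibly (under `<output_dir>/synthetic/`).
#' @export
run_simulate <- function(config) {
  config <- init_stage(config, "simulate")
  sim <- config$simulate %||% list()
  fam_cfg <- family_config(
    length = sim$length %||% 341,
    n_ingroup = sim$n_ingroup %||% 2,
    n_outgroup = sim$n_outgroup %||% 6,
    n_planted = sim$n_planted %||% 11,
    background = sim$background %||% 0.05,
    seed = config$seed
  )
  family <- generate_family(fam_cfg)
  truth <- random_variant_truth(
    n_variants = nrow(family$records) - 1,
    reference_id = family$records$id[1],
    seed = config$seed
  )
  truth$variant_id <- family$records$id
  truth$habitat <- family$records$habitat
  meas_cfg <- measurement_config(
    variants = truth,
    reference_id = family$records$id[1],
    cv = sim$cv %||% 0.1,
    n_replicates = sim$n_replicates %||% 3,
    dirichlet_conc = sim$dirichlet_conc %||% 100,
    seed = config$seed
  )
  measurements <- generate_measurements(meas_cfg)
  paths <- write_synthetic_dataset(family, measurements,
                                   file.path(config$output_dir, "synthetic"))
  pipeline_log(config, "simulate",
               sprintf("%d sequences, %d planted positions",
                       nrow(family$records), nrow(family$truth$planted)))
  invisible(paths)
}

#' Run every stage in dependency order
#'
#' When the config has no measured inputs, a synthetic dataset is generated
#' first and the remaining stages run on it.
#'
#' @param config Config path or list.
#' @return Named list of stage results, invisibly.
#' @export
run_all <- function(config) {
  config <- read_pipeline_config(config)
  if (is.null(config$sequences) && is.null(config$msa)) {
    paths <- run_simulate(config)
    config$msa <- paths[["msa"]]
    config$msa_format <- "fasta"
    config$habitat <- paths[["habitat"]]
    config$hydro <- paths[["hydro"]]
    config$blot <- paths[["blot"]]
    truth <- jsonlite::read_json(paths[["truth"]])
    config$reference_id <- config$reference_id %||%
      truth$variants[[1]]$variant_id
    if (is.null(config$scan)) {
      config$scan <- list(
        ingroup = vapply(truth$ingroup_ids, identity, character(1)),
        mode = "strict",
        target = truth$variants[[length(truth$variants)]]$variant_id
      )
    }
  }
  results <- list(
    identity = run_identity(config),
    tree = run_tree(config),
    quantify = run_quantify(config),
    scan = run_scan(config),
    correlate = run_correlate(config)
  )
  pipeline_log(config, "all", "pipeline complete")
  invisible(results)
}
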