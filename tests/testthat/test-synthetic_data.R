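test_that("family generation is seed-deterministic", {
  cfg <- family_config(seed = 12)
  a <- generate_family(cfg)
  b <- generate_family(cfg)
  expect_identical(unclass(a$msa), unclass(b$msa))
  expect_identical(a$truth$planted, b$truth$planted)
  c_ <- generate_family(family_config(seed = 13))
  expect_false(identical(unclass(a$msa), unclass(c_$msa)))
})

test_that("zero background leaves within-group rows identical off-plant", {
  fam <- generate_family(family_config(length = 60, n_planted = 4,
                                       background = 0, seed = 4))
  chars <- msa_matrix(fam$msa)
  planted <- fam$truth$planted$position
  off <- setdiff(seq_len(ncol(chars)), planted)
  for (col in off) {
    expect_equal(length(unique(chars[, col])), 1)
  }
  # in-group rows agree everywhere (planted residue is shared too)
  ingroup <- fam$truth$ingroup_ids
  expect_equal(unclass(fam$msa)[[ingroup[1]]], unclass(fam$msa)[[ingroup[2]]])
})

test_that("planted positions carry the designated residues", {
  planted <- tibble::tibble(
    position = c(5L, 20L, 33L),
    ingroup_residue = c("R", "S", "A"),
    outgroup_residues = c("QK", "T", "VG")
  )
  fam <- generate_family(family_config(length = 40, planted = planted,
                                       background = 0.05, seed = 9))
  chars <- msa_matrix(fam$msa)
  for (p in seq_len(nrow(planted))) {
    col <- chars[, planted$position[p]]
    expect_true(all(col[fam$truth$ingroup_ids] == planted$ingroup_residue[p]))
    outs <- strsplit(planted$outgroup_residues[p], "")[[1]]
    out_ids <- setdiff(names(fam$msa), fam$truth$ingroup_ids)
    expect_true(all(col[out_ids] %in% outs))
  }
})

test_that("planted/out-group residue collisions are config errors", {
  bad <- tibble::tibble(position = 3L, ingroup_residue = "R",
                        outgroup_residues = "RK")
  expect_error(family_config(length = 10, planted = bad),
               class = "aartools_config_error")
  dup <- tibble::tibble(position = c(3L, 3L), ingroup_residue = c("R", "S"),
                        outgroup_residues = c("K", "T"))
  expect_error(family_config(length = 10, planted = dup),
               class = "aartools_config_error")
})

test_that("strict scan recovers exactly the planted positions at background 0", {
  fam <- generate_family(family_config(background = 0, seed = 21))
  refmap <- build_reference_map(fam$msa, names(fam$msa)[1])
  hits <- scan_strict(fam$msa, group_spec(fam$truth$ingroup_ids, "strict"),
                      refmap)
  expect_equal(hits$ref_position, fam$truth$planted$position)
})

test_that("gap injection still yields a valid alignment and reference map", {
  fam <- generate_family(family_config(length = 80, gap_rate = 0.05,
                                       background = 0.05, seed = 31))
  expect_s3_class(fam$msa, "aar_msa")
  rm_ <- build_reference_map(fam$msa, names(fam$msa)[1])
  expect_equal(sum(!is.na(rm_$column_to_residue)),
               nchar(ungap_row(fam$msa, names(fam$msa)[1])))
})

test_that("noise-free measurements reproduce ground truth exactly", {
  truth <- random_variant_truth(5, seed = 8)
  cfg <- measurement_config(truth, cv = 0, dirichlet_conc = Inf, seed = 8)
  gm <- generate_measurements(cfg)
  profiles <- assemble_profiles(gm$hydro, gm$blot, "ref")
  ord <- match(truth$variant_id, profiles$variant_id)
  expect_equal(profiles$relative_activity[ord], truth$true_activity)
  expect_equal(profiles$relative_expression[ord], truth$true_expression)
  expect_equal(profiles$solubility_pct[ord], 100 * truth$true_solubility)
  for (i in seq_len(nrow(truth))) {
    mean_frac <- default_fraction_means()[[truth$habitat[i]]]
    row <- profiles[profiles$variant_id == truth$variant_id[i], ]
    expect_equal(unlist(row[c("f_c15", "f_c17_1", "f_c17_0")]),
                 setNames(unname(mean_frac), c("f_c15", "f_c17_1", "f_c17_0")))
  }
})

test_that("below-detection variants propagate to not-determined activity", {
  truth <- random_variant_truth(3, seed = 14)
  truth$detected[truth$variant_id == "v2"] <- FALSE
  gm <- generate_measurements(measurement_config(truth, cv = 0,
                                                 dirichlet_conc = Inf,
                                                 seed = 14))
  expect_true(all(!gm$blot$soluble_detected[gm$blot$variant_id == "v2"]))
  profiles <- assemble_profiles(gm$hydro, gm$blot, "ref")
  expect_true(is.na(profiles$relative_activity[profiles$variant_id == "v2"]))
  expect_false(anyNA(profiles$relative_activity[profiles$variant_id != "v2"]))
})

test_that("generated tables satisfy the quantification input invariants", {
  truth <- random_variant_truth(10, seed = 2)
  gm <- generate_measurements(measurement_config(truth, seed = 2))
  expect_true(all(gm$hydro$amount_c15 >= 0))
  expect_false(any(duplicated(gm$hydro[c("variant_id", "replicate")])))
  expect_false(any(duplicated(gm$blot[c("variant_id", "replicate")])))
  expect_equal(nrow(gm$hydro), 11 * 3)
})

test_that("recovered fractions converge on habitat means over many variants", {
  truth <- random_variant_truth(60, p_marine = 0.5, seed = 44)
  gm <- generate_measurements(measurement_config(truth, cv = 0.1,
                                                 dirichlet_conc = 100,
                                                 n_replicates = 3, seed = 44))
  profiles <- assemble_profiles(gm$hydro, gm$blot, "ref")
  merged <- dplyr::left_join(profiles, truth, by = "variant_id")
  marine_mean <- mean(merged$f_c15[merged$habitat == "marine"])
  fresh_mean <- mean(merged$f_c15[merged$habitat == "freshwater"])
  expect_equal(marine_mean, 0.75, tolerance = 0.05)
  expect_equal(fresh_mean, 0.15, tolerance = 0.25)
})

test_that("synthetic dataset files are readable by the pipeline readers", {
  fam <- generate_family(family_config(length = 50, n_planted = 3, seed = 6))
  truth <- random_variant_truth(nrow(fam$records) - 1,
                                reference_id = fam$records$id[1], seed = 6)
  truth$variant_id <- fam$records$id
  truth$habitat <- fam$records$habitat
  gm <- generate_measurements(measurement_config(truth, seed = 6))
  dir <- tempfile()
  paths <- write_synthetic_dataset(fam, gm, dir)
  expect_equal(read_fasta(paths[["fasta"]])$residues, fam$records$residues)
  msa_back <- read_alignment(paths[["msa"]])
  expect_equal(unclass(msa_back), unclass(fam$msa))
  expect_equal(unname(read_habitat_table(paths[["habitat"]])[fam$records$id]),
               fam$records$habitat)
  expect_equal(nrow(read_hydro_table(paths[["hydro"]])), nrow(gm$hydro))
  truth_back <- jsonlite::read_json(paths[["truth"]])
  expect_equal(length(truth_back$planted), nrow(fam$truth$planted))
})
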