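toy_msa <- function() {
  # columns:        123456
  new_msa(c(
    s1 = "MRKLVA",
    s2 = "MRKIVA",
    s3 = "MQKLTA",
    s4 = "MKKLTA"
  ))
}

test_that("strict scan reports in-group-conserved, out-group-absent columns", {
  msa <- toy_msa()
  refmap <- build_reference_map(msa, "s1")
  spec <- group_spec(c("s1", "s2"), "strict")
  hits <- scan_strict(msa, spec, refmap)
  # col 2: ingroup R/R, outgroup Q,K -> hit; col 5: V/V vs T,T -> hit
  # col 1,3,6 fully conserved -> excluded; col 4 ingroup L vs I disagrees
  expect_equal(hits$ref_position, c(2L, 5L))
  expect_equal(hits$ingroup_residues, c("R", "V"))
  expect_equal(hits$outgroup_residues, c("KQ", "T"))
  expect_equal(hits$criterion, c("strict", "strict"))
})

test_that("strict scan tolerance admits partial out-group matches", {
  msa <- new_msa(c(a = "R", b = "R", c = "R", d = "K"))
  refmap <- build_reference_map(msa, "a")
  strict0 <- scan_strict(msa, group_spec(c("a", "b"), "strict"), refmap)
  expect_equal(nrow(strict0), 0)   # one out-group R exceeds 0
  strict1 <- scan_strict(
    msa, group_spec(c("a", "b"), "strict", max_outgroup_matches = 1), refmap
  )
  expect_equal(strict1$ref_position, 1L)
})

test_that("in-group gaps or X disqualify; reference gaps are unnumberable", {
  msa <- new_msa(c(g1 = "M-RA", g2 = "MKRA", g3 = "MQDA", g4 = "MQEA"))
  refmap <- build_reference_map(msa, "g1")
  spec <- group_spec(c("g1", "g2"), "strict")
  hits <- scan_strict(msa, spec, refmap)
  # col 2 has an in-group gap -> excluded even though g2 has K
  # col 3: R/R vs D,E -> hit, numberable (ref non-gap), position 2 in g1
  expect_equal(hits$ref_position, 2L)
  expect_equal(hits$column, 3L)

  msa_x <- new_msa(c(g1 = "XA", g2 = "XA", g3 = "RA", g4 = "KA"))
  rm_x <- build_reference_map(msa_x, "g1")
  expect_equal(nrow(scan_strict(msa_x, group_spec(c("g1", "g2"), "strict"),
                                rm_x)), 0)

  # column that is a gap in the reference: reported but flagged unnumberable
  msa_g <- new_msa(c(ref = "M-A", in2 = "MRA", o1 = "MKT", o2 = "MQT"))
  rm_g <- build_reference_map(msa_g, "ref")
  hits_g <- scan_strict(msa_g, group_spec(c("ref", "in2"), "strict"), rm_g)
  expect_equal(nrow(hits_g), 1)
  expect_equal(hits_g$column, 3L)
  expect_equal(hits_g$ref_position, 2L)
})

test_that("similarity scan uses Clustal strong groups against the out-group", {
  # in-group I,V share MILV; out-group D,E do not -> reported
  msa <- new_msa(c(a = "I", b = "V", c = "D", d = "E"))
  refmap <- build_reference_map(msa, "a")
  spec <- group_spec(c("a", "b"), "similarity")
  expect_equal(nrow(scan_similarity(msa, spec, refmap)), 1)
  # in-group I,D share no class -> not reported
  msa2 <- new_msa(c(a = "I", b = "D", c = "D", d = "E"))
  expect_equal(nrow(scan_similarity(msa2, spec, build_reference_map(msa2, "a"))),
               0)
  # out-group M,L also in MILV -> not reported
  msa3 <- new_msa(c(a = "I", b = "V", c = "M", d = "L"))
  expect_equal(nrow(scan_similarity(msa3, spec, build_reference_map(msa3, "a"))),
               0)
})

test_that("scan output is sorted, criterion-consistent, and oracle-verified", {
  set.seed(202)
  for (trial in 1:5) {
    fam <- generate_family(family_config(length = 120, n_planted = 6,
                                         background = 0.1,
                                         seed = 300 + trial))
    refmap <- build_reference_map(fam$msa, names(fam$msa)[1])
    spec <- group_spec(fam$truth$ingroup_ids, "strict")
    hits <- scan_strict(fam$msa, spec, refmap)
    expect_false(is.unsorted(hits$ref_position, strictly = TRUE))
    expect_equal(sort(hits$column),
                 oracle_strict_columns(fam$msa, fam$truth$ingroup_ids))
  }
})

test_that("duplicating an in-group member never changes the strict scan", {
  fam <- generate_family(family_config(length = 80, n_planted = 5,
                                       background = 0.08, seed = 77))
  msa <- fam$msa
  refmap <- build_reference_map(msa, names(msa)[1])
  base <- scan_strict(msa, group_spec(fam$truth$ingroup_ids, "strict"), refmap)
  dup_rows <- unclass(msa)
  dup_rows <- c(dup_rows, twin = unname(dup_rows[fam$truth$ingroup_ids[1]]))
  msa2 <- new_msa(dup_rows)
  refmap2 <- build_reference_map(msa2, names(msa)[1])
  spec2 <- group_spec(c(fam$truth$ingroup_ids, "twin"), "strict")
  extended <- scan_strict(msa2, spec2, refmap2)
  expect_equal(extended$column, base$column)
  expect_equal(extended$ingroup_residues, base$ingroup_residues)
})

test_that("in-group validation rejects missing ids and improper subsets", {
  msa <- toy_msa()
  refmap <- build_reference_map(msa, "s1")
  expect_error(scan_strict(msa, group_spec("nope", "strict"), refmap),
               class = "aartools_argument_error")
  expect_error(
    scan_strict(msa, group_spec(names(msa), "strict"), refmap),
    class = "aartools_argument_error"
  )
  expect_error(group_spec(character(0), "strict"),
               class = "aartools_argument_error")
})

test_that("mutation proposals name wild type, position, and consensus", {
  msa <- new_msa(c(
    ref    = "MQRLVA",
    in2    = "MQRIVA",
    target = "MKQLTA",
    other  = "MKELTA"
  ))
  refmap <- build_reference_map(msa, "ref")
  spec <- group_spec(c("ref", "in2"), "strict")
  hits <- scan_strict(msa, spec, refmap)
  props <- propose_mutations(hits, "target", msa, spec)
  expect_equal(props$label, c("K2Q", "Q3R", "T5V"))
  expect_true(all(grepl("^[A-Z][0-9]+[A-Z]$", props$label)))
  expect_equal(props$label[props$ref_position == 3], "Q3R")
  expect_equal(props$variant_id[props$ref_position == 3], "target_Q3R")
  # a target already matching consensus yields no proposal at that position
  msa2 <- new_msa(c(ref = "R", in2 = "R", target = "R", other = "K"))
  spec2 <- group_spec(c("ref", "in2"), "strict")
  hits2 <- scan_strict(msa2, spec2, build_reference_map(msa2, "ref"))
  expect_equal(nrow(propose_mutations(hits2, "target", msa2, spec2)), 0)
  # targets inside the in-group are rejected
  expect_error(propose_mutations(hits, "in2", msa, spec),
               class = "aartools_argument_error")
})

test_that("target gaps at a scanned position are skipped with a warning", {
  msa <- new_msa(c(ref = "MRA", in2 = "MRA", target = "M-A", other = "MKA"))
  spec <- group_spec(c("ref", "in2"), "strict")
  hits <- scan_strict(msa, spec, build_reference_map(msa, "ref"))
  expect_warning(
    props <- propose_mutations(hits, "target", msa, spec),
    "gap"
  )
  expect_true(all(props$skipped))
  expect_true(all(is.na(props$label)))
})
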