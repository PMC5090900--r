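test_that("distance transform inverts identity on the percent scale", {
  m <- matrix(c(100, 53, 53, 100), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  d <- to_distance(m)
  expect_equal(d["a", "b"], 47)
  expect_equal(diag(d), c(a = 0, b = 0))
  expect_true(isSymmetric(unname(d)))
  dp <- to_distance(m, "poisson")
  expect_equal(dp["a", "b"], -100 * log(0.53))
})

test_that("two-taxon tree splits the single distance equally", {
  d <- matrix(c(0, 6, 6, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  tree <- neighbor_joining(d)
  expect_setequal(tree$tip.label, c("A", "B"))
  expect_equal(sort(tree$edge.length), c(3, 3))
})

test_that("three-taxon pendant lengths match the closed-form three-point values", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- neighbor_joining(d)
  lens <- setNames(tree$edge.length, tree$tip.label[tree$edge[, 2]])
  expect_equal(lens[c("A", "B", "C")], c(A = 1, B = 1, C = 3))

  set.seed(5)
  for (i in 1:25) {
    ids <- c("A", "B", "C")
    dd <- matrix(0, 3, 3, dimnames = list(ids, ids))
    dd[upper.tri(dd)] <- runif(3, 1, 10)
    dd <- dd + t(dd)
    # closed-form pendant lengths, clamped at zero
    expected <- c(
      A = (dd[1, 2] + dd[1, 3] - dd[2, 3]) / 2,
      B = (dd[1, 2] + dd[2, 3] - dd[1, 3]) / 2,
      C = (dd[1, 3] + dd[2, 3] - dd[1, 2]) / 2
    )
    expected <- pmax(expected, 0)
    tree <- neighbor_joining(dd)
    lens <- setNames(tree$edge.length, tree$tip.label[tree$edge[, 2]])
    expect_equal(lens[ids], expected, tolerance = 1e-9)
  }
})

test_that("NJ recovers topology and path lengths from additive matrices", {
  set.seed(99)
  for (i in 1:40) {
    n <- sample(4:8, 1)
    gen <- random_additive_tree(n)
    tree <- neighbor_joining(gen$d)
    expect_setequal(tree$tip.label, rownames(gen$d))
    expect_equal(ape::dist.topo(ape::unroot(tree), ape::unroot(gen$tree)),
                 structure(0, names = NULL), ignore_attr = TRUE)
    expect_equal(tree_leaf_distances(tree), gen$d, tolerance = 1e-8)
  }
})

test_that("four-taxon NJ split agrees with the four-point-condition oracle", {
  set.seed(17)
  for (i in 1:30) {
    gen <- random_additive_tree(4)
    tree <- neighbor_joining(gen$d)
    expect_equal(nj_split_of(tree), four_point_split(gen$d))
  }
})

test_that("NJ agrees with an independent implementation on random matrices", {
  set.seed(23)
  for (i in 1:10) {
    n <- sample(4:7, 1)
    ids <- paste0("t", seq_len(n))
    d <- matrix(0, n, n, dimnames = list(ids, ids))
    d[upper.tri(d)] <- runif(n * (n - 1) / 2, 5, 50)
    d <- d + t(d)
    mine <- neighbor_joining(d)
    ref <- ape::nj(d)
    expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(ref)),
                 structure(0, names = NULL), ignore_attr = TRUE)
  }
})

test_that("asymmetric distance input is rejected", {
  d <- matrix(c(0, 1, 2, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(neighbor_joining(d), class = "aartools_argument_error")
})

test_that("newick round trips preserve topology, lengths, and spaced labels", {
  gen <- random_additive_tree(6)
  txt <- write_newick(gen$tree)
  back <- read_newick(text = txt)
  expect_equal(ape::dist.topo(back, gen$tree),
               structure(0, names = NULL), ignore_attr = TRUE)
  expect_equal(tree_leaf_distances(back), tree_leaf_distances(gen$tree),
               tolerance = 1e-9)

  spaced <- gen$tree
  spaced$tip.label[1] <- "Synechococcus sp. PCC 7336"
  txt2 <- write_newick(spaced)
  expect_match(txt2, "'Synechococcus sp. PCC 7336'", fixed = TRUE)
  back2 <- read_newick(text = txt2)
  expect_true("Synechococcus sp. PCC 7336" %in% back2$tip.label)
})

test_that("clade cutting removes the longest internal edges first", {
  # caterpillar with one long internal edge between {A,B} and {C,D}
  txt <- "((A:1,B:1):10,(C:1,D:1):10,E:1);"
  tree <- read_newick(text = txt)
  groups <- clade_groups(tree, k = 2)
  split <- split(groups$id, groups$group)
  expect_true(any(vapply(split, function(g) setequal(g, c("A", "B")),
                         logical(1))) ||
              any(vapply(split, function(g) setequal(g, c("C", "D", "E")),
                         logical(1))))
  expect_equal(length(unique(groups$group)), 2)

  expect_equal(unique(clade_groups(tree, k = 1)$group), "group1")
  singletons <- clade_groups(tree, k = 5)
  expect_equal(length(unique(singletons$group)), 5)
  expect_error(clade_groups(tree, k = 0), class = "aartools_argument_error")
  expect_error(clade_groups(tree, k = 6), class = "aartools_argument_error")
})

test_that("clade grouping is invariant to leaf-order permutation", {
  set.seed(31)
  gen <- random_additive_tree(7)
  g1 <- clade_groups(neighbor_joining(gen$d), k = 3)
  perm <- sample(nrow(gen$d))
  d2 <- gen$d[perm, perm]
  g2 <- clade_groups(neighbor_joining(d2), k = 3)
  partition <- function(g) {
    unname(lapply(split(g$id, g$group), sort))
  }
  expect_setequal(partition(g1), partition(g2))
})

test_that("habitat summaries count and normalize per group", {
  groups <- tibble::tibble(
    id = c("a", "b", "c", "d", "e", "f"),
    group = c("group1", "group1", "group1", "group1", "group2", "group2")
  )
  habitat <- c(a = "marine", b = "marine", c = "marine", d = "marine",
               e = "marine", f = "freshwater")
  hs <- habitat_summary(groups, habitat)
  g1_marine <- hs$fraction[hs$group == "group1" & hs$habitat == "marine"]
  expect_equal(g1_marine, 1.0)
  g2 <- hs[hs$group == "group2", ]
  expect_equal(g2$fraction[g2$habitat == "marine"], 0.5)
  expect_equal(g2$fraction[g2$habitat == "freshwater"], 0.5)

  # 'both' has its own category; optionally out of the fraction denominator
  habitat2 <- c(a = "marine", b = "freshwater", c = "both", d = "both",
                e = "marine", f = "marine")
  hs_incl <- habitat_summary(groups, habitat2, include_both = TRUE)
  g1 <- hs_incl[hs_incl$group == "group1", ]
  expect_equal(g1$n[g1$habitat == "both"], 2L)
  expect_equal(g1$fraction[g1$habitat == "marine"], 0.25)
  hs_excl <- habitat_summary(groups, habitat2, include_both = FALSE)
  g1x <- hs_excl[hs_excl$group == "group1", ]
  expect_equal(g1x$fraction[g1x$habitat == "marine"], 0.5)
  expect_true(is.na(g1x$fraction[g1x$habitat == "both"]))
  # labeled fractions sum to 1 per group
  sums <- tapply(hs_incl$fraction, hs_incl$group, sum, na.rm = TRUE)
  expect_equal(as.numeric(sums), c(1, 1))
})
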