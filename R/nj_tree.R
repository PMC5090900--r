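# Neighbor-joining tree from identity-derived distances, clade grouping,
# and habitat composition summaries.
#
# Distances are the linear transform 100 - percent identity (a p-distance on
# the percent scale); no multiple-hit correction is applied by default since
# the tree is used for grouping, not for divergence-time inference. Trees are
# `ape::phylo` objects, unrooted with a trifurcating root node.

#' Convert an identity matrix to a distance matrix
#'
#' @param identity Symmetric percent-identity matrix (diagonal 100).
#' @param correction `"none"` (default): d = 100 - identity. `"poisson"`:
#'   d = -100 * log(identity / 100), a multiple-hit correction.
#' @return Symmetric non-negative distance matrix, zero diagonal.
#' @export
to_distance <- function(identity, correction = c("none", "poisson")) {
  correction <- match.arg(correction)
  validate_identity_matrix(identity)
  d <- switch(correction,
    none = 100 - identity,
    poisson = -100 * log(pmax(identity, 1e-8) / 100)
  )
  diag(d) <- 0
  d
}

validate_distance_matrix <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    abort_argument("distance matrix must be square")
  }
  if (is.null(rownames(d))) abort_argument("distance matrix must have id dimnames")
  if (!isSymmetric(unname(d), tol = 1e-8)) {
    abort_argument("distance matrix must be symmetric")
  }
  if (any(d < 0) || any(abs(diag(d)) > 1e-12)) {
    abort_argument("distances must be non-negative with zero diagonal")
  }
  d
}

quote_newick_label <- function(lab) {
  needs <- grepl("[][ \t():;,']", lab)
  lab[needs] <- paste0("'", gsub("'", "''", lab[needs]), "'")
  lab
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration: at each step the pair minimizing
#' Q(i,j) = (n-2) d(i,j) - r_i - r_j is joined, pendant branch lengths are
#' assigned by the rate-corrected split, and distances to the new node are
#' the reduction average. Ties in Q are broken by the first pair in row-major
#' id order, so output is deterministic. Negative computed branch lengths are
#' clamped to zero after assignment. For 2 taxa the single edge is split
#' equally.
#'
#' @param d Symmetric non-negative distance matrix with id dimnames.
#' @return An unrooted `ape::phylo` tree (trifurcating root for >= 3 taxa).
#' @export
neighbor_joining <- function(d) {
  validate_distance_matrix(d)
  n <- nrow(d)
  if (n < 2) abort_argument("need at least 2 taxa")
  ids <- rownames(d)
  # placeholder tip labels avoid Newick quoting issues during assembly
  nodes <- paste0("t", seq_len(n))
  clamp <- function(x) pmax(x, 0)
  fmt <- function(x) formatC(x, format = "g", digits = 15)

  if (n == 2) {
    half <- d[1, 2] / 2
    txt <- sprintf("(%s:%s,%s:%s);", nodes[1], fmt(half), nodes[2], fmt(half))
    tree <- ape::read.tree(text = txt)
    tree$tip.label <- ids[match(tree$tip.label, nodes)]
    return(tree)
  }

  labels <- nodes          # newick substring per active cluster
  m <- d
  while (length(labels) > 3) {
    k <- nrow(m)
    r <- rowSums(m)
    q <- (k - 2) * m - outer(r, r, "+")
    diag(q) <- Inf
    # first minimal entry in row-major order of the upper triangle
    best <- c(NA_integer_, NA_integer_)
    best_q <- Inf
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        if (q[i, j] < best_q - 1e-12) {
          best_q <- q[i, j]
          best <- c(i, j)
        }
      }
    }
    i <- best[1]; j <- best[2]
    li <- m[i, j] / 2 + (r[i] - r[j]) / (2 * (k - 2))
    lj <- m[i, j] - li
    li <- clamp(li); lj <- clamp(lj)
    new_label <- sprintf("(%s:%s,%s:%s)", labels[i], fmt(li), labels[j], fmt(lj))
    new_dist <- (m[i, ] + m[j, ] - m[i, j]) / 2
    keep <- setdiff(seq_len(k), c(i, j))
    m2 <- rbind(cbind(m[keep, keep, drop = FALSE], new_dist[keep]),
                c(new_dist[keep], 0))
    labels <- c(labels[keep], new_label)
    m <- m2
  }
  # final 3-way join: closed-form three-point pendant lengths
  la <- clamp((m[1, 2] + m[1, 3] - m[2, 3]) / 2)
  lb <- clamp((m[1, 2] + m[2, 3] - m[1, 3]) / 2)
  lc <- clamp((m[1, 3] + m[2, 3] - m[1, 2]) / 2)
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 labels[1], fmt(la), labels[2], fmt(lb), labels[3], fmt(lc))
  tree <- ape::read.tree(text = txt)
  tree$tip.label <- ids[match(tree$tip.label, nodes)]
  tree
}

#' Serialize a tree to Newick text
#'
#' Branch lengths are retained; labels containing spaces or Newick
#' metacharacters are single-quoted.
#'
#' @param tree An `ape::phylo`.
#' @return A single Newick string terminated by `;`.
#' @export
write_newick <- function(tree) {
  plain <- tree
  placeholder <- paste0("aartoolstip", seq_along(tree$tip.label))
  plain$tip.label <- placeholder
  txt <- ape::write.tree(plain)
  quoted <- quote_newick_label(tree$tip.label)
  for (i in seq_along(placeholder)) {
    txt <- sub(placeholder[i], quoted[i], txt, fixed = TRUE)
  }
  txt
}

#' Parse Newick text (supporting single-quoted labels)
#' @param text Newick string, or `NULL` when reading from `path`.
#' @param path Optional file to read from.
#' @return An `ape::phylo`.
#' @export
read_newick <- function(text = NULL, path = NULL) {
  if (is.null(text)) text <- paste(readLines(path, warn = FALSE), collapse = "")
  # pull out quoted labels so ape's reader never sees them
  quoted <- regmatches(text, gregexpr("'(?:[^']|'')*'", text))[[1]]
  restored <- character(length(quoted))
  for (i in seq_along(quoted)) {
    ph <- paste0("aartoolsq", i)
    text <- sub(quoted[i], ph, text, fixed = TRUE)
    inner <- substr(quoted[i], 2, nchar(quoted[i]) - 1)
    restored[i] <- gsub("''", "'", inner, fixed = TRUE)
  }
  tree <- ape::read.tree(text = text)
  for (i in seq_along(restored)) {
    tree$tip.label[tree$tip.label == paste0("aartoolsq", i)] <- restored[i]
  }
  tree
}

#' Cut a tree into k groups at its longest edges
#'
#' Removes the k-1 longest internal edges (ties broken by edge index) and
#' labels the resulting leaf partitions group1, group2, ... in tip order.
#' When k-1 exceeds the number of internal edges, the longest pendant edges
#' are removed next, so k may range up to the leaf count.
#'
#' @param tree An `ape::phylo`.
#' @param k Number of groups (default 3).
#' @return Tibble with columns `id` and `group`; per-group member counts in
#'   attribute `"counts"`.
#' @export
clade_groups <- function(tree, k = 3) {
  n_tip <- length(tree$tip.label)
  if (k < 1 || k > n_tip) abort_argument("k must be between 1 and the leaf count")
  edges <- tree$edge
  lens <- tree$edge.length %||% rep(0, nrow(edges))
  internal <- edges[, 2] > n_tip
  # rank edges: internal first, longest first, tie-break by edge index
  ord <- order(!internal, -lens, seq_len(nrow(edges)))

  leaf_partition <- function(keep) {
    n_node <- max(edges)
    parent <- seq_len(n_node)
    find <- function(x) {
      while (parent[x] != x) {
        parent[x] <<- parent[parent[x]]
        x <- parent[x]
      }
      x
    }
    for (e in keep) {
      a <- find(edges[e, 1]); b <- find(edges[e, 2])
      if (a != b) parent[a] <- b
    }
    vapply(seq_len(n_tip), find, integer(1))
  }

  # greedy: drop ranked edges whose removal actually splits the leaf set,
  # until k leaf groups exist (a removal can be vacuous once neighboring
  # edges are gone, e.g. pendant cuts around an already-isolated node)
  keep <- seq_len(nrow(edges))
  comp <- leaf_partition(keep)
  for (e in ord) {
    if (length(unique(comp)) >= k) break
    trial <- setdiff(keep, e)
    trial_comp <- leaf_partition(trial)
    if (length(unique(trial_comp)) > length(unique(comp))) {
      keep <- trial
      comp <- trial_comp
    }
  }
  group_ids <- unique(comp)                 # in tip order
  group <- paste0("group", match(comp, group_ids))
  out <- tibble::tibble(id = tree$tip.label, group = group)
  attr(out, "counts") <- table(out$group)
  out
}

#' Habitat composition of clade groups
#'
#' Counts leaves per group and habitat category. Fractions are computed over
#' leaves with a known habitat; with `include_both = FALSE`, leaves labeled
#' `"both"` are also excluded from the fraction denominator (they are always
#' counted in their own category).
#'
#' @param groups Grouping tibble from [clade_groups()].
#' @param habitat Named character vector (id -> habitat); missing ids are
#'   treated as `"unknown"`.
#' @param include_both Include `"both"` leaves in the fraction denominator?
#' @return Tibble with columns `group`, `habitat`, `n`, `fraction`.
#' @export
habitat_summary <- function(groups, habitat, include_both = TRUE) {
  hab <- unname(habitat[groups$id])
  hab[is.na(hab)] <- "unknown"
  tab <- tibble::tibble(group = groups$group,
                        habitat = factor(hab, levels = habitat_levels()))
  out <- dplyr::count(tab, .data$group, .data$habitat, .drop = FALSE,
                      name = "n")
  denom_levels <- if (include_both) c("marine", "freshwater", "both")
                  else c("marine", "freshwater")
  out <- dplyr::mutate(
    dplyr::group_by(out, .data$group),
    fraction = ifelse(
      as.character(.data$habitat) %in% denom_levels,
      .data$n / sum(.data$n[as.character(.data$habitat) %in% denom_levels]),
      NA_real_
    )
  )
  dplyr::ungroup(out)
}
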