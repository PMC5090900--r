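# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: alignment scores come from exhaustive
# enumeration of all monotone alignments, tree checks from closed forms and
# the four-point condition, and scan checks from a per-column tally.

# All complete move sequences ("D" consume both, "U" gap in b, "L" gap in a)
# for sequence lengths n and m. Each template carries its constant affine
# gap cost and the matrix of (i, j) index pairs matched by "D" moves.
enumerate_alignment_templates <- function(n, m, gap_open, gap_extend) {
  templates <- list()
  rec <- function(i, j, moves) {
    if (i > n && j > m) {
      runs <- rle(moves)
      gap_runs <- runs$lengths[runs$values != "D"]
      gap_cost <- sum(gap_open + gap_extend * gap_runs)
      pairs <- which(moves == "D")
      ii <- cumsum(moves != "L")[pairs]
      jj <- cumsum(moves != "U")[pairs]
      templates[[length(templates) + 1]] <<-
        list(gap_cost = gap_cost, pairs = cbind(ii, jj))
      return()
    }
    if (i <= n && j <= m) rec(i + 1, j + 1, c(moves, "D"))
    if (i <= n) rec(i + 1, j, c(moves, "U"))
    if (j <= m) rec(i, j + 1, c(moves, "L"))
  }
  rec(1, 1, character(0))
  templates
}

# Exhaustive-enumeration global alignment score for one pair of residue
# strings under an affine gap scheme.
oracle_align_score <- function(a, b, sub_mat, gap_open, gap_extend) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  templates <- enumerate_alignment_templates(length(ca), length(cb),
                                             gap_open, gap_extend)
  scores <- vapply(templates, function(t) {
    subs <- if (nrow(t$pairs) > 0) {
      sum(sub_mat[cbind(ca[t$pairs[, 1]], cb[t$pairs[, 2]])])
    } else 0
    subs - t$gap_cost
  }, numeric(1))
  max(scores)
}

# Vectorized oracle over every sequence pair of lengths (n, m) on a reduced
# alphabet: returns the score matrix [a-index, b-index] where sequences are
# enumerated in row-major base-|alphabet| order.
oracle_align_scores_all <- function(n, m, alphabet, sub_mat,
                                    gap_open, gap_extend) {
  templates <- enumerate_alignment_templates(n, m, gap_open, gap_extend)
  seqs_a <- as.matrix(expand.grid(rep(list(alphabet), n),
                                  stringsAsFactors = FALSE))
  seqs_b <- as.matrix(expand.grid(rep(list(alphabet), m),
                                  stringsAsFactors = FALSE))
  na_ <- nrow(seqs_a); nb_ <- nrow(seqs_b)
  idx_a <- rep(seq_len(na_), times = nb_)
  idx_b <- rep(seq_len(nb_), each = na_)
  best <- rep(-Inf, na_ * nb_)
  for (t in templates) {
    sc <- rep(-t$gap_cost, na_ * nb_)
    if (nrow(t$pairs) > 0) {
      for (p in seq_len(nrow(t$pairs))) {
        sc <- sc + sub_mat[cbind(seqs_a[idx_a, t$pairs[p, 1]],
                                 seqs_b[idx_b, t$pairs[p, 2]])]
      }
    }
    best <- pmax(best, sc)
  }
  list(
    scores = matrix(best, nrow = na_, ncol = nb_),
    seqs_a = apply(seqs_a, 1, paste, collapse = ""),
    seqs_b = apply(seqs_b, 1, paste, collapse = "")
  )
}

# Leaf-to-leaf path lengths of a phylo tree (independent route: ape).
tree_leaf_distances <- function(tree) {
  d <- ape::cophenetic.phylo(tree)
  d[order(rownames(d)), order(colnames(d))]
}

# The split {x1,x2} | {x3,x4} supported by a 4-taxon additive matrix under
# the four-point condition (smallest of the three pair sums).
four_point_split <- function(d) {
  ids <- rownames(d)
  sums <- c(
    d[ids[1], ids[2]] + d[ids[3], ids[4]],
    d[ids[1], ids[3]] + d[ids[2], ids[4]],
    d[ids[1], ids[4]] + d[ids[2], ids[3]]
  )
  splits <- list(c(1, 2), c(1, 3), c(1, 4))
  sort(ids[splits[[which.min(sums)]]])
}

# The split of a 4-taxon unrooted phylo, reported as the side containing the
# alphabetically first taxon (canonical form, comparable across trees).
nj_split_of <- function(tree) {
  four_point_split(tree_leaf_distances(tree))
}

# Random unrooted binary tree with positive branch lengths and its additive
# distance matrix (built with ape, independent of the package's NJ).
random_additive_tree <- function(n_taxa) {
  tree <- ape::rtree(n_taxa, rooted = FALSE,
                     tip.label = paste0("t", seq_len(n_taxa)))
  tree$edge.length <- stats::runif(nrow(tree$edge), 0.5, 5)
  d <- ape::cophenetic.phylo(tree)
  d <- d[order(rownames(d)), order(colnames(d))]
  list(tree = tree, d = d)
}

# Independent per-column strict-criterion check by explicit tally.
oracle_strict_columns <- function(msa, ingroup_ids, max_outgroup_matches = 0) {
  chars <- aartools::msa_matrix(msa)
  out_ids <- setdiff(rownames(chars), ingroup_ids)
  found <- integer(0)
  for (col in seq_len(ncol(chars))) {
    ing <- table(chars[ingroup_ids, col])
    if (length(ing) != 1) next
    r <- names(ing)
    if (r %in% c("-", "X")) next
    n_out_match <- sum(chars[out_ids, col] == r)
    if (n_out_match <= max_outgroup_matches) found <- c(found, col)
  }
  found
}

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}
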