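# Neighbour-joining tree construction and Newick I/O.
#
# Saitou-Nei neighbour joining on the Q-criterion, written independently of
# ape's implementation (ape::nj serves as a cross-check in the test suite).
# Trees are returned as ape "phylo" objects, the field-standard container.

#' Validate a distance matrix
#'
#' @param d square numeric matrix with labels as dimnames.
#' @return the matrix, with labels filled in when absent.
#' @export
validate_distance_matrix <- function(d) {
  d <- as.matrix(d)
  assert_that(nrow(d) == ncol(d), "distance matrix must be square")
  assert_that(all(is.finite(d)), "distance matrix has non-finite entries")
  assert_that(all(d >= 0), "distance matrix has negative entries")
  assert_that(max(abs(d - t(d))) < 1e-12, "distance matrix is not symmetric")
  assert_that(max(abs(diag(d))) < 1e-12, "distance matrix diagonal not zero")
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  }
  d
}

#' Neighbour-joining tree from a distance matrix
#'
#' Classic agglomerative neighbour joining: at each step the pair (i, j)
#' minimising `Q(i,j) = (n-2) d(i,j) - r_i - r_j` is joined, with branch
#' lengths `d(i,j)/2 +/- (r_i - r_j)/(2(n-2))` and reduced distances
#' `d(u,k) = (d(i,k) + d(j,k) - d(i,j))/2`. Ties break on the
#' lexicographically first pair, making the construction deterministic.
#' Negative branch lengths are clamped to zero with the deficit transferred
#' to the sibling edge, preserving the path length between the joined
#' leaves. On an additive matrix the leaf-to-leaf path lengths of the
#' output reproduce the input exactly.
#'
#' @param d a symmetric nonnegative distance matrix with zero diagonal
#'   (n >= 2; n = 2 yields the trivial two-leaf tree).
#' @return an unrooted `phylo` tree whose tip labels are the matrix labels.
#' @export
nj_tree <- function(d) {
  d <- validate_distance_matrix(d)
  n <- nrow(d)
  labels <- rownames(d)
  assert_that(n >= 2, "need at least two taxa")
  fmt <- function(x) sprintf("%.12g", max(0, x))
  if (n == 2) {
    nwk <- sprintf("(%s:%s,%s:%s);", labels[1], fmt(d[1, 2] / 2),
                   labels[2], fmt(d[1, 2] / 2))
    return(read_newick(nwk))
  }
  # active clusters carried as newick fragments
  frag <- labels
  while (n > 3) {
    r <- rowSums(d)
    q <- (n - 2) * d - outer(r, r, `+`)
    diag(q) <- Inf
    best <- which(q == min(q), arr.ind = TRUE)
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    i <- min(best); j <- max(best)
    bi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    bj <- d[i, j] - bi
    # clamp negatives, moving the deficit to the sibling edge
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    new_frag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt(bi), frag[j], fmt(bj))
    duk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], duk[keep]),
               c(duk[keep], 0))
    frag <- c(frag[keep], new_frag)
    n <- n - 1
  }
  # final unrooted star over the last three clusters
  b1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  b2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  b3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 frag[1], fmt(b1), frag[2], fmt(b2), frag[3], fmt(b3))
  read_newick(nwk)
}

#' Leaf-to-leaf path lengths of a tree
#'
#' @param tree a `phylo`.
#' @return symmetric matrix of patristic distances over the tip labels.
#' @export
tree_path_lengths <- function(tree) {
  m <- ape::cophenetic.phylo(tree)
  m[tree$tip.label, tree$tip.label]
}

#' Write a tree as Newick text
#'
#' @param tree a `phylo`.
#' @param path optional file; when NULL the Newick string is returned.
#' @param digits significant digits for branch lengths.
#' @return the Newick string (invisibly when written to a file).
#' @export
write_newick <- function(tree, path = NULL, digits = 10) {
  assert_that(inherits(tree, "phylo"), "tree must be a phylo object")
  txt <- ape::write.tree(tree, digits = digits)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Parse Newick text into a tree
#'
#' @param text a Newick string, or the path of a file holding one.
#' @return a `phylo`.
#' @export
read_newick <- function(text) {
  if (length(text) == 1 && !grepl("\\(", text) && file.exists(text)) {
    text <- paste(readLines(text), collapse = "")
  }
  # report unbalanced parentheses with a character position before handing
  # the string to the parser
  depth <- 0L
  chars <- strsplit(text, "")[[1]]
  for (k in seq_along(chars)) {
    if (chars[k] == "(") depth <- depth + 1L
    if (chars[k] == ")") depth <- depth - 1L
    if (depth < 0) {
      stop_mp("malformed newick: unmatched ')' at position %d", k)
    }
  }
  if (depth != 0) {
    stop_mp("malformed newick: %d unclosed '(' at end of text", depth)
  }
  tree <- tryCatch(ape::read.tree(text = text), error = function(e) NULL,
                   warning = function(w) NULL)
  assert_that(!is.null(tree) && inherits(tree, "phylo"),
              "malformed newick: could not parse '%s'",
              substr(text, 1, 60))
  tree
}

#' Robinson-Foulds distance by bipartition enumeration
#'
#' Counts the bipartitions (internal-edge splits) present in exactly one of
#' the two trees. Zero means identical unrooted topologies.
#'
#' @param t1,t2 `phylo` trees over the same tip set.
#' @return nonnegative integer RF distance.
#' @export
rf_distance <- function(t1, t2) {
  assert_that(setequal(t1$tip.label, t2$tip.label),
              "trees must share the same tip set")
  splits <- function(tree) {
    tree <- ape::unroot(tree)
    tips <- sort(tree$tip.label)
    n <- length(tips)
    out <- character(0)
    internal <- tree$edge[tree$edge[, 2] > n, 2]
    for (node in internal) {
      clade <- ape::extract.clade(tree, node)$tip.label
      side <- sort(clade)
      other <- sort(setdiff(tips, side))
      if (length(side) < 2 || length(other) < 2) next
      key <- if (tips[1] %in% side) paste(side, collapse = "|") else
        paste(other, collapse = "|")
      out <- c(out, key)
    }
    unique(out)
  }
  s1 <- splits(t1); s2 <- splits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}
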