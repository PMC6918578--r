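# Synthetic-data generators: randomized thermodynamic record sets and
# protein families evolved along a known tree. Both are deterministic under
# a fixed seed.

#' Generate Gaussian thermodynamic records around a known value
#'
#' Emulates a literature compilation: `n` independent estimates of one
#' property drawn from N(true_value, sigma_i) with stated per-record
#' one-sigma uncertainties.
#'
#' @param true_value the underlying property value.
#' @param sigmas per-record standard deviations (recycled to length `n`).
#' @param n number of records.
#' @param seed integer seed.
#' @param species_id,property labels for the generated records.
#' @return a `thermo_table`.
#' @export
generate_thermo_records <- function(true_value, sigmas, n = length(sigmas),
                                    seed = 1L,
                                    species_id = "synthetic_species",
                                    property = "formation_gibbs") {
  assert_that(n >= 1, "generate_thermo_records: n must be >= 1")
  sigmas <- rep_len(sigmas, n)
  assert_that(all(sigmas >= 0), "sigmas must be >= 0")
  withr_seed(seed, {
    vals <- stats::rnorm(n, mean = true_value, sd = sigmas)
  })
  thermo_records(species_id, property, vals,
                 uncertainty = sigmas,
                 source_label = sprintf("synthetic_%02d", seq_len(n)))
}

# evaluate expr under a local RNG seed without disturbing the caller's RNG
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Parameters for synthetic protein families
#'
#' @param n_taxa number of leaves (>= 3).
#' @param seq_length protein length in residues.
#' @param substitution_rate_per_site per-site substitution probability per
#'   unit branch length, in (0, 1).
#' @param tree_shape `balanced`, `caterpillar` or `random`.
#' @param seed integer seed.
#' @return a list of class `family_params`.
#' @export
family_params <- function(n_taxa = 8, seq_length = 200,
                          substitution_rate_per_site = 0.05,
                          tree_shape = c("balanced", "caterpillar", "random"),
                          seed = 1L) {
  tree_shape <- match.arg(tree_shape)
  assert_that(n_taxa >= 3, "n_taxa must be >= 3")
  assert_that(substitution_rate_per_site > 0 &&
                substitution_rate_per_site < 1,
              "substitution_rate_per_site must lie in (0, 1)")
  structure(list(n_taxa = as.integer(n_taxa),
                 seq_length = as.integer(seq_length),
                 substitution_rate_per_site = substitution_rate_per_site,
                 tree_shape = tree_shape, seed = as.integer(seed)),
            class = "family_params")
}

AA_ALPHABET20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Evolve a protein family along a known tree
#'
#' A root sequence drawn uniformly over the 20 amino acids is evolved along
#' every branch of a tree of the requested shape (all branch lengths one):
#' each site substitutes with probability equal to the per-site rate, to a
#' uniformly chosen different residue. Expected pairwise identity therefore
#' decays with path length. The generating tree is returned alongside.
#'
#' @param params a [family_params()].
#' @return list with `sequences` (named character vector, ids `t1..tn`) and
#'   `tree` (the generating `phylo`, unit branch lengths).
#' @export
generate_protein_family <- function(params = family_params()) {
  assert_that(inherits(params, "family_params"),
              "params must be built with family_params()")
  n <- params$n_taxa
  withr_seed(params$seed, {
    tree <- switch(params$tree_shape,
      balanced = ape::stree(n, type = "balanced"),
      caterpillar = ape::stree(n, type = "left"),
      random = ape::rtree(n, rooted = TRUE, br = NULL))
    tree$edge.length <- rep(1, nrow(tree$edge))
    tree$tip.label <- paste0("t", seq_len(n))
    root_seq <- sample(AA_ALPHABET20, params$seq_length, replace = TRUE)
    # propagate sequences from the root down each edge in preorder
    nnode <- max(tree$edge)
    seqs <- vector("list", nnode)
    root <- n + 1L
    seqs[[root]] <- root_seq
    edges <- tree$edge[order(tree$edge[, 1]), , drop = FALSE]
    # preorder traversal
    stack <- root
    while (length(stack) > 0) {
      node <- stack[1]; stack <- stack[-1]
      children <- tree$edge[tree$edge[, 1] == node, 2]
      for (ch in children) {
        s <- seqs[[node]]
        hit <- which(stats::runif(length(s)) < params$substitution_rate_per_site)
        for (i in hit) {
          s[i] <- sample(setdiff(AA_ALPHABET20, s[i]), 1)
        }
        seqs[[ch]] <- s
        stack <- c(stack, ch)
      }
    }
    out <- vapply(seq_len(n), function(i) paste(seqs[[i]], collapse = ""),
                  character(1))
    names(out) <- tree$tip.label
  })
  list(sequences = out, tree = tree)
}

#' Write named sequences as FASTA
#'
#' @param sequences named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file.
#' @return named character vector of residues.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(set), names(set))
}
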