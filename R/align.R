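# Global pairwise alignment, percent identity and greedy identity
# clustering of protein sequences.

AA_VALID <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
              "M", "F", "P", "S", "T", "W", "Y", "V", "X")

validate_protein <- function(x, what = "sequence") {
  assert_that(is.character(x) && length(x) == 1 && nchar(x) > 0,
              "%s must be a nonempty character string", what)
  chars <- strsplit(toupper(x), "")[[1]]
  bad <- setdiff(unique(chars), AA_VALID)
  assert_that(length(bad) == 0, "%s contains invalid residue(s): %s",
              what, paste(bad, collapse = ", "))
  paste(chars, collapse = "")
}

#' Optimal global alignment of two protein sequences
#'
#' Needleman-Wunsch global alignment with affine gaps (a gap of length L
#' costs `gap_open + L * gap_extend`), scored with BLOSUM62 by default.
#' Identity is the fraction of matching columns among alignment columns,
#' excluding terminal gap columns (BLAST-like); set
#' `denominator = "shorter"` to normalise by the shorter sequence instead.
#'
#' @param a,b protein sequences (20-letter alphabet plus X).
#' @param substitution_matrix scoring matrix name or matrix (default
#'   `"BLOSUM62"`).
#' @param gap_open,gap_extend affine gap parameters (positive costs).
#' @param denominator identity denominator convention.
#' @return list of class `alignment_result` with `aligned_a`, `aligned_b`,
#'   `identity` and `score`.
#' @export
global_align <- function(a, b, substitution_matrix = "BLOSUM62",
                         gap_open = 11, gap_extend = 1,
                         denominator = c("alignment", "shorter")) {
  denominator <- match.arg(denominator)
  a <- validate_protein(a, "sequence a")
  b <- validate_protein(b, "sequence b")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend,
    type = "global")
  al_a <- as.character(Biostrings::alignedPattern(pa))
  al_b <- as.character(Biostrings::alignedSubject(pa))
  structure(list(aligned_a = al_a, aligned_b = al_b,
                 identity = alignment_identity(al_a, al_b, denominator,
                                               nchar(a), nchar(b)),
                 score = Biostrings::score(pa)),
            class = "alignment_result")
}

# identity from two aligned strings of equal length
alignment_identity <- function(al_a, al_b,
                               denominator = "alignment",
                               len_a = NULL, len_b = NULL) {
  ca <- strsplit(al_a, "")[[1]]
  cb <- strsplit(al_b, "")[[1]]
  assert_that(length(ca) == length(cb), "aligned strings differ in length")
  gap <- ca == "-" & cb == "-"
  ca <- ca[!gap]; cb <- cb[!gap]
  matches <- sum(ca == cb & ca != "-")
  if (denominator == "shorter") {
    den <- min(len_a %||% sum(ca != "-"), len_b %||% sum(cb != "-"))
  } else {
    # exclude terminal gap columns (before either sequence starts or after
    # either has ended)
    lead_a <- cumsum(ca != "-") == 0 | cumsum(cb != "-") == 0
    trail_a <- rev(cumsum(rev(ca != "-")) == 0 | cumsum(rev(cb != "-")) == 0)
    den <- sum(!(lead_a | trail_a))
  }
  if (den == 0) 0 else matches / den
}

#' All-pairs identity distance matrix
#'
#' Pairwise global-alignment identities converted to p-distances
#' `d = 1 - identity`.
#'
#' @param sequences named character vector of protein sequences.
#' @param ... passed to [global_align()].
#' @return a symmetric matrix with zero diagonal, labelled by sequence ids.
#' @export
identity_distances <- function(sequences, ...) {
  n <- length(sequences)
  ids <- names(sequences) %||% paste0("s", seq_len(n))
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        idn <- global_align(sequences[[i]], sequences[[j]], ...)$identity
        d[i, j] <- d[j, i] <- 1 - idn
      }
    }
  }
  d
}

#' Greedy identity clustering of protein sequences
#'
#' BLASTclust-style redundancy removal: sequences are visited in order of
#' decreasing length (id as tiebreak); each joins the first existing cluster
#' whose representative it matches at or above the identity threshold,
#' otherwise it founds a new cluster with itself as representative. The
#' procedure is deterministic and independent of the input order.
#'
#' @param sequences named character vector of protein sequences.
#' @param threshold identity threshold in (0, 1], default 0.90.
#' @param ... passed to [global_align()].
#' @return data.frame with columns `cluster_id`, `representative`, `member`,
#'   `identity` (identity of the member to its representative).
#' @export
cluster_by_identity <- function(sequences, threshold = 0.90, ...) {
  assert_that(length(sequences) >= 1, "need at least one sequence")
  assert_that(threshold > 0 && threshold <= 1,
              "threshold must lie in (0, 1]")
  ids <- names(sequences) %||% paste0("s", seq_along(sequences))
  names(sequences) <- ids
  ord <- order(-nchar(sequences), ids)
  reps <- character(0)
  rows <- list()
  for (i in ord) {
    placed <- FALSE
    for (k in seq_along(reps)) {
      idn <- global_align(sequences[[reps[k]]], sequences[[i]], ...)$identity
      if (idn >= threshold) {
        rows[[length(rows) + 1]] <- data.frame(
          cluster_id = k, representative = reps[k], member = ids[i],
          identity = idn, stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, ids[i])
      rows[[length(rows) + 1]] <- data.frame(
        cluster_id = length(reps), representative = ids[i], member = ids[i],
        identity = 1, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$cluster_id, out$member), , drop = FALSE]
}
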