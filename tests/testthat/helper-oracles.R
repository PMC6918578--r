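# Independent oracles used across the suite. Each re-derives an expected
# value by a route unrelated to the implementation it checks.

# ---- brute-force global alignment with affine gaps ----------------------
# Enumerates every monotone alignment path of two short sequences and scores
# it directly: substitution score per aligned pair, gap_open + L * gap_extend
# per maximal gap run. Exponential; intended for lengths <= 5.
brute_force_align_score <- function(a, b, mat, gap_open = 11,
                                    gap_extend = 1) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, score, state) {
    if (i > length(ca) && j > length(cb)) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= length(ca) && j <= length(cb)) {
      rec(i + 1, j + 1, score + mat[ca[i], cb[j]], "m")
    }
    if (i <= length(ca)) {  # gap in b
      pen <- gap_extend + if (state == "ga") 0 else gap_open
      rec(i + 1, j, score - pen, "ga")
    }
    if (j <= length(cb)) {  # gap in a
      pen <- gap_extend + if (state == "gb") 0 else gap_open
      rec(i, j + 1, score - pen, "gb")
    }
  }
  rec(1, 1, 0, "start")
  best
}

# ---- vertex-enumeration LP oracle ---------------------------------------
# Maximise c'v over {S v = 0, lb <= v <= ub} by enumerating basic solutions:
# every choice of (n - rank(S)) variables pinned at a bound, the remainder
# solved from the equality system. Exact for small n.
lp_vertex_oracle <- function(S, lb, ub, cvec) {
  S <- as.matrix(S)
  n <- ncol(S)
  r <- qr(S)$rank
  k <- n - r
  best <- -Inf
  if (k == 0) stop("degenerate oracle problem: no free variables")
  combs <- utils::combn(n, k)
  for (ci in seq_len(ncol(combs))) {
    fixed <- combs[, ci]
    free <- setdiff(seq_len(n), fixed)
    Sf <- S[, free, drop = FALSE]
    if (qr(Sf)$rank < length(free)) next
    for (pattern in seq_len(2^k) - 1) {
      at_ub <- as.logical(bitwAnd(pattern, 2^(seq_len(k) - 1)))
      vf <- ifelse(at_ub, ub[fixed], lb[fixed])
      rhs <- -S[, fixed, drop = FALSE] %*% vf
      sol <- tryCatch(qr.solve(Sf, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      if (max(abs(Sf %*% sol - rhs)) > 1e-8) next
      v <- numeric(n)
      v[fixed] <- vf
      v[free] <- sol
      if (all(v >= lb - 1e-9) && all(v <= ub + 1e-9)) {
        best <- max(best, sum(cvec * v))
      }
    }
  }
  best
}

# ---- small hand-built models --------------------------------------------

# linear chain: substrate uptake -> A -> product secretion, 1:1 carbon
toy_chain_model <- function(uptake = 10) {
  metabolic_model(
    metabolites = data.frame(id = c("A", "B"), carbon = c(1, 1)),
    reactions = data.frame(id = c("EX_A", "CONV", "EX_B"),
                           lb = c(-uptake, 0, 0), ub = c(1000, 1000, 1000)),
    stoichiometry = list(EX_A = c(A = -1), CONV = c(A = -1, B = 1),
                         EX_B = c(B = -1)),
    objective = c(EX_B = 1))
}

# branched toy with a carbon-losing side reaction:
#   A -> B (keeps carbon), A -> C + CO2-like loss, product from B and C
toy_branch_model <- function() {
  metabolic_model(
    metabolites = data.frame(id = c("A", "B", "C", "L", "P"),
                             carbon = c(2, 2, 1, 1, 2)),
    reactions = data.frame(
      id = c("EX_A", "KEEP", "LOSE", "MAKE_B", "MAKE_C", "EX_P", "EX_L"),
      lb = c(-10, 0, 0, 0, 0, 0, 0),
      ub = c(1000, 6, 1000, 1000, 1000, 1000, 1000)),
    stoichiometry = list(
      EX_A = c(A = -1),
      KEEP = c(A = -1, B = 1),
      LOSE = c(A = -1, C = 1, L = 1),
      MAKE_B = c(B = -1, P = 1),
      MAKE_C = c(C = -2, P = 1),
      EX_P = c(P = -1),
      EX_L = c(L = -1)),
    objective = c(EX_P = 1))
}

# two redundant parallel routes carrying the same conversion
toy_parallel_model <- function(uptake = 10) {
  metabolic_model(
    metabolites = data.frame(id = c("A", "B"), carbon = c(1, 1)),
    reactions = data.frame(id = c("EX_A", "P1", "P2", "EX_B"),
                           lb = c(-uptake, 0, 0, 0),
                           ub = c(1000, 1000, 1000, 1000)),
    stoichiometry = list(EX_A = c(A = -1), P1 = c(A = -1, B = 1),
                         P2 = c(A = -1, B = 1), EX_B = c(B = -1)),
    objective = c(EX_B = 1))
}

# load the packaged BLOSUM62 once for the alignment oracles
blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

random_protein <- function(n, alphabet = c("A", "R", "N", "D", "C", "Q",
                                           "E", "G", "H", "I", "L", "K",
                                           "M", "F", "P", "S", "T", "W",
                                           "Y", "V")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
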