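# Dense two-phase simplex solver.
#
# A small, deterministic LP kernel sized for reduced metabolic models
# (tens of reactions). Standard tableau simplex: phase 1 minimises the sum
# of artificial variables, phase 2 optimises the user objective. Pivoting
# uses Dantzig's rule and falls back to Bland's rule (which cannot cycle)
# after a fixed number of iterations, so termination is guaranteed and the
# pivot sequence -- hence the returned vertex -- is reproducible.

LP_TOL <- 1e-9

#' Solve a linear program
#'
#' Maximise (or minimise) `obj %*% x` subject to `A x (<=|=|>=) b` and
#' `x >= 0`.
#'
#' @param obj objective coefficients (length n).
#' @param A constraint matrix (m x n).
#' @param b right-hand side (length m; any sign).
#' @param sense character vector of `"<="`, `"="`, `">="` per row.
#' @param maximize direction of optimisation.
#' @return list with `status` (`optimal`, `infeasible`, `unbounded`),
#'   `value` and `x`.
#' @export
lp_solve <- function(obj, A, b, sense, maximize = TRUE) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(b) == m, length(sense) == m, length(obj) == n)
  # normalise to b >= 0
  flip <- b < 0
  A[flip, ] <- -A[flip, , drop = FALSE]
  b[flip] <- -b[flip]
  sense[flip] <- c("<=" = ">=", ">=" = "<=", "=" = "=")[sense[flip]]

  n_slack <- sum(sense != "=")
  n_art <- sum(sense != "<=")
  N <- n + n_slack + n_art
  T_ <- matrix(0, m, N)
  T_[, seq_len(n)] <- A
  basis <- integer(m)
  s_col <- n; a_col <- n + n_slack
  for (i in seq_len(m)) {
    if (sense[i] == "<=") {
      s_col <- s_col + 1L
      T_[i, s_col] <- 1
      basis[i] <- s_col
    } else if (sense[i] == ">=") {
      s_col <- s_col + 1L
      T_[i, s_col] <- -1
      a_col <- a_col + 1L
      T_[i, a_col] <- 1
      basis[i] <- a_col
    } else {
      a_col <- a_col + 1L
      T_[i, a_col] <- 1
      basis[i] <- a_col
    }
  }
  rhs <- b
  art_cols <- seq(n + n_slack + 1L, length.out = n_art)

  pivot <- function(T_, rhs, r, c) {
    piv <- T_[r, c]
    T_[r, ] <- T_[r, ] / piv
    rhs[r] <- rhs[r] / piv
    for (i in seq_len(nrow(T_))) {
      if (i != r && abs(T_[i, c]) > 0) {
        f <- T_[i, c]
        T_[i, ] <- T_[i, ] - f * T_[r, ]
        rhs[i] <- rhs[i] - f * rhs[r]
      }
    }
    list(T_ = T_, rhs = rhs)
  }

  run_phase <- function(T_, rhs, basis, cost, allowed) {
    it <- 0L
    bland_after <- 200L * (m + N)
    repeat {
      it <- it + 1L
      if (it > 500L * (m + N) + 10000L) {
        return(list(status = "stalled", T_ = T_, rhs = rhs, basis = basis))
      }
      cb <- cost[basis]
      # z_j - c_j; a positive entry improves the (minimisation) objective
      red <- as.numeric(crossprod(cb, T_)) - cost
      red[!allowed] <- 0
      cand <- which(red > LP_TOL & allowed)
      if (length(cand) == 0) {
        return(list(status = "optimal", T_ = T_, rhs = rhs, basis = basis))
      }
      enter <- if (it > bland_after) min(cand) else cand[which.max(red[cand])]
      col <- T_[, enter]
      pos <- which(col > LP_TOL)
      if (length(pos) == 0) {
        return(list(status = "unbounded", T_ = T_, rhs = rhs, basis = basis))
      }
      ratio <- rhs[pos] / col[pos]
      rmin <- min(ratio)
      tied <- pos[ratio <= rmin + LP_TOL]
      leave <- tied[which.min(basis[tied])]  # Bland-style tiebreak
      p <- pivot(T_, rhs, leave, enter)
      T_ <- p$T_; rhs <- p$rhs
      basis[leave] <- enter
    }
  }

  # phase 1: minimise sum of artificials
  if (n_art > 0) {
    cost1 <- numeric(N)
    cost1[art_cols] <- 1
    ph1 <- run_phase(T_, rhs, basis, cost1, allowed = rep(TRUE, N))
    if (ph1$status != "optimal") {
      return(list(status = "infeasible", value = NA_real_, x = NULL))
    }
    T_ <- ph1$T_; rhs <- ph1$rhs; basis <- ph1$basis
    if (sum(rhs[basis %in% art_cols]) > 1e-7) {
      return(list(status = "infeasible", value = NA_real_, x = NULL))
    }
    # drive any zero-level artificial out of the basis
    for (i in which(basis %in% art_cols)) {
      row <- T_[i, seq_len(n + n_slack)]
      j <- which(abs(row) > LP_TOL)
      if (length(j) > 0) {
        p <- pivot(T_, rhs, i, j[1])
        T_ <- p$T_; rhs <- p$rhs
        basis[i] <- j[1]
      }
      # an all-zero row is redundant; its artificial stays basic at zero
    }
  }

  # phase 2
  cost2 <- numeric(N)
  cost2[seq_len(n)] <- if (maximize) -obj else obj  # minimise internally
  allowed <- rep(TRUE, N)
  if (n_art > 0) allowed[art_cols] <- FALSE
  ph2 <- run_phase(T_, rhs, basis, cost2, allowed)
  if (ph2$status == "unbounded") {
    return(list(status = "unbounded", value = NA_real_, x = NULL))
  }
  if (ph2$status != "optimal") {
    return(list(status = "infeasible", value = NA_real_, x = NULL))
  }
  x <- numeric(N)
  x[ph2$basis] <- ph2$rhs
  x <- x[seq_len(n)]
  list(status = "optimal", value = sum(obj * x), x = x)
}
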