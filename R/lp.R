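# Dense two-phase primal simplex with Bland's anti-cycling rule.
#
# DEA envelopment and multiplier programs are highly degenerate (many
# zero right-hand sides, ties on the frontier); general-purpose simplex
# routines that pivot by steepest reduced cost without anti-cycling
# safeguards stall or error on them. Problems here are tiny (tens of
# variables), so a dense Bland-rule simplex is both robust and fast.

# One simplex phase over min cost.x s.t. A x = b (A[, basis] = I, b >= 0).
simplex_iterate <- function(A, b, cost, basis, tol = 1e-9) {
  m <- nrow(A)
  repeat {
    r <- cost - as.vector(crossprod(cost[basis], A))
    r[basis] <- 0                       # kill rounding residue on basics
    enter <- which(r < -tol)
    if (length(enter) == 0)
      return(list(A = A, b = b, basis = basis, status = "optimal"))
    j <- min(enter)                     # Bland: smallest entering index
    col <- A[, j]
    pos <- which(col > tol)
    if (length(pos) == 0) return(list(status = "unbounded"))
    ratios <- b[pos] / col[pos]
    mn <- min(ratios)
    cand <- pos[ratios <= mn + tol]
    i <- cand[which.min(basis[cand])]   # Bland: smallest leaving basic index
    piv <- A[i, j]
    A[i, ] <- A[i, ] / piv
    b[i] <- b[i] / piv
    other <- seq_len(m)[-i]
    f <- A[other, j]
    A[other, ] <- A[other, , drop = FALSE] - outer(f, A[i, ])
    b[other] <- b[other] - f * b[i]
    b[b < 0 & b > -tol] <- 0
    basis[i] <- j
  }
}

# General LP over x >= 0:
#   max/min obj.x  s.t.  A_le x <= b_le,  A_ge x >= b_ge,  A_eq x = b_eq
solve_lp <- function(obj, A_le = NULL, b_le = NULL, A_ge = NULL, b_ge = NULL,
                     A_eq = NULL, b_eq = NULL, maximize = TRUE, tol = 1e-9) {
  n <- length(obj)
  n_le <- if (is.null(A_le)) 0L else nrow(A_le)
  n_ge <- if (is.null(A_ge)) 0L else nrow(A_ge)
  n_eq <- if (is.null(A_eq)) 0L else nrow(A_eq)
  m <- n_le + n_ge + n_eq
  if (m == 0) stop("solve_lp: no constraints", call. = FALSE)
  A <- rbind(A_le, A_ge, A_eq)
  b <- c(b_le, b_ge, b_eq)
  # slack (+1) for <= rows, surplus (-1) for >= rows
  S <- matrix(0, m, n_le + n_ge)
  if (n_le > 0) S[cbind(seq_len(n_le), seq_len(n_le))] <- 1
  if (n_ge > 0) S[cbind(n_le + seq_len(n_ge), n_le + seq_len(n_ge))] <- -1
  A <- cbind(A, S)
  N0 <- ncol(A)
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  b[neg] <- -b[neg]

  # phase 1: artificial basis, minimize infeasibility
  A1 <- cbind(A, diag(m))
  basis <- N0 + seq_len(m)
  cost1 <- c(rep(0, N0), rep(1, m))
  ph1 <- simplex_iterate(A1, b, cost1, basis, tol)
  if (!identical(ph1$status, "optimal"))
    stop("solve_lp: phase 1 ", ph1$status, call. = FALSE)
  if (sum(ph1$b[ph1$basis > N0]) > 1e-7)
    stop("solve_lp: infeasible", call. = FALSE)
  A1 <- ph1$A; b <- ph1$b; basis <- ph1$basis
  # pivot lingering artificials out of the basis (or drop redundant rows)
  drop_rows <- integer(0)
  for (i in which(basis > N0)) {
    j <- which(abs(A1[i, seq_len(N0)]) > tol)
    if (length(j) == 0) { drop_rows <- c(drop_rows, i); next }
    j <- j[1]
    piv <- A1[i, j]
    A1[i, ] <- A1[i, ] / piv
    b[i] <- b[i] / piv
    other <- seq_len(nrow(A1))[-i]
    f <- A1[other, j]
    A1[other, ] <- A1[other, , drop = FALSE] - outer(f, A1[i, ])
    b[other] <- b[other] - f * b[i]
    basis[i] <- j
  }
  if (length(drop_rows) > 0) {
    A1 <- A1[-drop_rows, , drop = FALSE]
    b <- b[-drop_rows]
    basis <- basis[-drop_rows]
  }

  # phase 2 on the original objective (internally minimized)
  A2 <- A1[, seq_len(N0), drop = FALSE]
  cost2 <- c(if (maximize) -obj else obj, rep(0, N0 - n))
  ph2 <- simplex_iterate(A2, b, cost2, basis, tol)
  if (!identical(ph2$status, "optimal"))
    stop("solve_lp: ", ph2$status, call. = FALSE)
  x <- numeric(N0)
  x[ph2$basis] <- ph2$b
  value <- sum(obj * x[seq_len(n)])
  list(value = value, x = x[seq_len(n)])
}
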