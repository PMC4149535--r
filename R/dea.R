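#' Define a DEA efficiency problem
#'
#' A decision-making unit (DMU; here, a data collection method) converts
#' inputs (costs) into outputs (quality-adjusted data). Efficiency is
#' measured radially against the frontier spanned by the observed DMUs,
#' under constant (CCR) or variable (BCC) returns to scale.
#'
#' @param inputs numeric matrix, DMUs x input dimensions, strictly positive;
#'   rownames are DMU ids. A vector is taken as a single input column.
#' @param outputs numeric matrix, DMUs x output dimensions, nonnegative with
#'   no all-zero row.
#' @param returns_to_scale `"CRS"` or `"VRS"`.
#' @param orientation `"input"` or `"output"`.
#' @return list classed `dea_problem`.
#' @export
dea_problem <- function(inputs, outputs,
                        returns_to_scale = c("CRS", "VRS"),
                        orientation = c("input", "output")) {
  to_mat <- function(x, what) {
    if (is.null(dim(x))) x <- matrix(x, ncol = 1,
                                     dimnames = list(names(x), what))
    as.matrix(x)
  }
  inputs <- to_mat(inputs, "input1")
  outputs <- to_mat(outputs, "output1")
  if (nrow(inputs) != nrow(outputs))
    stop("dea_problem: inputs and outputs must cover the same DMUs", call. = FALSE)
  ids <- rownames(inputs) %||% rownames(outputs) %||%
    paste0("dmu", seq_len(nrow(inputs)))
  rownames(inputs) <- rownames(outputs) <- ids
  if (any(inputs <= 0))
    stop("dea_problem: inputs must be strictly positive", call. = FALSE)
  if (any(outputs < 0) || any(rowSums(outputs) == 0))
    stop("dea_problem: outputs must be nonnegative with no all-zero DMU",
         call. = FALSE)
  structure(list(dmu_ids = ids, inputs = inputs, outputs = outputs,
                 returns_to_scale = match.arg(returns_to_scale),
                 orientation = match.arg(orientation)),
            class = "dea_problem")
}

# Multiplier-form LP matrices for one DMU. Variables: (v weights on inputs,
# u weights on outputs[, w+ , w- for the free VRS intercept]).
multiplier_lp <- function(X, Y, i, rts, orientation) {
  m <- ncol(X); s <- ncol(Y); n <- nrow(X)
  vrs <- rts == "VRS"
  k <- m + s + if (vrs) 2 else 0
  # frontier constraints, one row per DMU j
  A <- matrix(0, n, k)
  if (orientation == "input") {
    # max u.y_i (+ w)  s.t.  v.x_i = 1,  u.y_j + w - v.x_j <= 0
    A[, 1:m] <- -X
    A[, m + 1:s] <- Y
    if (vrs) { A[, m + s + 1] <- 1; A[, m + s + 2] <- -1 }
    obj <- c(rep(0, m), Y[i, ], if (vrs) c(1, -1))
    eq <- c(X[i, ], rep(0, s), if (vrs) c(0, 0))
    list(obj = obj, A_le = A, b_le = rep(0, n),
         A_eq = rbind(eq), b_eq = 1, maximize = TRUE)
  } else {
    # min v.x_i (+ w)  s.t.  u.y_i = 1,  v.x_j + w - u.y_j >= 0
    A[, 1:m] <- X
    A[, m + 1:s] <- -Y
    if (vrs) { A[, m + s + 1] <- 1; A[, m + s + 2] <- -1 }
    obj <- c(X[i, ], rep(0, s), if (vrs) c(1, -1))
    eq <- c(rep(0, m), Y[i, ], if (vrs) c(0, 0))
    list(obj = obj, A_ge = A, b_ge = rep(0, n),
         A_eq = rbind(eq), b_eq = 1, maximize = FALSE)
  }
}

snap_unit <- function(theta, tol = 1e-9) {
  theta[abs(theta - 1) <= tol] <- 1
  pmin(theta, 1)
}

#' Solve a DEA problem
#'
#' Solves the envelopment-form linear program once per DMU (two-phase
#' simplex) for the radial efficiency and peer set, and the dual multiplier
#' form for the optimal weights. Output-oriented expansion factors phi >= 1
#' are reported as `1/phi`, so every efficiency lies in (0, 1] under either
#' orientation; under CRS the two orientations agree. Input and output
#' columns are rescaled by their maxima before solving (efficiencies are
#' invariant to units), and efficiencies within 1e-9 of 1 are snapped to 1
#' for rank stability.
#'
#' @param problem a [dea_problem()].
#' @return list classed `dea_result`: `theta` (named efficiencies),
#'   `reference_set` (peers with positive intensity per DMU),
#'   `optimal_multipliers` (input/output weight vectors per DMU, on the
#'   original scale), `multiplier_value` (multiplier-form optimum, for
#'   duality checks).
#' @export
solve_dea <- function(problem) {
  stopifnot(inherits(problem, "dea_problem"))
  X0 <- problem$inputs; Y0 <- problem$outputs
  sx <- apply(X0, 2, max); sy <- apply(Y0, 2, max)
  sy[sy == 0] <- 1
  X <- sweep(X0, 2, sx, "/"); Y <- sweep(Y0, 2, sy, "/")
  n <- nrow(X); m <- ncol(X); s <- ncol(Y)
  ids <- problem$dmu_ids
  vrs <- problem$returns_to_scale == "VRS"
  theta <- numeric(n); mult_val <- numeric(n)
  refs <- vector("list", n); mults <- vector("list", n)
  for (i in seq_len(n)) {
    if (problem$orientation == "input") {
      # vars (theta, lambda): min theta
      # inputs:  sum_j lambda_j X[j,d] - theta X[i,d] <= 0
      # outputs: sum_j lambda_j Y[j,d]               >= Y[i,d]
      A_le <- cbind(-X[i, ], t(X))
      A_ge <- cbind(rep(0, s), t(Y))
      A_eq <- if (vrs) rbind(c(0, rep(1, n))) else NULL
      sol <- solve_lp(obj = c(1, rep(0, n)),
                      A_le = A_le, b_le = rep(0, m),
                      A_ge = A_ge, b_ge = Y[i, ],
                      A_eq = A_eq, b_eq = if (vrs) 1 else NULL,
                      maximize = FALSE)
      theta[i] <- sol$value
      lambda <- sol$x[-1]
    } else {
      # vars (phi, lambda): max phi
      A_le <- rbind(cbind(rep(0, m), t(X)),
                    cbind(Y[i, ], -t(Y)))
      A_eq <- if (vrs) rbind(c(0, rep(1, n))) else NULL
      sol <- solve_lp(obj = c(1, rep(0, n)),
                      A_le = A_le, b_le = c(X[i, ], rep(0, s)),
                      A_eq = A_eq, b_eq = if (vrs) 1 else NULL,
                      maximize = TRUE)
      theta[i] <- 1 / sol$value
      lambda <- sol$x[-1]
    }
    refs[[i]] <- ids[lambda > 1e-7]
    mlp <- multiplier_lp(X, Y, i, problem$returns_to_scale, problem$orientation)
    msol <- do.call(solve_lp, mlp)
    mult_val[i] <- if (problem$orientation == "input") msol$value else 1 / msol$value
    v <- msol$x[1:m] / sx
    u <- msol$x[m + 1:s] / sy
    mults[[i]] <- list(input_weights = stats::setNames(v, colnames(X0)),
                       output_weights = stats::setNames(u, colnames(Y0)))
  }
  theta <- snap_unit(theta)
  theta[theta <= 0] <- .Machine$double.eps   # guard; cannot occur for valid problems
  names(theta) <- ids
  # an efficient DMU is its own peer
  for (i in seq_len(n)) if (theta[i] == 1) refs[[i]] <- ids[i]
  structure(list(theta = theta,
                 reference_set = stats::setNames(refs, ids),
                 optimal_multipliers = stats::setNames(mults, ids),
                 multiplier_value = stats::setNames(snap_unit(mult_val), ids)),
            class = "dea_result")
}

# Brute-force LP over {x >= 0, A_le x <= b_le, A_eq x = b_eq}: enumerate all
# basic solutions (every subset of active constraints of size n) and take the
# best feasible one. Independent oracle for the simplex path; tiny instances.
lp_vertex_enum <- function(obj, A_le = NULL, b_le = NULL,
                           A_eq = NULL, b_eq = NULL, maximize = TRUE,
                           tol = 1e-9) {
  n <- length(obj)
  rows <- rbind(A_le, A_eq, diag(n))
  rhs <- c(b_le, b_eq, rep(0, n))
  n_le <- if (is.null(A_le)) 0 else nrow(A_le)
  n_eq <- if (is.null(A_eq)) 0 else nrow(A_eq)
  eq_idx <- if (n_eq > 0) n_le + seq_len(n_eq) else integer(0)
  free_idx <- setdiff(seq_len(nrow(rows)), eq_idx)
  best <- if (maximize) -Inf else Inf
  found <- FALSE
  pick <- utils::combn(free_idx, n - n_eq)
  for (j in seq_len(ncol(pick))) {
    act <- c(eq_idx, pick[, j])
    A <- rows[act, , drop = FALSE]
    if (abs(det(A)) < 1e-12) next
    x <- tryCatch(solve(A, rhs[act]), error = function(e) NULL)
    if (is.null(x)) next
    if (any(x < -tol)) next
    if (n_le > 0 && any(A_le %*% x > b_le + tol)) next
    if (n_eq > 0 && any(abs(A_eq %*% x - b_eq) > tol)) next
    val <- sum(obj * x)
    if ((maximize && val > best) || (!maximize && val < best)) best <- val
    found <- TRUE
  }
  if (!found) stop("lp_vertex_enum: no feasible vertex", call. = FALSE)
  best
}

#' Brute-force efficiency oracle for small DEA instances
#'
#' Enumerates every basic solution of the multiplier-form LP for one DMU and
#' returns the best feasible objective. Exponential in size -- restricted to
#' at most 3 total input+output dimensions and 6 DMUs -- and entirely
#' independent of the simplex solver, so it serves as a correctness oracle
#' for [solve_dea()].
#'
#' @param problem a [dea_problem()].
#' @param dmu id of the DMU to score.
#' @return the radial efficiency of `dmu` in (0, 1].
#' @export
vertex_oracle <- function(problem, dmu) {
  stopifnot(inherits(problem, "dea_problem"))
  if (ncol(problem$inputs) + ncol(problem$outputs) > 3)
    stop("vertex_oracle: limited to <= 3 total input+output dimensions",
         call. = FALSE)
  if (nrow(problem$inputs) > 6)
    stop("vertex_oracle: limited to <= 6 DMUs", call. = FALSE)
  i <- match(dmu, problem$dmu_ids)
  if (is.na(i)) stop("vertex_oracle: unknown dmu '", dmu, "'", call. = FALSE)
  mlp <- multiplier_lp(problem$inputs, problem$outputs, i,
                       problem$returns_to_scale, problem$orientation)
  # convert >= rows to <= for the enumerator
  A_le <- mlp$A_le; b_le <- mlp$b_le
  if (!is.null(mlp$A_ge)) { A_le <- -mlp$A_ge; b_le <- -mlp$b_ge }
  val <- lp_vertex_enum(mlp$obj, A_le = A_le, b_le = b_le,
                        A_eq = mlp$A_eq, b_eq = mlp$b_eq,
                        maximize = mlp$maximize)
  eff <- if (problem$orientation == "input") val else 1 / val
  unname(snap_unit(eff))
}
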