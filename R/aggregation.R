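quality_index_set <- function(method, values, weights_used = NULL) {
  if (any(values <= 0))
    stop("quality index degenerate: nonpositive index for ",
         paste(names(values)[values <= 0], collapse = ", "), call. = FALSE)
  structure(list(method = method, values = values, weights_used = weights_used),
            class = "quality_index_set")
}

#' Unweighted composite quality index
#'
#' Each DCM's criterion scores are averaged (sum of scores divided by the
#' number of criteria) and every mean is divided by the best DCM's mean, so
#' the top performer scores exactly 1 and all indices lie in (0, 1].
#'
#' @param matrix a [score_matrix()].
#' @return a `quality_index_set` with `method = "unweighted"` and one index
#'   per DCM.
#' @export
unweighted_index <- function(matrix) {
  stopifnot(inherits(matrix, "score_matrix"))
  means <- rowMeans(matrix)
  top <- max(means)
  if (top == 0) stop("unweighted_index: all scores zero", call. = FALSE)
  quality_index_set("unweighted", means / top)
}

#' Expert-weighted composite quality index
#'
#' Criterion weights fixed a priori (e.g. by expert consensus) are
#' normalized to sum to one; each DCM's weighted mean score is then divided
#' by the maximum weighted mean, mirroring the unweighted convention. Equal
#' weights reduce to [unweighted_index()].
#'
#' @param matrix a [score_matrix()].
#' @param weights named nonnegative vector covering every criterion,
#'   not all zero.
#' @return a `quality_index_set` with `method = "weighted"`.
#' @export
weighted_index <- function(matrix, weights) {
  stopifnot(inherits(matrix, "score_matrix"))
  crits <- colnames(matrix)
  if (!all(crits %in% names(weights)))
    stop("weighted_index: weights missing for ",
         paste(setdiff(crits, names(weights)), collapse = ", "), call. = FALSE)
  w <- weights[crits]
  if (any(w < 0)) stop("weighted_index: negative weight", call. = FALSE)
  if (sum(w) == 0) stop("weighted_index: zero weight vector", call. = FALSE)
  w <- w / sum(w)
  means <- drop(unclass(matrix) %*% w)
  top <- max(means)
  if (top == 0) stop("weighted_index: all weighted scores zero", call. = FALSE)
  quality_index_set("weighted", means / top, weights_used = w)
}

# benefit-of-the-doubt LP for one row: maximize w . y_eval subject to
# w . y_j <= 1 for every row j of the constraint set, w >= 0
bod_lp <- function(y_eval, constraint_rows) {
  sol <- solve_lp(obj = y_eval,
                  A_le = constraint_rows,
                  b_le = rep(1, nrow(constraint_rows)),
                  maximize = TRUE)
  list(value = snap_unit(sol$value), weights = sol$x)
}

#' Benefit-of-the-doubt (DEA-based) composite quality index
#'
#' Each DCM receives the criterion weights most favourable to itself:
#' maximize its own weighted score subject to no observation in the
#' constraint set exceeding 1, weights nonnegative (the multiplier form of
#' an output-only CCR model with a unit input). With only the consensus
#' matrix as constraint set the method has low discriminatory power -- most
#' DCMs attain 1; pooling the individual expert matrices multiplies the
#' number of observations and sharpens discrimination, with each DCM scored
#' as the mean of its per-expert optima.
#'
#' @param matrix the consensus [score_matrix()].
#' @param pooling `"consensus_only"` or `"pooled_experts"`.
#' @param panel list of expert [score_matrix()] objects; required for
#'   `"pooled_experts"`.
#' @return a `quality_index_set` with `method = "bod"`; `weights_used`
#'   holds each DCM's optimal weight vector (consensus mode).
#' @export
bod_index <- function(matrix, pooling = c("consensus_only", "pooled_experts"),
                      panel = NULL) {
  stopifnot(inherits(matrix, "score_matrix"))
  pooling <- match.arg(pooling)
  if (any(rowSums(matrix) == 0))
    stop("bod_index: all-zero score row for ",
         paste(rownames(matrix)[rowSums(matrix) == 0], collapse = ", "),
         call. = FALSE)
  ids <- rownames(matrix)
  if (pooling == "consensus_only") {
    cons <- unclass(matrix)
    res <- lapply(ids, function(id) bod_lp(cons[id, ], cons))
    vals <- vapply(res, `[[`, numeric(1), "value")
    w <- lapply(res, function(r)
      stats::setNames(r$weights, colnames(matrix)))
    quality_index_set("bod", stats::setNames(vals, ids),
                      weights_used = stats::setNames(w, ids))
  } else {
    if (is.null(panel) || length(panel) == 0)
      stop("bod_index: pooled_experts requires the expert panel", call. = FALSE)
    for (m in panel)
      if (!identical(dimnames(m), dimnames(matrix)))
        stop("bod_index: panel matrices must match the consensus shape",
             call. = FALSE)
    pooled <- do.call(rbind, lapply(panel, unclass))
    vals <- vapply(ids, function(id) {
      per_expert <- vapply(panel, function(m)
        bod_lp(unclass(m)[id, ], pooled)$value, numeric(1))
      mean(per_expert)
    }, numeric(1))
    quality_index_set("bod", vals)
  }
}
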