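#' Specify score distributions for a simulated expert panel
#'
#' Each (DCM, criterion) cell carries a triangular score distribution given
#' by its mean and support `[min, max]`, all within the 0-10 scoring scale.
#' A triangular distribution is natively parameterised by (min, mode, max);
#' from the mean identity `mean = (min + mode + max) / 3` the mode is
#' recovered as `mode = 3 * mean - min - max`, and specifications whose
#' implied mode falls outside the support are rejected.
#'
#' @param df data.frame with columns `dcm_id, criterion, mean, min, max`.
#' @return the validated data.frame, classed `score_distribution_spec`,
#'   with a derived `mode` column.
#' @export
score_distribution_spec <- function(df) {
  required <- c("dcm_id", "criterion", "mean", "min", "max")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop("score_distribution_spec: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df[c("dcm_id", "criterion")]))
    stop("score_distribution_spec: duplicated (dcm_id, criterion) cell",
         call. = FALSE)
  bad <- which(!(df$min >= 0 & df$max <= 10 & df$min <= df$mean &
                   df$mean <= df$max))
  if (length(bad) > 0)
    stop(sprintf("score_distribution_spec: cell (%s, %s): need 0 <= min <= mean <= max <= 10",
                 df$dcm_id[bad[1]], df$criterion[bad[1]]), call. = FALSE)
  df$mode <- 3 * df$mean - df$min - df$max
  eps <- 1e-9
  bad <- which(df$mode < df$min - eps | df$mode > df$max + eps)
  if (length(bad) > 0)
    stop(sprintf("score_distribution_spec: cell (%s, %s): derived mode %.4f outside [min, max] = [%.4f, %.4f]",
                 df$dcm_id[bad[1]], df$criterion[bad[1]],
                 df$mode[bad[1]], df$min[bad[1]], df$max[bad[1]]),
         call. = FALSE)
  df$mode <- pmin(pmax(df$mode, df$min), df$max)
  class(df) <- c("score_distribution_spec", "data.frame")
  df
}

#' Read a panel distribution spec from CSV
#'
#' Header: `dcm_id,criterion,mean,min,max`.
#'
#' @param path CSV file path.
#' @return a [score_distribution_spec()].
#' @export
read_panel_spec_csv <- function(path) {
  if (!file.exists(path)) stop("read_panel_spec_csv: file not found: ", path,
                               call. = FALSE)
  score_distribution_spec(utils::read.csv(path, stringsAsFactors = FALSE))
}

# Deterministic 31-bit stream id for one (dcm, criterion) cell under a master
# seed, so each cell draws from its own substream: editing one cell's spec
# never perturbs another cell's draws.
cell_seed <- function(seed, dcm_id, criterion) {
  key <- paste0(dcm_id, "\r", criterion)
  h <- 0
  for (v in utf8ToInt(key)) h <- (h * 31 + v) %% 2147483647
  as.integer((h + (as.numeric(seed) %% 2147483647) * 69069) %% 2147483647)
}

#' Draw scores from a triangular distribution
#'
#' Inverse-CDF sampling from Triangular(min, mode, max) with
#' `mode = 3 * mean - min - max`. A degenerate spec (`min == max`) returns
#' the constant. Draws are clipped to the 0-10 scoring scale as a defensive
#' guard (the spec validation already confines the support to it).
#'
#' @param min,mean,max distribution parameters on the score scale.
#' @param n number of draws.
#' @param seed optional integer; when given, draws come from a local RNG
#'   stream and the caller's RNG state is left untouched.
#' @return numeric vector of `n` scores.
#' @export
sample_triangular <- function(min, mean, max, n, seed = NULL) {
  if (n < 1) stop("sample_triangular: n must be >= 1", call. = FALSE)
  if (!(min <= mean && mean <= max))
    stop("sample_triangular: need min <= mean <= max", call. = FALSE)
  mode <- 3 * mean - min - max
  if (mode < min - 1e-9 || mode > max + 1e-9)
    stop(sprintf("sample_triangular: derived mode %.6f outside [%.6f, %.6f]",
                 mode, min, max), call. = FALSE)
  mode <- base::min(base::max(mode, min), max)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (is.null(old))
      suppressWarnings(rm(list = ".Random.seed", envir = globalenv()))
      else assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
  }
  if (max == min) return(rep(min, n))
  u <- stats::runif(n)
  fc <- (mode - min) / (max - min)
  x <- ifelse(u < fc,
              min + sqrt(u * (max - min) * (mode - min)),
              max - sqrt((1 - u) * (max - min) * (max - mode)))
  pmin(pmax(x, 0), 10)
}

#' Simulate an expert scoring panel
#'
#' Draws `n_experts` complete score matrices, each cell independently from
#' its triangular distribution. Each (DCM, criterion) cell uses a dedicated
#' RNG substream derived from `seed`, so the simulation is reproducible and
#' cells are mutually independent.
#'
#' @param spec a [score_distribution_spec()] covering every cell.
#' @param n_experts number of experts (the stylised example uses six).
#' @param seed master integer seed.
#' @return list of `n_experts` [score_matrix()] objects, panel ids
#'   `"expert1"`, `"expert2"`, ...
#' @export
generate_panel <- function(spec, n_experts = 6, seed = 1) {
  if (!inherits(spec, "score_distribution_spec"))
    spec <- score_distribution_spec(spec)
  if (n_experts < 1) stop("generate_panel: n_experts must be >= 1", call. = FALSE)
  dcms <- unique(spec$dcm_id)
  crits <- unique(spec$criterion)
  if (nrow(spec) != length(dcms) * length(crits))
    stop("generate_panel: spec incomplete over the DCM x criteria grid",
         call. = FALSE)
  draws <- matrix(NA_real_, nrow = nrow(spec), ncol = n_experts)
  for (i in seq_len(nrow(spec))) {
    draws[i, ] <- sample_triangular(spec$min[i], spec$mean[i], spec$max[i],
                                    n = n_experts,
                                    seed = cell_seed(seed, spec$dcm_id[i],
                                                     spec$criterion[i]))
  }
  lapply(seq_len(n_experts), function(e) {
    m <- matrix(NA_real_, length(dcms), length(crits),
                dimnames = list(dcms, crits))
    m[cbind(spec$dcm_id, spec$criterion)] <- draws[, e]
    score_matrix(m, panel_id = paste0("expert", e))
  })
}

#' Combine a panel of expert matrices into a consensus matrix
#'
#' The consensus is the cell-wise arithmetic mean of the expert matrices
#' (the simplest symmetric combiner; swap in another rule by combining the
#' matrices yourself).
#'
#' @param panel list of [score_matrix()] objects with identical dimnames.
#' @return a [score_matrix()] with `panel_id = "consensus"`.
#' @export
consensus_from_panel <- function(panel) {
  if (length(panel) < 1) stop("consensus_from_panel: empty panel", call. = FALSE)
  ref <- dimnames(panel[[1]])
  for (m in panel)
    if (!identical(dimnames(m), ref))
      stop("consensus_from_panel: score matrices have mismatched shapes",
           call. = FALSE)
  acc <- Reduce(`+`, lapply(panel, unclass))
  score_matrix(acc / length(panel), panel_id = "consensus")
}

#' Write panel score matrices to a long-format CSV
#'
#' Inverse of [read_scores_csv()]; used by the `simulate-panel` CLI
#' subcommand.
#'
#' @param matrices list of [score_matrix()] objects.
#' @param path output CSV path.
#' @export
write_scores_csv <- function(matrices, path) {
  rows <- lapply(matrices, function(m) {
    data.frame(dcm_id = rep(rownames(m), times = ncol(m)),
               panel_id = attr(m, "panel_id"),
               criterion = rep(colnames(m), each = nrow(m)),
               score = as.vector(unclass(m)))
  })
  df <- do.call(rbind, rows)
  df$score <- trimws(formatC(df$score, digits = 15, format = "g"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
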