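#' Quality-adjusted data index
#'
#' The QADI combines how much data a method produces with how good that
#' data is: `quality_index * quantity`, in person-equivalents of
#' fully-quality data.
#'
#' @param quality_index composite quality index in (0, 1].
#' @param quantity quantity-of-data measure (unit records or target
#'   population), persons.
#' @return person-equivalents; vectorized.
#' @export
qadi <- function(quality_index, quantity) {
  if (any(quality_index <= 0 | quality_index > 1))
    stop("qadi: quality_index must be in (0, 1]", call. = FALSE)
  if (any(quantity < 1)) stop("qadi: quantity must be >= 1", call. = FALSE)
  quality_index * quantity
}

#' Cost-effectiveness ratio: cost per QADI
#'
#' @param vital_stats_cost apportioned annual cost, currency.
#' @param qadi quality-adjusted data index, person-equivalents.
#' @return currency per person-equivalent; lower is better.
#' @export
cea_ratio <- function(vital_stats_cost, qadi) {
  if (any(vital_stats_cost <= 0)) stop("cea_ratio: cost must be > 0", call. = FALSE)
  if (any(qadi <= 0)) stop("cea_ratio: qadi must be > 0", call. = FALSE)
  vital_stats_cost / qadi
}

competition_rank <- function(x) as.integer(rank(x, ties.method = "min"))

#' Rank values ascending with competition ranking
#'
#' Smallest value gets rank 1; ties share the smallest applicable rank and
#' the next rank is skipped accordingly (1, 1, 3, ...). Ranks depend only on
#' the values, never on input order; display order of ties is by id.
#'
#' @param values named numeric vector (names = dcm ids).
#' @param method label stored in the resulting table.
#' @return list classed `rank_table`: `method`, `ranks`, `basis`.
#' @export
rank_ascending <- function(values, method = "ascending") {
  if (length(values) == 0) stop("rank_ascending: empty input", call. = FALSE)
  r <- competition_rank(values)
  names(r) <- names(values)
  structure(list(method = method, ranks = r, basis = values),
            class = "rank_table")
}

#' @export
print.rank_table <- function(x, ...) {
  ord <- order(x$ranks, names(x$ranks))
  df <- data.frame(dcm_id = names(x$ranks)[ord],
                   value = unname(x$basis[ord]),
                   rank = unname(x$ranks[ord]))
  cat("<rank_table>", x$method, "\n")
  print(df, row.names = FALSE)
  invisible(x)
}

#' DEA cost-efficiency index and ranking
#'
#' Builds the efficiency-analysis DEA problem from the scenario's
#' `dea_settings` and solves it. The default model uses the apportioned
#' vital-statistics cost as the single input and the QADI as the single
#' output under constant returns to scale, making the efficiency score
#' `theta_i` proportional to `QADI_i / cost_i` -- so its ranking coincides
#' exactly with the cost-per-QADI ranking. Alternative `outputs_mode`
#' settings (quantity and quality as separate outputs, or quantity plus the
#' raw criterion scores) are provided for sensitivity analysis.
#'
#' @param records [dcm_records()] already filtered to the evaluated DCMs.
#' @param quality a `quality_index_set` for those DCMs.
#' @param config a [scenario_config()].
#' @param scores the consensus [score_matrix()] (needed for
#'   `outputs_mode = "quantity_and_criteria"`).
#' @return list: `theta` (named efficiencies), `rank_table` (descending
#'   theta, competition ranks), `dea_result` (full [solve_dea()] output).
#' @export
efficiency_index <- function(records, quality, config, scores = NULL) {
  ids <- records$dcm_id
  quantity <- quantity_of(records, config$quantity_metric)
  cost <- vital_stats_cost(records)
  q <- quality$values[ids]
  outputs <- switch(config$dea$outputs_mode,
    qadi_single_output = cbind(qadi = qadi(q, quantity)),
    quantity_and_quality = cbind(quantity = quantity, quality = q),
    quantity_and_criteria = {
      if (is.null(scores))
        stop("efficiency_index: quantity_and_criteria needs the score matrix",
             call. = FALSE)
      cbind(quantity = quantity, unclass(scores)[ids, , drop = FALSE])
    })
  rownames(outputs) <- ids
  problem <- dea_problem(inputs = cbind(cost = cost), outputs = outputs,
                         returns_to_scale = config$dea$returns_to_scale,
                         orientation = config$dea$orientation)
  res <- solve_dea(problem)
  rt <- rank_ascending(-res$theta, method = "efficiency")
  rt$basis <- res$theta
  list(theta = res$theta, rank_table = rt, dea_result = res)
}

quantity_of <- function(records, metric) {
  stats::setNames(records[[metric]], records$dcm_id)
}

#' Run a full scenario evaluation
#'
#' Applies the scenario's policy switches (CRVS inclusion, quantity metric,
#' criteria set), aggregates quality by the configured method, and computes
#' QADI, cost per QADI with league-table ranks, and DEA efficiency with
#' ranks. Fully deterministic: identical inputs yield identical results.
#'
#' @param records a [dcm_records()] data.frame (may include CRVS; it is
#'   dropped when `config$include_crvs` is `FALSE`).
#' @param scores a consensus [score_matrix()], or a named list of score
#'   matrices containing a `"consensus"` element plus expert matrices
#'   (needed for benefit-of-the-doubt pooling).
#' @param config a [scenario_config()].
#' @return data.frame classed `dcm_evaluation` with columns `dcm_id,
#'   quality_index, quantity, vital_stats_cost, qadi, cost_per_qadi,
#'   cea_rank, efficiency_theta, ea_rank`; the scenario name, config and
#'   report precision are attached as attributes.
#' @export
run_scenario <- function(records, scores, config) {
  stopifnot(inherits(config, "scenario_config"))
  if (!inherits(records, "dcm_records")) records <- dcm_records(records)
  panel <- NULL
  if (is.list(scores) && !inherits(scores, "score_matrix")) {
    if (!"consensus" %in% names(scores))
      stop("run_scenario: score list must contain a 'consensus' matrix",
           call. = FALSE)
    panel <- scores[setdiff(names(scores), "consensus")]
    scores <- scores[["consensus"]]
  }
  stopifnot(inherits(scores, "score_matrix"))
  if (!config$include_crvs) records <- records[records$dcm_id != "CRVS", ]
  ids <- records$dcm_id
  if (!all(ids %in% rownames(scores)))
    stop("run_scenario: scores missing for dcm(s): ",
         paste(setdiff(ids, rownames(scores)), collapse = ", "), call. = FALSE)
  if (!all(config$criteria %in% colnames(scores)))
    stop("run_scenario: score matrix missing criteria: ",
         paste(setdiff(config$criteria, colnames(scores)), collapse = ", "),
         call. = FALSE)
  sm <- score_matrix(unclass(scores)[ids, as.character(config$criteria),
                                     drop = FALSE],
                     panel_id = attr(scores, "panel_id"))
  if (!is.null(panel))
    panel <- lapply(panel, function(m)
      score_matrix(unclass(m)[ids, as.character(config$criteria), drop = FALSE],
                   panel_id = attr(m, "panel_id")))
  quality <- switch(config$aggregation,
    unweighted = unweighted_index(sm),
    weighted = weighted_index(sm, config$expert_weights),
    bod = bod_index(sm, pooling = config$dea$pooling, panel = panel))
  quantity <- quantity_of(records, config$quantity_metric)
  cost <- vital_stats_cost(records)
  q <- quality$values[ids]
  qa <- qadi(q, quantity)
  ratio <- cea_ratio(cost, qa)
  cea <- rank_ascending(ratio, method = "cost per QADI")
  ea <- efficiency_index(records, quality, config, scores = sm)
  out <- data.frame(dcm_id = ids,
                    quality_index = unname(q),
                    quantity = unname(quantity),
                    vital_stats_cost = unname(cost),
                    qadi = unname(qa),
                    cost_per_qadi = unname(ratio),
                    cea_rank = unname(cea$ranks[ids]),
                    efficiency_theta = unname(ea$theta[ids]),
                    ea_rank = unname(ea$rank_table$ranks[ids]),
                    stringsAsFactors = FALSE)
  structure(out,
            class = c("dcm_evaluation", "data.frame"),
            scenario = config$name,
            config = config,
            report_precision = config$report_precision)
}

#' Concordance between two rankings
#'
#' Kendall's tau and Spearman's rho between the rank vectors of two
#' [rank_ascending()] tables (or two named rank vectors) over the same DCM
#' set, with standard tie corrections (tau-b).
#'
#' @param a,b `rank_table` objects or named integer vectors of ranks.
#' @return list: `kendall_tau`, `spearman_rho`, `n`.
#' @export
compare_rankings <- function(a, b) {
  ra <- if (inherits(a, "rank_table")) a$ranks else a
  rb <- if (inherits(b, "rank_table")) b$ranks else b
  if (!setequal(names(ra), names(rb)))
    stop("compare_rankings: mismatched DCM sets", call. = FALSE)
  rb <- rb[names(ra)]
  list(kendall_tau = stats::cor(ra, rb, method = "kendall"),
       spearman_rho = stats::cor(ra, rb, method = "spearman"),
       n = length(ra))
}
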