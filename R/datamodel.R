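#' Validate a table of data collection methods
#'
#' A DCM record describes one data collection method: its identifier, the
#' number of unit records it produces per year (`sample_size`), the
#' population it aims to cover (`target_population`), its total annual cost,
#' and the fraction of that cost attributable to vital-statistics work
#' (`apportion_fraction`).
#'
#' @param df data.frame with columns `dcm_id`, `name`, `sample_size`,
#'   `target_population`, `total_annual_cost`, `apportion_fraction`.
#' @return the validated data.frame, invisibly classed `dcm_records`.
#' @export
dcm_records <- function(df) {
  required <- c("dcm_id", "name", "sample_size", "target_population",
                "total_annual_cost", "apportion_fraction")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop("dcm_records: missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  df$dcm_id <- as.character(df$dcm_id)
  if (anyDuplicated(df$dcm_id))
    stop("dcm_records: duplicate dcm_id: ",
         paste(unique(df$dcm_id[duplicated(df$dcm_id)]), collapse = ", "),
         call. = FALSE)
  check_field <- function(field, ok, what) {
    bad <- which(!ok(df[[field]]))
    if (length(bad) > 0)
      stop(sprintf("dcm_records: row %d (dcm_id '%s'): %s must be %s (got %s)",
                   bad[1], df$dcm_id[bad[1]], field, what, df[[field]][bad[1]]),
           call. = FALSE)
  }
  check_field("sample_size", function(x) is.finite(x) & x >= 1, ">= 1")
  check_field("target_population", function(x) is.finite(x) & x >= 1, ">= 1")
  check_field("total_annual_cost", function(x) is.finite(x) & x > 0, "> 0")
  check_field("apportion_fraction",
              function(x) is.finite(x) & x > 0 & x <= 1, "in (0, 1]")
  class(df) <- c("dcm_records", "data.frame")
  df
}

#' Annual cost attributable to vital statistics
#'
#' Apportions each method's total annual cost to its vital-statistics
#' activity: `total_annual_cost * apportion_fraction`. Linear in the total
#' cost, so currency rescaling carries through unchanged.
#'
#' @param records a `dcm_records` data.frame (see [dcm_records()]).
#' @return named numeric vector of apportioned costs, one per DCM.
#' @export
vital_stats_cost <- function(records) {
  stats::setNames(records$total_annual_cost * records$apportion_fraction,
                  records$dcm_id)
}

#' Define the set of quality criteria
#'
#' The assessment framework scores each DCM on accuracy, relevance,
#' consistency, timeliness and accessibility; when the government pursues a
#' long-term CRVS policy, "improvement" (towards CRVS) is added as a sixth
#' criterion.
#'
#' @param criteria character vector of unique, non-empty criterion names.
#' @return character vector classed `criteria_set`.
#' @export
criteria_set <- function(criteria) {
  criteria <- as.character(criteria)
  if (length(criteria) == 0) stop("criteria_set: must be non-empty", call. = FALSE)
  if (anyDuplicated(criteria))
    stop("criteria_set: duplicate criterion names", call. = FALSE)
  structure(criteria, class = "criteria_set")
}

#' Construct a score matrix for one scoring panel
#'
#' Scores lie on a linear 0-10 scale, one value per (DCM, criterion) cell.
#' A matrix can hold the panel's consensus scores (`panel_id = "consensus"`)
#' or one expert's individual scores.
#'
#' @param scores numeric matrix, rows = DCMs (rownames = dcm_id),
#'   columns = criteria (colnames).
#' @param panel_id identifier of the panel or expert.
#' @return the matrix classed `score_matrix` with a `panel_id` attribute.
#' @export
score_matrix <- function(scores, panel_id = "consensus") {
  scores <- as.matrix(scores)
  if (is.null(rownames(scores)) || is.null(colnames(scores)))
    stop("score_matrix: scores must carry dcm_id rownames and criterion colnames",
         call. = FALSE)
  if (anyNA(scores)) {
    idx <- which(is.na(scores), arr.ind = TRUE)[1, ]
    stop(sprintf("score_matrix (panel '%s'): missing score for dcm '%s', criterion '%s'",
                 panel_id, rownames(scores)[idx[1]], colnames(scores)[idx[2]]),
         call. = FALSE)
  }
  if (any(scores < 0 | scores > 10)) {
    idx <- which(scores < 0 | scores > 10, arr.ind = TRUE)[1, ]
    stop(sprintf("score_matrix (panel '%s'): score %g for dcm '%s', criterion '%s' outside [0, 10]",
                 panel_id, scores[idx[1], idx[2]],
                 rownames(scores)[idx[1]], colnames(scores)[idx[2]]),
         call. = FALSE)
  }
  structure(scores, panel_id = as.character(panel_id),
            class = c("score_matrix", "matrix", "array"))
}

#' DEA model settings
#'
#' Configuration of the efficiency-analysis model. The default -- constant
#' returns to scale, input orientation, a single output (the QADI) against a
#' single input (the vital-statistics cost), scored from consensus data --
#' is the most transparent choice and makes the efficiency ranking provably
#' identical to the cost-effectiveness ranking.
#'
#' @param returns_to_scale `"CRS"` (constant) or `"VRS"` (variable).
#' @param orientation `"input"` (contract inputs) or `"output"` (expand
#'   outputs; reported as the reciprocal so scores stay in (0, 1]).
#' @param outputs_mode what the DEA outputs are: `"qadi_single_output"`
#'   (QADI only), `"quantity_and_quality"` (quantity and composite quality
#'   as two outputs), or `"quantity_and_criteria"` (quantity plus each raw
#'   criterion score).
#' @param pooling `"consensus_only"` or `"pooled_experts"` (benefit-of-the-
#'   doubt constraint set enlarged with each expert's rows).
#' @return list classed `dea_settings`.
#' @export
dea_settings <- function(returns_to_scale = c("CRS", "VRS"),
                         orientation = c("input", "output"),
                         outputs_mode = c("qadi_single_output",
                                          "quantity_and_quality",
                                          "quantity_and_criteria"),
                         pooling = c("consensus_only", "pooled_experts")) {
  structure(list(returns_to_scale = match.arg(returns_to_scale),
                 orientation = match.arg(orientation),
                 outputs_mode = match.arg(outputs_mode),
                 pooling = match.arg(pooling)),
            class = "dea_settings")
}

#' Scenario configuration
#'
#' Bundles the policy switches that define an evaluation scenario: which
#' quantity-of-data measure to use, whether CRVS itself is evaluated, the
#' criteria set, the aggregation method for the composite quality index, and
#' the DEA settings. In the bundled stylised example, Scenario A (long-term
#' CRVS policy) uses unit records approximated by sample size, excludes CRVS
#' from the comparison and includes the "improvement" criterion; Scenario B
#' uses target population, includes CRVS (with 30% of its cost apportioned
#' to vital statistics) and drops "improvement".
#'
#' @param name scenario label.
#' @param quantity_metric `"sample_size"` or `"target_population"`.
#' @param include_crvs logical; is CRVS one of the evaluated methods?
#' @param criteria a [criteria_set()] or character vector of criteria.
#' @param aggregation `"unweighted"`, `"weighted"` or `"bod"`
#'   (benefit of the doubt).
#' @param expert_weights named numeric vector of nonnegative criterion
#'   weights; required iff `aggregation = "weighted"`.
#' @param dea a [dea_settings()] object.
#' @param report_precision decimal places used when rendering reports.
#' @return list classed `scenario_config`.
#' @export
scenario_config <- function(name,
                            quantity_metric = c("sample_size", "target_population"),
                            include_crvs = FALSE,
                            criteria,
                            aggregation = c("unweighted", "weighted", "bod"),
                            expert_weights = NULL,
                            dea = dea_settings(),
                            report_precision = 4L) {
  aggregation <- match.arg(aggregation)
  if (!inherits(criteria, "criteria_set")) criteria <- criteria_set(criteria)
  if (aggregation == "weighted") {
    if (is.null(expert_weights))
      stop("scenario_config: expert_weights required for weighted aggregation",
           call. = FALSE)
    if (!all(criteria %in% names(expert_weights)))
      stop("scenario_config: expert_weights must cover every criterion",
           call. = FALSE)
  }
  if (!inherits(dea, "dea_settings")) stop("scenario_config: dea must be dea_settings()",
                                           call. = FALSE)
  structure(list(name = as.character(name),
                 quantity_metric = match.arg(quantity_metric),
                 include_crvs = isTRUE(include_crvs),
                 criteria = criteria,
                 aggregation = aggregation,
                 expert_weights = expert_weights,
                 dea = dea,
                 report_precision = as.integer(report_precision)),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>", x$name, "\n")
  cat("  quantity_metric:", x$quantity_metric,
      "| include_crvs:", x$include_crvs, "\n")
  cat("  criteria:", paste(x$criteria, collapse = ", "), "\n")
  cat("  aggregation:", x$aggregation,
      "| dea:", x$dea$returns_to_scale, x$dea$orientation,
      x$dea$outputs_mode, x$dea$pooling, "\n")
  invisible(x)
}
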