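#' Read a DCM descriptor table from CSV
#'
#' Expected header: `dcm_id,name,sample_size,target_population,
#' total_annual_cost,apportion_percent`. The apportion percentage in the
#' file (e.g. 30) is converted to a fraction (0.30) on read.
#'
#' @param path CSV file path.
#' @return a validated [dcm_records()] data.frame.
#' @export
read_dcm_csv <- function(path) {
  if (!file.exists(path)) stop("read_dcm_csv: file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("dcm_id", "name", "sample_size", "target_population",
                "total_annual_cost", "apportion_percent")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop("read_dcm_csv: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df$apportion_fraction <- df$apportion_percent / 100
  df$apportion_percent <- NULL
  dcm_records(df)
}

#' Read long-format score matrices from CSV
#'
#' Expected header: `dcm_id,panel_id,criterion,score`, one row per cell.
#' Rows for criteria outside `criteria` are ignored, so one file can serve
#' scenarios with different criteria sets. Each panel must be complete over
#' the DCM set crossed with the criteria set.
#'
#' @param path CSV file path.
#' @param criteria a [criteria_set()] or character vector.
#' @param dcm_ids optional character vector fixing the DCM set; defaults to
#'   the ids present in the file.
#' @return named list of [score_matrix()] objects, one per `panel_id`.
#' @export
read_scores_csv <- function(path, criteria, dcm_ids = NULL) {
  if (!file.exists(path)) stop("read_scores_csv: file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("dcm_id", "panel_id", "criterion", "score")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop("read_scores_csv: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  criteria <- as.character(criteria)
  df <- df[df$criterion %in% criteria, , drop = FALSE]
  if (nrow(df) == 0) stop("read_scores_csv: no panels found", call. = FALSE)
  if (is.null(dcm_ids)) dcm_ids <- unique(df$dcm_id)
  panels <- split(df, df$panel_id)
  out <- lapply(names(panels), function(pid) {
    sub <- panels[[pid]]
    m <- matrix(NA_real_, nrow = length(dcm_ids), ncol = length(criteria),
                dimnames = list(dcm_ids, criteria))
    keep <- sub$dcm_id %in% dcm_ids
    m[cbind(sub$dcm_id[keep], sub$criterion[keep])] <- sub$score[keep]
    score_matrix(m, panel_id = pid)   # completeness + range enforced here
  })
  stats::setNames(out, names(panels))
}

#' Read a scenario configuration from YAML
#'
#' Keys: `name, quantity_metric, include_crvs, criteria, aggregation,
#' expert_weights, dea: {returns_to_scale, orientation, outputs_mode,
#' pooling}, report_precision`.
#'
#' @param path YAML file path.
#' @return a [scenario_config()] object.
#' @export
read_scenario_yaml <- function(path) {
  if (!file.exists(path)) stop("read_scenario_yaml: file not found: ", path,
                               call. = FALSE)
  y <- yaml::read_yaml(path)
  dea_args <- y$dea %||% list()
  weights <- y$expert_weights
  if (!is.null(weights)) weights <- unlist(weights)
  scenario_config(name = y$name %||% tools::file_path_sans_ext(basename(path)),
                  quantity_metric = y$quantity_metric,
                  include_crvs = isTRUE(y$include_crvs),
                  criteria = unlist(y$criteria),
                  aggregation = y$aggregation %||% "unweighted",
                  expert_weights = weights,
                  dea = do.call(dea_settings, dea_args),
                  report_precision = y$report_precision %||% 4L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

extdata <- function(file) {
  p <- system.file("extdata", file, package = "dcmeval", mustWork = TRUE)
  p
}

#' Load the bundled stylised-country fixture
#'
#' Returns the worked example of a hypothetical low-income country (33
#' million population, incomplete CRVS, nine further health-information
#' systems). Scenario A evaluates 9 DCMs (CRVS excluded) on six criteria
#' with quantity = unit records (sample size); Scenario B evaluates all 10
#' DCMs on five criteria with quantity = target population. Consensus
#' scores are stored at full precision (means of six integer expert scores,
#' i.e. exact sixths); the published two-decimal values are these rounded.
#'
#' @param name `"scenarioA"` or `"scenarioB"`.
#' @return list with elements `records` ([dcm_records()]), `scores`
#'   (consensus [score_matrix()]) and `config` ([scenario_config()]).
#' @export
load_fixture <- function(name = c("scenarioA", "scenarioB")) {
  name <- match.arg(name)
  records <- read_dcm_csv(extdata(paste0(name, "_dcm.csv")))
  config <- read_scenario_yaml(extdata(paste0(name, ".yaml")))
  scores <- read_scores_csv(extdata(paste0(name, "_scores.csv")),
                            criteria = config$criteria,
                            dcm_ids = records$dcm_id)
  list(records = records, scores = scores[["consensus"]], config = config)
}

#' Write an evaluation report to CSV or JSON
#'
#' Columns, in fixed order: `dcm_id, quality_index, quantity,
#' vital_stats_cost, qadi, cost_per_qadi, cea_rank, efficiency_theta,
#' ea_rank`. Floating-point columns are rounded to `precision` decimals at
#' write time; internal computation is always at full precision.
#'
#' @param result an evaluation table from [run_scenario()].
#' @param path output file path.
#' @param format `"csv"` or `"json"`.
#' @param precision decimal places; defaults to the scenario's
#'   `report_precision`.
#' @export
write_report <- function(result, path, format = c("csv", "json"),
                         precision = NULL) {
  format <- match.arg(format)
  precision <- precision %||% attr(result, "report_precision") %||% 4L
  cols <- c("dcm_id", "quality_index", "quantity", "vital_stats_cost",
            "qadi", "cost_per_qadi", "cea_rank", "efficiency_theta", "ea_rank")
  out <- as.data.frame(result)[, cols]
  num <- c("quality_index", "quantity", "vital_stats_cost", "qadi",
           "cost_per_qadi", "efficiency_theta")
  out[num] <- lapply(out[num], round, digits = precision)
  out$cea_rank <- as.integer(out$cea_rank)
  out$ea_rank <- as.integer(out$ea_rank)
  if (format == "csv") {
    chr <- out
    ratio_cols <- c("quality_index", "cost_per_qadi", "efficiency_theta")
    chr[ratio_cols] <- lapply(chr[ratio_cols], formatC,
                              format = "f", digits = precision)
    big_cols <- c("quantity", "vital_stats_cost", "qadi")
    chr[big_cols] <- lapply(chr[big_cols], function(x)
      format(x, scientific = FALSE, trim = TRUE, drop0trailing = TRUE))
    utils::write.csv(chr, path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(out, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read back a report written by [write_report()]
#'
#' @param path report file path.
#' @param format `"csv"` or `"json"`; guessed from the extension by default.
#' @return data.frame with the report columns.
#' @export
read_report <- function(path, format = NULL) {
  format <- format %||% if (grepl("\\.json$", path)) "json" else "csv"
  if (format == "json") {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
}
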