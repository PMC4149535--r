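#' Build a run manifest for reproducibility
#'
#' Because rankings are sensitive to the scenario configuration (quantity
#' metric, criteria set, aggregation, DEA model), every rendered report
#' carries the full configuration, the MD5 checksums of its input files, and
#' any simulation seed.
#'
#' @param config a [scenario_config()].
#' @param input_files character vector of input file paths (checksummed if
#'   they exist).
#' @param seed simulation seed, if one was used.
#' @return list classed `run_manifest`.
#' @export
run_manifest <- function(config, input_files = character(0), seed = NULL) {
  existing <- input_files[file.exists(input_files)]
  sums <- if (length(existing)) tools::md5sum(existing) else character(0)
  structure(list(tool = paste0("dcmeval ",
                               as.character(utils::packageVersion("dcmeval"))),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 checksums = sums,
                 config = config,
                 seed = seed),
            class = "run_manifest")
}

fmt_num <- function(x, digits) formatC(x, format = "f", digits = digits)

md_table <- function(df) {
  df[] <- lapply(df, as.character)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, body)
}

#' Render an evaluation as a markdown report
#'
#' Produces a cost-effectiveness league table (sorted by CEA rank, ties by
#' dcm_id), an efficiency table (sorted by EA rank), and footnotes echoing
#' the aggregation method and DEA settings used. Pure function of its
#' arguments: identical inputs give identical text (the manifest timestamp
#' is whatever the manifest carries).
#'
#' @param result a `dcm_evaluation` from [run_scenario()].
#' @param manifest a [run_manifest()].
#' @return character vector of markdown lines.
#' @export
render_markdown <- function(result, manifest) {
  cfg <- manifest$config
  p <- cfg$report_precision
  df <- as.data.frame(result)
  lines <- c(paste0("# DCM evaluation report: ", cfg$name), "",
             paste0("Generated by ", manifest$tool, " at ", manifest$timestamp))
  if (!is.null(manifest$seed))
    lines <- c(lines, paste0("Simulation seed: ", manifest$seed))
  if (length(manifest$checksums))
    lines <- c(lines, "", "Input checksums (md5):",
               paste0("- `", names(manifest$checksums), "`: ",
                      manifest$checksums))
  league <- df[order(df$cea_rank, df$dcm_id),
               c("dcm_id", "vital_stats_cost", "qadi", "cost_per_qadi",
                 "cea_rank")]
  league$vital_stats_cost <- format(league$vital_stats_cost,
                                    big.mark = ",", scientific = FALSE,
                                    trim = TRUE)
  league$qadi <- format(round(league$qadi), big.mark = ",",
                        scientific = FALSE, trim = TRUE)
  league$cost_per_qadi <- fmt_num(league$cost_per_qadi, p)
  lines <- c(lines, "", "## Cost-effectiveness league table", "",
             md_table(league))
  effic <- df[order(df$ea_rank, df$dcm_id),
              c("dcm_id", "quality_index", "efficiency_theta", "ea_rank")]
  effic$quality_index <- fmt_num(effic$quality_index, p)
  effic$efficiency_theta <- fmt_num(effic$efficiency_theta, p)
  lines <- c(lines, "", "## Efficiency analysis", "", md_table(effic))
  lines <- c(lines, "", "## Methods", "",
             paste0("- Quality aggregation: ", cfg$aggregation),
             paste0("- Quantity metric: ", cfg$quantity_metric),
             paste0("- CRVS evaluated: ", cfg$include_crvs),
             paste0("- Criteria: ", paste(cfg$criteria, collapse = ", ")),
             paste0("- DEA model: ", cfg$dea$returns_to_scale, ", ",
                    cfg$dea$orientation, "-oriented, outputs = ",
                    cfg$dea$outputs_mode, ", scoring = ", cfg$dea$pooling),
             paste0("- Report precision: ", p, " decimals"))
  lines
}
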