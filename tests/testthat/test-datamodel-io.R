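test_that("read_dcm_csv converts percentages and validates records", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("dcm_id,name,sample_size,target_population,total_annual_cost,apportion_percent",
               "CRVS,Civil registration,3000000,20500000,750000,30",
               "FULL,Fully apportioned,100,100,5000,100"), path)
  rec <- read_dcm_csv(path)
  expect_s3_class(rec, "dcm_records")
  expect_equal(rec$apportion_fraction, c(0.30, 1.0))
  expect_equal(rec$total_annual_cost[1], 750000)

  writeLines(c("dcm_id,name,sample_size,target_population,total_annual_cost,apportion_percent",
               "BAD,Zero cost,100,100,0,30"), path)
  expect_error(read_dcm_csv(path), "total_annual_cost.*> 0")

  writeLines(c("dcm_id,name,sample_size,total_annual_cost,apportion_percent",
               "X,No target,100,10,30"), path)
  expect_error(read_dcm_csv(path), "missing column.*target_population")

  writeLines(c("dcm_id,name,sample_size,target_population,total_annual_cost,apportion_percent",
               "A,One,1,1,1,10", "A,Two,1,1,1,10"), path)
  expect_error(read_dcm_csv(path), "duplicate dcm_id")
})

test_that("read_scores_csv assembles complete panels and rejects bad cells", {
  crit <- criteria_set(c("c1", "c2"))
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("dcm_id,panel_id,criterion,score",
               "a,consensus,c1,4", "a,consensus,c2,5",
               "b,consensus,c1,2", "b,consensus,c2,3"), path)
  panels <- read_scores_csv(path, crit)
  expect_named(panels, "consensus")
  expect_equal(dim(panels$consensus), c(2, 2))
  expect_equal(unclass(panels$consensus)["b", "c2"], 3)

  writeLines("dcm_id,panel_id,criterion,score", path)
  expect_error(read_scores_csv(path, crit), "no panels found")

  writeLines(c("dcm_id,panel_id,criterion,score",
               "a,consensus,c1,10.5", "a,consensus,c2,5"), path)
  expect_error(read_scores_csv(path, crit), "outside \\[0, 10\\]")

  writeLines(c("dcm_id,panel_id,criterion,score",
               "a,consensus,c1,4", "a,consensus,c2,5",
               "b,consensus,c1,2"), path)
  expect_error(read_scores_csv(path, crit), "missing score.*'b'.*'c2'")
})

test_that("bundled fixtures carry the published study inputs", {
  fa <- load_fixture("scenarioA")
  fb <- load_fixture("scenarioB")

  # scenario shapes and policy switches
  expect_false("CRVS" %in% fa$records$dcm_id)
  expect_true("CRVS" %in% fb$records$dcm_id)
  expect_equal(fa$config$quantity_metric, "sample_size")
  expect_equal(fb$config$quantity_metric, "target_population")
  expect_true("improvement" %in% fa$config$criteria)
  expect_false("improvement" %in% fb$config$criteria)
  expect_equal(dim(fa$scores), c(9, 6))
  expect_equal(dim(fb$scores), c(10, 5))

  # spot quantities
  expect_equal(fa$records$sample_size[fa$records$dcm_id == "HMS"], 17000000)
  expect_equal(fa$records$sample_size[fa$records$dcm_id == "census"], 33000000)
  expect_equal(fb$records$target_population[fb$records$dcm_id == "CRVS"], 20500000)

  # checksum: every consensus score equals the printed two-decimal value
  printed <- printed_scores_A()
  expect_equal(round(unclass(fa$scores)[rownames(printed), colnames(printed)], 2),
               printed)
  # scenario B shares the same rows for its five criteria, plus CRVS
  expect_equal(round(unclass(fb$scores)[rownames(printed), colnames(printed)[1:5]], 2),
               printed[, 1:5])
  expect_equal(round(unclass(fb$scores)["CRVS", ], 2),
               c(accuracy = 0.33, relevance = 0.50, consistency = 4.50,
                 timeliness = 5.00, accessibility = 0.67))
  # fixture scores are exact sixths (means of six integer expert scores)
  expect_true(all(abs(unclass(fb$scores) * 6 - round(unclass(fb$scores) * 6)) < 1e-9))

  # costs, apportion percentages and vital-statistics costs as printed
  pc <- printed_costs()
  recs <- fb$records[match(pc$dcm_id, fb$records$dcm_id), ]
  expect_equal(recs$total_annual_cost, pc$total)
  expect_equal(recs$apportion_fraction, pc$percent / 100)
  expect_equal(unname(vital_stats_cost(recs)), pc$vital)
})

test_that("vital_stats_cost apportions and is linear in total cost", {
  rec <- tiny_records()
  expect_equal(unname(vital_stats_cost(rec)), c(50, 100, 50))
  scaled <- rec
  scaled$total_annual_cost <- scaled$total_annual_cost * 7
  expect_equal(vital_stats_cost(scaled), 7 * vital_stats_cost(rec))
  # identity when the full cost is attributed to vital statistics
  expect_equal(unname(vital_stats_cost(rec))[3], rec$total_annual_cost[3])
})

test_that("write_report renders at the requested precision and round-trips", {
  fx <- load_fixture("scenarioA")
  res <- run_scenario(fx$records, fx$scores, fx$config)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_report(res, csv, format = "csv")
  write_report(res, js, format = "json")

  back <- read_report(csv)
  expect_equal(nrow(back), 9)
  expect_equal(names(back),
               c("dcm_id", "quality_index", "quantity", "vital_stats_cost",
                 "qadi", "cost_per_qadi", "cea_rank", "efficiency_theta",
                 "ea_rank"))
  # four-decimal rendering of the census cost-per-QADI ratio
  raw <- readLines(csv)
  expect_match(raw[grepl("^census,", raw)], ",0.0847,")
  expect_type(back$cea_rank, "integer")

  jback <- read_report(js)
  expect_equal(jback$cost_per_qadi, round(res$cost_per_qadi, 4))
  expect_equal(jback$dcm_id, res$dcm_id)
  # csv and json agree after the same rounding
  expect_equal(back$cost_per_qadi, jback$cost_per_qadi)
})

test_that("score writer and reader round-trip at full precision", {
  fx <- load_fixture("scenarioA")
  path <- withr::local_tempfile(fileext = ".csv")
  write_scores_csv(list(fx$scores), path)
  back <- read_scores_csv(path, criteria = fx$config$criteria,
                          dcm_ids = rownames(fx$scores))
  expect_equal(unclass(back$consensus), unclass(fx$scores), tolerance = 1e-13)
})

test_that("scenario yaml reader builds a full config", {
  cfg <- read_scenario_yaml(system.file("extdata", "scenarioB.yaml",
                                        package = "dcmeval"))
  expect_s3_class(cfg, "scenario_config")
  expect_true(cfg$include_crvs)
  expect_equal(cfg$aggregation, "unweighted")
  expect_equal(cfg$dea$returns_to_scale, "CRS")
  expect_equal(cfg$report_precision, 4L)
})
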