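test_that("unweighted index is the mean normalized by the best mean", {
  fx <- load_fixture("scenarioA")
  q <- unweighted_index(fx$scores)
  expect_equal(unname(q$values["census"]), 0.76, tolerance = 1e-12)
  expect_equal(unname(q$values["Y-DSS"]), 1)
  expect_equal(max(q$values), 1)
  expect_true(all(q$values > 0 & q$values <= 1))

  fb <- load_fixture("scenarioB")
  qb <- unweighted_index(fb$scores)
  expect_rounds_to(qb$values["CRVS"], 0.3607)

  # single DCM self-normalizes to 1 whatever its scores
  solo <- score_matrix(matrix(c(2, 9), 1, 2,
                              dimnames = list("only", c("c1", "c2"))))
  expect_equal(unname(unweighted_index(solo)$values), 1)

  zeros <- score_matrix(matrix(0, 2, 2,
                               dimnames = list(c("a", "b"), c("c1", "c2"))))
  expect_error(unweighted_index(zeros), "zero")
})

test_that("weighted index reduces to unweighted under equal weights and is
          invariant to weight rescaling", {
  fx <- load_fixture("scenarioA")
  crits <- colnames(fx$scores)
  equal <- stats::setNames(rep(1, 6), crits)
  expect_equal(weighted_index(fx$scores, equal)$values,
               unweighted_index(fx$scores)$values)

  # all weight on timeliness: IDS holds the maximum (9.00) and scores 1
  timeliness_only <- stats::setNames(as.numeric(crits == "timeliness"), crits)
  wq <- weighted_index(fx$scores, timeliness_only)
  expect_equal(unname(wq$values["IDS"]), 1)
  expect_equal(unname(wq$values["census"]), 3 / 9, tolerance = 1e-12)

  w2 <- stats::setNames(c(2, 0, 0, 0, 0, 0), crits)
  w1 <- stats::setNames(c(1, 0, 0, 0, 0, 0), crits)
  expect_equal(weighted_index(fx$scores, w2)$values,
               weighted_index(fx$scores, w1)$values)

  expect_error(weighted_index(fx$scores, stats::setNames(c(-1, 1, 1, 1, 1, 1),
                                                         crits)), "negative")
  expect_error(weighted_index(fx$scores, stats::setNames(rep(0, 6), crits)),
               "zero weight")
})

test_that("benefit-of-the-doubt gives each DCM its most favourable weights", {
  fx <- load_fixture("scenarioA")
  q <- bod_index(fx$scores)
  # census holds the strict relevance maximum, so full weight there gives 1
  expect_equal(unname(q$values["census"]), 1)
  # printed value 0.8860; LP optimum from the full-precision scores
  expect_equal(unname(q$values["NHS"]), 0.8860, tolerance = 1e-3)
  expect_true(all(q$values > 0 & q$values <= 1))
  expect_equal(max(q$values), 1)

  # hand-derived two-unit instance: optimum at weights (0, 1/4)
  two <- score_matrix(matrix(c(4, 4, 2, 3), 2, byrow = TRUE,
                             dimnames = list(c("u1", "u2"), c("c1", "c2"))))
  expect_equal(unname(bod_index(two)$values), c(1, 0.75), tolerance = 1e-9)
})

test_that("BoD is invariant to criterion units and respects dominance", {
  fx <- load_fixture("scenarioA")
  base <- bod_index(fx$scores)$values
  scaled <- unclass(fx$scores)
  scaled[, "timeliness"] <- scaled[, "timeliness"] * 0.37
  expect_equal(bod_index(score_matrix(scaled))$values, base, tolerance = 1e-7)

  # component-wise dominance implies a BoD index at least as large
  set.seed(99)
  for (rep in 1:5) {
    y <- matrix(runif(12, 1, 9), 4, 3,
                dimnames = list(paste0("u", 1:4), paste0("c", 1:3)))
    y[2, ] <- y[1, ] + runif(3, 0.1, 0.5)   # u2 dominates u1
    y <- pmin(y, 10)
    v <- bod_index(score_matrix(y))$values
    expect_gte(v["u2"], v["u1"] - 1e-9)
    # a strict column maximum forces an index of exactly 1
    top <- rownames(y)[which.max(y[, 1])]
    y2 <- y; y2[top, 1] <- max(y[, 1]) + 0.5
    expect_equal(unname(bod_index(score_matrix(pmin(y2, 10)))$values[top]), 1)
  }
})

test_that("BoD LP optimum matches brute-force vertex enumeration on small
          instances", {
  set.seed(7)
  for (rep in 1:8) {
    n <- sample(2:5, 1)
    k <- sample(2:3, 1)
    y <- matrix(runif(n * k, 0.5, 9.5), n, k,
                dimnames = list(paste0("u", seq_len(n)), paste0("c", seq_len(k))))
    vals <- bod_index(score_matrix(y))$values
    for (i in seq_len(n)) {
      # brute-force enumeration of the BoD polytope's vertices
      brute <- dcmeval:::lp_vertex_enum(obj = y[i, ], A_le = y,
                                        b_le = rep(1, n), maximize = TRUE)
      expect_equal(unname(vals[i]), min(brute, 1), tolerance = 1e-9)
    }
    if (k == 2 && n <= 5) {
      # cross-module route: unit-input CRS multiplier problem, vertex oracle
      prob <- dea_problem(inputs = matrix(1, n, 1, dimnames = list(rownames(y),
                                                                   "unit")),
                          outputs = y)
      for (id in rownames(y))
        expect_equal(unname(vals[id]), vertex_oracle(prob, id),
                     tolerance = 1e-9)
    }
  }
})

test_that("consensus-only BoD barely discriminates while the unweighted
          index separates all DCMs", {
  fx <- load_fixture("scenarioA")
  bod <- bod_index(fx$scores)$values
  expect_gte(sum(bod == 1), 8)
  unw <- unweighted_index(fx$scores)$values
  expect_equal(length(unique(round(unw, 6))), length(unw))
})

test_that("pooled-experts BoD averages per-expert optima and reduces to the
          consensus result for identical experts", {
  fx <- load_fixture("scenarioA")
  clone <- function(pid) score_matrix(unclass(fx$scores), panel_id = pid)
  panel <- list(clone("expert1"), clone("expert2"), clone("expert3"))
  pooled <- bod_index(fx$scores, pooling = "pooled_experts", panel = panel)
  expect_equal(pooled$values, bod_index(fx$scores)$values, tolerance = 1e-9)
  expect_error(bod_index(fx$scores, pooling = "pooled_experts"), "panel")

  # heterogeneous experts: pooled constraint set has 6x the rows and the
  # score is the mean of per-expert optima, so discrimination improves
  spec <- read_panel_spec_csv(system.file("extdata", "panel_spec_scenarioA.csv",
                                          package = "dcmeval"))
  sim <- generate_panel(spec, n_experts = 6, seed = 42)
  pv <- bod_index(fx$scores, pooling = "pooled_experts", panel = sim)$values
  expect_true(all(pv > 0 & pv <= 1))
  expect_lt(sum(pv == 1), sum(bod_index(fx$scores)$values == 1) + 1)
})
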