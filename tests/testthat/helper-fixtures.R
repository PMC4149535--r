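# Shared builders for small in-code fixtures.

# minimal valid DCM table
tiny_records <- function(n = 3) {
  dcm_records(data.frame(
    dcm_id = paste0("dcm", seq_len(n)),
    name = paste("Method", seq_len(n)),
    sample_size = c(1000, 2000, 500)[seq_len(n)],
    target_population = c(10000, 20000, 5000)[seq_len(n)],
    total_annual_cost = c(100, 400, 50)[seq_len(n)],
    apportion_fraction = c(0.5, 0.25, 1)[seq_len(n)]))
}

tiny_scores <- function(panel_id = "consensus") {
  score_matrix(matrix(c(4, 4,
                        2, 3,
                        1, 2),
                      nrow = 3, byrow = TRUE,
                      dimnames = list(paste0("dcm", 1:3), c("c1", "c2"))),
               panel_id = panel_id)
}

# printed two-decimal consensus scores from the published simulated example;
# used to checksum the bundled full-precision fixtures
printed_scores_A <- function() {
  m <- rbind(census = c(2.33, 8.00, 5.50, 3.00, 5.67, 4.00),
             NHS    = c(0.83, 2.50, 4.50, 3.00, 6.67, 2.00),
             DHS    = c(1.00, 4.00, 6.00, 5.00, 7.67, 2.00),
             HMS    = c(4.83, 2.50, 5.00, 7.00, 3.67, 8.00),
             IDS    = c(3.17, 1.00, 5.50, 9.00, 4.00, 6.00),
             `X-DSS` = c(5.00, 6.50, 4.50, 7.50, 4.67, 7.00),
             `Y-DSS` = c(6.00, 6.50, 4.50, 8.50, 5.00, 7.00),
             MM     = c(4.50, 5.00, 5.50, 7.50, 4.00, 6.00),
             `A-DSS` = c(5.00, 4.50, 5.50, 8.50, 5.00, 5.00))
  colnames(m) <- c("accuracy", "relevance", "consistency", "timeliness",
                   "accessibility", "improvement")
  m
}

printed_costs <- function() {
  data.frame(
    dcm_id = c("census", "NHS", "DHS", "CRVS", "HMS", "IDS", "X-DSS",
               "Y-DSS", "MM", "A-DSS"),
    total = c(8500000, 840000, 870000, 750000, 2200000, 4500000, 200000,
              220000, 100000, 15000),
    percent = c(25, 5, 10, 30, 20, 15, 40, 40, 60, 30),
    vital = c(2125000, 42000, 87000, 225000, 440000, 675000, 80000, 88000,
              60000, 4500))
}

# raw score values without the score_matrix class / panel_id attribute
mat_of <- function(m) {
  m <- unclass(m)
  attr(m, "panel_id") <- NULL
  m
}

expect_rounds_to <- function(x, printed, digits = 4) {
  expect_equal(unname(round(x, digits)), unname(printed),
               tolerance = 1e-12)
}
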