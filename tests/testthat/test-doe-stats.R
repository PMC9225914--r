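test_that("L9 design decodes to the published nine runs and is balanced", {
  d <- build_L9()
  expect_equal(nrow(d), 9)
  # spot rows
  expect_equal(unlist(d[1, c("burn_temperature_C", "stick_size_mm",
                             "distance_mm", "ambient_C")], use.names = FALSE),
               c(600, 12, 25, 17))
  expect_equal(unlist(d[6, c("burn_temperature_C", "stick_size_mm",
                             "distance_mm", "ambient_C")], use.names = FALSE),
               c(625, 18, 25, 25))
  expect_equal(unlist(d[9, c("burn_temperature_C", "stick_size_mm",
                             "distance_mm", "ambient_C")], use.names = FALSE),
               c(650, 18, 30, 17))
  # decoded rows match the packaged design table exactly
  expect_equal(d[, c("run", "burn_temperature_C", "stick_size_mm",
                     "distance_mm", "ambient_C")],
               load_fixture("table5"), ignore_attr = TRUE)
  # balance: each level three times per factor, each pair combination once
  for (f in c("A", "B", "C", "D"))
    expect_equal(as.vector(table(d[[f]])), c(3, 3, 3))
  for (pair in combn(c("A", "B", "C", "D"), 2, simplify = FALSE)) {
    combos <- table(d[[pair[1]]], d[[pair[2]]])
    expect_true(all(combos == 1))
  }
})

test_that("range analysis reproduces the published table to two decimals", {
  y <- load_fixture("table7")$temperature_C
  ra <- range_analysis(build_L9(), y)
  tab <- ra$table
  r2 <- function(x) round_half_up(x, 2)
  # level means K_n1..K_n3 (published rows)
  expect_equal(r2(tab$K1), c(40.29, 39.22, 42.41, 39.82))
  expect_equal(r2(tab$K2), c(40.91, 41.37, 40.84, 40.99))
  expect_equal(r2(tab$K3), c(41.76, 42.37, 39.71, 42.14))
  # normalized level sums Kbar = K_sum / 9
  expect_equal(r2(tab$Kbar1), c(13.43, 13.07, 14.14, 13.27))
  expect_equal(r2(tab$Kbar2), c(13.64, 13.79, 13.61, 13.66))
  expect_equal(r2(tab$Kbar3), c(13.92, 14.12, 13.24, 14.05))
  # ranges and optimum
  expect_equal(r2(tab$R), c(1.48, 3.14, 2.70, 2.32))
  expect_equal(ra$optimal_combination, "A3B3C1D3")
  expect_equal(rank_factors(ra), c("B", "C", "D", "A"))
})

test_that("range analysis degenerates and shifts correctly", {
  d <- build_L9()
  # constant responses: all ranges zero
  ra0 <- range_analysis(d, rep(40, 9))
  expect_equal(ra0$table$R, rep(0, 4))
  expect_warning(rank_factors(ra0), "tie")
  # planted additive effect on B only: R_B equals the planted spread
  y <- 40 + c(0, -2, 2)[d$B]
  ra <- range_analysis(d, y)
  expect_equal(ra$table$R[ra$table$factor == "B"], 4)
  expect_equal(ra$table$R[ra$table$factor != "B"], rep(0, 3))
  expect_equal(ra$optimal_levels[["B"]], 3)
  # invariance to adding a constant
  y2 <- load_fixture("table7")$temperature_C
  ra1 <- range_analysis(d, y2)
  ra2 <- range_analysis(d, y2 + 7.5)
  expect_equal(ra2$table$R, ra1$table$R)
  expect_equal(ra2$optimal_levels, ra1$optimal_levels)
  expect_error(range_analysis(d, y2[-1]), "9")
})

test_that("saturated ANOVA matches stats::aov sums of squares and the
          orthogonal decomposition identity", {
  d <- build_L9()
  y <- load_fixture("table7")$temperature_C
  an <- doe_anova(d, y)
  # independent route: aov on the factor-coded design
  df <- data.frame(y = y, A = factor(d$A), B = factor(d$B),
                   C = factor(d$C), D = factor(d$D))
  ss_aov <- summary(stats::aov(y ~ A + B + C + D, df))[[1]][["Sum Sq"]]
  expect_equal(an$table$SS, ss_aov[1:4], tolerance = 1e-10,
               ignore_attr = TRUE)
  # hand-derived anchor for the dominant factor
  expect_equal(an$table$SS[an$table$factor == "B"], 15.50, tolerance = 1e-3)
  # decomposition: factor SS sum to total SS exactly (saturated design)
  expect_equal(sum(an$table$SS), an$total_ss, tolerance = 1e-9)
  # the stick size carries the largest F under both error strategies
  expect_equal(an$table$factor[which.max(an$table$F)], "B")
  an2 <- doe_anova(d, y, error_strategy = "pool-smallest-factor")
  expect_equal(an2$table$factor[which.max(an2$table$F)], "B")
  # pooled factor (A, smallest SS) is excluded from testing
  expect_true(is.na(an2$table$F[an2$table$factor == "A"]))
  # significance display convention: ranks 1 / 2-3 / 4
  expect_equal(an$table$significance[order(-an$table$F)],
               c("***", "**", "**", ""))
  # degenerate input
  expect_equal(doe_anova(d, rep(40, 9))$table$SS, rep(0, 4))
})

test_that("run_doe ingests an external response column and reports
          consistent range and variance analyses", {
  y <- load_fixture("table7")$temperature_C
  res <- run_doe(responses = y)
  expect_equal(res$responses, y)
  expect_equal(res$range$optimal_combination, "A3B3C1D3")
  expect_equal(res$ranking, c("B", "C", "D", "A"))
  expect_equal(res$range$table, range_analysis(build_L9(), y)$table)
  expect_null(res$runs)
  # degenerate ingest
  res0 <- run_doe(responses = rep(40, 9))
  expect_equal(res0$range$table$R, rep(0, 4))
})

test_that("simulated DOE runs emit a consistent optimal-combination report
          (coarse grid)", {
  stg <- fast_settings()
  res <- run_doe(settings = stg)
  expect_length(res$responses, 9)
  expect_length(res$runs, 9)
  # report is the range analysis of the very responses it simulated
  expect_equal(res$range$table,
               range_analysis(res$design, res$responses)$table)
  expect_equal(res$ranking, rank_factors(res$range))
  # all nine reference temperatures are physically sane
  expect_true(all(res$responses > 35 & res$responses < 75))
  # higher-flux runs heat the reference point more than lower-flux runs:
  # run 6 (18 mm stick at 25 mm) beats run 7 (12 mm stick at 35 mm)
  expect_gt(res$responses[6], res$responses[7])
})
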