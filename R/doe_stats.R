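# L9(3^4) orthogonal design, range analysis (R-method) and saturated-design
# variance analysis for the thermal-penetration study.

l9_levels <- matrix(c(1, 1, 1, 1,
                      1, 2, 2, 2,
                      1, 3, 3, 3,
                      2, 1, 2, 3,
                      2, 2, 3, 1,
                      2, 3, 1, 2,
                      3, 1, 3, 2,
                      3, 2, 1, 3,
                      3, 3, 2, 1),
                    nrow = 9, byrow = TRUE,
                    dimnames = list(NULL, c("A", "B", "C", "D")))

doe_level_values <- list(A = c(600, 625, 650),   # max burning temperature, C
                         B = c(12, 15, 18),      # stick diameter, mm
                         C = c(25, 30, 35),      # stick-to-skin distance, mm
                         D = c(17, 25, 32))      # ambient temperature, C

doe_factor_labels <- c(A = "max burning temperature",
                       B = "moxa stick size",
                       C = "stick-to-skin distance",
                       D = "ambient temperature")

#' Build the L9(3^4) orthogonal design
#'
#' Nine runs accommodating four three-level factors: A = maximum burning
#' temperature (600/625/650 degrees C), B = moxa stick diameter
#' (12/15/18 mm), C = stick-to-skin distance (25/30/35 mm), D = ambient
#' temperature (17/25/32 degrees C). Balanced so that each level occurs
#' three times per factor and every factor pair covers all nine level
#' combinations exactly once.
#'
#' @return an object of class `orthogonal_design`: a data.frame with run
#'   number, level indices `A..D` and decoded physical values
#'   `burn_temperature_C`, `stick_size_mm`, `distance_mm`, `ambient_C`;
#'   the per-factor level values are attached as attribute `level_values`.
#' @export
build_L9 <- function() {
  d <- data.frame(run = 1:9, l9_levels)
  d$burn_temperature_C <- doe_level_values$A[d$A]
  d$stick_size_mm <- doe_level_values$B[d$B]
  d$distance_mm <- doe_level_values$C[d$C]
  d$ambient_C <- doe_level_values$D[d$D]
  structure(d, level_values = doe_level_values,
            factor_labels = doe_factor_labels,
            class = c("orthogonal_design", "data.frame"))
}

check_responses <- function(design, responses) {
  stopifnot(inherits(design, "orthogonal_design"))
  if (!is.numeric(responses) || length(responses) != nrow(design) ||
      anyNA(responses))
    stop(sprintf("'responses' must be %d finite values ordered as the design rows",
                 nrow(design)), call. = FALSE)
  invisible(responses)
}

#' Range analysis (R-method) of an orthogonal experiment
#'
#' For each factor computes the level sums K, the level means K/3 (the
#' quantities reported in the published table rows K_n1..K_n3), the
#' normalized level sums Kbar = K/9, the range R = max - min of the level
#' means, and the optimal level (the level with the largest mean, since the
#' experimental indicator - reference-point temperature - is
#' larger-is-better).
#'
#' @param design an [build_L9()] design.
#' @param responses numeric vector of responses, one per design row.
#' @return an object of class `range_analysis`: a list with a `table`
#'   data.frame (factor, level sums/means, Kbar, R, optimal level) carrying
#'   full precision, `optimal_levels` (named, e.g. `c(A = 3, ...)`),
#'   `optimal_combination` (e.g. `"A3B3C1D3"`) and `responses`.
#' @export
range_analysis <- function(design, responses) {
  check_responses(design, responses)
  factors <- colnames(l9_levels)
  rows <- lapply(factors, function(f) {
    lv <- design[[f]]
    sums <- vapply(1:3, function(l) sum(responses[lv == l]), 0)
    means <- sums / 3
    data.frame(factor = f,
               K1 = means[1], K2 = means[2], K3 = means[3],
               Kbar1 = sums[1] / 9, Kbar2 = sums[2] / 9, Kbar3 = sums[3] / 9,
               R = max(means) - min(means),
               optimal_level = which.max(means))
  })
  tab <- do.call(rbind, rows)
  opt <- setNames(tab$optimal_level, tab$factor)
  structure(list(table = tab,
                 optimal_levels = opt,
                 optimal_combination = paste0(tab$factor, opt,
                                              collapse = ""),
                 responses = responses),
            class = "range_analysis")
}

#' Rank factors by influence (descending range)
#'
#' @param result a [range_analysis()] result.
#' @return character vector of factor names ordered by decreasing R; ties
#'   are broken by factor name order with a warning.
#' @export
rank_factors <- function(result) {
  stopifnot(inherits(result, "range_analysis"))
  tab <- result$table
  if (anyDuplicated(tab$R))
    warning("tied ranges; ties broken by factor name order")
  tab$factor[order(-tab$R, tab$factor)]
}

#' @export
print.range_analysis <- function(x, ...) {
  tab <- x$table
  disp <- tab
  num <- vapply(disp, is.numeric, TRUE)
  disp[num] <- lapply(disp[num], round_half_up, 2)
  cat("<range_analysis>\n")
  print.data.frame(disp, row.names = FALSE)
  cat(sprintf("optimal combination: %s; influence ranking: %s\n",
              x$optimal_combination,
              paste(suppressWarnings(rank_factors(x)), collapse = " > ")))
  invisible(x)
}

#' Variance analysis of a saturated orthogonal experiment
#'
#' Factor sums of squares `SS_n = 3 * sum((level mean - grand mean)^2)` with
#' 2 degrees of freedom each. The saturated L9 leaves no residual degrees of
#' freedom, so an error mean square must be constructed: `"pooled-mean"`
#' (default) uses the mean of all factor mean squares (equivalently total SS
#' over total df), `"pool-smallest-factor"` sacrifices the factor with the
#' smallest SS as the error estimate. F ratios from a saturated design are
#' descriptive, not inferential; the significance markers replicate the
#' published display convention (largest F `***`, middle ranks `**`,
#' smallest none).
#'
#' @param design an [build_L9()] design.
#' @param responses numeric vector of responses, one per design row.
#' @param error_strategy `"pooled-mean"` or `"pool-smallest-factor"`.
#' @return an object of class `doe_anova`: a list with a `table` data.frame
#'   (factor, SS, df, MS, F, significance), `error_ms`, `error_df`,
#'   `total_ss` and the strategy used. The factor SS always sum to the
#'   total SS (orthogonal decomposition identity).
#' @export
doe_anova <- function(design, responses,
                      error_strategy = c("pooled-mean",
                                         "pool-smallest-factor")) {
  error_strategy <- match.arg(error_strategy)
  check_responses(design, responses)
  factors <- colnames(l9_levels)
  gm <- mean(responses)
  SS <- vapply(factors, function(f) {
    means <- tapply(responses, design[[f]], mean)
    3 * sum((means - gm)^2)
  }, 0)
  df <- rep(2, length(factors))
  MS <- SS / df
  total_ss <- sum((responses - gm)^2)

  if (error_strategy == "pooled-mean") {
    error_ms <- mean(MS)
    error_df <- sum(df)
    in_test <- rep(TRUE, length(factors))
  } else {
    pool <- which.min(SS)
    error_ms <- MS[pool]
    error_df <- df[pool]
    in_test <- seq_along(factors) != pool
  }
  Fv <- ifelse(in_test,
               if (error_ms > 0) MS / error_ms else NA_real_,
               NA_real_)
  sig <- rep("", length(factors))
  rk <- rank(-Fv, ties.method = "first", na.last = "keep")
  sig[!is.na(rk) & rk == 1] <- "***"
  sig[!is.na(rk) & rk %in% c(2, 3)] <- "**"
  structure(list(table = data.frame(factor = factors, SS = SS, df = df,
                                    MS = MS, F = Fv, significance = sig,
                                    row.names = NULL),
                 error_ms = error_ms, error_df = error_df,
                 total_ss = total_ss, strategy = error_strategy),
            class = "doe_anova")
}

#' @export
print.doe_anova <- function(x, ...) {
  cat(sprintf("<doe_anova> (error: %s, MS = %.4g on %d df)\n",
              x$strategy, x$error_ms, x$error_df))
  disp <- x$table
  disp$SS <- round_half_up(disp$SS, 3)
  disp$MS <- round_half_up(disp$MS, 3)
  disp$F <- round_half_up(disp$F, 2)
  print.data.frame(disp, row.names = FALSE)
  cat(sprintf("total SS = %.4f (factor SS sum to %.4f)\n",
              x$total_ss, sum(x$table$SS)))
  invisible(x)
}

#' Run (or ingest) the orthogonal experiment
#'
#' Either executes the nine simulations of the L9 design - every run built
#' from the base scenario with the design's factor values, sharing the
#' perfusion tuned once at the base condition - or ingests an externally
#' provided response column (e.g. the published one), then performs range
#' analysis and variance analysis on the reference-point temperatures.
#'
#' @param scenario_base base scenario (default [standard_condition()]);
#'   only used when `responses` is `NULL`.
#' @param settings a [solver_settings()].
#' @param responses optional numeric vector of 9 responses to ingest
#'   instead of simulating.
#' @param design an [build_L9()] design.
#' @param error_strategy passed to [doe_anova()].
#' @return an object of class `doe_result`: list with `design`, `responses`,
#'   `range` ([range_analysis()]), `anova` ([doe_anova()]), `ranking` and,
#'   for simulated runs, the list of [run_simulation()] results.
#' @export
run_doe <- function(scenario_base = standard_condition(),
                    settings = solver_settings(), responses = NULL,
                    design = build_L9(),
                    error_strategy = "pooled-mean") {
  runs <- NULL
  if (is.null(responses)) {
    init <- initial_state(scenario_base, settings)
    base <- if (!is.null(init$scenario)) init$scenario else scenario_base
    base$block$initial_surface_temperature <- NA_real_  # tuned once, reused
    runs <- lapply(seq_len(nrow(design)), function(i) {
      sc <- base
      sc$schedule <- schedule_for_max(design$burn_temperature_C[i],
                                      sc$schedule)
      sc$stick$diameter_mm <- design$stick_size_mm[i]
      sc$distance_mm <- design$distance_mm[i]
      sc$ambient_temperature <- design$ambient_C[i]
      run_simulation(sc, settings, tune_initial = "never")
    })
    responses <- vapply(runs, `[[`, 0, "reference_point_temperature")
  }
  ra <- range_analysis(design, responses)
  structure(list(design = design, responses = responses, range = ra,
                 anova = doe_anova(design, responses, error_strategy),
                 ranking = suppressWarnings(rank_factors(ra)),
                 runs = runs),
            class = "doe_result")
}

#' @export
print.doe_result <- function(x, ...) {
  cat("<doe_result> responses:",
      paste(round_half_up(x$responses, 3), collapse = ", "), "\n")
  print(x$range)
  print(x$anova)
  invisible(x)
}
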