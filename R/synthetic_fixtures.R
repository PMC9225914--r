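# Packaged fixtures (the published tables as CSV), synthetic orthogonal
# response tables with known ground truth, and analytic heat-conduction
# reference problems used as solver oracles.

fixture_files <- c(table1 = "table1_materials.csv",
                   table2 = "table2_levels.csv",
                   table3 = "table3_validation.csv",
                   table5 = "table5_design.csv",
                   table6 = "table6_responses.csv",
                   table7 = "table7_responses.csv")

#' Load a packaged data table
#'
#' Returns one of the published tables shipped with the package as CSV:
#' `table1` (tissue material parameters), `table2` (sweep factor levels and
#' the standard condition), `table3` (validation temperature series with its
#' printed uncertainties and deviations), `table5` (the decoded L9 design),
#' `table6` / `table7` (the two printed orthogonal-experiment response
#' columns; `table7` is the one the published range analysis derives from).
#'
#' @param name one of `"table1"`, `"table2"`, `"table3"`, `"table5"`,
#'   `"table6"`, `"table7"`.
#' @return a data.frame.
#' @export
load_fixture <- function(name) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% names(fixture_files))
    stop(sprintf("unknown fixture '%s'; available: %s",
                 paste(name, collapse = ","),
                 paste(names(fixture_files), collapse = ", ")),
         call. = FALSE)
  path <- system.file("extdata", fixture_files[[name]],
                      package = "moxitherm", mustWork = TRUE)
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Specify a synthetic orthogonal-experiment response model
#'
#' The statistical structure the orthogonal analysis assumes: responses are
#' a grand mean plus additive per-factor level effects plus Gaussian noise.
#' Effects are identifiable (each factor's three effects sum to zero).
#'
#' @param grand_mean grand mean response, degrees C.
#' @param effects named list `list(A =, B =, C =, D =)` of length-3 numeric
#'   vectors of level effects, each summing to 0.
#' @param noise_sd Gaussian noise standard deviation, degrees C.
#' @param seed integer RNG seed.
#' @return an object of class `synthetic_doe_spec`.
#' @export
synthetic_doe_spec <- function(grand_mean = 40,
                               effects = list(A = c(0, 0, 0),
                                              B = c(0, 0, 0),
                                              C = c(0, 0, 0),
                                              D = c(0, 0, 0)),
                               noise_sd = 0, seed = 1L) {
  check_num(grand_mean, "grand_mean")
  if (!is.list(effects) || !setequal(names(effects), c("A", "B", "C", "D")))
    stop_field("effects", "must be a named list with elements A, B, C, D")
  for (f in names(effects)) {
    check_num(effects[[f]], sprintf("effects$%s", f), len = 3L)
    if (abs(sum(effects[[f]])) > 1e-8)
      stop_field(sprintf("effects$%s", f), "level effects must sum to 0")
  }
  check_num(noise_sd, "noise_sd", nonneg = TRUE)
  structure(list(grand_mean = grand_mean, effects = effects,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_doe_spec")
}

#' Generate synthetic orthogonal-experiment responses
#'
#' `response_i = grand_mean + sum_f effect_f[level_i(f)] + N(0, noise_sd)`,
#' reproducible from the spec's seed (the global RNG state is restored on
#' exit).
#'
#' @param spec a [synthetic_doe_spec()].
#' @param design an [build_L9()] design.
#' @return numeric vector of length `nrow(design)`.
#' @export
generate_doe_responses <- function(spec, design = build_L9()) {
  stopifnot(inherits(spec, "synthetic_doe_spec"),
            inherits(design, "orthogonal_design"))
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  y <- rep(spec$grand_mean, nrow(design))
  for (f in c("A", "B", "C", "D"))
    y <- y + spec$effects[[f]][design[[f]]]
  y + rnorm(nrow(design), 0, spec$noise_sd)
}

#' Analytic heat-conduction reference problems
#'
#' Closed-form solutions of the bioheat equation in analytically solvable
#' limits, used as independent oracles for the finite-volume solver:
#'
#' * `uniform_equilibrium` - no conduction gradients: the uniform fixed
#'   point `T = T_b + q_m / (omega_b C_b)` of the perfusion/metabolism
#'   balance.
#' * `semi_infinite_flux` - homogeneous half-space, constant surface flux
#'   q0: `dT(z, t)` with surface value `(2 q0 / k) sqrt(alpha t / pi)`.
#' * `two_slab_steady` - two slabs in series, bottom Dirichlet, constant
#'   top flux: piecewise-linear profile with flux continuity at the
#'   interface.
#' * `perfusion_relaxation` - spatially uniform transient: exponential
#'   approach to the equilibrium at rate `omega_b C_b / (rho c)`.
#'
#' @param name problem name (see above).
#' @param ... problem parameters overriding the defaults: see the `params`
#'   element of the returned object.
#' @return an object of class `analytic_problem`: list with `name`,
#'   `params`, and `evaluate` - a function of `(z, t)` (metres below the
#'   heated/top surface where relevant, seconds) returning temperature in
#'   degrees C (for `semi_infinite_flux`, the temperature *rise*).
#' @export
analytic_problem <- function(name = c("uniform_equilibrium",
                                      "semi_infinite_flux",
                                      "two_slab_steady",
                                      "perfusion_relaxation"), ...) {
  name <- match.arg(name)
  dots <- list(...)
  defaults <- switch(name,
    uniform_equilibrium = list(T_b = 37, q_m = 420, omega_b = 0.7,
                               C_b = 3617),
    semi_infinite_flux = list(q0 = 1000, k = 0.37, rho = 1109, c = 3391),
    two_slab_steady = list(k1 = 0.49, L1 = 0.015, k2 = 0.21, L2 = 0.010,
                           T_bottom = 37, q_top = 200),
    perfusion_relaxation = list(T0 = 30, T_b = 37, q_m = 0, omega_b = 0.7,
                                C_b = 3617, rho = 1090, c = 3421))
  bad <- setdiff(names(dots), names(defaults))
  if (length(bad))
    stop_field(bad[1], sprintf("not a parameter of '%s'", name))
  p <- modifyList(defaults, dots)
  evaluate <- switch(name,
    uniform_equilibrium = function(z = 0, t = Inf) {
      rep(p$T_b + if (p$omega_b > 0) p$q_m / (p$omega_b * p$C_b) else 0,
          length(z) * length(t))
    },
    semi_infinite_flux = function(z = 0, t) {
      # temperature rise below a constant flux q0 applied at z = 0
      alpha <- p$k / (p$rho * p$c)
      if (any(t < 0)) stop_field("t", "must be >= 0")
      ifelse(t == 0, 0,
             (2 * p$q0 / p$k) * sqrt(alpha * t / pi) *
               exp(-z^2 / (4 * alpha * t)) -
               (p$q0 * z / p$k) * erfc_(z / (2 * sqrt(alpha * t))))
    },
    two_slab_steady = function(z, t = Inf) {
      # z measured from the bottom (Dirichlet) face; slab 1 below slab 2
      ifelse(z <= p$L1,
             p$T_bottom + p$q_top * z / p$k1,
             p$T_bottom + p$q_top * (p$L1 / p$k1 + (z - p$L1) / p$k2))
    },
    perfusion_relaxation = function(z = 0, t) {
      lam <- p$omega_b * p$C_b / (p$rho * p$c)
      Tinf <- p$T_b + if (p$omega_b > 0) p$q_m / (p$omega_b * p$C_b) else 0
      Tinf + (p$T0 - Tinf) * exp(-lam * t)
    })
  structure(list(name = name, params = p, evaluate = evaluate),
            class = "analytic_problem")
}

# complementary error function via pnorm
erfc_ <- function(x) 2 * stats::pnorm(-sqrt(2) * x)
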