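# Axisymmetric finite-volume discretization and implicit time integration of
# the Pennes bioheat equation
#     rho c dT/dt = div(k grad T) + w_b C_b (T_b - T) + q_m + q_r
# over the layered tissue block, with the net radiative flux q_r as the
# top-surface boundary condition.

#' Solver settings
#'
#' @param dt time step, s.
#' @param theta implicit one-step family parameter in `[0.5, 1]`
#'   (1 = backward Euler, 0.5 = Crank-Nicolson).
#' @param tol relative tolerance for the Picard iteration on the nonlinear
#'   surface flux.
#' @param max_picard maximum Picard iterations per step.
#' @param base_dr,base_dz background grid spacings, m.
#' @param refine_dr radial spacing inside the refined probe disk, m.
#' @param refine_radius radius of the refined surface disk, m.
#' @param skin_dz vertical spacing in the surface (skin) layer, m.
#' @param record_dt probe recording cadence, s.
#' @param bottom bottom boundary: `"dirichlet"` (core temperature) or
#'   `"insulated"` (used by conservation tests).
#' @param surface top boundary: `"radiation"` (the moxibustion physics),
#'   `"flux"` (prescribed flux via `surface_flux`), or `"insulated"`.
#' @param surface_flux for `surface = "flux"`: either a single number
#'   (W m^-2) or a `function(t, r)` returning the imposed flux per top node.
#' @return an object of class `solver_settings`.
#' @export
solver_settings <- function(dt = 0.5, theta = 1, tol = 1e-6,
                            max_picard = 10L,
                            base_dr = 5e-4, base_dz = 5e-4,
                            refine_dr = 2.5e-4, refine_radius = 5e-3,
                            skin_dz = 2.5e-4, record_dt = 30,
                            bottom = c("dirichlet", "insulated"),
                            surface = c("radiation", "flux", "insulated"),
                            surface_flux = NULL) {
  check_num(dt, "dt", positive = TRUE)
  check_num(theta, "theta", lower = 0.5, upper = 1)
  check_num(tol, "tol", positive = TRUE)
  for (f in c("base_dr", "base_dz", "refine_dr", "refine_radius", "skin_dz"))
    check_num(get(f), f, positive = TRUE)
  check_num(record_dt, "record_dt", positive = TRUE)
  structure(list(dt = dt, theta = theta, tol = tol,
                 max_picard = as.integer(max_picard),
                 base_dr = base_dr, base_dz = base_dz,
                 refine_dr = refine_dr, refine_radius = refine_radius,
                 skin_dz = skin_dz, record_dt = record_dt,
                 bottom = match.arg(bottom), surface = match.arg(surface),
                 surface_flux = surface_flux),
            class = "solver_settings")
}

#' Build the axisymmetric (r, z) grid for a tissue block
#'
#' Tensor-product cell-centred grid. Radially the probe disk
#' (`r <= refine_radius`) is resolved at `refine_dr` and the rest of the
#' block at `base_dr`. Vertically each layer gets its own uniform spacing
#' (at most `base_dz`; at most `skin_dz` in the surface layer), chosen so
#' that layer interfaces coincide exactly with cell faces. z = 0 is the
#' muscle bottom; the skin surface sits at the total block depth (25 mm for
#' the default block), matching the coordinate frame in which the
#' moxibustion point is (0, 0, 25 mm).
#'
#' @param block a [tissue_block()].
#' @param settings a [solver_settings()].
#' @return an object of class `solver_grid`.
#' @export
build_grid <- function(block, settings = solver_settings()) {
  stopifnot(inherits(block, "tissue_block"))
  R <- block$lateral_radius
  rr <- min(settings$refine_radius, R)
  n1 <- max(1L, ceiling(rr / settings$refine_dr - 1e-9))
  r_f <- rr * (0:n1) / n1
  if (R > rr + 1e-12) {
    n2 <- max(1L, ceiling((R - rr) / settings$base_dr - 1e-9))
    r_f <- c(r_f, rr + (R - rr) * (1:n2) / n2)
  }
  nr <- length(r_f) - 1L
  r_c <- (r_f[-1] + r_f[-length(r_f)]) / 2

  layers_bottom_up <- rev(block$layers)
  dz <- numeric(0); layer_row <- integer(0)
  z0 <- 0; z_f <- 0
  n_layers <- length(layers_bottom_up)
  for (li in seq_len(n_layers)) {
    l <- layers_bottom_up[[li]]
    target <- if (li == n_layers) settings$skin_dz else settings$base_dz
    n <- max(1L, ceiling(l$thickness / target - 1e-9))
    h <- l$thickness / n
    dz <- c(dz, rep(h, n))
    layer_row <- c(layer_row, rep(li, n))
    z_f <- c(z_f, z0 + h * (1:n))
    z0 <- z0 + l$thickness
  }
  nz <- length(dz)
  z_c <- (z_f[-1] + z_f[-length(z_f)]) / 2

  prop <- function(f) vapply(layers_bottom_up, `[[`, 0, f)[layer_row]
  structure(list(
    nr = nr, nz = nz, r_f = r_f, r_c = r_c, z_f = z_f, z_c = z_c, dz = dz,
    depth = z0, layer_row = layer_row,
    layer_names = vapply(layers_bottom_up, `[[`, "", "name"),
    k_row = prop("conductivity"),
    rhoc_row = prop("density") * prop("specific_heat"),
    omega_row = prop("perfusion_rate"),
    qm_row = prop("metabolic_heat")),
    class = "solver_grid")
}

#' Assemble the discrete spatial operator
#'
#' Finite-volume conduction operator (harmonic-mean conductivity across layer
#' interfaces; symmetric positive-semidefinite) plus the perfusion sink, with
#' the constant source pieces (perfusion at blood temperature, metabolic
#' heat, bottom Dirichlet coupling) as right-hand-side vectors. Nodes are
#' numbered r-fastest, bottom row first.
#'
#' @param block a [tissue_block()].
#' @param grid a [build_grid()] result consistent with `block`.
#' @param bottom `"dirichlet"` or `"insulated"`.
#' @return a list with the conduction matrix `C`, heat-capacity vector `M`
#'   (rho c V, J K^-1), perfusion conductance vector `P` (W K^-1), source
#'   vectors, top/bottom index maps and face areas.
#' @export
assemble_operator <- function(block, grid, bottom = "dirichlet") {
  stopifnot(inherits(grid, "solver_grid"))
  if (!isTRUE(all.equal(grid$depth,
                        sum(vapply(block$layers, `[[`, 0, "thickness")))))
    stop("grid is inconsistent with the tissue block", call. = FALSE)
  nr <- grid$nr; nz <- grid$nz; N <- nr * nz
  idx <- function(i, j) i + (j - 1L) * nr
  A_z <- pi * (grid$r_f[-1]^2 - grid$r_f[-(nr + 1)]^2)  # annulus areas

  # radial faces (between i and i+1 within each row)
  i_r <- rep(seq_len(nr - 1L), nz)
  j_r <- rep(seq_len(nz), each = nr - 1L)
  g_r <- grid$k_row[j_r] * (2 * pi * grid$r_f[i_r + 1L] * grid$dz[j_r]) /
    (grid$r_c[i_r + 1L] - grid$r_c[i_r])
  p_r <- idx(i_r, j_r); q_r <- idx(i_r + 1L, j_r)

  # axial faces (between row j and j+1): series-resistance harmonic mean
  i_z <- rep(seq_len(nr), nz - 1L)
  j_z <- rep(seq_len(nz - 1L), each = nr)
  res <- grid$dz[j_z] / (2 * grid$k_row[j_z]) +
    grid$dz[j_z + 1L] / (2 * grid$k_row[j_z + 1L])
  g_z <- A_z[i_z] / res
  p_z <- idx(i_z, j_z); q_z <- idx(i_z, j_z + 1L)

  p <- c(p_r, p_z); q <- c(q_r, q_z); w <- c(g_r, g_z)
  C <- Matrix::sparseMatrix(i = c(p, q, p, q), j = c(q, p, p, q),
                            x = c(-w, -w, w, w), dims = c(N, N))

  V <- as.vector(outer(A_z, grid$dz))                 # cell volumes
  M <- V * rep(grid$rhoc_row, each = nr)
  P <- V * rep(grid$omega_row * block$blood$specific_heat, each = nr)
  b_qm <- V * rep(grid$qm_row, each = nr)

  idx_bottom <- idx(seq_len(nr), 1L)
  idx_top <- idx(seq_len(nr), nz)
  g_bottom <- if (bottom == "dirichlet") {
    A_z * (2 * grid$k_row[1] / grid$dz[1])
  } else rep(0, nr)

  list(C = C, M = M, P = P, V = V, b_qm = b_qm, A_top = A_z,
       idx_top = idx_top, idx_bottom = idx_bottom, g_bottom = g_bottom,
       nr = nr, nz = nz)
}

# ---- internal solver context ----------------------------------------------

solver_context <- function(scenario, settings) {
  stopifnot(inherits(scenario, "scenario_config"),
            inherits(settings, "solver_settings"))
  grid <- build_grid(scenario$block, settings)
  op <- assemble_operator(scenario$block, grid, bottom = settings$bottom)
  surf <- scenario$surfaces
  geom <- scenario_geometry(scenario)
  nK <- surf$refractive_index
  ctx <- list(
    scenario = scenario, settings = settings, grid = grid, op = op,
    geom = geom,
    Fv = view_factor(grid$r_c, geom),
    eb_amb = blackbody_emissive_power(C_to_K(scenario$ambient_temperature),
                                      nK),
    eps_skin = surf$skin_emissivity,
    eps_source = surf$source_emissivity,
    n_refr = nK,
    c_half = (grid$dz[grid$nz] / 2) / grid$k_row[grid$nz],
    b_lin = op$P * scenario$block$blood$temperature + op$b_qm +
      c(rep(0, length(op$M)))
  )
  ctx$b_lin[op$idx_bottom] <- ctx$b_lin[op$idx_bottom] +
    op$g_bottom * scenario$block$core_temperature
  ctx
}

# diagonal of the linear operator pieces: conduction + perfusion + bottom
ctx_L <- function(ctx) {
  L <- ctx$op$C + Matrix::Diagonal(x = ctx$op$P)
  d <- rep(0, length(ctx$op$M))
  d[ctx$op$idx_bottom] <- ctx$op$g_bottom
  L + Matrix::Diagonal(x = d)
}

# Surface temperature of each top cell from its centre temperature:
# solves T_s = T_c + (dz/2k) q_r(T_s) by fixed point (contraction factor
# ~ 4 eps sigma T^3 dz / 2k << 1).
surface_temps <- function(Tc_top, G, ctx) {
  Ts <- Tc_top
  for (it in 1:4) {
    q <- ctx$eps_skin *
      (G - blackbody_emissive_power(C_to_K(Ts), ctx$n_refr))
    Ts <- Tc_top + ctx$c_half * q
  }
  list(Ts = Ts, q = ctx$eps_skin *
         (G - blackbody_emissive_power(C_to_K(Ts), ctx$n_refr)))
}

# irradiation of the top cells at time t (scenario physics)
top_irradiation <- function(t, ctx) {
  Ta <- source_temperature(t, ctx$scenario$schedule)
  J <- ctx$eps_source * blackbody_emissive_power(C_to_K(Ta), ctx$n_refr)
  ctx$Fv * J + (1 - ctx$Fv) * ctx$eb_amb
}

# surface flux vector (W m^-2 per top cell) at time t given top-cell centre
# temperatures; returns also reconstructed surface temperatures
surface_flux_at <- function(t, Tc_top, ctx) {
  s <- ctx$settings
  if (s$surface == "insulated") {
    return(list(Ts = Tc_top, q = rep(0, ctx$op$nr)))
  }
  if (s$surface == "flux") {
    q <- if (is.function(s$surface_flux)) {
      s$surface_flux(t, ctx$grid$r_c)
    } else rep(s$surface_flux, ctx$op$nr)
    return(list(Ts = Tc_top + ctx$c_half * q, q = q))
  }
  surface_temps(Tc_top, top_irradiation(t, ctx), ctx)
}

new_field <- function(values, time, grid, Ts = NULL, scenario = NULL) {
  bad <- !is.finite(values)
  if (any(bad)) stop("non-finite temperatures in field", call. = FALSE)
  structure(list(values = values, time = time, grid = grid, surface = Ts,
                 scenario = scenario),
            class = "temperature_field")
}

#' Advance a temperature field by one implicit step
#'
#' One theta-weighted implicit step of the Pennes system; the nonlinear
#' radiative surface flux is handled by Picard iteration on the surface
#' temperature. Intended for experimentation and testing; [run_simulation()]
#' performs whole runs efficiently with a cached factorization.
#'
#' @param field a `temperature_field` (see [initial_state()]).
#' @param dt time step, s.
#' @param scenario a [scenario_config()].
#' @param settings a [solver_settings()] (its `dt` is ignored in favour of
#'   the `dt` argument).
#' @return the advanced `temperature_field`.
#' @export
step <- function(field, dt, scenario, settings = solver_settings()) {
  ctx <- solver_context(scenario, settings)
  A <- Matrix::forceSymmetric(
    Matrix::Diagonal(x = ctx$op$M / dt) + settings$theta * ctx_L(ctx))
  Ch <- Matrix::Cholesky(A, LDL = FALSE, perm = TRUE)
  st <- step_core(as.vector(field$values), field$time, dt, ctx, Ch,
                  ctx_L(ctx))
  new_field(matrix(st$T, ctx$op$nr, ctx$op$nz), field$time + dt, ctx$grid,
            Ts = st$Ts, scenario = scenario)
}

# core step: Tvec at t0 -> t0+dt. Ch: factorization of M/dt + theta*L.
step_core <- function(Tvec, t0, dt, ctx, Ch, L) {
  th <- ctx$settings$theta
  rhs0 <- (ctx$op$M / dt) * Tvec + ctx$b_lin
  if (th < 1) {
    rhs0 <- rhs0 - (1 - th) * as.vector(L %*% Tvec)
    f0 <- surface_flux_at(t0, Tvec[ctx$op$idx_top], ctx)
    rhs0[ctx$op$idx_top] <- rhs0[ctx$op$idx_top] +
      (1 - th) * ctx$op$A_top * f0$q
  }
  t1 <- t0 + dt
  Tg <- Tvec
  nonlinear <- ctx$settings$surface == "radiation"
  for (it in seq_len(ctx$settings$max_picard)) {
    f1 <- surface_flux_at(t1, Tg[ctx$op$idx_top], ctx)
    rhs <- rhs0
    rhs[ctx$op$idx_top] <- rhs[ctx$op$idx_top] + th * ctx$op$A_top * f1$q
    Tn <- as.vector(Matrix::solve(Ch, rhs, system = "A"))
    if (!nonlinear ||
        max(abs(Tn - Tg)) <= ctx$settings$tol * (1 + max(abs(Tn)))) {
      Tg <- Tn
      break
    }
    Tg <- Tn
  }
  f1 <- surface_flux_at(t1, Tg[ctx$op$idx_top], ctx)
  list(T = Tg, Ts = f1$Ts)
}

# steady state of the linear system with (possibly nonlinear) surface flux;
# source_on = FALSE evaluates the surface exchange with the ambient only.
steady_field <- function(ctx, source_on = FALSE, t_source = 0) {
  L <- ctx_L(ctx)
  if (ctx$settings$bottom != "dirichlet" && all(ctx$op$P == 0))
    stop("steady state undefined: no Dirichlet boundary and no perfusion",
         call. = FALSE)
  Ch <- Matrix::Cholesky(Matrix::forceSymmetric(L), LDL = FALSE, perm = TRUE)
  Tg <- rep(ctx$scenario$block$core_temperature, length(ctx$op$M))
  G_fun <- function() {
    if (ctx$settings$surface != "radiation") return(NULL)
    if (source_on) top_irradiation(t_source, ctx) else
      rep(ctx$eb_amb, ctx$op$nr)
  }
  G <- G_fun()
  for (it in 1:60) {
    f <- if (ctx$settings$surface == "radiation") {
      surface_temps(Tg[ctx$op$idx_top], G, ctx)
    } else surface_flux_at(t_source, Tg[ctx$op$idx_top], ctx)
    rhs <- ctx$b_lin
    rhs[ctx$op$idx_top] <- rhs[ctx$op$idx_top] + ctx$op$A_top * f$q
    Tn <- as.vector(Matrix::solve(Ch, rhs, system = "A"))
    conv <- max(abs(Tn - Tg)) <= 1e-9 * (1 + max(abs(Tn)))
    Tg <- Tn
    if (conv) break
  }
  if (!conv) stop("steady solve did not converge", call. = FALSE)
  f <- if (ctx$settings$surface == "radiation") {
    surface_temps(Tg[ctx$op$idx_top], G, ctx)
  } else surface_flux_at(t_source, Tg[ctx$op$idx_top], ctx)
  new_field(matrix(Tg, ctx$op$nr, ctx$op$nz), 0, ctx$grid, Ts = f$Ts,
            scenario = ctx$scenario)
}

# rescale all perfusion rates in a block by factor s
scale_perfusion <- function(block, s) {
  block$layers <- lapply(block$layers, function(l) {
    l$perfusion_rate <- l$perfusion_rate * s
    l
  })
  block
}

#' Resting (pre-moxibustion) temperature field
#'
#' Solves the steady state of the model without the moxa source (the skin
#' exchanges radiation with the surroundings only). When the block carries a
#' target `initial_surface_temperature` (and `tune` is `"auto"` or
#' `"always"`), the perfusion rates of all layers are rescaled by a common
#' factor so that the 5 mm disk-average surface temperature matches the
#' target to within 0.1 degrees C; the returned field's `scenario` element
#' carries the tuned block, which [run_simulation()] then uses for the whole
#' transient.
#'
#' @param scenario a [scenario_config()].
#' @param settings a [solver_settings()].
#' @param tune `"auto"` (tune when a target is set), `"never"`, or
#'   `"always"` (error if no target is set).
#' @return a `temperature_field` at time 0 with elements `values`
#'   (nr x nz matrix, degrees C), `grid`, `surface` (reconstructed surface
#'   temperatures) and `scenario`.
#' @export
initial_state <- function(scenario, settings = solver_settings(),
                          tune = c("auto", "never", "always")) {
  tune <- match.arg(tune)
  target <- scenario$block$initial_surface_temperature
  do_tune <- switch(tune, never = FALSE, always = TRUE, auto = !is.na(target))
  if (do_tune && is.na(target))
    stop("tune = 'always' requires block$initial_surface_temperature",
         call. = FALSE)
  ctx <- solver_context(scenario, settings)
  if (!do_tune) return(steady_field(ctx))

  disk_of <- function(s) {
    sc <- scenario
    sc$block <- scale_perfusion(scenario$block, s)
    cx <- solver_context(sc, settings)
    f <- steady_field(cx)
    list(dev = disk_average(f) - target, field = f, scenario = sc)
  }
  f1 <- disk_of(1)
  if (abs(f1$dev) <= 0.1) {
    f1$field$scenario <- f1$scenario
    return(f1$field)
  }
  g <- function(ls) disk_of(exp(ls))$dev
  lo <- log(0.02); hi <- log(50)
  glo <- g(lo); ghi <- g(hi)
  if (sign(glo) == sign(ghi))
    stop(sprintf(paste0("cannot match initial_surface_temperature %.1f C by ",
                        "perfusion scaling (achievable range %.2f..%.2f C)"),
                 target, target + min(glo, ghi), target + max(glo, ghi)),
         call. = FALSE)
  root <- uniroot(g, c(lo, hi), tol = 1e-4)
  res <- disk_of(exp(root$root))
  if (abs(res$dev) > 0.1)
    stop("perfusion tuning did not reach the initial surface temperature",
         call. = FALSE)
  res$field$scenario <- res$scenario
  res$field
}

#' Area-weighted disk-average surface temperature
#'
#' Mean surface temperature over the disk of given radius centred on the
#' moxibustion point, weighted by annulus areas (2 pi r dr).
#'
#' @param field a `temperature_field`.
#' @param radius disk radius, m (default the 5 mm probe disk).
#' @return average temperature, degrees C.
#' @export
disk_average <- function(field, radius = 5e-3) {
  stopifnot(inherits(field, "temperature_field"))
  g <- field$grid
  if (radius > g$r_f[length(g$r_f)] + 1e-12)
    stop_field("radius", "exceeds the lateral extent of the block")
  Tsurf <- if (!is.null(field$surface)) field$surface else
    field$values[, g$nz]
  rin <- pmin(g$r_f[-length(g$r_f)], radius)
  rout <- pmin(g$r_f[-1], radius)
  w <- pi * (rout^2 - rin^2)
  sum(w * Tsurf) / sum(w)
}

# linear probe along the axis (r = first column), z in metres from bottom;
# anchored by the core temperature at the bottom face and the reconstructed
# surface temperature at the top face.
axis_probe <- function(values, Ts, ctx, z_out) {
  g <- ctx$grid
  zz <- c(0, g$z_c, g$depth)
  vv <- c(if (ctx$settings$bottom == "dirichlet")
    ctx$scenario$block$core_temperature else values[1, 1],
    values[1, ], Ts[1])
  approx(zz, vv, xout = z_out, rule = 2)$y
}

#' Run a moxibustion simulation
#'
#' Integrates the Pennes system from the resting state over the scenario
#' duration, recording the probes of the study: the moxibustion-point
#' surface temperature (0, 0, 25 mm), the 5 mm disk-average surface
#' temperature, the subsurface reference point (0, 0, 20 mm), the final
#' radial surface profile to 40 mm and the final depth profile to 5 mm
#' below the moxibustion point.
#'
#' @param scenario a [scenario_config()].
#' @param settings a [solver_settings()].
#' @param tune_initial passed to [initial_state()] as `tune`.
#' @return an object of class `simulation_result` with elements
#'   `point_series`, `disk_average_series` (both data.frames with `t_s` and
#'   `temp_C`; the disk series also carries the reference-point series),
#'   `surface_radial_profile`, `depth_profile`,
#'   `reference_point_temperature`, `final_field`, and the (possibly
#'   perfusion-tuned) `scenario`.
#' @export
run_simulation <- function(scenario, settings = solver_settings(),
                           tune_initial = c("auto", "never", "always")) {
  init <- initial_state(scenario, settings, tune = tune_initial)
  scenario <- if (!is.null(init$scenario)) init$scenario else scenario
  ctx <- solver_context(scenario, settings)

  rec_dt <- min(settings$record_dt, scenario$duration_s)
  dt <- rec_dt / ceiling(rec_dt / settings$dt - 1e-9)
  n_rec <- floor(scenario$duration_s / rec_dt + 1e-9)
  steps_per_rec <- round(rec_dt / dt)
  tail_t <- scenario$duration_s - n_rec * rec_dt  # leftover (< rec_dt)

  A <- Matrix::forceSymmetric(
    Matrix::Diagonal(x = ctx$op$M / dt) + settings$theta * ctx_L(ctx))
  Ch <- Matrix::Cholesky(A, LDL = FALSE, perm = TRUE)
  L <- if (settings$theta < 1) ctx_L(ctx) else NULL

  Tvec <- as.vector(init$values)
  Ts <- init$surface
  n_out <- n_rec + 1L + (tail_t > 1e-9)
  out_t <- numeric(n_out); out_disk <- numeric(n_out)
  out_point <- numeric(n_out); out_ref <- numeric(n_out)
  record <- function(slot, t) {
    vals <- matrix(Tvec, ctx$op$nr, ctx$op$nz)
    fld <- new_field(vals, t, ctx$grid, Ts = Ts)
    out_t[slot] <<- t
    out_disk[slot] <<- disk_average(fld)
    out_point[slot] <<- Ts[1]
    out_ref[slot] <<- axis_probe(vals, Ts, ctx, ctx$grid$depth - 5e-3)
  }
  record(1L, 0)
  t <- 0
  slot <- 1L
  advance <- function(n, dt_loc, Ch_loc) {
    for (s in seq_len(n)) {
      st <- step_core(Tvec, t, dt_loc, ctx, Ch_loc, L)
      Tvec <<- st$T; Ts <<- st$Ts; t <<- t + dt_loc
    }
  }
  for (rchunk in seq_len(n_rec)) {
    advance(steps_per_rec, dt, Ch)
    slot <- slot + 1L
    record(slot, rchunk * rec_dt)
  }
  if (tail_t > 1e-9) {
    ntail <- ceiling(tail_t / dt - 1e-9)
    dtt <- tail_t / ntail
    At <- Matrix::forceSymmetric(
      Matrix::Diagonal(x = ctx$op$M / dtt) + settings$theta * ctx_L(ctx))
    advance(ntail, dtt, Matrix::Cholesky(At, LDL = FALSE, perm = TRUE))
    slot <- slot + 1L
    record(slot, scenario$duration_s)
  }

  vals <- matrix(Tvec, ctx$op$nr, ctx$op$nz)
  lo <- scenario$ambient_temperature - 5
  if (min(vals) < lo - 1e-9 || max(vals) > 120)
    warning(sprintf("field left the sanity band [%.1f, 120] C", lo))
  final <- new_field(vals, t, ctx$grid, Ts = Ts, scenario = scenario)

  keep_r <- ctx$grid$r_c <= 0.040 + 1e-12
  depth_mm <- seq(0, 5, by = 0.25)
  structure(list(
    point_series = data.frame(t_s = out_t, temp_C = out_point),
    disk_average_series = data.frame(t_s = out_t, temp_C = out_disk,
                                     reference_C = out_ref),
    surface_radial_profile = data.frame(offset_mm = ctx$grid$r_c[keep_r] * 1e3,
                                        temp_C = Ts[keep_r]),
    depth_profile = data.frame(
      depth_mm = depth_mm,
      temp_C = axis_probe(vals, Ts, ctx, ctx$grid$depth - depth_mm / 1e3)),
    reference_point_temperature = out_ref[slot],
    final_field = final,
    scenario = scenario),
    class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  n <- nrow(x$disk_average_series)
  cat("<simulation_result>\n")
  cat(sprintf("  duration %g s, %d recorded timepoints\n",
              x$disk_average_series$t_s[n], n))
  cat(sprintf("  final moxibustion-point temperature: %.2f C\n",
              x$point_series$temp_C[n]))
  cat(sprintf("  final 5 mm disk-average temperature: %.2f C\n",
              x$disk_average_series$temp_C[n]))
  cat(sprintf("  reference point (5 mm depth): %.2f C\n",
              x$reference_point_temperature))
  invisible(x)
}
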