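# Independent oracles and small builders shared across tests.

# Monte-Carlo ray-casting view factor from a planar element (normal +z) at
# (offset, 0, 0) to a sphere of radius R centred at (0, 0, H).
# F = (1/pi) * integral over the sphere's solid angle of cos(theta) dOmega,
# estimated by casting rays uniformly inside the circumscribed cone of the
# sphere (importance sampling: hit/miss over the full hemisphere would need
# ~1e10 rays for 1% relative error at F ~ 1e-3), testing each ray for
# sphere intersection, and weighting by cos(theta) * Omega_cone / pi.
mc_view_factor <- function(offset, R, H, n_rays = 1e6, seed = 42) {
  set.seed(seed)
  mx <- -offset; mz <- H               # element -> sphere centre (my = 0)
  D <- sqrt(mx^2 + mz^2)
  sin_a <- R / D
  cos_a <- sqrt(1 - sin_a^2)
  omega <- 2 * pi * (1 - cos_a)        # solid angle of the cone
  # directions uniform in the cone around the centre axis
  cos_g <- runif(n_rays, cos_a, 1)
  sin_g <- sqrt(1 - cos_g^2)
  phi <- runif(n_rays, 0, 2 * pi)
  # orthonormal frame around the axis a = (mx, 0, mz)/D
  ax <- mx / D; az <- mz / D
  # e1 = (az, 0, -ax), e2 = (0, 1, 0)
  dx <- cos_g * ax + sin_g * (cos(phi) * az)
  dy <- sin_g * sin(phi)
  dz <- cos_g * az + sin_g * (cos(phi) * -ax)
  # intersection test (all cone rays should hit; keep the test honest)
  b <- dx * mx + dz * mz
  hit <- b > 0 & (D^2 - b^2) <= R^2 * (1 + 1e-12)
  mean(ifelse(hit, pmax(dz, 0), 0)) * omega / pi
}

# quick uniform single-layer block for conduction tests
uniform_block <- function(thickness = 0.025, k = 0.37, rho = 1109,
                          cp = 3391, omega = 0, qm = 0, core = 37,
                          radius = 0.05) {
  tissue_block(list(tissue_layer("tissue", thickness, rho, cp, k,
                                 perfusion_rate = omega,
                                 metabolic_heat = qm)),
               lateral_radius = radius, core_temperature = core)
}

# coarse settings for unit tests that only need qualitative fields
fast_settings <- function(...) {
  args <- utils::modifyList(
    list(dt = 2, base_dr = 2e-3, base_dz = 1e-3,
         refine_dr = 1e-3, skin_dz = 5.5e-4),
    list(...))
  do.call(solver_settings, args)
}

# scenario with a prescribed constant surface flux and no radiation
flux_scenario <- function(block, flux, duration = 60, ambient = 25) {
  scenario_config(block = block, distance_mm = 35,
                  ambient_temperature = ambient, duration_s = duration)
}
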