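# Surface-to-surface radiative exchange between the spherical burning end,
# the skin surface, and the ambient surroundings.

#' Stefan-Boltzmann constant (W m^-2 K^-4)
#' @export
SIGMA_SB <- 5.67e-8

#' Blackbody emissive power
#'
#' \eqn{e_b(T) = n^2 \sigma T^4} with \eqn{\sigma = 5.67\times 10^{-8}}
#' W m^-2 K^-4 and refractive index n of the medium.
#'
#' @param T_K absolute temperature, K (vectorized).
#' @param n refractive index (default 1).
#' @return emissive power, W m^-2.
#' @export
blackbody_emissive_power <- function(T_K, n = 1) {
  if (!is.numeric(T_K) || anyNA(T_K) || any(T_K < 0))
    stop_field("T_K", "must be non-negative")
  n^2 * SIGMA_SB * T_K^4
}

#' Geometry of the spherical burning end above the skin
#'
#' The burning end is treated as a sphere of the stick radius; its centre
#' sits `distance + radius` above the skin plane so the lowest point of the
#' sphere is at the prescribed stick-to-skin distance.
#'
#' @param sphere_radius sphere (stick) radius, m.
#' @param center_height height of the sphere centre above the skin plane, m;
#'   must exceed the radius (no contact).
#' @return an object of class `source_geometry`.
#' @export
source_geometry <- function(sphere_radius, center_height) {
  check_num(sphere_radius, "sphere_radius", positive = TRUE)
  check_num(center_height, "center_height", positive = TRUE)
  if (center_height <= sphere_radius)
    stop_field("center_height", "must exceed sphere_radius (no contact)")
  structure(list(sphere_radius = sphere_radius,
                 center_height = center_height),
            class = "source_geometry")
}

# geometry implied by a scenario
scenario_geometry <- function(scenario) {
  r <- scenario$stick$diameter_mm / 2 / 1e3
  source_geometry(r, scenario$distance_mm / 1e3 + r)
}

#' View factor from a skin surface element to the spherical burning end
#'
#' For a differential planar element whose normal points upward, at radial
#' offset r from the sphere axis, with the sphere centre at height H and
#' radius R: the element-to-sphere view factor is
#' \deqn{F = R^2 H / (H^2 + r^2)^{3/2},}
#' i.e. \eqn{(R/D)^2 \cos\theta} with D the element-centre distance and
#' \eqn{\theta} the tilt of the line of centres; the formula is valid
#' whenever the whole sphere lies above the element's horizon (H > R, which
#' the geometry invariant guarantees).
#'
#' @param radial_offset radial offset(s) of the element from the axis, m
#'   (vectorized).
#' @param geometry a [source_geometry()].
#' @return view factor(s) in `[0, 1]`, non-increasing in offset and in
#'   centre height.
#' @export
view_factor <- function(radial_offset, geometry) {
  stopifnot(inherits(geometry, "source_geometry"))
  if (!is.numeric(radial_offset) || anyNA(radial_offset) ||
      any(radial_offset < 0))
    stop_field("radial_offset", "must be non-negative")
  R <- geometry$sphere_radius
  H <- geometry$center_height
  R^2 * H / (H^2 + radial_offset^2)^1.5
}

#' Irradiation of a skin node
#'
#' Input radiation G at a surface node: the fraction F of its view occupied
#' by the burning end contributes the ember radiosity
#' `J = source_emissivity * e_b(T_source)`, and the remaining (1 - F) sees
#' blackbody surroundings at the ambient temperature (single-bounce closure;
#' with skin reflectance of a few percent, multi-bounce corrections are
#' negligible).
#'
#' @param node_offset radial offset(s) of the node, m.
#' @param source_T burning-end temperature, degrees C.
#' @param ambient_T ambient temperature, degrees C.
#' @param geometry a [source_geometry()].
#' @param surfaces a [surface_exchange()].
#' @return irradiation G, W m^-2.
#' @export
skin_irradiation <- function(node_offset, source_T, ambient_T, geometry,
                             surfaces = surface_exchange()) {
  stopifnot(inherits(surfaces, "surface_exchange"))
  Fv <- view_factor(node_offset, geometry)
  n <- surfaces$refractive_index
  J_source <- surfaces$source_emissivity *
    blackbody_emissive_power(C_to_K(source_T), n)
  Fv * J_source + (1 - Fv) * blackbody_emissive_power(C_to_K(ambient_T), n)
}

#' Net radiative flux absorbed by the skin
#'
#' \eqn{q_r = \varepsilon_{skin} (G - e_b(T_{skin}))}; negative values mean a
#' net radiative loss.
#'
#' @param skin_T skin surface temperature(s), degrees C.
#' @param G irradiation, W m^-2.
#' @param surfaces a [surface_exchange()].
#' @return net absorbed flux q_r, W m^-2.
#' @export
net_absorbed_flux <- function(skin_T, G, surfaces = surface_exchange()) {
  stopifnot(inherits(surfaces, "surface_exchange"))
  n <- surfaces$refractive_index
  surfaces$skin_emissivity * (G - blackbody_emissive_power(C_to_K(skin_T), n))
}

#' Skin-node radiosity (diagnostic)
#'
#' The outgoing flux `J = eps * e_b(T) + rho_d * G` at a skin node; reported
#' for diagnostics, it does not feed back to the source in the single-bounce
#' closure.
#'
#' @inheritParams net_absorbed_flux
#' @return radiosity J, W m^-2.
#' @export
skin_radiosity <- function(skin_T, G, surfaces = surface_exchange()) {
  stopifnot(inherits(surfaces, "surface_exchange"))
  n <- surfaces$refractive_index
  surfaces$skin_emissivity * blackbody_emissive_power(C_to_K(skin_T), n) +
    surfaces$skin_reflectance * G
}
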