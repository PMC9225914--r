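# Scenario definition: tissue geometry and materials, moxa-stick geometry,
# burning schedule, surface radiative properties, and the study scenarios
# (standard condition, validation condition), plus YAML (de)serialization.

#' Define a tissue layer
#'
#' A homogeneous tissue slab with the thermal and perfusion properties that
#' enter the Pennes bioheat equation: density \eqn{\rho}, specific heat
#' \eqn{c}, conductivity \eqn{k}, blood perfusion rate \eqn{\omega_b} and
#' metabolic heat production \eqn{q_m}.
#'
#' @param name layer name (e.g. `"skin"`).
#' @param thickness layer thickness in metres.
#' @param density tissue density, kg m^-3.
#' @param specific_heat specific heat, J kg^-1 K^-1.
#' @param conductivity thermal conductivity, W m^-1 K^-1.
#' @param perfusion_rate blood mass flow per tissue volume, kg m^-3 s^-1.
#' @param metabolic_heat metabolic volumetric heat source, W m^-3.
#' @return an object of class `tissue_layer`.
#' @export
tissue_layer <- function(name, thickness, density, specific_heat,
                         conductivity, perfusion_rate = 0,
                         metabolic_heat = 0) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_field("name", "must be a non-empty string")
  check_num(thickness, "thickness", positive = TRUE)
  check_num(density, "density", positive = TRUE)
  check_num(specific_heat, "specific_heat", positive = TRUE)
  check_num(conductivity, "conductivity", positive = TRUE)
  check_num(perfusion_rate, "perfusion_rate", nonneg = TRUE)
  check_num(metabolic_heat, "metabolic_heat", nonneg = TRUE)
  structure(list(name = name, thickness = thickness, density = density,
                 specific_heat = specific_heat, conductivity = conductivity,
                 perfusion_rate = perfusion_rate,
                 metabolic_heat = metabolic_heat),
            class = "tissue_layer")
}

#' Blood properties for the Pennes perfusion term
#'
#' @param specific_heat blood specific heat \eqn{C_b}, J kg^-1 K^-1.
#' @param temperature arterial blood temperature \eqn{T_b}, degrees C.
#' @return an object of class `blood_properties`.
#' @export
blood_properties <- function(specific_heat = 3617, temperature = 37) {
  check_num(specific_heat, "blood$specific_heat", positive = TRUE)
  check_num(temperature, "blood$temperature", lower = 30, upper = 42)
  structure(list(specific_heat = specific_heat, temperature = temperature),
            class = "blood_properties")
}

#' Assemble a layered tissue block
#'
#' Layers are ordered from the skin surface downward. The bottom face is held
#' at the core temperature (Dirichlet); the top face exchanges radiatively
#' with the moxa stick and the surroundings.
#'
#' @param layers list of [tissue_layer()] objects, surface first.
#' @param blood a [blood_properties()] object.
#' @param lateral_radius lateral (cylinder) radius of the block, m. Must be at
#'   least 0.04 m so the 40 mm surface probes stay inside the domain.
#' @param core_temperature bottom boundary temperature, degrees C.
#' @param initial_surface_temperature target 5 mm disk-average surface
#'   temperature of the resting (pre-moxibustion) state, degrees C; `NA` to
#'   accept the untuned resting steady state.
#' @return an object of class `tissue_block`.
#' @export
tissue_block <- function(layers, blood = blood_properties(),
                         lateral_radius = 0.05, core_temperature = 37,
                         initial_surface_temperature = NA_real_) {
  if (!is.list(layers) || !length(layers) ||
      !all(vapply(layers, inherits, logical(1), "tissue_layer")))
    stop_field("layers", "must be a list of tissue_layer objects")
  stopifnot(inherits(blood, "blood_properties"))
  check_num(lateral_radius, "lateral_radius", lower = 0.04)
  check_num(core_temperature, "core_temperature", lower = 25, upper = 42)
  if (!is.na(initial_surface_temperature))
    check_num(initial_surface_temperature, "initial_surface_temperature",
              lower = 20, upper = 40)
  names(layers) <- vapply(layers, `[[`, character(1), "name")
  structure(list(layers = layers, blood = blood,
                 lateral_radius = lateral_radius,
                 core_temperature = core_temperature,
                 initial_surface_temperature = initial_surface_temperature),
            class = "tissue_block")
}

#' Default three-layer skin/fat/muscle block
#'
#' Thermal parameters (specific heat, density, conductivity) are the published
#' material values for skin, fat and muscle; layer thicknesses are 2.2 mm,
#' 12.4 mm and 10.4 mm (25 mm total depth). Perfusion rates, metabolic heats
#' and blood properties are literature-typical defaults; they are the free
#' parameters that [calibrate()] refines against the measured temperature
#' series, since the published model does not state them.
#'
#' @return a [tissue_block()] with three layers named skin, fat, muscle.
#' @export
default_tissue_block <- function() {
  tissue_block(
    layers = list(
      tissue_layer("skin",   2.2e-3, 1109, 3391, 0.37,
                   perfusion_rate = 0.5, metabolic_heat = 368),
      tissue_layer("fat",   12.4e-3,  911, 2348, 0.21,
                   perfusion_rate = 0.3, metabolic_heat = 180),
      tissue_layer("muscle", 10.4e-3, 1090, 3421, 0.49,
                   perfusion_rate = 0.7, metabolic_heat = 420)),
    blood = blood_properties(3617, 37),
    lateral_radius = 0.05,
    core_temperature = 37,
    initial_surface_temperature = 34.3)
}

#' Define a moxa stick
#'
#' The burning end is modelled as (part of) a sphere whose radius equals the
#' stick radius; `emissivity` is the emissivity of the glowing ember surface.
#'
#' @param diameter_mm stick diameter in mm (12, 15 or 18 in the study
#'   scenarios, any positive value accepted).
#' @param emissivity ember emissivity in (0, 1].
#' @return an object of class `moxa_stick`.
#' @export
moxa_stick <- function(diameter_mm = 18, emissivity = 0.9) {
  check_num(diameter_mm, "stick$diameter_mm", positive = TRUE)
  check_num(emissivity, "stick$emissivity", upper = 1)
  if (emissivity <= 0) stop_field("stick$emissivity", "must be in (0, 1]")
  structure(list(diameter_mm = diameter_mm, emissivity = emissivity),
            class = "moxa_stick")
}

#' Surface radiative-exchange properties
#'
#' Houses the quantities of the radiosity relation J = eps * e_b(T) + rho_d * G
#' with e_b(T) = n^2 * sigma * T^4: the emissivities of the burning end and of
#' the skin, the diffuse skin reflectance rho_d, and the refractive index n of
#' the intervening medium (air, n = 1).
#'
#' @param source_emissivity emissivity of the glowing burning end.
#' @param skin_emissivity skin emissivity.
#' @param skin_reflectance diffuse skin reflectance rho_d;
#'   `skin_emissivity + skin_reflectance` must not exceed 1.
#' @param refractive_index refractive index of the medium (default 1).
#' @return an object of class `surface_exchange`.
#' @export
surface_exchange <- function(source_emissivity = 0.9, skin_emissivity = 0.98,
                             skin_reflectance = 0.02, refractive_index = 1) {
  check_num(source_emissivity, "surfaces$source_emissivity", upper = 1)
  if (source_emissivity <= 0)
    stop_field("surfaces$source_emissivity", "must be in (0, 1]")
  check_num(skin_emissivity, "surfaces$skin_emissivity", upper = 1)
  if (skin_emissivity <= 0)
    stop_field("surfaces$skin_emissivity", "must be in (0, 1]")
  check_num(skin_reflectance, "surfaces$skin_reflectance", nonneg = TRUE)
  if (skin_reflectance >= 1)
    stop_field("surfaces$skin_reflectance", "must be in [0, 1)")
  if (skin_emissivity + skin_reflectance > 1 + 1e-12)
    stop_field("surfaces$skin_reflectance",
               "skin_emissivity + skin_reflectance must be <= 1")
  check_num(refractive_index, "surfaces$refractive_index", positive = TRUE)
  structure(list(source_emissivity = source_emissivity,
                 skin_emissivity = skin_emissivity,
                 skin_reflectance = skin_reflectance,
                 refractive_index = refractive_index),
            class = "surface_exchange")
}

#' Assemble a moxibustion scenario
#'
#' Bundles everything one simulation needs: the stick and its burning
#' schedule, the tissue block, the stick-to-skin distance, the ambient
#' temperature seen by the skin over the unobstructed view fraction, the
#' treatment duration and the surface radiative properties.
#'
#' @param stick a [moxa_stick()].
#' @param schedule a [burn_schedule()].
#' @param block a [tissue_block()].
#' @param distance_mm distance from the burning end to the skin surface, mm.
#' @param ambient_temperature ambient temperature, degrees C.
#' @param duration_s treatment duration, s.
#' @param surfaces a [surface_exchange()].
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(stick = moxa_stick(),
                            schedule = burn_schedule(),
                            block = default_tissue_block(),
                            distance_mm = 35,
                            ambient_temperature = 25,
                            duration_s = 900,
                            surfaces = surface_exchange()) {
  stopifnot(inherits(stick, "moxa_stick"), inherits(schedule, "burn_schedule"),
            inherits(block, "tissue_block"),
            inherits(surfaces, "surface_exchange"))
  check_num(distance_mm, "distance_mm", positive = TRUE)
  check_num(ambient_temperature, "ambient_temperature",
            lower = -20, upper = 45)
  check_num(duration_s, "duration_s", positive = TRUE)
  structure(list(stick = stick, schedule = schedule, block = block,
                 distance_mm = distance_mm,
                 ambient_temperature = ambient_temperature,
                 duration_s = duration_s, surfaces = surfaces),
            class = "scenario_config")
}

#' Standard moxibustion condition
#'
#' Maximum burning temperature 600 degrees C, 18 mm stick, 35 mm stick-to-skin
#' distance, 25 degrees C ambient, 15 min treatment.
#'
#' @return a [scenario_config()].
#' @export
standard_condition <- function() {
  scenario_config(stick = moxa_stick(18),
                  schedule = schedule_for_max(600),
                  block = default_tissue_block(),
                  distance_mm = 35, ambient_temperature = 25,
                  duration_s = 900)
}

#' Validation condition
#'
#' The scenario of the in-vivo verification experiment: 18 mm stick held 4 cm
#' above the skin for 15 min, ash cleaned once per minute, resting disk-average
#' skin temperature 34.3 degrees C. The ambient temperature was not reported
#' with the experiment; 20 degrees C is used, a typical indoor value at which
#' a 34.3 degrees C resting skin temperature is consistent with normal resting
#' perfusion under purely radiative surface exchange (see the methods
#' vignette).
#'
#' @return a [scenario_config()].
#' @export
validation_condition <- function() {
  scenario_config(stick = moxa_stick(18),
                  schedule = schedule_for_max(600),
                  block = default_tissue_block(),
                  distance_mm = 40, ambient_temperature = 20,
                  duration_s = 900)
}

# ---- serialization ---------------------------------------------------------

scenario_schema <- list(
  stick = c("diameter_mm", "emissivity"),
  schedule = c("max_temperature", "amplitude", "period", "clean_interval",
               "clean_duration", "clean_temperature", "reset_on_clean"),
  block = c("layers", "blood", "lateral_radius_mm", "core_temperature",
            "initial_surface_temperature"),
  layer = c("name", "thickness_mm", "density", "specific_heat",
            "conductivity", "perfusion_rate", "metabolic_heat"),
  blood = c("specific_heat", "temperature"),
  surfaces = c("source_emissivity", "skin_emissivity", "skin_reflectance",
               "refractive_index"),
  top = c("stick", "schedule", "block", "distance_mm",
          "ambient_temperature", "duration_s", "surfaces"))

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    stop(sprintf("unknown key%s in %s: %s", if (length(extra) > 1) "s" else "",
                 where, paste(extra, collapse = ", ")), call. = FALSE)
  missing <- setdiff(allowed, names(x))
  if (length(missing))
    stop(sprintf("missing key%s in %s: %s",
                 if (length(missing) > 1) "s" else "", where,
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(x)
}

#' Serialize a scenario to YAML
#'
#' @param scenario a [scenario_config()].
#' @param path optional file path; if `NULL` the YAML text is returned.
#' @return `path` invisibly, or the YAML string when `path` is `NULL`.
#' @seealso [load_scenario()]
#' @export
write_scenario <- function(scenario, path = NULL) {
  stopifnot(inherits(scenario, "scenario_config"))
  b <- scenario$block
  x <- list(
    stick = scenario$stick[c("diameter_mm", "emissivity")],
    schedule = scenario$schedule[scenario_schema$schedule],
    block = list(
      layers = lapply(unname(b$layers), function(l)
        list(name = l$name, thickness_mm = l$thickness * 1e3,
             density = l$density, specific_heat = l$specific_heat,
             conductivity = l$conductivity,
             perfusion_rate = l$perfusion_rate,
             metabolic_heat = l$metabolic_heat)),
      blood = b$blood[c("specific_heat", "temperature")],
      lateral_radius_mm = b$lateral_radius * 1e3,
      core_temperature = b$core_temperature,
      initial_surface_temperature = b$initial_surface_temperature),
    distance_mm = scenario$distance_mm,
    ambient_temperature = scenario$ambient_temperature,
    duration_s = scenario$duration_s,
    surfaces = scenario$surfaces[scenario_schema$surfaces])
  x <- rapply(x, unclass, how = "replace")
  txt <- yaml::as.yaml(x, precision = 15)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Load and validate a scenario from YAML
#'
#' Reads a scenario written by [write_scenario()] (or authored by hand in the
#' same schema), validating every field. Unknown keys and non-physical values
#' are rejected with an error naming the offending field.
#'
#' @param source a file path, or a YAML string (anything containing a
#'   newline is treated as YAML text).
#' @return a validated [scenario_config()].
#' @export
load_scenario <- function(source) {
  txt <- if (length(source) == 1L && !grepl("\n", source) &&
             file.exists(source)) {
    paste(readLines(source, warn = FALSE), collapse = "\n")
  } else paste(source, collapse = "\n")
  x <- yaml::yaml.load(txt)
  if (!is.list(x)) stop("scenario config did not parse to a mapping",
                        call. = FALSE)
  check_keys(x, scenario_schema$top, "scenario")
  check_keys(x$stick, scenario_schema$stick, "stick")
  check_keys(x$schedule, scenario_schema$schedule, "schedule")
  check_keys(x$block, scenario_schema$block, "block")
  check_keys(x$block$blood, scenario_schema$blood, "block$blood")
  check_keys(x$surfaces, scenario_schema$surfaces, "surfaces")
  layers <- lapply(seq_along(x$block$layers), function(i) {
    l <- x$block$layers[[i]]
    check_keys(l, scenario_schema$layer, sprintf("block$layers[[%d]]", i))
    tissue_layer(l$name, l$thickness_mm / 1e3, l$density, l$specific_heat,
                 l$conductivity, l$perfusion_rate, l$metabolic_heat)
  })
  init <- x$block$initial_surface_temperature
  scenario_config(
    stick = moxa_stick(x$stick$diameter_mm, x$stick$emissivity),
    schedule = burn_schedule(
      max_temperature = x$schedule$max_temperature,
      amplitude = x$schedule$amplitude, period = x$schedule$period,
      clean_interval = x$schedule$clean_interval,
      clean_duration = x$schedule$clean_duration,
      clean_temperature = x$schedule$clean_temperature,
      reset_on_clean = x$schedule$reset_on_clean),
    block = tissue_block(
      layers, blood_properties(x$block$blood$specific_heat,
                               x$block$blood$temperature),
      lateral_radius = x$block$lateral_radius_mm / 1e3,
      core_temperature = x$block$core_temperature,
      initial_surface_temperature = if (is.null(init)) NA_real_ else init),
    distance_mm = x$distance_mm,
    ambient_temperature = x$ambient_temperature,
    duration_s = x$duration_s,
    surfaces = surface_exchange(
      x$surfaces$source_emissivity, x$surfaces$skin_emissivity,
      x$surfaces$skin_reflectance, x$surfaces$refractive_index))
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>\n")
  cat(sprintf("  stick: %g mm (emissivity %.2f), burning end %g mm above skin\n",
              x$stick$diameter_mm, x$stick$emissivity, x$distance_mm))
  cat(sprintf("  schedule: peak %g C, amplitude %g C, period %g s, ash-clean every %g s\n",
              x$schedule$max_temperature, x$schedule$amplitude,
              x$schedule$period, x$schedule$clean_interval))
  cat(sprintf("  block: %s; lateral radius %g mm, core %g C\n",
              paste(sprintf("%s %.1f mm", names(x$block$layers),
                            vapply(x$block$layers, `[[`, 0, "thickness") * 1e3),
                    collapse = ", "),
              x$block$lateral_radius * 1e3, x$block$core_temperature))
  cat(sprintf("  ambient %g C, duration %g s\n",
              x$ambient_temperature, x$duration_s))
  invisible(x)
}
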