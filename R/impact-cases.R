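# Blunt-impact validation case catalog.
#
# Eight hub-impact families cover the torso front/back, abdomen, shoulder
# and lateral thorax/abdomen/hip.  The body model is rigidly rotated
# (z_rot then y_rot) before impact and the impactor always travels along
# global -x, so 0 deg corresponds to a frontal impact in the posterior
# direction and 90 deg to a lateral impact from the left.  Velocities are
# m/s, which equals mm/ms in the deck unit system.

#' A single blunt-impact validation case
#'
#' @param id case id (e.g. `"front_torso_hub_ls"`).
#' @param impactor list describing the rigid impactor: `shape`
#'   (`"cylinder"`, `"bar"`, `"rectangle"`), and `diameter_mm`, `width_mm`
#'   or `dims_mm` as fits the shape.
#' @param mass_kg impactor mass (kg), > 0.
#' @param speed one of `"LS"`, `"MS"`, `"HS"` (low/medium/high speed).
#' @param velocity_ms impact speed (m/s), > 0.
#' @param location impact-location landmark label (exactly one).
#' @param z_rot,y_rot pre-impact rigid rotation of the body model (deg).
#' @param posture `"seated"` or `"standing"`.
#' @param stroke_limiter is a discrete-element stroke limiter fitted (back
#'   impacts)?
#' @param mass_range_kg optional subject-to-subject impactor mass range.
#' @return Object of class `impact_case`.
#' @export
impact_case <- function(id, impactor, mass_kg, speed, velocity_ms,
                        location, z_rot = 0, y_rot = 0,
                        posture = c("seated", "standing"),
                        stroke_limiter = FALSE, mass_range_kg = NULL) {
  posture <- match.arg(posture)
  if (!speed %in% c("LS", "MS", "HS"))
    stop("unknown speed label '", speed, "' (use LS, MS or HS)")
  stopifnot(velocity_ms > 0, mass_kg > 0, length(location) == 1)
  geom_ok <- switch(impactor$shape,
                    cylinder = isTRUE(impactor$diameter_mm > 0),
                    bar = isTRUE(impactor$width_mm > 0),
                    rectangle = all(impactor$dims_mm > 0),
                    FALSE)
  if (!geom_ok) stop("invalid impactor geometry for case ", id)
  structure(list(id = id, impactor = impactor, mass_kg = mass_kg,
                 speed = speed, velocity_ms = velocity_ms,
                 location = location, z_rot = z_rot, y_rot = y_rot,
                 posture = posture, stroke_limiter = stroke_limiter,
                 mass_range_kg = mass_range_kg),
            class = "impact_case")
}

#' @export
print.impact_case <- function(x, ...) {
  cat(sprintf("Impact case %s: %s, %.1f kg at %.1f m/s -> %s (z %g, y %g, %s)\n",
              x$id, x$impactor$shape, x$mass_kg, x$velocity_ms, x$location,
              x$z_rot, x$y_rot, x$posture))
  invisible(x)
}

cyl <- function(d) list(shape = "cylinder", diameter_mm = d)

#' The built-in blunt-impact case catalog
#'
#' All hub-impact validation rows as machine-readable cases: front torso
#' hub (low/high speed), back torso hubs at T1/T6 and at T8 (with stroke
#' limiters), the abdominal bar, the lateral shoulder rectangle (from both
#' sides), and the lateral hubs at thorax, abdomen and hip in standing
#' posture.
#'
#' @return Named list of `impact_case` objects.
#' @export
default_impact_catalog <- function() {
  cases <- list(
    impact_case("front_torso_hub_ls", cyl(152), 23.6, "LS", 6.3,
                "mid_sternum", 0, 23, mass_range_kg = c(1.6, 23.6)),
    impact_case("front_torso_hub_hs", cyl(152), 23.6, "HS", 14.3,
                "mid_sternum", 0, 23, mass_range_kg = c(1.6, 23.6)),
    impact_case("back_torso_hub_t1_ls", cyl(152), 23.4, "LS", 4.4,
                "T1", 180, 23, stroke_limiter = TRUE),
    impact_case("back_torso_hub_t1_hs", cyl(152), 23.4, "HS", 6.6,
                "T1", 180, 23, stroke_limiter = TRUE),
    impact_case("back_torso_hub_t6_ls", cyl(152), 23.4, "LS", 4.4,
                "T6", 180, 23, stroke_limiter = TRUE),
    impact_case("back_torso_hub_t6_hs", cyl(152), 23.4, "HS", 6.6,
                "T6", 180, 23, stroke_limiter = TRUE),
    impact_case("back_torso_hub_t8_ls", cyl(152), 97.5, "LS", 3.0,
                "T8", 180, 12, stroke_limiter = TRUE),
    impact_case("back_torso_hub_t8_hs", cyl(152), 97.5, "HS", 5.5,
                "T8", 180, 12, stroke_limiter = TRUE),
    impact_case("abdominal_bar_ls", list(shape = "bar", width_mm = 25),
                48, "LS", 6.3, "L3", 180, 23),
    impact_case("abdominal_bar_hs", list(shape = "bar", width_mm = 25),
                48, "HS", 9.2, "L3", 180, 23),
    impact_case("shoulder_left_ls",
                list(shape = "rectangle", dims_mm = c(150, 80)), 23.4,
                "LS", 1.5, "glenohumeral_left", 90, 23),
    impact_case("shoulder_left_hs",
                list(shape = "rectangle", dims_mm = c(150, 80)), 23.4,
                "HS", 6, "glenohumeral_left", 90, 23),
    impact_case("shoulder_right_ls",
                list(shape = "rectangle", dims_mm = c(150, 80)), 23.4,
                "LS", 1.5, "glenohumeral_right", 270, 23),
    impact_case("shoulder_right_hs",
                list(shape = "rectangle", dims_mm = c(150, 80)), 23.4,
                "HS", 6, "glenohumeral_right", 270, 23),
    impact_case("lateral_thorax_ls", cyl(150), 23.4, "LS", 4.4,
                "xiphoid_process", 330, 0, posture = "standing"),
    impact_case("lateral_thorax_ms", cyl(150), 23.4, "MS", 6.5,
                "xiphoid_process", 330, 0, posture = "standing"),
    impact_case("lateral_abdomen_ls", cyl(150), 23.4, "LS", 4.8,
                "below_xiphoid_75mm", 330, 0, posture = "standing"),
    impact_case("lateral_abdomen_ms", cyl(150), 23.4, "MS", 6.8,
                "below_xiphoid_75mm", 330, 0, posture = "standing"),
    impact_case("lateral_hip_ls", cyl(150), 23.4, "LS", 5.2,
                "greater_trochanter", 270, 0, posture = "standing"),
    impact_case("lateral_hip_hs", cyl(150), 23.4, "HS", 9.8,
                "greater_trochanter", 270, 0, posture = "standing"))
  stats::setNames(cases, vapply(cases, `[[`, "", "id"))
}

#' Load an impact-case catalog from a config file
#'
#' Reads a YAML catalog (a list of case records with the fields of
#' [impact_case()]) or returns the built-in catalog when `config` is
#' `NULL`.
#'
#' @param config path to a YAML file, a pre-parsed list, or `NULL`.
#' @return Named list of `impact_case` objects.
#' @export
load_case_catalog <- function(config = NULL) {
  if (is.null(config)) return(default_impact_catalog())
  raw <- if (is.character(config)) yaml::read_yaml(config) else config
  cases <- lapply(raw, function(rec) {
    do.call(impact_case, rec)
  })
  stats::setNames(cases, vapply(cases, `[[`, "", "id"))
}
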