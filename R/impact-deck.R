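# Emission of blunt-impact simulation decks.
#
# The emitted deck contains the pre-rotated body model, a rigid shell
# impactor meshed to the case geometry and aligned with the impact
# landmark, an initial-velocity card launching the impactor along global
# -x, the surface-to-surface contact card (friction 0.3, viscous damping
# 20, SOFT 2, SBOPT 3, DEPTH 5), and a minimum-timestep control of
# 0.3 us.  No gravity is applied and the body model is unconstrained.
# Back-impact cases get a discrete-element stroke-limiter stub.

impactor_mesh <- function(case, centre, first_node, first_elem, part_id) {
  # plate in the y-z plane at x = centre[1]; travel axis is -x
  if (case$impactor$shape == "cylinder") {
    r <- case$impactor$diameter_mm / 2
    n <- 8L
    ys <- seq(-r, r, length.out = n + 1)
    zs <- seq(-r, r, length.out = n + 1)
    keep <- function(y, z) (y^2 + z^2) <= (r * 1.02)^2
  } else if (case$impactor$shape == "bar") {
    w <- case$impactor$width_mm; len <- 400
    ys <- seq(-len / 2, len / 2, length.out = 11L)
    zs <- seq(-w / 2, w / 2, length.out = 3L)
    keep <- function(y, z) TRUE
  } else {
    d <- case$impactor$dims_mm
    ys <- seq(-d[1] / 2, d[1] / 2, length.out = 6L)
    zs <- seq(-d[2] / 2, d[2] / 2, length.out = 4L)
    keep <- function(y, z) TRUE
  }
  grid <- expand.grid(y = ys, z = zs)
  nid <- matrix(NA_integer_, length(ys), length(zs))
  nodes <- list(); k <- 0L
  for (j in seq_along(zs)) for (i in seq_along(ys)) {
    nid[i, j] <- first_node + k
    nodes[[k + 1L]] <- c(first_node + k, centre[1],
                         centre[2] + ys[i], centre[3] + zs[j])
    k <- k + 1L
  }
  shells <- list(); e <- 0L
  for (j in seq_len(length(zs) - 1)) for (i in seq_len(length(ys) - 1)) {
    yc <- (ys[i] + ys[i + 1]) / 2; zc <- (zs[j] + zs[j + 1]) / 2
    if (!keep(yc, zc)) next
    shells[[e + 1L]] <- c(first_elem + e, part_id, nid[i, j], nid[i + 1, j],
                          nid[i + 1, j + 1], nid[i, j + 1])
    e <- e + 1L
  }
  nm <- do.call(rbind, nodes)
  used <- sort(unique(unlist(lapply(shells, function(s) s[3:6]))))
  nm <- nm[nm[, 1] %in% used, , drop = FALSE]
  sm <- do.call(rbind, shells)
  list(nodes = data.frame(id = as.integer(nm[, 1]), x = nm[, 2],
                          y = nm[, 3], z = nm[, 4], include = "impactor.k"),
       shells = data.frame(id = as.integer(sm[, 1]),
                           part = as.integer(sm[, 2]),
                           n1 = as.integer(sm[, 3]), n2 = as.integer(sm[, 4]),
                           n3 = as.integer(sm[, 5]), n4 = as.integer(sm[, 6]),
                           thickness = 2, include = "impactor.k"))
}

#' Emit a blunt-impact simulation deck
#'
#' Builds the complete impact deck for one validation case: the body model
#' rigidly pre-rotated by the case's (z_rot, y_rot), a rigid shell
#' impactor meshed to the case geometry and aligned with the (rotated)
#' impact landmark at a small stand-off gap along +x, all impactor degrees
#' of freedom locked except x-translation, the initial-velocity card with
#' the case magnitude along -x, the stated contact card, and the
#' minimum-timestep control card.  No gravity card is emitted.
#'
#' @param case `impact_case`.
#' @param assembly `hbm_assembly` of the body model (unrotated).
#' @param landmarks `hbm_landmarks` containing the case's impact-location
#'   label (in unrotated model coordinates).
#' @param gap_mm stand-off between landmark and impactor face (mm).
#' @param min_timestep_ms minimum-timestep control (ms); 3e-4 ms = 0.3 us.
#' @param stroke_limiter list with `stiffness_kN_mm` and `gap_mm` used for
#'   the discrete-element stroke-limiter stub on back impacts.
#' @return `hbm_assembly` of the impact deck (parseable and re-emittable
#'   through the keyword I/O layer).
#' @export
emit_impact_deck <- function(case, assembly, landmarks, gap_mm = 5,
                             min_timestep_ms = 3e-4,
                             stroke_limiter = list(stiffness_kN_mm = 1,
                                                   gap_mm = 50)) {
  hit <- match(case$location, landmarks$label)
  if (is.na(hit))
    stop("unknown impact landmark '", case$location, "'")
  model <- rigid_transform_model(assembly, case$z_rot, case$y_rot)
  R <- rotation_y(case$y_rot) %*% rotation_z(case$z_rot)
  loc <- as.numeric(R %*% unlist(landmarks[hit, c("x", "y", "z")]))

  nid0 <- max(model$nodes$id) + 1L
  eid0 <- max(c(model$solids$id, model$shells$id, model$discretes$id, 0L)) + 1L
  pid <- max(model$parts$id) + 1L
  imp <- impactor_mesh(case, loc + c(gap_mm, 0, 0), nid0, eid0, pid)

  parts <- rbind(model$parts,
                 data.frame(id = pid, name = paste0("impactor_", case$id),
                            region = "impactor", material = "900",
                            density = NA_real_, include = "impactor.k"))
  nodes <- rbind(model$nodes, imp$nodes)
  shells <- rbind(model$shells, imp$shells)
  discretes <- model$discretes
  extra <- model$extra

  extra[[length(extra) + 1L]] <- list(
    keyword = "*MAT_RIGID", include = "impact_setup.k",
    lines = c("*MAT_RIGID",
              "$ mid, rho, E, nu, cmo, con1, con2",
              "$ all impactor DOFs locked except x translation",
              "900,7.85e-06,210,0.3,1,011111,111111"))
  extra[[length(extra) + 1L]] <- list(
    keyword = "*INITIAL_VELOCITY_RIGID_BODY", include = "impact_setup.k",
    lines = c("*INITIAL_VELOCITY_RIGID_BODY",
              "$ pid, vx, vy, vz  (impactor travels along -x)",
              paste(pid, format_coord(-case$velocity_ms), 0, 0, sep = ",")))
  extra[[length(extra) + 1L]] <- list(
    keyword = "*CONTACT_AUTOMATIC_SURFACE_TO_SURFACE",
    include = "impact_setup.k",
    lines = c("*CONTACT_AUTOMATIC_SURFACE_TO_SURFACE",
              "$ ssid, msid, sstyp, mstyp",
              paste(pid, 0, 3, 2, sep = ","),
              "$ fs, fd, dc, vc, vdc",
              "0.3,0.3,0,0,20",
              "$ soft, sbopt, depth",
              "2,3,5"))
  extra[[length(extra) + 1L]] <- list(
    keyword = "*CONTROL_TIMESTEP", include = "impact_setup.k",
    lines = c("*CONTROL_TIMESTEP",
              "$ dtinit, tssfac, isdo, tslimt, dt2ms (negative: mass-scaled minimum dt)",
              paste(0, 0.9, 0, 0, format_coord(-min_timestep_ms), sep = ",")))

  if (isTRUE(case$stroke_limiter)) {
    # two-node spring between the impactor centre and a fixed anchor node
    centre_node <- imp$nodes$id[
      which.min((imp$nodes$y - loc[2])^2 + (imp$nodes$z - loc[3])^2)]
    anchor <- max(nodes$id) + 1L
    nodes <- rbind(nodes,
                   data.frame(id = anchor,
                              x = loc[1] + gap_mm + stroke_limiter$gap_mm,
                              y = loc[2], z = loc[3],
                              include = "impactor.k"))
    spid <- pid + 1L
    parts <- rbind(parts,
                   data.frame(id = spid, name = "stroke_limiter",
                              region = "impactor", material = "901",
                              density = NA_real_, include = "impactor.k"))
    discretes <- rbind(discretes,
                       data.frame(id = max(c(shells$id, eid0)) + 1L,
                                  part = spid, n1 = centre_node, n2 = anchor,
                                  include = "impactor.k"))
    extra[[length(extra) + 1L]] <- list(
      keyword = "*MAT_SPRING_ELASTIC", include = "impact_setup.k",
      lines = c("*MAT_SPRING_ELASTIC",
                "$ mid, stiffness (kN/mm)",
                paste(901, format_coord(stroke_limiter$stiffness_kN_mm),
                      sep = ",")))
  }

  hbm_assembly(nodes = nodes, solids = model$solids, shells = shells,
               discretes = discretes, parts = parts,
               parameters = c(model$parameters,
                              impact_velocity_ms = case$velocity_ms),
               includes = rbind(model$includes,
                                data.frame(name = c("impactor.k",
                                                    "impact_setup.k"),
                                           role = c("region-definition",
                                                    "control"))),
               extra = extra)
}

#' Read the impact settings back out of an emitted deck
#'
#' Parses the contact, timestep-control and initial-velocity cards that
#' [emit_impact_deck()] writes (and any deck following the same card
#' layout) from the opaque card blocks of a parsed assembly.
#'
#' @param assembly `hbm_assembly`, typically reparsed from an emitted deck.
#' @return List with `friction`, `friction_dynamic`, `viscous_damping`,
#'   `soft`, `sbopt`, `depth`, `min_timestep_ms`, `velocity` (vector,
#'   mm/ms) and `velocity_magnitude_ms`, plus `has_gravity`.
#' @export
read_impact_settings <- function(assembly) {
  out <- list(friction = NA_real_, friction_dynamic = NA_real_,
              viscous_damping = NA_real_, soft = NA_real_,
              sbopt = NA_real_, depth = NA_real_,
              min_timestep_ms = NA_real_,
              velocity = c(NA_real_, NA_real_, NA_real_),
              velocity_magnitude_ms = NA_real_, has_gravity = FALSE)
  datalines <- function(blk)
    blk$lines[-1][!startsWith(blk$lines[-1], "$")]
  nums <- function(line)
    suppressWarnings(as.numeric(strsplit(line, ",", fixed = TRUE)[[1]]))
  for (blk in assembly$extra) {
    kw <- blk$keyword
    if (kw == "*CONTACT_AUTOMATIC_SURFACE_TO_SURFACE") {
      dl <- datalines(blk)
      if (length(dl) >= 2) {
        v <- nums(dl[2])
        out$friction <- v[1]; out$friction_dynamic <- v[2]
        out$viscous_damping <- v[5]
      }
      if (length(dl) >= 3) {
        v <- nums(dl[3])
        out$soft <- v[1]; out$sbopt <- v[2]; out$depth <- v[3]
      }
    } else if (kw == "*CONTROL_TIMESTEP") {
      v <- nums(datalines(blk)[1])
      out$min_timestep_ms <- abs(v[5])
    } else if (kw == "*INITIAL_VELOCITY_RIGID_BODY") {
      v <- nums(datalines(blk)[1])
      out$velocity <- v[2:4]
      out$velocity_magnitude_ms <- sqrt(sum(v[2:4]^2))
    } else if (grepl("^\\*LOAD_BODY", kw)) {
      out$has_gravity <- TRUE
    }
  }
  out
}
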