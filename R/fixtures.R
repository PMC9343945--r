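# Deterministic synthetic fixtures.
#
# The generator emits a small hex-meshed two-limb "body": a box torso with
# an inner bone column (spine), two L-shaped legs (thigh forward, shank
# down - a schematic seated posture) each with an inner bone column, skin
# shell elements on the torso, a region partition, source landmark sets
# (outer skin + per-bone surfaces), and a two-stage morph plan
# (extremities then torso) with exterior-node bookkeeping.  It stands in
# for the template-mesh inputs of the real lineup so that every module is
# testable without the full model; it makes no claim to anatomical
# realism.

#' Fixture specification
#'
#' @param seed integer seed (used by the history generator; the mesh
#'   itself is fully deterministic).
#' @param elem_mm element edge length (mm).
#' @param torso_elems number of elements along x, y, z of the torso box.
#' @param thigh_elems,shank_elems elements along each limb segment.
#' @param limb_radius_mm half-width of the limb cross-section (mm); at
#'   least two elements must fit across the limb.
#' @param hip_angle,knee_angle posture-change angles (deg) used by the
#'   standing variant.
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, elem_mm = 60, torso_elems = c(4, 4, 5),
                         thigh_elems = 6, shank_elems = 6,
                         limb_radius_mm = 60, hip_angle = 90,
                         knee_angle = -90) {
  if (elem_mm <= 0 || any(torso_elems < 1) || thigh_elems < 1 ||
      shank_elems < 1)
    stop("all fixture dimensions must be positive")
  cross_e <- round(2 * limb_radius_mm / elem_mm)
  if (cross_e < 2)
    stop("infeasible discretization: fewer than 2 elements across the ",
         "limb radius")
  structure(list(seed = as.integer(seed), elem_mm = elem_mm,
                 torso_elems = torso_elems, thigh_elems = thigh_elems,
                 shank_elems = shank_elems, limb_radius_mm = limb_radius_mm,
                 cross_e = cross_e, hip_angle = hip_angle,
                 knee_angle = knee_angle),
            class = "fixture_spec")
}

# node registry keyed by rounded coordinates so adjoining boxes share nodes
fixture_mesher <- function() {
  env <- new.env(parent = emptyenv())
  env$key2id <- new.env(parent = emptyenv())
  env$coords <- list()
  env$solids <- list()
  env$next_node <- 1L
  env$next_elem <- 1L
  env$node_id <- function(p) {
    key <- sprintf("%.6f_%.6f_%.6f", p[1], p[2], p[3])
    id <- env$key2id[[key]]
    if (is.null(id)) {
      id <- env$next_node
      env$next_node <- env$next_node + 1L
      env$key2id[[key]] <- id
      env$coords[[id]] <- p
    }
    id
  }
  env$add_box <- function(xs, ys, zs, part_fun) {
    for (k in seq_len(length(zs) - 1)) for (j in seq_len(length(ys) - 1))
      for (i in seq_len(length(xs) - 1)) {
        c8 <- rbind(c(xs[i], ys[j], zs[k]), c(xs[i + 1], ys[j], zs[k]),
                    c(xs[i + 1], ys[j + 1], zs[k]), c(xs[i], ys[j + 1], zs[k]),
                    c(xs[i], ys[j], zs[k + 1]), c(xs[i + 1], ys[j], zs[k + 1]),
                    c(xs[i + 1], ys[j + 1], zs[k + 1]),
                    c(xs[i], ys[j + 1], zs[k + 1]))
        ids <- vapply(seq_len(8), function(r) env$node_id(c8[r, ]), 1L)
        ctr <- colMeans(c8)
        env$solids[[env$next_elem]] <- c(env$next_elem,
                                         part_fun(ctr), ids)
        env$next_elem <- env$next_elem + 1L
      }
  }
  env
}

fixture_part_table <- function() {
  data.frame(
    id = c(1L, 2L, 3L, 11L, 12L, 13L, 14L, 21L, 22L, 23L, 24L),
    name = c("torso_flesh", "torso_spine", "skin_shell",
             "thighL_flesh", "thighL_bone", "shankL_flesh", "shankL_bone",
             "thighR_flesh", "thighR_bone", "shankR_flesh", "shankR_bone"),
    region = c("torso", "torso", "torso",
               rep("left_extremity", 4), rep("right_extremity", 4)),
    material = c("flesh", "bone", "skin", rep(c("flesh", "bone"), 4)),
    density = c(1e-6, 2e-6, 1.1e-6, rep(c(1e-6, 2e-6), 4)),
    include = "parts.k")
}

# deterministic spherical point cloud (Fibonacci lattice)
fibonacci_sphere <- function(n, centre, radius) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(centre[1] + radius * sin(phi) * cos(theta),
        centre[2] + radius * sin(phi) * sin(theta),
        centre[3] + radius * cos(phi))
}

#' Generate the synthetic body fixture
#'
#' Builds the hex-meshed two-limb body, its landmark sets, region
#' partition, morph plan and auxiliary geometry (hip/knee centres,
#' femoral-head sample points for H-point fitting, material table for
#' timestep estimates).  Output is fully deterministic.
#'
#' @param spec [fixture_spec()].
#' @return Object of class `hbm_fixture` with fields `assembly`,
#'   `landmarks` (source), `plan`, `regions`, `node_sets`, `hip_centres`,
#'   `knee_centres`, `femoral_head`, `materials`, `spec`.
#' @export
make_fixture_body <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  e <- spec$elem_mm
  te <- spec$torso_elems
  half_x <- te[1] * e / 2; half_y <- te[2] * e / 2
  xs_t <- seq(-half_x, half_x, by = e)
  ys_t <- seq(-half_y, half_y, by = e)
  zs_t <- seq(0, te[3] * e, by = e)
  cw <- spec$cross_e * e          # limb cross-section width
  if (cw > half_y * 2)
    stop("infeasible discretization: limb does not fit under the torso")
  x_if <- half_x                  # hip interface plane
  x_knee0 <- x_if + (spec$thigh_elems - 1) * e
  x_knee1 <- x_if + spec$thigh_elems * e

  m <- fixture_mesher()
  # torso: flesh with a central 2 x 2-cell spine column
  spine_w <- e  # half-width of the spine column
  m$add_box(xs_t, ys_t, zs_t, function(ctr) {
    if (abs(ctr[1]) < spine_w && abs(ctr[2]) < spine_w) 2L else 1L
  })
  # limbs: thigh along +x, shank down -z from the distal thigh cell
  for (side in c("L", "R")) {
    sgn <- if (side == "L") 1 else -1
    ys_l <- if (side == "L") seq(0, cw, by = e) else seq(-cw, 0, by = e)
    zs_th <- seq(0, cw, by = e)
    xs_th <- seq(x_if, x_knee1, by = e)
    bone_y <- if (side == "L") c(0, e) else c(-e, 0)
    pid_th <- if (side == "L") c(11L, 12L) else c(21L, 22L)
    m$add_box(xs_th, ys_l, zs_th, function(ctr) {
      if (ctr[2] > bone_y[1] && ctr[2] < bone_y[2] && ctr[3] < e)
        pid_th[2] else pid_th[1]
    })
    xs_sh <- c(x_knee0, x_knee1)
    zs_sh <- seq(-spec$shank_elems * e, 0, by = e)
    pid_sh <- if (side == "L") c(13L, 14L) else c(23L, 24L)
    m$add_box(xs_sh, ys_l, zs_sh, function(ctr) {
      if (ctr[2] > bone_y[1] && ctr[2] < bone_y[2]) pid_sh[2] else pid_sh[1]
    })
  }

  coords <- do.call(rbind, m$coords)
  nodes <- data.frame(id = seq_len(nrow(coords)), x = coords[, 1],
                      y = coords[, 2], z = coords[, 3], include = "nodes.k")
  sol <- do.call(rbind, m$solids)
  solids <- data.frame(id = sol[, 1], part = sol[, 2])
  for (k in 1:8) solids[[paste0("n", k)]] <- sol[, 2 + k]
  solids$include <- "elements.k"

  # boundary faces of the solid mesh (faces used by exactly one hex)
  facemat <- NULL
  face_corners <- HEX_FACES
  keys <- character(); owners <- integer(); fnodes <- list()
  for (r in seq_len(nrow(solids))) {
    nn <- unlist(solids[r, paste0("n", 1:8)], use.names = FALSE)
    for (f in seq_len(6)) {
      fn <- nn[face_corners[f, ]]
      keys <- c(keys, paste(sort(fn), collapse = "_"))
      fnodes[[length(fnodes) + 1L]] <- fn
    }
  }
  tab <- table(keys)
  boundary_keys <- names(tab)[tab == 1]
  is_boundary_face <- keys %in% boundary_keys
  boundary_nodes <- sort(unique(unlist(fnodes[is_boundary_face])))

  # skin shells on the torso top face
  ztop <- max(zs_t)
  shell_faces <- fnodes[is_boundary_face]
  shell_faces <- Filter(function(fn)
    all(abs(nodes$z[fn] - ztop) < 1e-9), shell_faces)
  shells <- if (length(shell_faces)) {
    sm <- do.call(rbind, shell_faces)
    data.frame(id = max(solids$id) + seq_len(nrow(sm)), part = 3L,
               n1 = sm[, 1], n2 = sm[, 2], n3 = sm[, 3], n4 = sm[, 4],
               thickness = 2, include = "elements.k")
  } else empty_shells()

  parts <- fixture_part_table()
  assembly <- hbm_assembly(
    nodes = nodes, solids = solids, shells = shells, parts = parts,
    parameters = c(flesh_density_scale = 1),
    includes = data.frame(name = c("nodes.k", "elements.k", "parts.k"),
                          role = c("nodes", "region-definition",
                                   "region-definition")))

  # node sets per body region
  nodes_of_parts <- function(pids) {
    sel <- solids$part %in% pids
    sort(unique(unlist(solids[sel, paste0("n", 1:8)], use.names = FALSE)))
  }
  left_nodes <- nodes_of_parts(c(11L, 12L, 13L, 14L))
  right_nodes <- nodes_of_parts(c(21L, 22L, 23L, 24L))
  torso_nodes <- nodes_of_parts(c(1L, 2L))
  interface <- intersect(union(left_nodes, right_nodes), torso_nodes)
  limb_nodes <- union(left_nodes, right_nodes)
  torso_only <- setdiff(torso_nodes, interface)

  hip <- list(L = c(x_if, cw / 2, cw / 2), R = c(x_if, -cw / 2, cw / 2))
  knee <- list(L = c((x_knee0 + x_knee1) / 2, cw / 2, 0),
               R = c((x_knee0 + x_knee1) / 2, -cw / 2, 0))
  eps <- 1e-6

  # transition zones (no landmarks there; support sleeves take over when
  # the posture changes)
  hip_zone <- limb_nodes[nodes$x[limb_nodes] <= x_if + e + eps]
  knee_zone <- limb_nodes[nodes$x[limb_nodes] >= x_knee0 - eps &
                            nodes$z[limb_nodes] >= -e - eps &
                            nodes$z[limb_nodes] <= eps]
  excluded <- union(hip_zone, knee_zone)

  region_of_node <- function(id) {
    if (id %in% left_nodes && !(id %in% torso_nodes)) "left_extremity"
    else if (id %in% right_nodes && !(id %in% torso_nodes)) "right_extremity"
    else "torso"
  }
  lm_nodes <- setdiff(boundary_nodes, excluded)
  lm_region <- vapply(lm_nodes, region_of_node, "")
  skin <- landmark_set(paste0("skin:", lm_nodes), lm_region, "skin",
                       as.matrix(nodes[lm_nodes, c("x", "y", "z")]))
  bone_sets <- list()
  for (p in c(2L, 12L, 14L, 22L, 24L)) {
    pn <- setdiff(nodes_of_parts(p), excluded)
    if (!length(pn)) next
    pname <- parts$name[parts$id == p]
    bone_sets[[pname]] <- landmark_set(
      paste0("bone:", pname, ":", pn),
      vapply(pn, region_of_node, ""), paste0("bone:", pname),
      as.matrix(nodes[pn, c("x", "y", "z")]))
  }
  landmarks <- do.call(bind_landmarks, c(list(skin), unname(bone_sets)))

  limb_labels <- landmarks$label[landmarks$region %in%
                                   c("left_extremity", "right_extremity")]
  torso_labels <- landmarks$label[landmarks$region == "torso"]
  plan <- morph_plan(
    morph_stage("extremities", move_nodes = limb_nodes,
                landmark_labels = limb_labels, save_exterior = interface),
    morph_stage("torso", move_nodes = torso_only,
                landmark_labels = torso_labels))

  materials <- data.frame(
    part = parts$id,
    E = ifelse(parts$material == "bone", 15,
               ifelse(parts$material == "skin", 0.05, 0.001)),
    nu = ifelse(parts$material == "bone", 0.3, 0.45),
    rho = parts$density)

  structure(list(
    assembly = assembly, landmarks = landmarks, plan = plan,
    regions = parts[c("id", "name", "region")],
    node_sets = list(left = left_nodes, right = right_nodes,
                     torso = torso_nodes, torso_only = torso_only,
                     interface = interface, boundary = boundary_nodes,
                     hip_zone = hip_zone, knee_zone = knee_zone),
    hip_centres = hip, knee_centres = knee,
    femoral_head = list(L = fibonacci_sphere(30, hip$L, 30),
                        R = fibonacci_sphere(30, hip$R, 30)),
    materials = materials, spec = spec), class = "hbm_fixture")
}

#' @export
print.hbm_fixture <- function(x, ...) {
  cat("Synthetic body fixture\n")
  print(x$assembly)
  cat(sprintf("  landmarks: %d, plan stages: %d\n", nrow(x$landmarks),
              length(x$plan$stages)))
  invisible(x)
}

fixture_limb_transforms <- function(fixture, side, hip_angle, knee_angle) {
  hipc <- fixture$hip_centres[[side]]
  kneec <- fixture$knee_centres[[side]]
  t_thigh <- rotation_about_point(c(0, 1, 0), hip_angle, hipc)
  knee_new <- apply_transform(t_thigh, kneec)
  t_shank <- compose_transforms(
    rotation_about_point(c(0, 1, 0), knee_angle, knee_new), t_thigh)
  list(thigh = t_thigh, shank = t_shank)
}

#' Build target landmark sets for a fixture variant
#'
#' Variants emulate the lineup construction: `scaled_male` applies an
#' anisotropic stature-driven scaling to all landmarks (a pure affine
#' target map), `standing` rigidly reorients the limb landmark groups
#' about hip and knee and adds pre-morphed support sleeves around both
#' joints, and `scaled_standing` composes the two.
#'
#' @param fixture `hbm_fixture`.
#' @param variant `"scaled_male"`, `"standing"` or `"scaled_standing"`.
#' @param scale length-3 scale factors for the scaled variants (default
#'   `c(1.08, 1.05, 1.08)`, the stature-ratio-flavoured default).
#' @param anchor scaling anchor (mm).
#' @param hip_angle,knee_angle posture angles (deg); default from the
#'   fixture spec.
#' @return List with `source`, `target` (`hbm_landmarks`, matching label
#'   sequences), `plan` (variant-specific morph plan), `transforms`
#'   (per-limb rigid transforms, posture variants) and `support` (the
#'   support-surface construction, posture variants).
#' @export
make_fixture_targets <- function(fixture,
                                 variant = c("scaled_male", "standing",
                                             "scaled_standing"),
                                 scale = c(1.08, 1.05, 1.08),
                                 anchor = c(0, 0, 0), hip_angle = NULL,
                                 knee_angle = NULL) {
  variant <- match.arg(variant)
  src <- fixture$landmarks
  coords <- landmark_coords(src)
  if (is.null(hip_angle)) hip_angle <- fixture$spec$hip_angle
  if (is.null(knee_angle)) knee_angle <- fixture$spec$knee_angle
  scale_map <- function(p)
    scale_bone_volumetric(p, scale, anchor = anchor)

  if (variant == "scaled_male") {
    tgt_coords <- scale_map(coords)
    target <- landmark_set(src$label, src$region, src$surface, tgt_coords)
    return(list(source = src, target = target, plan = fixture$plan,
                transforms = NULL, support = NULL))
  }

  nodes <- fixture$assembly$nodes
  ns <- fixture$node_sets
  tr <- list(L = fixture_limb_transforms(fixture, "L", hip_angle,
                                         knee_angle),
             R = fixture_limb_transforms(fixture, "R", hip_angle,
                                         knee_angle))
  # classify each limb landmark into its bone group by its node position
  lm_node <- as.integer(sub("^.*:", "", src$label))
  tgt_coords <- coords
  for (i in seq_len(nrow(src))) {
    reg <- src$region[i]
    if (reg == "torso") next
    side <- if (reg == "left_extremity") "L" else "R"
    p <- coords[i, ]
    seg <- if (nodes$z[lm_node[i]] < -fixture$spec$elem_mm + 1e-6)
      "shank" else "thigh"
    tgt_coords[i, ] <- apply_transform(tr[[side]][[seg]], p)
  }

  # support sleeves: boundary nodes in the hip/knee transition zones,
  # pre-morphed by blending the two adjacent bone transforms
  bz <- ns$boundary
  surfaces <- list(); bone_points <- list(); transforms <- list()
  transforms[["torso"]] <- rigid_transform()
  bone_points[["torso"]] <- as.matrix(
    nodes[ns$torso_only, c("x", "y", "z")])
  for (side in c("L", "R")) {
    limbn <- if (side == "L") ns$left else ns$right
    sgn_nodes <- intersect(bz, limbn)
    hipn <- intersect(sgn_nodes, ns$hip_zone)
    kneen <- intersect(sgn_nodes, ns$knee_zone)
    thigh_ref <- setdiff(limbn, union(ns$hip_zone, ns$knee_zone))
    thigh_ref <- thigh_ref[nodes$z[thigh_ref] > -1e-6]
    shank_ref <- limbn[nodes$z[limbn] < -fixture$spec$elem_mm - 1e-6]
    transforms[[paste0("thigh", side)]] <- tr[[side]]$thigh
    transforms[[paste0("shank", side)]] <- tr[[side]]$shank
    bone_points[[paste0("thigh", side)]] <-
      as.matrix(nodes[thigh_ref, c("x", "y", "z")])
    bone_points[[paste0("shank", side)]] <-
      as.matrix(nodes[shank_ref, c("x", "y", "z")])
    if (length(hipn))
      surfaces[[paste0("hip", side)]] <- list(
        name = paste0("hip", side),
        points = as.matrix(nodes[hipn, c("x", "y", "z")]),
        bones = c("torso", paste0("thigh", side)),
        region = paste0(if (side == "L") "left" else "right",
                        "_extremity"))
    if (length(kneen))
      surfaces[[paste0("knee", side)]] <- list(
        name = paste0("knee", side),
        points = as.matrix(nodes[kneen, c("x", "y", "z")]),
        bones = c(paste0("thigh", side), paste0("shank", side)),
        region = paste0(if (side == "L") "left" else "right",
                        "_extremity"))
  }
  support <- pre_morph_support_surfaces(unname(surfaces), transforms,
                                        bone_points)
  target <- landmark_set(src$label, src$region, src$surface, tgt_coords)
  if (variant == "scaled_standing") {
    target <- landmark_set(src$label, src$region, src$surface,
                           scale_map(landmark_coords(target)))
    support$target <- landmark_set(support$target$label,
                                   support$target$region, "support",
                                   scale_map(landmark_coords(support$target)))
  }
  source_all <- bind_landmarks(src, support$source)
  target_all <- bind_landmarks(target, support$target)

  ext_labels <- source_all$label[source_all$region %in%
                                   c("left_extremity", "right_extremity")]
  torso_labels <- source_all$label[source_all$region == "torso" &
                                     source_all$surface != "support"]
  plan <- morph_plan(
    morph_stage("extremities",
                move_nodes = fixture$plan$stages[[1]]$move_nodes,
                landmark_labels = ext_labels,
                save_exterior = fixture$plan$stages[[1]]$save_exterior),
    morph_stage("torso",
                move_nodes = fixture$plan$stages[[2]]$move_nodes,
                landmark_labels = torso_labels))
  list(source = source_all, target = target_all, plan = plan,
       transforms = transforms, support = support)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate synthetic impact time histories with ground truth
#'
#' Emits analytic landmark/impactor/force histories for the postprocessing
#' pipeline: a rigid whole-body drift plus a prescribed relative
#' deformation `d(t) = A (1 - cos(w t)) / 2` (peak amplitude `A`), with
#' force from a linear spring `F = k d`.  The exact deflection and force
#' channels are recorded alongside, so pipeline outputs can be compared to
#' closed forms.  Optional seeded Gaussian noise is added to the emitted
#' histories (never to the ground truth).
#'
#' @param case_type passed to [deflection_channel()].
#' @param duration_ms,dt_ms time base (default 30 ms at 0.1 ms).
#' @param amplitude_mm peak deformation `A`.
#' @param period_ms period of the cosine deformation.
#' @param drift_mm_ms rigid whole-body drift velocity vector (mm/ms).
#' @param stiffness_kN_mm spring rate `k` relating force to deflection.
#' @param noise_sd standard deviation of additive coordinate noise (mm).
#' @param seed RNG seed for the noise (global RNG state is restored).
#' @return List with `histories` (named list of data.frames), `force`
#'   (`hbm_channel`, the force history), and `truth` (list with exact
#'   `deflection` and `force` channels).
#' @export
make_fixture_histories <- function(case_type = c("front", "back", "lateral",
                                                 "shoulder", "abdomen"),
                                   duration_ms = 30, dt_ms = 0.1,
                                   amplitude_mm = 30, period_ms = 20,
                                   drift_mm_ms = c(-1, 0, 0),
                                   stiffness_kN_mm = 0.05, noise_sd = 0,
                                   seed = 1L) {
  case_type <- match.arg(case_type)
  t <- seq(0, duration_ms, by = dt_ms)
  w <- 2 * pi / period_ms
  d <- amplitude_mm * (1 - cos(w * t)) / 2
  f <- stiffness_kN_mm * d
  drift <- outer(t, as.numeric(drift_mm_ms))
  mk <- function(base, defo = 0 * drift) {
    h <- data.frame(time = t,
                    x = base[1] + drift[, 1] + defo[, 1],
                    y = base[2] + drift[, 2] + defo[, 2],
                    z = base[3] + drift[, 3] + defo[, 3])
    if (noise_sd > 0) {
      h$x <- h$x + stats::rnorm(length(t), 0, noise_sd)
      h$y <- h$y + stats::rnorm(length(t), 0, noise_sd)
      h$z <- h$z + stats::rnorm(length(t), 0, noise_sd)
    }
    h
  }
  histories <- with_seed(seed, switch(case_type,
    front = ,
    back = list(sternum = mk(c(100, 0, 300), cbind(-d, 0 * d, 0 * d)),
                T8 = mk(c(-60, 0, 300))),
    # the lateral measure is the impactor's own travel (an absolute
    # measure), so the body drift does not enter its history
    lateral = list(impactor = data.frame(time = t, x = 150 - d, y = 0,
                                         z = 250)),
    shoulder = list(acromion_left = mk(c(0, 180, 420),
                                       cbind(0 * d, -d, 0 * d)),
                    acromion_right = mk(c(0, -180, 420))),
    abdomen = list(impactor = mk(c(130, 0, 150), cbind(-d, 0 * d, 0 * d)),
                   L3 = mk(c(-40, 0, 150)))))
  list(histories = histories,
       force = signal_channel(t, f, units = "kN", name = "impact_force"),
       truth = list(deflection = signal_channel(t, d, units = "mm",
                                                name = "true_deflection"),
                    force = signal_channel(t, f, units = "kN",
                                           name = "true_force")))
}
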