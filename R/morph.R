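#' Morph plans
#'
#' The whole-body morph is solved sequentially: fitting one interpolant to
#' every template landmark at once would mean inverting a single huge
#' matrix, so the body is split into regions morphed stage by stage.
#' Continuity across stages is enforced through *exterior nodes*: boundary
#' nodes morphed by an earlier stage are saved and re-used as additional
#' landmarks (source = their base position, target = their morphed
#' position) by later stages.
#'
#' A stage names the node set it moves, the landmark labels it is driven
#' by, and the node ids whose morphed positions are saved for later
#' stages.  Every model node must appear in exactly one stage's move set.
#'
#' @param name stage name (e.g. `"extremities"`, `"torso"`).
#' @param move_nodes integer node ids this stage moves.
#' @param landmark_labels labels of the source/target landmarks driving
#'   this stage.
#' @param save_exterior node ids (subset of `move_nodes`) saved as
#'   exterior-node landmarks for later stages.
#' @param use_saved should landmarks saved by earlier stages be appended?
#' @return `morph_stage` object.
#' @export
morph_stage <- function(name, move_nodes, landmark_labels,
                        save_exterior = integer(), use_saved = TRUE) {
  structure(list(name = name, move_nodes = as.integer(move_nodes),
                 landmark_labels = as.character(landmark_labels),
                 save_exterior = as.integer(save_exterior),
                 use_saved = isTRUE(use_saved)),
            class = "morph_stage")
}

#' @rdname morph_stage
#' @param ... `morph_stage` objects, in execution order.
#' @export
morph_plan <- function(...) {
  stages <- list(...)
  if (length(stages) == 1 && is.list(stages[[1]]) &&
      !inherits(stages[[1]], "morph_stage")) stages <- stages[[1]]
  stopifnot(all(vapply(stages, inherits, TRUE, "morph_stage")))
  structure(list(stages = stages), class = "morph_plan")
}

#' @export
print.morph_plan <- function(x, ...) {
  cat("Morph plan:", length(x$stages), "stage(s)\n")
  for (s in x$stages)
    cat(sprintf("  %-14s move %5d nodes, %4d landmarks, save %d exterior\n",
                s$name, length(s$move_nodes), length(s$landmark_labels),
                length(s$save_exterior)))
  invisible(x)
}

check_plan_coverage <- function(plan, node_ids) {
  cover <- table(unlist(lapply(plan$stages, `[[`, "move_nodes")))
  multi <- names(cover)[cover > 1]
  if (length(multi))
    stop("morph plan error: node(s) covered by more than one stage: ",
         paste(utils::head(multi, 10), collapse = ", "))
  missing <- setdiff(node_ids, as.integer(names(cover)))
  if (length(missing))
    stop("morph plan error: node(s) covered by no stage: ",
         paste(utils::head(missing, 10), collapse = ", "))
  invisible(TRUE)
}

#' Pre-morph support surfaces across a joint
#'
#' Joints that rotate far between postures (hip, knee, elbow) need guide
#' surfaces: auxiliary point sheets enclosing the joint whose targets are
#' predicted from the rigid transforms of the two adjacent bones and then
#' appended to the stage's target landmarks.  Each support point blends
#' the two bone transforms with inverse-distance weights to the two bone
#' surfaces (weights sum to one at every point), so the sheet follows the
#' near bone closely and interpolates smoothly across the joint.
#'
#' @param surfaces list of support-surface descriptions; each a list with
#'   `name`, `points` (k x 3, mm), `bones` (character(2): names of the two
#'   adjacent bones), `region` (region tag for the emitted landmarks).
#' @param transforms named list of `hbm_transform`, one per bone named in
#'   any surface.
#' @param bone_points named list of n x 3 matrices sampling each bone's
#'   surface (used for the distance weights).
#' @return List with `source` and `target` `hbm_landmarks` (surface tag
#'   `"support"`), and `weights`, a list of the per-point weight pairs.
#' @export
pre_morph_support_surfaces <- function(surfaces, transforms, bone_points) {
  src_list <- list(); tgt_list <- list(); wts <- list()
  for (sf in surfaces) {
    if (length(sf$bones) != 2)
      stop("support surface '", sf$name,
           "' must be adjacent to exactly two transformed bones")
    miss <- setdiff(sf$bones, names(transforms))
    if (length(miss))
      stop("support surface '", sf$name, "': no transform for bone(s) ",
           paste(miss, collapse = ", "))
    miss2 <- setdiff(sf$bones, names(bone_points))
    if (length(miss2))
      stop("support surface '", sf$name, "': no surface points for bone(s) ",
           paste(miss2, collapse = ", "))
    p <- as.matrix(sf$points)
    mindist <- function(bp) {
      bp <- as.matrix(bp)
      d2 <- outer(rowSums(p^2), rep(1, nrow(bp))) +
        outer(rep(1, nrow(p)), rowSums(bp^2)) - 2 * p %*% t(bp)
      sqrt(pmax(apply(d2, 1, min), 0))
    }
    d1 <- mindist(bone_points[[sf$bones[1]]])
    d2 <- mindist(bone_points[[sf$bones[2]]])
    w1 <- ifelse(d1 + d2 < 1e-12, 0.5,
                 ifelse(d1 < 1e-12, 1,
                        ifelse(d2 < 1e-12, 0, d2 / (d1 + d2))))
    t1 <- apply_transform(transforms[[sf$bones[1]]], p)
    t2 <- apply_transform(transforms[[sf$bones[2]]], p)
    tgt <- w1 * t1 + (1 - w1) * t2
    lab <- paste0("support:", sf$name, ":", seq_len(nrow(p)))
    region <- if (is.null(sf$region)) "support" else sf$region
    src_list[[sf$name]] <- landmark_set(lab, region, "support", p)
    tgt_list[[sf$name]] <- landmark_set(lab, region, "support", tgt)
    wts[[sf$name]] <- cbind(w1 = w1, w2 = 1 - w1)
  }
  list(source = do.call(bind_landmarks, unname(src_list)),
       target = do.call(bind_landmarks, unname(tgt_list)),
       weights = wts)
}

#' Morph a base model into a derivative node set
#'
#' Runs the sequential landmark-driven morph: for each stage in order, an
#' RBF interpolant is fitted to that stage's source/target landmarks (plus
#' any exterior-node landmarks saved by earlier stages) and applied to the
#' stage's node set.  Nodes outside a stage's move set are untouched by
#' that stage; ids and element tables never change, so the result is a
#' nodes-only include sharing everything else with the base model.
#'
#' @param base `hbm_assembly`.
#' @param plan `morph_plan` covering every node exactly once.
#' @param source,target `hbm_landmarks` with identical label sequences
#'   (include any pre-morphed support-surface landmarks).
#' @param ridge passed to [fit_rbf()].
#' @return Object of class `hbm_morph_result`: `assembly` (the morphed
#'   model), `nodes` (the nodes-only include as a data.frame), and
#'   `saved_exterior` (the exterior-node landmark bookkeeping).
#' @export
morph_derivative <- function(base, plan, source, target, ridge = NULL) {
  check_landmark_pairing(source, target)
  check_plan_coverage(plan, base$nodes$id)
  coords <- node_matrix(base)
  ids <- base$nodes$id
  new <- coords
  saved_src <- matrix(numeric(0), 0, 3)
  saved_tgt <- matrix(numeric(0), 0, 3)
  saved_ids <- integer()

  for (stage in plan$stages) {
    sel <- source$label %in% stage$landmark_labels
    if (!any(sel))
      stop("stage '", stage$name, "' selects no landmarks")
    src <- landmark_coords(source)[sel, , drop = FALSE]
    tgt <- landmark_coords(target)[sel, , drop = FALSE]
    if (stage$use_saved && nrow(saved_src)) {
      src <- rbind(src, saved_src)
      tgt <- rbind(tgt, saved_tgt)
    }
    model <- fit_rbf(src, tgt, ridge = ridge)
    rows <- match(stage$move_nodes, ids)
    if (anyNA(rows))
      stop("stage '", stage$name, "' moves unknown node id(s)")
    new[rows, ] <- apply_rbf(model, coords[rows, , drop = FALSE])
    if (length(stage$save_exterior)) {
      er <- match(stage$save_exterior, ids)
      saved_src <- rbind(saved_src, coords[er, , drop = FALSE])
      saved_tgt <- rbind(saved_tgt, new[er, , drop = FALSE])
      saved_ids <- c(saved_ids, stage$save_exterior)
    }
  }
  morphed <- set_node_matrix(base, new)
  nodes <- data.frame(id = ids, x = new[, 1], y = new[, 2], z = new[, 3],
                      include = "nodes.k")
  structure(list(assembly = morphed, nodes = nodes,
                 saved_exterior = list(ids = saved_ids, source = saved_src,
                                       target = saved_tgt)),
            class = "hbm_morph_result")
}

#' @export
print.hbm_morph_result <- function(x, ...) {
  cat(sprintf("Morph result: %d nodes morphed, %d exterior nodes saved\n",
              nrow(x$nodes), length(x$saved_exterior$ids)))
  invisible(x)
}

#' Mesh-quality report for a morphed derivative
#'
#' Compares element quality between a base model and a derivative with the
#' same topology: per-metric histograms for both, violation counts against
#' the thresholds, maximum nodal displacement, and the worst elements per
#' metric (candidates for manual nodal fixes).
#'
#' @param base,derivative `hbm_assembly` objects with identical element
#'   tables and node ids.
#' @param thresholds [quality_thresholds()].
#' @param n_worst how many worst elements to list per metric.
#' @return Object of class `hbm_morph_report`.
#' @export
morph_report <- function(base, derivative,
                         thresholds = quality_thresholds(), n_worst = 10) {
  same_topo <- identical(base$solids[c("id", "part", paste0("n", 1:8))],
                         derivative$solids[c("id", "part", paste0("n", 1:8))]) &&
    identical(base$shells[c("id", "part", paste0("n", 1:4))],
              derivative$shells[c("id", "part", paste0("n", 1:4))]) &&
    identical(base$nodes$id, derivative$nodes$id)
  if (!same_topo)
    stop("base and derivative topologies differ; cannot compare quality")
  qb <- classify_elements(base, thresholds)
  qd <- classify_elements(derivative, thresholds)
  disp <- sqrt(rowSums((node_matrix(derivative) - node_matrix(base))^2))
  worst <- list(
    jacobian = utils::head(qd$elements[order(qd$elements$jacobian), ],
                           n_worst),
    aspect = utils::head(qd$elements[order(-qd$elements$aspect), ], n_worst),
    warp = utils::head(
      qd$elements[order(-ifelse(is.na(qd$elements$warp), -Inf,
                                qd$elements$warp)), ], n_worst))
  structure(list(base = qb, derivative = qd,
                 max_displacement = max(disp),
                 displaced_nodes = sum(disp > 0),
                 violations_base = qb$n_failed,
                 violations_derivative = qd$n_failed,
                 worst = worst, thresholds = thresholds),
            class = "hbm_morph_report")
}

#' @export
print.hbm_morph_report <- function(x, ...) {
  cat("Morph quality report\n")
  cat(sprintf("  max nodal displacement: %.3f mm (%d nodes moved)\n",
              x$max_displacement, x$displaced_nodes))
  cat(sprintf("  failing elements: base %d -> derivative %d\n",
              x$violations_base, x$violations_derivative))
  invisible(x)
}
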