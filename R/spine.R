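# Spine curvature re-definition.
#
# The thoracic/lumbar spine curve is not taken from the template mesh;
# instead it is rebuilt from four joint landmarks (OC/C1, C7/T1, T12/L1,
# L5/S1) under the assumption that, between these points, the spine follows
# the curvature of the skin on the back.  The construction offsets the
# back-skin polyline inward along its in-plane normal by the skin-to-spine
# distance measured at each joint landmark (linearly interpolated in arc
# length in between), then corrects the result so it passes exactly through
# the four landmarks.  Vertebrae are placed on the new curve at their
# preserved arc-length fraction between bounding joints and rigidly rotated
# so their axis follows the new tangent (axial twist is preserved: the
# rotation is the minimal one between old and new tangents).

polyline_s <- function(P) {
  seg <- sqrt(rowSums((P[-1, , drop = FALSE] -
                         P[-nrow(P), , drop = FALSE])^2))
  c(0, cumsum(seg))
}

polyline_point <- function(P, s_vertices, s) {
  i <- findInterval(s, s_vertices, rightmost.closed = TRUE)
  i <- min(max(i, 1L), nrow(P) - 1L)
  t <- (s - s_vertices[i]) / max(s_vertices[i + 1] - s_vertices[i], 1e-300)
  P[i, ] + t * (P[i + 1, ] - P[i, ])
}

# tangent at arc position s; averages adjacent segment directions when the
# evaluation point lies (numerically) on a vertex
polyline_tangent <- function(P, s_vertices, s, snap = 1e-9) {
  n <- nrow(P)
  total <- s_vertices[n]
  dirs <- P[-1, , drop = FALSE] - P[-n, , drop = FALSE]
  dirs <- dirs / sqrt(rowSums(dirs^2))
  hit <- which(abs(s_vertices - s) <= snap * max(total, 1))
  if (length(hit)) {
    k <- hit[1]
    d <- if (k == 1) dirs[1, ] else if (k == n) dirs[n - 1, ]
    else dirs[k - 1, ] + dirs[k, ]
    return(d / sqrt(sum(d^2)))
  }
  i <- min(max(findInterval(s, s_vertices, rightmost.closed = TRUE), 1L),
           n - 1L)
  dirs[i, ]
}

project_on_polyline <- function(P, q) {
  n <- nrow(P)
  best <- list(dist2 = Inf)
  sv <- polyline_s(P)
  for (i in seq_len(n - 1)) {
    a <- P[i, ]; d <- P[i + 1, ] - a
    L2 <- sum(d^2)
    t <- if (L2 == 0) 0 else min(max(sum((q - a) * d) / L2, 0), 1)
    pt <- a + t * d
    d2 <- sum((q - pt)^2)
    if (d2 < best$dist2)
      best <- list(dist2 = d2, s = sv[i] + t * sqrt(L2), point = pt)
  }
  best
}

#' Spine joint landmarks and back-skin profile
#'
#' Bundles the four spinal joint landmarks (OC/C1, C7/T1, T12/L1, L5/S1,
#' ordered cranial to caudal) with the back-skin profile polyline that
#' shapes the curve between them.
#'
#' @param joints 4 x 3 matrix of joint landmark coordinates (mm), rows in
#'   the order OC/C1, C7/T1, T12/L1, L5/S1.
#' @param profile m x 3 polyline of back-skin points (mm), ordered cranial
#'   to caudal and densely sampled.
#' @return Object of class `hbm_spine`.
#' @export
spine_joint_landmarks <- function(joints, profile) {
  joints <- as.matrix(joints); profile <- as.matrix(profile)
  stopifnot(nrow(joints) == 4, ncol(joints) == 3, ncol(profile) == 3,
            nrow(profile) >= 2)
  rownames(joints) <- c("OC_C1", "C7_T1", "T12_L1", "L5_S1")
  structure(list(joints = joints, profile = profile), class = "hbm_spine")
}

spine_plane_normal <- function(profile, offsets) {
  ctr <- sweep(profile, 2, colMeans(profile))
  sv <- svd(ctr, nu = 0)
  if (nrow(profile) >= 3 && sv$d[2] > 1e-9 * max(sv$d[1], 1)) {
    return(sv$v[, 3])
  }
  # colinear profile: take the plane spanned by the line and the offsets
  tbar <- profile[nrow(profile), ] - profile[1, ]
  tbar <- tbar / sqrt(sum(tbar^2))
  dbar <- colMeans(offsets)
  dbar <- dbar - sum(dbar * tbar) * tbar
  if (sqrt(sum(dbar^2)) < 1e-12) {
    # offsets vanish too; any orthogonal direction serves
    dbar <- if (abs(tbar[1]) < 0.9) c(1, 0, 0) else c(0, 0, 1)
    dbar <- dbar - sum(dbar * tbar) * tbar
  }
  dbar <- dbar / sqrt(sum(dbar^2))
  c(tbar[2] * dbar[3] - tbar[3] * dbar[2],
    tbar[3] * dbar[1] - tbar[1] * dbar[3],
    tbar[1] * dbar[2] - tbar[2] * dbar[1])
}

# Build the target spine curve: offset profile + exact landmark correction.
# Returns the trimmed polyline and the arc positions of the four joints.
spine_target_curve <- function(spine) {
  P <- spine$profile
  J <- spine$joints
  svP <- polyline_s(P)
  proj <- lapply(seq_len(4), function(k) project_on_polyline(P, J[k, ]))
  sj <- vapply(proj, `[[`, 0, "s")
  if (any(diff(sj) <= 0))
    stop("joint landmarks are not monotone along the back-skin profile")
  feet <- t(vapply(proj, `[[`, numeric(3), "point"))
  offs <- J - feet
  m <- spine_plane_normal(P, offs)

  s_grid <- sort(unique(c(svP[svP > sj[1] & svP < sj[4]], sj)))
  pts <- t(vapply(s_grid, function(s) polyline_point(P, svP, s), numeric(3)))
  tans <- t(vapply(s_grid, function(s) polyline_tangent(P, svP, s),
                   numeric(3)))
  nrml <- t(apply(tans, 1, function(tt) {
    v <- c(tt[2] * m[3] - tt[3] * m[2],
           tt[3] * m[1] - tt[1] * m[3],
           tt[1] * m[2] - tt[2] * m[1])
    v / sqrt(sum(v^2))
  }))
  n_at_joint <- t(vapply(sj, function(s) {
    tt <- polyline_tangent(P, svP, s)
    v <- c(tt[2] * m[3] - tt[3] * m[2],
           tt[3] * m[1] - tt[1] * m[3],
           tt[1] * m[2] - tt[2] * m[1])
    v / sqrt(sum(v^2))
  }, numeric(3)))
  mu_j <- rowSums(offs * n_at_joint)
  mu <- stats::approx(sj, mu_j, xout = s_grid, rule = 2)$y
  C <- pts + mu * nrml

  # exact pass through the joints: interpolate the residual in arc length
  joint_idx <- vapply(sj, function(s) which.min(abs(s_grid - s)), 1L)
  resid <- J - C[joint_idx, , drop = FALSE]
  corr <- vapply(1:3, function(c3)
    stats::approx(sj, resid[, c3], xout = s_grid, rule = 2)$y,
    numeric(length(s_grid)))
  C <- C + corr
  list(curve = C, s = polyline_s(C),
       joint_s = polyline_s(C)[joint_idx])
}

#' Re-define the spine curve and transport the vertebrae onto it
#'
#' Builds a new spine curve through the four joint landmarks that follows
#' the curvature of the back skin in between (see the package vignette for
#' the construction), then places every vertebra on the new curve at its
#' preserved arc-length fraction between its bounding joints and returns
#' the per-vertebra rigid transform (translation to the new centre plus the
#' minimal rotation aligning the old local tangent with the new curve
#' tangent).  Each vertebra's internal geometry is preserved exactly.
#'
#' @param spine `hbm_spine` from [spine_joint_landmarks()]; the profile
#'   describes the TARGET back skin.
#' @param vertebrae named list; each entry a list with `centre` (length-3,
#'   mm) giving the vertebral body centre in the source model.  Centres
#'   must lie between the C7/T1 and L5/S1 joints of the source spine.
#' @param source_joints optional 4 x 3 matrix of the source joint landmarks
#'   (defaults to `spine$joints`, i.e. re-shaping in place).
#' @return List with one entry per vertebra: `label`, `centre_old`,
#'   `centre_new`, `rotation` (3 x 3), `transform` (`hbm_transform` acting
#'   on model coordinates); plus attribute `"curve"`, the fitted target
#'   curve polyline.
#' @export
redefine_spine_curve <- function(spine, vertebrae, source_joints = NULL) {
  tgt <- spine_target_curve(spine)
  Jsrc <- if (is.null(source_joints)) spine$joints else {
    sj <- as.matrix(source_joints); stopifnot(nrow(sj) == 4); sj
  }

  centres <- t(vapply(vertebrae, function(v) as.numeric(v$centre),
                      numeric(3)))
  labels <- names(vertebrae)
  if (is.null(labels)) labels <- paste0("V", seq_len(nrow(centres)))

  # order the centres along the source joint chain and build the source
  # spine polyline: joints with vertebra centres inserted in order
  chainJ <- Jsrc
  svJ <- polyline_s(chainJ)
  proj <- lapply(seq_len(nrow(centres)), function(k)
    project_on_polyline(chainJ, centres[k, ]))
  s_c <- vapply(proj, `[[`, 0, "s")
  if (any(s_c <= svJ[2] - 1e-9) || any(s_c >= svJ[4] + 1e-9))
    stop("vertebra centres must lie between the C7/T1 and L5/S1 joints")
  ord <- order(s_c)

  rows <- list(); tags <- character()
  for (j in 1:4) { rows[[length(rows) + 1L]] <- Jsrc[j, ]
                   tags <- c(tags, paste0("J", j)) }
  # interleave: walk joints and centres by arc position
  allpts <- rbind(Jsrc, centres)
  alls <- c(svJ, s_c)
  allt <- c(paste0("J", 1:4), paste0("C", seq_len(nrow(centres))))
  o <- order(alls)
  S <- allpts[o, , drop = FALSE]
  St <- allt[o]
  svS <- polyline_s(S)
  jpos <- match(paste0("J", 1:4), St)
  cpos <- match(paste0("C", seq_len(nrow(centres))), St)

  out <- vector("list", nrow(centres))
  for (k in seq_len(nrow(centres))) {
    idx <- cpos[k]
    jb <- max(jpos[jpos < idx]); ja <- min(jpos[jpos > idx])
    kj_lo <- which(jpos == jb); kj_hi <- which(jpos == ja)
    frac <- (svS[idx] - svS[jb]) / (svS[ja] - svS[jb])
    s_new <- tgt$joint_s[kj_lo] +
      frac * (tgt$joint_s[kj_hi] - tgt$joint_s[kj_lo])
    c_new <- polyline_point(tgt$curve, tgt$s, s_new)
    t_old <- polyline_tangent(S, svS, svS[idx])
    t_new <- polyline_tangent(tgt$curve, tgt$s, s_new)
    R <- minimal_rotation(t_old, t_new)
    c_old <- centres[k, ]
    tr <- rigid_transform(R, as.numeric(c_new - R %*% c_old))
    out[[k]] <- list(label = labels[k], centre_old = c_old,
                     centre_new = c_new, rotation = R, transform = tr)
  }
  names(out) <- labels
  attr(out, "curve") <- tgt$curve
  out
}
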