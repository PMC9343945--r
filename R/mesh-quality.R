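# Element quality metrics.
#
# Definitions (standard, oracle-checkable; exact parity with a particular
# commercial preprocessor is not claimed):
#   scaled Jacobian - minimum over corner evaluation points of the
#     normalized Jacobian determinant (corner edge triple product divided
#     by the product of the three edge lengths);
#   aspect ratio    - longest / shortest element edge;
#   warpage         - angle between the normals of the two corner triangles
#     of a quad, maximized over the two diagonal splits, in degrees.

HEX_CORNER_EDGES <- list(
  c(2, 4, 5), c(3, 1, 6), c(4, 2, 7), c(1, 3, 8),
  c(8, 6, 1), c(5, 7, 2), c(6, 8, 3), c(7, 5, 4))

HEX_EDGES <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1),
                   c(5, 6), c(6, 7), c(7, 8), c(8, 5),
                   c(1, 5), c(2, 6), c(3, 7), c(4, 8))
QUAD_EDGES <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1))
PENTA_EDGES <- rbind(c(1, 2), c(2, 3), c(3, 1),
                     c(4, 5), c(5, 6), c(6, 4),
                     c(1, 4), c(2, 5), c(3, 6))
PENTA_CORNER_EDGES <- list(
  c(2, 3, 4), c(3, 1, 5), c(1, 2, 6),
  c(6, 5, 1), c(4, 6, 2), c(5, 4, 3))

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

corner_jacobian <- function(corners, edges) {
  vals <- vapply(seq_along(edges), function(i) {
    e <- corners[edges[[i]], , drop = FALSE] -
      corners[rep(i, 3), , drop = FALSE]
    len <- sqrt(rowSums(e^2))
    if (any(len == 0)) return(0)
    det(e) / prod(len)
  }, numeric(1))
  min(vals)
}

#' Scaled Jacobian of an element
#'
#' Minimum over the element's corners of the normalized Jacobian
#' determinant; 1 for a rectangular box (or square), <= 0 for degenerate
#' or inverted elements.  Invariant under rigid motion and uniform
#' scaling.
#'
#' @param corners 8 x 3 (hex8), 4 x 3 (quad4) or 6 x 3 (penta6, bottom
#'   triangle then top triangle) corner coordinate matrix.
#' @param kind element kind: `"hex8"`, `"quad4"` or `"penta6"`.
#' @return Value in \[-1, 1\]; repeated corners give a value <= 0 rather
#'   than an error.
#' @export
scaled_jacobian <- function(corners, kind = c("hex8", "quad4", "penta6")) {
  kind <- match.arg(kind)
  p <- as.matrix(corners)
  if (kind == "hex8") {
    stopifnot(nrow(p) == 8)
    return(corner_jacobian(p, HEX_CORNER_EDGES))
  }
  if (kind == "penta6") {
    stopifnot(nrow(p) == 6)
    # normalization so a right prism over a right triangle scores 1
    return(corner_jacobian(p, PENTA_CORNER_EDGES))
  }
  stopifnot(nrow(p) == 4)
  # quad: corner cross products against the mean plane normal
  nsum <- c(0, 0, 0)
  for (i in 1:4) {
    e1 <- p[i %% 4 + 1, ] - p[i, ]
    e2 <- p[(i + 2) %% 4 + 1, ] - p[i, ]
    nsum <- nsum + cross3(e1, e2)
  }
  if (sqrt(sum(nsum^2)) == 0) return(0)
  nhat <- nsum / sqrt(sum(nsum^2))
  vals <- vapply(1:4, function(i) {
    e1 <- p[i %% 4 + 1, ] - p[i, ]
    e2 <- p[(i + 2) %% 4 + 1, ] - p[i, ]
    l1 <- sqrt(sum(e1^2)); l2 <- sqrt(sum(e2^2))
    if (l1 == 0 || l2 == 0) return(0)
    sum(cross3(e1, e2) * nhat) / (l1 * l2)
  }, numeric(1))
  min(vals)
}

#' Aspect ratio of an element
#'
#' Longest over shortest element edge; 1 for a cube or square,
#' `Inf` when an edge has zero length.
#'
#' @inheritParams scaled_jacobian
#' @return Value >= 1 (or `Inf`).
#' @export
aspect_ratio <- function(corners, kind = c("hex8", "quad4", "penta6")) {
  kind <- match.arg(kind)
  p <- as.matrix(corners)
  edges <- switch(kind, hex8 = HEX_EDGES, quad4 = QUAD_EDGES,
                  penta6 = PENTA_EDGES)
  stopifnot(nrow(p) == max(edges))
  len <- sqrt(rowSums((p[edges[, 1], , drop = FALSE] -
                         p[edges[, 2], , drop = FALSE])^2))
  if (min(len) == 0) return(Inf)
  max(len) / min(len)
}

#' Warpage of a quadrilateral
#'
#' Angle in degrees between the normals of the two corner triangles of the
#' quad, maximized over the two diagonal splits; 0 for a planar quad.
#' Invariant under rigid motion and uniform scaling.
#'
#' @param corners 4 x 3 corner coordinates (in cyclic order).
#' @return Warp angle in degrees.
#' @export
warpage <- function(corners) {
  p <- as.matrix(corners)
  stopifnot(nrow(p) == 4)
  tri_normal <- function(a, b, c) {
    n <- cross3(p[b, ] - p[a, ], p[c, ] - p[a, ])
    l <- sqrt(sum(n^2))
    if (l == 0) stop("degenerate corner triangle in warpage computation")
    n / l
  }
  angle <- function(n1, n2) {
    d <- max(-1, min(1, sum(n1 * n2)))
    acos(d) * 180 / pi
  }
  a1 <- angle(tri_normal(1, 2, 3), tri_normal(1, 3, 4))  # split on 1-3
  a2 <- angle(tri_normal(2, 3, 4), tri_normal(2, 4, 1))  # split on 2-4
  max(a1, a2)
}

#' Quality thresholds (100% failure levels)
#'
#' The pass/fail classification uses a minimum scaled Jacobian of 0.3, a
#' maximum aspect ratio of 12, and a maximum warpage of 30 degrees for
#' shells.
#'
#' @param jacobian_min minimum acceptable scaled Jacobian, in (0, 1].
#' @param aspect_max maximum acceptable aspect ratio, >= 1.
#' @param warp_max maximum acceptable shell warpage in degrees, >= 0.
#' @return Object of class `quality_thresholds`.
#' @export
quality_thresholds <- function(jacobian_min = 0.3, aspect_max = 12,
                               warp_max = 30) {
  stopifnot(jacobian_min > 0, jacobian_min <= 1, aspect_max >= 1,
            warp_max >= 0)
  structure(list(jacobian_min = jacobian_min, aspect_max = aspect_max,
                 warp_max = warp_max), class = "quality_thresholds")
}

# detect the collapsed-hex pentahedron encoding (edge 3-4 and edge 7-8
# collapsed); returns the 6 wedge corners or NULL
solid_kind <- function(nn) {
  if (length(unique(nn)) == 8) return(list(kind = "hex8", idx = 1:8))
  if (nn[3] == nn[4] && nn[7] == nn[8] && length(unique(nn)) == 6)
    return(list(kind = "penta6", idx = c(1, 2, 3, 5, 6, 7)))
  list(kind = "degenerate", idx = 1:8)
}

#' Classify all elements of an assembly against quality thresholds
#'
#' Computes the metric triple for every solid and shell element and flags
#' failures: scaled Jacobian below `jacobian_min`, aspect above
#' `aspect_max`, or (shells only) warpage above `warp_max`.
#'
#' @param assembly `hbm_assembly`.
#' @param thresholds [quality_thresholds()].
#' @return Object of class `hbm_quality_report`: `elements` (data.frame
#'   with id, type, kind, the three metrics and per-metric fail flags),
#'   `violations` (element ids per metric), `histograms` (per metric), and
#'   `n_failed`.
#' @export
classify_elements <- function(assembly, thresholds = quality_thresholds()) {
  xyz <- node_matrix(assembly)
  lookup <- function(ids) xyz[match(ids, assembly$nodes$id), , drop = FALSE]

  rows <- list()
  for (r in seq_len(nrow(assembly$solids))) {
    nn <- unlist(assembly$solids[r, paste0("n", 1:8)], use.names = FALSE)
    sk <- solid_kind(nn)
    if (sk$kind == "degenerate") {
      p <- lookup(nn)
      rows[[length(rows) + 1L]] <- data.frame(
        id = assembly$solids$id[r], type = "solid", kind = "degenerate",
        jacobian = 0, aspect = Inf, warp = NA_real_)
      next
    }
    p <- lookup(nn[sk$idx])
    rows[[length(rows) + 1L]] <- data.frame(
      id = assembly$solids$id[r], type = "solid", kind = sk$kind,
      jacobian = scaled_jacobian(p, sk$kind),
      aspect = aspect_ratio(p, sk$kind), warp = NA_real_)
  }
  for (r in seq_len(nrow(assembly$shells))) {
    nn <- unlist(assembly$shells[r, paste0("n", 1:4)], use.names = FALSE)
    p <- lookup(nn)
    rows[[length(rows) + 1L]] <- data.frame(
      id = assembly$shells$id[r], type = "shell", kind = "quad4",
      jacobian = scaled_jacobian(p, "quad4"),
      aspect = aspect_ratio(p, "quad4"),
      warp = tryCatch(warpage(p), error = function(e) NA_real_))
  }
  elements <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = integer(), type = character(), kind = character(),
               jacobian = numeric(), aspect = numeric(), warp = numeric())
  elements$fail_jacobian <- elements$jacobian < thresholds$jacobian_min
  elements$fail_aspect <- elements$aspect > thresholds$aspect_max
  elements$fail_warp <- !is.na(elements$warp) &
    elements$warp > thresholds$warp_max
  elements$fail <- elements$fail_jacobian | elements$fail_aspect |
    elements$fail_warp
  breaks_j <- seq(-1, 1, by = 0.1)
  histo <- list(
    jacobian = graphics::hist(pmin(pmax(elements$jacobian, -1), 1),
                              breaks = breaks_j, plot = FALSE),
    aspect = graphics::hist(pmin(elements$aspect, 50),
                            breaks = seq(0, 50, by = 1), plot = FALSE),
    warp = graphics::hist(pmin(elements$warp[!is.na(elements$warp)], 180),
                          breaks = seq(0, 180, by = 5), plot = FALSE))
  structure(list(
    elements = elements,
    violations = list(jacobian = elements$id[elements$fail_jacobian],
                      aspect = elements$id[elements$fail_aspect],
                      warp = elements$id[elements$fail_warp]),
    histograms = histo,
    n_failed = sum(elements$fail),
    thresholds = thresholds), class = "hbm_quality_report")
}

#' @export
print.hbm_quality_report <- function(x, ...) {
  cat(sprintf("Quality report: %d elements, %d failing\n",
              nrow(x$elements), x$n_failed))
  cat(sprintf("  jacobian < %.2g: %d   aspect > %g: %d   warp > %g deg: %d\n",
              x$thresholds$jacobian_min, length(x$violations$jacobian),
              x$thresholds$aspect_max, length(x$violations$aspect),
              x$thresholds$warp_max, length(x$violations$warp)))
  invisible(x)
}
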