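#' Fit a radial-basis-function landmark interpolant
#'
#' Fits the volumetric deformation field that carries each source landmark
#' to its target.  The interpolant is a triharmonic RBF in 3-D,
#' `f(x) = c0 + C x + sum_i w_i |x - x_i|^3`, i.e. the radial kernel `r^3`
#' plus a full affine polynomial, solved with the usual orthogonality side
#' conditions on the weights (`sum w_i = 0`, `sum w_i x_i = 0`).  The
#' affine term makes the interpolant reproduce any affine target map
#' exactly; with zero ridge the interpolation at the landmarks is exact to
#' numerical precision.
#'
#' Source landmarks closer together than `merge_tol` are merged (their
#' targets averaged) before solving, so duplicated template points cannot
#' make the system singular.
#'
#' @param source,target `hbm_landmarks` with identical label sequences, or
#'   plain n x 3 coordinate matrices.
#' @param ridge non-negative Tikhonov regularization added to the kernel
#'   diagonal (kernel units, mm^3).  The default `NULL` uses the mild value
#'   `1e-10 *` (mean squared landmark spacing), which leaves near-exact
#'   interpolation while guarding against close-but-not-merged landmarks;
#'   pass `0` for strictly exact interpolation.
#' @param merge_tol merge tolerance for near-duplicate source landmarks
#'   (mm).
#' @return Object of class `hbm_rbf`: kernel id, centre coordinates,
#'   weights (n x 3), affine coefficients (4 x 3), ridge used.
#' @export
fit_rbf <- function(source, target, ridge = NULL, merge_tol = 1e-6) {
  if (inherits(source, "hbm_landmarks") || inherits(target, "hbm_landmarks")) {
    check_landmark_pairing(source, target)
    src <- landmark_coords(source)
    tgt <- landmark_coords(target)
  } else {
    src <- as.matrix(source); tgt <- as.matrix(target)
    if (nrow(src) != nrow(tgt))
      stop("source and target landmark sets must have identical label ",
           "sequences")
  }
  stopifnot(ncol(src) == 3, ncol(tgt) == 3)
  if (nrow(src) < 4)
    stop("need at least 4 landmarks to determine the affine term")

  # merge near-duplicate sources, averaging their targets
  D <- as.matrix(stats::dist(src))
  n <- nrow(src)
  group <- seq_len(n)
  for (i in seq_len(n - 1)) {
    close <- which(D[i, ] < merge_tol & seq_len(n) > i)
    group[close] <- pmin(group[close], group[i])
  }
  if (length(unique(group)) < n) {
    keep <- !duplicated(group)
    tgt <- apply(tgt, 2, function(col) tapply(col, group, mean))
    src <- src[keep, , drop = FALSE]
    D <- D[keep, keep, drop = FALSE]
    n <- nrow(src)
  }

  # solve in normalized coordinates (centred, scaled by the mean landmark
  # spacing) so the saddle system is well conditioned for mm-scale meshes
  shift <- colMeans(src)
  h <- mean(D[upper.tri(D)])
  if (!is.finite(h) || h <= 0) h <- 1
  Dn <- D / h
  if (is.null(ridge)) ridge <- 1e-10 * mean(Dn[upper.tri(Dn)]^2)
  srcn <- sweep(src, 2, shift) / h
  tgtn <- sweep(tgt, 2, shift) / h
  K <- Dn^3
  if (ridge > 0) diag(K) <- diag(K) + ridge
  P <- cbind(1, srcn)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4, 4)))
  rhs <- rbind(tgtn, matrix(0, 4, 3))
  sol <- tryCatch(solve(A, rhs), error = function(e)
    stop("singular RBF system (coincident or degenerate landmarks); ",
         "try a larger ridge", call. = FALSE))
  structure(list(kernel = "triharmonic_r3", centres = unname(src),
                 centres_scaled = unname(srcn),
                 weights = unname(sol[seq_len(n), , drop = FALSE]),
                 affine = unname(sol[n + 1:4, , drop = FALSE]),
                 shift = unname(shift), scale = h, ridge = ridge),
            class = "hbm_rbf")
}

#' @export
print.hbm_rbf <- function(x, ...) {
  cat(sprintf("RBF interpolant: kernel %s, %d centres, ridge %g\n",
              x$kernel, nrow(x$centres), x$ridge))
  invisible(x)
}

#' Evaluate an RBF deformation field
#'
#' Maps query points through a fitted interpolant.  When given an
#' `hbm_assembly`, only the node coordinates change: ids, counts and all
#' element tables are untouched.
#'
#' @param model `hbm_rbf` from [fit_rbf()].
#' @param nodes n x 3 coordinate matrix, or an `hbm_assembly`.
#' @param block evaluation block size (rows of the query-by-centre distance
#'   matrix held in memory at once).
#' @return Mapped coordinates (same shape), or the assembly with morphed
#'   coordinates.
#' @export
apply_rbf <- function(model, nodes, block = 20000L) {
  if (inherits(nodes, "hbm_assembly"))
    return(set_node_matrix(nodes, apply_rbf(model, node_matrix(nodes),
                                            block = block)))
  p <- as.matrix(nodes)
  if (nrow(p) == 0) return(p[, 1:3, drop = FALSE])
  stopifnot(ncol(p) == 3)
  out <- matrix(0, nrow(p), 3)
  ctr <- model$centres_scaled
  pn <- sweep(p, 2, model$shift) / model$scale
  for (start in seq(1, nrow(p), by = block)) {
    idx <- start:min(start + block - 1, nrow(p))
    q <- pn[idx, , drop = FALSE]
    d2 <- outer(rowSums(q^2), rep(1, nrow(ctr))) +
      outer(rep(1, nrow(q)), rowSums(ctr^2)) - 2 * q %*% t(ctr)
    d2[d2 < 0] <- 0
    out[idx, ] <- (d2^1.5) %*% model$weights +
      cbind(1, q) %*% model$affine
  }
  out <- out * model$scale +
    matrix(model$shift, nrow(out), 3, byrow = TRUE)
  dimnames(out) <- dimnames(p)
  out
}

#' Interpolation residual at the landmarks
#'
#' @param model `hbm_rbf`.
#' @param target target coordinates the model was fitted to (post-merge
#'   order); defaults to re-evaluating at the centres only and returning
#'   displacement magnitudes against the stored solution.
#' @return Maximum absolute residual (mm) of the interpolant at its
#'   centres against `target`.
#' @export
rbf_residual <- function(model, target) {
  pred <- apply_rbf(model, model$centres)
  max(abs(pred - as.matrix(target)))
}
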