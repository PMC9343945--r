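#' Landmark sets
#'
#' An ordered table of labelled 3-D points used as morphing correspondences.
#' Each landmark carries a body-region tag and a surface tag: `skin`,
#' `bone:<name>` for a named skeletal surface, or `support` for pre-morphed
#' auxiliary surfaces guiding large joint rotations.  A source set and a
#' target set that are used together must have identical label sequences.
#'
#' @param label character vector of unique labels.
#' @param region body-region tag per landmark.
#' @param surface surface tag per landmark (`skin`, `bone:<name>`,
#'   `support`).
#' @param coords n x 3 numeric matrix of coordinates (mm).
#' @return Object of class `hbm_landmarks` (a data.frame with columns
#'   `label`, `region`, `surface`, `x`, `y`, `z`).
#' @export
landmark_set <- function(label, region, surface, coords) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3, length(label) == nrow(coords))
  if (anyDuplicated(label))
    stop("landmark labels must be unique; duplicated: ",
         paste(utils::head(unique(label[duplicated(label)]), 5),
               collapse = ", "))
  d <- data.frame(label = as.character(label),
                  region = rep_len(as.character(region), length(label)),
                  surface = rep_len(as.character(surface), length(label)),
                  x = coords[, 1], y = coords[, 2], z = coords[, 3])
  class(d) <- c("hbm_landmarks", "data.frame")
  d
}

#' @export
print.hbm_landmarks <- function(x, ...) {
  cat(sprintf("Landmark set: %d landmarks, %d region(s), surfaces: %s\n",
              nrow(x), length(unique(x$region)),
              paste(unique(x$surface), collapse = ", ")))
  print.data.frame(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("  ...\n")
  invisible(x)
}

#' @rdname landmark_set
#' @param x `hbm_landmarks`.
#' @export
landmark_coords <- function(x) {
  m <- as.matrix(as.data.frame(x)[c("x", "y", "z")])
  rownames(m) <- x$label
  m
}

#' Combine landmark sets
#'
#' @param ... `hbm_landmarks` objects.
#' @return Single `hbm_landmarks`; labels must remain unique.
#' @export
bind_landmarks <- function(...) {
  d <- do.call(rbind, lapply(list(...), as.data.frame))
  landmark_set(d$label, d$region, d$surface, as.matrix(d[c("x", "y", "z")]))
}

#' Subset a landmark set
#'
#' @param x `hbm_landmarks`.
#' @param region,surface optional tag filters (exact match; `surface`
#'   also matches prefixes like `"bone"` against `"bone:femur"`).
#' @param labels optional label filter.
#' @return Filtered `hbm_landmarks` (ordering preserved).
#' @export
filter_landmarks <- function(x, region = NULL, surface = NULL,
                             labels = NULL) {
  keep <- rep(TRUE, nrow(x))
  if (!is.null(region)) keep <- keep & x$region %in% region
  if (!is.null(surface))
    keep <- keep & (x$surface %in% surface |
                      sub(":.*$", "", x$surface) %in% surface)
  if (!is.null(labels)) keep <- keep & x$label %in% labels
  d <- as.data.frame(x)[keep, , drop = FALSE]
  landmark_set(d$label, d$region, d$surface, as.matrix(d[c("x", "y", "z")]))
}

#' Read / write landmark tables
#'
#' Landmark sets are exchanged as plain-text whitespace-separated tables
#' with columns `label region surface x y z` and a header line.
#'
#' @param path file path.
#' @return `hbm_landmarks` (for the reader).
#' @export
read_landmarks <- function(path) {
  d <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  landmark_set(d$label, d$region, d$surface, as.matrix(d[c("x", "y", "z")]))
}

#' @rdname read_landmarks
#' @param x `hbm_landmarks`.
#' @export
write_landmarks <- function(x, path) {
  utils::write.table(as.data.frame(x), path, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# internal: assert source/target label agreement
check_landmark_pairing <- function(source, target) {
  if (!identical(source$label, target$label))
    stop("source and target landmark sets must have identical label ",
         "sequences")
  invisible(TRUE)
}
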