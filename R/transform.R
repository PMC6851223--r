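#' Rotate vectors about an axis (Rodrigues' formula)
#'
#' Computes `v cos(theta) + (axis x v) sin(theta) + axis (axis . v)(1 - cos(theta))`
#' for one vector or each row of a matrix of vectors.
#'
#' @param v A length-3 vector or an n x 3 matrix of row vectors.
#' @param axis Unit rotation axis (length-3; norm must be 1 within 1e-9).
#' @param angle Rotation angle in radians.
#' @return Rotated vector(s), same shape as `v`.
#' @examples
#' rodrigues_rotate(c(1, 0, 0), c(0, 0, 1), pi / 2)
#' @export
rodrigues_rotate <- function(v, axis, angle) {
  axis <- as.numeric(axis)
  if (length(axis) != 3 || abs(sqrt(sum(axis^2)) - 1) > 1e-9) {
    stop_validation("axis must be a unit 3-vector (|axis| = 1 within 1e-9)")
  }
  vec_in <- !is.matrix(v)
  if (vec_in) v <- matrix(as.numeric(v), nrow = 1)
  if (ncol(v) != 3) stop_validation("v must be a 3-vector or an n x 3 matrix")
  ct <- cos(angle); st <- sin(angle)
  kx <- axis[1]; ky <- axis[2]; kz <- axis[3]
  cross <- cbind(
    ky * v[, 3] - kz * v[, 2],
    kz * v[, 1] - kx * v[, 3],
    kx * v[, 2] - ky * v[, 1]
  )
  dot <- v[, 1] * kx + v[, 2] * ky + v[, 3] * kz
  out <- v * ct + cross * st + outer(dot * (1 - ct), axis)
  if (vec_in) as.numeric(out) else out
}

#' Translate fibers
#'
#' @param phantom A `fiber_phantom` tibble.
#' @param offset Length-3 numeric translation (micrometres).
#' @param groups,fibers Optional selection: group paths (subtrees included)
#'   and/or fiber ids to transform; default all.
#' @return The transformed phantom.
#' @export
translate_fibers <- function(phantom, offset, groups = NULL, fibers = NULL) {
  phantom <- as_fiber_phantom(phantom)
  offset <- as.numeric(offset)
  if (length(offset) != 3 || any(!is.finite(offset))) {
    stop_validation("offset must be a finite 3-vector")
  }
  keep <- select_rows(phantom, groups, fibers)
  phantom$x[keep] <- phantom$x[keep] + offset[1]
  phantom$y[keep] <- phantom$y[keep] + offset[2]
  phantom$z[keep] <- phantom$z[keep] + offset[3]
  phantom
}

#' Rotate fibers about an axis through a pivot point
#'
#' An isometry of the selected point set: all pairwise distances are
#' preserved. The pivot defaults to the centroid of the selected points.
#'
#' @inheritParams translate_fibers
#' @param axis Rotation axis (any nonzero 3-vector; normalized internally).
#' @param angle Rotation angle in radians.
#' @param pivot Optional pivot point (length-3); default selection centroid.
#' @return The transformed phantom.
#' @export
rotate_fibers <- function(phantom, axis, angle, pivot = NULL,
                          groups = NULL, fibers = NULL) {
  phantom <- as_fiber_phantom(phantom)
  axis <- as.numeric(axis)
  nrm <- sqrt(sum(axis^2))
  if (length(axis) != 3 || !is.finite(nrm) || nrm == 0) {
    stop_validation("rotation axis must be a nonzero 3-vector")
  }
  axis <- axis / nrm
  keep <- select_rows(phantom, groups, fibers)
  pts <- cbind(phantom$x[keep], phantom$y[keep], phantom$z[keep])
  if (is.null(pivot)) pivot <- colMeans(pts)
  pivot <- as.numeric(pivot)
  if (length(pivot) != 3) stop_validation("pivot must be a 3-vector")
  rot <- rodrigues_rotate(sweep(pts, 2, pivot), axis, angle)
  rot <- sweep(rot, 2, pivot, `+`)
  phantom$x[keep] <- rot[, 1]
  phantom$y[keep] <- rot[, 2]
  phantom$z[keep] <- rot[, 3]
  phantom
}

#' Scale fibers uniformly
#'
#' Coordinates scale about the pivot; radii scale by the same factor.
#'
#' @inheritParams rotate_fibers
#' @param factor Positive scale factor.
#' @return The transformed phantom.
#' @export
scale_fibers <- function(phantom, factor, pivot = NULL,
                         groups = NULL, fibers = NULL) {
  phantom <- as_fiber_phantom(phantom)
  if (!is.numeric(factor) || length(factor) != 1 || !is.finite(factor) ||
      factor <= 0) {
    stop_validation("scale factor must be a positive number")
  }
  keep <- select_rows(phantom, groups, fibers)
  pts <- cbind(phantom$x[keep], phantom$y[keep], phantom$z[keep])
  if (is.null(pivot)) pivot <- colMeans(pts)
  pivot <- as.numeric(pivot)
  scaled <- sweep(sweep(pts, 2, pivot) * factor, 2, pivot, `+`)
  phantom$x[keep] <- scaled[, 1]
  phantom$y[keep] <- scaled[, 2]
  phantom$z[keep] <- scaled[, 3]
  phantom$r[keep] <- phantom$r[keep] * factor
  phantom
}

#' Duplicate fibers or groups
#'
#' Returns the phantom with a deep copy of the selection appended; the
#' original rows are untouched. Copied fibers get new ids with `suffix`
#' appended and are placed under `new_group` (default: the original group
#' path with `suffix` appended).
#'
#' @inheritParams translate_fibers
#' @param suffix Text appended to copied fiber ids (and group paths when
#'   `new_group` is `NULL`).
#' @param new_group Optional group path for all copies.
#' @return Phantom with copies appended.
#' @export
duplicate_fibers <- function(phantom, groups = NULL, fibers = NULL,
                             suffix = "_copy", new_group = NULL) {
  phantom <- as_fiber_phantom(phantom)
  keep <- select_rows(phantom, groups, fibers)
  if (!any(keep)) stop_validation("selection matches no fibers")
  copy <- phantom[keep, ]
  copy$fiber <- paste0(copy$fiber, suffix)
  copy$group <- if (is.null(new_group)) {
    ifelse(copy$group == "", "", paste0(copy$group, suffix))
  } else {
    new_group
  }
  as_fiber_phantom(bind_rows(phantom, copy))
}
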