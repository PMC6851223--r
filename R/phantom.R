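#' Fiber phantoms as tidy tables
#'
#' A fiber phantom is a tibble with one row per fiber data point and columns
#' `group` (slash-separated group path, `""` for the root), `fiber` (fiber
#' identifier, unique within the phantom), `point` (1-based index along the
#' fiber), and `x`, `y`, `z`, `r` (coordinates and radius, micrometres).
#' Every user-facing function in the package takes such a table first and
#' returns one, so operations chain with the pipe.
#'
#' Invariants enforced by [as_fiber_phantom()]: finite coordinates, radii
#' >= 0, at least two points per fiber, and no two identical consecutive
#' points (zero-length segments carry no direction).
#'
#' @param x A data frame with columns `fiber`, `x`, `y`, `z`, `r` (and
#'   optionally `group`, `point`).
#' @return A tibble of class `fiber_phantom`.
#' @examples
#' helix <- parametric_fiber("sin(t)", "cos(t)", "t", "1", 0, 10, 100)
#' n_fibers(helix)
#' @export
as_fiber_phantom <- function(x) {
  if (!is.data.frame(x)) {
    stop_validation("a fiber phantom must be a data frame of fiber points")
  }
  x <- as_tibble(x)
  if (!"group" %in% names(x)) x$group <- ""
  needed <- c("fiber", "x", "y", "z", "r")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols)) {
    stop_validation(paste0(
      "fiber phantom is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  x$fiber <- as.character(x$fiber)
  x$group <- as.character(x$group)
  if (!"point" %in% names(x)) {
    x <- x %>%
      group_by(.data$group, .data$fiber) %>%
      mutate(point = seq_len(n())) %>%
      ungroup()
  }
  x <- x %>%
    select(all_of(c("group", "fiber", "point", "x", "y", "z", "r"))) %>%
    arrange(.data$group, .data$fiber, .data$point)
  validate_fiber_phantom(x)
  class(x) <- c("fiber_phantom", class(tibble()))
  x
}

validate_fiber_phantom <- function(x) {
  coords <- c(x$x, x$y, x$z)
  if (any(!is.finite(coords))) {
    stop_validation("fiber coordinates must be finite")
  }
  if (any(!is.finite(x$r)) || any(x$r < 0)) {
    stop_validation("fiber radii must be finite and >= 0")
  }
  # a fiber id must not recur across groups
  per_fiber <- x %>%
    group_by(.data$fiber) %>%
    summarise(n = n(), ngrp = n_distinct(.data$group), .groups = "drop")
  if (any(per_fiber$ngrp > 1)) {
    bad <- per_fiber$fiber[per_fiber$ngrp > 1][1]
    stop_validation(paste0("fiber '", bad, "' appears in more than one group"))
  }
  if (any(per_fiber$n < 2)) {
    bad <- per_fiber$fiber[per_fiber$n < 2][1]
    stop_validation(paste0("fiber '", bad, "' has fewer than 2 points"))
  }
  seg <- x %>%
    group_by(.data$fiber) %>%
    mutate(
      zero = .data$x == lag(.data$x) & .data$y == lag(.data$y) &
        .data$z == lag(.data$z)
    ) %>%
    ungroup()
  if (any(seg$zero, na.rm = TRUE)) {
    bad <- seg$fiber[which(seg$zero)[1]]
    stop_validation(paste0(
      "fiber '", bad, "' has identical consecutive points (zero-length segment)"
    ))
  }
  invisible(x)
}

#' Build a single-fiber phantom from coordinate vectors
#'
#' @param x,y,z,r Numeric vectors of equal length (micrometres).
#' @param fiber Fiber identifier.
#' @param group Group path the fiber belongs to (`""` = root).
#' @return A `fiber_phantom` tibble with one fiber.
#' @export
fiber_points <- function(x, y, z, r, fiber = "fiber_1", group = "") {
  n <- length(x)
  if (length(y) != n || length(z) != n || length(r) != n) {
    stop_validation("x, y, z, r must have equal length")
  }
  as_fiber_phantom(tibble(
    group = group, fiber = fiber, point = seq_len(n),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z), r = as.numeric(r)
  ))
}

#' Count fibers in a phantom
#' @param phantom A `fiber_phantom` tibble.
#' @return Integer number of distinct fibers.
#' @export
n_fibers <- function(phantom) {
  length(unique(phantom$fiber))
}

#' List the group paths present in a phantom
#' @inheritParams n_fibers
#' @return Character vector of group paths (including implied ancestors).
#' @export
phantom_groups <- function(phantom) {
  paths <- unique(phantom$group)
  anc <- unlist(lapply(paths, function(p) {
    if (p == "") return("")
    parts <- strsplit(p, "/", fixed = TRUE)[[1]]
    vapply(seq_along(parts), function(k) paste(parts[1:k], collapse = "/"), "")
  }))
  sort(unique(c("", anc)))
}

#' Combine phantoms into one
#'
#' Fiber ids must remain unique; clashing ids get a numeric suffix.
#'
#' @param ... `fiber_phantom` tibbles.
#' @return A combined `fiber_phantom`.
#' @export
bind_phantoms <- function(...) {
  parts <- list(...)
  parts <- parts[!vapply(parts, is.null, logical(1))]
  out <- bind_rows(parts)
  if (anyDuplicated(unique(out[, c("group", "fiber")])$fiber)) {
    out <- out %>%
      group_by(.data$group, .data$fiber) %>%
      mutate(.gid = dplyr::cur_group_id()) %>%
      ungroup() %>%
      mutate(fiber = paste0(.data$fiber, "_", .data$.gid)) %>%
      select(-".gid")
  }
  as_fiber_phantom(out)
}

#' @export
print.fiber_phantom <- function(x, ...) {
  cat(sprintf(
    "# fiber phantom: %d fiber(s), %d point(s), %d group(s)\n",
    n_fibers(x), nrow(x), length(setdiff(unique(x$group), ""))
  ))
  NextMethod()
}

# internal: centroid of a set of phantom rows
phantom_centroid <- function(phantom) {
  c(mean(phantom$x), mean(phantom$y), mean(phantom$z))
}

# internal: select rows belonging to given groups (prefix match on path) and/or
# fiber ids; NULL selects everything
select_rows <- function(phantom, groups = NULL, fibers = NULL) {
  keep <- rep(TRUE, nrow(phantom))
  if (!is.null(groups)) {
    keep <- keep & Reduce(`|`, lapply(groups, function(g) {
      phantom$group == g | startsWith(phantom$group, paste0(g, "/"))
    }))
  }
  if (!is.null(fibers)) {
    keep <- if (is.null(groups)) phantom$fiber %in% fibers else
      keep | phantom$fiber %in% fibers
  }
  keep
}
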