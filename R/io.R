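# Serialization. Both on-disk dialects store coordinates and radii in single
# precision (float32); reading back reproduces every value after float32
# quantization, and text -> HDF5 -> text conversion is byte-stable.

#' Quantize numeric values to single precision
#'
#' Round-trips values through IEEE-754 binary32, the storage precision of
#' the fiber-model file formats.
#'
#' @param x Numeric vector.
#' @return Numeric vector whose values are exactly representable in float32.
#' @export
as_float32 <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4L), "numeric",
          n = length(x), size = 4L)
}

quantize_phantom <- function(phantom) {
  phantom$x <- as_float32(phantom$x)
  phantom$y <- as_float32(phantom$y)
  phantom$z <- as_float32(phantom$z)
  phantom$r <- as_float32(phantom$r)
  phantom
}

# fibers in deterministic file order: by group path, then fiber id
phantom_file_order <- function(phantom) {
  phantom %>% arrange(.data$group, .data$fiber, .data$point)
}

#' Write a phantom to the plain-text format
#'
#' One line per point (`x y z r`, space-separated, 9 significant digits --
#' lossless for float32), one blank line between fibers, and comment lines
#' `# group: <path>` / `# fiber: <id>` introducing groups and fibers.
#'
#' @param phantom A `fiber_phantom` (must contain at least one fiber).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fiber_text <- function(phantom, path) {
  phantom <- as_fiber_phantom(phantom)
  if (nrow(phantom) == 0) stop_validation("cannot write an empty phantom")
  phantom <- quantize_phantom(phantom_file_order(phantom))
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop_io(paste0("cannot open '", path, "' for writing: ", conditionMessage(e)))
  })
  on.exit(close(con))
  writeLines(c("# fibrecup fiber model text v1", "# units: um"), con)
  last_group <- NA_character_
  for (fid in unique(phantom$fiber)) {
    fb <- phantom[phantom$fiber == fid, ]
    if (!identical(fb$group[1], last_group)) {
      writeLines(paste0("# group: ", ifelse(fb$group[1] == "", "/", fb$group[1])), con)
      last_group <- fb$group[1]
    }
    writeLines(paste0("# fiber: ", fid), con)
    writeLines(sprintf("%.9g %.9g %.9g %.9g", fb$x, fb$y, fb$z, fb$r), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read a phantom from the plain-text format
#'
#' @param path Input file path.
#' @return A `fiber_phantom`.
#' @export
read_fiber_text <- function(path) {
  if (!file.exists(path)) stop_io(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  group <- ""
  fiber_id <- NULL
  auto_id <- 0L
  cur <- list()
  fibers <- list()
  flush_fiber <- function(at_line) {
    if (!length(cur)) return(invisible())
    if (length(cur) < 2) {
      stop_io(paste0(
        "fiber ending at line ", at_line, " has fewer than 2 points"
      ))
    }
    m <- do.call(rbind, cur)
    if (is.null(fiber_id)) {
      auto_id <<- auto_id + 1L
      fiber_id <<- sprintf("fiber_%03d", auto_id)
    }
    fibers[[length(fibers) + 1]] <<- tibble(
      group = group, fiber = fiber_id, point = seq_len(nrow(m)),
      x = m[, 1], y = m[, 2], z = m[, 3], r = m[, 4]
    )
    cur <<- list()
    fiber_id <<- NULL
  }
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (line == "") { flush_fiber(ln); next }
    if (startsWith(line, "# group:")) {
      flush_fiber(ln)
      g <- trimws(sub("^# group:", "", line))
      group <- if (g == "/") "" else g
      next
    }
    if (startsWith(line, "# fiber:")) {
      flush_fiber(ln)
      fiber_id <- trimws(sub("^# fiber:", "", line))
      next
    }
    if (startsWith(line, "#")) next
    vals <- suppressWarnings(as.numeric(strsplit(line, "[[:space:]]+")[[1]]))
    if (length(vals) != 4 || any(is.na(vals))) {
      stop_io(paste0("malformed point line ", ln, ": '", lines[ln], "'"))
    }
    cur[[length(cur) + 1]] <- vals
  }
  flush_fiber(length(lines))
  if (!length(fibers)) stop_io(paste0("no fibers found in ", path))
  as_fiber_phantom(bind_rows(fibers))
}

.h5_format_version <- "1"

#' Write a phantom to the HDF5 dialect
#'
#' Hierarchical layout: one HDF5 group per fiber group, one `N x 4`
#' single-precision dataset per fiber named `fiber_<index>` (columns
#' x, y, z, r) carrying the fiber id in a `label` attribute. File-level
#' attributes record the format version and units (`um`).
#'
#' @inheritParams write_fiber_text
#' @return `path`, invisibly.
#' @export
write_fiber_h5 <- function(phantom, path) {
  phantom <- as_fiber_phantom(phantom)
  if (nrow(phantom) == 0) stop_validation("cannot write an empty phantom")
  phantom <- phantom_file_order(phantom)
  if (file.exists(path)) unlink(path)
  ok <- tryCatch(rhdf5::h5createFile(path), error = function(e) FALSE)
  if (!isTRUE(ok)) stop_io(paste0("cannot create HDF5 file: ", path))
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(.h5_format_version, fid, "format_version")
  rhdf5::h5writeAttribute("um", fid, "units")
  rhdf5::H5Fclose(fid)
  for (g in setdiff(phantom_groups(phantom), "")) {
    rhdf5::h5createGroup(path, g)
  }
  fids <- unique(phantom$fiber)
  for (k in seq_along(fids)) {
    fb <- phantom[phantom$fiber == fids[k], ]
    dsname <- if (fb$group[1] == "") {
      sprintf("fiber_%05d", k - 1L)
    } else {
      sprintf("%s/fiber_%05d", fb$group[1], k - 1L)
    }
    m <- cbind(fb$x, fb$y, fb$z, fb$r)
    rhdf5::h5createDataset(path, dsname, dims = dim(m),
                           H5type = "H5T_IEEE_F32LE")
    rhdf5::h5write(m, path, dsname)
    fh <- rhdf5::H5Fopen(path)
    dh <- rhdf5::H5Dopen(fh, dsname)
    rhdf5::h5writeAttribute(fids[k], dh, "label")
    rhdf5::H5Dclose(dh)
    rhdf5::H5Fclose(fh)
  }
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read a phantom from the HDF5 dialect
#'
#' @param path Input file path.
#' @return A `fiber_phantom`.
#' @export
read_fiber_h5 <- function(path) {
  if (!file.exists(path)) stop_io(paste0("file not found: ", path))
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  attrs <- tryCatch(rhdf5::h5readAttributes(path, "/"),
                    error = function(e) {
                      stop_io(paste0("cannot read HDF5 file ", path, ": ",
                                     conditionMessage(e)))
                    })
  ver <- attrs[["format_version"]]
  if (is.null(ver) || !identical(as.character(ver), .h5_format_version)) {
    stop_io(paste0(
      "unknown fiber-model format version in ", path, ": ",
      if (is.null(ver)) "<missing>" else as.character(ver)
    ))
  }
  ls <- rhdf5::h5ls(path)
  ds <- ls[ls$otype == "H5I_DATASET" & grepl("^fiber_[0-9]+$", ls$name), ]
  if (!nrow(ds)) stop_io(paste0("no fiber datasets found in ", path))
  ds$path <- ifelse(ds$group == "/", paste0("/", ds$name),
                    paste0(ds$group, "/", ds$name))
  ds <- ds[order(ds$path), ]
  fibers <- lapply(seq_len(nrow(ds)), function(k) {
    m <- rhdf5::h5read(path, ds$path[k])
    lab <- tryCatch({
      a <- rhdf5::h5readAttributes(path, ds$path[k])[["label"]]
      if (is.null(a)) ds$name[k] else as.character(a)
    }, error = function(e) ds$name[k])
    grp <- sub("^/", "", ds$group[k])
    tibble(
      group = grp, fiber = lab, point = seq_len(nrow(m)),
      x = as.numeric(m[, 1]), y = as.numeric(m[, 2]),
      z = as.numeric(m[, 3]), r = as.numeric(m[, 4])
    )
  })
  as_fiber_phantom(bind_rows(fibers))
}
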