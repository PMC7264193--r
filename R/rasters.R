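# Lightweight time-indexed raster container.
#
# Layers are plain matrices on a regular lat/lon grid shared by all time
# steps: element [i, j] covers the half-open cell
# [west + (j-1)*cs, west + j*cs) x [south + (i-1)*cs, south + i*cs),
# so row 1 is the southernmost row and every interior point maps to
# exactly one pixel.

#' Construct a time-indexed raster stack
#'
#' @param variable variable name (e.g. `"MAT"`).
#' @param units units string (e.g. `"degC"`, `"mm"`, `"persons/km2"`).
#' @param origin numeric `c(west, south)` corner in degrees.
#' @param cellsize cell edge in degrees (square cells).
#' @param times integer vector of time labels (years or decade start years),
#'   one per layer.
#' @param layers list of numeric matrices (rows = latitude, row 1 = south),
#'   all with identical dimensions.
#' @return an object of class `raster_stack`.
#' @export
raster_stack <- function(variable, units, origin, cellsize, times, layers) {
  stopifnot(length(origin) == 2L, cellsize > 0,
            length(times) == length(layers), length(layers) >= 1L)
  dims <- vapply(layers, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all time steps must share one grid geometry")
  structure(
    list(variable = variable, units = units,
         origin = as.numeric(origin), cellsize = as.numeric(cellsize),
         ny = dims[1, 1], nx = dims[2, 1],
         times = as.integer(times), layers = layers),
    class = "raster_stack")
}

#' @export
print.raster_stack <- function(x, ...) {
  cat(sprintf("<raster_stack> %s [%s], %d x %d cells @ %g deg, %d time step(s): %s\n",
              x$variable, x$units, x$ny, x$nx, x$cellsize,
              length(x$times), paste(range(x$times), collapse = "-")))
  invisible(x)
}

# Cell (row, col) index for points; NA where the point falls outside the
# raster extent. Half-open cells [west, east) x [south, north).
raster_cell_index <- function(stack, lon, lat) {
  j <- floor((lon - stack$origin[1]) / stack$cellsize) + 1
  i <- floor((lat - stack$origin[2]) / stack$cellsize) + 1
  bad <- !is.finite(i) | !is.finite(j) | i < 1 | i > stack$ny | j < 1 | j > stack$nx
  i[bad] <- NA_integer_; j[bad] <- NA_integer_
  cbind(row = as.integer(i), col = as.integer(j))
}

# Index of the layer used for a requested time: exact match if present,
# otherwise the nearest available time at or before it (falling back to the
# first layer for times before coverage starts when allowed).
raster_time_index <- function(stack, time, nearest = FALSE) {
  idx <- match(time, stack$times)
  if (anyNA(idx)) {
    if (!nearest) {
      stop(sprintf("time(s) %s not covered by %s stack",
                   paste(unique(time[is.na(idx)]), collapse = ", "), stack$variable))
    }
    for (k in which(is.na(idx))) {
      before <- which(stack$times <= time[k])
      idx[k] <- if (length(before)) max(before) else 1L
    }
  }
  idx
}

#' Extract raster values at point locations
#'
#' Returns the value of the grid cell containing each point, from the layer
#' matching each point's time label. Points outside the raster extent yield
#' `NA`.
#'
#' @param stack a [raster_stack()].
#' @param lon,lat point coordinates (degrees).
#' @param time time label per point (recycled if length 1).
#' @param nearest_time if `TRUE`, a time absent from the stack uses the
#'   nearest available layer at or before it instead of erroring.
#' @return numeric vector of extracted values.
#' @export
raster_extract <- function(stack, lon, lat, time, nearest_time = FALSE) {
  n <- length(lon)
  time <- rep_len(time, n)
  ij <- raster_cell_index(stack, lon, lat)
  ti <- raster_time_index(stack, time, nearest = nearest_time)
  out <- rep(NA_real_, n)
  ok <- !is.na(ij[, 1]) & !is.na(ti)
  if (any(ok)) {
    for (t in unique(ti[ok])) {
      sel <- ok & ti == t
      out[sel] <- stack$layers[[t]][ij[sel, , drop = FALSE]]
    }
  }
  out
}

#' Write / read a raster stack as plain text
#'
#' Serialized as a JSON header plus one long-format CSV of cell values
#' (time, row, col, value), a text-only interchange format.
#'
#' @param stack a [raster_stack()].
#' @param basepath path prefix; writes `<basepath>.json` and `<basepath>.csv`.
#' @return `write_raster_stack()`: invisibly, the two file paths;
#'   `read_raster_stack()`: the reconstructed stack.
#' @export
write_raster_stack <- function(stack, basepath) {
  meta <- stack[c("variable", "units", "origin", "cellsize", "ny", "nx", "times")]
  jsonlite::write_json(meta, paste0(basepath, ".json"),
                       auto_unbox = TRUE, digits = NA)
  vals <- do.call(rbind, lapply(seq_along(stack$times), function(k) {
    m <- stack$layers[[k]]
    data.frame(time = stack$times[k],
               row = rep(seq_len(stack$ny), ncol(m)),
               col = rep(seq_len(stack$nx), each = nrow(m)),
               value = as.vector(m))
  }))
  write.csv(vals, paste0(basepath, ".csv"), row.names = FALSE)
  invisible(paste0(basepath, c(".json", ".csv")))
}

#' @rdname write_raster_stack
#' @export
read_raster_stack <- function(basepath) {
  meta <- jsonlite::read_json(paste0(basepath, ".json"), simplifyVector = TRUE)
  vals <- read.csv(paste0(basepath, ".csv"))
  layers <- lapply(meta$times, function(t) {
    sub <- vals[vals$time == t, ]
    m <- matrix(NA_real_, meta$ny, meta$nx)
    m[cbind(sub$row, sub$col)] <- sub$value
    m
  })
  raster_stack(meta$variable, meta$units, meta$origin, meta$cellsize,
               meta$times, layers)
}
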