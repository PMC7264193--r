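# Pair each record with climate of its collection year and log human
# population density of its decade, and standardize continuous predictors.

#' Pair records with MAT and MAP of their collection year
#'
#' Each record receives the value of the grid cell containing its point,
#' from the layer matching its collection year. Points outside the raster
#' extent are excluded and reported.
#'
#' @param records a record data.frame with coordinates and `year`.
#' @param mat_stack,map_stack year-indexed [raster_stack()]s.
#' @return `list(records, removed, n_removed)`; retained records gain
#'   `MAT` (degC) and `MAP` (mm) columns.
#' @export
extract_climate <- function(records, mat_stack, map_stack) {
  records$MAT <- raster_extract(mat_stack, records$decimalLongitude,
                                records$decimalLatitude, records$year)
  records$MAP <- raster_extract(map_stack, records$decimalLongitude,
                                records$decimalLatitude, records$year)
  bad <- is.na(records$MAT) | is.na(records$MAP)
  list(records = records[!bad, , drop = FALSE],
       removed = records[bad, , drop = FALSE],
       n_removed = sum(bad))
}

#' Aggregate a density raster by block means
#'
#' Mean over `factor` x `factor` pixel windows; partial blocks at the east
#' and north edges are averaged over the pixels available. When all blocks
#' are complete the raster-wide mean is conserved.
#'
#' @param stack a [raster_stack()].
#' @param factor integer aggregation factor (`>= 1`).
#' @return a coarser [raster_stack()].
#' @export
aggregate_density <- function(stack, factor) {
  stopifnot(factor == round(factor), factor >= 1)
  if (factor == 1) return(stack)
  if (factor > stack$ny || factor > stack$nx)
    stop("aggregation factor exceeds raster dimension")
  gi <- ceiling(seq_len(stack$ny) / factor)
  gj <- ceiling(seq_len(stack$nx) / factor)
  agg_one <- function(m) {
    # block means via two grouped means (rows then columns)
    rowagg <- rowsum(m, gi) / as.vector(table(gi))
    colagg <- t(rowsum(t(rowagg), gj) / as.vector(table(gj)))
    dimnames(colagg) <- NULL
    colagg
  }
  raster_stack(stack$variable, stack$units, stack$origin,
               stack$cellsize * factor, stack$times,
               lapply(stack$layers, agg_one))
}

#' Pair records with log human population density of their decade
#'
#' The density layer of the record's collection decade (nearest available
#' decade at or before it when the exact decade is missing, so records
#' after the last layer use that last layer) is read at the requested
#' aggregation scale, and the natural log of (density + floor) is returned.
#'
#' @param records a record data.frame with coordinates and `year`.
#' @param density_stack a decade-indexed [raster_stack()] at base (1 km
#'   nominal) resolution.
#' @param scale_km aggregation scale: 1, 4 or 10 (pixel aggregation factor
#'   relative to the base grid).
#' @param floor additive floor before logging (default 0.01 persons/km^2).
#' @return `list(records, removed, n_removed)`; retained records gain a
#'   `log_density` column (and keep the scale in the
#'   `"scale_km"` attribute of that column).
#' @export
extract_density <- function(records, density_stack, scale_km = 1,
                            floor = 0.01) {
  stopifnot(scale_km %in% c(1, 4, 10))
  stk <- aggregate_density(density_stack, as.integer(scale_km))
  dec <- 1790 + 10 * floor((records$year - 1790) / 10)
  dec <- pmin(pmax(dec, min(stk$times)), max(stk$times))
  d <- raster_extract(stk, records$decimalLongitude, records$decimalLatitude,
                      dec, nearest_time = TRUE)
  records$log_density <- log(d + floor)
  attr(records$log_density, "scale_km") <- scale_km
  bad <- is.na(records$log_density)
  list(records = records[!bad, , drop = FALSE],
       removed = records[bad, , drop = FALSE],
       n_removed = sum(bad))
}

#' Mean-centre and standardize continuous predictors
#'
#' Each variable is transformed to `(x - mean) / SD` using the sample
#' (n-1) standard deviation; the means and SDs are stored so fitted
#' coefficients can be expressed per natural unit (degC, mm,
#' log persons/km^2) via [unstandardize()].
#'
#' @param dataset a data.frame.
#' @param variables character vector of column names; each must have
#'   positive SD on the dataset.
#' @param suffix suffix for the standardized columns (default `"_z"`).
#' @return the dataset with added standardized columns and a
#'   `"standardization"` attribute (data.frame of variable, mean, sd,
#'   convention).
#' @export
standardize <- function(dataset, variables, suffix = "_z") {
  meta <- data.frame(variable = variables, mean = NA_real_, sd = NA_real_,
                     convention = "sample (n-1) SD")
  for (k in seq_along(variables)) {
    v <- variables[k]
    x <- dataset[[v]]
    mu <- mean(x, na.rm = TRUE); sdev <- sd(x, na.rm = TRUE)
    if (!is.finite(sdev) || sdev == 0)
      stop(sprintf("variable '%s' has zero SD and cannot be standardized", v))
    meta$mean[k] <- mu; meta$sd[k] <- sdev
    dataset[[paste0(v, suffix)]] <- (x - mu) / sdev
  }
  attr(dataset, "standardization") <-
    rbind(attr(dataset, "standardization"), meta)
  dataset
}

#' Back-transform a standardized column to natural units
#'
#' @param dataset a data.frame carrying a `"standardization"` attribute.
#' @param variable the original variable name.
#' @return numeric vector `x * sd + mean` recovered from the standardized
#'   column.
#' @export
unstandardize <- function(dataset, variable) {
  meta <- attr(dataset, "standardization")
  if (is.null(meta) || !variable %in% meta$variable)
    stop("no standardization metadata for ", variable)
  row <- meta[meta$variable == variable, ][1, ]
  dataset[[paste0(variable, "_z")]] * row$sd + row$mean
}

#' Attach all model covariates to a harmonized dataset
#'
#' Convenience wrapper: climate extraction, density extraction at the
#' requested scale, decade-index column, and standardization of the
#' continuous predictors (`MAT`, `MAP`, `log_density`, `decade_bin`).
#'
#' @param records a harmonized record data.frame (with `decade_bin`).
#' @param climate `list(mat =, map =)` of stacks.
#' @param density_stack decade-indexed density stack.
#' @param scale_km density aggregation scale (default 1).
#' @return the dataset with `MAT`, `MAP`, `log_density` and standardized
#'   `*_z` columns (including `decade_bin_z`), plus metadata.
#' @export
attach_covariates <- function(records, climate, density_stack, scale_km = 1) {
  cl <- extract_climate(records, climate$mat, climate$map)
  de <- extract_density(cl$records, density_stack, scale_km)
  standardize(de$records, c("MAT", "MAP", "log_density", "decade_bin"))
}
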