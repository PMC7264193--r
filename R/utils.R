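# Internal helpers shared across stages.

#' Derive a reproducible child seed for a named pipeline stage
#'
#' One top-level seed fans out to per-stage seeds so stages can be rerun
#' independently while the whole pipeline stays deterministic. The child
#' seed is a 31-bit hash of the parent seed and the stage name.
#'
#' @param seed integer parent seed.
#' @param stage character stage label, e.g. `"simulate"`.
#' @return a single integer in `[0, 2^31 - 1)`.
#' @export
child_seed <- function(seed, stage) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(stage))
  h <- as.double(seed) %% 2147483647
  for (ch in utf8ToInt(stage)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

#' Append a structured entry to a JSON-lines log
#'
#' Pipeline stages log per-step record counts as one JSON object per line,
#' mirroring the removed-records narrative of the harmonization audit.
#'
#' @param path file path, or `NULL` to skip logging.
#' @param ... named fields to record.
#' @return invisibly, the JSON line written (or `NULL`).
#' @export
log_jsonl <- function(path, ...) {
  if (is.null(path)) return(invisible(NULL))
  entry <- list(...)
  line <- jsonlite::toJSON(entry, auto_unbox = TRUE, digits = NA)
  cat(line, "\n", sep = "", file = path, append = TRUE)
  invisible(line)
}

# Validate a lat/lon bounding box given as list(lon = c(w, e), lat = c(s, n)).
check_bounds <- function(region_bounds) {
  if (!is.list(region_bounds) || !all(c("lon", "lat") %in% names(region_bounds)))
    stop("region_bounds must be list(lon = c(west, east), lat = c(south, north))")
  lon <- region_bounds$lon; lat <- region_bounds$lat
  if (length(lon) != 2L || length(lat) != 2L || lon[1] >= lon[2] || lat[1] >= lat[2])
    stop("inverted or degenerate region bounds")
  invisible(region_bounds)
}
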