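# Ecoregion assignment and the stochastic 200 x 200 km grid-zonation
# optimizer that defines spatiotemporal replicates.

# ---- equal-area projection ---------------------------------------------

# Albers equal-area conic for the conterminous US (standard parallels
# 29.5/45.5 N, origin 23 N 96 W, spherical earth), so "200 x 200 km" cells
# are metrically meaningful. Returns coordinates in metres.
.albers <- local({
  R <- 6370997
  d2r <- pi / 180
  phi1 <- 29.5 * d2r; phi2 <- 45.5 * d2r
  phi0 <- 23 * d2r; lam0 <- -96 * d2r
  n <- (sin(phi1) + sin(phi2)) / 2
  C <- cos(phi1)^2 + 2 * n * sin(phi1)
  rho0 <- R * sqrt(C - 2 * n * sin(phi0)) / n
  list(R = R, d2r = d2r, n = n, C = C, rho0 = rho0, lam0 = lam0)
})

#' Project lon/lat to conterminous-US Albers equal-area coordinates
#'
#' @param lon,lat coordinates in degrees (WGS84).
#' @return data.frame with columns `x`, `y` in metres.
#' @export
albers_project <- function(lon, lat) {
  a <- .albers
  phi <- lat * a$d2r
  theta <- a$n * (lon * a$d2r - a$lam0)
  rho <- a$R * sqrt(a$C - 2 * a$n * sin(phi)) / a$n
  data.frame(x = rho * sin(theta), y = a$rho0 - rho * cos(theta))
}

#' Inverse of [albers_project()]
#'
#' @param x,y Albers coordinates in metres.
#' @return data.frame with columns `lon`, `lat` in degrees.
#' @export
albers_inverse <- function(x, y) {
  a <- .albers
  rho <- sqrt(x^2 + (a$rho0 - y)^2)
  theta <- atan2(x, a$rho0 - y)
  phi <- asin((a$C - (rho * a$n / a$R)^2) / (2 * a$n))
  lam <- a$lam0 + theta / a$n
  data.frame(lon = lam / a$d2r, lat = phi / a$d2r)
}

# ---- ecoregions ---------------------------------------------------------

#' Construct an ecoregion map from polygons and split rules
#'
#' @param polygons named list of closed rings (two-column lon/lat matrices,
#'   first row repeated last).
#' @param split data.frame with columns `region`, `split_lat`: regions whose
#'   membership labels are re-designated `"Northern <region>"` /
#'   `"Southern <region>"` by latitude at or above / below the split.
#' @return an object of class `ecoregion_map`.
#' @export
ecoregion_map <- function(polygons, split = NULL) {
  stopifnot(is.list(polygons), length(names(polygons)) == length(polygons))
  if (is.null(split)) split <- data.frame(region = character(), split_lat = numeric())
  structure(list(polygons = polygons, split = split), class = "ecoregion_map")
}

#' Assign ecoregion membership to records
#'
#' Point-in-polygon labelling; polygons are tested in lexicographic name
#' order so a point on a shared edge deterministically takes the
#' lexicographically first region. Regions with a split rule are suffixed
#' Northern/Southern by latitude at or above / below the split latitude
#' (42 degrees N by default in [make_ecoregion_map()]).
#'
#' @param records a record data.frame with `decimalLongitude`/`decimalLatitude`.
#' @param map an [ecoregion_map()].
#' @return `list(records, removed, n_removed)`: records gain an `ecoregion`
#'   column; points inside no polygon are excluded and returned in `removed`.
#' @export
assign_ecoregion <- function(records, map) {
  stopifnot(inherits(map, "ecoregion_map"))
  n <- nrow(records)
  lab <- rep(NA_character_, n)
  pts <- cbind(records$decimalLongitude, records$decimalLatitude)
  # byte-order (C collation) so the tie-break is locale-independent
  ord <- sort(names(map$polygons), method = "radix")
  # points on any polygon edge are labelled by the edge-inclusive test in
  # lexicographic order (the declared tie-break); interior points go
  # through the fast interior test
  boundary <- rep(FALSE, n)
  for (nm in ord) boundary <- boundary | .on_edge(map$polygons[[nm]],
                                                  pts[, 1], pts[, 2])
  for (nm in ord) {
    todo <- is.na(lab) & !boundary
    if (any(todo)) {
      ring <- map$polygons[[nm]]
      inside <- mgcv::in.out(rbind(ring, c(NA, NA)), pts[todo, , drop = FALSE])
      lab[todo][inside] <- nm
    }
    todo_b <- is.na(lab) & boundary
    if (any(todo_b)) {
      hit <- .on_or_in(map$polygons[[nm]], pts[todo_b, 1], pts[todo_b, 2])
      lab[todo_b][hit] <- nm
    }
  }
  for (k in seq_len(nrow(map$split))) {
    reg <- map$split$region[k]; sl <- map$split$split_lat[k]
    hit <- !is.na(lab) & lab == reg
    lab[hit] <- ifelse(records$decimalLatitude[hit] >= sl,
                       paste("Northern", reg), paste("Southern", reg))
  }
  records$ecoregion <- lab
  keep <- !is.na(lab)
  list(records = records[keep, , drop = FALSE],
       removed = records[!keep, , drop = FALSE],
       n_removed = sum(!keep))
}

# Vectorized on-edge test and edge-inclusive even-odd containment.
# Boundary points are measure-zero but must be labelled deterministically
# (lexicographically first region), which interior-only tests cannot
# guarantee; these helpers route them.
.on_edge <- function(ring, x, y, tol = 1e-9) {
  hit <- rep(FALSE, length(x))
  for (k in seq_len(nrow(ring) - 1)) {
    x1 <- ring[k, 1]; y1 <- ring[k, 2]
    x2 <- ring[k + 1, 1]; y2 <- ring[k + 1, 2]
    hit <- hit |
      (abs((x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)) < tol &
         x >= min(x1, x2) - tol & x <= max(x1, x2) + tol &
         y >= min(y1, y2) - tol & y <= max(y1, y2) + tol)
  }
  hit
}

.on_or_in <- function(ring, x, y) {
  inside <- rep(FALSE, length(x))
  for (k in seq_len(nrow(ring) - 1)) {
    x1 <- ring[k, 1]; y1 <- ring[k, 2]
    x2 <- ring[k + 1, 1]; y2 <- ring[k + 1, 2]
    crosses <- (y1 > y) != (y2 > y)
    denom <- y2 - y1
    denom[denom == 0] <- 1  # never used: crosses is FALSE there
    xint <- x1 + (y - y1) * (x2 - x1) / denom
    inside <- xor(inside, crosses & x < xint)
  }
  inside | .on_edge(ring, x, y)
}

# ---- zonation criteria --------------------------------------------------

#' Does a cell's record set qualify as a spatiotemporal replicate?
#'
#' A cell qualifies when it holds at least `min_total` records and at least
#' `min_decades` decade bins each hold at least `min_per_decade` records.
#'
#' @param decade_bins integer vector: the decade bin of each record in the cell.
#' @param min_total minimum total records (default 75).
#' @param min_decades minimum number of well-sampled decade bins (default 4).
#' @param min_per_decade minimum records for a decade bin to count (default 10).
#' @return logical scalar.
#' @export
cell_satisfies <- function(decade_bins, min_total = 75, min_decades = 4,
                           min_per_decade = 10) {
  if (length(decade_bins) < min_total) return(FALSE)
  tab <- tabulate(decade_bins)
  sum(tab >= min_per_decade) >= min_decades
}

# ---- grid-zonation optimizer -------------------------------------------

#' Stochastically optimize a set of non-overlapping grid zones
#'
#' Samples square cells (lower-left corners uniform over the projected
#' bounding box of the records) and retains those meeting the
#' record-density criteria (see [cell_satisfies()]). A qualifying candidate
#' that overlaps no retained cell is added; one that overlaps retained cells
#' replaces all of them iff its record count strictly exceeds their combined
#' total (`replace_rule = "combined"`, the default, which makes the total
#' retained record count non-decreasing over iterations) or each of their
#' individual totals (`replace_rule = "per_cell"`).
#'
#' @param records a record data.frame with `decade_bin` assigned; projected
#'   coordinates are computed internally from lon/lat via [albers_project()].
#' @param cell_km cell edge in km (default 200).
#' @param criteria list with `min_total`, `min_decades`, `min_per_decade`
#'   (defaults 75/4/10).
#' @param max_iter iteration budget (default 200000).
#' @param seed integer RNG seed.
#' @param replace_rule `"combined"` or `"per_cell"`.
#' @param keep_trace if `TRUE`, record the retained total after every
#'   accepted state change (used by invariant checks).
#' @return an object of class `grid_zonation`: `cells` (data.frame of
#'   retained lower-left corners, in metres, with record totals),
#'   `membership` (record index -> cell id, `NA` when unzoned), `cell_km`,
#'   `iterations`, `seed`, and optionally `trace`.
#' @export
optimize_grid_zones <- function(records, cell_km = 200,
                                criteria = list(min_total = 75, min_decades = 4,
                                                min_per_decade = 10),
                                max_iter = 200000, seed = 1,
                                replace_rule = c("combined", "per_cell"),
                                keep_trace = FALSE) {
  replace_rule <- match.arg(replace_rule)
  stopifnot(max_iter >= 1)
  crit <- utils::modifyList(list(min_total = 75, min_decades = 4,
                                 min_per_decade = 10), criteria)
  pr <- albers_project(records$decimalLongitude, records$decimalLatitude)
  px <- pr$x; py <- pr$y
  ok <- is.finite(px) & is.finite(py)
  if (!any(ok)) stop("no record has projectable coordinates")
  dec <- records$decade_bin
  L <- cell_km * 1000

  # spatial index: bin records on a fine lattice and keep 2-d cumulative
  # counts for an O(1) upper bound on any candidate cell's record total
  b <- L / 8
  xmin <- min(px[ok]); ymin <- min(py[ok])
  bx <- pmin(floor((px - xmin) / b) + 1, .Machine$integer.max)
  by <- pmin(floor((py - ymin) / b) + 1, .Machine$integer.max)
  nbx <- max(bx[ok]); nby <- max(by[ok])
  cnt <- matrix(0L, nby, nbx)
  tb <- table(factor(by[ok], levels = seq_len(nby)),
              factor(bx[ok], levels = seq_len(nbx)))
  cnt[] <- as.integer(tb)
  cum <- matrix(apply(cnt, 2, cumsum), nby, nbx)       # cumsum down rows
  cum <- matrix(t(apply(cum, 1, cumsum)), nby, nbx)    # then across columns
  rect_ub <- function(i0, i1, j0, j1) {            # inclusive bin ranges
    i1 <- min(i1, nby); j1 <- min(j1, nbx)
    if (i0 > i1 || j0 > j1) return(0L)
    tot <- cum[i1, j1]
    if (i0 > 1) tot <- tot - cum[i0 - 1, j1]
    if (j0 > 1) tot <- tot - cum[i1, j0 - 1]
    if (i0 > 1 && j0 > 1) tot <- tot + cum[i0 - 1, j0 - 1]
    tot
  }
  # record indices grouped by bin, for exact membership of screened candidates
  binid <- (bx - 1) * nby + by
  binid[!ok] <- NA
  by_bin <- split(seq_along(px)[ok], binid[ok])

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  xs <- runif(max_iter, xmin - L, max(px[ok]))
  ys <- runif(max_iter, ymin - L, max(py[ok]))

  cells <- data.frame(x0 = numeric(), y0 = numeric(), n = integer())
  members <- list()
  trace <- if (keep_trace) data.frame(iteration = integer(), total = integer())

  members_of <- function(x0, y0) {
    j0 <- max(1, floor((x0 - xmin) / b) + 1)
    i0 <- max(1, floor((y0 - ymin) / b) + 1)
    j1 <- floor((x0 + L - xmin) / b) + 1
    i1 <- floor((y0 + L - ymin) / b) + 1
    keys <- as.character(outer(seq(max(1, i0), min(i1, nby)),
                               (seq(max(1, j0), min(j1, nbx)) - 1) * nby, `+`))
    idx <- unlist(by_bin[keys], use.names = FALSE)
    idx[px[idx] >= x0 & px[idx] < x0 + L & py[idx] >= y0 & py[idx] < y0 + L]
  }

  for (it in seq_len(max_iter)) {
    x0 <- xs[it]; y0 <- ys[it]
    # O(1) upper-bound screen before exact counting
    j0 <- floor((x0 - xmin) / b) + 1
    i0 <- floor((y0 - ymin) / b) + 1
    ub <- rect_ub(max(1, i0), i0 + 8, max(1, j0), j0 + 8)
    if (ub < crit$min_total) next
    idx <- members_of(x0, y0)
    if (!cell_satisfies(dec[idx], crit$min_total, crit$min_decades,
                        crit$min_per_decade)) next
    ncand <- length(idx)
    if (nrow(cells)) {
      ovl <- which(cells$x0 < x0 + L & cells$x0 + L > x0 &
                   cells$y0 < y0 + L & cells$y0 + L > y0)
    } else ovl <- integer()
    if (!length(ovl)) {
      cells <- rbind(cells, data.frame(x0 = x0, y0 = y0, n = ncand))
      members[[nrow(cells)]] <- idx
    } else {
      beats <- if (replace_rule == "combined") ncand > sum(cells$n[ovl])
               else all(ncand > cells$n[ovl])
      if (!beats) next
      cells <- cells[-ovl, , drop = FALSE]
      members <- members[-ovl]
      cells <- rbind(cells, data.frame(x0 = x0, y0 = y0, n = ncand))
      members[[nrow(cells)]] <- idx
    }
    if (keep_trace) trace <- rbind(trace,
      data.frame(iteration = it, total = sum(cells$n)))
  }

  membership <- rep(NA_integer_, nrow(records))
  if (nrow(cells)) {
    cells$cell_id <- seq_len(nrow(cells))
    for (k in seq_len(nrow(cells))) membership[members[[k]]] <- k
  } else {
    cells$cell_id <- integer()
  }
  structure(list(cells = cells, membership = membership, cell_km = cell_km,
                 criteria = crit, iterations = max_iter, seed = seed,
                 trace = trace),
            class = "grid_zonation")
}

#' @export
print.grid_zonation <- function(x, ...) {
  cat(sprintf("<grid_zonation> %d cell(s) of %d km, %d zoned record(s), %d iteration(s), seed %d\n",
              nrow(x$cells), x$cell_km, sum(!is.na(x$membership)),
              x$iterations, x$seed))
  invisible(x)
}

#' Summarize a grid zonation
#'
#' @param z a `grid_zonation`.
#' @param decade_bins optional integer vector (one per record used in the
#'   optimization) to tabulate per-cell per-decade counts.
#' @return list with `cells` (per-cell totals and, when decades are given,
#'   per-decade counts) and `coverage` (fraction of records zoned).
#' @export
zonation_summary <- function(z, decade_bins = NULL) {
  if (!nrow(z$cells)) {
    return(list(cells = data.frame(cell_id = integer(), n = integer()),
                coverage = 0))
  }
  cells <- z$cells[order(z$cells$cell_id), c("cell_id", "x0", "y0", "n")]
  if (!is.null(decade_bins)) {
    tab <- table(z$membership, decade_bins)
    per_dec <- as.data.frame.matrix(tab)
    names(per_dec) <- paste0("decade_", colnames(tab))
    cells <- cbind(cells, per_dec[match(as.character(cells$cell_id),
                                        rownames(tab)), , drop = FALSE])
    rownames(cells) <- NULL
  }
  list(cells = cells,
       coverage = mean(!is.na(z$membership)))
}

#' Serialize a zonation's cells as GeoJSON polygons
#'
#' Cell corners are inverse-projected from Albers metres back to lon/lat.
#'
#' @param z a `grid_zonation`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_zonation_geojson <- function(z, path) {
  L <- z$cell_km * 1000
  feats <- lapply(seq_len(nrow(z$cells)), function(k) {
    c0 <- z$cells[k, ]
    corners <- rbind(c(c0$x0, c0$y0), c(c0$x0 + L, c0$y0),
                     c(c0$x0 + L, c0$y0 + L), c(c0$x0, c0$y0 + L),
                     c(c0$x0, c0$y0))
    ll <- albers_inverse(corners[, 1], corners[, 2])
    list(type = "Feature",
         properties = list(cell_id = c0$cell_id, n = c0$n),
         geometry = list(type = "Polygon",
                         coordinates = list(Map(c, ll$lon, ll$lat))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
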