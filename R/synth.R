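# Synthetic study system: climate and human-population-density layers,
# ecoregion polygons, and multi-source trait records with fully known
# generative parameters, so every downstream stage can be validated
# against known truth without any download.

#' Default lat/lon study window (a conterminous-US-like box)
#' @return `list(lon = c(west, east), lat = c(south, north))`.
#' @export
default_region_bounds <- function() list(lon = c(-120, -85), lat = c(30, 48))

# ---- generative truth ---------------------------------------------------

#' Construct the generative-truth parameter set
#'
#' Holds every parameter of the record simulator: standardized fixed
#' effects, sex and season offsets, random-effect SDs (ecoregion, data
#' source, and the correlated per-zone intercept/decadal-slope pair),
#' residual SD, the live-capture HB-length measurement bias, and the
#' contamination rates for the quality-filter classes. Defaults are the
#' package's reference study conditions: effect sizes on the order of those
#' estimated for deer mouse body mass (climate and decade effects around
#' -0.5 / -0.2 g per SD of predictor, females ~0.65 g heavier, fall the
#' lightest season, ecoregion SD 1.23 g, source SD 0.2 g) with a strongly
#' negative zone slope-intercept correlation.
#'
#' @param intercept_mass,intercept_hb baseline adult body mass (g) and
#'   head-body length (mm) for a fall-collected male at covariate means.
#' @param beta_mat,beta_map,beta_density,beta_decade standardized effects
#'   (response units per SD of MAT, MAP, log density, decade index).
#' @param sex_offset female-minus-male size difference (g).
#' @param season_offsets named additive offsets (Fall is the reference).
#' @param sigma_ecoregion,sigma_source,sigma_zone_intercept,sigma_zone_slope
#'   random-effect SDs (all >= 0).
#' @param rho_slope_intercept correlation between zone intercepts and zone
#'   decade slopes, in `[-1, 1]`.
#' @param sigma_resid residual SD (g).
#' @param source_hb_bias additive HB-length bias (mm) for the live-capture
#'   NEON source; its magnitude is not pinned down empirically, only its
#'   negative sign, so it is configurable.
#' @param hb_signal_scale multiplier mapping the mass-scale linear predictor
#'   onto the HB-length scale (lengths respond more strongly, in mm).
#' @param hb_resid_sd total HB-length residual SD (mm).
#' @param resid_share fraction of the mass residual variance that is an
#'   individual "condition" component shared with HB length (through
#'   `hb_signal_scale`), inducing the moderate mass-length allometric
#'   correlation seen in real animals; marginal trait variances are
#'   unaffected. 0 makes the two trait residuals independent.
#' @param tail_mean,tail_sd tail-length distribution (mm).
#' @param juvenile_frac,sub9g_frac,bad_date_frac,ambiguous_sex_frac,outlier_frac
#'   contamination rates in `[0, 1]` (mutually exclusive classes; their sum
#'   must be < 1).
#' @param outlier_shift absolute size of an injected gross measurement error
#'   (g for mass, scaled x4 for total length).
#' @param resid_trunc truncation point of every trait-noise distribution, in
#'   multiples of its SD (default `Inf` = pure Gaussian). A k-SD outlier
#'   rule applied to unbounded noise flags a small fraction of clean records
#'   by construction; fixtures that need exact audit bookkeeping set this
#'   below the outlier multiplier (e.g. 2.5).
#' @param n_zones number of densely sampled 200 km lattice cells.
#' @param background_frac fraction of records scattered uniformly outside
#'   the dense cells.
#' @param zone_concentration Dirichlet concentration for uneven per-zone
#'   sampling weights.
#' @param decade_weights relative sampling weight of each of the 13 decade
#'   bins (1895-2019): sparse early decades, a mid-century census pulse and
#'   a present-day pulse.
#' @return an object of class `generative_truth`.
#' @export
generative_truth <- function(intercept_mass = 20, intercept_hb = 90,
                             beta_mat = -0.5, beta_map = -0.5,
                             beta_density = -0.3, beta_decade = -0.2,
                             sex_offset = 0.65,
                             season_offsets = c(Fall = 0, Spring = 1.8,
                                                Summer = 0.8, Winter = 0.9),
                             sigma_ecoregion = 1.23, sigma_source = 0.2,
                             sigma_zone_intercept = 0.5,
                             sigma_zone_slope = 0.3,
                             rho_slope_intercept = -0.9,
                             sigma_resid = 3.6,
                             source_hb_bias = -4,
                             hb_signal_scale = 1.8, hb_resid_sd = 6,
                             resid_share = 0.55,
                             tail_mean = 65, tail_sd = 6,
                             juvenile_frac = 0.05, sub9g_frac = 0.02,
                             bad_date_frac = 0.04, ambiguous_sex_frac = 0.03,
                             outlier_frac = 0.01, outlier_shift = 30,
                             resid_trunc = Inf,
                             n_zones = 40, background_frac = 0.05,
                             zone_concentration = 5,
                             decade_weights = c(2, 2, 3, 3, 4, 10, 8, 5,
                                                4, 4, 4, 5, 9)) {
  truth <- as.list(environment())
  sds <- c(sigma_ecoregion, sigma_source, sigma_zone_intercept,
           sigma_zone_slope, sigma_resid, hb_resid_sd, tail_sd)
  if (any(sds < 0)) stop("all SDs must be >= 0")
  if (resid_trunc <= 0) stop("resid_trunc must be positive")
  if (abs(rho_slope_intercept) > 1) stop("rho_slope_intercept must be in [-1, 1]")
  fr <- c(juvenile_frac, sub9g_frac, bad_date_frac, ambiguous_sex_frac,
          outlier_frac, background_frac, resid_share)
  if (any(fr < 0 | fr > 1)) stop("all fractions must be in [0, 1]")
  if (sum(fr[1:5]) >= 1) stop("contamination fractions must sum to < 1")
  if (!all(c("Fall", "Spring", "Summer", "Winter") %in% names(season_offsets)))
    stop("season_offsets must name all four seasons")
  if (length(decade_weights) != 13 || any(decade_weights < 0))
    stop("decade_weights must be 13 non-negative weights")
  structure(truth, class = "generative_truth")
}

#' @export
print.generative_truth <- function(x, ...) {
  cat("<generative_truth>\n")
  cat(sprintf("  beta: MAT %.2f, MAP %.2f, density %.2f, decade %.2f; sex %.2f\n",
              x$beta_mat, x$beta_map, x$beta_density, x$beta_decade, x$sex_offset))
  cat(sprintf("  random SDs: ecoregion %.2f, source %.2f, zone (%.2f, %.2f) rho %.2f; resid %.2f\n",
              x$sigma_ecoregion, x$sigma_source, x$sigma_zone_intercept,
              x$sigma_zone_slope, x$rho_slope_intercept, x$sigma_resid))
  cat(sprintf("  contamination: juvenile %.2f, sub-9g %.2f, bad date %.2f, ambiguous sex %.2f, outlier %.2f\n",
              x$juvenile_frac, x$sub9g_frac, x$bad_date_frac,
              x$ambiguous_sex_frac, x$outlier_frac))
  invisible(x)
}

# ---- environmental layers ----------------------------------------------

# smooth spatial noise: a sum of random Gaussian bumps over the grid
.bump_field <- function(lon_grid, lat_grid, bounds, n_bumps, amp_sd, width) {
  field <- matrix(0, length(lat_grid), length(lon_grid))
  if (n_bumps == 0) return(field)
  cx <- runif(n_bumps, bounds$lon[1], bounds$lon[2])
  cy <- runif(n_bumps, bounds$lat[1], bounds$lat[2])
  amp <- rnorm(n_bumps, 0, amp_sd)
  for (k in seq_len(n_bumps)) {
    gx <- exp(-((lon_grid - cx[k])^2) / (2 * width^2))
    gy <- exp(-((lat_grid - cy[k])^2) / (2 * width^2))
    field <- field + amp[k] * outer(gy, gx)
  }
  field
}

#' Generate year-indexed MAT and MAP climate surfaces
#'
#' Mean annual temperature decreases with latitude (plus smooth spatial
#' noise and an optional linear warming trend per year); mean annual
#' precipitation has an independent west-east gradient with its own noise
#' and no trend. Both stacks share one grid geometry.
#'
#' @param region_bounds `list(lon = c(w, e), lat = c(s, n))`.
#' @param years integer vector of years to cover.
#' @param seed integer RNG seed.
#' @param cellsize grid cell edge in degrees (default 0.5).
#' @param warming_trend linear MAT trend in degC per year (default 0).
#' @return `list(mat = <raster_stack>, map = <raster_stack>)`.
#' @export
make_climate_surfaces <- function(region_bounds, years, seed,
                                  cellsize = 0.5, warming_trend = 0) {
  check_bounds(region_bounds)
  if (!length(years)) stop("years must be non-empty")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  lon_grid <- seq(region_bounds$lon[1] + cellsize / 2, region_bounds$lon[2],
                  by = cellsize)
  lat_grid <- seq(region_bounds$lat[1] + cellsize / 2, region_bounds$lat[2],
                  by = cellsize)
  origin <- c(region_bounds$lon[1], region_bounds$lat[1])

  mat_base <- outer(36 - 0.9 * lat_grid, rep(1, length(lon_grid))) +
    .bump_field(lon_grid, lat_grid, region_bounds, 25, 1.5, 3)
  map_base <- outer(rep(1, length(lat_grid)),
                    250 + 22 * (lon_grid - region_bounds$lon[1])) +
    .bump_field(lon_grid, lat_grid, region_bounds, 25, 80, 3)
  map_base[map_base < 50] <- 50

  mat_layers <- lapply(years, function(y)
    mat_base + warming_trend * (y - years[1]))
  map_layers <- rep(list(map_base), length(years))
  list(mat = raster_stack("MAT", "degC", origin, cellsize, years, mat_layers),
       map = raster_stack("MAP", "mm", origin, cellsize, years, map_layers))
}

#' Generate a decade-indexed human population density stack
#'
#' Density is a strictly positive floor plus a sum of exponentially
#' decaying city kernels whose amplitudes grow monotonically over decades,
#' emulating decadal gridded population-density layers.
#'
#' @param region_bounds `list(lon = c(w, e), lat = c(s, n))`.
#' @param decades sorted ascending integer decade start years (e.g.
#'   `seq(1900, 2010, 10)`).
#' @param n_cities number of city kernels (`>= 0`).
#' @param seed integer RNG seed.
#' @param cellsize grid cell edge in degrees (default 0.1; a scaled-down
#'   stand-in for a 1 km base resolution).
#' @param floor strictly positive background density (persons/km^2,
#'   default 0.01) so logs are finite.
#' @return a `raster_stack` of density (persons/km^2).
#' @export
make_density_stack <- function(region_bounds, decades, n_cities, seed,
                               cellsize = 0.1, floor = 0.01) {
  check_bounds(region_bounds)
  if (n_cities < 0) stop("n_cities must be >= 0")
  if (is.unsorted(decades, strictly = TRUE)) stop("decades must be sorted ascending")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  lon_grid <- seq(region_bounds$lon[1] + cellsize / 2, region_bounds$lon[2],
                  by = cellsize)
  lat_grid <- seq(region_bounds$lat[1] + cellsize / 2, region_bounds$lat[2],
                  by = cellsize)
  origin <- c(region_bounds$lon[1], region_bounds$lat[1])
  ny <- length(lat_grid); nx <- length(lon_grid)

  kernels <- list(); base_amp <- growth <- numeric(0)
  if (n_cities > 0) {
    cx <- runif(n_cities, region_bounds$lon[1], region_bounds$lon[2])
    cy <- runif(n_cities, region_bounds$lat[1], region_bounds$lat[2])
    scale <- runif(n_cities, 0.2, 0.8)               # decay scale, degrees
    base_amp <- exp(rnorm(n_cities, log(200), 1))    # peak density, 1st decade
    growth <- runif(n_cities, 0, 0.25)               # per-decade log growth
    kernels <- lapply(seq_len(n_cities), function(k) {
      dx <- abs(outer(rep(1, ny), lon_grid - cx[k]))
      dy <- abs(outer(lat_grid - cy[k], rep(1, nx)))
      exp(-sqrt(dx^2 + dy^2) / scale[k])
    })
  }
  layers <- lapply(seq_along(decades), function(d) {
    m <- matrix(floor, ny, nx)
    for (k in seq_along(kernels)) {
      m <- m + base_amp[k] * exp(growth[k] * (d - 1)) * kernels[[k]]
    }
    m
  })
  raster_stack("density", "persons/km2", origin, cellsize, decades, layers)
}

# ---- ecoregions ---------------------------------------------------------

#' Generate a synthetic ecoregion map
#'
#' Five west-to-east longitudinal bands named after broad North American
#' Level-I-style ecoregions; three of them (Northwestern Forested
#' Mountains, North American Deserts, Great Plains) carry a 42 degrees N
#' split rule producing Northern/Southern daughters, giving 8 membership
#' labels in total.
#'
#' @param region_bounds `list(lon = c(w, e), lat = c(s, n))`.
#' @param split_lat split latitude for the three wide-ranging regions
#'   (default 42).
#' @return an [ecoregion_map()].
#' @export
make_ecoregion_map <- function(region_bounds = default_region_bounds(),
                               split_lat = 42) {
  check_bounds(region_bounds)
  nm <- c("Marine West Coast Forests", "Northwestern Forested Mountains",
          "North American Deserts", "Great Plains",
          "Eastern Temperate Forests")
  cuts <- seq(region_bounds$lon[1], region_bounds$lon[2], length.out = 6)
  s <- region_bounds$lat[1]; n <- region_bounds$lat[2]
  polys <- lapply(seq_len(5), function(k) {
    w <- cuts[k]; e <- cuts[k + 1]
    rbind(c(w, s), c(e, s), c(e, n), c(w, n), c(w, s))
  })
  names(polys) <- nm
  ecoregion_map(polys,
                split = data.frame(region = nm[2:4], split_lat = split_lat))
}

# ---- record simulator ---------------------------------------------------

# lattice of cell_km cells (Albers metres) covering the projected bounds
zone_lattice <- function(region_bounds, cell_km = 200) {
  corners <- expand.grid(lon = region_bounds$lon, lat = region_bounds$lat)
  pr <- albers_project(corners$lon, corners$lat)
  L <- cell_km * 1000
  x0 <- floor(min(pr$x) / L) * L
  y0 <- floor(min(pr$y) / L) * L
  xs <- seq(x0, max(pr$x), by = L)
  ys <- seq(y0, max(pr$y), by = L)
  g <- expand.grid(x0 = xs, y0 = ys)
  g$zone_id <- seq_len(nrow(g))
  g
}

# Gaussian noise, optionally truncated at +-trunc SDs (inverse-CDF draw)
.rnorm_trunc <- function(n, sd, trunc = Inf) {
  if (!is.finite(trunc)) return(rnorm(n, 0, sd))
  u <- runif(n, pnorm(-trunc), pnorm(trunc))
  qnorm(u) * sd
}

# Sample a valid calendar date (month, day) uniformly within a year.
# 1 January is never drawn for clean records: that signature is reserved
# for the misreported-date contaminant class (and real New Year's Day
# collecting is vanishingly rare), keeping the audit bookkeeping exact.
.sample_dates <- function(years) {
  m <- sample.int(12, length(years), replace = TRUE)
  dmax <- days_in_month(years, m)
  d <- 1L + as.integer(floor(runif(length(years)) * dmax))
  jan1 <- m == 1L & d == 1L
  d[jan1] <- 2L
  list(month = m, day = d)
}

#' Simulate multi-source trait records with known generative truth
#'
#' Each record draws a location (concentrated in `truth$n_zones` dense
#' 200 km lattice cells plus a uniform background fraction), a collection
#' date weighted by decade, a sex and a data source; its body mass is
#' built from the truth's linear predictor on standardized covariates
#' (MAT and MAP of the collection year, log density of the decade,
#' standardized decade index), sex/season offsets, ecoregion and source
#' random effects, a correlated per-zone (intercept, decade-slope) pair,
#' and Gaussian residual noise. Head-body length shares the same linear
#' predictor scaled to the length scale, receives the live-capture
#' (NEON) measurement bias, and is emitted as total and tail lengths.
#' Contaminant classes (labelled juveniles, sub-9 g unlabelled juveniles,
#' unusable dates, ambiguous sexes, gross measurement outliers) are
#' injected at the truth's rates and recorded in a hidden truth column.
#'
#' @param truth a [generative_truth()].
#' @param climate `list(mat =, map =)` of [raster_stack()]s covering
#'   `year_range`.
#' @param density a decade-indexed density [raster_stack()].
#' @param ecoregions an [ecoregion_map()].
#' @param n number of records (`>= 1`).
#' @param year_range `c(first, last)` collection years.
#' @param seed integer RNG seed.
#' @param region_bounds study window (defaults to the climate stack extent).
#' @return a data.frame of records (see [run_pipeline()]) with hidden
#'   truth columns prefixed `true_`; attributes `truth` (the parameter
#'   set) and `zone_effects` (the drawn per-zone intercept/slope pairs).
#' @export
simulate_records <- function(truth, climate, density, ecoregions, n,
                             year_range, seed,
                             region_bounds = NULL) {
  stopifnot(inherits(truth, "generative_truth"), n >= 1)
  if (is.null(region_bounds)) {
    region_bounds <- list(
      lon = c(climate$mat$origin[1],
              climate$mat$origin[1] + climate$mat$nx * climate$mat$cellsize),
      lat = c(climate$mat$origin[2],
              climate$mat$origin[2] + climate$mat$ny * climate$mat$cellsize))
  }
  if (year_range[1] < min(climate$mat$times) || year_range[2] > max(climate$mat$times))
    stop("requested year range outside climate layer coverage")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  # --- locations: dense lattice zones + uniform background ---
  lat_bb <- zone_lattice(region_bounds, 200)
  # keep lattice cells whose centre inverse-projects inside the window
  # a dense cell qualifies only if all four corners fall inside the
  # covariate-covered window, so no simulated animal lacks covariates
  margin <- 0.1
  corner_ok <- function(dx, dy) {
    cc <- albers_inverse(lat_bb$x0 + dx, lat_bb$y0 + dy)
    cc$lon > region_bounds$lon[1] + margin &
      cc$lon < region_bounds$lon[2] - margin &
      cc$lat > region_bounds$lat[1] + margin &
      cc$lat < region_bounds$lat[2] - margin
  }
  inside <- corner_ok(0, 0) & corner_ok(2e5, 0) &
    corner_ok(0, 2e5) & corner_ok(2e5, 2e5)
  lat_ok <- lat_bb[inside, , drop = FALSE]
  nz <- min(truth$n_zones, nrow(lat_ok))
  dense <- lat_ok[sample.int(nrow(lat_ok), nz), , drop = FALSE]
  w <- rgamma(nz, truth$zone_concentration, 1)
  w <- w / sum(w)
  is_bg <- runif(n) < truth$background_frac
  zone_pick <- sample.int(nz, n, replace = TRUE, prob = w)
  x <- dense$x0[zone_pick] + runif(n) * 2e5
  y <- dense$y0[zone_pick] + runif(n) * 2e5
  if (any(is_bg)) {
    nb <- sum(is_bg)
    bg_lon <- runif(nb, region_bounds$lon[1] + margin,
                    region_bounds$lon[2] - margin)
    bg_lat <- runif(nb, region_bounds$lat[1] + margin,
                    region_bounds$lat[2] - margin)
    pr <- albers_project(bg_lon, bg_lat)
    x[is_bg] <- pr$x; y[is_bg] <- pr$y
  }
  ll <- albers_inverse(x, y)
  # true zone = containing lattice cell (known lattice, not optimizer output)
  all_lat <- zone_lattice(region_bounds, 200)
  L <- 2e5
  zx <- floor((x - min(all_lat$x0)) / L)
  zy <- floor((y - min(all_lat$y0)) / L)
  true_zone <- paste0("Z", zx, "_", zy)

  # --- dates, sex, source ---
  dw <- truth$decade_weights
  bins <- assign_decade(year_range[1]):assign_decade(year_range[2])
  bin <- bins[sample.int(length(bins), n, replace = TRUE, prob = dw[bins])]
  y_lo <- pmax(1895 + 10 * (bin - 1), year_range[1])
  y_hi <- pmin(1895 + 10 * (bin - 1) + 9, year_range[2])
  year <- y_lo + as.integer(floor(runif(n) * (y_hi - y_lo + 1)))
  md <- .sample_dates(year)
  season <- assign_season(md$month, md$day)
  sex <- sample(c("female", "male"), n, replace = TRUE)
  source <- rep("VertNet", n)
  nacsm_era <- year >= 1948 & year <= 1956
  source[nacsm_era & runif(n) < 0.5] <- "NACSM"
  neon_era <- year >= 2013
  source[neon_era & runif(n) < 0.5] <- "NEON"

  # --- covariates at the drawn locations/times ---
  mat <- raster_extract(climate$mat, ll$lon, ll$lat, year)
  map <- raster_extract(climate$map, ll$lon, ll$lat, year)
  dec_start <- pmin(pmax(1790 + 10 * floor((year - 1790) / 10),
                         min(density$times)), max(density$times))
  dens <- raster_extract(density, ll$lon, ll$lat, dec_start, nearest_time = TRUE)
  log_dens <- log(dens + 0.01)
  zs <- function(v) (v - mean(v, na.rm = TRUE)) / sd(v, na.rm = TRUE)
  matz <- zs(mat); mapz <- zs(map); densz <- zs(log_dens); decz <- zs(bin)

  # --- random effects ---
  er <- assign_ecoregion(data.frame(decimalLongitude = ll$lon,
                                    decimalLatitude = ll$lat), ecoregions)
  eco <- rep(NA_character_, n)
  eco[as.integer(rownames(er$records))] <- er$records$ecoregion
  eco[is.na(eco)] <- "Unassigned"
  eco_lvls <- unique(eco)
  eco_eff <- setNames(rnorm(length(eco_lvls), 0, truth$sigma_ecoregion), eco_lvls)
  src_lvls <- c("VertNet", "NACSM", "NEON")
  src_eff <- setNames(rnorm(3, 0, truth$sigma_source), src_lvls)
  zone_lvls <- sort(unique(true_zone), method = "radix")  # locale-independent
  Sig <- matrix(c(truth$sigma_zone_intercept^2,
                  rep(truth$rho_slope_intercept * truth$sigma_zone_intercept *
                        truth$sigma_zone_slope, 2),
                  truth$sigma_zone_slope^2), 2, 2)
  zb <- MASS::mvrnorm(length(zone_lvls), c(0, 0), Sig)
  if (length(zone_lvls) == 1L) zb <- matrix(zb, 1, 2)
  zone_effects <- data.frame(zone = zone_lvls, b0 = zb[, 1], b1 = zb[, 2])

  # --- linear predictor and traits ---
  fix <- truth$beta_mat * matz + truth$beta_map * mapz +
    truth$beta_density * densz + truth$beta_decade * decz +
    ifelse(sex == "male", -truth$sex_offset, 0) +
    truth$season_offsets[season]
  ranef <- eco_eff[eco] + src_eff[source] +
    zone_effects$b0[match(true_zone, zone_effects$zone)] +
    zone_effects$b1[match(true_zone, zone_effects$zone)] * decz
  signal <- as.numeric(fix + ranef)
  # residual split: a shared individual condition component couples the two
  # traits (allometry) without changing either trait's marginal variance
  sd_cond <- sqrt(truth$resid_share) * truth$sigma_resid
  cond <- .rnorm_trunc(n, sd_cond, truth$resid_trunc)
  mass_spec <- .rnorm_trunc(n, sqrt(1 - truth$resid_share) * truth$sigma_resid,
                            truth$resid_trunc)
  hb_spec_sd <- sqrt(max(0, truth$hb_resid_sd^2 -
                           (truth$hb_signal_scale * sd_cond)^2))
  mass <- truth$intercept_mass + signal + cond + mass_spec
  hb <- truth$intercept_hb + truth$hb_signal_scale * (signal + cond) +
    .rnorm_trunc(n, hb_spec_sd, truth$resid_trunc)
  hb[source == "NEON"] <- hb[source == "NEON"] + truth$source_hb_bias
  tail_len <- truth$tail_mean + .rnorm_trunc(n, truth$tail_sd, truth$resid_trunc)
  total_len <- hb + tail_len
  life_stage <- rep("adult", n)

  # --- contamination (exclusive classes, exact bookkeeping) ---
  classes <- c("juvenile", "sub9g", "bad_date", "ambiguous_sex", "outlier")
  probs <- c(truth$juvenile_frac, truth$sub9g_frac, truth$bad_date_frac,
             truth$ambiguous_sex_frac, truth$outlier_frac)
  contaminant <- rep("none", n)
  u <- runif(n)
  cum <- cumsum(probs)
  for (k in rev(seq_along(classes))) {
    lo <- if (k == 1) 0 else cum[k - 1]
    contaminant[u >= lo & u < cum[k]] <- classes[k]
  }
  month <- md$month; day <- md$day
  j <- contaminant == "juvenile"
  life_stage[j] <- "juvenile"
  mass[j] <- mass[j] * runif(sum(j), 0.45, 0.7)
  s9 <- contaminant == "sub9g"
  mass[s9] <- runif(sum(s9), 4, 8.9)
  life_stage[s9] <- "unknown"
  bd <- which(contaminant == "bad_date")
  if (length(bd)) {
    mode <- sample.int(4, length(bd), replace = TRUE)
    month[bd[mode == 1]] <- NA; day[bd[mode == 1]] <- NA
    month[bd[mode == 2]] <- 1L; day[bd[mode == 2]] <- 1L
    year[bd[mode == 3]] <- sample(1850:1894, sum(mode == 3), replace = TRUE)
    month[bd[mode == 4]] <- 2L; day[bd[mode == 4]] <- 30L
  }
  ax <- which(contaminant == "ambiguous_sex")
  if (length(ax)) {
    sex[ax] <- sample(c("female?", "male?", "undetermined", "unknown", ""),
                      length(ax), replace = TRUE)
  }
  ol <- which(contaminant == "outlier")
  if (length(ol)) {
    on_mass <- runif(length(ol)) < 0.5
    mass[ol[on_mass]] <- mass[ol[on_mass]] + truth$outlier_shift
    total_len[ol[!on_mass]] <- total_len[ol[!on_mass]] + 4 * truth$outlier_shift
  }

  out <- data.frame(
    record_id = sprintf("rec%06d", seq_len(n)),
    source = source,
    decimalLongitude = ll$lon, decimalLatitude = ll$lat,
    year = year, month = month, day = day,
    sex = sex, life_stage = life_stage,
    body_mass = mass, total_length = total_len, tail_length = tail_len,
    true_contaminant = contaminant,
    true_zone = true_zone, true_ecoregion = eco,
    true_matz = matz, true_mapz = mapz, true_densz = densz,
    true_decadez = decz, true_season = season,
    true_eco_eff = as.numeric(eco_eff[eco]),
    true_source_eff = as.numeric(src_eff[source]),
    true_zone_b0 = zone_effects$b0[match(true_zone, zone_effects$zone)],
    true_zone_b1 = zone_effects$b1[match(true_zone, zone_effects$zone)],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "truth") <- truth
  attr(out, "zone_effects") <- zone_effects
  attr(out, "dense_zones") <- paste0(
    "Z", floor((dense$x0 - min(all_lat$x0)) / L), "_",
    floor((dense$y0 - min(all_lat$y0)) / L))
  out
}

# ---- record I/O ---------------------------------------------------------

#' Write / read records as a Darwin-Core-flavoured CSV
#'
#' Columns are renamed to Darwin-Core-style headers
#' (`decimalLatitude`, `decimalLongitude`, `eventDate`, `sex`, `lifeStage`,
#' `institutionCode`, `massInGrams`, `totalLengthInMM`, `tailLengthInMM`);
#' hidden `true_*` columns are preserved verbatim when present.
#'
#' @param records a record data.frame.
#' @param path CSV path.
#' @return `write_records()`: invisibly, the path; `read_records()`: the
#'   internal-format record data.frame.
#' @export
write_records <- function(records, path) {
  out <- data.frame(
    occurrenceID = records$record_id,
    institutionCode = records$source,
    decimalLatitude = records$decimalLatitude,
    decimalLongitude = records$decimalLongitude,
    eventDate = ifelse(is.na(records$month) | is.na(records$day),
                       sprintf("%04d", records$year),
                       sprintf("%04d-%02d-%02d", records$year,
                               records$month, records$day)),
    year = records$year, month = records$month, day = records$day,
    sex = records$sex, lifeStage = records$life_stage,
    massInGrams = records$body_mass,
    totalLengthInMM = records$total_length,
    tailLengthInMM = records$tail_length,
    stringsAsFactors = FALSE)
  truths <- grep("^true_", names(records), value = TRUE)
  for (tc in truths) out[[tc]] <- records[[tc]]
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  out <- data.frame(
    record_id = raw$occurrenceID,
    source = raw$institutionCode,
    decimalLongitude = raw$decimalLongitude,
    decimalLatitude = raw$decimalLatitude,
    year = raw$year, month = raw$month, day = raw$day,
    sex = raw$sex, life_stage = raw$lifeStage,
    body_mass = raw$massInGrams,
    total_length = raw$totalLengthInMM,
    tail_length = raw$tailLengthInMM,
    stringsAsFactors = FALSE)
  truths <- grep("^true_", names(raw), value = TRUE)
  for (tc in truths) out[[tc]] <- raw[[tc]]
  out
}
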