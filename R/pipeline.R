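# End-to-end orchestration: simulate a study system, run the
# harmonize -> covariates -> zonation -> models chain over dataset
# variants, and check parameter recovery against generative truth.
# These functions are the package's command surface; each is a thin,
# configurable wrapper over the stage functions.

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file.
#' @return a named list.
#' @export
read_config <- function(path) yaml::read_yaml(path)

# fill config defaults shared by the commands
.sim_defaults <- function(config = list()) {
  defaults <- list(
    seed = 1L, n = 20000L,
    year_range = c(1945L, 2019L),
    region_bounds = default_region_bounds(),
    n_cities = 25L,
    climate_cellsize = 0.5, density_cellsize = 0.1,
    warming_trend = 0,
    truth = list())
  cfg <- utils::modifyList(defaults, config)
  if (is.list(cfg$region_bounds) && is.null(names(cfg$region_bounds)))
    names(cfg$region_bounds) <- c("lon", "lat")
  cfg
}

#' Simulate a full study bundle
#'
#' Builds climate surfaces, a density stack, the ecoregion map, the
#' generative truth (defaults overridable through `config$truth`) and the
#' simulated records, deterministically from `config$seed` (per-stage
#' child seeds keep stages independently rerunnable).
#'
#' @param config list; recognised keys: `seed`, `n`, `year_range`,
#'   `region_bounds`, `n_cities`, `climate_cellsize`, `density_cellsize`,
#'   `warming_trend`, and `truth` (argument overrides for
#'   [generative_truth()]).
#' @return list with `records`, `climate`, `density`, `ecoregions`,
#'   `truth`, `config`.
#' @export
simulate_bundle <- function(config = list()) {
  cfg <- .sim_defaults(config)
  if (cfg$n < 1) stop("config n must be >= 1")
  truth <- do.call(generative_truth, cfg$truth)
  years <- seq(min(1895, cfg$year_range[1]), cfg$year_range[2])
  climate <- make_climate_surfaces(cfg$region_bounds, years,
                                   seed = child_seed(cfg$seed, "climate"),
                                   cellsize = cfg$climate_cellsize,
                                   warming_trend = cfg$warming_trend)
  density <- make_density_stack(cfg$region_bounds, seq(1900L, 2010L, 10L),
                                n_cities = cfg$n_cities,
                                seed = child_seed(cfg$seed, "density"),
                                cellsize = cfg$density_cellsize)
  ecoregions <- make_ecoregion_map(cfg$region_bounds)
  records <- simulate_records(truth, climate, density, ecoregions,
                              n = cfg$n, year_range = cfg$year_range,
                              seed = child_seed(cfg$seed, "records"),
                              region_bounds = cfg$region_bounds)
  list(records = records, climate = climate, density = density,
       ecoregions = ecoregions, truth = truth, config = cfg)
}

#' Simulate and write a study bundle to disk
#'
#' Writes the records CSV (Darwin-Core-style headers), the climate and
#' density rasters (JSON header + long CSV each), the ecoregion polygons
#' as GeoJSON, the truth parameters as JSON, and a manifest with file
#' digests.
#'
#' @param config see [simulate_bundle()]; plus `out` (output directory).
#' @return invisibly, the bundle.
#' @export
cmd_simulate <- function(config = list()) {
  out <- config$out %||% "pemasize_out"
  bundle <- simulate_bundle(config)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_records(bundle$records, file.path(out, "records.csv"))
  write_raster_stack(bundle$climate$mat, file.path(out, "mat"))
  write_raster_stack(bundle$climate$map, file.path(out, "map"))
  write_raster_stack(bundle$density, file.path(out, "density"))
  write_ecoregion_geojson(bundle$ecoregions, file.path(out, "ecoregions.geojson"))
  jsonlite::write_json(unclass(bundle$truth), file.path(out, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(out, bundle$config)
  invisible(bundle)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize an ecoregion map to GeoJSON
#' @param map an [ecoregion_map()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_ecoregion_geojson <- function(map, path) {
  feats <- lapply(names(map$polygons), function(nm) {
    ring <- map$polygons[[nm]]
    list(type = "Feature", properties = list(name = nm),
         geometry = list(type = "Polygon",
                         coordinates = list(Map(c, ring[, 1], ring[, 2]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats,
                            split = map$split),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# manifest with config snapshot, seeds, and file digests
write_manifest <- function(out, config, timing = NULL) {
  files <- setdiff(list.files(out, recursive = TRUE), "manifest.json")
  digests <- as.list(tools::md5sum(file.path(out, files)))
  names(digests) <- files
  jsonlite::write_json(
    list(config = config, files = digests, timing = timing,
         package_version = as.character(utils::packageVersion("pemasize"))),
    file.path(out, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(file.path(out, "manifest.json"))
}

#' Build a model-ready dataset from a harmonized trait dataset
#'
#' Assigns ecoregion membership, extracts climate and density covariates,
#' optionally restricts to zoned records (attaching the zonation's cell id
#' as `zone`, or the generator's true lattice zone when
#' `zone_source = "truth"`), and standardizes the continuous predictors
#' over the final dataset.
#'
#' @param harmonized one trait dataset from [run_pipeline()].
#' @param climate `list(mat =, map =)` stacks.
#' @param density decade-indexed density stack.
#' @param ecoregions an [ecoregion_map()].
#' @param zonation optional `grid_zonation` fitted on this dataset (its
#'   membership must be parallel to `harmonized` rows).
#' @param zone_source `"zonation"`, `"truth"` (use the hidden
#'   `true_zone` column), or `"none"`.
#' @param min_zone_n minimum records per zone; zones below it are dropped
#'   before standardization (0 keeps all). Grid-zonation cells already
#'   satisfy the 75/4/10 density criteria, so this mainly matters for
#'   `zone_source = "truth"`, where it restricts the analysis to the
#'   densely sampled lattice cells the way the zonation criteria would.
#' @param scale_km density aggregation scale (default 1).
#' @return the model-ready data.frame.
#' @export
build_model_dataset <- function(harmonized, climate, density, ecoregions,
                                zonation = NULL,
                                zone_source = c("none", "zonation", "truth"),
                                min_zone_n = 0, scale_km = 1) {
  zone_source <- match.arg(zone_source)
  er <- assign_ecoregion(harmonized, ecoregions)
  d <- er$records
  cl <- extract_climate(d, climate$mat, climate$map)
  de <- extract_density(cl$records, density, scale_km)
  d <- de$records
  if (zone_source == "zonation") {
    if (is.null(zonation)) stop("zone_source = 'zonation' needs a zonation")
    idx <- match(d$record_id, harmonized$record_id)
    d$zone <- ifelse(is.na(zonation$membership[idx]), NA_character_,
                     paste0("cell", zonation$membership[idx]))
    d <- d[!is.na(d$zone), , drop = FALSE]
  } else if (zone_source == "truth") {
    d$zone <- d$true_zone
  }
  if (zone_source != "none" && min_zone_n > 0) {
    tab <- table(d$zone)
    d <- d[d$zone %in% names(tab)[tab >= min_zone_n], , drop = FALSE]
  }
  standardize(d, c("MAT", "MAP", "log_density", "decade_bin"))
}

#' Run the full analysis over dataset variants
#'
#' For each requested variant (trait x juveniles x NEON x spatial/temporal)
#' runs harmonization, covariate pairing, zonation (temporal variants),
#' and optionally the candidate model suite with AICc ranking, writing
#' per-variant artifacts and a manifest. The default variant grid is the
#' study's 12 datasets: spatial variants toggle juveniles and NEON
#' (2 traits x 2 x 2); temporal variants toggle juveniles and always
#' exclude the live-capture source (2 traits x 2).
#'
#' @param bundle a [simulate_bundle()] result (or a compatible list with
#'   `records`, `climate`, `density`, `ecoregions`).
#' @param config list; recognised keys: `out` (directory or `NULL` to skip
#'   writing), `fit_models` (default `FALSE`), `candidates` (explicit
#'   fixed-term list for [enumerate_candidates()]), `max_iter` (zonation
#'   budget, default 20000), `seed`, `scale_km`, `variants` (data.frame to
#'   override the grid).
#' @return list with `variants` (summary data.frame), and per-variant
#'   `results` (datasets, zonations, selection tables when fitted).
#' @export
cmd_run_all <- function(bundle, config = list()) {
  cfg <- utils::modifyList(
    list(out = NULL, fit_models = FALSE, candidates = NULL,
         max_iter = 20000, seed = 1L, scale_km = 1), config)
  variants <- cfg$variants %||% local({
    sp <- expand.grid(trait = c("body_mass", "hb_length"),
                      juveniles = c(FALSE, TRUE), neon = c(FALSE, TRUE),
                      mode = "spatial", stringsAsFactors = FALSE)
    tm <- expand.grid(trait = c("body_mass", "hb_length"),
                      juveniles = c(FALSE, TRUE), neon = FALSE,
                      mode = "temporal", stringsAsFactors = FALSE)
    rbind(sp, tm)
  })
  if (!is.null(cfg$out)) dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)

  results <- list(); summary_rows <- list()
  t0 <- proc.time()[["elapsed"]]
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    vname <- sprintf("%s_%s_%s_%s", v$trait, v$mode,
                     if (v$juveniles) "juv" else "nojuv",
                     if (v$neon) "neon" else "noneon")
    hz <- run_pipeline(bundle$records,
                       list(include_juveniles = v$juveniles,
                            include_neon = v$neon,
                            temporal = v$mode == "temporal"))
    traitset <- if (v$trait == "body_mass") hz$mass else hz$hb
    zon <- NULL; n_zones <- NA_integer_
    zone_source <- "none"
    if (v$mode == "temporal") {
      zon <- optimize_grid_zones(traitset, max_iter = cfg$max_iter,
                                 seed = child_seed(cfg$seed, vname))
      n_zones <- nrow(zon$cells)
      zone_source <- "zonation"
    }
    ds <- tryCatch(
      build_model_dataset(traitset, bundle$climate, bundle$density,
                          bundle$ecoregions, zonation = zon,
                          zone_source = zone_source,
                          scale_km = cfg$scale_km),
      error = function(e) NULL)
    res <- list(variant = v, dataset = ds, zonation = zon, audit = hz$audit)
    fitted <- FALSE
    if (cfg$fit_models && !is.null(ds) && nrow(ds) > 50 &&
        (v$mode == "spatial" || (!is.null(zon) && n_zones >= 2))) {
      specs <- enumerate_candidates(v$trait, v$mode, cfg$candidates)
      fits <- lapply(specs, function(s) fit_lmm(ds, s))
      res$selection <- rank_models(fits)
      res$top_fit <- attr(res$selection, "fits")[[1]]
      res$r2 <- nakagawa_r2(res$top_fit)
      if (v$mode == "temporal") {
        res$diagnostics <- tryCatch(random_effect_diagnostics(res$top_fit),
                                    error = function(e) NULL)
        res$zone_trends <- fit_per_zone_trends(ds, v$trait)
      }
      fitted <- TRUE
      if (!is.null(cfg$out)) {
        write.csv(as.data.frame(res$selection),
                  file.path(cfg$out, paste0(vname, "_selection.csv")),
                  row.names = FALSE)
        write.csv(res$top_fit$coefficients,
                  file.path(cfg$out, paste0(vname, "_coefficients.csv")),
                  row.names = FALSE)
        if (!is.null(res$diagnostics)) {
          write.csv(res$diagnostics$per_zone,
                    file.path(cfg$out, paste0(vname, "_zone_scatter.csv")),
                    row.names = FALSE)
        }
      }
    } else if (cfg$fit_models && v$mode == "temporal" &&
               (is.null(zon) || n_zones < 2)) {
      message("variant ", vname,
              ": zonation too sparse (<2 qualifying cells); models skipped")
    }
    summary_rows[[i]] <- data.frame(
      variant = vname, trait = v$trait, mode = v$mode,
      juveniles = v$juveniles, neon = v$neon,
      n_records = if (is.null(ds)) 0L else nrow(ds),
      n_zones = n_zones, fitted = fitted)
    results[[vname]] <- res
  }
  summary <- do.call(rbind, summary_rows)
  if (!is.null(cfg$out)) {
    write.csv(summary, file.path(cfg$out, "variant_summary.csv"),
              row.names = FALSE)
    write_manifest(cfg$out, cfg,
                   timing = proc.time()[["elapsed"]] - t0)
  }
  list(variants = summary, results = results)
}

#' Simulate, analyse, and compare estimates against generative truth
#'
#' The recovery harness: simulates a bundle, harmonizes the mass dataset,
#' attaches covariates, fits the global temporal mixed model with the
#' generator's true lattice zones as grouping (so recovery truth is
#' unambiguous), and tabulates true versus estimated parameters with
#' 3-standard-error coverage flags, plus both zone slope-intercept
#' correlation estimates against the generative correlation.
#'
#' @param config see [simulate_bundle()]; `config$truth` sets the truth.
#' @param bundle optionally, a pre-built bundle (skips simulation).
#' @return list with `table` (parameter recovery data.frame), `rho`
#'   (truth/model/BLUP correlations), `fit`, and `dataset`.
#' @export
cmd_recover <- function(config = list(), bundle = NULL) {
  if (is.null(bundle)) bundle <- simulate_bundle(config)
  truth <- bundle$truth
  hz <- run_pipeline(bundle$records, list(temporal = TRUE, include_neon = FALSE))
  ds <- build_model_dataset(hz$mass, bundle$climate, bundle$density,
                            bundle$ecoregions, zone_source = "truth",
                            min_zone_n = 30)
  spec <- model_spec("body_mass",
                     c("MAT", "MAP", "sex", "season", "log_density", "decade"),
                     "temporal")
  fit <- fit_lmm(ds, spec)
  cf <- fit$coefficients
  grab <- function(term) cf[cf$term == term, ]
  truth_map <- data.frame(
    term = c("MAT_z", "MAP_z", "log_density_z", "decade_bin_z", "sexmale"),
    true = c(truth$beta_mat, truth$beta_map, truth$beta_density,
             truth$beta_decade, -truth$sex_offset))
  season_terms <- data.frame(
    term = paste0("season", c("Spring", "Summer", "Winter")),
    true = unname(truth$season_offsets[c("Spring", "Summer", "Winter")] -
                    truth$season_offsets["Fall"]))
  truth_map <- rbind(truth_map, season_terms)
  rows <- lapply(seq_len(nrow(truth_map)), function(k) {
    est <- grab(truth_map$term[k])
    if (!nrow(est)) return(NULL)
    data.frame(term = truth_map$term[k], true = truth_map$true[k],
               estimate = est$estimate, se = est$se,
               covered_3se = abs(est$estimate - truth_map$true[k]) <= 3 * est$se)
  })
  tab <- do.call(rbind, rows)
  diag <- tryCatch(random_effect_diagnostics(fit), error = function(e) NULL)
  list(table = tab,
       rho = list(true = truth$rho_slope_intercept,
                  model = if (!is.null(diag)) diag$model_rho else NA_real_,
                  blup = if (!is.null(diag)) diag$blup_rho else NA_real_),
       fit = fit, dataset = ds)
}
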