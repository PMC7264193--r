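# small balanced synthetic dataset for mixed-model tests: n_per records in
# each of n_zones zones, with per-zone (intercept, slope) pairs drawn at
# correlation rho, plus optional ecoregion/source labels
zone_panel <- function(n_zones = 40, n_per = 60, rho = -0.9,
                       sd_int = 1, sd_slope = 0.5, sd_e = 1, seed = 1) {
  set.seed(seed)
  Sig <- matrix(c(sd_int^2, rho * sd_int * sd_slope,
                  rho * sd_int * sd_slope, sd_slope^2), 2, 2)
  bb <- MASS::mvrnorm(n_zones, c(0, 0), Sig)
  d <- expand.grid(zone = sprintf("z%02d", seq_len(n_zones)),
                   rep = seq_len(n_per))
  d$decade_bin_z <- rnorm(nrow(d))
  iz <- as.integer(factor(d$zone))
  d$body_mass <- 20 + bb[iz, 1] + bb[iz, 2] * d$decade_bin_z +
    rnorm(nrow(d), 0, sd_e)
  d$sex <- sample(c("female", "male"), nrow(d), TRUE)
  d$season <- sample(c("Fall", "Spring", "Summer", "Winter"), nrow(d), TRUE)
  d$ecoregion <- sample(c("E1", "E2", "E3", "E4"), nrow(d), TRUE)
  d$source <- sample(c("VertNet", "NACSM"), nrow(d), TRUE)
  d$MAT_z <- rnorm(nrow(d)); d$MAP_z <- rnorm(nrow(d))
  d$log_density_z <- rnorm(nrow(d))
  d
}

test_that("allometry regression recovers an exact power law and rejects bad input", {
  L <- seq(70, 110, length.out = 20)
  r <- make_records(20, hb_length = L, body_mass = 2e-5 * L^3)
  r$hb_length <- L
  fit <- suppressWarnings(fit_allometry(r))  # lm warns on a perfect fit
  expect_equal(fit$slope, 3.0, tolerance = 1e-10)
  expect_equal(fit$adj_r2, 1.0, tolerance = 1e-10)

  set.seed(5)
  r2 <- make_records(2000, body_mass = exp(rnorm(2000, 3, 0.2)))
  r2$hb_length <- exp(rnorm(2000, 4.5, 0.1))
  expect_lt(abs(fit_allometry(r2)$adj_r2), 0.01)

  r3 <- make_records(5, body_mass = c(10, 12, -1, 14, 15))
  r3$hb_length <- c(80, 85, 90, 95, 100)
  expect_error(fit_allometry(r3), "positive")
  expect_error(fit_allometry(make_records(2, hb_length = c(80, 90))), ">= 3")
})

test_that("allometry coefficients match the closed-form normal-equation solution", {
  L <- c(72, 81, 88, 95, 104)
  M <- c(14.1, 17.3, 19.9, 23.0, 27.2)
  r <- make_records(5, body_mass = M)
  r$hb_length <- L
  fit <- fit_allometry(r)
  beta <- unname(ols_normal_eq(log(L), log(M)))
  expect_equal(fit$intercept, beta[1], tolerance = 1e-10)
  expect_equal(fit$slope, beta[2], tolerance = 1e-10)
})

test_that("candidate enumeration covers all subsets and honours explicit lists", {
  expect_length(enumerate_candidates("body_mass", "spatial"), 32)
  expect_length(enumerate_candidates("hb_length", "temporal"), 64)
  custom <- replicate(29, sample(c("MAT", "MAP", "sex"), 2), simplify = FALSE)
  expect_length(enumerate_candidates("body_mass", "spatial", custom), 29)
  expect_error(model_spec("body_mass", c("MAT", "decade"), "spatial"),
               "never include")
  expect_error(model_spec("body_mass", "bogus", "spatial"), "unknown fixed")
})

test_that("AICc matches its closed form and limits", {
  ic <- aicc(-47, 3, 100)
  expect_equal(ic$aic, 100)
  expect_equal(ic$aicc, 100.25)
  # n = k + 2: correction is exactly 2k(k+1)
  ic2 <- aicc(-10, 4, 6)
  expect_equal(ic2$aicc, ic2$aic + 2 * 4 * 5)
  # n -> infinity: correction vanishes
  ic3 <- aicc(-10, 4, 1e9)
  expect_equal(ic3$aicc, ic3$aic, tolerance = 1e-6)
  expect_error(aicc(-10, 4, 5), "n <= k")
  # AICc >= AIC whenever defined
  expect_gte(aicc(-5, 2, 50)$aicc, aicc(-5, 2, 50)$aic)
})

test_that("Akaike weights match the closed form, normalize, and tie-break stably", {
  mk <- function(name, aicc_val) {
    structure(list(name = name, AICc = aicc_val, n = 100, k = 3,
                   converged = TRUE), class = "fit_result")
  }
  tab <- rank_models(list(mk("b", 102), mk("a", 100)))
  expect_equal(tab$delta_AICc, c(0, 2))
  expect_equal(tab$weight, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(round(tab$weight, 4), c(0.7311, 0.2689))
  expect_equal(sum(tab$weight), 1, tolerance = 1e-12)

  tied <- rank_models(list(mk("m2", 100), mk("m1", 100)))
  expect_equal(tied$model, c("m1", "m2"))  # stable name tie-break
  expect_equal(tied$weight, c(0.5, 0.5))

  single <- rank_models(list(mk("only", 50)))
  expect_equal(single$weight, 1)
  expect_error(rank_models(list(structure(list(name = "x", converged = FALSE),
                                          class = "fit_result"))),
               "no converged")
})

test_that("one-level grouping collapses the mixed model to OLS", {
  set.seed(11)
  d <- zone_panel(n_zones = 2, n_per = 30, rho = 0, sd_int = 0, sd_slope = 0)
  d$ecoregion <- "only"; d$source <- "only"
  spec <- model_spec("body_mass", c("MAT", "sex"), "spatial")
  fit <- fit_lmm(d, spec)
  ols <- lm(body_mass ~ MAT_z + sex, data = prepare_model_data(d))
  expect_equal(fit$coefficients$estimate, unname(coef(ols)), tolerance = 1e-6)
  expect_equal(nrow(fit$varcomp), 0L)
})

test_that("ML variance components match a brute-force likelihood oracle on a tiny fixture", {
  # printed 8-row balanced two-group fixture
  d <- data.frame(
    body_mass = c(19.1, 20.3, 21.0, 19.8, 23.2, 24.1, 22.7, 23.9),
    ecoregion = rep(c("north", "south"), each = 4),
    source = "VertNet", sex = "female", season = "Fall",
    MAT_z = 0, MAP_z = 0, log_density_z = 0, decade_bin_z = 0)
  spec <- model_spec("body_mass", character(), "spatial")
  fit <- fit_lmm(d, spec)
  oracle <- lmm_grid_oracle(d$body_mass, cbind(rep(1, 8)), d$ecoregion)
  expect_equal(fit$loglik, oracle$loglik, tolerance = 1e-3)
  sd_group <- fit$varcomp$sdcor[fit$varcomp$grp == "ecoregion"]
  expect_equal(sd_group, oracle$sigma_g, tolerance = 1e-3)
  expect_equal(fit$sigma, oracle$sigma_e, tolerance = 1e-3)
  # k: intercept + group SD + residual SD
  expect_equal(fit$k, 3)
})

test_that("marginal/conditional R2 follow the variance-component plug-in formula", {
  fake <- list(var_fixed = 2,
               varcomp = data.frame(grp = c("g", "Residual"),
                                    var1 = c("(Intercept)", NA),
                                    var2 = c(NA, NA), vcov = c(1, 1),
                                    sdcor = c(1, 1)),
               sigma = 1)
  r2 <- nakagawa_r2(fake)
  expect_equal(r2$marginal, 0.5)
  expect_equal(r2$conditional, 0.75)

  # no random terms: marginal equals conditional
  ols_like <- list(var_fixed = 3, varcomp = data.frame(), sigma = 1)
  r2o <- nakagawa_r2(ols_like)
  expect_equal(r2o$marginal, r2o$conditional)

  # intercept-only fixed part: marginal 0
  null_like <- list(var_fixed = 0,
                    varcomp = data.frame(grp = "g", var1 = "(Intercept)",
                                         var2 = NA, vcov = 2, sdcor = sqrt(2)),
                    sigma = 1)
  expect_equal(nakagawa_r2(null_like)$marginal, 0)
})

test_that("conditional R2 >= marginal R2 on real fits, both in [0, 1]", {
  d <- zone_panel(seed = 3)
  for (spec in list(model_spec("body_mass", c("MAT", "sex"), "spatial"),
                    model_spec("body_mass", c("MAT", "decade"), "temporal"))) {
    fit <- fit_lmm(d, spec)
    r2 <- nakagawa_r2(fit)
    expect_gte(r2$conditional, r2$marginal)
    expect_gte(r2$marginal, 0); expect_lte(r2$conditional, 1)
  }
})

test_that("zone slope-intercept correlation is recovered at rho = -0.9", {
  d <- zone_panel(n_zones = 40, n_per = 200, rho = -0.9, seed = 17)
  fit <- fit_lmm(d, model_spec("body_mass", "decade", "temporal"))
  diag <- random_effect_diagnostics(fit)
  expect_true(diag$reliable)
  expect_lte(diag$model_rho, -0.7); expect_gte(diag$model_rho, -1)
  expect_lte(diag$blup_rho, -0.7); expect_gte(diag$blup_rho, -1)
  expect_equal(nrow(diag$per_zone), 40)
})

test_that("zone slope-intercept correlation stays near zero under a null truth", {
  # at 40 zones the estimator's sampling SD is ~1/sqrt(40-3) ~ 0.17, so the
  # null check asserts centring and spread rather than a tighter bound the
  # sample size cannot support
  rhos <- vapply(seq_len(10), function(k) {
    d <- zone_panel(n_zones = 40, n_per = 200, rho = 0, seed = 100 + k)
    fit <- fit_lmm(d, model_spec("body_mass", "decade", "temporal"))
    random_effect_diagnostics(fit)$blup_rho
  }, numeric(1))
  expect_lte(mean(abs(rhos)), 0.25)
  expect_gte(sum(abs(rhos) <= 0.4), 9)
})

test_that("a 2-zone fit flags the degenerate empirical correlation as unreliable", {
  d <- zone_panel(n_zones = 2, n_per = 50, rho = 0, seed = 23)
  fit <- fit_lmm(d, model_spec("body_mass", character(), "temporal"))
  diag <- random_effect_diagnostics(fit)
  expect_false(diag$reliable)
  expect_equal(abs(diag$blup_rho), 1, tolerance = 1e-6)
})

test_that("diagnostics demand a random decade slope", {
  d <- zone_panel(seed = 31)
  fit <- fit_lmm(d, model_spec("body_mass", "MAT", "spatial"))
  expect_error(random_effect_diagnostics(fit), "zone")
})

test_that("per-zone exploratory trends recover known slopes and skip thin zones", {
  d <- data.frame(zone = rep(c("a", "b", "c"), each = 8),
                  decade_bin = rep(6:13, 3),
                  body_mass = c(25 - 0.1 * (6:13),   # linear decline
                                rep(20, 8),          # constant
                                21 + 0.2 * (6:13)))
  d$decade_bin[d$zone == "c"] <- 6L  # zone c: single decade -> skipped
  out <- fit_per_zone_trends(d)
  expect_equal(out$slope[out$zone == "a"], -0.1, tolerance = 1e-10)
  expect_equal(out$slope[out$zone == "b"], 0, tolerance = 1e-10)
  expect_false("c" %in% out$zone)
  expect_equal(attr(out, "skipped"), "c")
})

test_that("zones with smaller animals trend larger when rho is strongly negative", {
  ok <- 0
  n_rep <- 10
  for (k in seq_len(n_rep)) {
    d <- zone_panel(n_zones = 30, n_per = 80, rho = -0.9, seed = 200 + k)
    d$decade_bin <- round(10 + 2 * d$decade_bin_z)
    tr <- fit_per_zone_trends(d)
    if (cor(tr$mean_size, tr$slope) < 0) ok <- ok + 1
  }
  expect_gte(ok, 9)
})

test_that("AICc-top model contains the true effects when only MAT and sex act", {
  hits <- 0
  n_rep <- 10
  for (k in seq_len(n_rep)) {
    set.seed(300 + k)
    d <- zone_panel(n_zones = 20, n_per = 200, rho = 0,
                    sd_int = 0.4, sd_slope = 0, sd_e = 2, seed = 300 + k)
    d$body_mass <- 20 - 0.5 * d$MAT_z +
      ifelse(d$sex == "male", -0.6, 0) + rnorm(nrow(d), 0, 2)
    subsets <- list(character(), "MAT", "sex", "MAP",
                    c("MAT", "sex"), c("MAT", "MAP"),
                    c("sex", "MAP"), c("MAT", "MAP", "sex"))
    specs <- enumerate_candidates("body_mass", "spatial", subsets)
    fits <- lapply(specs, function(s) fit_lmm(d, s))
    top <- attr(rank_models(fits), "fits")[[1]]
    if (all(c("MAT", "sex") %in% top$spec$fixed)) hits <- hits + 1
  }
  expect_gte(hits, 9)
})
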