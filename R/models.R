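# Candidate linear mixed-effects model suites: enumeration, ML fitting,
# AICc ranking, marginal/conditional R-squared, and random-effect
# diagnostics including the zone slope-intercept correlation.

# ---- allometry ----------------------------------------------------------

#' Head-body length / body mass allometry
#'
#' Ordinary least squares of log body mass on log head-body length. A
#' moderate fit (adjusted R-squared well below 1) justifies analysing the
#' two size proxies separately.
#'
#' @param records data.frame with positive `hb_length` and `body_mass` on
#'   at least 3 records.
#' @return list with `slope`, `intercept`, `r2`, `adj_r2`, `n`.
#' @export
fit_allometry <- function(records) {
  d <- records[!is.na(records$hb_length) & !is.na(records$body_mass), ]
  if (nrow(d) < 3) stop("fit_allometry needs >= 3 complete records")
  if (any(d$hb_length <= 0 | d$body_mass <= 0))
    stop("fit_allometry requires positive trait values")
  fit <- lm(log(body_mass) ~ log(hb_length), data = d)
  s <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r2 = s$r.squared, adj_r2 = s$adj.r.squared, n = nrow(d))
}

# ---- model specification ------------------------------------------------

# canonical fixed-term vocabulary -> model column
.term_cols <- c(MAT = "MAT_z", MAP = "MAP_z", sex = "sex", season = "season",
                log_density = "log_density_z", decade = "decade_bin_z")

#' Construct a candidate model specification
#'
#' @param response `"body_mass"` or `"hb_length"`.
#' @param fixed subset of `c("MAT", "MAP", "sex", "season", "log_density",
#'   "decade")` (may be empty for the intercept-only model).
#' @param mode `"spatial"` (random intercepts for ecoregion and data
#'   source; never includes the decade term) or `"temporal"` (additionally
#'   a correlated random intercept + decade slope within zone).
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(response = c("body_mass", "hb_length"),
                       fixed = character(), mode = c("spatial", "temporal")) {
  response <- match.arg(response)
  mode <- match.arg(mode)
  fixed <- unique(fixed)
  bad <- setdiff(fixed, names(.term_cols))
  if (length(bad)) stop("unknown fixed term(s): ", paste(bad, collapse = ", "))
  if (mode == "spatial" && "decade" %in% fixed)
    stop("spatial models never include the decade term")
  random <- c("(1 | ecoregion)", "(1 | source)")
  if (mode == "temporal") random <- c(random, "(decade_bin_z | zone)")
  structure(list(response = response, fixed = fixed, mode = mode,
                 random = random),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(spec_name(x), "\n")
  invisible(x)
}

#' Human-readable name of a model specification
#' @param spec a [model_spec()].
#' @return a single string such as `"body_mass ~ MAT + sex [temporal]"`.
#' @export
spec_name <- function(spec) {
  fx <- if (length(spec$fixed)) paste(spec$fixed, collapse = " + ") else "1"
  sprintf("%s ~ %s [%s]", spec$response, fx, spec$mode)
}

spec_formula <- function(spec) {
  rhs <- c(.term_cols[spec$fixed], spec$random)
  if (!length(spec$fixed)) rhs <- c("1", spec$random)
  as.formula(paste(spec$response, "~", paste(rhs, collapse = " + ")))
}

#' Enumerate the candidate model set
#'
#' Default is all subsets of the mode's global fixed-effect set (including
#' the intercept-only model), each carrying the mode's full random
#' structure: 32 spatial candidates over `{MAT, MAP, sex, season,
#' log_density}` and 64 temporal candidates with `decade` added. An
#' explicit candidate list (list of character vectors of fixed terms) can
#' be supplied instead, e.g. from a configuration file, to reproduce a
#' bespoke enumeration.
#'
#' @param response `"body_mass"` or `"hb_length"`.
#' @param mode `"spatial"` or `"temporal"`.
#' @param candidates optional list of fixed-term character vectors to use
#'   verbatim.
#' @return list of [model_spec()]s.
#' @export
enumerate_candidates <- function(response = "body_mass",
                                 mode = c("spatial", "temporal"),
                                 candidates = NULL) {
  mode <- match.arg(mode)
  if (!is.null(candidates)) {
    return(lapply(candidates, function(fx) model_spec(response, fx, mode)))
  }
  global <- c("MAT", "MAP", "sex", "season", "log_density")
  if (mode == "temporal") global <- c(global, "decade")
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), length(global)))
  lapply(seq_len(nrow(subsets)), function(i)
    model_spec(response, global[unlist(subsets[i, ])], mode))
}

# ---- information criteria ----------------------------------------------

#' Small-sample corrected Akaike information criterion
#'
#' `AIC = -2 logLik + 2k`; `AICc = AIC + 2k(k+1)/(n-k-1)`. The parameter
#' count `k` includes fixed effects, variance/covariance parameters and
#' the residual variance.
#'
#' @param loglik maximized log-likelihood.
#' @param k number of estimated parameters.
#' @param n sample size (`> k + 1`).
#' @return list with `aic` and `aicc`.
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stop("AICc undefined for n <= k + 1")
  aic <- -2 * loglik + 2 * k
  list(aic = aic, aicc = aic + 2 * k * (k + 1) / (n - k - 1))
}

# ---- fitting ------------------------------------------------------------

# Prepare modelling factors: season with Fall reference (so reported
# contrasts are fall-spring, fall-summer, fall-winter), binary sex with
# female reference (the male coefficient is the male-minus-female
# difference).
prepare_model_data <- function(dataset) {
  dataset$sex <- factor(dataset$sex, levels = c("female", "male"))
  dataset$season <- factor(dataset$season,
                           levels = c("Fall", "Spring", "Summer", "Winter"))
  dataset
}

#' Fit one candidate linear mixed model by maximum likelihood
#'
#' Gaussian LMM estimated by ML (not REML), so likelihoods of candidates
#' differing in fixed effects are comparable; a REML refit of a selected
#' model is available via `refit_reml`. Random terms whose grouping factor
#' has fewer than two levels in the data are dropped (collapsing to OLS
#' when none remain). Non-convergence triggers one retry with a different
#' optimizer; a fit that still fails is returned with
#' `converged = FALSE` and is excluded by [rank_models()].
#'
#' @param dataset model-ready data.frame with standardized covariate
#'   columns (`MAT_z`, `MAP_z`, `log_density_z`, `decade_bin_z`), factors
#'   `sex`, `season`, and grouping columns `ecoregion`, `source` (and
#'   `zone` for temporal specs).
#' @param spec a [model_spec()].
#' @param refit_reml if `TRUE`, variance components and coefficients are
#'   reported from a REML refit (the ML log-likelihood, AIC and AICc are
#'   always from the ML fit, so information criteria remain comparable).
#' @return an object of class `fit_result`: coefficient table (Wald z
#'   tests), variance components, residual SD, log-likelihood, `k`, `n`,
#'   `AIC`, `AICc`, convergence status, per-group conditional modes
#'   (BLUPs), and the variance of the fixed-effect linear predictor.
#' @export
fit_lmm <- function(dataset, spec, refit_reml = FALSE) {
  stopifnot(inherits(spec, "model_spec"))
  dataset <- prepare_model_data(dataset)
  need <- unique(c(spec$response, unname(.term_cols[spec$fixed])))
  miss <- setdiff(need, names(dataset))
  if (length(miss)) stop("dataset lacks column(s): ", paste(miss, collapse = ", "))

  # drop degenerate random terms
  grp_of <- function(rt) trimws(sub(".*\\|", "", gsub("[()]", "", rt)))
  random <- spec$random
  grp_cols <- vapply(random, grp_of, character(1))
  keep <- vapply(grp_cols, function(g)
    g %in% names(dataset) && length(unique(dataset[[g]])) >= 2, logical(1))
  if (spec$mode == "temporal" && !"zone" %in% names(dataset))
    stop("temporal specs require a 'zone' column")
  random <- random[keep]

  dataset <- dataset[complete.cases(dataset[, intersect(
    c(need, grp_cols[keep]), names(dataset)), drop = FALSE]), , drop = FALSE]
  n <- nrow(dataset)

  rhs_fixed <- if (length(spec$fixed)) unname(.term_cols[spec$fixed]) else "1"
  if (!length(random)) {
    fml <- as.formula(paste(spec$response, "~", paste(rhs_fixed, collapse = " + ")))
    fit <- lm(fml, data = dataset)
    beta <- coef(fit); se <- sqrt(diag(vcov(fit)))
    k <- length(beta) + 1
    ll <- as.numeric(logLik(fit))
    ic <- aicc(ll, k, n)
    coefs <- data.frame(term = names(beta), estimate = unname(beta),
                        se = unname(se), z = unname(beta / se),
                        p = 2 * pnorm(-abs(beta / se)), row.names = NULL)
    return(structure(list(spec = spec, name = spec_name(spec),
                          coefficients = coefs,
                          varcomp = data.frame(grp = character(), var1 = character(),
                                               var2 = character(), vcov = numeric(),
                                               sdcor = numeric()),
                          sigma = summary(fit)$sigma,
                          var_fixed = var(as.numeric(predict(fit))),
                          loglik = ll, k = k, n = n,
                          AIC = ic$aic, AICc = ic$aicc,
                          converged = TRUE, ranef = list()),
                     class = "fit_result"))
  }

  fml <- as.formula(paste(spec$response, "~",
                          paste(c(rhs_fixed, random), collapse = " + ")))
  fit_once <- function(optimizer) {
    suppressMessages(suppressWarnings(
      lme4::lmer(fml, data = dataset, REML = FALSE,
                 control = lme4::lmerControl(optimizer = optimizer,
                                             calc.derivs = FALSE))))
  }
  # a boundary ("singular") fit is a valid ML optimum (a variance or
  # correlation at its limit), not a convergence failure; only optimizer
  # errors and non-singularity warnings count as non-convergence
  is_converged <- function(f) {
    msgs <- f@optinfo$conv$lme4$messages
    opt_ok <- f@optinfo$conv$opt == 0
    msgs <- msgs[!grepl("singular", msgs, ignore.case = TRUE)]
    opt_ok && !length(msgs)
  }
  fit <- fit_once("nloptwrap")
  converged <- is_converged(fit)
  if (!converged) {
    fit2 <- fit_once("bobyqa")
    if (is_converged(fit2)) { fit <- fit2; converged <- TRUE }
  }
  singular <- lme4::isSingular(fit)

  ml_ll <- as.numeric(logLik(fit))
  k <- length(lme4::fixef(fit)) + length(lme4::getME(fit, "theta")) + 1
  ic <- aicc(ml_ll, k, n)

  rep_fit <- fit
  if (refit_reml && converged) {
    rep_fit <- suppressMessages(suppressWarnings(
      lme4::lmer(fml, data = dataset, REML = TRUE)))
  }
  beta <- lme4::fixef(rep_fit)
  se <- sqrt(diag(as.matrix(vcov(rep_fit))))
  vc <- as.data.frame(lme4::VarCorr(rep_fit))
  names(vc)[names(vc) == "grp"] <- "grp"
  X <- lme4::getME(rep_fit, "X")
  var_fixed <- var(as.numeric(X %*% beta))
  re <- lme4::ranef(rep_fit, condVar = FALSE)
  re <- lapply(re, function(d) { d <- as.data.frame(d); d$level <- rownames(d); d })

  structure(list(spec = spec, name = spec_name(spec),
                 coefficients = data.frame(
                   term = names(beta), estimate = unname(beta),
                   se = unname(se), z = unname(beta / se),
                   p = 2 * pnorm(-abs(beta / se)), row.names = NULL),
                 varcomp = vc,
                 sigma = stats::sigma(rep_fit),
                 var_fixed = var_fixed,
                 loglik = ml_ll, k = k, n = n,
                 AIC = ic$aic, AICc = ic$aicc,
                 converged = converged, singular = singular, ranef = re),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s\n  n = %d, k = %d, logLik = %.2f, AICc = %.2f, converged: %s\n",
              x$name, x$n, x$k, x$loglik, x$AICc, x$converged))
  print(x$coefficients, digits = 3)
  invisible(x)
}

# ---- selection ----------------------------------------------------------

#' Rank fitted candidates by AICc
#'
#' Non-converged fits are excluded (and reported). Weights are the usual
#' Akaike weights `exp(-delta/2) / sum(exp(-delta/2))`; exact AICc ties
#' are broken stably by model name.
#'
#' @param fits list of [fit_lmm()] results.
#' @return an object of class `selection_table`: a data.frame with
#'   `model`, `n`, `k`, `AICc`, `delta_AICc`, `weight` (and the excluded
#'   model names in the `"excluded"` attribute); the ranked fits are kept
#'   in the `"fits"` attribute.
#' @export
rank_models <- function(fits) {
  conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (!any(conv)) stop("no converged fits to rank")
  excluded <- vapply(fits[!conv], function(f) f$name, character(1))
  fits <- fits[conv]
  nm <- vapply(fits, function(f) f$name, character(1))
  a <- vapply(fits, function(f) f$AICc, numeric(1))
  ord <- order(a, nm, method = "radix")  # locale-independent tie-break
  fits <- fits[ord]; a <- a[ord]; nm <- nm[ord]
  delta <- a - a[1]
  w <- exp(-delta / 2); w <- w / sum(w)
  tab <- data.frame(model = nm,
                    n = vapply(fits, function(f) f$n, numeric(1)),
                    k = vapply(fits, function(f) f$k, numeric(1)),
                    AICc = a, delta_AICc = delta, weight = w)
  attr(tab, "fits") <- fits
  attr(tab, "excluded") <- excluded
  class(tab) <- c("selection_table", "data.frame")
  tab
}

#' @export
print.selection_table <- function(x, ...) {
  cat("Model selection (AICc):\n")
  print.data.frame(head(as.data.frame(x), 10), digits = 4, row.names = FALSE)
  if (nrow(x) > 10) cat("  ... ", nrow(x) - 10, " more model(s)\n", sep = "")
  invisible(x)
}

#' Marginal and conditional R-squared of a mixed-model fit
#'
#' Variance-component decomposition: the marginal R-squared is the share
#' of total variance explained by the fixed effects,
#' `var_fixed / (var_fixed + sum(random variances) + residual variance)`;
#' the conditional R-squared adds the random-effect variances to the
#' numerator. `var_fixed` is the variance of the fixed-effect linear
#' predictor over the dataset.
#'
#' @param fit a [fit_lmm()] result (or a list with `var_fixed`, `varcomp`,
#'   `sigma`).
#' @return list with `marginal` and `conditional`.
#' @export
nakagawa_r2 <- function(fit) {
  vc <- fit$varcomp
  ran <- if (nrow(vc)) sum(vc$vcov[vc$grp != "Residual" & is.na(vc$var2)]) else 0
  denom <- fit$var_fixed + ran + fit$sigma^2
  if (denom <= 0) stop("zero total variance")
  list(marginal = fit$var_fixed / denom,
       conditional = (fit$var_fixed + ran) / denom)
}

# ---- random-effect diagnostics -----------------------------------------

#' Zone slope-intercept correlation diagnostics
#'
#' For a fit with the correlated per-zone (intercept, decade slope)
#' structure, returns both the estimated correlation parameter from the
#' random-effect covariance matrix and the Pearson correlation of the
#' per-zone conditional modes (BLUPs), together with the per-zone table
#' behind the intercept-vs-slope scatter. A negative correlation means
#' zones holding larger animals trend smaller over decades and vice versa.
#' With fewer than 3 zones the empirical correlation is degenerate and
#' flagged unreliable.
#'
#' @param fit a [fit_lmm()] result from a temporal spec.
#' @return list with `model_rho`, `blup_rho`, `per_zone`
#'   (zone, intercept, slope), and `reliable`.
#' @export
random_effect_diagnostics <- function(fit) {
  if (!"zone" %in% names(fit$ranef))
    stop("fit lacks a per-zone random structure")
  rz <- fit$ranef$zone
  if (!"decade_bin_z" %in% names(rz))
    stop("fit lacks a random decade slope within zone")
  vc <- fit$varcomp
  rho_row <- vc[vc$grp == "zone" & !is.na(vc$var2), ]
  model_rho <- if (nrow(rho_row)) rho_row$sdcor[1] else NA_real_
  blup_rho <- if (nrow(rz) >= 2) cor(rz[["(Intercept)"]], rz[["decade_bin_z"]])
              else NA_real_
  list(model_rho = model_rho, blup_rho = blup_rho,
       per_zone = data.frame(zone = rz$level,
                             intercept = rz[["(Intercept)"]],
                             slope = rz[["decade_bin_z"]]),
       reliable = nrow(rz) >= 3)
}

#' Exploratory per-zone trends of size on decade
#'
#' Fits an independent OLS of the response on the decade bin index within
#' each zone (zones with fewer than two distinct decades are skipped) and
#' joins the zone's mean size, for the size-versus-trend scatter.
#'
#' @param dataset data.frame with `zone`, `decade_bin` and the response.
#' @param response response column (default `"body_mass"`).
#' @return data.frame with `zone`, `slope` (response units per decade
#'   bin), `mean_size`, `n`, and `skipped` zones in an attribute.
#' @export
fit_per_zone_trends <- function(dataset, response = "body_mass") {
  zones <- unique(dataset$zone)
  rows <- list(); skipped <- character()
  for (z in zones) {
    d <- dataset[dataset$zone == z & !is.na(dataset[[response]]), ]
    if (length(unique(d$decade_bin)) < 2) { skipped <- c(skipped, z); next }
    fit <- lm(d[[response]] ~ d$decade_bin)
    rows[[length(rows) + 1]] <- data.frame(
      zone = z, slope = unname(coef(fit)[2]),
      mean_size = mean(d[[response]]), n = nrow(d))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(zone = character(), slope = numeric(),
               mean_size = numeric(), n = integer())
  attr(out, "skipped") <- skipped
  out
}
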