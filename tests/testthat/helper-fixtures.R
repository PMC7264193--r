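# Shared fixtures and independent oracles for the test suite.

# minimal record data.frame with sensible defaults, overridable per column
make_records <- function(n, ...) {
  base <- data.frame(
    record_id = sprintf("r%03d", seq_len(n)),
    source = rep("VertNet", n),
    decimalLongitude = rep(-100, n),
    decimalLatitude = rep(40, n),
    year = rep(1960L, n), month = rep(6L, n), day = rep(15L, n),
    sex = rep("female", n), life_stage = rep("adult", n),
    body_mass = rep(20, n), total_length = rep(155, n),
    tail_length = rep(65, n),
    stringsAsFactors = FALSE)
  override <- list(...)
  for (nm in names(override)) base[[nm]] <- override[[nm]]
  base
}

# constant-valued raster stack fixture
const_stack <- function(value, variable = "MAT", units = "degC",
                        origin = c(-110, 35), cellsize = 1,
                        ny = 10, nx = 10, times = 1960L) {
  raster_stack(variable, units, origin, cellsize, times,
               lapply(times, function(t) matrix(value, ny, nx)))
}

# a small simulated bundle, cached across test files for speed
cached_bundle <- local({
  cache <- list()
  function(seed = 101, n = 6000, truth = list()) {
    key <- paste0(seed, "_", n, "_", paste(names(truth), unlist(truth),
                                           collapse = "_"))
    if (is.null(cache[[key]])) {
      cache[[key]] <<- simulate_bundle(list(seed = seed, n = n, truth = truth))
    }
    cache[[key]]
  }
})

# ---- independent oracles ------------------------------------------------

# OLS via explicit normal equations (closed form, no lm())
ols_normal_eq <- function(x, y) {
  X <- cbind(1, x)
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# Gaussian LMM log-likelihood for y ~ X beta + (1|g), beta profiled out by
# GLS, at given variance components (brute-force oracle for tiny fixtures)
lmm_loglik_at <- function(y, X, g, sigma2_g, sigma2_e) {
  n <- length(y)
  Z <- outer(g, sort(unique(g)), `==`) * 1
  V <- sigma2_g * Z %*% t(Z) + sigma2_e * diag(n)
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  as.numeric(-0.5 * (determinant(V)$modulus + n * log(2 * pi) +
                       t(r) %*% Vi %*% r))
}

# two-stage grid search maximizing the oracle likelihood
lmm_grid_oracle <- function(y, X, g, sg_range = c(0.01, 6),
                            se_range = c(0.05, 6)) {
  best <- c(NA, NA, -Inf)
  search <- function(sgs, ses) {
    for (sg in sgs) for (se in ses) {
      ll <- lmm_loglik_at(y, X, g, sg^2, se^2)
      if (ll > best[3]) best <<- c(sg, se, ll)
    }
  }
  search(seq(sg_range[1], sg_range[2], length.out = 60),
         seq(se_range[1], se_range[2], length.out = 60))
  for (shrink in c(10, 100, 1000)) {
    w_sg <- diff(sg_range) / shrink; w_se <- diff(se_range) / shrink
    search(seq(max(1e-6, best[1] - w_sg), best[1] + w_sg, length.out = 40),
           seq(max(1e-6, best[2] - w_se), best[2] + w_se, length.out = 40))
  }
  list(sigma_g = best[1], sigma_e = best[2], loglik = best[3])
}

# brute-force zonation oracle: enumerate cell placements on a fine lattice,
# keep qualifying ones, exhaustively maximize total records over
# non-overlapping subsets (small instances only)
zonation_lattice_oracle <- function(px, py, dec, L, crit, step = L / 8) {
  xs <- seq(min(px) - L, max(px), by = step)
  ys <- seq(min(py) - L, max(py), by = step)
  cand <- list()
  for (x0 in xs) for (y0 in ys) {
    inside <- px >= x0 & px < x0 + L & py >= y0 & py < y0 + L
    if (cell_satisfies(dec[inside], crit$min_total, crit$min_decades,
                       crit$min_per_decade)) {
      cand[[length(cand) + 1]] <- c(x0, y0, sum(inside))
    }
  }
  if (!length(cand)) return(list(total = 0, cells = NULL))
  cand <- do.call(rbind, cand)
  # exhaustive search over non-overlapping subsets via recursion with
  # pruning (candidate sets here are small by construction)
  ord <- order(-cand[, 3])
  cand <- cand[ord, , drop = FALSE]
  m <- nrow(cand)
  overlaps <- function(a, b) {
    cand[a, 1] < cand[b, 1] + L && cand[a, 1] + L > cand[b, 1] &&
      cand[a, 2] < cand[b, 2] + L && cand[a, 2] + L > cand[b, 2]
  }
  best <- 0
  recurse <- function(i, chosen, total) {
    if (i > m) { best <<- max(best, total); return() }
    if (total + sum(cand[i:m, 3]) <= best) return()
    ok <- !length(chosen) || !any(vapply(chosen, overlaps, logical(1), a = i))
    if (ok) recurse(i + 1, c(chosen, i), total + cand[i, 3])
    recurse(i + 1, chosen, total)
    invisible()
  }
  recurse(1, integer(), 0)
  list(total = best, cells = cand)
}

# independent season oracle via R Date arithmetic in a fixed leap year
season_oracle <- function(month, day) {
  d <- as.Date(sprintf("2020-%02d-%02d", month, day))
  b <- function(s) as.Date(paste0("2020-", s))
  ifelse(d >= b("03-20") & d <= b("06-20"), "Spring",
  ifelse(d >= b("06-21") & d <= b("09-21"), "Summer",
  ifelse(d >= b("09-22") & d <= b("12-20"), "Fall", "Winter")))
}
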