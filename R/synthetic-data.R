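#' Simulation configuration
#'
#' Bundles every knob of the synthetic survey-and-environment generator.
#' Defaults emulate the real survey programme's conditions: a 0.05-degree
#' grid, a September--May survey season, roadside-clustered sampling, and a
#' latent abundance model that is additive on the square-root scale (the
#' same scale the fitted GAM works on, so the generator's truth is exactly
#' the model's estimand).
#'
#' @param seed integer RNG seed; the generator is fully deterministic given
#'   the seed.
#' @param bbox numeric `c(lon_min, lon_max, lat_min, lat_max)` in degrees.
#' @param grid_step grid spacing in degrees (default 0.05).
#' @param date_range `c(start, end)` coercible to `Date`; daily weather is
#'   generated for every day in this range.
#' @param n_surveys number of survey records to generate.
#' @param season_only if `TRUE`, survey dates are restricted to the austral
#'   spring--autumn season (September to May).
#' @param roadside_bias in `[0, 1]`: fraction of surveys clustered along
#'   synthetic road transects (points at roughly 10 km spacing) rather than
#'   placed uniformly.
#' @param true_effects named list of functions; each maps a covariate value
#'   to its additive contribution to the latent square-root-scale abundance.
#'   Names may be any of `lon`, `lat`, `doy`, `ndvi`, `tmax`, `tmin`,
#'   `rain`, `vp`, `rad` (weather/NDVI are the same-day, nearest-cell
#'   values).
#' @param eta0 baseline (intercept) of the latent square-root abundance.
#'   The default is calibrated so that roughly a third of surveys observe
#'   locusts under the default effects.
#' @param eta_floor positive floor applied to the latent predictor before
#'   squaring (the square-root link requires a positive mean).
#' @param spatial_amp amplitude of the smooth latent spatial field.
#' @param seasonal_amp amplitude of the latent seasonal (day-of-year) cycle.
#' @param nb_dispersion negative binomial size parameter `theta` of the
#'   realized counts.
#' @param detection_prob probability that locusts present at a site are
#'   detected by the drive-by survey; a detection failure records an
#'   absence (class 0). 1 means perfect detection; lower values inflate
#'   recorded absences with covariate-independent noise, the way roadside
#'   surveys of mobile insects do.
#' @param p_nymph probability that a positive survey records nymphs rather
#'   than adults.
#' @param ar1_phi lag-1 autocorrelation of daily weather anomalies.
#' @param min_history_days surveys are dated at least this many days after
#'   the weather record starts, so long-window covariates are computable.
#' @param class_scheme a [density_class_scheme()] used to bin realized
#'   densities.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              bbox = c(142, 144, -32, -30),
                              grid_step = 0.05,
                              date_range = c("2009-07-01", "2010-06-30"),
                              n_surveys = 2000L,
                              season_only = TRUE,
                              roadside_bias = 0.7,
                              true_effects = default_true_effects(),
                              eta0 = 0.52,
                              eta_floor = 0.05,
                              spatial_amp = 0.3,
                              seasonal_amp = 0.25,
                              nb_dispersion = 1.0,
                              detection_prob = 1.0,
                              p_nymph = 0.125,
                              ar1_phi = 0.8,
                              min_history_days = 60L,
                              class_scheme = default_class_scheme()) {
  stopifnot(grid_step > 0, bbox[1] < bbox[2], bbox[3] < bbox[4],
            n_surveys >= 1, nb_dispersion > 0,
            roadside_bias >= 0, roadside_bias <= 1,
            detection_prob > 0, detection_prob <= 1,
            eta_floor > 0, abs(ar1_phi) < 1,
            inherits(class_scheme, "density_class_scheme"))
  date_range <- as.Date(date_range)
  stopifnot(length(date_range) == 2, date_range[1] <= date_range[2])
  structure(list(
    seed = as.integer(seed), bbox = bbox, grid_step = grid_step,
    date_range = date_range, n_surveys = as.integer(n_surveys),
    season_only = isTRUE(season_only), roadside_bias = roadside_bias,
    true_effects = true_effects, eta0 = eta0, eta_floor = eta_floor,
    spatial_amp = spatial_amp, seasonal_amp = seasonal_amp,
    nb_dispersion = nb_dispersion, detection_prob = detection_prob,
    p_nymph = p_nymph, ar1_phi = ar1_phi,
    min_history_days = as.integer(min_history_days),
    class_scheme = class_scheme
  ), class = "simulation_config")
}

#' Default latent covariate effects
#'
#' Mild, smooth dependencies of latent abundance on greenness and recent
#' rain; used by [simulation_config()] unless overridden.
#' @return named list of functions.
#' @export
default_true_effects <- function() {
  list(
    ndvi = function(v) 1.6 * (v - 0.35),
    rain = function(v) 0.05 * (pmin(v, 10) - 2)
  )
}

# Smooth a nlat x nlon matrix with a separable Gaussian kernel (sd in cells).
gaussian_smooth_matrix <- function(m, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  pad_apply <- function(mat) {
    n <- nrow(mat)
    idx <- pmin(pmax(seq_len(n + 2 * half) - half, 1L), n)  # replicate edges
    padded <- mat[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(mat))
    for (i in seq_along(k)) {
      out <- out + k[i] * padded[(i - 1) + seq_len(n), , drop = FALSE]
    }
    out
  }
  t(pad_apply(t(pad_apply(m))))
}

# Spatially smooth unit-variance random field over the grid, as a vector in
# cell order (lon varying fastest).
smooth_field <- function(nlon, nlat, sigma = 3) {
  m <- gaussian_smooth_matrix(matrix(stats::rnorm(nlat * nlon), nlat, nlon),
                              sigma)
  m <- m / stats::sd(m)
  as.vector(t(m))  # row = lat, transpose so lon varies fastest
}

# AR(1) anomaly stack: ncell x ndays, unit marginal variance, spatially
# smooth innovations.
ar1_anomalies <- function(nlon, nlat, ndays, phi, sigma = 3) {
  ncell <- nlon * nlat
  a <- matrix(0, ncell, ndays)
  a[, 1] <- smooth_field(nlon, nlat, sigma)
  w <- sqrt(1 - phi^2)
  for (t in seq_len(ndays)[-1]) {
    a[, t] <- phi * a[, t - 1] + w * smooth_field(nlon, nlat, sigma)
  }
  a
}

day_of_year <- function(dates) as.integer(format(dates, "%j"))

# Austral seasonal shape: peaks mid-January, minimum mid-July.
austral_cycle <- function(doy) cos(2 * pi * (doy - 15) / 365.25)

#' Generate a synthetic environmental grid
#'
#' Produces a regular lon/lat grid of daily weather (maximum and minimum
#' temperature, rain, vapour pressure, solar radiation), monthly NDVI and
#' static soil fractions with the statistical structure the analysis
#' assumes: spatially smooth fields, AR(1) day-to-day persistence around a
#' seasonal cycle, zero-inflated rain (majority of days dry), vapour
#' pressure coupled to minimum temperature, and radiation depressed on wet
#' days.
#'
#' @param config a [simulation_config()].
#' @return an object of class `env_grid`: list with coordinate vectors
#'   `lons`, `lats`, daily `dates`, monthly `months`, matrices
#'   `tmax`, `tmin`, `rain`, `vp`, `rad` (cell x day), `ndvi`
#'   (cell x month), and static vectors `clay`, `sand`, `silt`. Cells are
#'   ordered with longitude varying fastest.
#' @export
generate_env_grid <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  lons <- seq(config$bbox[1], config$bbox[2], by = config$grid_step)
  lats <- seq(config$bbox[3], config$bbox[4], by = config$grid_step)
  if (length(lons) < 1 || length(lats) < 1) stop("degenerate bbox: no cells")
  nlon <- length(lons); nlat <- length(lats); ncell <- nlon * nlat
  dates <- seq(config$date_range[1], config$date_range[2], by = "day")
  ndays <- length(dates)
  doy <- day_of_year(dates)
  phi <- config$ar1_phi

  set.seed(config$seed)
  base_t <- smooth_field(nlon, nlat)     # static spatial structure
  base_g <- smooth_field(nlon, nlat)
  a_tmax <- ar1_anomalies(nlon, nlat, ndays, phi)
  a_gap  <- ar1_anomalies(nlon, nlat, ndays, phi)
  a_wet  <- ar1_anomalies(nlon, nlat, ndays, phi)
  a_amt  <- ar1_anomalies(nlon, nlat, ndays, phi)
  a_vp   <- ar1_anomalies(nlon, nlat, ndays, phi)
  a_rad  <- ar1_anomalies(nlon, nlat, ndays, phi)

  seas_t <- 27 + 8 * austral_cycle(doy)          # degC
  tmax <- sweep(4.5 * a_tmax, 2, seas_t, "+") + 1.5 * base_t
  gap <- pmax(9 + 2 * a_gap + 1.5 * base_g, 0.5) # diurnal range, > 0
  tmin <- tmax - gap

  p_wet <- 0.28 + 0.07 * austral_cycle(doy)      # wetter in summer
  wet <- sweep(stats::pnorm(a_wet), 2, 1 - p_wet, ">")
  # exponential-tail amounts, probability bounded away from 1 so daily
  # rain stays finite (caps near 37 mm)
  amount <- stats::qexp(pmin(stats::pnorm(a_amt), 0.998)) * 6
  rain <- ifelse(wet, amount, 0)

  vp <- pmax(6 + 0.55 * tmin + 1.5 * a_vp, 0.1)  # hPa, tracks tmin

  seas_r <- 19 + 9 * austral_cycle(doy)          # MJ/m^2
  rad <- pmax(sweep(2 * a_rad, 2, seas_r, "+") - 6 * wet, 0.1)

  months <- seq(as.Date(format(dates[1], "%Y-%m-01")),
                as.Date(format(dates[ndays], "%Y-%m-01")), by = "month")
  mdoy <- day_of_year(months) + 14
  ndvi_base <- smooth_field(nlon, nlat)
  ndvi <- sapply(seq_along(months), function(i) {
    f <- 0.37 + 0.10 * austral_cycle(mdoy[i]) + 0.12 * ndvi_base +
      0.06 * smooth_field(nlon, nlat)
    pmin(pmax(f, -0.2), 1)
  })

  sf <- cbind(smooth_field(nlon, nlat), smooth_field(nlon, nlat),
              smooth_field(nlon, nlat))
  e <- exp(0.8 * sf)
  # mineral-fraction total varies by cell and stays below 1
  total <- 0.75 + 0.15 * stats::plogis(smooth_field(nlon, nlat))
  frac <- total * e / rowSums(e)

  structure(list(
    lons = lons, lats = lats, dates = dates, months = months,
    tmax = tmax, tmin = tmin, rain = rain, vp = vp, rad = rad,
    ndvi = ndvi, clay = frac[, 1], sand = frac[, 2], silt = frac[, 3],
    ar1_phi = phi
  ), class = "env_grid")
}

# Points along random piecewise-linear transects, ~10 km apart.
transect_points <- function(n, bbox) {
  pts <- matrix(numeric(0), ncol = 2)
  while (nrow(pts) < n) {
    x0 <- stats::runif(1, bbox[1], bbox[2])
    y0 <- stats::runif(1, bbox[3], bbox[4])
    ang <- stats::runif(1, 0, pi)
    len <- stats::runif(1, 0.5, 1.5)
    s <- seq(0, len, by = 0.09)                  # ~10 km spacing
    px <- x0 + s * cos(ang) + stats::rnorm(length(s), 0, 0.005)
    py <- y0 + s * sin(ang) + stats::rnorm(length(s), 0, 0.005)
    keep <- px >= bbox[1] & px <= bbox[2] & py >= bbox[3] & py <= bbox[4]
    pts <- rbind(pts, cbind(px[keep], py[keep]))
  }
  pts[sample.int(nrow(pts), n, replace = n > nrow(pts)), , drop = FALSE]
}

#' Generate synthetic survey records
#'
#' Draws survey dates (September--May if `season_only`), locations (mixture
#' of roadside-transect clusters and uniform background), and realized
#' abundances from the latent model
#' `eta = eta0 + sum_j f_j(x_j) + spatial field + seasonal cycle`,
#' floored at `eta_floor`, with mean abundance `mu = eta^2` and negative
#' binomial counts with dispersion `nb_dispersion`. Realized densities are
#' binned into the ordinal class scheme; life stage is recorded for positive
#' surveys only.
#'
#' @param config a [simulation_config()].
#' @param env an `env_grid` from [generate_env_grid()] built from a config
#'   covering the same bbox and dates.
#' @return data frame with columns `id`, `date`, `lon`, `lat`, `stage`
#'   (`nymph`/`adult`/`none`), `density_class`, and the simulation-only
#'   hidden fields `true_density` and `true_eta`. Coordinates are recorded
#'   to 0.01 degrees.
#' @export
generate_surveys <- function(config, env) {
  stopifnot(inherits(config, "simulation_config"), inherits(env, "env_grid"))
  if (is.null(config$class_scheme)) stop("class scheme missing from config")
  n <- config$n_surveys
  set.seed(config$seed + 1L)

  ok <- env$dates >= (config$date_range[1] + config$min_history_days)
  if (config$season_only) {
    m <- as.integer(format(env$dates, "%m"))
    ok <- ok & (m >= 9 | m <= 5)
  }
  pool <- env$dates[ok]
  if (!length(pool)) stop("no eligible survey dates in range")
  dates <- sort(sample(pool, n, replace = TRUE))

  n_road <- round(config$roadside_bias * n)
  locs <- matrix(NA_real_, n, 2)
  if (n_road > 0) locs[seq_len(n_road), ] <- transect_points(n_road, config$bbox)
  if (n_road < n) {
    idx <- (n_road + 1):n
    locs[idx, 1] <- stats::runif(length(idx), config$bbox[1], config$bbox[2])
    locs[idx, 2] <- stats::runif(length(idx), config$bbox[3], config$bbox[4])
  }
  lon <- pmin(pmax(round(locs[, 1], 2), config$bbox[1]), config$bbox[2])
  lat <- pmin(pmax(round(locs[, 2], 2), config$bbox[3]), config$bbox[4])

  latent_field <- smooth_field(length(env$lons), length(env$lats))
  cell <- nearest_cell(env, lon, lat)
  doy <- day_of_year(dates)

  eta <- rep(config$eta0, n)
  for (nm in names(config$true_effects)) {
    f <- config$true_effects[[nm]]
    x <- switch(nm,
      lon = lon, lat = lat, doy = doy,
      ndvi = {
        mi <- month_index(env, dates)
        env$ndvi[cbind(cell, mi)]
      },
      {
        di <- match(dates, env$dates)
        env[[nm]][cbind(cell, di)]
      })
    eta <- eta + f(x)
  }
  eta <- eta + config$spatial_amp * latent_field[cell] +
    config$seasonal_amp * austral_cycle(doy)
  eta <- pmax(eta, config$eta_floor)

  mu <- eta^2
  dens <- stats::rnbinom(n, size = config$nb_dispersion, mu = mu)
  if (config$detection_prob < 1) {
    dens[stats::runif(n) > config$detection_prob] <- 0
  }
  cls <- bin_density(dens, config$class_scheme)
  stage <- ifelse(cls == 0L, "none",
                  ifelse(stats::runif(n) < config$p_nymph, "nymph", "adult"))

  data.frame(
    id = sprintf("S%06d", seq_len(n)),
    date = dates, lon = lon, lat = lat, stage = stage,
    density_class = cls, true_density = as.numeric(dens), true_eta = eta,
    stringsAsFactors = FALSE
  )
}

#' Write / read survey records as CSV
#'
#' ISO-8601 dates; lon/lat at 0.01-degree precision. The simulation-only
#' columns (`true_density`, `true_eta`) are kept if present.
#'
#' @param surveys survey data frame.
#' @param path CSV file path.
#' @return `read_surveys` returns the survey data frame.
#' @export
write_surveys <- function(surveys, path) {
  utils::write.csv(surveys, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_surveys
#' @export
read_surveys <- function(path) {
  s <- utils::read.csv(path, stringsAsFactors = FALSE)
  s$date <- as.Date(s$date)
  s
}
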