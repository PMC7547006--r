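#' Great-circle distance (haversine)
#'
#' Spherical-Earth haversine distance with radius 6371 km; at the 50-km
#' masking scale the ellipsoidal correction is below 0.3%.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in degrees (vectorized).
#' @return distance(s) in km.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  r <- pi / 180
  dlat <- (lat2 - lat1) * r / 2
  dlon <- (lon2 - lon1) * r / 2
  a <- sin(dlat)^2 + cos(lat1 * r) * cos(lat2 * r) * sin(dlon)^2
  2 * 6371 * asin(pmin(sqrt(a), 1))
}

#' Survey-proximity mask
#'
#' Estimates are only shown within `radius_km` (default 50 km) of a site
#' that was surveyed at some time; a cell is masked when its great-circle
#' distance to the nearest ever-surveyed site exceeds the radius.
#'
#' @param cell_lon,cell_lat cell-centre coordinates.
#' @param site_lon,site_lat ever-surveyed site coordinates (non-empty).
#' @param radius_km mask radius in km.
#' @return logical vector, `TRUE` where the cell is masked (too far).
#' @export
proximity_mask <- function(cell_lon, cell_lat, site_lon, site_lat,
                           radius_km = 50) {
  if (!length(site_lon)) stop("no surveyed sites supplied")
  dmin <- rep(Inf, length(cell_lon))
  for (chunk in split(seq_along(site_lon),
                      ceiling(seq_along(site_lon) / 200))) {
    for (s in chunk) {
      d <- haversine_km(cell_lon, cell_lat, site_lon[s], site_lat[s])
      dmin <- pmin(dmin, d)
    }
    if (all(dmin <= radius_km)) break
  }
  dmin > radius_km
}

# Class-sampling variance per positive class code, by Monte Carlo.
class_sampling_variance <- function(scheme, n_draws, seed = 1) {
  codes <- scheme$code[scheme$code > 0]
  v <- setNames(numeric(length(codes) + 1), c(0, codes))
  if (n_draws > 1) {
    set.seed(seed)
    for (cc in codes) {
      v[as.character(cc)] <- stats::var(sample_density(rep(cc, n_draws),
                                                       scheme))
    }
  }
  v
}

#' Predict abundance on the environmental grid for one date
#'
#' Engineers the per-cell covariates exactly as for surveys (same rolling
#' windows, threshold counts, NDVI month, soils, daylength), predicts with
#' the fitted GAM, back-transforms to the density scale, and attaches a
#' combined uncertainty: delta-method model variance through the link (and
#' the sixth-root back-transform when active) plus the class-sampling
#' variance of the ordinal-to-continuous conversion at the predicted
#' class, estimated by Monte Carlo. Cells with negative NDVI (or otherwise
#' unengineerable covariates) carry `NA` estimates and are masked.
#'
#' @param model an `abundance_gam`.
#' @param env an `env_grid` covering the 60-day history before `date`.
#' @param date prediction date.
#' @param scheme the [density_class_scheme()] used for the sampling-
#'   variance term.
#' @param n_uncertainty_draws Monte Carlo draws per class (default 200;
#'   0 disables the sampling-variance term).
#' @param surveyed_sites optional data frame with `lon`, `lat` of all
#'   ever-surveyed sites, enabling the 50-km proximity mask.
#' @param radius_km proximity-mask radius.
#' @param seed seed for the Monte Carlo draws.
#' @return a `prediction_grid` data frame: `date`, `lon`, `lat`, `eta`,
#'   `se_eta`, `estimate` (individuals/m^2), `var_model`, `var_sampling`,
#'   `uncertainty_fraction`, `masked`.
#' @export
predict_grid <- function(model, env, date, scheme = default_class_scheme(),
                         n_uncertainty_draws = 200, surveyed_sites = NULL,
                         radius_km = 50, seed = 1) {
  stopifnot(inherits(model, "abundance_gam"), inherits(env, "env_grid"))
  date <- as.Date(date)
  di <- match(date, env$dates)
  if (is.na(di) || di <= 60) {
    stop("environment does not cover the 60-day history before ", date)
  }
  cells <- expand.grid(lon = env$lons, lat = env$lats)  # lon fastest
  pseudo <- data.frame(
    id = sprintf("C%06d", seq_len(nrow(cells))),
    date = date, lon = cells$lon, lat = cells$lat, stage = "none",
    density_class = 0L, sampled_density = 0, stringsAsFactors = FALSE
  )
  ft <- build_feature_table(pseudo, env,
                            lambda = if (is.null(model$lambda)) 1 / 6
                                     else model$lambda)
  pr <- predict_abundance(model, ft)

  lambda <- if (is.null(model$lambda)) 1 / 6 else model$lambda
  eta <- pr$eta; se <- pr$se_eta
  if (model$response_scale == "sixth_root") {
    # estimate = (eta^2)^(1/lambda); d/d eta = (2/lambda) * eta^(2/lambda - 1)
    est <- pmax(eta, 0)^(2 / lambda)
    deriv <- (2 / lambda) * pmax(eta, 0)^(2 / lambda - 1)
  } else {
    est <- eta^2
    deriv <- 2 * eta
  }
  var_model <- (deriv * se)^2
  cls <- bin_density(pmax(est, 0), scheme)
  cls_var <- class_sampling_variance(scheme,
                                     if (n_uncertainty_draws > 0)
                                       n_uncertainty_draws else 0,
                                     seed = seed)
  var_sampling <- unname(cls_var[as.character(cls)])
  total <- var_model + var_sampling
  ufrac <- ifelse(est > 0, sqrt(total) / est, ifelse(total == 0, 0, Inf))

  out <- data.frame(date = date, lon = cells$lon, lat = cells$lat,
                    eta = NA_real_, se_eta = NA_real_, estimate = NA_real_,
                    var_model = NA_real_, var_sampling = NA_real_,
                    uncertainty_fraction = NA_real_, masked = TRUE)
  ok <- match(ft$id, pseudo$id)   # rows retained by covariate engineering
  out$eta[ok] <- eta; out$se_eta[ok] <- se
  out$estimate[ok] <- est
  out$var_model[ok] <- var_model; out$var_sampling[ok] <- var_sampling
  out$uncertainty_fraction[ok] <- ufrac
  out$masked[ok] <- FALSE
  if (!is.null(surveyed_sites)) {
    far <- proximity_mask(out$lon, out$lat,
                          surveyed_sites$lon, surveyed_sites$lat,
                          radius_km = radius_km)
    out$masked <- out$masked | far
  }
  class(out) <- c("prediction_grid", class(out))
  out
}

# Blended blue x yellow bivariate palette: density drives blue, relative
# uncertainty drives yellow; both high blends to grey.
bivariate_palette <- function(n_bins = 3) {
  pal <- matrix("", n_bins, n_bins)
  for (d in seq_len(n_bins)) {
    for (u in seq_len(n_bins)) {
      fd <- (d - 1) / (n_bins - 1)
      fu <- (u - 1) / (n_bins - 1)
      blue <- c(0.10, 0.45, 0.85)
      yellow <- c(0.95, 0.85, 0.10)
      base <- c(0.92, 0.92, 0.92)
      col <- base * (1 - fd) * (1 - fu) + blue * fd * (1 - fu) +
        yellow * fu * (1 - fd) + (blue + yellow) / 2 * fd * fu
      pal[d, u] <- grDevices::rgb(col[1], col[2], col[3])
    }
  }
  pal
}

#' Bivariate density/uncertainty classification
#'
#' Bins the abundance estimate and the uncertainty fraction of unmasked
#' cells into terciles (or `n_bins`-tiles) and assigns each cell a
#' `(density_bin, uncertainty_bin)` class for a bivariate map: bright blue
#' = high density, low uncertainty; bright yellow = low density, high
#' uncertainty; grey blend = high on both. Masked cells carry no class.
#'
#' @param grid a `prediction_grid`.
#' @param n_bins bins per axis (default 3).
#' @return the grid with `density_bin`, `uncertainty_bin` and `class_index`
#'   (`(density_bin - 1) * n_bins + uncertainty_bin`) columns; attributes
#'   `palette` (n_bins x n_bins hex matrix), `density_edges`,
#'   `uncertainty_edges`.
#' @export
bivariate_classify <- function(grid, n_bins = 3) {
  un <- !grid$masked & is.finite(grid$estimate) &
    is.finite(grid$uncertainty_fraction)
  if (sum(un) < n_bins^2) stop("fewer unmasked cells than classes")
  tile <- function(x) {
    probs <- seq(0, 1, length.out = n_bins + 1)
    edges <- unique(stats::quantile(x, probs, names = FALSE))
    if (length(edges) < 3) {
      warning("near-constant field; falling back to a single bin")
      return(list(bin = rep(1L, length(x)), edges = range(x)))
    }
    bin <- findInterval(x, edges, rightmost.closed = TRUE,
                        all.inside = TRUE)
    list(bin = bin, edges = edges)
  }
  dt <- tile(grid$estimate[un])
  ut <- tile(grid$uncertainty_fraction[un])
  grid$density_bin <- grid$uncertainty_bin <- NA_integer_
  grid$density_bin[un] <- dt$bin
  grid$uncertainty_bin[un] <- ut$bin
  grid$class_index <- (grid$density_bin - 1L) * n_bins + grid$uncertainty_bin
  attr(grid, "palette") <- bivariate_palette(n_bins)
  attr(grid, "density_edges") <- dt$edges
  attr(grid, "uncertainty_edges") <- ut$edges
  grid
}

#' Gridded RMSE of survey predictions
#'
#' Aggregates per-survey residuals (on the transformed response scale)
#' into coarse cells and reports each cell's RMSE, exposing where the
#' model performs worst.
#'
#' @param surveys data frame with `lon`, `lat`, `observed`, `predicted`.
#' @param cell_size_deg cell size in degrees (default 0.5).
#' @return data frame `cell_lon`, `cell_lat` (cell centres), `n`, `rmse`.
#' @export
rmse_map <- function(surveys, cell_size_deg = 0.5) {
  stopifnot(all(c("lon", "lat", "observed", "predicted") %in%
                  names(surveys)))
  cx <- floor(surveys$lon / cell_size_deg)
  cy <- floor(surveys$lat / cell_size_deg)
  key <- paste(cx, cy)
  parts <- split(seq_len(nrow(surveys)), key)
  rows <- lapply(parts, function(i) {
    data.frame(cell_lon = (cx[i][1] + 0.5) * cell_size_deg,
               cell_lat = (cy[i][1] + 0.5) * cell_size_deg,
               n = length(i),
               rmse = sqrt(mean((surveys$predicted[i] -
                                   surveys$observed[i])^2)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$cell_lat, out$cell_lon), ]
}
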