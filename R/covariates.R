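# Nearest index on a regular sorted coordinate vector; ties toward the
# lower index.
nearest_index <- function(grid, x) {
  i <- findInterval(x, grid, all.inside = TRUE)
  d_lo <- abs(x - grid[i])
  d_hi <- abs(grid[i + 1] - x)
  out <- ifelse(d_hi < d_lo, i + 1L, i)  # tie (d_hi == d_lo) keeps lower i
  as.integer(out)
}

# Cell index (lon varying fastest) of the nearest grid-cell centre.
nearest_cell <- function(env, lon, lat) {
  step <- env$lons[2] - env$lons[1]
  if (any(lon < env$lons[1] - step / 2 - 1e-9) ||
      any(lon > env$lons[length(env$lons)] + step / 2 + 1e-9) ||
      any(lat < env$lats[1] - step / 2 - 1e-9) ||
      any(lat > env$lats[length(env$lats)] + step / 2 + 1e-9)) {
    stop("site outside grid bounds")
  }
  i <- nearest_index(env$lons, lon)
  j <- nearest_index(env$lats, lat)
  (j - 1L) * length(env$lons) + i
}

# Index into env$months for the calendar month containing each date.
month_index <- function(env, dates) {
  m <- as.Date(format(as.Date(dates), "%Y-%m-01"))
  idx <- match(m, env$months)
  if (anyNA(idx)) stop("date outside NDVI month range")
  idx
}

#' Extract environment values at a survey site and date
#'
#' Values are taken from the grid cell whose centre is nearest to the site
#' (Euclidean in degrees on the regular grid; ties broken toward the lower
#' index). NDVI comes from the calendar month containing the date; soil
#' fractions are static.
#'
#' @param env an `env_grid`.
#' @param lon,lat site coordinates (degrees); must lie within the grid.
#' @param date the survey date.
#' @return one-row data frame: `tmax`, `tmin`, `rain`, `vp`, `rad`, `ndvi`,
#'   `clay`, `sand`, `silt`.
#' @export
extract_at_site <- function(env, lon, lat, date) {
  date <- as.Date(date)
  cell <- nearest_cell(env, lon, lat)
  di <- match(date, env$dates)
  if (anyNA(di)) stop("date outside environment date range")
  mi <- month_index(env, date)
  data.frame(
    tmax = env$tmax[cbind(cell, di)], tmin = env$tmin[cbind(cell, di)],
    rain = env$rain[cbind(cell, di)], vp = env$vp[cbind(cell, di)],
    rad = env$rad[cbind(cell, di)],
    ndvi = env$ndvi[cbind(cell, mi)],
    clay = env$clay[cell], sand = env$sand[cell], silt = env$silt[cell]
  )
}

#' Rolling-window statistic of a daily series
#'
#' The memory window is inclusive of the survey date: a 10-day window
#' ending 15 March spans 5--15 March, i.e. `length + 1` daily values.
#' Advancing the survey date by one day shifts the window by one day.
#'
#' @param values daily values aligned with `dates`.
#' @param dates `Date` vector (consecutive days).
#' @param survey_date date the window ends on.
#' @param window_length window length in days (10 or 60).
#' @param stat one of `"min"`, `"max"`, `"mean"`.
#' @return the statistic over the `window_length + 1` values.
#' @export
window_stat <- function(values, dates, survey_date, window_length,
                        stat = c("mean", "min", "max")) {
  stat <- match.arg(stat)
  survey_date <- as.Date(survey_date)
  i <- match(survey_date, dates)
  if (is.na(i) || i - window_length < 1) {
    stop("insufficient history for window ending ", survey_date)
  }
  w <- values[(i - window_length):i]
  switch(stat, mean = mean(w), min = min(w), max = max(w))
}

#' Threshold specification for count covariates
#'
#' @param dry_rain_threshold rain at or below this (mm) counts as a dry day.
#' @param cold_tmin_threshold days with minimum below this (degC) are counted.
#' @param hot_tmax_threshold days with maximum above this (degC) are counted.
#' @return a named list.
#' @export
threshold_spec <- function(dry_rain_threshold = 0.0,
                           cold_tmin_threshold = 18,
                           hot_tmax_threshold = 42) {
  stopifnot(is.finite(dry_rain_threshold), is.finite(cold_tmin_threshold),
            is.finite(hot_tmax_threshold))
  list(dry_rain_threshold = dry_rain_threshold,
       cold_tmin_threshold = cold_tmin_threshold,
       hot_tmax_threshold = hot_tmax_threshold)
}

#' Threshold-day counts over a memory window
#'
#' Counts, over the inclusive window ending on the survey date, the days
#' with no rainfall (dry days), with minimum temperature below 18 degC, and
#' with maximum temperature above 42 degC (default thresholds adapted from
#' locust ecophysiology).
#'
#' @param tmin,tmax,rain daily series aligned with `dates`.
#' @param dates `Date` vector.
#' @param survey_date window end date.
#' @param window_length window length in days.
#' @param spec a [threshold_spec()].
#' @return named vector `c(dry_days, days_below18, days_above42)`, each in
#'   `[0, window_length + 1]`.
#' @export
threshold_counts <- function(tmin, tmax, rain, dates, survey_date,
                             window_length, spec = threshold_spec()) {
  survey_date <- as.Date(survey_date)
  i <- match(survey_date, dates)
  if (is.na(i) || i - window_length < 1) {
    stop("insufficient history for window ending ", survey_date)
  }
  idx <- (i - window_length):i
  c(dry_days = sum(rain[idx] <= spec$dry_rain_threshold),
    days_below18 = sum(tmin[idx] < spec$cold_tmin_threshold),
    days_above42 = sum(tmax[idx] > spec$hot_tmax_threshold))
}

#' Astronomical daylength
#'
#' Daylength in hours from the standard solar declination / hour-angle
#' formula with declination `-23.44 * cos(2*pi*(doy + 10)/365)` degrees.
#' Valid equatorward of the polar circles.
#'
#' @param lat latitude in degrees, `|lat| < 66.5`.
#' @param doy day of year (1--366).
#' @return daylength in hours, in (0, 24).
#' @export
daylength <- function(lat, doy) {
  if (any(abs(lat) >= 66.5)) {
    stop("polar latitudes are outside the supported region")
  }
  decl <- -23.44 * cos(2 * pi * (doy + 10) / 365) * pi / 180
  h <- acos(pmin(pmax(-tan(lat * pi / 180) * tan(decl), -1), 1))
  24 * h / pi
}

#' Covariate catalog
#'
#' The canonical naming and bookkeeping of engineered covariates:
#' 39 candidates = 5 weather variables x 2 windows (10/60 d) x 3 statistics
#' (min/max/mean) minus the 2 rain minima (always ~0) + 6 threshold counts
#' + NDVI + daylength + 3 soil fractions. The full model removes 12
#' candidates (all tmin summaries, both rain maxima, the 10-day tmax
#' min/max, both dry-day counts), leaving 27; the reduced model keeps 10
#' covariates of particular importance or ecological interest. The space--
#' time coordinates (`lon`, `lat`, `doy`) enter the GAM's tensor separately,
#' giving the full model 30 variables in all.
#'
#' @return list with character vectors `candidates` (39), `excluded` (12),
#'   `full` (27), `reduced` (10), and `tensor` (3).
#' @export
covariate_catalog <- function() {
  vars <- c("tmax", "tmin", "rain", "vp", "rad")
  stats_ <- c("min", "max", "mean")
  wins <- c(10, 60)
  grid <- expand.grid(stat = stats_, win = wins, var = vars,
                      stringsAsFactors = FALSE)
  weather <- sprintf("%s_%s_%dd", grid$var, grid$stat, grid$win)
  weather <- setdiff(weather, c("rain_min_10d", "rain_min_60d"))
  counts <- c(t(outer(c("dry_days", "days_below18", "days_above42"),
                      wins, function(a, b) sprintf("%s_%dd", a, b))))
  candidates <- c(weather, counts, "ndvi", "daylength_h",
                  "clay", "sand", "silt")
  excluded <- c(sprintf("tmin_%s_10d", stats_), sprintf("tmin_%s_60d", stats_),
                "rain_max_10d", "rain_max_60d",
                "tmax_min_10d", "tmax_max_10d",
                "dry_days_10d", "dry_days_60d")
  reduced <- c("rain_mean_60d", "tmax_mean_60d", "days_above42_60d",
               "vp_mean_60d", "vp_max_60d", "vp_mean_10d", "rad_mean_10d",
               "daylength_h", "ndvi", "sand")
  list(candidates = candidates, excluded = excluded,
       full = setdiff(candidates, excluded), reduced = reduced,
       tensor = c("lon", "lat", "doy"))
}

#' Build the per-survey covariate table
#'
#' Engineers every candidate covariate for each survey: 10- and 60-day
#' min/max/mean of the five weather variables (rain minima omitted),
#' threshold-day counts for both windows, monthly NDVI, soil fractions and
#' daylength, all taken at the nearest grid cell; plus the unscaled
#' coordinates (`lon`, `lat`, `doy`) and the transformed response
#' `sampled_density^lambda`. Rows with insufficient weather history or with
#' negative NDVI are dropped, with counts recorded in the `drop_counts`
#' attribute.
#'
#' @param surveys survey data frame carrying a `sampled_density` column
#'   (see [add_sampled_density()]).
#' @param env an `env_grid` covering the surveys.
#' @param lambda response transform exponent (default 1/6).
#' @param thresholds a [threshold_spec()].
#' @param catalog a [covariate_catalog()].
#' @return a `feature_table` data frame: `id`, `date`, `stage`, `lon`,
#'   `lat`, `doy`, all 39 candidate covariates, `sampled_density`,
#'   `response`; attributes `drop_counts`, `lambda`, `catalog`.
#' @export
build_feature_table <- function(surveys, env, lambda = 1 / 6,
                                thresholds = threshold_spec(),
                                catalog = covariate_catalog()) {
  stopifnot(inherits(env, "env_grid"),
            "sampled_density" %in% names(surveys))
  n <- nrow(surveys)
  dates <- as.Date(surveys$date)
  di <- match(dates, env$dates)
  has_hist <- !is.na(di) & di > 60
  n_hist <- sum(!has_hist)

  s <- surveys[has_hist, , drop = FALSE]
  di <- di[has_hist]
  cell <- nearest_cell(env, s$lon, s$lat)
  mi <- month_index(env, s$date)
  ndvi <- env$ndvi[cbind(cell, mi)]
  neg_ndvi <- ndvi < 0
  n_ndvi <- sum(neg_ndvi)
  keep <- !neg_ndvi
  s <- s[keep, , drop = FALSE]; di <- di[keep]; cell <- cell[keep]
  ndvi <- ndvi[keep]
  if (!nrow(s)) stop("no surveys retained after history/NDVI filtering")

  wins <- c(10L, 60L)
  vars <- c("tmax", "tmin", "rain", "vp", "rad")
  m <- nrow(s)
  out <- list()
  for (v in vars) {
    field <- env[[v]]
    for (w in wins) {
      sl <- vapply(seq_len(m), function(r) {
        x <- field[cell[r], (di[r] - w):di[r]]
        c(min(x), max(x), mean(x))
      }, numeric(3))
      for (k in 1:3) {
        nm <- sprintf("%s_%s_%dd", v, c("min", "max", "mean")[k], w)
        if (nm %in% catalog$candidates) out[[nm]] <- sl[k, ]
      }
    }
  }
  for (w in wins) {
    cnt <- vapply(seq_len(m), function(r) {
      idx <- (di[r] - w):di[r]
      c(sum(env$rain[cell[r], idx] <= thresholds$dry_rain_threshold),
        sum(env$tmin[cell[r], idx] < thresholds$cold_tmin_threshold),
        sum(env$tmax[cell[r], idx] > thresholds$hot_tmax_threshold))
    }, numeric(3))
    out[[sprintf("dry_days_%dd", w)]] <- cnt[1, ]
    out[[sprintf("days_below18_%dd", w)]] <- cnt[2, ]
    out[[sprintf("days_above42_%dd", w)]] <- cnt[3, ]
  }
  doy <- day_of_year(as.Date(s$date))
  out$ndvi <- ndvi
  out$daylength_h <- daylength(s$lat, doy)
  out$clay <- env$clay[cell]
  out$sand <- env$sand[cell]
  out$silt <- env$silt[cell]

  tab <- cbind(
    data.frame(id = s$id, date = as.Date(s$date), stage = s$stage,
               lon = s$lon, lat = s$lat, doy = doy,
               stringsAsFactors = FALSE),
    as.data.frame(out[catalog$candidates])
  )
  tab$sampled_density <- s$sampled_density
  tab$response <- power_transform(s$sampled_density, lambda)
  attr(tab, "drop_counts") <- c(insufficient_history = n_hist,
                                negative_ndvi = n_ndvi)
  attr(tab, "lambda") <- lambda
  attr(tab, "catalog") <- catalog
  class(tab) <- c("feature_table", class(tab))
  tab
}

#' Standardize covariate columns using training-set statistics
#'
#' Centres and scales the named columns to training-set mean 0 and standard
#' deviation 1, as required by the GLM feature-selection stage (the GAM path
#' consumes unscaled covariates). Validation/holdout rows are scaled with
#' the *training* statistics, so their scaled means are not exactly 0. The
#' scaling record is stored for prediction-time reuse, and a second
#' application to an already-standardized table is refused.
#'
#' @param table a `feature_table`.
#' @param train logical vector (or row indices) marking training rows whose
#'   statistics define the scaling.
#' @param columns columns to scale (default: all catalog candidates).
#' @param scaling optional scaling record from a previous call, to apply the
#'   same transformation to new data.
#' @return the table with scaled columns and attribute `scaling`
#'   (data frame `column`, `mean`, `sd`).
#' @export
standardize_features <- function(table, train = seq_len(nrow(table)),
                                 columns = NULL, scaling = NULL) {
  if (!is.null(attr(table, "scaling"))) {
    stop("table is already standardized; refusing to scale twice")
  }
  if (is.null(columns)) {
    cat_ <- attr(table, "catalog")
    columns <- if (!is.null(cat_)) cat_$candidates else
      stop("no catalog attribute; supply `columns`")
  }
  if (is.null(scaling)) {
    tr <- table[train, columns, drop = FALSE]
    mu <- vapply(tr, mean, numeric(1))
    sdev <- vapply(tr, stats::sd, numeric(1))
    if (any(sdev == 0)) {
      stop("zero-variance column(s) in training set: ",
           paste(columns[sdev == 0], collapse = ", "))
    }
    scaling <- data.frame(column = columns, mean = mu, sd = sdev,
                          row.names = NULL, stringsAsFactors = FALSE)
  }
  for (k in seq_len(nrow(scaling))) {
    cn <- scaling$column[k]
    table[[cn]] <- (table[[cn]] - scaling$mean[k]) / scaling$sd[k]
  }
  attr(table, "scaling") <- scaling
  table
}

#' Write / read a feature table with its JSON sidecar
#'
#' The CSV holds the rows; the sidecar records the transform exponent, the
#' covariate catalog, drop counts and (if present) the scaling record.
#'
#' @param table a `feature_table`.
#' @param path CSV path; the sidecar is written to `paste0(path, ".json")`.
#' @return `read_feature_table` returns the table with attributes restored.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  meta <- list(lambda = attr(table, "lambda"),
               catalog = attr(table, "catalog"),
               drop_counts = as.list(attr(table, "drop_counts")),
               scaling = attr(table, "scaling"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$date <- as.Date(tab$date)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  attr(tab, "lambda") <- meta$lambda
  attr(tab, "catalog") <- lapply(meta$catalog, as.character)
  attr(tab, "drop_counts") <- unlist(meta$drop_counts)
  if (!is.null(meta$scaling)) attr(tab, "scaling") <- meta$scaling
  class(tab) <- c("feature_table", class(tab))
  tab
}
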