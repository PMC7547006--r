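make_series <- function(start = "2010-01-01", n = 120, seed = 1) {
  set.seed(seed)
  list(dates = seq(as.Date(start), by = "day", length.out = n),
       values = round(stats::rexp(n, 0.3), 1) * stats::rbinom(n, 1, 0.4))
}

test_that("memory window is inclusive: 10-day window ending 15 March spans 5-15 March", {
  s <- make_series()
  d <- as.Date("2010-03-15")
  idx <- s$dates >= as.Date("2010-03-05") & s$dates <= d
  expect_identical(sum(idx), 11L)
  expect_equal(window_stat(s$values, s$dates, d, 10, "mean"),
               mean(s$values[idx]))
  # constant series: every statistic returns the constant
  const <- rep(3.7, length(s$dates))
  for (st in c("min", "max", "mean")) {
    expect_equal(window_stat(const, s$dates, d, 60, st), 3.7)
  }
})

test_that("window statistics equal brute-force recomputation over random cases", {
  s <- make_series(n = 200, seed = 42)
  set.seed(43)
  for (i in 1:50) {
    w <- sample(c(10, 60), 1)
    d <- sample(s$dates[(w + 1):200], 1)
    st <- sample(c("min", "max", "mean"), 1)
    brute <- get(st)(s$values[which(s$dates == d) - (w:0)])
    expect_equal(window_stat(s$values, s$dates, d, w, st), brute)
  }
})

test_that("advancing the survey date by one day shifts the window by one day", {
  s <- make_series(n = 80, seed = 9)
  d <- as.Date("2010-02-20")
  i <- which(s$dates == d)
  m1 <- window_stat(s$values, s$dates, d, 10, "mean")
  m2 <- window_stat(s$values, s$dates, d + 1, 10, "mean")
  expect_equal(m2 - m1, (s$values[i + 1] - s$values[i - 10]) / 11)
  expect_error(window_stat(s$values, s$dates, s$dates[5], 10),
               "insufficient history")
})

test_that("threshold counts match their definitions and brute force", {
  n <- 80
  dates <- seq(as.Date("2010-01-01"), by = "day", length.out = n)
  # all dry over a 10-day window: inclusive count is 11
  cnt <- threshold_counts(rep(10, n), rep(30, n), rep(0, n), dates,
                          dates[40], 10)
  expect_identical(unname(cnt["dry_days"]), 11L)
  # exactly 3 days at 43 degrees in the long window
  tmax <- rep(30, n); tmax[c(12, 30, 55)] <- 43
  cnt <- threshold_counts(rep(20, n), tmax, rep(1, n), dates, dates[65], 60)
  expect_identical(unname(cnt["days_above42"]), 3L)
  set.seed(7)
  tmin <- stats::runif(n, 5, 25); tmax <- tmin + stats::runif(n, 1, 25)
  rain <- stats::rexp(n) * stats::rbinom(n, 1, 0.3)
  for (w in c(10, 60)) {
    idx <- (65 - w):65
    brute <- c(sum(rain[idx] <= 0), sum(tmin[idx] < 18), sum(tmax[idx] > 42))
    cnt <- threshold_counts(tmin, tmax, rain, dates, dates[65], w)
    expect_identical(unname(cnt), brute)
    expect_true(all(cnt >= 0 & cnt <= w + 1))
  }
})

test_that("site extraction uses the nearest cell centre, ties toward lower index", {
  env <- shared_env()
  # exactly at a centre
  v <- extract_at_site(env, env$lons[4], env$lats[6], env$dates[100])
  expect_equal(v$tmax, env$tmax[(6 - 1) * length(env$lons) + 4, 100])
  # 0.026 degrees east of a centre with 0.05 spacing: next cell east
  v2 <- extract_at_site(env, env$lons[4] + 0.026, env$lats[6], env$dates[100])
  expect_equal(v2$tmax, env$tmax[(6 - 1) * length(env$lons) + 5, 100])
  # midway ties resolve to the lower-index cell (dyadic grid: exact halves)
  tiny <- list(lons = c(0, 0.5, 1), lats = c(0, 0.5, 1),
               dates = env$dates[1:3],
               months = env$months[1],
               tmax = matrix(1:27, 9, 3), tmin = matrix(0, 9, 3),
               rain = matrix(0, 9, 3), vp = matrix(1, 9, 3),
               rad = matrix(1, 9, 3), ndvi = matrix(0.5, 9, 1),
               clay = 1:9 / 10, sand = rep(0.1, 9), silt = rep(0.1, 9))
  class(tiny) <- "env_grid"
  v4 <- extract_at_site(tiny, 0.25, 0.25, tiny$dates[1])
  expect_equal(v4$tmax, tiny$tmax[1, 1])  # ties on both axes -> cell 1
  expect_error(extract_at_site(env, env$lons[1] - 1, env$lats[1],
                               env$dates[100]), "outside grid")
})

test_that("nearest-cell lookup matches exhaustive search on random sites", {
  env <- shared_env()
  centres <- expand.grid(lon = env$lons, lat = env$lats)
  set.seed(11)
  lon <- stats::runif(100, min(env$lons), max(env$lons))
  lat <- stats::runif(100, min(env$lats), max(env$lats))
  day <- env$dates[90]
  for (i in 1:100) {
    got <- extract_at_site(env, lon[i], lat[i], day)
    cell <- which.min((centres$lon - lon[i])^2 + (centres$lat - lat[i])^2)
    expect_equal(got$tmax, env$tmax[cell, 90])
    expect_equal(got$clay, env$clay[cell])
  }
})

test_that("daylength behaves like the astronomical formula", {
  expect_equal(daylength(0, 80), 12, tolerance = 0.2 / 12)
  expect_equal(daylength(0, 300), 12, tolerance = 0.2 / 12)
  # independent NOAA-declination oracle, austral summer solstice
  expect_equal(daylength(-35, 355), noaa_daylength(-35, 355),
               tolerance = 0.1 / 14)
  for (doy in c(1, 100, 200, 355)) {
    expect_equal(daylength(-35, doy) + daylength(35, doy), 24,
                 tolerance = 0.3 / 24)
  }
  expect_error(daylength(70, 100), "polar")
})

test_that("covariate catalog arithmetic matches the design", {
  cat_ <- covariate_catalog()
  expect_length(cat_$candidates, 39)
  expect_length(cat_$excluded, 12)
  expect_length(cat_$full, 27)
  expect_length(cat_$reduced, 10)
  expect_true(all(cat_$excluded %in% cat_$candidates))
  expect_true(all(cat_$reduced %in% cat_$full))
  expect_false(any(c("rain_min_10d", "rain_min_60d") %in% cat_$candidates))
  expect_length(c(cat_$full, cat_$tensor), 30)
})

test_that("feature table: negative-NDVI rows dropped, drop accounting balances", {
  env <- shared_env()
  sv <- utils::head(shared_surveys(), 100)
  set.seed(8)
  sv <- add_sampled_density(sv, default_class_scheme())
  ft0 <- build_feature_table(sv, env)
  base_drops <- attr(ft0, "drop_counts")
  # force negative NDVI for two retained surveys whose (cell, month) pair is
  # not shared by any other survey
  env2 <- env
  centres <- expand.grid(lon = env$lons, lat = env$lats)
  cell <- apply(cbind(sv$lon, sv$lat), 1, function(p) {
    which.min((centres$lon - p[1])^2 + (centres$lat - p[2])^2)
  })
  mo <- match(as.Date(format(sv$date, "%Y-%m-01")), env$months)
  key <- paste(cell, mo)
  unique_retained <- sv$id %in% ft0$id & !(key %in% key[duplicated(key)])
  pick <- which(unique_retained)[1:2]
  for (i in pick) env2$ndvi[cell[i], mo[i]] <- -0.05
  ft <- build_feature_table(sv, env2)
  expect_identical(nrow(ft), nrow(ft0) - 2L)
  drops <- attr(ft, "drop_counts")
  expect_identical(unname(drops["negative_ndvi"] - base_drops["negative_ndvi"]),
                   2L)
  expect_identical(nrow(ft) + sum(drops), nrow(sv))
  expect_true(all(ft$ndvi >= 0))
  expect_true(all(ft$doy >= 1 & ft$doy <= 366))
  expect_true(all(ft$response >= 0))
  expect_false(anyNA(ft[covariate_catalog()$candidates]))
})

test_that("feature table has all 39 candidate columns and the response transform", {
  ft <- shared_features()
  cat_ <- covariate_catalog()
  expect_true(all(cat_$candidates %in% names(ft)))
  expect_identical(sum(names(ft) %in% cat_$candidates), 39L)
  expect_equal(ft$response, ft$sampled_density^(1 / 6))
})

test_that("feature rows with early dates are dropped as insufficient history", {
  env <- shared_env()
  sv <- utils::head(shared_surveys(), 50)
  set.seed(8)
  sv <- add_sampled_density(sv, default_class_scheme())
  sv$date[1:3] <- env$dates[10]   # inside the 60-day spin-up
  ft <- build_feature_table(sv, env)
  expect_identical(unname(attr(ft, "drop_counts")["insufficient_history"]), 3L)
  expect_identical(nrow(ft) + sum(attr(ft, "drop_counts")), 50L)
})

test_that("standardization uses training statistics only and refuses reapplication", {
  ft <- shared_features()
  cols <- covariate_catalog()$candidates
  n <- nrow(ft)
  train <- seq_len(n) <= floor(0.8 * n)
  st <- standardize_features(ft, train = train)
  tr <- as.data.frame(st)[train, cols]
  expect_true(all(abs(vapply(tr, mean, numeric(1))) < 1e-12))
  expect_true(all(abs(vapply(tr, stats::sd, numeric(1)) - 1) < 1e-12))
  # held-out columns are scaled with training statistics, so not mean zero
  va <- as.data.frame(st)[!train, cols]
  va_means <- vapply(va, mean, numeric(1))
  expect_gt(max(abs(va_means)), 1e-6)
  # and the held-out means match recomputation from the stored record
  rec <- attr(st, "scaling")
  manual <- vapply(cols, function(cn) {
    (mean(ft[[cn]][!train]) - rec$mean[rec$column == cn]) /
      rec$sd[rec$column == cn]
  }, numeric(1))
  expect_equal(unname(va_means), unname(manual))
  expect_error(standardize_features(st, train = train), "refusing")
  # zero-variance guard names the column
  ft2 <- ft
  ft2$sand <- 1
  attr(ft2, "scaling") <- NULL
  expect_error(standardize_features(ft2, train = train), "sand")
})

test_that("feature table round-trips through CSV with sidecar metadata", {
  ft <- utils::head(shared_features(), 30)
  attr(ft, "drop_counts") <- attr(shared_features(), "drop_counts")
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(ft, path)
  back <- read_feature_table(path)
  expect_equal(back$response, ft$response)
  expect_equal(attr(back, "lambda"), attr(ft, "lambda"))
  expect_equal(attr(back, "catalog")$full, attr(ft, "catalog")$full)
})
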