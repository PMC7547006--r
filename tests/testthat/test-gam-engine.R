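# Simulated single-covariate NB data with square-root-scale truth eta(x).
sim_nb <- function(n, eta_fun, theta = 3, seed = 1) {
  set.seed(seed)
  x <- stats::runif(n)
  eta <- eta_fun(x)
  stopifnot(all(eta > 0))
  data.frame(x = x, y = stats::rnbinom(n, size = theta, mu = eta^2))
}

test_that("cyclic day-of-year basis wraps: identical rows at doy 1 and 366", {
  doy <- c(1, 50, 150, 250, 330, seq(10, 360, by = 17))
  b <- build_basis(doy, "cyclic_spline", k = 8)
  row1 <- mgcv::PredictMat(b$smooth, data.frame(x = 1))
  row366 <- mgcv::PredictMat(b$smooth, data.frame(x = 366))
  expect_lt(max(abs(row1 - row366)), 1e-10)
})

test_that("second-order penalty vanishes on straight lines", {
  set.seed(2)
  x <- sort(stats::runif(80))
  b <- build_basis(x, "cubic_spline", k = 10)
  line <- 2 * x + 1
  beta <- stats::lm.fit(b$design, line - mean(line))$coefficients
  quad <- drop(t(beta) %*% b$penalty[[1]] %*% beta)
  expect_lt(quad / sum(beta^2), 1e-10)
  expect_error(build_basis(rep(1:3, 10), "cubic_spline", k = 10),
               "distinct")
})

test_that("penalty quadratic form integrates the squared second derivative", {
  set.seed(3)
  x <- seq(0, 1, length.out = 60)
  b <- build_basis(x, "cubic_spline", k = 10)
  beta <- stats::rnorm(ncol(b$design))
  quad <- drop(t(beta) %*% b$penalty[[1]] %*% beta)
  # numerical oracle: finite-difference f'' on a fine grid
  grid <- seq(0, 1, length.out = 2001)
  f <- drop(mgcv::PredictMat(b$smooth, data.frame(x = grid)) %*% beta)
  h <- grid[2] - grid[1]
  fpp <- diff(f, differences = 2) / h^2
  integral <- sum(fpp^2) * h
  expect_equal(quad, integral, tolerance = 0.05)
})

test_that("tensor basis is a positive semidefinite sum of marginal penalties", {
  set.seed(4)
  dat <- data.frame(lon = stats::runif(300, 142, 144),
                    lat = stats::runif(300, -32, -30),
                    doy = sample(1:365, 300, replace = TRUE))
  b <- build_basis(dat, "tensor3", k = c(4, 4, 4))
  expect_length(b$penalty, 3)
  for (S in b$penalty) {
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8 * max(abs(ev)))
  }
  # constraint absorbed: columns orthogonal to the intercept
  expect_lt(max(abs(colSums(b$design))), 1e-8)
})

test_that("null signal yields near-zero smooths with shrunken freedom", {
  d <- sim_nb(800, function(x) rep(1.5, length(x)), seed = 5)
  g <- fit_abundance_gam(d, "x", response = "y", response_scale = "density",
                         tensor = FALSE, select = TRUE)
  edf <- sum(g$fit$edf[-1])
  expect_lt(edf, 0.5)
  rc <- response_curves(g, "x")
  expect_gte(mean(abs(rc$fit) <= 2 * pmax(rc$se, 1e-8)), 0.95)
  expect_false(any(rc$snr_mask))
})

test_that("a sinusoidal square-root-scale truth is recovered pointwise", {
  d <- sim_nb(5000, function(x) 2 + 0.8 * sin(2 * pi * x), seed = 6)
  g <- fit_abundance_gam(d, "x", response = "y", response_scale = "density",
                         tensor = FALSE)
  rc <- response_curves(g, "x", n_grid = 100)
  truth <- 0.8 * sin(2 * pi * rc$x)
  expect_gte(stats::cor(rc$fit, truth - mean(truth)), 0.95)
})

test_that("infinite smoothing collapses a cubic smooth to a straight line", {
  d <- sim_nb(1000, function(x) 1.5 + 0.5 * sin(2 * pi * x), seed = 7)
  g <- fit_abundance_gam(d, "x", response = "y", response_scale = "density",
                         tensor = FALSE)
  heavy <- mgcv::gam(y ~ s(x, bs = "cr", k = 10), data = d,
                     family = mgcv::nb(link = "sqrt"), sp = 1e10)
  grid <- data.frame(x = seq(0, 1, length.out = 50))
  f <- as.numeric(mgcv::predict.gam(heavy, grid, type = "terms")[, 1])
  resid_line <- stats::resid(stats::lm(f ~ grid$x))
  expect_lt(max(abs(resid_line)) / max(abs(f)), 1e-4)
})

test_that("training deviance never exceeds the null deviance; edf bounded", {
  d <- sim_nb(1200, function(x) 1.2 + 0.6 * x, seed = 8)
  g <- fit_abundance_gam(d, "x", response = "y", response_scale = "density",
                         tensor = FALSE, k = 10)
  expect_lte(g$fit$deviance, g$fit$null.deviance)
  expect_gte(g$deviance_explained, 0)
  expect_lte(g$deviance_explained, 1)
  edf_smooth <- sum(g$fit$edf[-1])
  expect_gte(edf_smooth, 0)
  expect_lte(edf_smooth, 10 - 1)
})

test_that("negative binomial at huge dispersion matches the Poisson fit", {
  set.seed(9)
  x <- stats::runif(2000)
  mu <- (1.8 + 0.6 * sin(2 * pi * x))^2
  y <- stats::rpois(2000, mu)
  d <- data.frame(x = x, y = y)
  nbfit <- mgcv::gam(y ~ s(x, bs = "cr", k = 10), data = d,
                     family = mgcv::negbin(1e6, link = "sqrt"),
                     method = "REML")
  pofit <- mgcv::gam(y ~ s(x, bs = "cr", k = 10), data = d,
                     family = stats::poisson(link = "sqrt"),
                     method = "REML")
  expect_lt(max(abs(stats::coef(nbfit) - stats::coef(pofit))), 1e-3)
})

test_that("prediction reproduces fitted values and the dense covariance oracle", {
  d <- sim_nb(900, function(x) 1.5 + 0.7 * x, seed = 10)
  d$lon <- stats::runif(900, 142, 144)
  d$lat <- stats::runif(900, -32, -30)
  d$doy <- sample(1:365, 900, replace = TRUE)
  g <- fit_abundance_gam(d, "x", response = "y", response_scale = "density",
                         tensor = TRUE, tensor_k = c(4, 4, 4))
  pr <- predict_abundance(g, d)
  expect_equal(pr$mu, unname(g$fit$fitted.values), tolerance = 1e-8)
  # duplicated row predicts identically
  pr2 <- predict_abundance(g, d[c(1, 1), ])
  expect_identical(pr2$eta[1], pr2$eta[2])
  # dense linear-algebra oracle for the standard error
  Xp <- mgcv::predict.gam(g$fit, newdata = d, type = "lpmatrix")
  se_dense <- sqrt(rowSums((Xp %*% g$fit$Vp) * Xp))
  expect_equal(pr$se_eta, unname(se_dense), tolerance = 1e-8)
  expect_true(all(is.finite(pr$se_eta)) && all(pr$se_eta >= 0))
  # out-of-range covariates are clamped and counted
  far <- d[1:3, ]
  far$x <- 99
  prf <- predict_abundance(g, far)
  expect_identical(attr(prf, "n_clamped"), 3L)
  expect_error(predict_abundance(g, d[, c("x", "lon", "lat")]), "missing")
})

test_that("response curves are centred, masked by SNR, and monotone for linear truth", {
  d <- sim_nb(4000, function(x) 1.5 + 0.9 * (x - 0.5), seed = 11)
  g <- fit_abundance_gam(d, "x", response = "y", response_scale = "density",
                         tensor = FALSE)
  # identifiability: smooth contribution at the training points centres to 0
  at_train <- mgcv::predict.gam(g$fit, type = "terms")[, "s(x)"]
  expect_lt(abs(mean(at_train)), 1e-6)
  rc <- response_curves(g, "x", n_grid = 200)
  expect_equal(rc$lower, rc$fit - 2 * rc$se)
  expect_equal(rc$upper, rc$fit + 2 * rc$se)
  masked <- which(rc$snr_mask)
  steps <- diff(rc$fit[masked])
  expect_gte(mean(steps > 0), 0.98)
  expect_error(response_curves(g, "lon"), "tensor|no univariate")
})

test_that("tensor slices wrap at the year boundary and match the dense oracle", {
  set.seed(12)
  n <- 2000
  d <- data.frame(lon = stats::runif(n, 142, 144),
                  lat = stats::runif(n, -32, -30),
                  doy = sample(1:365, n, replace = TRUE))
  hotspot <- 1.2 * exp(-((d$lon - 143)^2 + (d$lat + 31)^2) / (2 * 0.25^2))
  d$y <- stats::rnbinom(n, size = 3, mu = (1 + hotspot)^2)
  d$x <- stats::runif(n)
  g <- fit_abundance_gam(d, "x", response = "y", response_scale = "density",
                         tensor_k = c(5, 5, 4))
  s1 <- tensor_slices(g, 1, n_grid = 15)
  s366 <- tensor_slices(g, 366, n_grid = 15)
  expect_lt(max(abs(s1$value - s366$value)), 1e-6)
  expect_error(tensor_slices(g, 400), "doy")
  # dense oracle: evaluate the tensor block directly
  lab <- grep("^te\\(", vapply(g$fit$smooth, function(s) s$label, ""))
  sm <- g$fit$smooth[[lab]]
  nd <- data.frame(lon = s1$lon, lat = s1$lat, doy = 1)
  Xt <- mgcv::PredictMat(sm, nd)
  contrib <- drop(Xt %*% stats::coef(g$fit)[sm$first.para:sm$last.para])
  expect_equal(s1$value, contrib, tolerance = 1e-8)
})
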