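#' Build a penalized spline basis
#'
#' Exposes the basis/penalty construction used by the abundance GAM:
#' cubic regression splines with a second-order penalty for ordinary
#' covariates, a cyclic cubic spline (period 366, for day of year), or the
#' three-way tensor product over longitude, latitude and day of year whose
#' penalty is the standard sum of marginal-penalty Kronecker terms. The
#' sum-to-zero identifiability constraint is absorbed into the
#' reparameterized columns (each block is orthogonal to the intercept).
#'
#' @param x covariate values: a numeric vector, or for `"tensor3"` a data
#'   frame with columns `lon`, `lat`, `doy`.
#' @param basis `"cubic_spline"`, `"cyclic_spline"`, or `"tensor3"`.
#' @param k basis dimension (per margin for the tensor; defaults 10 and
#'   `c(8, 8, 6)`).
#' @return list with `design` (n x p matrix, constraint absorbed) and
#'   `penalty` (list of p x p positive semidefinite matrices), plus the
#'   underlying mgcv smooth object as `smooth`.
#' @export
build_basis <- function(x, basis = c("cubic_spline", "cyclic_spline",
                                     "tensor3"), k = NULL) {
  basis <- match.arg(basis)
  if (basis == "tensor3") {
    stopifnot(is.data.frame(x), all(c("lon", "lat", "doy") %in% names(x)))
    if (is.null(k)) k <- c(8, 8, 6)
    sm <- mgcv::smoothCon(
      mgcv::te(lon, lat, doy, bs = c("cr", "cr", "cc"), k = k),
      data = x, knots = list(doy = c(1, 366)), absorb.cons = TRUE,
      scale.penalty = FALSE)[[1]]
  } else {
    if (is.null(k)) k <- 10
    xv <- as.numeric(x)
    if (k >= length(unique(xv))) {
      stop("basis dimension k must be below the number of distinct values")
    }
    dat <- data.frame(x = xv)
    knots <- NULL
    bs <- if (basis == "cyclic_spline") "cc" else "cr"
    if (basis == "cyclic_spline") knots <- list(x = c(1, 366))
    sm <- mgcv::smoothCon(mgcv::s(x, bs = bs, k = k), data = dat,
                          knots = knots, absorb.cons = TRUE,
                          scale.penalty = FALSE)[[1]]
  }
  list(design = sm$X, penalty = sm$S, smooth = sm)
}

#' Fit the negative binomial square-root-link abundance GAM
#'
#' The core model: an additive predictor on the square-root scale made of
#' univariate cubic-spline smooths of the chosen covariates plus one
#' space--time tensor smooth over (unscaled) longitude, latitude and day of
#' year (cyclic margin, period 366), with a negative binomial response
#' family, square-root link (`mu = eta^2`), REML smoothing-parameter
#' selection and profiled dispersion `theta`. Fitting is delegated to
#' mgcv's penalized IRLS (`gam`, or `bam` for large tables).
#'
#' Two response scales are supported: `"sixth_root"` models the transformed
#' density `sampled_density^(1/6)` (the continuous response treated under
#' negative binomial quasi-likelihood), `"density"` models the density
#' itself.
#'
#' @param table a `feature_table` (or any data frame with the covariates,
#'   `lon`, `lat`, `doy`, and the response column).
#' @param covariates character vector of univariate smooth covariates.
#' @param response_scale `"sixth_root"` (default) or `"density"`; ignored
#'   if `response` is given.
#' @param response optional explicit response column name.
#' @param k univariate basis dimension (default 10).
#' @param tensor include the lon x lat x doy tensor (default TRUE).
#' @param tensor_k marginal basis dimensions for the tensor,
#'   default `c(8, 8, 6)`.
#' @param engine `"auto"` (default), `"gam"`, or `"bam"`. `"auto"` uses
#'   mgcv's large-data `bam` fitter for the sixth-root response (whose
#'   near-zero dispersion makes the fully iterated `gam` path fragile) and
#'   `gam` with exact REML otherwise.
#' @param theta negative binomial dispersion: `NULL` (default) profiles it
#'   for the `"density"` scale and pins it at `1e5` (the stable
#'   near-Poisson limit) for the underdispersed continuous `"sixth_root"`
#'   scale; a numeric value fixes it; `NA` forces profiling.
#' @param select allow smooths to be penalized to zero effective degrees of
#'   freedom (mgcv's double-penalty shrinkage).
#' @param check_n error if `n < 10 x` the total coefficient count.
#' @return an object of class `abundance_gam` wrapping the mgcv fit with
#'   metadata: covariate training ranges, response scale, smoothing
#'   criterion, dispersion `theta`, deviance explained.
#' @export
fit_abundance_gam <- function(table, covariates,
                              response_scale = c("sixth_root", "density"),
                              response = NULL, k = 10, tensor = TRUE,
                              tensor_k = c(8, 8, 6),
                              engine = c("auto", "gam", "bam"),
                              theta = NULL, select = FALSE,
                              check_n = TRUE) {
  response_scale <- match.arg(response_scale)
  engine <- match.arg(engine)
  if (engine == "auto") {
    engine <- if (response_scale == "sixth_root") "bam" else "gam"
  }
  # Dispersion: profiled for count-like densities. The continuous
  # sixth-root response is underdispersed relative to any finite-theta
  # negative binomial, so its profile either diverges or sticks at a poor
  # interior mode; theta is pinned at the stable near-Poisson limit there.
  if (is.null(theta)) {
    theta <- if (response_scale == "sixth_root") 1e5 else NA_real_
  }
  if (is.null(response)) {
    response <- if (response_scale == "sixth_root") "response"
                else "sampled_density"
  }
  stopifnot(response %in% names(table),
            all(covariates %in% names(table)))
  y <- table[[response]]
  if (any(y < 0)) stop("response must be non-negative")
  n <- nrow(table)
  n_coef <- 1 + length(covariates) * (k - 1) +
    if (tensor) prod(tensor_k) - 1 else 0
  if (check_n && n < 10 * n_coef) {
    stop(sprintf(paste0("n = %d is below 10x the coefficient count (%d); ",
                        "reduce k/tensor_k or set check_n = FALSE"),
         n, n_coef))
  }
  terms <- sprintf("s(%s, bs = \"cr\", k = %d)", covariates, k)
  if (tensor) {
    terms <- c(terms, sprintf(
      "te(lon, lat, doy, bs = c(\"cr\", \"cr\", \"cc\"), k = c(%d, %d, %d))",
      tensor_k[1], tensor_k[2], tensor_k[3]))
  }
  fml <- stats::as.formula(paste(response, "~", paste(terms, collapse = " + ")))
  knots <- if (tensor) list(doy = c(1, 366)) else NULL
  dat <- as.data.frame(table)
  fam <- if (is.na(theta)) mgcv::nb(link = "sqrt")
         else mgcv::negbin(theta, link = "sqrt")
  # At a pinned near-Poisson theta the quasi-likelihood scale loop can hit
  # its iteration cap with stable estimates; record that warning on the
  # model instead of raising it. All other warnings pass through.
  caught <- character(0)
  fit <- withCallingHandlers(
    if (engine == "bam") {
      mgcv::bam(fml, data = dat, family = fam, method = "fREML",
                knots = knots, select = select)
    } else {
      mgcv::gam(fml, data = dat, family = fam, method = "REML",
                knots = knots, select = select)
    },
    warning = function(w) {
      if (grepl("algorithm did not converge", conditionMessage(w)) &&
          response_scale == "sixth_root") {
        caught <<- c(caught, conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    })
  ranges <- lapply(dat[c(covariates, if (tensor) c("lon", "lat", "doy"))],
                   range)
  structure(list(
    fit = fit, covariates = covariates, tensor = tensor,
    response = response, response_scale = response_scale,
    lambda = attr(table, "lambda"),
    k = k, tensor_k = tensor_k, ranges = ranges,
    criterion = if (engine == "bam") "fREML" else "REML",
    warnings = caught,
    theta = if (is.na(theta)) fit$family$getTheta(TRUE) else theta,
    theta_source = if (is.na(theta)) "profiled" else "fixed",
    deviance_explained = 1 - fit$deviance / fit$null.deviance,
    aic = stats::AIC(fit)
  ), class = "abundance_gam")
}

#' @export
print.abundance_gam <- function(x, ...) {
  cat("<abundance_gam> NB(theta =", signif(x$theta, 4),
      ") sqrt link |", length(x$covariates), "smooths",
      if (x$tensor) "+ lon x lat x doy tensor", "\n",
      "deviance explained:", round(100 * x$deviance_explained, 1),
      "% | AIC:", round(x$aic, 1), "\n")
  invisible(x)
}

# Clamp new covariate values into the training range; returns the data and
# the count of clamped entries.
clamp_to_ranges <- function(newdata, ranges) {
  clamped <- 0L
  for (nm in names(ranges)) {
    if (!nm %in% names(newdata)) next
    v <- newdata[[nm]]
    r <- ranges[[nm]]
    out <- v < r[1] | v > r[2]
    clamped <- clamped + sum(out)
    newdata[[nm]] <- pmin(pmax(v, r[1]), r[2])
  }
  list(data = newdata, n_clamped = clamped)
}

#' Predict from a fitted abundance GAM
#'
#' Returns the link-scale prediction `eta = X beta`, its standard error
#' from the coefficient covariance (`se_eta = sqrt(diag(X V X'))`), and the
#' response-scale mean `mu = eta^2`. Covariates outside the training range
#' are clamped to it, with the clamp count reported.
#'
#' @param model an `abundance_gam`.
#' @param newdata data frame carrying all model covariates (and `lon`,
#'   `lat`, `doy` if the model has a tensor).
#' @return data frame with columns `eta`, `mu`, `se_eta`; attribute
#'   `n_clamped`.
#' @export
predict_abundance <- function(model, newdata) {
  stopifnot(inherits(model, "abundance_gam"))
  need <- c(model$covariates, if (model$tensor) c("lon", "lat", "doy"))
  miss <- setdiff(need, names(newdata))
  if (length(miss)) stop("missing covariates: ", paste(miss, collapse = ", "))
  cl <- clamp_to_ranges(as.data.frame(newdata), model$ranges)
  pr <- mgcv::predict.gam(model$fit, newdata = cl$data, type = "link",
                          se.fit = TRUE)
  out <- data.frame(eta = as.numeric(pr$fit),
                    mu = as.numeric(pr$fit)^2,
                    se_eta = as.numeric(pr$se.fit))
  attr(out, "n_clamped") <- cl$n_clamped
  out
}

# Reference row: medians of the training covariates (mode for character).
reference_row <- function(model) {
  dat <- model$fit$model
  ref <- lapply(dat, function(col) {
    if (is.numeric(col)) stats::median(col) else col[1]
  })
  as.data.frame(ref)
}

#' Response curve of a univariate smooth
#'
#' Evaluates the centred smooth contribution `f(x)` of one covariate on an
#' equally spaced grid over its training range, with pointwise standard
#' errors, a plus/minus 2 standard deviation band, and a signal-to-noise
#' mask that is true where the standard error is below half the absolute
#' response (SNR of at least 2), the region recommended for
#' interpretation.
#'
#' @param model an `abundance_gam`.
#' @param covariate name of a univariate smooth covariate.
#' @param n_grid grid size (default 100).
#' @return data frame of class `response_curve`: `x`, `fit`, `se`, `lower`,
#'   `upper`, `snr_mask`.
#' @export
response_curves <- function(model, covariate, n_grid = 100) {
  stopifnot(inherits(model, "abundance_gam"))
  if (!covariate %in% model$covariates) {
    stop(if (covariate %in% c("lon", "lat", "doy"))
      "space-time coordinates belong to the tensor; use tensor_slices()"
      else paste("no univariate smooth for", covariate))
  }
  r <- model$ranges[[covariate]]
  grid <- seq(r[1], r[2], length.out = n_grid)
  nd <- reference_row(model)[rep(1, n_grid), , drop = FALSE]
  nd[[covariate]] <- grid
  term <- sprintf("s(%s)", covariate)
  pr <- mgcv::predict.gam(model$fit, newdata = nd, type = "terms",
                          terms = term, se.fit = TRUE)
  fit <- as.numeric(pr$fit[, term])
  se <- as.numeric(pr$se.fit[, term])
  out <- data.frame(x = grid, fit = fit, se = se,
                    lower = fit - 2 * se, upper = fit + 2 * se,
                    snr_mask = se < abs(fit) / 2)
  class(out) <- c("response_curve", class(out))
  out
}

#' Spatial slice of the space--time tensor
#'
#' Evaluates the tensor smooth's centred contribution on a lon x lat grid
#' at a fixed day of year. The day-of-year margin is cyclic, so slices at
#' doy 1 and doy 366 coincide.
#'
#' @param model an `abundance_gam` with a tensor term.
#' @param doy day of year in `[1, 366]`.
#' @param n_grid grid points per spatial axis.
#' @return data frame `lon`, `lat`, `value` (tensor contribution on the
#'   link scale).
#' @export
tensor_slices <- function(model, doy, n_grid = 40) {
  stopifnot(inherits(model, "abundance_gam"))
  if (!model$tensor) stop("model has no tensor term")
  if (doy < 1 || doy > 366) stop("doy must be in [1, 366]")
  lon <- seq(model$ranges$lon[1], model$ranges$lon[2], length.out = n_grid)
  lat <- seq(model$ranges$lat[1], model$ranges$lat[2], length.out = n_grid)
  g <- expand.grid(lon = lon, lat = lat)
  nd <- reference_row(model)[rep(1, nrow(g)), , drop = FALSE]
  nd$lon <- g$lon; nd$lat <- g$lat; nd$doy <- doy
  labels <- vapply(model$fit$smooth, function(s) s$label, "")
  term <- grep("^te\\(", labels, value = TRUE)[1]
  pr <- mgcv::predict.gam(model$fit, newdata = nd, type = "terms",
                          terms = term)
  data.frame(lon = g$lon, lat = g$lat, value = as.numeric(pr[, term]))
}
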