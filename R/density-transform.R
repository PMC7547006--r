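#' Ordinal density-class scheme
#'
#' Field surveys record locust abundance as an ordinal density class rather
#' than a count. A scheme maps each class code to a density interval
#' (individuals per square metre) and a midpoint used for stochastic
#' back-conversion; class 0 always means absence (exactly zero density).
#'
#' Interval bounds between consecutive positive classes are placed at the
#' geometric mean of adjacent midpoints, so classes tile `(0, Inf)` without
#' gaps; the top class is open above.
#'
#' @param midpoints strictly increasing positive midpoints (individuals/m^2)
#'   of the positive classes, in class-code order.
#' @param labels optional labels, one per positive class.
#' @param cv coefficient of variation of the class-sampling distribution
#'   (standard deviation as a fraction of the midpoint), in (0, 1).
#' @return An object of class `density_class_scheme`: a data frame with
#'   columns `code`, `label`, `lower`, `upper`, `midpoint`, plus attribute
#'   `cv`. Row 1 is the absence class.
#' @export
density_class_scheme <- function(midpoints, labels = NULL, cv = 0.30) {
  stopifnot(length(midpoints) >= 1, all(midpoints > 0),
            all(diff(midpoints) > 0), cv > 0, cv < 1)
  np <- length(midpoints)
  if (is.null(labels)) labels <- paste0("class", seq_len(np))
  stopifnot(length(labels) == np)
  # geometric bounds between adjacent midpoints; class 1 lower bound is 0
  cuts <- if (np > 1) sqrt(midpoints[-np] * midpoints[-1]) else numeric(0)
  lower <- c(0, 0, cuts)
  upper <- c(0, cuts, Inf)
  scheme <- data.frame(
    code = 0:np,
    label = c("absent", labels),
    lower = lower,
    upper = upper,
    midpoint = c(0, midpoints),
    stringsAsFactors = FALSE
  )
  attr(scheme, "cv") <- cv
  class(scheme) <- c("density_class_scheme", class(scheme))
  scheme
}

#' Default density-class scheme
#'
#' Six classes (0--5) spanning the densities discussed for Australian plague
#' locust surveys: absent, isolated (0.05/m^2), scattered (0.5), numerous (5),
#' concentrated (25), swarm (75); log-spaced midpoints, CV 30%.
#'
#' @param cv coefficient of variation for class sampling (default 0.30).
#' @return a [density_class_scheme()].
#' @export
default_class_scheme <- function(cv = 0.30) {
  density_class_scheme(
    midpoints = c(0.05, 0.5, 5, 25, 75),
    labels = c("isolated", "scattered", "numerous", "concentrated", "swarm"),
    cv = cv
  )
}

#' Bin a continuous density into a class code
#'
#' Inverse of the class-sampling step: assigns the class whose half-open
#' interval `(lower, upper]` contains the density; exactly zero maps to the
#' absence class 0.
#'
#' @param density non-negative densities (individuals/m^2).
#' @param scheme a [density_class_scheme()].
#' @return integer class codes.
#' @export
bin_density <- function(density, scheme) {
  stopifnot(inherits(scheme, "density_class_scheme"))
  if (any(density < 0)) stop("density must be non-negative")
  pos <- scheme[scheme$code > 0, ]
  # breaks: 0 | upper bounds of positive classes (last is Inf)
  breaks <- c(0, pos$upper)
  code <- findInterval(density, breaks, left.open = TRUE)
  code[density == 0] <- 0L
  as.integer(code)
}

#' Sample a continuous density for an ordinal class
#'
#' Converts ordinal density classes to continuous abundance by drawing from
#' a normal distribution centred on the class midpoint with standard
#' deviation `cv * midpoint` (default CV 30%, the precision ceiling the
#' survey protocol implies). Negative draws are rejected and redrawn, so the
#' class-conditional mean stays near the midpoint and zero remains reserved
#' for true absence. Class 0 returns exactly 0.
#'
#' @param class_code integer vector of class codes valid in `scheme`.
#' @param scheme a [density_class_scheme()].
#' @return numeric vector of sampled densities, one per input code. Uses the
#'   R session RNG; set a seed for reproducibility.
#' @export
sample_density <- function(class_code, scheme) {
  stopifnot(inherits(scheme, "density_class_scheme"))
  class_code <- as.integer(class_code)
  if (any(!class_code %in% scheme$code)) {
    stop("unknown class code(s): ",
         paste(setdiff(class_code, scheme$code), collapse = ", "))
  }
  cv <- attr(scheme, "cv")
  mid <- scheme$midpoint[match(class_code, scheme$code)]
  out <- numeric(length(class_code))
  pos <- which(class_code > 0L)
  if (length(pos)) {
    m <- mid[pos]
    draw <- stats::rnorm(length(pos), m, cv * m)
    bad <- which(draw <= 0)
    while (length(bad)) {  # rejection sampling of non-positive draws
      draw[bad] <- stats::rnorm(length(bad), m[bad], cv * m[bad])
      bad <- bad[draw[bad] <= 0]
    }
    out[pos] <- draw
  }
  out
}

#' Append sampled densities to a survey table
#'
#' @param surveys data frame with a `density_class` column.
#' @param scheme a [density_class_scheme()].
#' @return `surveys` with a `sampled_density` column added.
#' @export
add_sampled_density <- function(surveys, scheme) {
  stopifnot("density_class" %in% names(surveys))
  surveys$sampled_density <- sample_density(surveys$density_class, scheme)
  surveys
}

#' Power transform of density
#'
#' The model response is `density^lambda` with `lambda = 1/6` by default.
#' A power transform (rather than a log) is used so that zero densities
#' (absences) map to zero and stay in the model.
#'
#' @param density non-negative densities.
#' @param lambda exponent in (0, 1); default 1/6.
#' @return `density^lambda`.
#' @export
power_transform <- function(density, lambda = 1 / 6) {
  stopifnot(lambda > 0, lambda < 1)
  if (any(density < 0)) stop("density must be non-negative")
  density^lambda
}

#' Inverse power transform
#'
#' Maps model-scale predictions back to densities: `y^(1/lambda)`.
#'
#' @param y non-negative transformed values.
#' @param lambda exponent used in [power_transform()].
#' @return densities `y^(1/lambda)`.
#' @export
inverse_power_transform <- function(y, lambda = 1 / 6) {
  stopifnot(lambda > 0, lambda < 1)
  if (any(y < 0)) stop("transformed response must be non-negative")
  y^(1 / lambda)
}
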