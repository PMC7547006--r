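# Shared small fixtures, built once per test run.

tiny_config <- function(seed = 7, n_surveys = 400, ...) {
  simulation_config(seed = seed, bbox = c(142, 143, -31, -30),
                    n_surveys = n_surveys, ...)
}

.fixtures <- new.env(parent = emptyenv())

# 21 x 21 cell grid over one degree, one year of days, 400 surveys.
shared_env <- function() {
  if (is.null(.fixtures$env)) .fixtures$env <- generate_env_grid(tiny_config())
  .fixtures$env
}

shared_surveys <- function() {
  if (is.null(.fixtures$surveys)) {
    .fixtures$surveys <- generate_surveys(tiny_config(), shared_env())
  }
  .fixtures$surveys
}

shared_features <- function() {
  if (is.null(.fixtures$features)) {
    sv <- shared_surveys()
    set.seed(99)
    sv <- add_sampled_density(sv, default_class_scheme())
    .fixtures$features <- build_feature_table(sv, shared_env())
  }
  .fixtures$features
}

# Independent geometric daylength oracle: NOAA Fourier-series declination,
# zenith 90 degrees (no refraction term, matching an astronomical daylength).
noaa_daylength <- function(lat, doy) {
  g <- 2 * pi / 365 * (doy - 1)
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  phi <- lat * pi / 180
  h <- acos(pmin(pmax(-tan(phi) * tan(decl), -1), 1))
  24 * h / pi
}
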