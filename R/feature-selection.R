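new_linear_fit <- function(method, coefficients, standard_errors,
                           t_statistics, aic, selected, penalty = NA_real_,
                           intercept = NA_real_, meta = list()) {
  structure(list(
    method = method, coefficients = coefficients,
    standard_errors = standard_errors, t_statistics = t_statistics,
    aic = aic, selected = selected, penalty = penalty,
    intercept = intercept, meta = meta
  ), class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat("<linear_fit>", x$method, "|", length(x$selected), "of",
      length(x$coefficients), "covariates | AIC", round(x$aic, 1), "\n")
  invisible(x)
}

# OLS fit with SEs/t on a named design matrix; shared by the refits below.
ols_core <- function(X, y) {
  qrx <- qr(cbind(`(Intercept)` = 1, X))
  if (qrx$rank < ncol(X) + 1) {
    keep <- qrx$pivot[seq_len(qrx$rank)]
    bad <- setdiff(colnames(cbind(`(Intercept)` = 1, X)),
                   colnames(cbind(`(Intercept)` = 1, X))[keep])
    stop("design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  n <- nrow(X); p <- ncol(X)
  beta <- qr.coef(qrx, y)
  res <- y - qr.fitted(qrx, y)
  rss <- sum(res^2)
  sigma2 <- rss / (n - p - 1)
  XtXinv <- chol2inv(qr.R(qrx))
  se <- sqrt(diag(XtXinv) * sigma2)
  tval <- beta / se
  # Gaussian log-likelihood AIC, same convention as stats::AIC on lm
  aic <- n * log(2 * pi * rss / n) + n + 2 * (p + 2)
  list(beta = beta, se = se, t = tval, aic = aic, rss = rss,
       tss = sum((y - mean(y))^2))
}

#' Ordinary least squares (Gaussian GLM) fit
#'
#' The baseline of the feature-selection stage: a Gaussian linear model of
#' the transformed response on the standardized covariates, with
#' coefficient standard errors, t-statistics, and AIC (Gaussian
#' log-likelihood convention, matching `stats::AIC` on `lm`).
#'
#' @param X standardized design matrix (no intercept column), `n > p`,
#'   full column rank.
#' @param y transformed response vector.
#' @return a `linear_fit` (method `"glm"`); all covariates are "selected".
#' @export
fit_ols_glm <- function(X, y) {
  X <- as.matrix(X)
  stopifnot(nrow(X) > ncol(X), nrow(X) == length(y))
  fit <- ols_core(X, y)
  new_linear_fit("glm",
                 coefficients = fit$beta[-1], standard_errors = fit$se[-1],
                 t_statistics = fit$t[-1], aic = fit$aic,
                 selected = colnames(X), intercept = fit$beta[1],
                 meta = list(aic_convention = "gaussian_loglik",
                             rss = fit$rss, tss = fit$tss,
                             r_squared = 1 - fit$rss / fit$tss))
}

# Exact ridge solution via SVD of the centred design (intercept
# unpenalized): beta = V diag(d/(d^2 + lambda)) U' yc.
ridge_solve <- function(X, y, lambda) {
  xbar <- colMeans(X); ybar <- mean(y)
  Xc <- sweep(X, 2, xbar)
  sv <- svd(Xc)
  beta <- sv$v %*% ((sv$d / (sv$d^2 + lambda)) * crossprod(sv$u, y - ybar))
  beta <- drop(beta)
  names(beta) <- colnames(X)
  list(beta = beta, intercept = ybar - sum(xbar * beta))
}

#' Ridge regression with cross-validated penalty
#'
#' Minimizes `RSS + lambda * ||beta||_2^2` (intercept unpenalized), solved
#' exactly through the SVD of the centred design. `lambda` is chosen from
#' the supplied grid by tenfold cross-validated mean squared error with
#' deterministic folds. t-statistics for variable importance come from an
#' unpenalized OLS refit.
#'
#' @param X standardized design matrix.
#' @param y response vector.
#' @param lambda_grid candidate penalties (default 100 log-spaced values
#'   spanning `1e-3` to `1e3` times `n`-scaled unity).
#' @param cv_folds folds for penalty selection.
#' @param seed fold-assignment seed.
#' @return a `linear_fit` (method `"ridge"`) with the chosen `penalty`.
#' @export
fit_ridge <- function(X, y, lambda_grid = 10^seq(-3, 3, length.out = 100),
                      cv_folds = 10, seed = 1) {
  X <- as.matrix(X)
  if (!length(lambda_grid)) stop("empty lambda grid")
  n <- nrow(X)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(cv_folds), n))
  cv_mse <- vapply(lambda_grid, function(lam) {
    err <- 0
    for (f in seq_len(cv_folds)) {
      tr <- fold != f
      s <- ridge_solve(X[tr, , drop = FALSE], y[tr], lam)
      pred <- X[!tr, , drop = FALSE] %*% s$beta + s$intercept
      err <- err + sum((y[!tr] - pred)^2)
    }
    err / n
  }, numeric(1))
  lam <- lambda_grid[which.min(cv_mse)]
  s <- ridge_solve(X, y, lam)
  refit <- ols_core(X, y)
  new_linear_fit("ridge",
                 coefficients = s$beta, standard_errors = refit$se[-1],
                 t_statistics = refit$t[-1], aic = refit$aic,
                 selected = colnames(X), penalty = lam,
                 intercept = s$intercept,
                 meta = list(cv_mse = cv_mse, lambda_grid = lambda_grid,
                             t_source = "ols_refit"))
}

#' Lasso regression with cross-validated penalty
#'
#' Coordinate-descent solution (via glmnet) of
#' `RSS/(2n) + lambda * ||beta||_1` on the standardized design; `lambda` is
#' chosen by tenfold cross-validation with the one-standard-error rule on a
#' 100-point log grid descending four decades from `lambda_max`
#' (the smallest penalty that zeroes every slope). Covariates with exactly
#' zero coefficients are recorded as non-selected; t-statistics come from a
#' post-selection OLS refit on the active set.
#'
#' @param X standardized design matrix.
#' @param y response vector.
#' @param lambda_grid optional penalty grid; default as described.
#' @param cv_folds folds.
#' @param seed fold-assignment seed.
#' @return a `linear_fit` (method `"lasso"`).
#' @export
fit_lasso <- function(X, y, lambda_grid = NULL, cv_folds = 10, seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(lambda_grid)) {
    lam_max <- max(abs(crossprod(X, y - mean(y)))) / n
    lambda_grid <- 10^seq(log10(lam_max), log10(lam_max) - 4,
                          length.out = 100)
  }
  lambda_grid <- sort(unique(lambda_grid), decreasing = TRUE)
  if (length(lambda_grid) == 1) {
    # fixed penalty: no cross-validation
    lam <- lambda_grid
    gfit <- glmnet::glmnet(X, y, alpha = 1,
                           lambda = c(2 * lam, lam), standardize = FALSE,
                           thresh = 1e-12)
    co <- drop(stats::coef(gfit, s = lam))
  } else {
    set.seed(seed)
    foldid <- sample(rep_len(seq_len(cv_folds), n))
    cvf <- glmnet::cv.glmnet(X, y, alpha = 1, lambda = lambda_grid,
                             foldid = foldid, standardize = FALSE,
                             thresh = 1e-12)
    lam <- cvf$lambda.1se
    co <- drop(stats::coef(cvf, s = lam))
  }
  beta <- co[-1]
  names(beta) <- colnames(X)
  active <- names(beta)[beta != 0]
  se <- tval <- setNames(rep(0, ncol(X)), colnames(X))
  if (length(active)) {
    refit <- ols_core(X[, active, drop = FALSE], y)
    se[active] <- refit$se[-1]
    tval[active] <- refit$t[-1]
    aic <- refit$aic
  } else {
    rss <- sum((y - mean(y))^2)
    aic <- n * log(2 * pi * rss / n) + n + 2 * 2
  }
  new_linear_fit("lasso", coefficients = beta, standard_errors = se,
                 t_statistics = tval, aic = aic, selected = active,
                 penalty = lam, intercept = co[1],
                 meta = list(lambda_grid = lambda_grid,
                             rule = "1se", t_source = "ols_refit"))
}

#' Stepwise model selection by AIC
#'
#' Greedy bidirectional search starting from the full model: at each step
#' the single add/drop move that most reduces AIC is applied, stopping at a
#' local minimum (via `MASS::stepAIC`). Deterministic given column order.
#'
#' @param X standardized design matrix, `p <= 60`.
#' @param y response vector.
#' @return a `linear_fit` (method `"step_aic"`); dropped covariates carry
#'   zero coefficients and t-statistics.
#' @export
fit_step_aic <- function(X, y) {
  X <- as.matrix(X)
  stopifnot(ncol(X) <= 60)
  dat <- data.frame(.y = y, X, check.names = FALSE)
  full <- stats::lm(.y ~ ., data = dat)
  step <- MASS::stepAIC(full, direction = "both", trace = 0)
  active <- intersect(colnames(X), names(stats::coef(step)))
  beta <- se <- tval <- setNames(rep(0, ncol(X)), colnames(X))
  if (length(active)) {
    refit <- ols_core(X[, active, drop = FALSE], y)
    beta[active] <- refit$beta[-1]
    se[active] <- refit$se[-1]
    tval[active] <- refit$t[-1]
    intercept <- refit$beta[1]
  } else {
    intercept <- mean(y)
  }
  new_linear_fit("step_aic", coefficients = beta, standard_errors = se,
                 t_statistics = tval, aic = stats::AIC(step),
                 selected = active, intercept = intercept,
                 meta = list(direction = "both"))
}

#' Variable importance from t-statistics
#'
#' Importance of covariate `j` is `|t_j|` normalized so importances sum to
#' 100%; covariates not selected by the method get importance 0.
#'
#' @param fit a `linear_fit`.
#' @return named numeric vector of percentages summing to 100.
#' @export
variable_importance <- function(fit) {
  stopifnot(inherits(fit, "linear_fit"))
  t_abs <- abs(fit$t_statistics)
  t_abs[!names(t_abs) %in% fit$selected] <- 0
  if (all(t_abs == 0)) stop("all t-statistics are zero; VI undefined")
  100 * t_abs / sum(t_abs)
}

#' Variable-importance table across selection methods
#'
#' One row per covariate with each method's coefficient, significance code
#' (`***` p < 0.001, `**` < 0.01, `*` < 0.05, `.` < 0.1) and VI%.
#'
#' @param fits named list of `linear_fit` objects over a common design.
#' @param n sample size used (for p-value degrees of freedom).
#' @return data frame, one row per covariate.
#' @export
vi_table <- function(fits, n) {
  stopifnot(length(fits) >= 1)
  covs <- names(fits[[1]]$coefficients)
  out <- data.frame(covariate = covs, stringsAsFactors = FALSE)
  for (nm in names(fits)) {
    f <- fits[[nm]]
    vi <- variable_importance(f)
    p <- 2 * stats::pt(-abs(f$t_statistics), df = n - length(covs) - 1)
    code <- cut(p, c(0, 0.001, 0.01, 0.05, 0.1, 1),
                labels = c("***", "**", "*", ".", ""), include.lowest = TRUE)
    out[[paste0(nm, "_coef")]] <- round(f$coefficients[covs], 4)
    out[[paste0(nm, "_sig")]] <- as.character(code[match(covs, names(p))])
    out[[paste0(nm, "_vi")]] <- round(vi[covs], 2)
  }
  out
}
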