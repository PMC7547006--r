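#' Train/validation split plan
#'
#' The evaluation protocol: 20% of rows are held out for final assessment;
#' the remaining 80% are partitioned into tenfold cross-validation folds,
#' so each CV iteration trains on 72% of all rows (80% x 9/10) and tests
#' on 8%. A life-stage subset may be applied before splitting: nymph-only
#' and adult-only models are fitted on the surveys where that stage was
#' observed; `"all"` keeps everything including absences.
#'
#' @param train_fraction fraction of rows used for training (default 0.8).
#' @param cv_folds number of CV folds within the training set (default 10).
#' @param seed split seed.
#' @param subset `"all"`, `"nymph_only"`, or `"adult_only"`.
#' @return a `split_plan` list.
#' @export
split_plan <- function(train_fraction = 0.8, cv_folds = 10, seed = 1,
                       subset = c("all", "nymph_only", "adult_only")) {
  stopifnot(train_fraction > 0, train_fraction < 1, cv_folds >= 2)
  structure(list(train_fraction = train_fraction, cv_folds = cv_folds,
                 seed = as.integer(seed), subset = match.arg(subset)),
            class = "split_plan")
}

#' Label rows with holdout / cross-validation fold membership
#'
#' @param table a `feature_table` (needs a `stage` column if a stage subset
#'   is requested).
#' @param plan a [split_plan()].
#' @return the (possibly subset) table with a `split_label` column:
#'   `"holdout"` or `"fold01"` ... `"fold10"`. Deterministic given the
#'   plan's seed.
#' @export
make_split <- function(table, plan = split_plan()) {
  stopifnot(inherits(plan, "split_plan"))
  if (plan$subset != "all") {
    stage <- sub("_only$", "", plan$subset)
    table <- table[table$stage == stage, , drop = FALSE]
  }
  n <- nrow(table)
  if (!n) stop("subset '", plan$subset, "' selects no rows")
  if (n < plan$cv_folds) stop("fewer rows than folds")
  set.seed(plan$seed)
  n_hold <- round((1 - plan$train_fraction) * n)
  hold <- sample.int(n, n_hold)
  lab <- character(n)
  lab[hold] <- "holdout"
  tr <- setdiff(seq_len(n), hold)
  lab[tr] <- sprintf("fold%02d", sample(rep_len(seq_len(plan$cv_folds),
                                                length(tr))))
  table$split_label <- lab
  table
}

#' Model comparison metrics
#'
#' The comparison metrics used across models: AIC (from the fit), R^2 as
#' deviance explained (`1 - deviance/null deviance`), RMSE of predictions
#' on the transformed (sixth-root) response scale, and the Spearman and
#' Kendall rank correlations between observed and predicted (average-rank
#' tie handling).
#'
#' @param observed,predicted equal-length finite numeric vectors on the
#'   transformed response scale.
#' @param fit optional fitted model (`abundance_gam` or `linear_fit`)
#'   supplying AIC and deviance explained.
#' @param model label for the report row.
#' @param n_variables number of covariates, for the report.
#' @return one-row data frame: `model`, `n_variables`, `aic`, `r_squared`,
#'   `rmse`, `spearman_rho`, `kendall_tau`, `n`.
#' @export
eval_metrics <- function(observed, predicted, fit = NULL, model = "",
                         n_variables = NA_integer_) {
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must have equal length")
  }
  stopifnot(all(is.finite(observed)), all(is.finite(predicted)))
  aic <- r2 <- NA_real_
  if (inherits(fit, "abundance_gam")) {
    aic <- fit$aic
    r2 <- fit$deviance_explained
  } else if (inherits(fit, "linear_fit")) {
    aic <- fit$aic
    if (!is.null(fit$meta$r_squared)) r2 <- fit$meta$r_squared
  }
  data.frame(
    model = model, n_variables = n_variables, aic = aic, r_squared = r2,
    rmse = sqrt(mean((predicted - observed)^2)),
    spearman_rho = stats::cor(observed, predicted, method = "spearman"),
    kendall_tau = stats::cor(observed, predicted, method = "kendall"),
    n = length(observed), stringsAsFactors = FALSE
  )
}

#' Observed-versus-predicted bias diagnostic
#'
#' Bins observations and reports the mean prediction bias
#' (`mean(predicted - observed)`) per bin, with its standard error. A
#' positive bias in low-density bins and negative bias in high-density bins
#' is the signature of shrinkage toward the mean.
#'
#' @param observed,predicted vectors on a common (density or transformed)
#'   scale.
#' @param breaks bin breakpoints for `observed`; exactly-zero observations
#'   get their own bin. Default: zero bin plus `(0, 0.6], (0.6, 1], (1, Inf)`.
#' @return data frame `bin`, `n`, `mean_observed`, `mean_predicted`,
#'   `bias`, `se_bias`; bins partition the data (counts sum to `n`).
#' @export
obs_vs_pred_diagnostic <- function(observed, predicted,
                                   breaks = c(0, 0.6, 1, Inf)) {
  stopifnot(length(observed) == length(predicted))
  zero <- observed == 0
  bin <- rep(NA_character_, length(observed))
  bin[zero] <- "zero"
  if (any(!zero)) {
    cut_ <- cut(observed[!zero], breaks = unique(c(0, breaks, Inf)),
                include.lowest = FALSE)
    bin[!zero] <- as.character(cut_)
  }
  parts <- split(seq_along(observed), bin)
  rows <- lapply(names(parts), function(b) {
    i <- parts[[b]]
    d <- predicted[i] - observed[i]
    data.frame(bin = b, n = length(i),
               mean_observed = mean(observed[i]),
               mean_predicted = mean(predicted[i]),
               bias = mean(d),
               se_bias = if (length(i) > 1) stats::sd(d) / sqrt(length(i))
                         else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$mean_observed), ]
}
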