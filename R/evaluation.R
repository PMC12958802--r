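# Evaluation under the five-problem taxonomy: across/within-environment
# metrics, RMSE decomposition, intercept baseline, and replicate-aware
# Dunnett comparisons against a control model.

PROBLEM_MODALITIES <- list(
  `1` = c("additive"),
  `2` = c("additive", "dominance"),
  `3` = c("additive", "dominance", "genomic_nonlinear"),
  `4` = c("additive", "dominance", "genomic_nonlinear", "soil", "weather",
          "interaction"),
  `5` = c("soil", "weather")
)

PROBLEM_PREDICTANDS <- c(`1` = "breeding value", `2` = "hybrid value",
                         `3` = "total genetic value", `4` = "phenotype",
                         `5` = "site mean")

#' Specification of a prediction problem
#'
#' The five problems form a hierarchy of data modalities and predictands:
#' (1) additive genomic data only, predicting breeding values; (2) adding
#' dominance deviations, predicting hybrid values; (3) adding non-linear
#' genomic kernels or genomic networks, predicting total genetic values;
#' (4) adding soil, weather and their interactions, predicting phenotypes;
#' (5) environmental data only, predicting site means.
#'
#' @param problem Integer 1-5.
#' @return A `problem_spec` with `problem`, `allowed_modalities`,
#'   `predictand`.
#' @export
problem_spec <- function(problem) {
  problem <- check_count(problem, "problem")
  if (problem > 5L) stopf("`problem` must be one of 1..5")
  key <- as.character(problem)
  structure(list(problem = problem,
                 allowed_modalities = PROBLEM_MODALITIES[[key]],
                 predictand = PROBLEM_PREDICTANDS[[key]]),
            class = "problem_spec")
}

#' @export
print.problem_spec <- function(x, ...) {
  cat(sprintf("Prediction problem %d: %s from {%s}\n", x$problem, x$predictand,
              paste(x$allowed_modalities, collapse = ", ")))
  invisible(x)
}

#' Pearson correlation and RMSE, across and within environments
#'
#' @param observed,predicted Aligned numeric vectors.
#' @param env Optional environment labels; per-environment metrics are
#'   computed for environments with at least `min_group` records. An
#'   environment with zero variance in the observed values gets a missing
#'   correlation with a warning.
#' @param min_group Minimum records per scored environment (default 3).
#' @return Tidy data frame (scope, env, metric, value).
#' @export
score <- function(observed, predicted, env = NULL, min_group = 3L) {
  if (length(observed) != length(predicted)) stopf("vectors must be aligned")
  if (length(observed) < min_group) stopf("need at least %d records", min_group)
  one <- function(o, p, scope, envname) {
    r <- if (stats::sd(o) < .Machine$double.eps || stats::sd(p) < .Machine$double.eps) {
      warning(sprintf("zero variance in %s: correlation undefined", envname),
              call. = FALSE)
      NA_real_
    } else {
      stats::cor(o, p)
    }
    data.frame(scope = scope, env = envname, metric = c("r", "rmse"),
               value = c(r, rmse(o, p)))
  }
  out <- one(observed, predicted, "across", "all")
  if (!is.null(env)) {
    for (e in unique(env)) {
      idx <- which(env == e)
      if (length(idx) >= min_group) {
        out <- rbind(out, one(observed[idx], predicted[idx], "within", e))
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Three-component orthogonal decomposition of the MSE
#'
#' `MSE = (mean_pred - mean_obs)^2 + (sd_pred - sd_obs)^2 +
#' 2 sd_pred sd_obs (1 - r)`: squared bias, squared standard-deviation
#' mismatch, and lack of correlation. Standard deviations use the 1/n
#' convention so the three parts sum to the MSE exactly; when either sd is
#' zero the correlation term is set to 0.
#'
#' @param observed,predicted Aligned numeric vectors (length >= 3).
#' @return Named numeric: `bias2`, `sd_mismatch2`, `correlation_lack`.
#' @export
rmse_decomposition <- function(observed, predicted) {
  n <- length(observed)
  if (n < 3L || n != length(predicted)) stopf("need aligned vectors of length >= 3")
  mo <- mean(observed); mp <- mean(predicted)
  so <- sqrt(mean((observed - mo)^2))
  sp <- sqrt(mean((predicted - mp)^2))
  r <- if (so * sp > 0) stats::cor(observed, predicted) else 0
  c(bias2 = (mp - mo)^2, sd_mismatch2 = (sp - so)^2,
    correlation_lack = 2 * sp * so * (1 - r))
}

#' RMSE of the intercept-only baseline
#'
#' Predicts every test record with the training-set mean; the floor any
#' useful model must beat.
#'
#' @param train_y,test_y Training and test responses.
#' @return The baseline RMSE.
#' @export
intercept_baseline <- function(train_y, test_y) {
  if (length(train_y) == 0L || length(test_y) == 0L) stopf("empty partition")
  rmse(test_y, rep(mean(train_y), length(test_y)))
}

#' Dunnett many-to-one comparisons of replicate metrics
#'
#' Compares each model's replicate metric values against a designated
#' control with familywise error control, one-sided in the direction that
#' means "better" ("greater" for correlation, "less" for RMSE). Uses the
#' multivariate-t reference distribution of the maximum statistic. When the
#' residual variance is exactly zero and all group means equal the
#' control's, the adjusted p-values are reported as 1.
#'
#' @param values Numeric metric values (one per model replicate).
#' @param groups Model labels, same length as `values`.
#' @param control The control model's label.
#' @param direction "greater" or "less": the alternative for a better
#'   model.
#' @return Data frame (comparison, estimate, p_adjusted).
#' @export
dunnett_test <- function(values, groups, control,
                         direction = c("greater", "less")) {
  direction <- match.arg(direction)
  groups <- as.character(groups)
  if (!control %in% groups) stopf("control group '%s' not present", control)
  if (min(table(groups)) < 2L) stopf("need at least 2 replicates per group")
  g <- stats::relevel(factor(groups), ref = control)
  df <- data.frame(value = values, g = g)
  if (stats::sd(values) < .Machine$double.eps) {
    cmp <- setdiff(levels(g), control)
    return(data.frame(comparison = paste(cmp, "-", control),
                      estimate = 0, p_adjusted = 1))
  }
  fit <- stats::aov(value ~ g, data = df)
  glt <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"),
                        alternative = direction)
  sm <- summary(glt)
  data.frame(comparison = names(sm$test$coefficients),
             estimate = as.numeric(sm$test$coefficients),
             p_adjusted = as.numeric(sm$test$pvalues))
}

#' Score a set of fitted models under one prediction problem
#'
#' Every supplied model must use only modalities allowed by the problem;
#' a violation is an error naming the offending modality (a Problem-3
#' model is never silently scored inside a Problem-1 report). Each model
#' contributes replicate prediction vectors which are scored across and
#' within environments; replicate across-environment metrics feed a
#' Dunnett comparison against the designated control.
#'
#' @param problem A [problem_spec()] (or integer 1-5).
#' @param models Named list; each element has `predictions` (replicates x
#'   test-record matrix) and `modalities` (character vector).
#' @param observed Test-set observed responses (aligned with prediction
#'   columns).
#' @param env Optional test-record environment labels.
#' @param train_y Training responses for the intercept baseline.
#' @param control Model name used as the Dunnett control (default: best
#'   mean r).
#' @return An `eval_report`: `metrics` (model x replicate x scope tidy
#'   frame), `decomposition`, `dunnett` (per metric), `baseline_rmse`,
#'   `problem`.
#' @export
run_taxonomy <- function(problem, models, observed, env = NULL, train_y = NULL,
                         control = NULL) {
  if (!inherits(problem, "problem_spec")) problem <- problem_spec(problem)
  if (is.null(names(models)) || any(names(models) == "")) {
    stopf("`models` must be a named list")
  }
  for (nm in names(models)) {
    bad <- setdiff(models[[nm]]$modalities, problem$allowed_modalities)
    if (length(bad) > 0L) {
      stopf("model '%s' uses modality '%s' not allowed in problem %d",
            nm, bad[1], problem$problem)
    }
  }
  metrics <- NULL
  decomp <- NULL
  for (nm in names(models)) {
    P <- models[[nm]]$predictions
    if (is.null(dim(P))) P <- matrix(P, nrow = 1L)
    for (rep_i in seq_len(nrow(P))) {
      sc <- score(observed, P[rep_i, ], env = env)
      sc$model <- nm
      sc$replicate <- rep_i
      metrics <- rbind(metrics, sc)
      dc <- rmse_decomposition(observed, P[rep_i, ])
      decomp <- rbind(decomp, data.frame(model = nm, replicate = rep_i,
                                         t(dc)))
    }
  }
  across <- metrics[metrics$scope == "across", ]
  dunnett <- NULL
  if (length(models) >= 2L && all(table(across$model[across$metric == "r"]) >= 2L)) {
    mean_r <- tapply(across$value[across$metric == "r"],
                     across$model[across$metric == "r"], mean)
    ctrl <- control %||% names(which.max(mean_r))
    dunnett <- list(
      r = dunnett_test(across$value[across$metric == "r"],
                       across$model[across$metric == "r"], ctrl, "greater"),
      rmse = dunnett_test(across$value[across$metric == "rmse"],
                          across$model[across$metric == "rmse"], ctrl, "less"),
      control = ctrl)
  }
  structure(list(metrics = metrics, decomposition = decomp, dunnett = dunnett,
                 baseline_rmse = if (!is.null(train_y)) {
                   intercept_baseline(train_y, observed)
                 } else NA_real_,
                 problem = problem),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation report, problem %d (%s)\n", x$problem$problem,
              x$problem$predictand))
  across <- x$metrics[x$metrics$scope == "across", ]
  agg <- stats::aggregate(value ~ model + metric, across, mean)
  print(stats::reshape(agg, idvar = "model", timevar = "metric",
                       direction = "wide"))
  if (!is.na(x$baseline_rmse)) {
    cat(sprintf("intercept-only baseline RMSE: %.4f\n", x$baseline_rmse))
  }
  invisible(x)
}
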