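# Model-ready environmental covariates: windowed weather summaries and
# train-statistics standardization.

#' Average daily weather over non-overlapping windows
#'
#' Summarizes each site-year's daily series as the mean over consecutive,
#' non-overlapping windows of `window_days` days. When the day count is not
#' divisible by the window length, the trailing partial window is kept and
#' averaged over its available days (a 280-day season at 3-day windows thus
#' gives 93 full windows plus one 1-day window, 94 in all).
#'
#' @param trial A `trial_design` (from [simulate_environments()]) or a named
#'   list of variables x days matrices sharing one day grid.
#' @param window_days Window length in days (default 3).
#' @return A `windowed_weather`: list with `values` (site-years x
#'   variable-window columns named `<variable>_w<k>`), `n_windows`, and
#'   `window_days`.
#' @export
window_weather <- function(trial, window_days = 3L) {
  window_days <- check_count(window_days, "window_days")
  grids <- if (inherits(trial, "trial_design")) trial$weather else trial
  if (!is.list(grids) || length(grids) == 0L) stopf("empty weather series")
  n_days <- ncol(grids[[1]])
  if (n_days == 0L) stopf("empty weather series")
  if (!all(vapply(grids, ncol, 0L) == n_days)) {
    stopf("all site-years must share the same day range")
  }
  win <- rep(seq_len(ceiling(n_days / window_days)), each = window_days)[seq_len(n_days)]
  n_win <- max(win)
  vars <- rownames(grids[[1]]) %||% sprintf("wx%02d", seq_len(nrow(grids[[1]])))
  vals <- t(vapply(grids, function(W) {
    # rows: variables; per-variable window means, laid out variable-major
    wm <- apply(W, 1L, function(x) tapply(x, win, mean))  # n_win x n_vars
    if (is.null(dim(wm))) wm <- matrix(wm, nrow = 1L)
    as.vector(wm)
  }, numeric(nrow(grids[[1]]) * n_win)))
  colnames(vals) <- as.vector(t(outer(vars, seq_len(n_win),
                                      function(v, k) sprintf("%s_w%d", v, k))))
  rownames(vals) <- names(grids)
  structure(list(values = vals, n_windows = n_win, window_days = window_days),
            class = "windowed_weather")
}

#' @export
print.windowed_weather <- function(x, ...) {
  cat(sprintf("Windowed weather: %d site-years x %d columns (%d windows of %d days)\n",
              nrow(x$values), ncol(x$values), x$n_windows, x$window_days))
  invisible(x)
}

#' Standardize feature columns by training-set statistics
#'
#' Centers and scales each column by the mean and standard deviation of the
#' training rows only; the stored statistics are applied unchanged to test
#' rows, so no test information leaks into the transformation.
#' Zero-variance training columns are dropped with a warning.
#'
#' @param table Numeric matrix (rows = records/site-years) or a
#'   `windowed_weather` object.
#' @param train_ids Row names (or logical/integer index) of the training
#'   rows used to compute the statistics.
#' @return List with `values` (standardized matrix over all rows), `center`,
#'   `scale`, and `dropped` column names.
#' @export
standardize_features <- function(table, train_ids) {
  X <- if (inherits(table, "windowed_weather")) table$values else as.matrix(table)
  rows <- if (is.character(train_ids)) match(train_ids, rownames(X)) else train_ids
  Xtr <- X[rows, , drop = FALSE]
  if (nrow(Xtr) == 0L || anyNA(rows)) stopf("empty or unmatched training subset")
  ctr <- colMeans(Xtr)
  scl <- apply(Xtr, 2L, stats::sd)
  bad <- !is.finite(scl) | scl < .Machine$double.eps
  if (any(bad)) {
    warning(sprintf("dropping %d zero-variance column(s): %s", sum(bad),
                    paste(utils::head(colnames(X)[bad], 5L), collapse = ", ")),
            call. = FALSE)
  }
  keep <- !bad
  out <- sweep(sweep(X[, keep, drop = FALSE], 2L, ctr[keep], `-`),
               2L, scl[keep], `/`)
  list(values = out, center = ctr[keep], scale = scl[keep],
       dropped = colnames(X)[bad])
}

#' Undo a training-statistics standardization
#'
#' @param std Output of [standardize_features()].
#' @param values Standardized matrix (defaults to `std$values`).
#' @return Matrix on the original scale.
#' @export
destandardize_features <- function(std, values = std$values) {
  sweep(sweep(values, 2L, std$scale, `*`), 2L, std$center, `+`)
}
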