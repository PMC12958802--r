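# Multi-kernel Bayesian RKHS model fitted by Gibbs sampling in the kernel
# eigenbasis: y = 1 mu + sum_k u_k + eps, u_k ~ N(0, K_k sigma2_k).

#' Specify a multi-kernel Bayesian RKHS model
#'
#' @param kernels Named list of [eigendecompose()] bases, each over the full
#'   record set (training and prediction records), sharing one labeling.
#' @param iterations,burnin,thin Chain settings (defaults 15000 / 5000 / 5).
#' @param seed Chain seed. Each kernel is given its own RNG stream keyed by
#'   its name, so the draws attributed to a kernel do not depend on its
#'   position in the list.
#' @param prior_df Degrees of freedom of the scaled-inverse-chi-square
#'   priors on every variance (default 5).
#' @param prior_scales Optional named scales for the variance priors
#'   (entries per kernel plus `residual`); by default chosen so each prior
#'   mode equals `var(y_train) / (n_kernels + 1)`.
#' @return A `model_spec`.
#' @export
model_spec <- function(kernels, iterations = 15000L, burnin = 5000L, thin = 5L,
                       seed = 1L, prior_df = 5, prior_scales = NULL) {
  if (length(kernels) == 0L) stopf("at least one kernel is required")
  if (is.null(names(kernels)) || any(names(kernels) == "")) {
    names(kernels) <- sprintf("K%d", seq_along(kernels))
  }
  for (b in kernels) stopifnot(inherits(b, "eigen_basis"))
  n <- nrow(kernels[[1]]$vectors)
  for (b in kernels) {
    if (nrow(b$vectors) != n) stopf("all kernels must span the same records")
    if (!identical(b$labels, kernels[[1]]$labels)) {
      stopf("kernel record labels disagree")
    }
  }
  iterations <- check_count(iterations, "iterations")
  burnin <- check_count(burnin, "burnin", min = 0L)
  thin <- check_count(thin, "thin")
  if (iterations <= burnin) stopf("iterations must exceed burnin")
  structure(list(kernels = kernels, iterations = iterations, burnin = burnin,
                 thin = thin, seed = as.integer(seed), prior_df = prior_df,
                 prior_scales = prior_scales, n_records = n,
                 labels = kernels[[1]]$labels),
            class = "model_spec")
}

#' Fit the multi-kernel model by Gibbs sampling
#'
#' Samples, in turn, the eigenbasis coefficients of each kernel's random
#' effect (whose full conditionals are independent Gaussians because the
#' eigenvectors are orthonormal), the kernel and residual variances from
#' scaled-inverse-chi-square full conditionals, and the mean from its
#' Gaussian full conditional with a flat prior. Records with `NA`
#' responses are handled by exact data augmentation (imputed from the
#' current conditional distribution each sweep), so the posterior is the
#' one conditioned on the observed (training) records only, while every
#' conditional stays diagonal.
#'
#' @param y Numeric response vector over all records in the spec's
#'   labeling, `NA` for records to predict; standardized scale recommended.
#' @param spec A [model_spec()].
#' @param fixed_variances Optional named list freezing variances instead of
#'   sampling them (entries per kernel and/or `residual`) — used for
#'   closed-form equivalence checks.
#' @param verbose Print progress every 1000 sweeps.
#' @return A `posterior_draws` object: retained draws of `mu`, each
#'   variance, and the record-level genetic values `g = sum_k u_k`.
#' @export
fit_multikernel <- function(y, spec, fixed_variances = NULL, verbose = FALSE) {
  stopifnot(inherits(spec, "model_spec"))
  n <- spec$n_records
  if (length(y) != n) stopf("`y` must have one entry per record in the spec")
  obs <- which(!is.na(y))
  if (length(obs) < 2L) stopf("need at least 2 observed records")
  miss <- which(is.na(y))
  kn <- names(spec$kernels)
  nk <- length(kn)
  nu <- spec$prior_df

  vy <- stats::var(y[obs])
  default_mode <- vy / (nk + 1)
  scales <- spec$prior_scales %||%
    stats::setNames(rep(default_mode * (nu + 2) / nu, nk + 1L), c(kn, "residual"))

  U <- lapply(spec$kernels, function(b) b$vectors)
  lam <- lapply(spec$kernels, function(b) pmax(b$values, 1e-12))
  r_k <- vapply(lam, length, 0L)

  fixed <- names(fixed_variances %||% list())
  s2 <- stats::setNames(rep(vy / (nk + 1), nk + 1L), c(kn, "residual"))
  for (f in fixed) s2[[f]] <- fixed_variances[[f]]

  streams <- rng_streams(spec$seed, c(kn, ".global"))

  mu <- mean(y[obs])
  yfull <- y
  if (length(miss) > 0L) yfull[miss] <- mu
  b <- lapply(r_k, function(r) numeric(r))
  u <- lapply(seq_len(nk), function(k) numeric(n))
  names(b) <- names(u) <- kn
  e <- yfull - mu

  n_ret <- (spec$iterations - spec$burnin) %/% spec$thin
  draw_mu <- numeric(n_ret)
  draw_s2 <- matrix(NA_real_, n_ret, nk + 1L,
                    dimnames = list(NULL, c(kn, "residual")))
  draw_g <- matrix(NA_real_, n_ret, n)
  colnames(draw_g) <- spec$labels %||% as.character(seq_len(n))
  ridx <- 0L

  for (it in seq_len(spec$iterations)) {
    for (k in kn) {
      e <- e + u[[k]]
      # the stream expression evaluates in this frame: `<-` updates locals
      stream_eval(streams, k, {
        v <- crossprod(U[[k]], e)
        cond_var <- 1 / (1 / s2[["residual"]] + 1 / (lam[[k]] * s2[[k]]))
        cond_mean <- cond_var * v / s2[["residual"]]
        b[[k]] <- cond_mean + sqrt(cond_var) * stats::rnorm(r_k[[k]])
        if (!(k %in% fixed)) {
          ss <- sum(b[[k]]^2 / lam[[k]])
          s2[[k]] <- (ss + nu * scales[[k]]) / stats::rchisq(1L, nu + r_k[[k]])
        }
      })
      u[[k]] <- as.vector(U[[k]] %*% b[[k]])
      e <- e - u[[k]]
    }
    stream_eval(streams, ".global", {
      # mean (flat prior)
      e <- e + mu
      mu <- mean(e) + stats::rnorm(1L) * sqrt(s2[["residual"]] / n)
      e <- e - mu
      # residual variance
      if (!("residual" %in% fixed)) {
        s2[["residual"]] <- (sum(e^2) + nu * scales[["residual"]]) /
          stats::rchisq(1L, nu + n)
      }
      # impute unobserved responses
      if (length(miss) > 0L) {
        eps <- stats::rnorm(length(miss)) * sqrt(s2[["residual"]])
        g_miss <- Reduce(`+`, lapply(u, `[`, miss))
        yfull[miss] <- mu + g_miss + eps
        e[miss] <- eps
      }
    })
    if (!all(is.finite(e))) stopf("divergence: non-finite residuals at iteration %d", it)
    if (it > spec$burnin && (it - spec$burnin) %% spec$thin == 0L) {
      ridx <- ridx + 1L
      draw_mu[ridx] <- mu
      draw_s2[ridx, ] <- s2
      draw_g[ridx, ] <- Reduce(`+`, u)
    }
    if (verbose && it %% 1000L == 0L) {
      message(sprintf("iteration %d / %d", it, spec$iterations))
    }
  }
  structure(list(mu = draw_mu, sigma2 = draw_s2, g = draw_g,
                 n_retained = n_ret, labels = colnames(draw_g),
                 observed = obs, spec_settings = spec[c("iterations", "burnin", "thin", "seed")],
                 kernel_names = kn),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("Posterior draws: %d retained (%d kernels, %d records)\n",
              x$n_retained, length(x$kernel_names), ncol(x$g)))
  invisible(x)
}

#' Posterior-mean predictions for requested records
#'
#' @param object A `posterior_draws` fit.
#' @param ids Record labels (or indices) to predict; defaults to all.
#' @param train_stats Optional named vector `c(mean=, sd=)` to map
#'   standardized predictions back to the original response scale.
#' @param ... Unused.
#' @return Named numeric vector of posterior means of `mu + g`.
#' @export
predict.posterior_draws <- function(object, ids = NULL, train_stats = NULL, ...) {
  idx <- if (is.null(ids)) {
    seq_len(ncol(object$g))
  } else if (is.numeric(ids)) {
    ids
  } else {
    m <- match(ids, object$labels)
    if (anyNA(m)) stopf("unknown record id(s): %s",
                        paste(utils::head(ids[is.na(m)], 5L), collapse = ", "))
    m
  }
  pred <- mean(object$mu) + colMeans(object$g[, idx, drop = FALSE])
  names(pred) <- object$labels[idx]
  if (!is.null(train_stats)) {
    pred <- pred * train_stats[["sd"]] + train_stats[["mean"]]
  }
  pred
}

#' Posterior summary of variance components
#'
#' @param draws A `posterior_draws` fit.
#' @return Data frame with one row per variance (each kernel plus the
#'   residual): posterior mean, sd, 95% credible interval, and the
#'   posterior mean proportion of total variance (proportions computed per
#'   draw, so the column sums to 1).
#' @export
variance_components <- function(draws) {
  stopifnot(inherits(draws, "posterior_draws"))
  if (draws$n_retained == 0L) stopf("no retained draws: empty summary")
  S <- draws$sigma2
  prop <- S / rowSums(S)
  data.frame(component = colnames(S),
             mean = colMeans(S),
             sd = apply(S, 2L, stats::sd),
             q2.5 = apply(S, 2L, stats::quantile, 0.025),
             q97.5 = apply(S, 2L, stats::quantile, 0.975),
             proportion = colMeans(prop),
             row.names = NULL)
}
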