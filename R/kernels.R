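# Kernel engine: linear, Gaussian, and arc-cosine kernels; composite
# weather kernels; Hadamard-product expansion; truncated eigendecomposition.

new_kernel <- function(values, kind, hyper = list(), normalized = FALSE) {
  values <- (values + t(values)) / 2  # enforce exact symmetry of roundoff
  structure(values, class = c("kernel_matrix", "matrix"),
            kind = kind, hyper = hyper, normalized = normalized)
}

#' @export
print.kernel_matrix <- function(x, ...) {
  cat(sprintf("%s kernel: %d x %d", attr(x, "kind"), nrow(x), ncol(x)))
  h <- attr(x, "hyper")
  if (length(h) > 0) {
    cat(" (", paste(names(h), unlist(h), sep = "=", collapse = ", "), ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Validate the defining properties of a kernel matrix
#'
#' Checks symmetry (to 1e-10), finiteness, and positive semi-definiteness
#' (minimum eigenvalue >= -1e-8 times the maximum).
#'
#' @param K Square numeric matrix.
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_kernel <- function(K) {
  if (!isTRUE(all(is.finite(K)))) stopf("kernel contains non-finite entries")
  if (max(abs(K - t(K))) > 1e-10) stopf("kernel is not symmetric")
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) {
    stopf("kernel is not positive semi-definite (min eigenvalue %g)", min(ev))
  }
  invisible(TRUE)
}

#' Linear (genomic-relationship) kernel
#'
#' Computes `X X'` and normalizes it by `tr(X X')/n` so that the trace of
#' the returned kernel equals the record count, placing linear kernels of
#' different predictor sets on a common scale.
#'
#' @param X Numeric matrix of (coded) features, records x features.
#' @return A `kernel_matrix` of kind "linear" with trace `n`.
#' @export
linear_kernel <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stopf("need at least 2 records")
  K0 <- tcrossprod(X)
  tr <- sum(diag(K0))
  if (tr < .Machine$double.eps) stopf("degenerate input: all-zero feature matrix")
  K <- K0 / (tr / nrow(X))
  rownames(K) <- colnames(K) <- rownames(X)
  new_kernel(K, "linear", normalized = TRUE)
}

squared_distances <- function(X) {
  sq <- rowSums(X^2)
  D2 <- outer(sq, sq, `+`) - 2 * tcrossprod(X)
  D2[D2 < 0] <- 0
  diag(D2) <- 0
  D2
}

#' Gaussian kernel with median-distance scaling
#'
#' `k(i, i') = exp(-h * d2(i, i') / q)` where `d2` is the squared Euclidean
#' distance and `q` the median of the off-diagonal squared distances, so
#' the bandwidth `h` is unitless across predictor sets. The diagonal is
#' exactly 1.
#'
#' @param X Records x features matrix.
#' @param h Bandwidth (> 0) controlling the decay of similarity.
#' @param q Optional pre-computed median squared distance (reused when
#'   scanning over `h`).
#' @return A `kernel_matrix` of kind "gaussian" with hyperparameters `h`, `q`.
#' @export
gaussian_kernel <- function(X, h = 1, q = NULL) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stopf("need at least 2 records")
  if (!is.numeric(h) || h <= 0) stopf("bandwidth `h` must be positive")
  D2 <- squared_distances(X)
  q <- q %||% stats::median(D2[upper.tri(D2)])
  if (q < .Machine$double.eps) stopf("degenerate distances: all records identical")
  K <- exp(-h * D2 / q)
  diag(K) <- 1
  rownames(K) <- colnames(K) <- rownames(X)
  new_kernel(K, "gaussian", hyper = list(h = h, q = q))
}

acos_clipped <- function(x, tol = 1e-12) {
  over <- abs(x) - 1
  if (any(over > tol)) {
    stopf("arc-cosine argument outside [-1, 1] beyond tolerance (max overshoot %g)",
          max(over))
  }
  acos(pmin(pmax(x, -1), 1))
}

ak_J <- function(theta) sin(theta) + (pi - theta) * cos(theta)

#' Arc-cosine kernel of a given depth
#'
#' The order-1 arc-cosine kernel equals the covariance function of an
#' infinite-width single-hidden-layer ReLU network; deeper kernels are
#' obtained by recursion. Layer 1 uses the angle between input vectors,
#' `k1 = (1/pi) |x| |x'| J(theta)` with
#' `J(theta) = sin(theta) + (pi - theta) cos(theta)`; layer `l+1` applies
#' the same construction to the layer-`l` kernel.
#'
#' @param X Records x features matrix with no zero-norm row.
#' @param layers Depth `l >= 1`.
#' @return A `kernel_matrix` of kind "arccosine" with hyperparameter `l`.
#' @export
arc_cosine_kernel <- function(X, layers = 1L) {
  X <- as.matrix(X)
  layers <- check_count(layers, "layers")
  norms <- sqrt(rowSums(X^2))
  if (any(norms < .Machine$double.eps)) stopf("zero-norm row: arc-cosine kernel undefined")
  npnp <- outer(norms, norms)
  costheta <- tcrossprod(X) / npnp
  K <- (1 / pi) * npnp * ak_J(acos_clipped(costheta))
  if (layers > 1L) {
    for (l in seq_len(layers - 1L)) {
      dk <- diag(K)
      np <- sqrt(outer(dk, dk))
      K <- (1 / pi) * np * ak_J(acos_clipped(K / np))
    }
  }
  rownames(K) <- colnames(K) <- rownames(X)
  new_kernel(K, "arccosine", hyper = list(l = layers))
}

#' Combine per-variable kernels into a composite weather kernel
#'
#' Linear constituents are summed and trace-normalized (each covariate
#' enters with equal weight); Gaussian and arc-cosine constituents are
#' combined as a weighted average with weights proportional to the inverse
#' of each variable's optimized hyperparameter (bandwidth or layer count),
#' normalized to sum to 1, so variables with strong global similarity
#' contribute more.
#'
#' @param kernels Named list of `kernel_matrix` objects sharing record
#'   labels.
#' @param kind One of "linear", "gaussian", "arccosine".
#' @param hyperparams Optional numeric vector of constituent hyperparameters
#'   (defaults to each kernel's own stored `h` or `l`).
#' @return A composite `kernel_matrix`.
#' @export
composite_weather_kernel <- function(kernels, kind = c("linear", "gaussian", "arccosine"),
                                     hyperparams = NULL) {
  kind <- match.arg(kind)
  if (length(kernels) == 0L) stopf("no constituent kernels")
  labs <- rownames(kernels[[1]])
  for (K in kernels) {
    if (!identical(rownames(K), labs)) stopf("constituent kernels have mismatched record labels")
  }
  if (kind == "linear") {
    S <- Reduce(`+`, lapply(kernels, unclass))
    tr <- sum(diag(S))
    out <- S / (tr / nrow(S))
    return(new_kernel(out, "composite", hyper = list(kind = kind), normalized = TRUE))
  }
  hp <- hyperparams %||% vapply(kernels, function(K) {
    h <- attr(K, "hyper")
    as.numeric(h$h %||% h$l %||% NA_real_)
  }, numeric(1))
  if (anyNA(hp) || any(hp <= 0)) stopf("constituent hyperparameters must be positive")
  w <- (1 / hp) / sum(1 / hp)
  S <- Reduce(`+`, Map(function(K, wi) wi * unclass(K), kernels, w))
  new_kernel(S, "composite", hyper = list(kind = kind, weights = w))
}

#' Incidence matrix mapping records to factor levels
#'
#' @param labels Character vector: the level of each record.
#' @param levels Optional level ordering (defaults to order of appearance).
#' @return Binary records x levels matrix.
#' @export
incidence_matrix <- function(labels, levels = unique(labels)) {
  Z <- matrix(0L, length(labels), length(levels),
              dimnames = list(NULL, levels))
  Z[cbind(seq_along(labels), match(labels, levels))] <- 1L
  Z
}

#' Expand kernels to the record level via the Hadamard product
#'
#' Expands level-wise kernels (e.g. a hybrid kernel and an environment
#' kernel) to the similarity structure over all records:
#' `(Z_a K_a Z_a') * (Z_b K_b Z_b')` elementwise. For a main-effect
#' (single-data) expansion, pass `K_b = "identity"` to substitute an
#' identity kernel over the second factor's levels, or omit `K_b`/`Z_b`
#' entirely to return `Z_a K_a Z_a'`.
#'
#' @param K_a Kernel over the levels of factor a.
#' @param Z_a Records x levels incidence for factor a.
#' @param K_b Kernel over factor-b levels, `"identity"`, or `NULL`.
#' @param Z_b Records x levels incidence for factor b.
#' @return A `kernel_matrix` of kind "interaction" (or the expanded
#'   main-effect kernel).
#' @export
expand_kernel <- function(K_a, Z_a, K_b = NULL, Z_b = NULL) {
  K_a <- as.matrix(K_a)
  if (ncol(Z_a) != nrow(K_a)) stopf("Z_a columns must match K_a dimension")
  A <- Z_a %*% K_a %*% t(Z_a)
  if (is.null(K_b)) {
    return(new_kernel(A, "interaction", hyper = list(expansion = "main")))
  }
  if (is.null(Z_b)) stopf("Z_b required when K_b is supplied")
  if (identical(K_b, "identity")) K_b <- diag(ncol(Z_b))
  K_b <- as.matrix(K_b)
  if (ncol(Z_b) != nrow(K_b)) stopf("Z_b columns must match K_b dimension")
  if (nrow(Z_b) != nrow(Z_a)) stopf("incidence matrices must cover the same records")
  B <- Z_b %*% K_b %*% t(Z_b)
  new_kernel(A * B, "interaction", hyper = list(expansion = "hadamard"))
}

#' Truncated eigendecomposition of a kernel
#'
#' Eigendecomposes a symmetric kernel and truncates at eigenvalues below
#' `tol` or at `max_rank` components, whichever binds first.
#'
#' @param K Symmetric kernel matrix.
#' @param tol Eigenvalue truncation threshold (default 1e-10).
#' @param max_rank Maximum retained components (default 7500).
#' @return An `eigen_basis`: `vectors` (n x r), `values` (descending),
#'   `variance_captured` (retained over total positive eigenmass),
#'   `labels`, and the truncation rule applied.
#' @export
eigendecompose <- function(K, tol = 1e-10, max_rank = 7500L) {
  K <- as.matrix(K)
  if (max(abs(K - t(K))) > 1e-8) stopf("matrix is not symmetric: not a valid kernel")
  eg <- eigen((K + t(K)) / 2, symmetric = TRUE)
  keep <- which(eg$values >= tol)
  rule <- "tolerance"
  if (length(keep) > max_rank) {
    keep <- keep[seq_len(max_rank)]
    rule <- "max_rank"
  }
  total <- sum(pmax(eg$values, 0))
  structure(list(vectors = eg$vectors[, keep, drop = FALSE],
                 values = eg$values[keep],
                 variance_captured = if (total > 0) sum(eg$values[keep]) / total else NA_real_,
                 truncation = rule, tol = tol, max_rank = max_rank,
                 labels = rownames(K)),
            class = "eigen_basis")
}

#' @export
print.eigen_basis <- function(x, ...) {
  cat(sprintf("Eigenbasis: %d components retained (%.2f%% of positive eigenmass, %s truncation)\n",
              length(x$values), 100 * x$variance_captured, x$truncation))
  invisible(x)
}
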