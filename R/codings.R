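# Genomic predictor sets: additive/dominance codings, principal components,
# hybrid-PC algebra, Fisher combination, and mixed-model GWAS selection.

resolve_geno <- function(G) {
  if (inherits(G, "geno_matrix")) return(G)
  geno_matrix(G)
}

check_freqs <- function(freqs) {
  if (any(freqs <= 0 | freqs >= 1)) {
    stopf("monomorphic locus (allele frequency 0 or 1); drop such loci before coding")
  }
  freqs
}

#' Drop monomorphic loci from a genotype matrix
#'
#' @param G A `geno_matrix`.
#' @return The `geno_matrix` restricted to polymorphic loci; warns when loci
#'   are removed.
#' @export
drop_monomorphic <- function(G) {
  G <- resolve_geno(G)
  poly <- G$freqs > 0 & G$freqs < 1
  if (!all(poly)) {
    warning(sprintf("dropping %d monomorphic loci", sum(!poly)), call. = FALSE)
    G <- geno_matrix(G$calls[, poly, drop = FALSE], G$freqs[poly])
  }
  G
}

#' Additive marker coding
#'
#' Centers reference-allele counts by twice the allele frequency: a call
#' `c` at a locus with reference frequency `p` maps to `c - 2p`, so under
#' Hardy-Weinberg proportions the coded value has expectation zero.
#'
#' @param G A `geno_matrix` (or raw call matrix) with calls in {0,1,2}.
#' @param freqs Optional reference allele frequencies, e.g. computed from
#'   the training individuals; defaults to frequencies stored in `G`.
#' @return Numeric matrix of coded values with attributes `coding`
#'   ("additive") and `freqs`.
#' @export
additive_code <- function(G, freqs = NULL) {
  G <- resolve_geno(G)
  p <- check_freqs(freqs %||% G$freqs)
  out <- sweep(G$calls, 2L, 2 * p, `-`)
  structure(out, coding = "additive", freqs = p)
}

#' Dominance deviation coding
#'
#' Under Hardy-Weinberg equilibrium with reference frequency `p` and
#' `q = 1 - p`, calls (0, 1, 2) map to (-2p^2, 2pq, -2q^2), giving the
#' classical dominance-deviation contrast with zero HWE expectation.
#'
#' @inheritParams additive_code
#' @return Numeric matrix with attributes `coding` ("dominance"), `freqs`.
#' @export
dominance_code <- function(G, freqs = NULL) {
  G <- resolve_geno(G)
  p <- check_freqs(freqs %||% G$freqs)
  q <- 1 - p
  calls <- G$calls
  if (any(!calls %in% c(0, 1, 2))) stopf("dominance coding requires calls in {0,1,2}")
  P <- matrix(p, nrow(calls), ncol(calls), byrow = TRUE)
  Q <- 1 - P
  out <- -2 * P^2 * (calls == 0) + 2 * P * Q * (calls == 1) - 2 * Q^2 * (calls == 2)
  dimnames(out) <- dimnames(calls)
  structure(out, coding = "dominance", freqs = p)
}

#' Principal components of a (coded) genotype matrix
#'
#' Centered PCA retaining the minimal leading set of components whose
#' cumulative explained variance reaches `var_threshold`.
#'
#' @param X Numeric matrix, individuals x features (coded or raw calls).
#' @param var_threshold Fraction of variance to capture (default 0.99).
#' @return A `pc_basis`: loadings (features x components), scores
#'   (individuals x components), explained-variance fractions for all
#'   components, the centering vector, and the retained count.
#' @export
compute_pcs <- function(X, var_threshold = 0.99) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stopf("PCA needs at least 2 individuals")
  if (all(apply(X, 2L, stats::var) < .Machine$double.eps)) {
    stopf("degenerate input: constant matrix has no principal components")
  }
  if (var_threshold <= 0 || var_threshold > 1) stopf("`var_threshold` must be in (0, 1]")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  explained <- ev / sum(ev)
  k <- which(cumsum(explained) >= var_threshold - 1e-12)[1]
  structure(list(loadings = pc$rotation[, seq_len(k), drop = FALSE],
                 scores = pc$x[, seq_len(k), drop = FALSE],
                 explained = explained, center = pc$center,
                 n_retained = k, threshold = var_threshold),
            class = "pc_basis")
}

#' @export
print.pc_basis <- function(x, ...) {
  cat(sprintf("PC basis: %d components retained (%.1f%% variance, threshold %.0f%%)\n",
              x$n_retained, 100 * sum(x$explained[seq_len(x$n_retained)]),
              100 * x$threshold))
  invisible(x)
}

#' Project new rows onto a fitted PC basis
#'
#' @param basis A `pc_basis`.
#' @param X_new Matrix with the same feature columns as the training data.
#' @return Scores matrix (rows x retained components).
#' @export
project_onto_basis <- function(basis, X_new) {
  stopifnot(inherits(basis, "pc_basis"))
  sweep(as.matrix(X_new), 2L, basis$center, `-`) %*% basis$loadings
}

#' Hybrid principal-component scores from parental scores
#'
#' The score of a hybrid is the mean of its two parents' PC scores, which is
#' algebraically identical to averaging the parental genotypes first and
#' then projecting onto the parental loadings.
#'
#' @param parent_basis `pc_basis` fitted on the parents.
#' @param design A `cross_design`; its parents must be rows of the basis
#'   scores.
#' @return Hybrid scores matrix (hybrids x components).
#' @export
hybrid_gpcs <- function(parent_basis, design) {
  stopifnot(inherits(parent_basis, "pc_basis"), inherits(design, "cross_design"))
  M <- design$M
  sc <- parent_basis$scores
  missing <- setdiff(colnames(M), rownames(sc))
  if (length(missing) > 0L) {
    stopf("parents missing from the PC basis: %s", paste(missing, collapse = ", "))
  }
  out <- 0.5 * (M %*% sc[colnames(M), , drop = FALSE])
  rownames(out) <- rownames(M)
  out
}

#' Hybrid SNP-covariance identity report
#'
#' Computes the hybrid SNP covariance two ways: directly from the hybrid
#' genotype matrix, `(1/4m) (MX)'(MX)`, and through the parent-contribution
#' factorization `(1/4m) X'(M'M)X`, returning both together with their
#' maximum absolute discrepancy and the parent-contribution matrix `M'M`
#' (whose diagonal counts each parent's progeny).
#'
#' @param X Parental `geno_matrix` or calls matrix.
#' @param design A `cross_design`.
#' @return List with `S_direct`, `S_factored`, `MtM`, `max_discrepancy`.
#' @export
hybrid_covariance_identity <- function(X, design) {
  G <- resolve_geno(X)
  M <- design$M
  Xp <- G$calls[colnames(M), , drop = FALSE]
  m <- nrow(M)
  MX <- M %*% Xp
  S1 <- crossprod(MX) / (4 * m)
  MtM <- crossprod(M)
  S2 <- t(Xp) %*% MtM %*% Xp / (4 * m)
  list(S_direct = S1, S_factored = S2, MtM = MtM,
       max_discrepancy = max(abs(S1 - S2)))
}

#' Combine p-values with Fisher's method
#'
#' The statistic `-2 * sum(log p)` is referred to a chi-square distribution
#' with `2k` degrees of freedom. Zero p-values are clipped to `floor` with
#' a warning.
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @param floor Lower clip applied to zero/underflowed p-values.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
fisher_combine <- function(pvals, floor = 1e-300) {
  pvals <- pvals[!is.na(pvals)]
  if (length(pvals) == 0L) stopf("no p-values to combine")
  if (any(pvals < 0 | pvals > 1)) stopf("p-values must lie in [0, 1]")
  if (any(pvals < floor)) {
    warning("p-values below the floor were clipped", call. = FALSE)
    pvals <- pmax(pvals, floor)
  }
  stat <- -2 * sum(log(pvals))
  df <- 2L * length(pvals)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

# Spectral single-random-effect mixed model: estimate the variance ratio
# lambda = sigma2_g / sigma2_e on the null model by ML profile over the
# eigenbasis of K, then reuse the rotation for per-marker GLS scans.
null_spectral_fit <- function(y, K, X0 = NULL) {
  n <- length(y)
  X0 <- X0 %||% matrix(1, n, 1)
  eg <- eigen(K, symmetric = TRUE)
  U <- eg$vectors
  d <- pmax(eg$values, 0)
  yt <- crossprod(U, y)
  Xt <- crossprod(U, X0)
  negll <- function(loglam) {
    lam <- exp(loglam)
    w <- 1 / (lam * d + 1)
    XtWX <- crossprod(Xt, Xt * w)
    XtWy <- crossprod(Xt, yt * w)
    beta <- tryCatch(solve(XtWX, XtWy), error = function(e) NULL)
    if (is.null(beta)) return(1e10)
    r <- yt - Xt %*% beta
    s2 <- sum(w * r^2) / n
    0.5 * (n * log(s2) + sum(log(lam * d + 1)))
  }
  opt <- stats::optimize(negll, c(-12, 12))
  lambda <- exp(opt$minimum)
  list(U = U, d = d, lambda = lambda, yt = yt, Xt = Xt)
}

# Per-marker GLS scan at fixed variance ratio (population parameters
# previously determined / EMMAX-style approximation).
marker_scan <- function(fit, markers) {
  w <- 1 / (fit$lambda * fit$d + 1)
  n <- length(fit$yt)
  p0 <- ncol(fit$Xt)
  pvals <- rep(NA_real_, ncol(markers))
  Mt <- crossprod(fit$U, markers)
  for (j in seq_len(ncol(markers))) {
    X <- cbind(fit$Xt, Mt[, j])
    XtWX <- crossprod(X, X * w)
    beta <- tryCatch(solve(XtWX, crossprod(X, fit$yt * w)), error = function(e) NULL)
    if (is.null(beta)) next
    r <- fit$yt - X %*% beta
    df <- n - p0 - 1L
    s2 <- sum(w * r^2) / df
    se <- sqrt(s2 * solve(XtWX)[p0 + 1L, p0 + 1L])
    tval <- beta[p0 + 1L] / se
    pvals[j] <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  }
  pvals
}

#' Mixed-model GWAS marker selection across training environments
#'
#' Runs a single-marker mixed-model scan in each training environment
#' (variance components estimated once per environment on the null model by
#' a spectral maximum-likelihood profile, then per-marker generalized least
#' squares), combines per-locus p-values over environments with Fisher's
#' method, and selects the loci with the smallest combined p-values. A
#' locus monomorphic within an environment is skipped there and combined
#' over the environments where it was testable.
#'
#' @param H Coded genotype matrix (hybrids x loci) with hybrid row names.
#' @param phenos Data frame with columns `hybrid_id`, `site_year`, and the
#'   response named by `response` (default `y_std`); training records only.
#' @param K Kinship/similarity `matrix` over the hybrids in `H` (row/col
#'   names matching), e.g. a linear kernel of the additive codes.
#' @param n_select Number of loci to select.
#' @param n_pc_covariates Number of kinship PCs included as fixed
#'   covariates in each scan (default 0).
#' @param response Column of `phenos` to scan (default "y_std").
#' @return A `gwas_selection`: list with `per_env_p` (loci x environments),
#'   `combined_p`, and `selected` locus ids.
#' @export
gwas_select_snps <- function(H, phenos, K, n_select, n_pc_covariates = 0L,
                             response = "y_std") {
  H <- as.matrix(H)
  if (is.null(rownames(H))) stopf("`H` needs hybrid row names")
  envs <- unique(phenos$site_year)
  if (length(envs) < 2L) stopf("GWAS selection needs at least 2 environments")
  n_select <- check_count(n_select, "n_select")
  if (n_select > ncol(H)) stopf("n_select exceeds the locus count")
  pcs <- NULL
  if (n_pc_covariates > 0L) {
    pcs <- eigen(K, symmetric = TRUE)$vectors[, seq_len(n_pc_covariates), drop = FALSE]
    rownames(pcs) <- rownames(K)
  }
  per_env <- matrix(NA_real_, ncol(H), length(envs),
                    dimnames = list(colnames(H), envs))
  for (e in envs) {
    rec <- phenos[phenos$site_year == e, , drop = FALSE]
    idx <- match(rec$hybrid_id, rownames(H))
    if (anyNA(idx)) stopf("phenotype hybrids missing from the genotype matrix")
    y <- rec[[response]]
    He <- H[idx, , drop = FALSE]
    Ke <- K[idx, idx, drop = FALSE]
    X0 <- matrix(1, length(idx), 1L)
    if (!is.null(pcs)) X0 <- cbind(X0, pcs[idx, , drop = FALSE])
    fit <- tryCatch(null_spectral_fit(y, Ke, X0), error = function(err) {
      stopf("singular null model in environment %s: %s", e, conditionMessage(err))
    })
    testable <- apply(He, 2L, function(x) stats::sd(x) > 0)
    if (any(testable)) {
      per_env[testable, e] <- marker_scan(fit, He[, testable, drop = FALSE])
    }
  }
  combined <- apply(per_env, 1L, function(p) {
    p <- p[!is.na(p)]
    if (length(p) == 0L) return(NA_real_)
    fisher_combine(p)$p_value
  })
  ord <- order(combined, na.last = TRUE)
  selected <- colnames(H)[ord[seq_len(n_select)]]
  structure(list(per_env_p = per_env, combined_p = combined, selected = selected),
            class = "gwas_selection")
}

#' @export
print.gwas_selection <- function(x, ...) {
  cat(sprintf("GWAS selection: %d loci selected from %d over %d environments\n",
              length(x$selected), nrow(x$per_env_p), ncol(x$per_env_p)))
  invisible(x)
}
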