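# synthetic multi-environment testcross generator: inbred panel, testcross
# design, hybrid genotypes, trial environments, phenotypes, and splits.

#' Simulate a homozygous inbred SNP panel
#'
#' Draws a per-locus reference allele frequency from the configured MAF
#' spectrum and samples fully homozygous calls in {0, 2}. Loci whose
#' realized minor allele frequency falls below the lower MAF bound (or that
#' are monomorphic) are rejected and redrawn, mimicking the MAF filter
#' applied to real genotyping panels.
#'
#' @param config A [sim_config()].
#' @return A `geno_matrix`: list with `calls` (individuals x loci, values in
#'   {0,2}), and `freqs` (per-locus reference allele frequency computed from
#'   the panel).
#' @export
simulate_inbred_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_inbreds
  p <- config$n_snps
  lo <- config$maf_range[1]
  hi <- config$maf_range[2]
  with_seed(derive_seed(config$seed, "inbred_panel"), {
    calls <- matrix(NA_real_, n, p)
    todo <- seq_len(p)
    tries <- 0L
    while (length(todo) > 0L && tries < 200L) {
      pf <- stats::runif(length(todo), lo, hi)
      # reference allele frequency: put the minor allele on either side
      flip <- stats::runif(length(todo)) < 0.5
      pf[flip] <- 1 - pf[flip]
      newcalls <- matrix(2 * stats::rbinom(n * length(todo), 1L,
                                           rep(pf, each = n)), n, length(todo))
      freq <- colMeans(newcalls) / 2
      maf <- pmin(freq, 1 - freq)
      ok <- maf >= lo
      calls[, todo[ok]] <- newcalls[, ok, drop = FALSE]
      todo <- todo[!ok]
      tries <- tries + 1L
    }
    if (length(todo) > 0L) {
      stopf("could not realize MAF >= %g at %d loci; increase n_inbreds", lo, length(todo))
    }
    rownames(calls) <- sprintf("I%03d", seq_len(n))
    colnames(calls) <- sprintf("snp%05d", seq_len(p))
    geno_matrix(calls)
  })
}

#' Construct a genotype matrix object
#'
#' @param calls Individuals x loci matrix with values in {0, 1, 2}.
#' @param freqs Optional per-locus reference allele frequencies; computed
#'   from `calls` when omitted.
#' @return A `geno_matrix`.
#' @export
geno_matrix <- function(calls, freqs = NULL) {
  check_calls(calls)
  if (is.null(rownames(calls))) rownames(calls) <- sprintf("ind%d", seq_len(nrow(calls)))
  if (is.null(colnames(calls))) colnames(calls) <- sprintf("snp%d", seq_len(ncol(calls)))
  if (is.null(freqs)) freqs <- colMeans(calls) / 2
  if (length(freqs) != ncol(calls)) stopf("`freqs` length must equal the locus count")
  structure(list(calls = calls, freqs = as.numeric(freqs)), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d individuals x %d loci; mean ref freq %.3f\n",
              nrow(x$calls), ncol(x$calls), mean(x$freqs)))
  invisible(x)
}

#' Build a testcross design linking hybrids to parents
#'
#' Each of `n_lines` candidate lines is crossed to `crosses_per_line`
#' testers, chosen as a cyclic block over the tester set so the design is a
#' deterministic function of the counts. The incidence matrix `M` has one
#' row per hybrid with exactly two unit entries (tester and line).
#'
#' @param n_testers,n_lines Tester and line counts (disjoint parent sets).
#' @param crosses_per_line Testers crossed to each line (<= `n_testers`).
#' @param tester_ids,line_ids Optional parent labels; must be disjoint.
#' @return A `cross_design`: list with binary incidence `M`
#'   (hybrids x parents), `hybrid_ids`, and a `parents` data frame.
#' @export
make_testcross_design <- function(n_testers, n_lines, crosses_per_line = 1L,
                                  tester_ids = NULL, line_ids = NULL) {
  n_testers <- check_count(n_testers, "n_testers")
  n_lines <- check_count(n_lines, "n_lines")
  crosses_per_line <- check_count(crosses_per_line, "crosses_per_line")
  if (crosses_per_line > n_testers) stopf("crosses_per_line exceeds n_testers")
  tester_ids <- tester_ids %||% sprintf("T%02d", seq_len(n_testers))
  line_ids <- line_ids %||% sprintf("L%03d", seq_len(n_lines))
  if (length(intersect(tester_ids, line_ids)) > 0L) {
    stopf("tester set overlaps line set: invalid testcross design")
  }
  parents <- character(0)
  tester_of <- character(0)
  line_of <- character(0)
  for (i in seq_len(n_lines)) {
    t_idx <- ((i - 1L + seq_len(crosses_per_line) - 1L) %% n_testers) + 1L
    tester_of <- c(tester_of, tester_ids[t_idx])
    line_of <- c(line_of, rep(line_ids[i], crosses_per_line))
  }
  hybrid_ids <- paste(tester_of, line_of, sep = "x")
  parent_ids <- c(tester_ids, line_ids)
  M <- matrix(0L, length(hybrid_ids), length(parent_ids),
              dimnames = list(hybrid_ids, parent_ids))
  M[cbind(seq_along(hybrid_ids), match(tester_of, parent_ids))] <- 1L
  M[cbind(seq_along(hybrid_ids), match(line_of, parent_ids))] <- 1L
  structure(list(M = M, hybrid_ids = hybrid_ids,
                 parents = data.frame(hybrid_id = hybrid_ids, tester = tester_of,
                                      line = line_of, stringsAsFactors = FALSE)),
            class = "cross_design")
}

#' @export
print.cross_design <- function(x, ...) {
  cat(sprintf("Testcross design: %d hybrids from %d parents\n",
              nrow(x$M), ncol(x$M)))
  invisible(x)
}

#' Derive hybrid genotypes as parental averages
#'
#' Hybrid marker calls are the average of the two parental calls,
#' `(1/2) M X` in matrix form, so crosses of homozygous parents yield calls
#' in {0, 1, 2}.
#'
#' @param X A parental `geno_matrix` whose rows cover all parents in `M`.
#' @param design A `cross_design`.
#' @return A `geno_matrix` of hybrid calls with frequencies computed from
#'   the hybrids.
#' @export
derive_hybrid_genotypes <- function(X, design) {
  stopifnot(inherits(X, "geno_matrix"), inherits(design, "cross_design"))
  M <- design$M
  if (!all(colnames(M) %in% rownames(X$calls))) {
    stopf("parents in the design are missing from the genotype matrix")
  }
  Xp <- X$calls[colnames(M), , drop = FALSE]
  H <- 0.5 * (M %*% Xp)
  rownames(H) <- rownames(M)
  geno_matrix(H)
}

#' Simulate trial environments: sites, soil vectors, and weather series
#'
#' Soil covariates are drawn once per site (years of the same site share the
#' soil vector exactly). Each site-year weather variable is a smooth
#' seasonal signal (site + year level shifts, a random-phase seasonal wave)
#' plus day-level noise, on the configured day grid.
#'
#' @param config A [sim_config()].
#' @return A `trial_design`: list with `site_years`, `sites`, `soil`
#'   (sites x soil variables), and `weather` (named list of
#'   variables x days matrices, one per site-year).
#' @export
simulate_environments <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  days <- seq(config$day_range[1], config$day_range[2])
  sites <- sprintf("S%02d", seq_len(config$n_sites))
  years <- sprintf("Y%d", seq_len(config$n_years))
  site_years <- as.vector(outer(sites, years, paste, sep = "_"))
  with_seed(derive_seed(config$seed, "environments"), {
    soil <- matrix(stats::rnorm(config$n_sites * config$n_soil_vars), config$n_sites,
                   dimnames = list(sites, sprintf("soil%02d", seq_len(config$n_soil_vars))))
    site_level <- matrix(stats::rnorm(config$n_sites * config$n_weather_vars, sd = 1),
                         config$n_sites)
    weather <- vector("list", length(site_years))
    names(weather) <- site_years
    for (sy in site_years) {
      s_idx <- match(sub("_Y\\d+$", "", sy), sites)
      year_shift <- stats::rnorm(config$n_weather_vars, sd = 0.5)
      W <- matrix(0, config$n_weather_vars, length(days),
                  dimnames = list(sprintf("wx%02d", seq_len(config$n_weather_vars)),
                                  as.character(days)))
      for (v in seq_len(config$n_weather_vars)) {
        phase <- stats::runif(1, 0, 2 * pi)
        amp <- stats::runif(1, 0.5, 1.5)
        signal <- site_level[s_idx, v] + year_shift[v] +
          amp * sin(2 * pi * (days - days[1]) / length(days) + phase)
        W[v, ] <- signal + stats::rnorm(length(days), sd = 0.3)
      }
      weather[[sy]] <- W
    }
    structure(list(site_years = site_years, sites = sites, years = years,
                   soil = soil, weather = weather, days = days),
              class = "trial_design")
  })
}

#' @export
print.trial_design <- function(x, ...) {
  cat(sprintf("Trial design: %d site-years (%d sites x %d years), %d soil vars, %d weather vars x %d days\n",
              length(x$site_years), length(x$sites), length(x$years),
              ncol(x$soil), nrow(x$weather[[1]]), ncol(x$weather[[1]])))
  invisible(x)
}

#' Simulate phenotypes with a controlled variance decomposition
#'
#' Generates yield records for every hybrid x site-year plot as
#' `y = mu + a + d + i + gxe + e + eps`: additive and dominance terms are
#' coded genotypes times sampled effects; epistasis is a sum over random
#' locus pairs of products of additive codes; the environmental main effect
#' is a site-year index built from soil and season-average weather; GxE is
#' a rank-1 product of a per-hybrid additive score and a per-environment
#' index; the residual is iid Gaussian. Every component is rescaled so its
#' realized variance over records equals the requested fraction exactly
#' (fractions of a unit total on the simulation scale), then the standard
#' scale is affine-mapped to a plausible grain-yield range in bu/ac.
#'
#' @param hybrids Hybrid `geno_matrix`.
#' @param trial A `trial_design`.
#' @param config A [sim_config()] supplying `variance_fractions` and `seed`.
#' @param mean_yield,sd_yield Affine map from the standardized simulation
#'   scale to bu/ac (defaults 150 and 25).
#' @param n_epi_pairs Number of additive-by-additive locus pairs (default
#'   `n_snps`).
#' @return A `pheno_table` data frame with columns `hybrid_id`, `site_year`,
#'   `yield` (bu/ac), and `partition` (NA until [split_train_test()]); the
#'   true simulated components are kept in `attr(, "components")`.
#' @export
simulate_phenotypes <- function(hybrids, trial, config,
                                mean_yield = 150, sd_yield = 25,
                                n_epi_pairs = NULL) {
  stopifnot(inherits(hybrids, "geno_matrix"), inherits(trial, "trial_design"),
            inherits(config, "sim_config"))
  vf <- config$variance_fractions
  if (sum(vf[c("additive", "dominance", "epistatic", "gxe")]) == 0 &&
      vf[["residual"]] + vf[["environment"]] == 0) {
    stopf("no variance requested: invalid configuration")
  }
  n_epi_pairs <- n_epi_pairs %||% config$n_snps
  ids <- rownames(hybrids$calls)
  sy <- trial$site_years
  records <- expand.grid(hybrid_id = ids, site_year = sy,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  nrec <- nrow(records)
  hyb_idx <- match(records$hybrid_id, ids)
  env_idx <- match(records$site_year, sy)

  rescale <- function(x, frac) {
    if (frac == 0) return(rep(0, length(x)))
    v <- stats::var(x)
    if (v < .Machine$double.eps) {
      stopf("requested a non-zero variance fraction for a degenerate component")
    }
    (x - mean(x)) * sqrt(frac / (v * (length(x) - 1) / length(x)))
  }

  with_seed(derive_seed(config$seed, "phenotypes"), {
    A <- additive_code(hybrids)
    D <- dominance_code(hybrids)
    p <- ncol(A)

    a_h <- as.vector(A %*% stats::rnorm(p, sd = 1 / sqrt(p)))
    d_h <- as.vector(D %*% stats::rnorm(p, sd = 1 / sqrt(p)))
    pair1 <- sample.int(p, n_epi_pairs, replace = TRUE)
    pair2 <- sample.int(p, n_epi_pairs, replace = TRUE)
    E_feat <- A[, pair1, drop = FALSE] * A[, pair2, drop = FALSE]
    i_h <- as.vector(E_feat %*% stats::rnorm(n_epi_pairs, sd = 1 / sqrt(n_epi_pairs)))

    # per-environment index from soil + season-average weather
    wmeans <- t(vapply(trial$weather, rowMeans, numeric(nrow(trial$weather[[1]]))))
    soil_by_sy <- trial$soil[sub("_Y\\d+$", "", sy), , drop = FALSE]
    env_mat <- cbind(soil_by_sy, wmeans)
    env_index <- as.vector(scale(env_mat %*% stats::rnorm(ncol(env_mat))))

    gxe_score <- if (stats::var(a_h) > 0) as.vector(scale(a_h)) else stats::rnorm(length(a_h))

    comp <- list(
      additive = rescale(a_h[hyb_idx], vf[["additive"]]),
      dominance = rescale(d_h[hyb_idx], vf[["dominance"]]),
      epistatic = rescale(i_h[hyb_idx], vf[["epistatic"]]),
      gxe = rescale(gxe_score[hyb_idx] * env_index[env_idx], vf[["gxe"]]),
      environment = rescale(env_index[env_idx], vf[["environment"]]),
      residual = rescale(stats::rnorm(nrec), vf[["residual"]])
    )
    y_std <- Reduce(`+`, comp)
    records$yield <- mean_yield + sd_yield * y_std
    records$partition <- NA_character_
    structure(records,
              class = c("pheno_table", "data.frame"),
              components = as.data.frame(comp),
              sim_scale = c(mean = mean_yield, sd = sd_yield),
              seed = config$seed)
  })
}

#' Split phenotype records into training and test site-years
#'
#' Holds out `test_site_year_count` whole site-years as the test set (the
#' "tested genotypes in untested environments" structure), then caps every
#' site-year at `cap` records by random down-sampling (dropped records are
#' removed). Standardization statistics (training mean and sd of yield) are
#' stored and a `y_std` column added.
#'
#' @param table A `pheno_table`.
#' @param test_site_year_count Number of held-out site-years (default 16).
#' @param cap Maximum records per site-year (default 265; `Inf` disables).
#' @param seed Integer seed.
#' @return The `pheno_table` with `partition` set to "train"/"test", a
#'   `y_std` column, and `attr(, "train_stats")`.
#' @export
split_train_test <- function(table, test_site_year_count = 16L, cap = 265,
                             seed = 1L) {
  stopifnot(inherits(table, "pheno_table"))
  if (!is.infinite(cap)) cap <- check_count(cap, "cap")
  sys <- unique(table$site_year)
  test_site_year_count <- check_count(test_site_year_count, "test_site_year_count", min = 1L)
  if (test_site_year_count >= length(sys)) {
    stopf("test_site_year_count must be smaller than the number of site-years (%d)",
          length(sys))
  }
  atts <- attributes(table)
  with_seed(derive_seed(seed, "train_test_split"), {
    test_sys <- sample(sys, test_site_year_count)
    keep <- logical(nrow(table))
    for (s in sys) {
      idx <- which(table$site_year == s)
      if (length(idx) > cap) idx <- sample(idx, cap)
      keep[idx] <- TRUE
    }
    out <- table[keep, , drop = FALSE]
    out$partition <- ifelse(out$site_year %in% test_sys, "test", "train")
    mu <- mean(out$yield[out$partition == "train"])
    sdv <- stats::sd(out$yield[out$partition == "train"])
    out$y_std <- (out$yield - mu) / sdv
    rownames(out) <- NULL
    structure(out, class = c("pheno_table", "data.frame"),
              components = atts$components[keep, , drop = FALSE],
              sim_scale = atts$sim_scale, seed = atts$seed,
              train_stats = c(mean = mu, sd = sdv),
              test_site_years = sort(test_sys))
  })
}

#' Sample training/validation partitions by site-year
#'
#' Builds `n_splits` train/validation partitions of the training records by
#' sampling `n_env_per_split` training site-years; each validation set is
#' all records of the sampled site-years.
#'
#' @param table A split `pheno_table` (training partition flagged).
#' @param n_splits Number of partitions (default 10).
#' @param n_env_per_split Site-years per validation set (default 16).
#' @param seed Integer seed.
#' @return List of length `n_splits`; each element has integer row indices
#'   `train` and `validation` into `table`, and `validation_site_years`.
#' @export
make_validation_splits <- function(table, n_splits = 10L, n_env_per_split = 16L,
                                   seed = 1L) {
  stopifnot(inherits(table, "pheno_table"))
  n_splits <- check_count(n_splits, "n_splits")
  n_env_per_split <- check_count(n_env_per_split, "n_env_per_split")
  train_idx <- which(table$partition == "train")
  if (length(train_idx) == 0L) stopf("no training records; run split_train_test() first")
  train_sys <- unique(table$site_year[train_idx])
  if (n_env_per_split >= length(train_sys)) {
    stopf("n_env_per_split must be smaller than the number of training site-years (%d)",
          length(train_sys))
  }
  with_seed(derive_seed(seed, "validation_splits"), {
    lapply(seq_len(n_splits), function(k) {
      val_sys <- sample(train_sys, n_env_per_split)
      val <- train_idx[table$site_year[train_idx] %in% val_sys]
      list(train = setdiff(train_idx, val), validation = val,
           validation_site_years = sort(val_sys))
    })
  })
}
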