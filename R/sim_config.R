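#' Configuration for the synthetic multi-environment testcross simulator
#'
#' Bundles and validates every knob of the synthetic data generator: panel
#' and marker dimensions, the minor-allele-frequency (MAF) spectrum, the
#' trial network (sites x years), and the phenotypic variance decomposition
#' into additive, dominance, epistatic, genotype-by-environment (GxE),
#' environmental main-effect, and residual fractions.
#'
#' @param n_inbreds Number of inbred parents in the panel.
#' @param n_testers Number of testers in the testcross design.
#' @param n_snps Number of biallelic SNP loci.
#' @param maf_range Length-2 numeric in (0, 0.5]: bounds of the per-locus
#'   minor allele frequency spectrum.
#' @param n_sites,n_years Trial network dimensions; site-years are the
#'   crossing of the two.
#' @param variance_fractions Named numeric with entries `additive`,
#'   `dominance`, `epistatic`, `gxe`, `environment`, `residual`, summing to 1.
#' @param n_soil_vars Number of site-level soil covariates (default 21).
#' @param n_weather_vars Number of daily weather variables (default 19).
#' @param day_range Integer pair of days relative to planting covered by the
#'   weather series (default -75..204, i.e. 280 days).
#' @param seed Integer seed; every generator in the package is a
#'   deterministic function of its inputs and this seed.
#' @return An object of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_inbreds = 30, n_snps = 100, seed = 1)
#' cfg$variance_fractions
sim_config <- function(n_inbreds = 100L,
                       n_testers = 3L,
                       n_snps = 500L,
                       maf_range = c(0.03, 0.5),
                       n_sites = 8L,
                       n_years = 2L,
                       variance_fractions = c(additive = 0.30, dominance = 0.05,
                                              epistatic = 0.10, gxe = 0.10,
                                              environment = 0.25, residual = 0.20),
                       n_soil_vars = 21L,
                       n_weather_vars = 19L,
                       day_range = c(-75L, 204L),
                       seed = 1L) {
  n_inbreds <- check_count(n_inbreds, "n_inbreds")
  n_testers <- check_count(n_testers, "n_testers")
  n_snps <- check_count(n_snps, "n_snps")
  n_sites <- check_count(n_sites, "n_sites")
  n_years <- check_count(n_years, "n_years")
  n_soil_vars <- check_count(n_soil_vars, "n_soil_vars")
  n_weather_vars <- check_count(n_weather_vars, "n_weather_vars")
  if (length(maf_range) != 2L || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2]) {
    stopf("`maf_range` must be an increasing pair within (0, 0.5]")
  }
  if (length(day_range) != 2L || day_range[1] > day_range[2]) {
    stopf("`day_range` must be an increasing integer pair")
  }
  comp <- c("additive", "dominance", "epistatic", "gxe", "environment", "residual")
  if (!all(comp %in% names(variance_fractions))) {
    stopf("`variance_fractions` must name: %s", paste(comp, collapse = ", "))
  }
  vf <- variance_fractions[comp]
  if (any(vf < 0)) stopf("variance fractions must be non-negative")
  if (abs(sum(vf) - 1) > 1e-12) stopf("variance fractions must sum to 1 (got %g)", sum(vf))
  structure(list(n_inbreds = n_inbreds, n_testers = n_testers, n_snps = n_snps,
                 maf_range = as.numeric(maf_range), n_sites = n_sites,
                 n_years = n_years, variance_fractions = vf,
                 n_soil_vars = n_soil_vars, n_weather_vars = n_weather_vars,
                 day_range = as.integer(day_range), seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic testcross simulation config\n")
  cat(sprintf("  inbreds: %d (testers: %d), SNPs: %d, MAF in [%.3f, %.3f]\n",
              x$n_inbreds, x$n_testers, x$n_snps, x$maf_range[1], x$maf_range[2]))
  cat(sprintf("  sites x years: %d x %d; soil vars: %d; weather vars: %d over days %d..%d\n",
              x$n_sites, x$n_years, x$n_soil_vars, x$n_weather_vars,
              x$day_range[1], x$day_range[2]))
  cat("  variance fractions:\n")
  print(round(x$variance_fractions, 3))
  invisible(x)
}
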