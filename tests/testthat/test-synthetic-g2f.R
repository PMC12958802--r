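# Synthetic testcross generator: panel, design, hybrids, environments,
# phenotypes, and splits.

test_that("inbred panel is homozygous, respects the MAF spectrum, and is seed-deterministic", {
  cfg <- sim_config(n_inbreds = 100L, n_snps = 500L, maf_range = c(0.03, 0.5),
                    seed = 11L)
  panel <- simulate_inbred_panel(cfg)
  expect_true(all(panel$calls %in% c(0, 2)))
  # brute-force frequency scan: realized MAF never below the lower bound
  freq <- colMeans(panel$calls) / 2
  expect_true(all(pmin(freq, 1 - freq) >= 0.03))
  # symmetric spectrum: mean call per locus near 1 within 3 binomial SEs
  cfg_sym <- sim_config(n_inbreds = 400L, n_snps = 50L,
                        maf_range = c(0.5, 0.5), seed = 2L)
  sym <- simulate_inbred_panel(cfg_sym)
  se3 <- 3 * sqrt(0.25 / 400) * 2
  expect_true(all(abs(colMeans(sym$calls) - 1) <= se3 * 1.2))
  expect_lt(mean(abs(colMeans(sym$calls) - 1) > se3), 0.05)
  # determinism
  expect_identical(simulate_inbred_panel(cfg)$calls, panel$calls)
  expect_error(sim_config(n_snps = 0), "integer")
})

test_that("testcross design has two parents per hybrid and correct progeny counts", {
  d <- make_testcross_design(1L, 3L)
  expect_equal(dim(d$M), c(3L, 4L))
  expect_true(all(d$M[, 1] == 1))  # the single tester parents every hybrid
  expect_true(all(rowSums(d$M) == 2))
  d2 <- make_testcross_design(3L, 10L, crosses_per_line = 2L)
  expect_true(all(rowSums(d2$M) == 2))
  # M'M diagonal equals progeny counts, counted directly from the pair list
  counts <- table(c(d2$parents$tester, d2$parents$line))
  MtM <- crossprod(d2$M)
  expect_equal(diag(MtM)[names(counts)], as.numeric(counts),
               ignore_attr = TRUE)
  expect_error(make_testcross_design(2L, 3L, tester_ids = c("A", "B"),
                                     line_ids = c("B", "C", "D")),
               "overlaps")
})

test_that("hybrid genotypes equal parental averages (loop oracle)", {
  fx <- make_testcross_fixture(n_inbreds = 20L, n_snps = 40L, seed = 7L)
  H <- fx$hybrids$calls
  M <- fx$design$M
  X <- fx$panel$calls[colnames(M), ]
  # explicit per-hybrid loop
  for (i in seq_len(nrow(M))) {
    par <- colnames(M)[M[i, ] == 1]
    expect_equal(H[i, ], (X[par[1], ] + X[par[2], ]) / 2)
  }
  expect_true(all(H %in% c(0, 1, 2)))
  # spot values: parents (0,2) -> 1, (2,2) -> 2 are implied by the loop oracle
  expect_equal(unname(H), unname(0.5 * M %*% X))
})

test_that("trial environments cover the day grid, share soil within site, and are deterministic", {
  cfg <- sim_config(n_sites = 3L, n_years = 2L, seed = 5L)
  trial <- simulate_environments(cfg)
  expect_equal(ncol(trial$weather[[1]]), 280L)  # -75..204 inclusive
  expect_equal(length(trial$site_years), 6L)
  # soil is site-level: year replicates reference the same soil row
  expect_equal(trial$soil["S01", ], simulate_environments(cfg)$soil["S01", ])
  expect_identical(trial$weather, simulate_environments(cfg)$weather)
})

test_that("phenotype components realize the requested variance fractions", {
  vf <- c(additive = 0.3, dominance = 0.05, epistatic = 0.1, gxe = 0.1,
          environment = 0.25, residual = 0.2)
  fx <- make_testcross_fixture(n_inbreds = 60L, n_snps = 150L, n_sites = 6L,
                               n_years = 2L, seed = 21L, vf = vf)
  ph <- simulate_phenotypes(fx$hybrids, fx$trial, fx$cfg)
  comp <- attr(ph, "components")
  expect_gte(nrow(comp), 500L)
  realized <- vapply(comp, function(x) mean(x^2) - mean(x)^2, numeric(1))
  expect_true(all(abs(realized - vf) <= 0.02 * pmax(vf, 1e-12) + 1e-12))
  # components reassemble the standardized phenotype exactly
  scale <- attr(ph, "sim_scale")
  expect_equal(ph$yield, scale["mean"] + scale["sd"] * rowSums(comp),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("an additive-only simulation is perfectly predicted by the additive model", {
  vf <- c(additive = 1, dominance = 0, epistatic = 0, gxe = 0,
          environment = 0, residual = 0)
  fx <- make_testcross_fixture(n_inbreds = 30L, n_snps = 60L, n_sites = 2L,
                               n_years = 1L, seed = 13L, vf = vf)
  ph <- simulate_phenotypes(fx$hybrids, fx$trial, fx$cfg)
  A <- additive_code(fx$hybrids)
  idx <- match(ph$hybrid_id, rownames(A))
  fit <- stats::lm(ph$yield ~ A[idx, ])
  expect_gt(stats::cor(ph$yield, stats::fitted(fit)), 1 - 1e-8)
})

test_that("with zero genetic variance, hybrids do not differ within environments", {
  vf <- c(additive = 0, dominance = 0, epistatic = 0, gxe = 0,
          environment = 0.4, residual = 0.6)
  fx <- make_testcross_fixture(n_inbreds = 40L, n_snps = 50L, n_sites = 5L,
                               n_years = 2L, seed = 17L, vf = vf)
  ph <- simulate_phenotypes(fx$hybrids, fx$trial, fx$cfg)
  an <- stats::anova(stats::aov(yield ~ site_year + hybrid_id, data = ph))
  expect_gt(an["hybrid_id", "Pr(>F)"], 0.01)
})

test_that("train/test split holds out whole site-years and caps records", {
  ph <- structure(data.frame(
    hybrid_id = sprintf("h%03d", c(seq_len(300), rep(1:50, 4))),
    site_year = c(rep("A_Y1", 300), rep(c("B_Y1", "C_Y1", "D_Y1", "E_Y1"), each = 50)),
    yield = stats::rnorm(500, 150, 20), partition = NA_character_,
    stringsAsFactors = FALSE), class = c("pheno_table", "data.frame"))
  sp <- split_train_test(ph, test_site_year_count = 1L, cap = 265, seed = 4L)
  expect_equal(sum(sp$site_year == "A_Y1"), 265L)
  expect_length(intersect(sp$site_year[sp$partition == "train"],
                          sp$site_year[sp$partition == "test"]), 0L)
  tr <- sp$y_std[sp$partition == "train"]
  expect_lt(abs(mean(tr)), 1e-10)
  expect_lt(abs(stats::sd(tr) - 1), 1e-10)
  # cap = Inf drops nothing
  sp2 <- split_train_test(ph, test_site_year_count = 1L, cap = Inf, seed = 4L)
  expect_equal(nrow(sp2), nrow(ph))
  # bit-identical re-run
  expect_identical(split_train_test(ph, 1L, 265, seed = 4L), sp)
})

test_that("validation splits partition the training records by site-year", {
  fx <- make_testcross_fixture(seed = 9L)
  ph <- simulate_phenotypes(fx$hybrids, fx$trial, fx$cfg)
  sp <- split_train_test(ph, test_site_year_count = 2L, cap = Inf, seed = 1L)
  vs <- make_validation_splits(sp, n_splits = 10L, n_env_per_split = 2L, seed = 6L)
  expect_length(vs, 10L)
  expect_gt(length(unique(vapply(vs, function(v)
    paste(v$validation_site_years, collapse = ","), ""))), 1L)
  train_idx <- which(sp$partition == "train")
  for (v in vs) {
    expect_length(intersect(v$train, v$validation), 0L)
    expect_setequal(c(v$train, v$validation), train_idx)
    expect_length(intersect(sp$site_year[v$train],
                            sp$site_year[v$validation]), 0L)
  }
  expect_identical(make_validation_splits(sp, 10L, 2L, seed = 6L), vs)
})

test_that("writers round-trip genotypes and record the seed sidecar", {
  fx <- make_testcross_fixture(n_inbreds = 10L, n_snps = 15L, seed = 2L)
  tmp <- tempfile(fileext = ".tsv")
  write_genotypes(fx$panel, tmp, seed = 2L)
  back <- read_genotypes(tmp)
  expect_equal(back$calls, fx$panel$calls)
  expect_true(file.exists(paste0(tmp, ".meta")))
  expect_match(paste(readLines(paste0(tmp, ".meta")), collapse = " "), "seed: 2")
  vcf <- tempfile(fileext = ".vcf")
  write_vcf(fx$hybrids, vcf)
  lines <- readLines(vcf)
  expect_match(lines[1], "fileformat=VCFv4.2")
  expect_equal(sum(!startsWith(lines, "#")), 15L)
})
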