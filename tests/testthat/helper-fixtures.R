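# Shared fixtures and independent oracles used across test files.

# Small testcross dataset built from the generator.
make_testcross_fixture <- function(n_inbreds = 40L, n_testers = 2L,
                                   n_snps = 120L, n_sites = 5L, n_years = 2L,
                                   seed = 3L, vf = NULL,
                                   crosses_per_line = 1L) {
  cfg_args <- list(n_inbreds = n_inbreds, n_testers = n_testers,
                   n_snps = n_snps, n_sites = n_sites, n_years = n_years,
                   seed = seed)
  if (!is.null(vf)) cfg_args$variance_fractions <- vf
  cfg <- do.call(sim_config, cfg_args)
  panel <- simulate_inbred_panel(cfg)
  ids <- rownames(panel$calls)
  design <- make_testcross_design(n_testers, n_inbreds - n_testers,
                                  crosses_per_line = crosses_per_line,
                                  tester_ids = ids[seq_len(n_testers)],
                                  line_ids = ids[-seq_len(n_testers)])
  hybrids <- derive_hybrid_genotypes(panel, design)
  trial <- simulate_environments(cfg)
  list(cfg = cfg, panel = panel, design = design, hybrids = hybrids,
       trial = trial)
}

# Batch-means Monte Carlo standard error for a vector of correlated draws.
mcse_batch <- function(draws, n_batches = 20L) {
  n <- length(draws)
  bs <- n %/% n_batches
  means <- vapply(seq_len(n_batches), function(b) {
    mean(draws[((b - 1L) * bs + 1L):(b * bs)])
  }, numeric(1))
  stats::sd(means) / sqrt(n_batches)
}

# Brute-force implementation of the binned-loss configuration selector:
# explicit loops, no vectorized shortcuts.
brute_select_config <- function(top, n_bins = 10L) {
  n_cfg <- length(top)
  E <- nrow(top[[1]]$trajectories)
  width <- ceiling(E / n_bins)
  bin_loss <- matrix(NA_real_, n_cfg, n_bins)
  for (ci in seq_len(n_cfg)) {
    traj <- top[[ci]]$trajectories
    score <- numeric(E)
    for (e in seq_len(E)) {
      vals <- traj[e, ]
      score[e] <- mean(vals) + stats::sd(vals)
    }
    for (b in seq_len(n_bins)) {
      lo <- (b - 1L) * width + 1L
      hi <- min(b * width, E)
      if (lo <= E) bin_loss[ci, b] <- mean(score[lo:hi])
    }
  }
  wins <- integer(n_cfg)
  for (b in seq_len(n_bins)) {
    mn <- min(bin_loss[, b])
    for (ci in seq_len(n_cfg)) {
      if (bin_loss[ci, b] <= mn + 1e-12) wins[ci] <- wins[ci] + 1L
    }
  }
  best <- which(wins == max(wins))
  if (length(best) > 1L) {
    np <- vapply(top[best], function(e) e$n_params, 0L)
    best <- best[order(np)]
  }
  best[1]
}

# Brute-force rolling-mean epoch selector: evaluate every epoch directly.
brute_select_epochs <- function(traj, window = 20L) {
  E <- nrow(traj)
  summed <- numeric(E)
  for (e in seq_len(E)) summed[e] <- sum(traj[e, ])
  best_e <- NA_integer_
  best_v <- Inf
  for (e in seq_len(E)) {
    if (e < window) next
    v <- mean(summed[(e - window + 1L):e])
    if (v < best_v - 0) {
      best_v <- v
      best_e <- e
    }
  }
  best_e
}
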