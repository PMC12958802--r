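# Network engine and the tuning/epoch-selection protocol.

test_that("an identity-activation single layer reduces to linear regression", {
  set.seed(41)
  n <- 40; p <- 4
  X <- matrix(stats::rnorm(n * p), n)
  y <- as.vector(X %*% c(1, -2, 0.5, 3))
  spec <- architecture_spec("genomic", "identity", units = 6L, dropout = 0)
  m <- build_network(spec, p, seed = 1L)
  fit <- train_network(m, X, y, epochs = 1500L, batch_size = 20L, lr = 0.01,
                       seed = 1L)
  final_mse <- mean((predict_network(fit$model, X) - y)^2)
  expect_lt(final_mse, 1e-6)
  ols <- stats::lm.fit(cbind(1, X), y)
  expect_lt(max(abs(predict_network(fit$model, X) - (cbind(1, X) %*% ols$coefficients))),
            0.01)
})

test_that("dense layer parameter counts follow units x inputs + units", {
  spec <- architecture_spec("genomic", "relu", units = c(7L, 3L))
  m <- build_network(spec, 11L, seed = 2L)
  expect_equal(count_params(m), (11 * 7 + 7) + (7 * 3 + 3) + (3 * 1 + 1))
})

test_that("evaluation-mode forward passes are deterministic; training is seed-reproducible", {
  set.seed(42)
  X <- matrix(stats::rnorm(30 * 5), 30)
  y <- stats::rnorm(30)
  spec <- architecture_spec("soil", "relu", units = c(8L, 4L), dropout = 0.2)
  m <- build_network(spec, 5L, seed = 3L)
  f1 <- train_network(m, X, y, epochs = 20L, batch_size = 10L, seed = 7L)
  f2 <- train_network(m, X, y, epochs = 20L, batch_size = 10L, seed = 7L)
  expect_identical(predict_network(f1$model, X), predict_network(f2$model, X))
  p1 <- predict_network(f1$model, X)
  expect_identical(p1, predict_network(f1$model, X))
})

test_that("early stopping restores the best epoch within patience", {
  set.seed(43)
  n <- 60
  X <- matrix(stats::rnorm(n * 6), n)
  y <- as.vector(X %*% stats::rnorm(6)) + stats::rnorm(n, sd = 0.2)
  spec <- architecture_spec("genomic", "relu", units = 16L)
  m <- build_network(spec, 6L, seed = 4L)
  fit <- train_network(m, X[1:40, ], y[1:40], epochs = 200L, batch_size = 16L,
                       validation = list(X = X[41:60, ], y = y[41:60]),
                       patience = 7L, seed = 5L)
  expect_lte(fit$trained_epochs, 200L)
  expect_lte(fit$best_epoch, fit$trained_epochs)
  best_val <- min(fit$history$val_rmse)
  expect_equal(rmse_val <- sqrt(mean((predict_network(fit$model, X[41:60, ]) -
                                        y[41:60])^2)), best_val,
               tolerance = 1e-10)
})

test_that("tuning records a split and trajectory for every evaluated config", {
  set.seed(44)
  n <- 80; p <- 6
  X <- matrix(stats::rnorm(n * p), n)
  y <- as.vector(X %*% stats::rnorm(p)) + stats::rnorm(n, sd = 0.3)
  splits <- lapply(1:3, function(k) {
    idx <- sample(n, 60)
    list(X_train = X[idx, ], y_train = y[idx],
         X_val = X[-idx, ], y_val = y[-idx])
  })
  space <- search_space("genomic", desk_scale = TRUE, max_epochs = 15L)
  tr <- tune_hyperparameters(space, splits, input_shape = p, budget = 3L,
                             max_epochs = 15L, final_epochs = 15L, seed = 13L)
  expect_equal(nrow(tr$evaluated), 3L)
  expect_true(all(tr$evaluated$split_id %in% 1:3))
  expect_true(all(is.finite(tr$evaluated$best_val_rmse)))
  expect_lte(length(tr$top), 3L)
  for (entry in tr$top) {
    expect_equal(dim(entry$trajectories), c(15L, 3L))
    expect_true(all(is.finite(entry$trajectories)))
    expect_gt(entry$n_params, 0L)
  }
  # budget = 1: the single config is trivially top-1
  tr1 <- tune_hyperparameters(space, splits, input_shape = p, budget = 1L,
                              max_epochs = 10L, final_epochs = 10L, seed = 14L)
  expect_length(tr1$top, 1L)
})

test_that("binned-loss selection picks the config winning the most bins", {
  mk <- function(level, E = 100L, S = 5L, noise = 0.01, params = 100L) {
    list(trajectories = matrix(level + stats::rnorm(E * S, sd = noise), E, S),
         n_params = params, config = list(), config_id = NA)
  }
  set.seed(45)
  # uniformly better config wins all bins
  top <- list(mk(1.0), mk(0.5))
  best <- select_best_config(top)
  expect_equal(best$bins_won, 10L)
  expect_equal(best$n_params, top[[2]]$n_params)
  # crafted 6-vs-4 bin split: A lower in epochs 1-60, B lower in 61-100
  a <- matrix(rep(c(rep(0.2, 60), rep(0.8, 40)), 5), 100, 5)
  bmat <- matrix(rep(c(rep(0.6, 60), rep(0.3, 40)), 5), 100, 5)
  top2 <- list(list(trajectories = a, n_params = 10L),
               list(trajectories = bmat, n_params = 10L))
  sel <- select_best_config(top2)
  expect_equal(sel$bins_won, 6L)
  expect_equal(sel$trajectories, a)
  # equal constant trajectories: tie broken by parameter count
  t1 <- list(trajectories = matrix(0.5, 100, 5), n_params = 50L)
  t2 <- list(trajectories = matrix(0.5, 100, 5), n_params = 10L)
  expect_equal(select_best_config(list(t1, t2))$n_params, 10L)
})

test_that("epoch selection minimizes the trailing rolling mean, earliest on ties", {
  # monotone decreasing: minimum at the final epoch
  dec <- matrix(rep(seq(1, 0.1, length.out = 100), 3), 100, 3)
  expect_equal(select_epochs(dec), 100L)
  # V-shape with minimum at epoch 100 of 200
  v <- c(seq(1, 0.1, length.out = 100), seq(0.1, 1, length.out = 100))
  traj <- matrix(rep(v, 4), 200, 4)
  sel <- select_epochs(traj)
  expect_true(sel >= 95 && sel <= 125)
  bf <- brute_select_epochs(traj)
  expect_equal(sel, bf)
  # two equal minima: the earliest epoch is returned
  flat <- matrix(0.5, 100, 2)
  expect_equal(select_epochs(flat), 20L)
})

test_that("selection protocols agree with brute-force implementations on random trajectories", {
  set.seed(46)
  for (i in 1:25) {
    top <- lapply(1:3, function(k) {
      list(trajectories = matrix(stats::runif(100 * 5, 0.2, 1), 100, 5),
           n_params = sample(10:500, 1), config = list(), config_id = k)
    })
    mine <- select_best_config(top)
    bf <- brute_select_config(top)
    expect_equal(mine$config_id, bf)
    traj <- top[[1]]$trajectories
    expect_equal(select_epochs(traj), brute_select_epochs(traj))
  }
})

test_that("final training returns replicate predictions that vary across seeds", {
  set.seed(47)
  n <- 60; p <- 5
  X <- matrix(stats::rnorm(n * p), n)
  y <- as.vector(X %*% stats::rnorm(p)) + stats::rnorm(n, sd = 0.2)
  config <- list(arch = architecture_spec("genomic", "relu", units = 8L),
                 lr = 0.01, beta1 = 0.9, beta2 = 0.999, batch_size = 16L)
  fin <- train_final(config, X[1:45, ], y[1:45], X[46:60, ], epochs = 25L,
                     input_shape = p, n_replicates = 3L, seed = 21L)
  expect_equal(fin$n_replicates, 3L)
  expect_equal(dim(fin$predictions), c(3L, 15L))
  expect_gt(stats::sd(fin$predictions[, 1]), 0)
  # same seed reproduces the replicate set exactly
  fin2 <- train_final(config, X[1:45, ], y[1:45], X[46:60, ], epochs = 25L,
                      input_shape = p, n_replicates = 3L, seed = 21L)
  expect_identical(fin$predictions, fin2$predictions)
})

test_that("fusion assembly concatenates one replicate per modality reproducibly", {
  set.seed(48)
  reps <- list(genomic = lapply(1:3, function(i) matrix(i, 10, 4)),
               soil = lapply(1:2, function(i) matrix(10 * i, 10, 2)),
               weather = list(matrix(99, 10, 5)))
  sets <- assemble_fusion_inputs(reps, n_sets = 10L, seed = 5L)
  expect_length(sets, 10L)
  for (s in sets) {
    expect_equal(ncol(s$features), 4L + 2L + 5L)
    expect_named(s$chosen, c("genomic", "soil", "weather"))
  }
  sets2 <- assemble_fusion_inputs(reps, n_sets = 10L, seed = 5L)
  expect_identical(lapply(sets, `[[`, "chosen"), lapply(sets2, `[[`, "chosen"))
  # a single replicate per modality makes every set identical
  single <- lapply(reps, function(r) r[1])
  s1 <- assemble_fusion_inputs(single, n_sets = 4L, seed = 1L)
  expect_true(all(vapply(s1, function(s) identical(s$features, s1[[1]]$features),
                         logical(1))))
  expect_error(assemble_fusion_inputs(list(genomic = list())), "modality")
})

test_that("the weather convolution module trains on array inputs", {
  set.seed(49)
  n <- 40; C <- 3; L <- 24
  X <- array(stats::rnorm(n * C * L), c(n, C, L))
  y <- apply(X[, 1, ], 1, mean) + stats::rnorm(n, sd = 0.05)
  spec <- architecture_spec("weather", conv_blocks = 1L,
                            conv_layers_per_block = 2L, filters = c(6L, 4L),
                            pooling = "max")
  m <- build_network(spec, c(C, L), seed = 6L)
  fit <- train_network(m, X, y, epochs = 60L, batch_size = 16L, lr = 0.01,
                       seed = 8L)
  expect_lt(utils::tail(fit$history$train_rmse, 1), stats::sd(y))
  feats <- network_features(fit$model, X)
  expect_equal(nrow(feats), n)
  expect_gt(ncol(feats), 1L)
})
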