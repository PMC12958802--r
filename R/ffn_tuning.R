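# Hyperparameter tuning and epoch-selection protocol for the network
# models: random search over a declared space, one randomly chosen
# training/validation pair per candidate with early stopping, retraining
# of the 4 best candidates on all pairs, binned-loss configuration
# selection, and rolling-mean epoch selection.

#' Hyperparameter search space for a network module
#'
#' Defaults mirror the full search ranges used for each module kind
#' (genomic/soil/fusion dense stacks and the convolutional weather stack):
#' 1-7 layers, 4-256 units (genomic) or 4-64 (soil/fusion), dropout 0-0.3,
#' 1-7 convolution blocks of 1-4 layers with 4-512 filters and max/average
#' pooling, learning rate grid {0.1, 0.01, 0.001, 0.0001}, Adam moment
#' decays in [0.9, 0.9999], batch sizes 32-256 in steps of 16, and up to
#' 1000 epochs. `desk_scale = TRUE` shrinks the ranges (<= 3 layers, <= 32
#' units/filters, <= 2 blocks) for small simulated datasets.
#'
#' @param kind Module kind, as in [architecture_spec()].
#' @param desk_scale Shrink ranges for small-data experiments.
#' @param layers,units,dropout,conv_blocks,conv_layers,filters,pooling
#'   Range overrides (length-2 bounds, or a set for `pooling`).
#' @param learning_rate,beta1,beta2,batch_size,max_epochs Training ranges.
#' @return A `search_space`.
#' @export
search_space <- function(kind = c("genomic", "soil", "weather", "fusion"),
                         desk_scale = FALSE,
                         layers = NULL, units = NULL, dropout = c(0, 0.3),
                         conv_blocks = NULL, conv_layers = NULL, filters = NULL,
                         pooling = c("max", "average"),
                         learning_rate = c(0.1, 0.01, 0.001, 0.0001),
                         beta1 = c(0.9, 0.9999), beta2 = c(0.9, 0.9999),
                         batch_size = NULL, max_epochs = NULL) {
  kind <- match.arg(kind)
  big_units <- if (kind == "genomic") c(4L, 256L) else c(4L, 64L)
  defaults <- if (desk_scale) {
    list(layers = c(1L, 3L), units = c(4L, 32L), conv_blocks = c(1L, 2L),
         conv_layers = c(1L, 2L), filters = c(4L, 16L),
         batch_size = c(16L, 64L), max_epochs = 100L)
  } else {
    list(layers = c(1L, 7L), units = big_units, conv_blocks = c(1L, 7L),
         conv_layers = c(1L, 4L), filters = c(4L, 512L),
         batch_size = seq(32L, 256L, 16L), max_epochs = 1000L)
  }
  structure(list(kind = kind,
                 layers = layers %||% defaults$layers,
                 units = units %||% defaults$units,
                 dropout = dropout,
                 conv_blocks = conv_blocks %||% defaults$conv_blocks,
                 conv_layers = conv_layers %||% defaults$conv_layers,
                 filters = filters %||% defaults$filters,
                 pooling = pooling,
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 batch_size = batch_size %||% defaults$batch_size,
                 max_epochs = max_epochs %||% defaults$max_epochs),
            class = "search_space")
}

#' Draw one random configuration from a search space
#'
#' @param space A [search_space()].
#' @param activation Activation for the module.
#' @return List with an `arch` ([architecture_spec()]) and training
#'   hyperparameters `lr`, `beta1`, `beta2`, `batch_size`.
#' @export
sample_config <- function(space, activation = "relu") {
  stopifnot(inherits(space, "search_space"))
  ri <- function(b) if (length(b) == 2L) sample(seq(b[1], b[2]), 1L) else sample(b, 1L)
  if (space$kind == "weather") {
    nb <- ri(space$conv_blocks)
    npb <- ri(space$conv_layers)
    arch <- architecture_spec(kind = "weather", activation = "relu",
                              conv_blocks = nb, conv_layers_per_block = npb,
                              filters = replicate(nb * npb, ri(space$filters)),
                              pooling = sample(space$pooling, 1L))
  } else {
    nl <- ri(space$layers)
    arch <- architecture_spec(kind = space$kind, activation = activation,
                              units = replicate(nl, ri(space$units)),
                              dropout = stats::runif(nl, space$dropout[1], space$dropout[2]))
  }
  bs <- if (length(space$batch_size) == 2L) {
    sample(seq(space$batch_size[1], space$batch_size[2], 16L), 1L)
  } else {
    sample(space$batch_size, 1L)
  }
  list(arch = arch,
       lr = sample(space$learning_rate, 1L),
       beta1 = stats::runif(1L, space$beta1[1], space$beta1[2]),
       beta2 = stats::runif(1L, space$beta2[1], space$beta2[2]),
       batch_size = bs)
}

train_config <- function(config, split, input_shape, epochs, patience, seed) {
  model <- build_network(config$arch, input_shape, seed = seed)
  train_network(model, split$X_train, split$y_train, epochs = epochs,
                batch_size = config$batch_size, lr = config$lr,
                beta1 = config$beta1, beta2 = config$beta2,
                validation = list(X = split$X_val, y = split$y_val),
                patience = patience, seed = seed)
}

#' Random-search tuning with the replicated-validation protocol
#'
#' Samples `budget` configurations; each is trained on one randomly chosen
#' training/validation pair with early stopping (patience `patience`, at
#' most `max_epochs` epochs) and scored by its best-epoch validation RMSE.
#' The 4 best configurations are then retrained on every pair for
#' `final_epochs` epochs without early stopping, recording the full
#' validation-loss trajectories needed by [select_best_config()] and
#' [select_epochs()].
#'
#' @param space A [search_space()].
#' @param splits List of training/validation pairs, each a list with
#'   `X_train`, `y_train`, `X_val`, `y_val`.
#' @param input_shape As in [build_network()].
#' @param budget Number of sampled configurations (default 40).
#' @param max_epochs,patience Early-stopping settings for the search stage.
#' @param final_epochs Epochs for the top-4 retraining stage (defaults to
#'   `max_epochs`).
#' @param activation Module activation.
#' @param n_top Configurations advanced to the retraining stage.
#' @param seed Seed for sampling, initialization and shuffling.
#' @return A `tuning_result`: `evaluated` bookkeeping data frame (config,
#'   split id, best validation RMSE), `configs`, and `top` — a list of the
#'   advanced configurations with their epoch x split validation-loss
#'   trajectory matrices and parameter counts.
#' @export
tune_hyperparameters <- function(space, splits, input_shape, budget = 40L,
                                 max_epochs = 500L, patience = 7L,
                                 final_epochs = max_epochs,
                                 activation = "relu", n_top = 4L, seed = 1L) {
  if (length(splits) < 2L) stopf("at least 2 training/validation splits are required")
  budget <- check_count(budget, "budget")
  configs <- vector("list", budget)
  split_id <- integer(budget)
  best_val <- rep(NA_real_, budget)
  with_seed(derive_seed(seed, "tuning_sample"), {
    for (i in seq_len(budget)) {
      configs[[i]] <- sample_config(space, activation)
      split_id[i] <- sample.int(length(splits), 1L)
    }
  })
  for (i in seq_len(budget)) {
    fit <- tryCatch(
      train_config(configs[[i]], splits[[split_id[i]]], input_shape,
                   epochs = max_epochs, patience = patience,
                   seed = derive_seed(seed, paste0("cfg", i))),
      error = function(e) NULL)
    if (!is.null(fit)) best_val[i] <- min(fit$history$val_rmse, na.rm = TRUE)
  }
  ok <- which(is.finite(best_val))
  if (length(ok) == 0L) stopf("every candidate configuration failed to train")
  n_top <- min(n_top, length(ok))
  top_idx <- ok[order(best_val[ok])][seq_len(n_top)]
  top <- lapply(top_idx, function(i) {
    traj <- matrix(NA_real_, final_epochs, length(splits))
    n_params <- NA_integer_
    for (s in seq_along(splits)) {
      fit <- train_config(configs[[i]], splits[[s]], input_shape,
                          epochs = final_epochs, patience = Inf,
                          seed = derive_seed(seed, paste0("cfg", i, "s", s)))
      traj[seq_len(nrow(fit$history)), s] <- fit$history$val_rmse
      n_params <- count_params(fit$model)
    }
    list(config = configs[[i]], config_id = i, trajectories = traj,
         n_params = n_params)
  })
  structure(list(evaluated = data.frame(config_id = seq_len(budget),
                                        split_id = split_id,
                                        best_val_rmse = best_val),
                 configs = configs, top = top, seed = seed),
            class = "tuning_result")
}

#' @export
print.tuning_result <- function(x, ...) {
  cat(sprintf("Tuning result: %d configs evaluated, %d advanced to full retraining\n",
              nrow(x$evaluated), length(x$top)))
  invisible(x)
}

# Binned mean+sd trajectory scores: one row per config, one column per bin.
binned_scores <- function(top, n_bins) {
  t(vapply(top, function(entry) {
    traj <- entry$trajectories
    m <- rowMeans(traj)
    s <- apply(traj, 1L, stats::sd)
    score <- m + s
    bin <- rep(seq_len(n_bins), each = ceiling(length(score) / n_bins))[seq_along(score)]
    as.vector(tapply(score, bin, mean))
  }, numeric(n_bins)))
}

#' Select the best configuration by binned validation loss
#'
#' For each retrained configuration, the per-epoch mean-plus-standard-
#' deviation of the validation loss across splits is averaged within
#' `n_bins` equal-width epoch bins; the configuration that attains the
#' minimal bin loss in the most bins wins. Ties are broken by fewest
#' parameters, then lowest overall mean validation loss.
#'
#' @param tuning A `tuning_result` (or its `top` list).
#' @param n_bins Number of epoch bins (default 10).
#' @return The winning entry of `top` with `bins_won` attached.
#' @export
select_best_config <- function(tuning, n_bins = 10L) {
  top <- if (inherits(tuning, "tuning_result")) tuning$top else tuning
  if (length(top) == 0L) stopf("no retrained configurations to select from")
  scores <- binned_scores(top, n_bins)
  # a config wins a bin if it attains the bin minimum (ties shared)
  wins <- rowSums(apply(scores, 2L, function(col) col <= min(col) + 1e-12))
  best <- which(wins == max(wins))
  if (length(best) > 1L) {
    np <- vapply(top[best], function(e) e$n_params %||% NA_integer_, 0L)
    best <- best[order(np, vapply(top[best], function(e) mean(e$trajectories), 0))]
  }
  out <- top[[best[1]]]
  out$bins_won <- wins[best[1]]
  out
}

#' Select the training epoch count from validation trajectories
#'
#' Sums the validation loss across the training/validation pairs at each
#' epoch, smooths with a trailing rolling mean of `window` epochs, and
#' returns the earliest epoch minimizing the smoothed loss.
#'
#' @param trajectories Epoch x split matrix of validation losses (e.g. the
#'   winner's `trajectories` from [select_best_config()]).
#' @param window Rolling-mean width in epochs (default 20).
#' @return Integer epoch count.
#' @export
select_epochs <- function(trajectories, window = 20L) {
  trajectories <- as.matrix(trajectories)
  E <- nrow(trajectories)
  if (E < window) stopf("need at least %d epochs of trajectory", window)
  summed <- rowSums(trajectories)
  roll <- stats::filter(summed, rep(1 / window, window), sides = 1)
  roll <- as.vector(roll)
  which.min(roll)  # which.min returns the earliest minimizer
}

#' Train replicated final models and collect test predictions
#'
#' Trains `n_replicates` independently initialized copies of the selected
#' configuration for the selected epoch budget on the full training data,
#' returning per-replicate models, test predictions, and fusion features.
#'
#' @param config A configuration (as in [sample_config()]).
#' @param X_train,y_train Full training data.
#' @param X_test Test inputs.
#' @param epochs Selected epoch count.
#' @param input_shape As in [build_network()].
#' @param n_replicates Number of replicate trainings (default 10).
#' @param seed Base seed; replicate `r` uses a seed derived from it.
#' @return List with `predictions` (replicates x test records matrix),
#'   `models`, and `features` (per-replicate final-layer training features).
#' @export
train_final <- function(config, X_train, y_train, X_test, epochs, input_shape,
                        n_replicates = 10L, seed = 1L) {
  n_replicates <- check_count(n_replicates, "n_replicates")
  preds <- NULL
  models <- vector("list", n_replicates)
  feats <- vector("list", n_replicates)
  kept <- logical(n_replicates)
  for (r in seq_len(n_replicates)) {
    rs <- derive_seed(seed, paste0("replicate", r))
    fit <- tryCatch({
      model <- build_network(config$arch, input_shape, seed = rs)
      train_network(model, X_train, y_train, epochs = epochs,
                    batch_size = config$batch_size, lr = config$lr,
                    beta1 = config$beta1, beta2 = config$beta2, seed = rs)
    }, error = function(e) {
      warning(sprintf("replicate %d diverged and was excluded: %s", r,
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (is.null(fit)) next
    kept[r] <- TRUE
    models[[r]] <- fit$model
    feats[[r]] <- network_features(fit$model, X_train)
    pr <- predict_network(fit$model, X_test)
    preds <- rbind(preds, pr)
  }
  rownames(preds) <- sprintf("rep%d", which(kept))
  list(predictions = preds, models = models[kept], features = feats[kept],
       n_replicates = sum(kept))
}

#' Assemble fusion training sets from single-modality replicates
#'
#' Each fusion set concatenates the final-layer features of one randomly
#' chosen replicate per modality, propagating single-model sampling
#' variability into fusion training.
#'
#' @param modality_replicates Named list; each element is a list of
#'   replicate feature matrices with aligned rows.
#' @param n_sets Number of concatenated sets (default 10).
#' @param seed Seed for replicate selection.
#' @return List of `n_sets` elements, each with `features` (row-aligned
#'   concatenation) and `chosen` (replicate index per modality).
#' @export
assemble_fusion_inputs <- function(modality_replicates, n_sets = 10L, seed = 1L) {
  if (length(modality_replicates) == 0L ||
      any(vapply(modality_replicates, length, 0L) == 0L)) {
    stopf("every modality must supply at least one replicate")
  }
  n_sets <- check_count(n_sets, "n_sets")
  with_seed(derive_seed(seed, "fusion_assembly"), {
    lapply(seq_len(n_sets), function(s) {
      chosen <- vapply(modality_replicates, function(reps) sample.int(length(reps), 1L), 0L)
      mats <- Map(function(reps, ch) reps[[ch]], modality_replicates, chosen)
      list(features = do.call(cbind, mats), chosen = chosen)
    })
  })
}
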