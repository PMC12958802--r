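# A compact network engine for the neural-network arm of the model
# comparison: dense stacks for genomic/soil/fusion inputs, a 1-D
# convolutional stack for windowed weather, trained by mini-batch Adam on
# squared error (reported as RMSE).

ACTIVATIONS <- list(
  relu = list(f = function(z) pmax(z, 0), g = function(z, a) (z > 0) * 1),
  sigmoid = list(f = function(z) 1 / (1 + exp(-z)), g = function(z, a) a * (1 - a)),
  tanh = list(f = tanh, g = function(z, a) 1 - a^2),
  identity = list(f = identity, g = function(z, a) 1)
)

#' Architecture specification for a network module
#'
#' @param kind One of "genomic", "soil", "weather", "fusion". Dense kinds
#'   take `units`/`dropout` per hidden layer; "weather" takes convolution
#'   blocks (each: `conv_layers_per_block` 1-D convolutions followed by one
#'   pooling step) and a filter count per convolution layer.
#' @param activation Hidden activation: "relu", "sigmoid", or "tanh"
#'   ("identity" is also accepted, collapsing the stack to a linear model —
#'   useful as a regression baseline and in degeneracy checks).
#' @param units Integer vector of dense hidden-layer widths.
#' @param dropout Dropout rate per dense hidden layer (recycled).
#' @param conv_blocks Number of convolution blocks (weather only).
#' @param conv_layers_per_block Convolutions per block.
#' @param filters Filters per convolution layer (recycled over layers).
#' @param pooling "max" or "average" (weather only).
#' @param kernel_width Convolution window width in weather windows.
#' @param pool_size Pooling width/stride.
#' @return An `arch_spec`.
#' @export
architecture_spec <- function(kind = c("genomic", "soil", "weather", "fusion"),
                              activation = c("relu", "sigmoid", "tanh", "identity"),
                              units = 16L, dropout = 0,
                              conv_blocks = 1L, conv_layers_per_block = 1L,
                              filters = 8L, pooling = c("max", "average"),
                              kernel_width = 3L, pool_size = 2L) {
  kind <- match.arg(kind)
  activation <- match.arg(activation)
  pooling <- match.arg(pooling)
  if (kind == "weather") {
    conv_blocks <- check_count(conv_blocks, "conv_blocks")
    conv_layers_per_block <- check_count(conv_layers_per_block, "conv_layers_per_block")
    n_conv <- conv_blocks * conv_layers_per_block
    filters <- as.integer(rep_len(filters, n_conv))
  } else {
    if (length(units) < 1L) stopf("at least one hidden layer is required")
    units <- vapply(units, check_count, 0L, name = "units")
    dropout <- rep_len(dropout, length(units))
    if (any(dropout < 0 | dropout >= 1)) stopf("dropout rates must lie in [0, 1)")
  }
  structure(list(kind = kind, activation = activation, units = units,
                 dropout = dropout, conv_blocks = conv_blocks,
                 conv_layers_per_block = conv_layers_per_block,
                 filters = filters, pooling = pooling,
                 kernel_width = check_count(kernel_width, "kernel_width"),
                 pool_size = check_count(pool_size, "pool_size")),
            class = "arch_spec")
}

init_mat <- function(nr, nc, fan_in, activation) {
  sdv <- if (activation == "relu") sqrt(2 / fan_in) else sqrt(1 / fan_in)
  matrix(stats::rnorm(nr * nc, sd = sdv), nr, nc)
}

#' Build a trainable network from an architecture specification
#'
#' Dense modules are affine + activation + dropout stacks; the weather
#' module is a stack of convolution blocks (1-D convolutions over the
#' window axis with pooling) flattened into the final linear unit. All
#' networks end in a single linear output neuron.
#'
#' @param spec An [architecture_spec()].
#' @param input_shape Integer: feature count for dense modules, or
#'   `c(channels, length)` for the weather module.
#' @param seed Seed for weight initialization.
#' @return An `ffn_model`: list of layers with initialized parameters.
#' @export
build_network <- function(spec, input_shape, seed = 1L) {
  stopifnot(inherits(spec, "arch_spec"))
  with_seed(derive_seed(seed, "ffn_init"), {
    layers <- list()
    if (spec$kind == "weather") {
      if (length(input_shape) != 2L) stopf("weather input shape must be c(channels, length)")
      C <- input_shape[1]; L <- input_shape[2]
      li <- 0L
      for (bk in seq_len(spec$conv_blocks)) {
        for (j in seq_len(spec$conv_layers_per_block)) {
          li <- li + 1L
          f <- spec$filters[li]
          kw <- min(spec$kernel_width, L)
          if (L - kw + 1L < 1L) stopf("build error: sequence too short for convolution")
          layers[[length(layers) + 1L]] <- list(
            type = "conv", kw = kw,
            W = init_mat(C * kw, f, C * kw, "relu"),
            b = numeric(f), activation = "relu")
          C <- f
          L <- L - kw + 1L
        }
        if (L >= spec$pool_size) {
          layers[[length(layers) + 1L]] <- list(type = "pool",
                                                pooling = spec$pooling,
                                                size = spec$pool_size)
          L <- L %/% spec$pool_size
        }
      }
      layers[[length(layers) + 1L]] <- list(type = "flatten")
      p <- C * L
    } else {
      if (length(input_shape) != 1L) stopf("dense input shape must be a feature count")
      p <- input_shape
      for (i in seq_along(spec$units)) {
        layers[[length(layers) + 1L]] <- list(
          type = "dense", W = init_mat(p, spec$units[i], p, spec$activation),
          b = numeric(spec$units[i]), activation = spec$activation,
          dropout = spec$dropout[i])
        p <- spec$units[i]
      }
    }
    layers[[length(layers) + 1L]] <- list(type = "dense",
                                          W = init_mat(p, 1L, p, "identity"),
                                          b = 0, activation = "identity",
                                          dropout = 0)
    structure(list(layers = layers, spec = spec, input_shape = input_shape),
              class = "ffn_model")
  })
}

#' Number of trainable parameters in a network
#' @param model An `ffn_model`.
#' @return Integer parameter count.
#' @export
count_params <- function(model) {
  sum(vapply(model$layers, function(l) {
    if (l$type %in% c("dense", "conv")) length(l$W) + length(l$b) else 0L
  }, 0L))
}

# --- array plumbing for 1-D convolutions -----------------------------------

im2col <- function(X, kw) {
  d <- dim(X); n <- d[1]; C <- d[2]; L <- d[3]
  L_out <- L - kw + 1L
  out <- matrix(0, n * L_out, C * kw)
  for (o in seq_len(kw)) {
    slab <- X[, , o:(o + L_out - 1L), drop = FALSE]
    out[, ((o - 1L) * C + 1L):(o * C)] <- matrix(aperm(slab, c(1, 3, 2)), n * L_out, C)
  }
  out
}

col2im <- function(dcol, n, C, L, kw) {
  L_out <- L - kw + 1L
  dX <- array(0, c(n, C, L))
  for (o in seq_len(kw)) {
    block <- array(dcol[, ((o - 1L) * C + 1L):(o * C)], c(n, L_out, C))
    dX[, , o:(o + L_out - 1L)] <- dX[, , o:(o + L_out - 1L), drop = FALSE] +
      aperm(block, c(1, 3, 2))
  }
  dX
}

pool_forward <- function(X, size, pooling) {
  d <- dim(X); L <- d[3]
  L_pool <- L %/% size
  take <- function(o) X[, , seq(o, by = size, length.out = L_pool), drop = FALSE]
  if (pooling == "average") {
    out <- Reduce(`+`, lapply(seq_len(size), take)) / size
    list(out = out, argmax = NULL)
  } else {
    cur <- take(1L)
    idx <- array(1L, dim(cur))
    for (o in seq_len(size)[-1]) {
      cand <- take(o)
      upd <- cand > cur
      cur[upd] <- cand[upd]
      idx[upd] <- o
    }
    list(out = cur, argmax = idx)
  }
}

pool_backward <- function(dY, cache, size, pooling, L) {
  d <- dim(dY); L_pool <- d[3]
  dX <- array(0, c(d[1], d[2], L))
  for (o in seq_len(size)) {
    pos <- seq(o, by = size, length.out = L_pool)
    if (pooling == "average") {
      dX[, , pos] <- dY / size
    } else {
      mask <- cache$argmax == o
      slab <- array(0, d)
      slab[mask] <- dY[mask]
      dX[, , pos] <- slab
    }
  }
  dX
}

# Forward pass; when `training`, applies inverted dropout and stores caches.
ffn_forward <- function(model, X, training = FALSE) {
  caches <- vector("list", length(model$layers))
  A <- X
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    if (l$type == "dense") {
      Z <- sweep(A %*% l$W, 2L, l$b, `+`)
      act <- ACTIVATIONS[[l$activation]]
      out <- act$f(Z)
      mask <- NULL
      if (training && l$dropout > 0) {
        mask <- (matrix(stats::runif(length(out)), nrow(out)) >= l$dropout) / (1 - l$dropout)
        out <- out * mask
      }
      caches[[i]] <- list(input = A, Z = Z, A = out, mask = mask)
      A <- out
    } else if (l$type == "conv") {
      Xcol <- im2col(A, l$kw)
      Zc <- sweep(Xcol %*% l$W, 2L, l$b, `+`)
      Ac <- pmax(Zc, 0)
      n <- dim(A)[1]
      L_out <- dim(A)[3] - l$kw + 1L
      out <- aperm(array(Ac, c(n, L_out, ncol(l$W))), c(1, 3, 2))
      caches[[i]] <- list(in_dim = dim(A), Xcol = Xcol, Zc = Zc)
      A <- out
    } else if (l$type == "pool") {
      pf <- pool_forward(A, l$size, l$pooling)
      caches[[i]] <- list(in_dim = dim(A), pool = pf)
      A <- pf$out
    } else if (l$type == "flatten") {
      caches[[i]] <- list(in_dim = dim(A))
      A <- matrix(A, dim(A)[1])
    }
  }
  list(yhat = as.vector(A), caches = caches)
}

# Backward pass from output gradient `dout` (n x 1); returns per-layer
# parameter gradients.
ffn_backward <- function(model, caches, dout) {
  grads <- vector("list", length(model$layers))
  dA <- dout
  for (i in rev(seq_along(model$layers))) {
    l <- model$layers[[i]]
    cc <- caches[[i]]
    if (l$type == "dense") {
      if (!is.null(cc$mask)) dA <- dA * cc$mask
      act <- ACTIVATIONS[[l$activation]]
      dZ <- dA * act$g(cc$Z, if (l$activation == "identity") cc$Z else act$f(cc$Z))
      grads[[i]] <- list(W = crossprod(cc$input, dZ), b = colSums(dZ))
      dA <- dZ %*% t(l$W)
    } else if (l$type == "conv") {
      n <- cc$in_dim[1]
      L_out <- cc$in_dim[3] - l$kw + 1L
      dAc <- matrix(aperm(dA, c(1, 3, 2)), n * L_out, ncol(l$W))
      dZc <- dAc * (cc$Zc > 0)
      grads[[i]] <- list(W = crossprod(cc$Xcol, dZc), b = colSums(dZc))
      dcol <- dZc %*% t(l$W)
      dA <- col2im(dcol, n, cc$in_dim[2], cc$in_dim[3], l$kw)
    } else if (l$type == "pool") {
      dA <- pool_backward(dA, cc$pool, l$size, l$pooling, cc$in_dim[3])
    } else if (l$type == "flatten") {
      dA <- array(dA, cc$in_dim)
    }
  }
  grads
}

subset_input <- function(X, idx) {
  if (is.matrix(X)) X[idx, , drop = FALSE] else X[idx, , , drop = FALSE]
}

rmse <- function(obs, pred) sqrt(mean((obs - pred)^2))

#' Predictions from a trained network
#'
#' Evaluation-mode forward pass (dropout disabled); deterministic given the
#' weights.
#'
#' @param model An `ffn_model`.
#' @param X Input matrix (dense) or `c(n, channels, length)` array (weather).
#' @return Numeric prediction vector.
#' @export
predict_network <- function(model, X) {
  ffn_forward(model, X, training = FALSE)$yhat
}

#' Final-hidden-layer outputs (fusion features)
#'
#' Returns the activations feeding the output neuron: the learned
#' representation that fusion networks concatenate across modalities.
#'
#' @inheritParams predict_network
#' @return Matrix n x width of the last hidden layer.
#' @export
network_features <- function(model, X) {
  feats <- X
  for (l in model$layers[-length(model$layers)]) {
    feats <- forward_one(l, feats)
  }
  if (!is.matrix(feats)) feats <- matrix(feats, dim(feats)[1])
  feats
}

forward_one <- function(l, A) {
  if (l$type == "dense") {
    act <- ACTIVATIONS[[l$activation]]
    act$f(sweep(A %*% l$W, 2L, l$b, `+`))
  } else if (l$type == "conv") {
    Xcol <- im2col(A, l$kw)
    Zc <- sweep(Xcol %*% l$W, 2L, l$b, `+`)
    n <- dim(A)[1]; L_out <- dim(A)[3] - l$kw + 1L
    aperm(array(pmax(Zc, 0), c(n, L_out, ncol(l$W))), c(1, 3, 2))
  } else if (l$type == "pool") {
    pool_forward(A, l$size, l$pooling)$out
  } else {
    matrix(A, dim(A)[1])
  }
}

#' Train a network by mini-batch Adam
#'
#' Minimizes squared error (whose gradient equals the RMSE gradient up to a
#' positive factor); the per-epoch history records RMSE. Optional
#' validation data enable early stopping: training stops after `patience`
#' epochs without improvement of validation RMSE and the best-epoch weights
#' are restored.
#'
#' @param model An `ffn_model` from [build_network()].
#' @param X,y Training inputs and responses.
#' @param epochs Maximum epochs.
#' @param batch_size Mini-batch size.
#' @param lr,beta1,beta2 Adam step size and moment decay rates.
#' @param validation Optional `list(X =, y =)`.
#' @param patience Early-stopping patience in epochs (default `Inf`: none).
#' @param seed Seed controlling batch shuffling and dropout.
#' @return List: trained `model`, `history` data frame (epoch, train_rmse,
#'   val_rmse), `best_epoch`, and `trained_epochs`.
#' @export
train_network <- function(model, X, y, epochs = 100L, batch_size = 32L,
                          lr = 0.001, beta1 = 0.9, beta2 = 0.999,
                          validation = NULL, patience = Inf, seed = 1L) {
  n <- if (is.matrix(X)) nrow(X) else dim(X)[1]
  if (length(y) != n) stopf("response length must match the input rows")
  batch_size <- min(check_count(batch_size, "batch_size"), n)
  eps <- 1e-8
  mstate <- vstate <- lapply(model$layers, function(l) {
    if (l$type %in% c("dense", "conv")) list(W = l$W * 0, b = l$b * 0) else NULL
  })
  tstep <- 0
  hist_train <- hist_val <- numeric(0)
  best_val <- Inf
  best_epoch <- 0L
  best_layers <- model$layers
  wait <- 0L
  with_seed(derive_seed(seed, "ffn_train"), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        Xb <- subset_input(X, idx)
        fw <- ffn_forward(model, Xb, training = TRUE)
        dout <- matrix(2 * (fw$yhat - y[idx]) / length(idx), ncol = 1L)
        grads <- ffn_backward(model, fw$caches, dout)
        tstep <- tstep + 1
        for (i in seq_along(model$layers)) {
          if (is.null(grads[[i]])) next
          for (nm in c("W", "b")) {
            g <- grads[[i]][[nm]]
            mstate[[i]][[nm]] <- beta1 * mstate[[i]][[nm]] + (1 - beta1) * g
            vstate[[i]][[nm]] <- beta2 * vstate[[i]][[nm]] + (1 - beta2) * g^2
            mhat <- mstate[[i]][[nm]] / (1 - beta1^tstep)
            vhat <- vstate[[i]][[nm]] / (1 - beta2^tstep)
            model$layers[[i]][[nm]] <- model$layers[[i]][[nm]] -
              lr * mhat / (sqrt(vhat) + eps)
          }
        }
      }
      tr <- rmse(y, predict_network(model, X))
      hist_train[ep] <- tr
      if (!is.null(validation)) {
        vl <- rmse(validation$y, predict_network(model, validation$X))
        hist_val[ep] <- vl
        if (vl < best_val - 1e-12) {
          best_val <- vl
          best_epoch <- ep
          best_layers <- model$layers
          wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= patience) break
        }
      } else {
        best_epoch <- ep
        best_layers <- model$layers
      }
      if (!is.finite(tr)) stopf("training diverged (non-finite loss) at epoch %d", ep)
    }
  })
  model$layers <- best_layers
  history <- data.frame(epoch = seq_along(hist_train), train_rmse = hist_train,
                        val_rmse = if (length(hist_val)) hist_val else NA_real_)
  list(model = model, history = history, best_epoch = best_epoch,
       trained_epochs = length(hist_train))
}
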