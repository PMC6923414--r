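#' Configuration of the N-terminal signal network
#'
#' Architecture and optimisation settings for the compact convolutional
#' network behind the three-class N-terminal classifier. The faithful default
#' is a 70 x 20 one-hot input; a first convolutional layer that compresses the
#' 20 residue channels into `n_channel_kernels = 5` feature maps (one kernel
#' spans all 20 channels at a single position), ReLU, no pooling; a second
#' one-dimensional convolutional layer running `n_motif_kernels` kernels of
#' length `motif_kernel_length` along the 70-position axis; global max pooling
#' over positions per kernel, ReLU; one dense layer; and a softmax over the
#' three classes (SP / TM70 / IN_CELL).
#'
#' @param window_length Input window length in residues (default 70).
#' @param n_channel_kernels Kernels of the channel-reduction layer (default 5).
#' @param n_motif_kernels Number of motif kernels (default 64).
#' @param motif_kernel_length Motif kernel length in positions (default 15,
#'   long enough to span a hydrophobic H-region).
#' @param dense_units Units of the dense layer (default 64).
#' @param n_classes Output classes (default 3).
#' @param learning_rate Adam learning rate (default 2e-3).
#' @param weight_decay L2 penalty coefficient on the convolutional and dense
#'   weights (default 0.01); the small training sets the network sees make
#'   explicit regularisation matter.
#' @param batch_size Mini-batch size (default 32).
#' @param epochs Maximum training epochs (default 60).
#' @param patience Early-stopping patience on validation loss, in epochs
#'   (default 10).
#' @param restarts Independent initialisations per fit; the restart with the
#'   best validation loss is kept (default 2).
#' @return A `sp_model_config` list.
#' @export
sp_model_config <- function(window_length = 70, n_channel_kernels = 5,
                            n_motif_kernels = 64, motif_kernel_length = 15,
                            dense_units = 64, n_classes = 3,
                            learning_rate = 2e-3, weight_decay = 0.01,
                            batch_size = 32, epochs = 60, patience = 10,
                            restarts = 2) {
  cfg <- list(
    window_length = as.integer(window_length),
    n_channel_kernels = as.integer(n_channel_kernels),
    n_motif_kernels = as.integer(n_motif_kernels),
    motif_kernel_length = as.integer(motif_kernel_length),
    dense_units = as.integer(dense_units),
    n_classes = as.integer(n_classes),
    learning_rate = learning_rate,
    weight_decay = weight_decay,
    batch_size = as.integer(batch_size),
    epochs = as.integer(epochs),
    patience = as.integer(patience),
    restarts = as.integer(restarts)
  )
  sizes <- unlist(cfg[c("window_length", "n_channel_kernels",
                        "n_motif_kernels", "motif_kernel_length",
                        "dense_units", "n_classes", "batch_size",
                        "epochs")])
  if (any(sizes < 1) || learning_rate <= 0 || weight_decay < 0 ||
      restarts < 1) {
    stop("All network sizes must be positive integers, the learning rate ",
         "positive and the weight decay nonnegative", call. = FALSE)
  }
  if (cfg$motif_kernel_length > cfg$window_length) {
    stop("motif_kernel_length cannot exceed window_length", call. = FALSE)
  }
  structure(cfg, class = "sp_model_config")
}

# ---- encoding -------------------------------------------------------------

# n x L integer matrix of alphabet indices (0 = pad / non-standard residue).
encode_index_matrix <- function(sequences, window_length) {
  n <- length(sequences)
  out <- matrix(0L, nrow = n, ncol = window_length)
  windows <- n_terminal_window(sequences, window_length)
  for (i in seq_len(n)) {
    idx <- aa_indices(windows[i])
    k <- min(length(idx), window_length)
    if (k > 0) out[i, seq_len(k)] <- idx[seq_len(k)]
  }
  out
}

# ---- parameters -----------------------------------------------------------

# He-style initialisation; relies on the caller's RNG state for determinism.
cnn_init <- function(config) {
  C <- config$n_channel_kernels
  K <- config$n_motif_kernels
  klen <- config$motif_kernel_length
  D <- config$dense_units
  nc <- config$n_classes
  he <- function(nr, nc_, fan_in) {
    matrix(stats::rnorm(nr * nc_, sd = sqrt(2 / fan_in)), nr, nc_)
  }
  list(
    W1 = he(C, 20, 20), b1 = numeric(C),
    W2 = he(C * klen, K, C * klen), b2 = numeric(K),
    W3 = he(K, D, K), b3 = numeric(D),
    W4 = he(D, nc, D), b4 = numeric(nc)
  )
}

# im2col gather map: (n*T) x (C*klen) matrix of linear indices into the
# (C, L, n) layer-1 activation array. Row r = (sample-1)*T + position.
# Cached per shape: the same map is reused for every mini-batch.
.im2col_cache <- new.env(parent = emptyenv())

im2col_map <- function(n, L, C, klen) {
  key <- paste(n, L, C, klen, sep = "_")
  cached <- .im2col_cache[[key]]
  if (!is.null(cached)) return(cached)
  out <- im2col_map_build(n, L, C, klen)
  if (length(ls(.im2col_cache)) > 24) {
    rm(list = ls(.im2col_cache), envir = .im2col_cache)
  }
  .im2col_cache[[key]] <- out
  out
}

im2col_map_build <- function(n, L, C, klen) {
  T_ <- L - klen + 1L
  s_vec <- rep(seq_len(n), each = T_)
  t_vec <- rep(seq_len(T_), times = n)
  out <- matrix(0L, nrow = n * T_, ncol = C * klen)
  j <- 0L
  for (d in seq_len(klen)) {
    for (c in seq_len(C)) {
      j <- j + 1L
      out[, j] <- c + (t_vec + d - 2L) * C + (s_vec - 1L) * C * L
    }
  }
  out
}

# ---- forward / backward ---------------------------------------------------

# Forward pass over an n x L index matrix; returns softmax scores plus the
# intermediate activations needed for backprop (or for inspection).
cnn_forward <- function(params, config, idx_matrix, keep_cache = FALSE) {
  n <- nrow(idx_matrix)
  L <- config$window_length
  C <- config$n_channel_kernels
  K <- config$n_motif_kernels
  klen <- config$motif_kernel_length
  T_ <- L - klen + 1L

  # layer 1: one-hot x W1 reduces to a column gather (pad column = zeros)
  iv <- as.integer(t(idx_matrix)) + 1L
  W1aug <- cbind(0, params$W1)
  Z1 <- W1aug[, iv, drop = FALSE] + params$b1     # C x (L*n)
  A1 <- Z1 * (Z1 > 0)

  map <- im2col_map(n, L, C, klen)
  A <- matrix(A1[map], nrow = n * T_)             # (n*T) x (C*klen)
  Z2 <- A %*% params$W2
  Z2 <- Z2 + rep(params$b2, each = n * T_)        # (n*T) x K

  # global max pool over the T positions of each (sample, kernel)
  M <- matrix(Z2, nrow = T_)                      # T x (n*K)
  amax <- max.col(t(M), ties.method = "first")
  P <- matrix(M[cbind(amax, seq_len(n * K))], nrow = n)  # n x K
  Hp <- P * (P > 0)

  Z3 <- Hp %*% params$W3 + rep(params$b3, each = n)
  A3 <- Z3 * (Z3 > 0)
  Z4 <- A3 %*% params$W4 + rep(params$b4, each = n)
  S <- exp(Z4 - apply(Z4, 1, max))
  S <- S / rowSums(S)

  out <- list(scores = S)
  if (keep_cache) {
    out$cache <- list(iv = iv, Z1 = Z1, A1 = A1, map = map, A = A,
                      P = P, Hp = Hp, amax = amax, Z3 = Z3, A3 = A3,
                      n = n, L = L, C = C, K = K, T_ = T_)
  }
  out
}

# Weighted cross-entropy loss; y is an integer class vector (1..n_classes).
cnn_loss <- function(scores, y, weights) {
  p <- scores[cbind(seq_along(y), y)]
  -sum(weights * log(pmax(p, 1e-12))) / sum(weights)
}

# Backprop of the weighted cross-entropy through the full network.
cnn_backward <- function(params, config, fwd, y, weights) {
  cache <- fwd$cache
  n <- cache$n; L <- cache$L; C <- cache$C; K <- cache$K; T_ <- cache$T_
  S <- fwd$scores
  Y <- matrix(0, n, config$n_classes)
  Y[cbind(seq_len(n), y)] <- 1
  wn <- weights / sum(weights)

  dZ4 <- (S - Y) * wn
  dW4 <- t(cache$A3) %*% dZ4
  db4 <- colSums(dZ4)
  dA3 <- dZ4 %*% t(params$W4)
  dZ3 <- dA3 * (cache$Z3 > 0)
  dW3 <- t(cache$Hp) %*% dZ3
  db3 <- colSums(dZ3)
  dHp <- dZ3 %*% t(params$W3)
  dP <- dHp * (cache$P > 0)

  # scatter pooled gradients back to the argmax positions
  q <- seq_len(n * K)
  s_of_q <- ((q - 1L) %% n) + 1L
  k_of_q <- ((q - 1L) %/% n) + 1L
  lin <- (s_of_q - 1L) * T_ + cache$amax + (k_of_q - 1L) * n * T_
  dZ2 <- numeric(n * T_ * K)
  dZ2[lin] <- as.numeric(dP)
  dim(dZ2) <- c(n * T_, K)

  dW2 <- t(cache$A) %*% dZ2
  db2 <- colSums(dZ2)
  dAim <- dZ2 %*% t(params$W2)

  dA1 <- numeric(C * L * n)
  for (j in seq_len(ncol(cache$map))) {
    idx <- cache$map[, j]
    dA1[idx] <- dA1[idx] + dAim[, j]
  }
  dim(dA1) <- c(C, L * n)
  dZ1 <- dA1 * (cache$Z1 > 0)
  db1 <- rowSums(dZ1)
  grp <- rowsum(t(dZ1), group = cache$iv)          # groups sorted ascending
  present <- sort(unique(cache$iv))
  dW1 <- matrix(0, C, 20)
  std <- present[present >= 2L]
  dW1[, std - 1L] <- t(grp[match(std, present), , drop = FALSE])

  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
       W3 = dW3, b3 = db3, W4 = dW4, b4 = db4)
}

# ---- optimisation ---------------------------------------------------------

adam_state <- function(params) {
  list(m = purrr::map(params, ~ .x * 0), v = purrr::map(params, ~ .x * 0),
       t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# ---- training -------------------------------------------------------------

# Train one network on indexed windows with Adam, class-weighted
# cross-entropy, and early stopping on validation loss (best weights kept).
# `restarts` independent initialisations are trained and the one with the
# best validation loss wins: restart selection only ever sees the inner
# validation partition, never test data.
cnn_train <- function(idx_train, y_train, idx_val, y_val, config,
                      class_weights = NULL, seed = 1,
                      restarts = config$restarts) {
  fits <- purrr::map(seq_len(restarts), function(r) {
    cnn_train_once(idx_train, y_train, idx_val, y_val, config,
                   class_weights, seed = seed + 100000L * (r - 1L))
  })
  fits[[which.min(purrr::map_dbl(fits, "val_loss"))]]
}

cnn_train_once <- function(idx_train, y_train, idx_val, y_val, config,
                           class_weights = NULL, seed = 1) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  n <- nrow(idx_train)
  if (is.null(class_weights)) {
    tab <- tabulate(y_train, nbins = config$n_classes)
    class_weights <- n / (config$n_classes * pmax(tab, 1))
  }
  w_train <- class_weights[y_train]
  w_val <- class_weights[y_val]

  params <- cnn_init(config)
  state <- adam_state(params)
  best <- list(loss = Inf, params = params, epoch = 0L)
  history <- vector("list", config$epochs)
  stale <- 0L
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    for (s0 in starts) {
      batch <- ord[s0:min(s0 + config$batch_size - 1L, n)]
      fwd <- cnn_forward(params, config, idx_train[batch, , drop = FALSE],
                         keep_cache = TRUE)
      grads <- cnn_backward(params, config, fwd, y_train[batch],
                            w_train[batch])
      if (config$weight_decay > 0) {
        for (nm in c("W1", "W2", "W3", "W4")) {
          grads[[nm]] <- grads[[nm]] + config$weight_decay * params[[nm]]
        }
      }
      upd <- adam_step(params, grads, state, config$learning_rate)
      params <- upd$params
      state <- upd$state
    }
    val_scores <- cnn_forward(params, config, idx_val)$scores
    val_loss <- cnn_loss(val_scores, y_val, w_val)
    history[[epoch]] <- tibble::tibble(epoch = epoch, val_loss = val_loss)
    if (val_loss < best$loss - 1e-6) {
      best <- list(loss = val_loss, params = params, epoch = epoch)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= config$patience) break
    }
  }
  list(params = best$params, config = config,
       val_loss = best$loss, best_epoch = best$epoch,
       history = dplyr::bind_rows(history))
}

#' Build an untrained N-terminal signal network
#'
#' Instantiates the network of [sp_model_config()] with randomly initialised
#' weights, mainly for inspection and testing; training is normally driven by
#' [train_sp()].
#'
#' @param config A [sp_model_config()].
#' @param seed Integer seed for weight initialisation.
#' @return An `sp_network` object.
#' @export
build_sp_network <- function(config = sp_model_config(), seed = 1) {
  stopifnot(inherits(config, "sp_model_config"))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  structure(list(params = cnn_init(config), config = config, trained = FALSE),
            class = "sp_network")
}

#' Layer-by-layer activations of a signal network
#'
#' Runs the forward pass and exposes the intermediate representations: the
#' channel-reduction feature maps (`n_channel_kernels` maps of
#' `window_length` positions per protein), the pooled motif features (one
#' scalar per motif kernel), and the final softmax scores.
#'
#' @param network An `sp_network` (or a trained ensemble member).
#' @param sequences Character vector of protein sequences.
#' @return List with `channel_maps` (array `n_channel_kernels` x
#'   `window_length` x n), `motif_features` (n x `n_motif_kernels`) and
#'   `scores` (n x `n_classes`).
#' @export
sp_network_activations <- function(network, sequences) {
  config <- network$config
  idx <- encode_index_matrix(sequences, config$window_length)
  fwd <- cnn_forward(network$params, config, idx, keep_cache = TRUE)
  maps <- fwd$cache$A1
  dim(maps) <- c(config$n_channel_kernels, config$window_length, nrow(idx))
  list(channel_maps = maps, motif_features = fwd$cache$Hp,
       scores = fwd$scores)
}

#' Rectified linear unit
#'
#' `f(x) = max(0, x)`, elementwise.
#'
#' @param x Numeric vector, matrix or array.
#' @return Object of the same shape with negative entries replaced by 0.
#' @examples
#' relu(c(-2, 0, 3.5))
#' @export
relu <- function(x) {
  x * (x > 0)
}
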