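# Parallel two-branch 2D CNN for ictal/interictal window classification.
#
# Input windows are N electrode-rows x 1024 time samples. All convolution
# kernels span 1 row x k samples (k = 3 in one branch, 5 in the other), so
# channels are never mixed by convolution; rows are folded into the batch
# axis for the whole convolutional stack and only recombined by global
# average pooling before the dense head. Internally activations are arrays
# of shape (M, L, C) with M = N * batch.
#
# Each branch: [conv(32, stride 2) -> batch norm -> ReLU -> max-pool 3] ->
# [conv(64, stride 2) -> bn -> ReLU -> pool] -> [conv(128, stride 1) -> bn ->
# ReLU -> pool]; branch features are concatenated after global average
# pooling and passed through a dense ReLU layer to a 2-way softmax whose
# second entry is the ictal probability.
#
# Convolutions use "same"-style padding (output length = ceiling(L/stride));
# max-pooling is non-overlapping with truncation (output length = floor(L/3)).

#' CNN model configuration
#'
#' Defaults follow the reference architecture: 32/64/128 filters, kernel
#' lengths 3 and 5 in the two parallel branches, strides 2/2/1, pooling size
#' 3, RMSprop at learning rate 3e-4, binary cross-entropy, early stopping
#' with patience 15 on validation loss.
#'
#' @param conv_filters strictly increasing integer triple of filter counts.
#' @param kernel_a,kernel_b temporal kernel lengths of the two branches.
#' @param strides integer triple of convolution strides.
#' @param pool_size max-pooling length (stride equal, no padding).
#' @param dense_units width of the hidden fully connected layer.
#' @param learning_rate RMSprop learning rate.
#' @param rho,epsilon RMSprop decay and stabilizer.
#' @param bn_momentum,bn_eps batch-normalization running-average momentum and
#'   variance stabilizer; the 0.9 default lets the inference statistics track
#'   the batch statistics within the short training schedules used here.
#' @param patience early-stopping patience in epochs (validation loss).
#' @param max_epochs training epoch cap.
#' @param batch_size balanced batch size (even).
#' @param epoch_batches batches drawn per epoch.
#' @param seed RNG seed governing initialization and batch sampling.
#' @return an object of class `model_config`.
#' @export
model_config <- function(conv_filters = c(32L, 64L, 128L),
                         kernel_a = 3L, kernel_b = 5L,
                         strides = c(2L, 2L, 1L),
                         pool_size = 3L,
                         dense_units = 64L,
                         learning_rate = 3e-4,
                         rho = 0.9, epsilon = 1e-7,
                         bn_momentum = 0.9, bn_eps = 1e-3,
                         patience = 15L,
                         max_epochs = 50L,
                         batch_size = 32L,
                         epoch_batches = 50L,
                         seed = 1L) {
  stopifnot(length(conv_filters) == 3, all(diff(conv_filters) > 0),
            length(strides) == 3, all(strides >= 1),
            patience >= 1, max_epochs >= 1,
            batch_size >= 2, batch_size %% 2 == 0,
            learning_rate > 0, pool_size >= 2)
  structure(list(conv_filters = as.integer(conv_filters),
                 kernel_a = as.integer(kernel_a),
                 kernel_b = as.integer(kernel_b),
                 strides = as.integer(strides),
                 pool_size = as.integer(pool_size),
                 dense_units = as.integer(dense_units),
                 learning_rate = learning_rate, rho = rho, epsilon = epsilon,
                 bn_momentum = bn_momentum, bn_eps = bn_eps,
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 epoch_batches = as.integer(epoch_batches),
                 seed = as.integer(seed)),
            class = "model_config")
}

glorot <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dims)
}

#' Build an untrained classifier
#'
#' @param cfg a `model_config`.
#' @param n_channels number of electrode rows N of the input windows.
#' @param input_samples temporal window length (default 1024 = 4 s at 256 Hz).
#' @return an object of class `seizure_cnn`.
#' @export
build_model <- function(cfg = model_config(), n_channels,
                        input_samples = 1024L) {
  stopifnot(inherits(cfg, "model_config"))
  if (n_channels < 1) stop_monoseize("n_channels must be >= 1")
  params <- list()
  state <- list()
  with_seed(cfg$seed, {
    for (br in c("a", "b")) {
      k <- if (br == "a") cfg$kernel_a else cfg$kernel_b
      c_in <- 1L
      for (l in 1:3) {
        f <- cfg$conv_filters[l]
        nm <- paste0(br, l)
        params[[paste0(nm, ".W")]] <- glorot(k * c_in, k * f, c(k, c_in, f))
        params[[paste0(nm, ".b")]] <- numeric(f)
        params[[paste0(nm, ".gamma")]] <- rep(1, f)
        params[[paste0(nm, ".beta")]] <- numeric(f)
        state[[paste0(nm, ".mean")]] <- numeric(f)
        state[[paste0(nm, ".var")]] <- rep(1, f)
        c_in <- f
      }
    }
    n_feat <- 2L * cfg$conv_filters[3]
    params[["fc1.W"]] <- glorot(n_feat, cfg$dense_units,
                                c(n_feat, cfg$dense_units))
    params[["fc1.b"]] <- numeric(cfg$dense_units)
    params[["fc2.W"]] <- glorot(cfg$dense_units, 2L, c(cfg$dense_units, 2L))
    params[["fc2.b"]] <- numeric(2L)
  })
  structure(list(cfg = cfg, n_channels = as.integer(n_channels),
                 input_samples = as.integer(input_samples),
                 params = params, state = state,
                 history = NULL, trained = FALSE),
            class = "seizure_cnn")
}

#' @export
print.seizure_cnn <- function(x, ...) {
  cat(sprintf(
    "<seizure_cnn> %d x %d input, branches 1x%d / 1x%d, %s filters, %d params%s\n",
    x$n_channels, x$input_samples, x$cfg$kernel_a, x$cfg$kernel_b,
    paste(x$cfg$conv_filters, collapse = "/"), count_params(x),
    if (x$trained) sprintf(" [trained, %d epochs]", nrow(x$history)) else ""))
  invisible(x)
}

#' Trainable parameter count
#' @param model a `seizure_cnn`.
#' @return total number of trainable parameters (batch-norm running averages
#'   excluded).
#' @export
count_params <- function(model) {
  sum(vapply(model$params, length, 0L))
}

## ---- layers ----------------------------------------------------------------

# Thin wrappers over the compiled kernels in src/cnn_ops.cpp; all keep the
# (M, L, C) activation layout documented above.

conv_fwd <- function(x, W, b, stride) {
  list(out = conv1d_fwd_cpp(x, W, b, stride),
       cache = list(x = x, stride = stride))
}

conv_bwd <- function(dy, cache, W) {
  conv1d_bwd_cpp(cache$x, W, dy, cache$stride)
}

bn_fwd <- function(x, gamma, beta, run_mean, run_var, training,
                   momentum, eps) {
  if (training) {
    r <- bn_train_cpp(x, gamma, beta, eps)
    list(out = r$out,
         cache = list(xhat = r$xhat, ivar = r$ivar, gamma = gamma),
         run_mean = momentum * run_mean + (1 - momentum) * r$mu,
         run_var = momentum * run_var + (1 - momentum) * r$var)
  } else {
    list(out = bn_infer_cpp(x, gamma, beta, run_mean, run_var, eps),
         cache = NULL, run_mean = run_mean, run_var = run_var)
  }
}

bn_bwd <- function(dy, cache) {
  bn_bwd_cpp(dy, cache$xhat, cache$gamma, cache$ivar)
}

pool_fwd <- function(x, p) {
  l <- dim(x)[2]
  if (l %/% p < 1)
    stop_monoseize("temporal length %d too short for pool %d", l, p)
  r <- pool_fwd_cpp(x, p)
  list(out = r$out, cache = list(which = r$which, p = p, l = l))
}

pool_bwd <- function(dy, cache) {
  pool_bwd_cpp(dy, cache$which, cache$p, cache$l)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

## ---- forward / backward ----------------------------------------------------

branch_fwd <- function(x, params, state, br, cfg, training, keep_cache) {
  caches <- list()
  for (l in 1:3) {
    nm <- paste0(br, l)
    cv <- conv_fwd(x, params[[paste0(nm, ".W")]], params[[paste0(nm, ".b")]],
                   cfg$strides[l])
    bn <- bn_fwd(cv$out, params[[paste0(nm, ".gamma")]],
                 params[[paste0(nm, ".beta")]],
                 state[[paste0(nm, ".mean")]], state[[paste0(nm, ".var")]],
                 training, cfg$bn_momentum, cfg$bn_eps)
    if (training) {
      state[[paste0(nm, ".mean")]] <- bn$run_mean
      state[[paste0(nm, ".var")]] <- bn$run_var
    }
    act <- relu_fwd_cpp(bn$out)
    pool <- pool_fwd(act, cfg$pool_size)
    if (keep_cache)
      caches[[nm]] <- list(conv = cv$cache, bn = bn$cache, act = act,
                           pool = pool$cache)
    x <- pool$out
  }
  list(out = x, caches = caches, state = state)
}

branch_bwd <- function(dx, caches, params, br, cfg) {
  grads <- list()
  for (l in 3:1) {
    nm <- paste0(br, l)
    cc <- caches[[nm]]
    dact <- pool_bwd(dx, cc$pool)
    dbn_out <- relu_bwd_cpp(dact, cc$act)
    bb <- bn_bwd(dbn_out, cc$bn)
    grads[[paste0(nm, ".gamma")]] <- bb$dgamma
    grads[[paste0(nm, ".beta")]] <- bb$dbeta
    cb <- conv_bwd(bb$dx, cc$conv, params[[paste0(nm, ".W")]])
    grads[[paste0(nm, ".W")]] <- cb$dW
    grads[[paste0(nm, ".b")]] <- cb$db
    dx <- cb$dx
  }
  grads
}

# windows: array (N, W, B); returns probs (B, 2) with col 2 = ictal.
cnn_fwd <- function(model, windows, training = FALSE, keep_cache = FALSE,
                    params = model$params, state = model$state) {
  if (length(dim(windows)) == 2) dim(windows) <- c(dim(windows), 1L)
  n <- dim(windows)[1]; w <- dim(windows)[2]; b <- dim(windows)[3]
  if (n != model$n_channels || w != model$input_samples)
    stop_monoseize("window shape (%d x %d) does not match model (%d x %d)",
                   n, w, model$n_channels, model$input_samples,
                   class = "monoseize_shape_error")
  x <- aperm(windows, c(1, 3, 2))        # (N, B, W)
  dim(x) <- c(n * b, w, 1L)              # rows folded into batch, n fastest
  cfg <- model$cfg
  fa <- branch_fwd(x, params, state, "a", cfg, training, keep_cache)
  state <- fa$state
  fb <- branch_fwd(x, params, state, "b", cfg, training, keep_cache)
  state <- fb$state
  gap_one <- function(y) {
    dy <- dim(y)
    ym <- colMeans(aperm(y, c(2, 1, 3)), dims = 1)   # (M, C): mean over time
    dim(ym) <- c(n, b, dy[3])
    colMeans(ym, dims = 1)                           # (B, C): mean over rows
  }
  ga <- gap_one(fa$out)
  gb_ <- gap_one(fb$out)
  feat <- cbind(ga, gb_)
  z1 <- feat %*% params[["fc1.W"]] + rep(params[["fc1.b"]], each = b)
  a1 <- pmax(z1, 0)
  z2 <- a1 %*% params[["fc2.W"]] + rep(params[["fc2.b"]], each = b)
  probs <- softmax_rows(z2)
  list(probs = probs, state = state,
       cache = if (keep_cache)
         list(a = fa$caches, b = fb$caches, la = dim(fa$out)[2],
              lb = dim(fb$out)[2], feat = feat, a1 = a1, z1 = z1,
              n = n, batch = b))
}

# One training step's loss and gradients. y: integer vector, 1 = ictal.
cnn_loss_grad <- function(model, windows, y, params, state) {
  fw <- cnn_fwd(model, windows, training = TRUE, keep_cache = TRUE,
                params = params, state = state)
  cc <- fw$cache
  b <- cc$batch
  p_ict <- fw$probs[, 2]
  eps <- 1e-12
  loss <- -mean(y * log(p_ict + eps) + (1 - y) * log(1 - p_ict + eps))
  acc <- mean((p_ict >= 0.5) == (y == 1))
  y1h <- cbind(1 - y, y)
  dz2 <- (fw$probs - y1h) / b
  grads <- list()
  grads[["fc2.W"]] <- crossprod(cc$a1, dz2)
  grads[["fc2.b"]] <- colSums(dz2)
  da1 <- dz2 %*% t(params[["fc2.W"]])
  dz1 <- da1 * (cc$z1 > 0)
  grads[["fc1.W"]] <- crossprod(cc$feat, dz1)
  grads[["fc1.b"]] <- colSums(dz1)
  dfeat <- dz1 %*% t(params[["fc1.W"]])
  nf <- model$cfg$conv_filters[3]
  n <- cc$n
  ungap <- function(dg, lf) {
    # (B, C) -> (M, lf, C): each of the N rows and lf time points shares the
    # mean's gradient
    dym <- dg[rep(seq_len(b), each = n), , drop = FALSE] / n
    dx <- array(0, c(n * b, lf, ncol(dg)))
    for (l in seq_len(lf)) dx[, l, ] <- dym / lf
    dx
  }
  ga <- branch_bwd(ungap(dfeat[, seq_len(nf), drop = FALSE], cc$la),
                   cc$a, params, "a", model$cfg)
  gb_ <- branch_bwd(ungap(dfeat[, nf + seq_len(nf), drop = FALSE], cc$lb),
                    cc$b, params, "b", model$cfg)
  list(loss = loss, acc = acc, grads = c(grads, ga, gb_), state = fw$state)
}

#' Ictal probabilities for a batch of windows
#'
#' Inference always uses the stored batch-normalization running statistics,
#' so each window's probability is independent of batch composition. Class
#' rule: a window is called ictal iff its probability is >= 0.5.
#'
#' @param model a (trained) `seizure_cnn`.
#' @param windows N x W matrix for one window, or N x W x B array.
#' @param chunk maximum windows evaluated per internal batch.
#' @return numeric vector of ictal probabilities in \[0, 1\].
#' @export
predict_proba <- function(model, windows, chunk = 512L) {
  stopifnot(inherits(model, "seizure_cnn"))
  if (length(dim(windows)) == 2) dim(windows) <- c(dim(windows), 1L)
  nb <- dim(windows)[3]
  out <- numeric(nb)
  for (s in seq.int(1L, nb, by = chunk)) {
    e <- min(s + chunk - 1L, nb)
    fw <- cnn_fwd(model, windows[, , s:e, drop = FALSE], training = FALSE)
    out[s:e] <- fw$probs[, 2]
  }
  out
}

#' Temporal shape trace of the convolutional stack
#'
#' Runs a forward pass on a zero window and reports each branch layer's
#' post-convolution and post-pooling temporal lengths, as realized by the
#' actual layer implementations.
#'
#' @param model a `seizure_cnn`.
#' @return data frame with columns branch, layer, conv_len, pool_len.
#' @export
model_shape <- function(model) {
  xin <- array(0, c(model$n_channels, model$input_samples, 1L))
  cfg <- model$cfg
  rows <- list()
  for (br in c("a", "b")) {
    cur <- xin
    for (l in 1:3) {
      nm <- paste0(br, l)
      cv <- conv_fwd(cur, model$params[[paste0(nm, ".W")]],
                     model$params[[paste0(nm, ".b")]], cfg$strides[l])
      pool <- pool_fwd(cv$out, cfg$pool_size)
      rows[[length(rows) + 1L]] <-
        data.frame(branch = br, layer = l,
                   conv_len = dim(cv$out)[2], pool_len = dim(pool$out)[2])
      cur <- pool$out
    }
  }
  do.call(rbind, rows)
}
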