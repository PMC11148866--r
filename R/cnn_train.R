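# Training loop: balanced batches, RMSprop, early stopping on validation
# loss with best-weight restoration.

#' Early-stopping monitor
#'
#' Returns a closure that consumes one validation loss per epoch and reports
#' whether the epoch improved on the best loss so far and whether training
#' should stop (no improvement for `patience` consecutive epochs). With a
#' validation loss that worsens from the first epoch onward, training runs
#' exactly `1 + patience` epochs.
#'
#' @param patience epochs without improvement tolerated before stopping.
#' @return function(loss) -> list(improved, stop, best, best_epoch, epoch).
#' @export
make_early_stopper <- function(patience = 15L) {
  stopifnot(patience >= 1)
  best <- Inf
  best_epoch <- 0L
  wait <- 0L
  epoch <- 0L
  function(loss) {
    epoch <<- epoch + 1L
    improved <- loss < best
    if (improved) {
      best <<- loss
      best_epoch <<- epoch
      wait <<- 0L
    } else {
      wait <<- wait + 1L
    }
    list(improved = improved, stop = wait >= patience,
         best = best, best_epoch = best_epoch, epoch = epoch)
  }
}

eval_loss_acc <- function(model, segs, params, state, chunk = 512L) {
  n <- n_segments(segs)
  y <- as.integer(segs$segments$label == "ictal")
  p <- numeric(n)
  for (s in seq.int(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    win <- segment_windows(segs, s:e)
    fw <- cnn_fwd(model, win, training = FALSE, params = params, state = state)
    p[s:e] <- fw$probs[, 2]
  }
  eps <- 1e-12
  list(loss = -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps)),
       acc = mean((p >= 0.5) == (y == 1L)))
}

#' Train the classifier
#'
#' Balanced batches (equal ictal/interictal counts per batch) are drawn from
#' the training set each epoch; parameters are updated by RMSprop minimizing
#' binary cross-entropy. After each epoch the full validation set is scored;
#' training stops when validation loss has not improved for `patience` epochs
#' or at `max_epochs`, and the parameters of the best-validation epoch are
#' restored. Deterministic under the configuration seed.
#'
#' @param model an untrained `seizure_cnn` from [build_model()].
#' @param train,val `segment_set`s containing both classes.
#' @param verbose print one line per epoch.
#' @return the trained `seizure_cnn`, with a `history` data frame (epoch,
#'   train_loss, train_acc, val_loss, val_acc).
#' @export
train_model <- function(model, train, val, verbose = FALSE) {
  stopifnot(inherits(model, "seizure_cnn"),
            inherits(train, "segment_set"), inherits(val, "segment_set"))
  for (part in list(train = train, val = val)) {
    lab <- part$segments$label
    if (!all(c("ictal", "interictal") %in% lab))
      stop_monoseize("both classes must be present in train and val sets",
                     class = "monoseize_train_error")
  }
  cfg <- model$cfg
  params <- model$params
  state <- model$state
  vel <- lapply(params, function(p) array(0, dim(p) %||% length(p)))
  stopper <- make_early_stopper(cfg$patience)
  best_params <- params
  best_state <- state
  history <- NULL
  labels <- train$segments$label
  with_seed(cfg$seed + 1L, {
    ict_pool <- make_pool(which(labels == "ictal"))
    int_pool <- make_pool(which(labels == "interictal"))
    for (ep in seq_len(cfg$max_epochs)) {
      batches <- balanced_epoch_indices(labels, cfg$batch_size,
                                        cfg$epoch_batches, ict_pool, int_pool)
      tl <- ta <- 0
      for (bi in batches) {
        win <- segment_windows(train, bi)
        y <- as.integer(train$segments$label[bi] == "ictal")
        lg <- cnn_loss_grad(model, win, y, params, state)
        if (!is.finite(lg$loss))
          stop_monoseize("non-finite training loss at epoch %d", ep,
                         class = "monoseize_train_error")
        state <- lg$state
        for (nm in names(lg$grads)) {
          g <- lg$grads[[nm]]
          vel[[nm]] <- cfg$rho * vel[[nm]] + (1 - cfg$rho) * g * g
          params[[nm]] <- params[[nm]] -
            cfg$learning_rate * g / (sqrt(vel[[nm]]) + cfg$epsilon)
        }
        tl <- tl + lg$loss
        ta <- ta + lg$acc
      }
      vm <- eval_loss_acc(model, val, params, state)
      history <- rbind(history, data.frame(
        epoch = ep,
        train_loss = tl / length(batches), train_acc = ta / length(batches),
        val_loss = vm$loss, val_acc = vm$acc))
      st <- stopper(vm$loss)
      if (st$improved) {
        best_params <- params
        best_state <- state
      }
      if (verbose)
        message(sprintf(
          "epoch %3d  train loss %.4f acc %.3f | val loss %.4f acc %.3f%s",
          ep, tl / length(batches), ta / length(batches), vm$loss, vm$acc,
          if (st$improved) " *" else ""))
      if (st$stop) break
    }
  })
  model$params <- best_params
  model$state <- best_state
  model$history <- history
  model$trained <- TRUE
  model
}

#' Export a training history as CSV
#' @param model a trained `seizure_cnn`.
#' @param path output CSV path.
#' @export
write_history <- function(model, path) {
  if (is.null(model$history)) stop_monoseize("model has no training history")
  utils::write.csv(model$history, path, row.names = FALSE)
  invisible(path)
}
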