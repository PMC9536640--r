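# ---------------------------------------------------------------------------
# Training recipe: hyperparameters, Xavier initialization, momentum SGD with
# step decay, cross-entropy loss, evaluation and checkpoints.
# ---------------------------------------------------------------------------

#' Training hyperparameters
#'
#' Defaults follow the study recipe: 13 classes, batches of 32, 50 epochs,
#' momentum SGD (momentum 0.9), initial learning rate 0.001 decayed by a
#' factor of 0.1 every 10 epochs, cross-entropy loss, Xavier initialization
#' with zero biases, inputs resized to 224 x 224. Every field can be
#' overridden by name (or from a YAML file via [read_train_hyper()]).
#'
#' @param classes Number of identities.
#' @param batch_size Minibatch size.
#' @param epochs Training epochs.
#' @param momentum SGD momentum coefficient.
#' @param lr Initial learning rate.
#' @param lr_decay Multiplicative decay factor.
#' @param lr_step Epochs between decays.
#' @param input_side Input image side after resizing.
#' @return A `train_hyper` list.
#' @export
train_hyper <- function(classes = 13, batch_size = 32, epochs = 50,
                        momentum = 0.9, lr = 0.001, lr_decay = 0.1,
                        lr_step = 10, input_side = 224) {
  structure(list(classes = chk_posint(classes, "classes"),
                 batch_size = chk_posint(batch_size, "batch_size"),
                 epochs = as.integer(epochs),
                 momentum = momentum, lr = lr, lr_decay = lr_decay,
                 lr_step = chk_posint(lr_step, "lr_step"),
                 input_side = chk_posint(input_side, "input_side")),
            class = "train_hyper")
}

#' Desk-scale training preset
#'
#' The short-schedule companion of [desk_model_config()]: 10 epochs at
#' 48-pixel inputs with the initial learning rate raised to 0.01. A 5x
#' shorter schedule than the full recipe warrants a proportionally larger
#' rate; momentum, batch size, loss, initialization and the step-decay rule
#' are unchanged. Used for the synthetic-herd sanity runs.
#'
#' @param classes Number of identities.
#' @param epochs Training epochs.
#' @return A `train_hyper`.
#' @export
desk_train_hyper <- function(classes = 13, epochs = 10) {
  train_hyper(classes = classes, epochs = epochs, lr = 0.01, input_side = 48)
}

#' @rdname train_hyper
#' @param path YAML file whose keys override [train_hyper()] defaults.
#' @export
read_train_hyper <- function(path) {
  doc <- yaml::read_yaml(path)
  doc <- doc[intersect(names(doc), names(formals(train_hyper)))]
  do.call(train_hyper, doc)
}

#' Learning rate at a given epoch
#'
#' Step schedule: `lr * lr_decay ^ floor(epoch / lr_step)`.
#'
#' @param hyper A [train_hyper()].
#' @param epoch Zero-based epoch index.
#' @return The learning rate in effect during that epoch.
#' @export
lr_at_epoch <- function(hyper, epoch) {
  if (any(epoch < 0)) stop("epoch must be non-negative")
  hyper$lr * hyper$lr_decay^(floor(epoch / hyper$lr_step))
}

#' Xavier-initialize a model in place
#'
#' Convolution and dense weights are drawn from the Xavier-uniform range
#' `+/- sqrt(6 / (fan_in + fan_out))`; all biases and normalization shifts
#' are set to exactly 0, normalization scales to 1, running moments reset.
#' Bit-reproducible for a fixed seed.
#'
#' @param model A network module (modified in place).
#' @param seed Integer seed.
#' @return The model, invisibly.
#' @export
initialize_weights <- function(model, seed = 1) {
  refs <- nn_parameters(model)
  with_seed(seed, {
    for (nm in names(refs)) {
      r <- refs[[nm]]
      w <- r$env[[r$field]]
      if (r$field %in% c("bias", "beta")) {
        r$env[[r$field]] <- w * 0
      } else if (r$field == "gamma") {
        r$env[[r$field]] <- rep(1, length(w))
      } else {
        d <- dim(w)
        fans <- if (length(d) == 4) {
          c(d[1] * d[2] * d[3], d[1] * d[2] * d[4])   # conv (k,k,cin/g,cout)
        } else {
          c(d[2], d[1])                               # dense (out,in)
        }
        a <- sqrt(6 / sum(fans))
        r$env[[r$field]] <- array(stats::runif(length(w), -a, a), dim = d)
      }
    }
  })
  reset_running_stats(model)
  invisible(model)
}

reset_running_stats <- function(m) {
  if (inherits(m, "nn_batchnorm2d")) {
    m$running_mean <- rep(0, m$channels)
    m$running_var <- rep(1, m$channels)
  }
  for (k in m$children) reset_running_stats(k)
  invisible(m)
}

# column-wise softmax cross-entropy; y is an integer vector in 1..K
softmax_xent <- function(logits, y) {
  p <- softmax_cols(logits)
  n <- ncol(logits)
  ll <- p[cbind(y, seq_len(n))]
  g <- p
  g[cbind(y, seq_len(n))] <- g[cbind(y, seq_len(n))] - 1
  list(loss = -mean(log(pmax(ll, 1e-12))), grad = g / n)
}

# momentum SGD step over every parameter; `state` holds velocity buffers
sgd_step <- function(refs, state, lr, momentum) {
  for (nm in names(refs)) {
    r <- refs[[nm]]
    g <- r$env[[paste0("g_", r$field)]]
    if (is.null(g)) next
    v <- state[[nm]]
    v <- if (is.null(v)) g else momentum * v + g
    state[[nm]] <- v
    r$env[[r$field]] <- r$env[[r$field]] - lr * v
  }
  state
}

#' Train a model on in-memory arrays
#'
#' Runs the full recipe: Xavier initialization, shuffled minibatches,
#' cross-entropy loss, momentum SGD with the step-decay schedule, per-epoch
#' validation, and best-validation checkpoint selection (ties go to the
#' earlier epoch). All randomness (initialization, shuffles) is driven by
#' `seed`.
#'
#' @param model A built network whose head matches `hyper$classes`.
#' @param train List with `x` (array `(H, W, 3, N)`) and `y` (integer labels
#'   in `1..classes`).
#' @param val Like `train`, or `NULL` to skip validation.
#' @param hyper A [train_hyper()].
#' @param seed Integer seed.
#' @param init Re-initialize weights before training.
#' @param verbose Print one line per epoch.
#' @return A list: `history` (data.frame epoch, lr, train_loss, train_acc,
#'   val_acc, seconds), `best` (list params, epoch, val_acc), `model`.
#' @export
fit_model <- function(model, train, val = NULL, hyper = train_hyper(),
                      seed = 1, init = TRUE, verbose = FALSE) {
  n <- length(train$y)
  if (n == 0) stop("empty training set")
  if (any(train$y < 1 | train$y > hyper$classes))
    stop("class label outside [1, classes]")
  if (isTRUE(init)) initialize_weights(model, seed = seed)
  refs <- nn_parameters(model)
  state <- list()
  hist <- data.frame(epoch = integer(), lr = numeric(),
                     train_loss = numeric(), train_acc = numeric(),
                     val_acc = numeric(), seconds = numeric())
  best <- list(params = snapshot_params(model), epoch = -1L, val_acc = -Inf)
  if (hyper$epochs > 0) with_seed(seed + 1L, {
    for (ep in seq_len(hyper$epochs) - 1L) {
      t0 <- proc.time()[3]
      lr <- lr_at_epoch(hyper, ep)
      ord <- sample(n)
      tot_loss <- 0; tot_correct <- 0
      for (b0 in seq(1, n, by = hyper$batch_size)) {
        idx <- ord[b0:min(b0 + hyper$batch_size - 1, n)]
        xb <- train$x[, , , idx, drop = FALSE]
        yb <- train$y[idx]
        nn_zero_grad(model)
        logits <- nn_forward(model, xb, training = TRUE)
        l <- softmax_xent(logits, yb)
        nn_backward(model, l$grad)
        state <- sgd_step(refs, state, lr, hyper$momentum)
        tot_loss <- tot_loss + l$loss * length(idx)
        tot_correct <- tot_correct + sum(max.col(t(logits)) == yb)
      }
      va <- if (!is.null(val)) evaluate_arrays(model, val,
                                               hyper$batch_size)$accuracy
            else NA_real_
      hist <- rbind(hist, data.frame(
        epoch = ep, lr = lr, train_loss = tot_loss / n,
        train_acc = tot_correct / n, val_acc = va,
        seconds = proc.time()[3] - t0))
      if (!is.null(val) && va > best$val_acc + 1e-12) {
        best <- list(params = snapshot_params(model), epoch = ep, val_acc = va)
      }
      if (verbose)
        message(sprintf(
          "epoch %2d lr %.1e loss %.4f train_acc %.3f val_acc %s (%.1fs)",
          ep, lr, tot_loss / n, tot_correct / n,
          ifelse(is.na(va), "-", sprintf("%.3f", va)),
          proc.time()[3] - t0))
    }
  })
  if (is.null(val) || best$epoch < 0)
    best <- list(params = snapshot_params(model),
                 epoch = if (hyper$epochs > 0) hyper$epochs - 1L else -1L,
                 val_acc = NA_real_)
  rownames(hist) <- NULL
  list(history = hist, best = best, model = model)
}

snapshot_params <- function(model) {
  refs <- nn_parameters(model)
  out <- lapply(refs, function(r) r$env[[r$field]])
  # carry batch-norm running moments so a restored model evaluates identically
  attr(out, "running") <- collect_running(model)
  out
}

collect_running <- function(m, prefix = "") {
  out <- list()
  if (inherits(m, "nn_batchnorm2d"))
    out[[prefix]] <- list(mean = m$running_mean, var = m$running_var)
  for (nm in names(m$children))
    out <- c(out, collect_running(m$children[[nm]],
                                  if (nzchar(prefix)) paste0(prefix, ".", nm) else nm))
  out
}

#' Restore a parameter snapshot into a model
#'
#' @param model Target network (architecture must match the snapshot).
#' @param params A snapshot from `fit_model()$best$params` or a checkpoint.
#' @return The model, invisibly.
#' @export
restore_params <- function(model, params) {
  refs <- nn_parameters(model)
  if (!setequal(names(refs), names(params)))
    stop("checkpoint does not match the model architecture")
  for (nm in names(refs)) {
    r <- refs[[nm]]
    r$env[[r$field]] <- params[[nm]]
  }
  run <- attr(params, "running")
  if (!is.null(run)) restore_running(model, run, "")
  invisible(model)
}

restore_running <- function(m, run, prefix) {
  if (inherits(m, "nn_batchnorm2d") && prefix %in% names(run)) {
    m$running_mean <- run[[prefix]]$mean
    m$running_var <- run[[prefix]]$var
  }
  for (nm in names(m$children))
    restore_running(m$children[[nm]], run,
                    if (nzchar(prefix)) paste0(prefix, ".", nm) else nm)
  invisible(m)
}

evaluate_arrays <- function(model, set, batch_size = 32) {
  n <- length(set$y)
  if (n == 0) stop("empty evaluation set")
  K <- nrow(nn_forward(model, set$x[, , , 1, drop = FALSE]))
  pred <- integer(n)
  for (b0 in seq(1, n, by = batch_size)) {
    idx <- b0:min(b0 + batch_size - 1, n)
    logits <- nn_forward(model, set$x[, , , idx, drop = FALSE])
    pred[idx] <- max.col(t(logits))
  }
  cm <- table(factor(set$y, levels = seq_len(K)),
              factor(pred, levels = seq_len(K)), dnn = c("truth", "pred"))
  list(accuracy = sum(pred == set$y) / n, confusion = cm, predictions = pred)
}

#' Evaluate a trained model or checkpoint
#'
#' @param object A network module, or a checkpoint list from
#'   [make_checkpoint()] / [load_checkpoint()].
#' @param set List with `x` (image array) and `y` (integer labels).
#' @param batch_size Evaluation batch size.
#' @return List: top-1 `accuracy` in `[0, 1]`, `confusion` table whose row
#'   sums equal the per-class item counts, and `predictions`.
#' @export
evaluate <- function(object, set, batch_size = 32) {
  model <- if (inherits(object, "nn_module")) object else {
    m <- assemble_model(object$config)
    restore_params(m, object$params)
    m
  }
  K <- model$config$num_classes
  if (any(set$y < 1 | set$y > K))
    stop("label outside the checkpoint's class range")
  evaluate_arrays(model, set, batch_size)
}

#' Create / save / load a checkpoint
#'
#' A checkpoint bundles the weights with the configuration used to build
#' them; restoring into a mismatched architecture is an error.
#'
#' @param model A trained network built from a `gh_model_config`.
#' @param params Optional parameter snapshot (defaults to current weights).
#' @param classes Optional character vector of class labels.
#' @return A `gh_checkpoint` list.
#' @export
make_checkpoint <- function(model, params = NULL, classes = NULL) {
  stopifnot(inherits(model, "gh_model"))
  structure(list(config = model$config,
                 params = if (is.null(params)) snapshot_params(model) else params,
                 classes = classes),
            class = "gh_checkpoint")
}

#' @rdname make_checkpoint
#' @param checkpoint A `gh_checkpoint`.
#' @param path File path (RDS).
#' @export
save_checkpoint <- function(checkpoint, path) {
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname make_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!inherits(ck, "gh_checkpoint")) stop("not a ghostherd checkpoint")
  ck
}
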