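#' Training configuration
#'
#' Defaults: initial learning rate 1e-4,
#' gradually reduced (cosine), batch size 256, Ranger-style optimizer
#' (RAdam + Lookahead), 10% factor dropout and 10% additive data shift on
#' the standardized scale, class-weighted cross-entropy.
#'
#' @param lr initial learning rate (> 0).
#' @param batch_size minibatch size.
#' @param epochs maximum number of epochs.
#' @param factor_dropout probability of zeroing each entry during
#'   augmentation (in [0, 1)).
#' @param shift_magnitude half-width of the additive uniform perturbation
#'   applied to surviving entries, on the standardized scale (in [0, 1)).
#' @param optimizer `"ranger"` (RAdam + Lookahead) or `"adam"`.
#' @param lr_schedule `"cosine"` or `"none"`.
#' @param seed integer seed for shuffling and augmentation.
#' @param early_stop_patience epochs without validation-loss improvement
#'   before stopping.
#' @param weighted use inverse-frequency class weights (default TRUE).
#' @return An object of class `train_config`.
#' @export
train_config <- function(lr = 1e-4, batch_size = 256L, epochs = 100L,
                         factor_dropout = 0.10, shift_magnitude = 0.10,
                         optimizer = c("ranger", "adam"),
                         lr_schedule = c("cosine", "none"),
                         seed = 0L, early_stop_patience = 10L,
                         weighted = TRUE) {
  stopifnot(lr > 0, factor_dropout >= 0, factor_dropout < 1 || factor_dropout == 1,
            shift_magnitude >= 0, shift_magnitude < 1)
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 factor_dropout = factor_dropout,
                 shift_magnitude = shift_magnitude,
                 optimizer = match.arg(optimizer),
                 lr_schedule = match.arg(lr_schedule),
                 seed = as.integer(seed),
                 early_stop_patience = as.integer(early_stop_patience),
                 weighted = isTRUE(weighted)),
            class = "train_config")
}

#' Inverse-frequency class weights
#'
#' `w_c = n_total / (2 * n_c)`: mean-one when the classes are balanced, and
#' up-weighting the minority class otherwise. Used by the weighted
#' cross-entropy loss to counter the ~59/41 label imbalance.
#'
#' @param labels integer 0/1 vector with both classes present.
#' @return An object of class `class_weights` with elements `w0`, `w1`.
#' @export
class_weights <- function(labels) {
  labels <- as.integer(labels)
  n0 <- sum(labels == 0L); n1 <- sum(labels == 1L)
  if (n0 == 0L || n1 == 0L) {
    stop("class_weights: both classes must be present")
  }
  n <- n0 + n1
  structure(list(w0 = n / (2 * n0), w1 = n / (2 * n1)), class = "class_weights")
}

#' Class-weighted cross-entropy loss
#'
#' Mean over samples of `w_{y_i} * (-log softmax(logits_i)[y_i])`. With
#' unit weights this reduces to the ordinary cross-entropy.
#'
#' @param logits n x 2 matrix of class logits.
#' @param labels integer 0/1 vector of length n.
#' @param weights a [class_weights()] object (default unit weights).
#' @param gradient if `TRUE`, also return `dlogits`.
#' @return The scalar loss, or (with `gradient = TRUE`) a list
#'   `list(loss, dlogits)`.
#' @export
weighted_cross_entropy <- function(logits, labels,
                                   weights = structure(list(w0 = 1, w1 = 1),
                                                       class = "class_weights"),
                                   gradient = FALSE) {
  logits <- if (is.null(dim(logits))) matrix(logits, nrow = 1L) else as.matrix(logits)
  labels <- as.integer(labels)
  stopifnot(nrow(logits) == length(labels), ncol(logits) == 2L)
  if (any(!is.finite(logits))) stop("weighted_cross_entropy: non-finite logits")
  n <- nrow(logits)
  p <- softmax_rows(logits)
  w <- ifelse(labels == 1L, weights$w1, weights$w0)
  picked <- p[cbind(seq_len(n), labels + 1L)]
  loss <- mean(w * (-log(pmax(picked, 1e-300))))
  if (!gradient) return(loss)
  onehot <- matrix(0, n, 2L)
  onehot[cbind(seq_len(n), labels + 1L)] <- 1
  dlogits <- (p - onehot) * (w / n)
  list(loss = loss, dlogits = dlogits)
}

#' Factor-dropout and data-shift augmentation
#'
#' Each entry of the (standardized) batch is independently zeroed with
#' probability `factor_dropout`; surviving entries receive additive
#' uniform noise in `[-shift_magnitude, +shift_magnitude]`. Draws come
#' from R's RNG stream, so seeding before the call makes the augmentation
#' reproducible.
#'
#' @param batch numeric matrix of standardized rows.
#' @param config a [train_config()].
#' @param mode must be `"train"`; augmenting evaluation data is a contract
#'   error.
#' @return The augmented batch.
#' @export
augment_batch <- function(batch, config, mode = "train") {
  if (!identical(mode, "train")) {
    stop("contract error: augment_batch must only be used in training mode")
  }
  batch <- as.matrix(batch)
  m <- length(batch)
  keep <- matrix(rbinom(m, 1L, 1 - config$factor_dropout), nrow(batch))
  noise <- if (config$shift_magnitude > 0) {
    matrix(runif(m, -config$shift_magnitude, config$shift_magnitude), nrow(batch))
  } else 0
  (batch + noise) * keep
}

# --- RAdam + Lookahead ("Ranger") -----------------------------------------
# RAdam rectifies the adaptive-term variance in early steps; Lookahead
# keeps a slow copy of the weights and interpolates every k fast steps.

optimizer_new <- function(params, kind, beta1 = 0.9, beta2 = 0.999,
                          eps = 1e-8, la_k = 6L, la_alpha = 0.5) {
  st <- new.env(parent = emptyenv())
  st$kind <- kind
  st$t <- 0L
  st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st$m <- lapply(params, function(p) p * 0)
  st$v <- lapply(params, function(p) p * 0)
  st$la_k <- la_k; st$la_alpha <- la_alpha
  st$slow <- if (kind == "ranger") params else NULL
  st
}

optimizer_step <- function(st, params, grads, lr) {
  st$t <- st$t + 1L
  t <- st$t; b1 <- st$beta1; b2 <- st$beta2
  rho_inf <- 2 / (1 - b2) - 1
  rho_t <- rho_inf - 2 * t * b2^t / (1 - b2^t)
  for (nm in names(params)) {
    g <- grads[[nm]]
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g^2
    mhat <- st$m[[nm]] / (1 - b1^t)
    if (st$kind == "adam") {
      vhat <- sqrt(st$v[[nm]] / (1 - b2^t))
      params[[nm]] <- params[[nm]] - lr * mhat / (vhat + st$eps)
    } else {
      if (rho_t > 4) {
        r <- sqrt(((rho_t - 4) * (rho_t - 2) * rho_inf) /
                    ((rho_inf - 4) * (rho_inf - 2) * rho_t))
        vhat <- sqrt(st$v[[nm]] / (1 - b2^t))
        params[[nm]] <- params[[nm]] - lr * r * mhat / (vhat + st$eps)
      } else {
        params[[nm]] <- params[[nm]] - lr * mhat
      }
    }
  }
  if (st$kind == "ranger" && st$t %% st$la_k == 0L) {
    for (nm in names(params)) {
      st$slow[[nm]] <- st$slow[[nm]] + st$la_alpha * (params[[nm]] - st$slow[[nm]])
      params[[nm]] <- st$slow[[nm]]
    }
  }
  params
}

cosine_lr <- function(lr0, epoch, epochs) {
  lr0 * 0.5 * (1 + cos(pi * (epoch - 1) / max(1L, epochs - 1L)))
}

#' Train a network with weighted cross-entropy
#'
#' Minibatch optimization on the standardized training partition with the
#' configured optimizer and learning-rate schedule, factor-dropout /
#' data-shift augmentation, and early stopping on validation loss. The
#' weights of the best-validation-loss epoch are returned. Fully
#' reproducible under the configuration seed.
#'
#' @param dataset a standardized `encoded_dataset` with labels.
#' @param split a `split_result` over the dataset.
#' @param model_cfg a [glnet_config()]; defaults to one matching the
#'   dataset width with the training seed.
#' @param train_cfg a [train_config()].
#' @param verbose print per-epoch progress.
#' @return A list of class `glnet_fit`: `model`, `history` (data.frame with
#'   per-epoch train loss, validation loss and accuracy, learning rate),
#'   `best_epoch`, `class_weights`.
#' @export
train_model <- function(dataset, split, model_cfg = NULL,
                        train_cfg = train_config(), verbose = FALSE) {
  if (!isTRUE(dataset$standardized)) {
    warning("train_model: dataset is not standardized; training quality will suffer")
  }
  if (length(split$validation) == 0L) {
    stop("config error: validation set is empty")
  }
  if (is.null(model_cfg)) {
    model_cfg <- glnet_config(input_dim = ncol(dataset$x), seed = train_cfg$seed)
  }
  model <- init_model(model_cfg)
  xtr <- dataset$x[split$train, , drop = FALSE]
  ytr <- dataset$y[split$train]
  xval <- dataset$x[split$validation, , drop = FALSE]
  yval <- dataset$y[split$validation]
  w <- if (train_cfg$weighted) class_weights(ytr) else
    structure(list(w0 = 1, w1 = 1), class = "class_weights")

  opt <- optimizer_new(model$params, train_cfg$optimizer)
  best <- list(val_loss = Inf, params = model$params, running = model$running,
               epoch = 0L)
  hist <- list()
  patience_left <- train_cfg$early_stop_patience
  set.seed(derive_seed(train_cfg$seed, "optimize"))
  n <- nrow(xtr)
  for (epoch in seq_len(train_cfg$epochs)) {
    lr <- if (train_cfg$lr_schedule == "cosine") {
      cosine_lr(train_cfg$lr, epoch, train_cfg$epochs)
    } else train_cfg$lr
    ord <- sample.int(n)
    batch_losses <- c()
    for (start in seq(1L, n, by = train_cfg$batch_size)) {
      ix <- ord[start:min(start + train_cfg$batch_size - 1L, n)]
      if (length(ix) < 2L) next   # batch moments need >= 2 rows
      xb <- xtr[ix, , drop = FALSE]
      if (train_cfg$factor_dropout > 0 || train_cfg$shift_magnitude > 0) {
        xb <- augment_batch(xb, train_cfg)
      }
      fw <- glnet_forward_internal(model, xb, mode = "train", want_cache = TRUE)
      model$running <- fw$running
      lg <- weighted_cross_entropy(fw$logits, ytr[ix], w, gradient = TRUE)
      grads <- glnet_backward(model, fw$cache, lg$dlogits)
      model$params <- optimizer_step(opt, model$params, grads, lr)
      batch_losses <- c(batch_losses, lg$loss)
    }
    vlog <- glnet_forward_internal(model, xval, mode = "eval")$logits
    val_loss <- weighted_cross_entropy(vlog, yval, w)
    val_acc <- mean((softmax_rows(vlog)[, 2L] >= 0.5) == (yval == 1L))
    hist[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                train_loss = mean(batch_losses),
                                val_loss = val_loss, val_acc = val_acc)
    if (verbose) {
      message(sprintf("epoch %3d  lr %.2e  train %.4f  val %.4f  acc %.3f",
                      epoch, lr, mean(batch_losses), val_loss, val_acc))
    }
    if (val_loss < best$val_loss - 1e-12) {
      best <- list(val_loss = val_loss, params = model$params,
                   running = model$running, epoch = epoch)
      patience_left <- train_cfg$early_stop_patience
    } else {
      patience_left <- patience_left - 1L
      if (patience_left <= 0L) break
    }
  }
  model$params <- best$params
  model$running <- best$running
  structure(list(model = model, history = do.call(rbind, hist),
                 best_epoch = best$epoch, class_weights = w,
                 train_cfg = train_cfg),
            class = "glnet_fit")
}

#' @export
print.glnet_fit <- function(x, ...) {
  cat("<glnet_fit> epochs run:", nrow(x$history),
      "| best epoch:", x$best_epoch,
      "| best val loss:", signif(min(x$history$val_loss), 5), "\n")
  invisible(x)
}
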