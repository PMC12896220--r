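#' Configuration of a global-local state-space network
#'
#' The network maps `input_dim` encoded factors to `embed_dim` deep
#' features, pushes them through four Global-and-Local Blocks (two
#' dimension-doubling, two halving, joined U-style by a residual
#' connection at the doubled width) and a linear two-class head.
#'
#' @param input_dim number of encoded factor columns.
#' @param embed_dim width after the embedding layer; must be divisible by 4
#'   so two doublings followed by two halvings return to `embed_dim`
#'   (default 128).
#' @param ssm_state_dim state dimension N of the selective scan (default 16).
#' @param conv_kernel odd kernel size of the local 1-D convolution
#'   (default 3).
#' @param leaky_slope negative-side slope of the leaky-ReLU (default 0.01).
#' @param head_classes number of output classes (default 2).
#' @param seed integer seed governing weight initialization.
#' @return An object of class `glnet_config`.
#' @export
glnet_config <- function(input_dim, embed_dim = 128L, ssm_state_dim = 16L,
                         conv_kernel = 3L, leaky_slope = 0.01,
                         head_classes = 2L, seed = 0L) {
  input_dim <- as.integer(input_dim)
  embed_dim <- as.integer(embed_dim)
  if (input_dim < 1L) stop("config error: input_dim must be >= 1")
  if (embed_dim %% 4L != 0L) {
    stop("config error: embed_dim must be divisible by 4 (got ", embed_dim, ")")
  }
  if (conv_kernel %% 2L != 1L) {
    stop("config error: conv_kernel must be odd for length-preserving padding")
  }
  structure(list(input_dim = input_dim, embed_dim = embed_dim,
                 ssm_state_dim = as.integer(ssm_state_dim),
                 conv_kernel = as.integer(conv_kernel),
                 leaky_slope = leaky_slope,
                 head_classes = as.integer(head_classes),
                 seed = as.integer(seed)),
            class = "glnet_config")
}

block_dims <- function(config) {
  e <- config$embed_dim
  list(input = c(e, 2L * e, 4L * e, 2L * e),
       output = c(2L * e, 4L * e, 2L * e, e),
       direction = c("up", "up", "down", "down"))
}

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
}

#' Initialize a network from a configuration
#'
#' All weights come from a generator seeded by `config$seed`, so two
#' initializations with the same configuration are bit-identical. The
#' diagonal continuous-time state matrix starts at -(1..N) and the step
#' size at softplus(bias) ~= 0.01, a standard stable scan initialization;
#' the per-channel skip starts at 1 and the convolution near identity so
#' the untrained block approximately passes its input through.
#'
#' @param config a [glnet_config()].
#' @return An object of class `glnet_model` holding a flat named parameter
#'   list, batch-normalization running moments, and the configuration.
#' @export
init_model <- function(config) {
  stopifnot(inherits(config, "glnet_config"))
  dims <- block_dims(config)
  N <- config$ssm_state_dim
  K <- config$conv_kernel
  params <- list()
  running <- list()
  with_seed(derive_seed(config$seed, "init"), {
    params[["embed.W"]] <- glorot(config$input_dim, config$embed_dim)
    params[["embed.b"]] <- numeric(config$embed_dim)
    for (k in 1:4) {
      p <- paste0("glb", k, ".")
      params[[paste0(p, "ssm.A")]] <- -as.numeric(1:N)
      params[[paste0(p, "ssm.wd")]] <- rnorm(1, 0, 0.1)
      params[[paste0(p, "ssm.bd")]] <- log(expm1(0.01))   # softplus^-1(0.01)
      params[[paste0(p, "ssm.wB")]] <- rnorm(N, 0, 1 / sqrt(N))
      params[[paste0(p, "ssm.bB")]] <- rnorm(N, 0, 1 / sqrt(N))
      params[[paste0(p, "ssm.wC")]] <- rnorm(N, 0, 1 / sqrt(N))
      params[[paste0(p, "ssm.bC")]] <- rnorm(N, 0, 1 / sqrt(N))
      params[[paste0(p, "ssm.D")]] <- 1.0
      w <- rnorm(K, 0, 0.1)
      w[(K + 1L) %/% 2L] <- w[(K + 1L) %/% 2L] + 1.0
      params[[paste0(p, "conv.w")]] <- w
      params[[paste0(p, "conv.b")]] <- 0.0
      params[[paste0(p, "fc.W")]] <- glorot(dims$input[k], dims$output[k])
      params[[paste0(p, "fc.b")]] <- numeric(dims$output[k])
      params[[paste0(p, "bn.gamma")]] <- rep(1.0, dims$output[k])
      params[[paste0(p, "bn.beta")]] <- numeric(dims$output[k])
      running[[paste0("glb", k)]] <- list(mean = numeric(dims$output[k]),
                                          var = rep(1.0, dims$output[k]),
                                          momentum = 0.1, eps = 1e-5)
    }
    params[["head.W"]] <- glorot(config$embed_dim, config$head_classes)
    params[["head.b"]] <- numeric(config$head_classes)
  })
  structure(list(config = config, params = params, running = running),
            class = "glnet_model")
}

#' @export
print.glnet_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat("<glnet_model> input_dim", x$config$input_dim, "| embed_dim",
      x$config$embed_dim, "|", np, "parameters\n")
  invisible(x)
}

ssm_par <- function(model, k) {
  p <- paste0("glb", k, ".ssm.")
  list(A = model$params[[paste0(p, "A")]],
       wd = model$params[[paste0(p, "wd")]],
       bd = model$params[[paste0(p, "bd")]],
       wB = model$params[[paste0(p, "wB")]],
       bB = model$params[[paste0(p, "bB")]],
       wC = model$params[[paste0(p, "wC")]],
       bC = model$params[[paste0(p, "bC")]],
       D = model$params[[paste0(p, "D")]])
}

#' Selective state-space scan over feature sequences
#'
#' Runs the zero-order-hold discretized selective scan
#' `h_t = exp(Delta_t A) h_{t-1} + Delta_t B_t x_t`,
#' `y_t = <C_t, h_t> + D x_t` with input-dependent `Delta_t = softplus(wd
#' x_t + bd)`, `B_t = wB x_t + bB`, `C_t = wC x_t + bC` and `h_0 = 0`.
#'
#' @param x a numeric vector (one sequence) or an n x L matrix of row
#'   sequences.
#' @param params a list with elements `A` (length-N, strictly negative),
#'   scalars `wd`, `bd`, `D`, and length-N vectors `wB`, `bB`, `wC`, `bC`.
#' @return Output of the same shape as `x`.
#' @export
ssm_scan <- function(x, params) {
  vec_in <- is.null(dim(x))
  X <- if (vec_in) matrix(x, nrow = 1L) else as.matrix(x)
  if (ncol(X) < 1L) stop("contract error: empty sequence")
  if (any(params$A >= 0)) stop("contract error: A must be strictly negative")
  out <- .ssm_scan_forward_cpp(X, as.numeric(params$A),
                               params$wd, params$bd,
                               as.numeric(params$wB), as.numeric(params$bB),
                               as.numeric(params$wC), as.numeric(params$bC),
                               params$D, FALSE)$Y
  if (vec_in) as.numeric(out) else out
}

conv1d_forward <- function(X, w, b) {
  K <- length(w)
  half <- (K - 1L) %/% 2L
  L <- ncol(X)
  Y <- matrix(b, nrow(X), L)
  for (k in seq_len(K)) {
    off <- k - 1L - half
    src <- seq_len(L) + off
    ok <- src >= 1L & src <= L
    Y[, ok] <- Y[, ok] + w[k] * X[, src[ok], drop = FALSE]
  }
  Y
}

conv1d_backward <- function(X, w, dY) {
  K <- length(w)
  half <- (K - 1L) %/% 2L
  L <- ncol(X)
  dX <- matrix(0, nrow(X), L)
  dw <- numeric(K)
  for (k in seq_len(K)) {
    off <- k - 1L - half
    src <- seq_len(L) + off
    ok <- src >= 1L & src <= L
    dX[, src[ok]] <- dX[, src[ok]] + w[k] * dY[, ok, drop = FALSE]
    dw[k] <- sum(dY[, ok, drop = FALSE] * X[, src[ok], drop = FALSE])
  }
  list(dX = dX, dw = dw, db = sum(dY))
}

# Forward through one Global-and-Local Block. `mode` controls batch
# normalization: "train" uses batch moments (and returns updated running
# moments), "eval" uses the frozen running moments so per-sample outputs
# are batch-size invariant.
glb_forward_internal <- function(model, k, Z, mode, want_cache = FALSE) {
  pfx <- paste0("glb", k, ".")
  sp <- ssm_par(model, k)
  scan <- .ssm_scan_forward_cpp(Z, as.numeric(sp$A), sp$wd, sp$bd,
                                as.numeric(sp$wB), as.numeric(sp$bB),
                                as.numeric(sp$wC), as.numeric(sp$bC),
                                sp$D, want_cache)
  S <- scan$Y
  Cv <- conv1d_forward(S, model$params[[paste0(pfx, "conv.w")]],
                       model$params[[paste0(pfx, "conv.b")]])
  slope <- model$config$leaky_slope
  Aout <- ifelse(Cv > 0, Cv, slope * Cv)
  Fm <- Aout %*% model$params[[paste0(pfx, "fc.W")]]
  Fm <- sweep(Fm, 2L, model$params[[paste0(pfx, "fc.b")]], "+")
  run <- model$running[[paste0("glb", k)]]
  if (mode == "train") {
    n <- nrow(Fm)
    mu <- colMeans(Fm)
    v <- colMeans(Fm^2) - mu^2
    v[v < 0] <- 0
    xhat <- sweep(sweep(Fm, 2L, mu, "-"), 2L, sqrt(v + run$eps), "/")
    unb <- if (n > 1L) v * n / (n - 1L) else v
    new_run <- run
    new_run$mean <- (1 - run$momentum) * run$mean + run$momentum * mu
    new_run$var <- (1 - run$momentum) * run$var + run$momentum * unb
  } else {
    mu <- run$mean; v <- run$var
    xhat <- sweep(sweep(Fm, 2L, mu, "-"), 2L, sqrt(v + run$eps), "/")
    new_run <- run
  }
  out <- sweep(sweep(xhat, 2L, model$params[[paste0(pfx, "bn.gamma")]], "*"),
               2L, model$params[[paste0(pfx, "bn.beta")]], "+")
  res <- list(out = out, running = new_run)
  if (want_cache) {
    res$cache <- list(Z = Z, H = scan$H, Delta = scan$Delta, S = S, Cv = Cv,
                      Aout = Aout, xhat = xhat, mu = mu, v = v, mode = mode)
  }
  res
}

#' Forward pass of one Global-and-Local Block
#'
#' Lays the feature vector out as a sequence of scalar channels and applies
#' selective scan -> same-padded 1-D convolution -> leaky-ReLU -> linear
#' expand/compress -> batch normalization.
#'
#' @param features numeric vector (one sample) or matrix of row samples,
#'   width matching the block's input dimension.
#' @param model a `glnet_model`.
#' @param k block index 1-4 (blocks 1-2 double the width, 3-4 halve it).
#' @param mode `"eval"` (running-moment normalization; batch-size
#'   invariant) or `"train"` (batch-moment normalization).
#' @return Matrix (or vector) of block outputs.
#' @export
glb_forward <- function(features, model, k, mode = "eval") {
  vec_in <- is.null(dim(features))
  Z <- if (vec_in) matrix(features, nrow = 1L) else as.matrix(features)
  dims <- block_dims(model$config)
  if (ncol(Z) != dims$input[k]) {
    stop("contract error: block ", k, " expects width ", dims$input[k],
         ", got ", ncol(Z))
  }
  out <- glb_forward_internal(model, k, Z, mode)$out
  if (vec_in) as.numeric(out) else out
}

# Full forward; optionally keeps every intermediate needed by the backward
# pass and the updated running moments.
glnet_forward_internal <- function(model, X, mode, want_cache = FALSE) {
  X1 <- sweep(X %*% model$params[["embed.W"]], 2L, model$params[["embed.b"]], "+")
  b1 <- glb_forward_internal(model, 1L, X1, mode, want_cache)
  b2 <- glb_forward_internal(model, 2L, b1$out, mode, want_cache)
  b3 <- glb_forward_internal(model, 3L, b2$out, mode, want_cache)
  in4 <- b3$out + b1$out                       # U-shaped residual at width 2E
  b4 <- glb_forward_internal(model, 4L, in4, mode, want_cache)
  logits <- sweep(b4$out %*% model$params[["head.W"]], 2L,
                  model$params[["head.b"]], "+")
  out <- list(logits = logits,
              running = list(glb1 = b1$running, glb2 = b2$running,
                             glb3 = b3$running, glb4 = b4$running))
  if (want_cache) {
    out$cache <- list(X = X, X1 = X1, blocks = list(b1$cache, b2$cache,
                                                    b3$cache, b4$cache),
                      g4 = b4$out)
  }
  out
}

#' Forward pass of the full network
#'
#' Embedding -> two expanding blocks -> two compressing blocks with the
#' width-2E residual connection -> linear head. In `"eval"` mode the
#' forward is a deterministic pure function of (weights, input).
#'
#' @param x numeric vector, matrix, or `encoded_dataset` (a warning is
#'   issued if it has not been standardized).
#' @param model a `glnet_model`.
#' @param mode `"eval"` or `"train"` (batch-moment normalization).
#' @return n x `head_classes` matrix of class logits.
#' @export
glnet_forward <- function(x, model, mode = "eval") {
  if (inherits(x, "encoded_dataset")) {
    if (!isTRUE(x$standardized)) {
      warning("glnet_forward: input has not been standardized; the model ",
              "expects standardized factors")
    }
    x <- x$x
  }
  X <- if (is.null(dim(x))) matrix(x, nrow = 1L) else as.matrix(x)
  if (ncol(X) != model$config$input_dim) {
    stop("contract error: expected ", model$config$input_dim,
         " input columns, got ", ncol(X))
  }
  glnet_forward_internal(model, X, mode)$logits
}

#' Predicted probability of the positive (depressed) class
#'
#' @param x input rows (vector, matrix or `encoded_dataset`).
#' @param model a `glnet_model`.
#' @return Numeric vector of class-1 probabilities in [0, 1].
#' @export
predict_proba <- function(x, model) {
  p <- softmax_rows(glnet_forward(x, model, mode = "eval"))
  as.numeric(p[, 2L])
}

# Backward through one block given dL/d(out); fills `grads` (an
# environment) and returns dL/d(input). Only valid for train-mode caches.
glb_backward_internal <- function(model, k, cache, dOut, grads) {
  pfx <- paste0("glb", k, ".")
  run <- model$running[[paste0("glb", k)]]
  gamma <- model$params[[paste0(pfx, "bn.gamma")]]
  n <- nrow(dOut)
  xhat <- cache$xhat
  grads[[paste0(pfx, "bn.gamma")]] <- grads[[paste0(pfx, "bn.gamma")]] +
    colSums(dOut * xhat)
  grads[[paste0(pfx, "bn.beta")]] <- grads[[paste0(pfx, "bn.beta")]] +
    colSums(dOut)
  dxhat <- sweep(dOut, 2L, gamma, "*")
  if (cache$mode == "train") {
    ivar <- 1 / sqrt(cache$v + run$eps)
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * xhat)
    dF <- sweep(dxhat, 2L, s1 / n, "-") - sweep(xhat, 2L, s2 / n, "*")
    dF <- sweep(dF, 2L, ivar, "*")
  } else {
    dF <- sweep(dxhat, 2L, 1 / sqrt(cache$v + run$eps), "*")
  }
  W <- model$params[[paste0(pfx, "fc.W")]]
  grads[[paste0(pfx, "fc.W")]] <- grads[[paste0(pfx, "fc.W")]] +
    crossprod(cache$Aout, dF)
  grads[[paste0(pfx, "fc.b")]] <- grads[[paste0(pfx, "fc.b")]] + colSums(dF)
  dAout <- tcrossprod(dF, W)
  slope <- model$config$leaky_slope
  dCv <- dAout * ifelse(cache$Cv > 0, 1, slope)
  cb <- conv1d_backward(cache$S, model$params[[paste0(pfx, "conv.w")]], dCv)
  grads[[paste0(pfx, "conv.w")]] <- grads[[paste0(pfx, "conv.w")]] + cb$dw
  grads[[paste0(pfx, "conv.b")]] <- grads[[paste0(pfx, "conv.b")]] + cb$db
  sp <- ssm_par(model, k)
  sb <- .ssm_scan_backward_cpp(cache$Z, cache$H, cache$Delta, cb$dX,
                               as.numeric(sp$A), sp$wd, sp$bd,
                               as.numeric(sp$wB), as.numeric(sp$bB),
                               as.numeric(sp$wC), as.numeric(sp$bC), sp$D)
  grads[[paste0(pfx, "ssm.A")]] <- grads[[paste0(pfx, "ssm.A")]] + sb$dA
  grads[[paste0(pfx, "ssm.wd")]] <- grads[[paste0(pfx, "ssm.wd")]] + sb$dwd
  grads[[paste0(pfx, "ssm.bd")]] <- grads[[paste0(pfx, "ssm.bd")]] + sb$dbd
  grads[[paste0(pfx, "ssm.wB")]] <- grads[[paste0(pfx, "ssm.wB")]] + sb$dwB
  grads[[paste0(pfx, "ssm.bB")]] <- grads[[paste0(pfx, "ssm.bB")]] + sb$dbB
  grads[[paste0(pfx, "ssm.wC")]] <- grads[[paste0(pfx, "ssm.wC")]] + sb$dwC
  grads[[paste0(pfx, "ssm.bC")]] <- grads[[paste0(pfx, "ssm.bC")]] + sb$dbC
  grads[[paste0(pfx, "ssm.D")]] <- grads[[paste0(pfx, "ssm.D")]] + sb$dD
  sb$dX
}

# Full backward from dL/dlogits; returns a named gradient list matching
# model$params plus dL/dX under "input".
glnet_backward <- function(model, cache, dlogits) {
  grads <- new.env(parent = emptyenv())
  for (nm in names(model$params)) {
    p <- model$params[[nm]]
    grads[[nm]] <- if (is.matrix(p)) matrix(0, nrow(p), ncol(p)) else numeric(length(p))
  }
  grads[["head.W"]] <- crossprod(cache$g4, dlogits)
  grads[["head.b"]] <- colSums(dlogits)
  dg4 <- tcrossprod(dlogits, model$params[["head.W"]])
  din4 <- glb_backward_internal(model, 4L, cache$blocks[[4L]], dg4, grads)
  dg3 <- din4
  dg1 <- din4                                  # residual branch
  dg2 <- glb_backward_internal(model, 3L, cache$blocks[[3L]], dg3, grads)
  dg1 <- dg1 + glb_backward_internal(model, 2L, cache$blocks[[2L]], dg2, grads)
  dX1 <- glb_backward_internal(model, 1L, cache$blocks[[1L]], dg1, grads)
  grads[["embed.W"]] <- crossprod(cache$X, dX1)
  grads[["embed.b"]] <- colSums(dX1)
  out <- as.list(grads)
  out[["input"]] <- tcrossprod(dX1, model$params[["embed.W"]])
  out
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single JSON file holding the configuration, every
#' named parameter tensor, the batch-normalization running moments and an
#' optional standardizer reference hash. Doubles are serialized with 17
#' significant digits so a load/save round trip is bit-exact.
#'
#' @param model a `glnet_model`.
#' @param path file path.
#' @param standardizer_hash optional string tying the checkpoint to the
#'   standardizer it was trained with.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns a `glnet_model`.
#' @export
save_checkpoint <- function(model, path, standardizer_hash = NULL) {
  enc <- function(x) {
    list(dim = as.list(dim(x) %||% integer(0)),
         data = sprintf("%.17g", as.numeric(x)))
  }
  obj <- list(config = unclass(model$config),
              params = lapply(model$params, enc),
              running = lapply(model$running, function(r) {
                list(mean = sprintf("%.17g", r$mean),
                     var = sprintf("%.17g", r$var),
                     momentum = r$momentum, eps = r$eps)
              }),
              standardizer_hash = standardizer_hash)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(glnet_config, as.list(obj$config))
  dec <- function(e) {
    x <- as.numeric(e$data)
    d <- unlist(e$dim)
    if (length(d) == 2L) matrix(x, d[1], d[2]) else x
  }
  params <- lapply(obj$params, dec)
  running <- lapply(obj$running, function(r) {
    list(mean = as.numeric(r$mean), var = as.numeric(r$var),
         momentum = r$momentum, eps = r$eps)
  })
  structure(list(config = cfg, params = params, running = running),
            class = "glnet_model")
}
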