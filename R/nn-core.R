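#' @useDynLib ghostherd, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# Minimal neural-network engine.
#
# A module is a mutable environment carrying trainable arrays (listed in
# $param_names), accumulated gradients (g_<name>), persistent state (batch-norm
# running moments), an ordered list of child modules, and per-forward caches
# used by the backward pass. Activations are R arrays of dim (H, W, C, N).
# ---------------------------------------------------------------------------

nn_module <- function(type, ...) {
  m <- new.env(parent = emptyenv())
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = m)
  m$type <- type
  if (is.null(m$param_names)) m$param_names <- character()
  if (is.null(m$children)) m$children <- list()
  class(m) <- c(paste0("nn_", type), "nn_module")
  m
}

#' Forward pass through a network module
#'
#' @param m A network module (any block built by the `build_*` constructors or
#'   [assemble_model()]).
#' @param x Input activation array of dim `(H, W, C, N)` (matrix `(C, N)` for
#'   the classifier head).
#' @param training Logical; when `TRUE` the module caches intermediates for
#'   [nn_backward()] and batch normalization uses batch statistics.
#' @return The output activation.
#' @export
nn_forward <- function(m, x, training = FALSE) UseMethod("nn_forward")

#' Backward pass through a network module
#'
#' Accumulates parameter gradients inside the module (fields `g_<name>`) and
#' returns the gradient with respect to the module input. Must follow a
#' forward pass with `training = TRUE`.
#'
#' @param m A network module.
#' @param gy Gradient of the loss with respect to the module output.
#' @return Gradient with respect to the module input.
#' @export
nn_backward <- function(m, gy) UseMethod("nn_backward")

#' Enumerate the trainable parameters of a module tree
#'
#' @param m A network module.
#' @param prefix Name prefix used during recursion.
#' @return A named list; each element is `list(env, field)` pointing at the
#'   environment slot holding one trainable array. Names are dotted paths
#'   such as `stage1.entry.conv1.weight`.
#' @export
nn_parameters <- function(m, prefix = "") {
  out <- list()
  for (p in m$param_names) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", p) else p
    out[[key]] <- list(env = m, field = p)
  }
  kids <- m$children
  for (nm in names(kids)) {
    sub <- nn_parameters(kids[[nm]],
                         if (nzchar(prefix)) paste0(prefix, ".", nm) else nm)
    out <- c(out, sub)
  }
  out
}

#' Clear accumulated gradients in a module tree
#'
#' @param m A network module.
#' @return The module, invisibly.
#' @export
nn_zero_grad <- function(m) {
  for (ref in nn_parameters(m)) {
    ref$env[[paste0("g_", ref$field)]] <- NULL
  }
  invisible(m)
}

acc_grad <- function(m, field, g) {
  key <- paste0("g_", field)
  cur <- m[[key]]
  m[[key]] <- if (is.null(cur)) g else cur + g
}

# -- convolution -------------------------------------------------------------

nn_conv2d <- function(in_channels, out_channels, kernel, stride = 1L,
                      dilation = 1L, groups = 1L, bias = FALSE) {
  stopifnot(in_channels >= 1, out_channels >= 1, kernel >= 1,
            stride >= 1, dilation >= 1, groups >= 1)
  if (in_channels %% groups != 0 || out_channels %% groups != 0)
    stop("in_channels and out_channels must be divisible by groups")
  if (kernel %% 2 == 0)
    stop("even kernels are not supported with 'same'-style padding")
  eff <- dilation * (kernel - 1L) + 1L
  m <- nn_module("conv2d",
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 kernel = as.integer(kernel), stride = as.integer(stride),
                 dilation = as.integer(dilation), groups = as.integer(groups),
                 pad = as.integer((eff - 1L) / 2L), has_bias = isTRUE(bias))
  m$weight <- array(0, c(kernel, kernel, in_channels %/% groups, out_channels))
  m$param_names <- "weight"
  if (m$has_bias) {
    m$bias <- numeric(out_channels)
    m$param_names <- c("weight", "bias")
  }
  m
}

#' @export
nn_forward.nn_conv2d <- function(m, x, training = FALSE) {
  d <- dim(x)
  if (d[3] != m$in_channels)
    stop(sprintf("conv2d expects %d input channels, got %d", m$in_channels, d[3]))
  y <- conv2d_fwd_cpp(x, as.integer(d), m$weight, m$kernel, m$out_channels,
                      m$stride, m$pad, m$dilation, m$groups,
                      if (m$has_bias) m$bias else NULL)
  dy <- dim(y)
  m$last_out_shape <- dy
  m$last_macs <- as.numeric(m$kernel)^2 * (m$in_channels / m$groups) *
    m$out_channels * dy[1] * dy[2]
  if (training) m$cache_x <- x
  y
}

#' @export
nn_backward.nn_conv2d <- function(m, gy) {
  r <- conv2d_bwd_cpp(m$cache_x, as.integer(dim(m$cache_x)), m$weight,
                      m$kernel, m$out_channels, gy,
                      m$stride, m$pad, m$dilation, m$groups, m$has_bias)
  acc_grad(m, "weight", r$gw)
  if (m$has_bias) acc_grad(m, "bias", r$gb)
  m$cache_x <- NULL
  r$gx
}

# -- batch normalization -----------------------------------------------------

nn_batchnorm2d <- function(channels, eps = 1e-5, momentum = 0.1) {
  m <- nn_module("batchnorm2d", channels = as.integer(channels),
                 eps = eps, momentum = momentum)
  m$gamma <- rep(1, channels)
  m$beta <- rep(0, channels)
  m$running_mean <- rep(0, channels)
  m$running_var <- rep(1, channels)
  m$param_names <- c("gamma", "beta")
  m
}

# broadcast a per-channel vector over (H, W, C, N); relies on R recycling:
# rep(v, each = H*W) has length H*W*C which tiles over samples.
bcast_c <- function(v, d) rep(v, each = d[1] * d[2])

#' @export
nn_forward.nn_batchnorm2d <- function(m, x, training = FALSE) {
  d <- as.integer(dim(x))
  if (training) {
    mo <- channel_moments_cpp(x, d)
    mu <- mo$mean
    v <- mo$var
    ivar <- 1 / sqrt(v + m$eps)
    mrate <- m$momentum
    nel <- d[1] * d[2] * d[4]
    m$running_mean <- (1 - mrate) * m$running_mean + mrate * mu
    # running variance uses the unbiased estimator, as is conventional
    ub <- if (nel > 1) v * nel / (nel - 1) else v
    m$running_var <- (1 - mrate) * m$running_var + mrate * ub
    r <- batchnorm_fwd_cpp(x, d, mu, ivar, m$gamma, m$beta, TRUE)
    m$cache_xhat <- r$xhat
    m$cache_ivar <- ivar
    r$y
  } else {
    ivar <- 1 / sqrt(m$running_var + m$eps)
    batchnorm_fwd_cpp(x, d, m$running_mean, ivar, m$gamma, m$beta, FALSE)$y
  }
}

#' @export
nn_backward.nn_batchnorm2d <- function(m, gy) {
  r <- batchnorm_bwd_cpp(gy, m$cache_xhat, as.integer(dim(gy)),
                         m$gamma, m$cache_ivar)
  acc_grad(m, "gamma", r$ggamma)
  acc_grad(m, "beta", r$gbeta)
  m$cache_xhat <- NULL
  m$cache_ivar <- NULL
  r$gx
}

# -- pointwise nonlinearities ------------------------------------------------

nn_relu <- function() nn_module("relu")

#' @export
nn_forward.nn_relu <- function(m, x, training = FALSE) {
  y <- relu_fwd_cpp(x)
  if (training) m$cache_y <- y
  y
}

#' @export
nn_backward.nn_relu <- function(m, gy) {
  gx <- relu_bwd_cpp(gy, m$cache_y)
  m$cache_y <- NULL
  gx
}

nn_sigmoid <- function() nn_module("sigmoid")

#' @export
nn_forward.nn_sigmoid <- function(m, x, training = FALSE) {
  y <- 1 / (1 + exp(-x))
  if (training) m$cache_y <- y
  y
}

#' @export
nn_backward.nn_sigmoid <- function(m, gy) {
  y <- m$cache_y
  m$cache_y <- NULL
  gy * y * (1 - y)
}

# -- pooling -----------------------------------------------------------------

nn_maxpool2d <- function(kernel = 3L, stride = 2L, pad = 1L) {
  nn_module("maxpool2d", kernel = as.integer(kernel),
            stride = as.integer(stride), pad = as.integer(pad))
}

#' @export
nn_forward.nn_maxpool2d <- function(m, x, training = FALSE) {
  r <- maxpool_fwd_cpp(x, as.integer(dim(x)), m$kernel, m$stride, m$pad)
  if (training) {
    m$cache_idx <- r$idx
    m$cache_xdim <- dim(x)
  }
  r$y
}

#' @export
nn_backward.nn_maxpool2d <- function(m, gy) {
  gx <- maxpool_bwd_cpp(gy, m$cache_idx, as.integer(m$cache_xdim))
  m$cache_idx <- NULL
  gx
}

nn_global_avgpool <- function() nn_module("gap")

#' @export
nn_forward.nn_gap <- function(m, x, training = FALSE) {
  d <- dim(x)
  if (training) m$cache_d <- d
  a <- x; dim(a) <- c(d[1] * d[2], d[3], d[4])
  colMeans(a)                                   # C x N
}

#' @export
nn_backward.nn_gap <- function(m, gy) {
  d <- m$cache_d
  m$cache_d <- NULL
  gx <- rep(gy, each = d[1] * d[2]) / (d[1] * d[2])
  dim(gx) <- d
  gx
}

# -- fully connected ---------------------------------------------------------

nn_linear <- function(in_features, out_features, bias = TRUE) {
  m <- nn_module("linear", in_features = as.integer(in_features),
                 out_features = as.integer(out_features),
                 has_bias = isTRUE(bias))
  m$weight <- matrix(0, out_features, in_features)
  m$param_names <- "weight"
  if (m$has_bias) {
    m$bias <- numeric(out_features)
    m$param_names <- c("weight", "bias")
  }
  m
}

#' @export
nn_forward.nn_linear <- function(m, x, training = FALSE) {
  # x: in_features x N
  y <- m$weight %*% x
  if (m$has_bias) y <- y + m$bias
  m$last_macs <- as.numeric(m$in_features) * m$out_features
  m$last_out_shape <- dim(y)
  if (training) m$cache_x <- x
  y
}

#' @export
nn_backward.nn_linear <- function(m, gy) {
  acc_grad(m, "weight", gy %*% t(m$cache_x))
  if (m$has_bias) acc_grad(m, "bias", rowSums(gy))
  gx <- t(m$weight) %*% gy
  m$cache_x <- NULL
  gx
}

# -- sequential container ----------------------------------------------------

nn_sequential <- function(...) {
  kids <- list(...)
  if (length(kids) == 1 && is.list(kids[[1]]) && !inherits(kids[[1]], "nn_module"))
    kids <- kids[[1]]
  if (is.null(names(kids)) || any(!nzchar(names(kids))))
    names(kids) <- sprintf("b%02d", seq_along(kids))
  nn_module("sequential", children = kids)
}

#' @export
nn_forward.nn_sequential <- function(m, x, training = FALSE) {
  for (k in m$children) x <- nn_forward(k, x, training)
  x
}

#' @export
nn_backward.nn_sequential <- function(m, gy) {
  for (k in rev(m$children)) gy <- nn_backward(k, gy)
  gy
}

# -- channel concatenation helpers ------------------------------------------

concat_c <- function(x1, x2) {
  d1 <- dim(x1); d2 <- dim(x2)
  out <- array(0, c(d1[1], d1[2], d1[3] + d2[3], d1[4]))
  out[, , seq_len(d1[3]), ] <- x1
  out[, , d1[3] + seq_len(d2[3]), ] <- x2
  out
}
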