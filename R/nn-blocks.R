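# ---------------------------------------------------------------------------
# Builders turning block specifications into runnable network modules.
# ---------------------------------------------------------------------------

#' Build the stem block
#'
#' Convolution (optionally dilated) + batch normalization + ReLU, optionally
#' followed by a 3x3 stride-2 max pool. The final model's stem is a 3x3
#' convolution with dilation 3: the effective receptive field matches a 7x7
#' kernel while the parameter count stays that of a 3x3 (dilation spaces the
#' taps, it adds none).
#'
#' @param spec A [conv_spec()].
#' @param pool Append a 3x3/stride-2/pad-1 max pool.
#' @return A network block.
#' @export
build_stem <- function(spec, pool = FALSE) {
  stopifnot(inherits(spec, "conv_spec"))
  kids <- list(
    conv = nn_conv2d(spec$in_channels, spec$out_channels, spec$kernel,
                     stride = spec$stride, dilation = spec$dilation,
                     groups = spec$groups, bias = spec$has_bias),
    bn = nn_batchnorm2d(spec$out_channels),
    relu = nn_relu())
  if (isTRUE(pool)) kids$pool <- nn_maxpool2d(3L, 2L, 1L)
  m <- nn_sequential(kids)
  m$spec <- spec
  m
}

#' Build a standard residual bottleneck
#'
#' 1x1 reduce -> 3x3 (strided) -> 1x1 expand, batch norm after every
#' convolution, additive shortcut (1x1 projection when the shape changes),
#' ReLU after the addition.
#'
#' @param spec A [bottleneck_spec()].
#' @return A network block.
#' @export
build_bottleneck <- function(spec) {
  stopifnot(inherits(spec, "bottleneck_spec"))
  m <- nn_module("bottleneck", spec = spec)
  kids <- list(
    conv1 = nn_conv2d(spec$in_channels, spec$mid_channels, 1L),
    bn1 = nn_batchnorm2d(spec$mid_channels),
    relu1 = nn_relu(),
    conv2 = nn_conv2d(spec$mid_channels, spec$mid_channels, 3L,
                      stride = spec$stride),
    bn2 = nn_batchnorm2d(spec$mid_channels),
    relu2 = nn_relu(),
    conv3 = nn_conv2d(spec$mid_channels, spec$out_channels, 1L),
    bn3 = nn_batchnorm2d(spec$out_channels),
    relu_out = nn_relu())
  if (spec$has_projection) {
    kids$proj_conv <- nn_conv2d(spec$in_channels, spec$out_channels, 1L,
                                stride = spec$stride)
    kids$proj_bn <- nn_batchnorm2d(spec$out_channels)
  }
  m$children <- kids
  m
}

#' @export
nn_forward.nn_bottleneck <- function(m, x, training = FALSE) {
  k <- m$children
  h <- nn_forward(k$conv1, x, training)
  h <- nn_forward(k$bn1, h, training)
  h <- nn_forward(k$relu1, h, training)
  h <- nn_forward(k$conv2, h, training)
  h <- nn_forward(k$bn2, h, training)
  h <- nn_forward(k$relu2, h, training)
  h <- nn_forward(k$conv3, h, training)
  h <- nn_forward(k$bn3, h, training)
  s <- if (m$spec$has_projection) {
    nn_forward(k$proj_bn, nn_forward(k$proj_conv, x, training), training)
  } else x
  if (!identical(dim(h), dim(s)))
    stop("bottleneck shortcut/main shape mismatch; projection required")
  nn_forward(k$relu_out, h + s, training)
}

#' @export
nn_backward.nn_bottleneck <- function(m, gy) {
  k <- m$children
  g <- nn_backward(k$relu_out, gy)
  gh <- nn_backward(k$bn3, g)
  gh <- nn_backward(k$conv3, gh)
  gh <- nn_backward(k$relu2, gh)
  gh <- nn_backward(k$bn2, gh)
  gh <- nn_backward(k$conv2, gh)
  gh <- nn_backward(k$relu1, gh)
  gh <- nn_backward(k$bn1, gh)
  gx <- nn_backward(k$conv1, gh)
  gs <- if (m$spec$has_projection)
    nn_backward(k$proj_conv, nn_backward(k$proj_bn, g))
  else g
  gx + gs
}

#' Build a ghost module
#'
#' The primary pointwise convolution produces `out_channels / ratio_s`
#' feature maps; a cheap depthwise convolution derives the remaining
#' channels from them; the two halves are concatenated. Each branch carries
#' batch normalization (and ReLU when `relu = TRUE`).
#'
#' @param spec A [ghost_module_spec()].
#' @param relu Apply ReLU in both branches (the projection ghost module of a
#'   GhostBottleneck omits it).
#' @return A network block.
#' @export
build_ghost_module <- function(spec, relu = TRUE) {
  stopifnot(inherits(spec, "ghost_module_spec"))
  init <- spec$primary_channels
  cheap_out <- spec$out_channels - init
  m <- nn_module("ghost_module", spec = spec, init = init, use_relu = isTRUE(relu))
  m$children <- list(
    pconv = nn_conv2d(spec$in_channels, init, 1L, stride = spec$stride),
    pbn = nn_batchnorm2d(init),
    prelu = nn_relu(),
    cconv = nn_conv2d(init, cheap_out, spec$cheap_kernel_d, groups = init),
    cbn = nn_batchnorm2d(cheap_out),
    crelu = nn_relu())
  m
}

#' @export
nn_forward.nn_ghost_module <- function(m, x, training = FALSE) {
  k <- m$children
  p <- nn_forward(k$pbn, nn_forward(k$pconv, x, training), training)
  if (m$use_relu) p <- nn_forward(k$prelu, p, training)
  cc <- nn_forward(k$cbn, nn_forward(k$cconv, p, training), training)
  if (m$use_relu) cc <- nn_forward(k$crelu, cc, training)
  concat_c(p, cc)
}

#' @export
nn_backward.nn_ghost_module <- function(m, gy) {
  k <- m$children
  init <- m$init
  d <- dim(gy)
  gp <- gy[, , seq_len(init), , drop = FALSE]
  gc <- gy[, , init + seq_len(d[3] - init), , drop = FALSE]
  if (m$use_relu) gc <- nn_backward(k$crelu, gc)
  gc <- nn_backward(k$cbn, gc)
  gp <- gp + nn_backward(k$cconv, gc)
  if (m$use_relu) gp <- nn_backward(k$prelu, gp)
  gp <- nn_backward(k$pbn, gp)
  nn_backward(k$pconv, gp)
}

#' Build a GhostBottleneck
#'
#' Ghost expansion (with ReLU) -> optional stride-2 depthwise convolution ->
#' ghost projection (no ReLU), plus an additive shortcut: identity when shape
#' is preserved, otherwise depthwise (if strided) + pointwise projection.
#'
#' @param spec A [ghost_bottleneck_spec()].
#' @return A network block.
#' @export
build_ghost_bottleneck <- function(spec) {
  stopifnot(inherits(spec, "ghost_bottleneck_spec"))
  m <- nn_module("ghost_bottleneck", spec = spec)
  kids <- list(ghost1 = build_ghost_module(spec$expand, relu = TRUE))
  if (spec$stride == 2L) {
    kids$dwconv <- nn_conv2d(spec$hidden_channels, spec$hidden_channels, 3L,
                             stride = 2L, groups = spec$hidden_channels)
    kids$dwbn <- nn_batchnorm2d(spec$hidden_channels)
  }
  kids$ghost2 <- build_ghost_module(spec$project, relu = FALSE)
  if (spec$shortcut == "projection") {
    if (spec$stride == 2L) {
      kids$sc_dwconv <- nn_conv2d(spec$in_channels, spec$in_channels, 3L,
                                  stride = 2L, groups = spec$in_channels)
      kids$sc_dwbn <- nn_batchnorm2d(spec$in_channels)
    }
    kids$sc_conv <- nn_conv2d(spec$in_channels, spec$out_channels, 1L)
    kids$sc_bn <- nn_batchnorm2d(spec$out_channels)
  }
  m$children <- kids
  m
}

#' @export
nn_forward.nn_ghost_bottleneck <- function(m, x, training = FALSE) {
  k <- m$children
  sp <- m$spec
  h <- nn_forward(k$ghost1, x, training)
  if (sp$stride == 2L)
    h <- nn_forward(k$dwbn, nn_forward(k$dwconv, h, training), training)
  h <- nn_forward(k$ghost2, h, training)
  s <- if (sp$shortcut == "identity") x else {
    z <- x
    if (sp$stride == 2L)
      z <- nn_forward(k$sc_dwbn, nn_forward(k$sc_dwconv, z, training), training)
    nn_forward(k$sc_bn, nn_forward(k$sc_conv, z, training), training)
  }
  h + s
}

#' @export
nn_backward.nn_ghost_bottleneck <- function(m, gy) {
  k <- m$children
  sp <- m$spec
  gh <- nn_backward(k$ghost2, gy)
  if (sp$stride == 2L)
    gh <- nn_backward(k$dwconv, nn_backward(k$dwbn, gh))
  gx <- nn_backward(k$ghost1, gh)
  gs <- if (sp$shortcut == "identity") gy else {
    z <- nn_backward(k$sc_conv, nn_backward(k$sc_bn, gy))
    if (sp$stride == 2L)
      z <- nn_backward(k$sc_dwconv, nn_backward(k$sc_dwbn, z))
    z
  }
  gx + gs
}

#' Build a channel + spatial attention block (CBAM)
#'
#' Channel attention first: spatial average- and max-pooled descriptors pass
#' through a shared two-layer bottleneck mapping (no biases), are summed and
#' logistic-squashed into per-channel gates. Spatial attention second:
#' channelwise average and max maps are concatenated and convolved with a
#' wide kernel (no bias), logistic-squashed into a per-pixel gate. Each gate
#' multiplies the feature map; the output shape equals the input shape.
#'
#' @param spec A [cbam_spec()].
#' @return A network block.
#' @export
build_cbam <- function(spec) {
  stopifnot(inherits(spec, "cbam_spec"))
  C <- spec$channels
  cr <- C %/% spec$reduction_r
  m <- nn_module("cbam", spec = spec)
  m$w1 <- matrix(0, cr, C)   # shared mapping: C -> C/r (ReLU) -> C
  m$w2 <- matrix(0, C, cr)
  m$param_names <- c("w1", "w2")
  m$children <- list(sconv = nn_conv2d(2L, 1L, spec$spatial_kernel,
                                       bias = FALSE))
  m
}

#' @export
nn_forward.nn_cbam <- function(m, x, training = FALSE) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  hw <- H * W
  if (C != m$spec$channels)
    stop(sprintf("cbam expects %d channels, got %d", m$spec$channels, C))

  # channel attention
  a3 <- x; dim(a3) <- c(hw, C, N)
  savg <- colMeans(a3)                       # C x N
  dim(savg) <- c(C, N)
  mm <- matrix(x, hw, C * N)
  imax <- max.col(t(mm), ties.method = "first")
  smax <- matrix(mm[cbind(imax, seq_len(C * N))], C, N)
  h1a <- m$w1 %*% savg; r1a <- h1a * (h1a > 0); ha <- m$w2 %*% r1a
  h1m <- m$w1 %*% smax; r1m <- h1m * (h1m > 0); hm <- m$w2 %*% r1m
  a <- 1 / (1 + exp(-(ha + hm)))             # C x N in (0,1)
  y1 <- x * rep(a, each = hw)
  dim(y1) <- d

  # spatial attention
  yp <- aperm(y1, c(1, 2, 4, 3))             # H, W, N, C
  m2 <- matrix(yp, hw * N, C)
  sm <- rowMeans(m2)
  jmax <- max.col(m2, ties.method = "first")
  sx <- m2[cbind(seq_len(hw * N), jmax)]
  s2 <- array(0, c(H, W, 2L, N))
  s2[, , 1L, ] <- array(sm, c(H, W, N))
  s2[, , 2L, ] <- array(sx, c(H, W, N))
  z2 <- nn_forward(m$children$sconv, s2, training)   # H, W, 1, N
  av <- 1 / (1 + exp(-as.vector(z2)))                 # (H*W*N,) gate
  bb <- aperm(array(av, c(H, W, N, C)), c(1, 2, 4, 3))
  y <- y1 * bb

  m$last_macs <- 4 * as.numeric(C) * (C %/% m$spec$reduction_r)
  if (training) {
    m$cache <- list(x = x, a = a, imax = imax, savg = savg, smax = smax,
                    h1a = h1a, r1a = r1a, h1m = h1m, r1m = r1m,
                    y1 = y1, av = av, bb = bb, jmax = jmax, d = d)
  }
  y
}

#' @export
nn_backward.nn_cbam <- function(m, gy) {
  cc <- m$cache
  m$cache <- NULL
  d <- cc$d
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  hw <- H * W

  # spatial gate
  gy1 <- gy * cc$bb
  gz <- matrix(aperm(gy * cc$y1, c(1, 2, 4, 3)), hw * N, C)
  gav <- rowSums(gz) * cc$av * (1 - cc$av)           # through the logistic
  gs2 <- nn_backward(m$children$sconv, array(gav, c(H, W, 1L, N)))
  gsm <- as.vector(gs2[, , 1L, ])
  gsx <- as.vector(gs2[, , 2L, ])
  b1 <- matrix(gsm / C, hw * N, C)
  b1[cbind(seq_len(hw * N), cc$jmax)] <-
    b1[cbind(seq_len(hw * N), cc$jmax)] + gsx
  gy1 <- gy1 + aperm(array(b1, c(H, W, N, C)), c(1, 2, 4, 3))

  # channel gate
  gx <- gy1 * rep(cc$a, each = hw)
  z <- gy1 * cc$x; dim(z) <- c(hw, C, N)
  ga <- colSums(z); dim(ga) <- c(C, N)
  gzc <- ga * cc$a * (1 - cc$a)
  # shared mapping, average branch
  gr1a <- t(m$w2) %*% gzc; gr1a[cc$h1a <= 0] <- 0
  gr1m <- t(m$w2) %*% gzc; gr1m[cc$h1m <= 0] <- 0
  acc_grad(m, "w2", gzc %*% t(cc$r1a) + gzc %*% t(cc$r1m))
  acc_grad(m, "w1", gr1a %*% t(cc$savg) + gr1m %*% t(cc$smax))
  gsavg <- t(m$w1) %*% gr1a
  gsmax <- t(m$w1) %*% gr1m
  gx <- gx + rep(gsavg, each = hw) / hw
  gmm <- matrix(0, hw, C * N)
  gmm[cbind(cc$imax, seq_len(C * N))] <- as.vector(gsmax)
  dim(gx) <- d
  gx <- gx + array(gmm, d)
  gx
}

#' Assemble the full identification network from a configuration
#'
#' Stem -> stage1 -> attention -> stage2 -> attention -> stage3 -> attention
#' -> global average pool -> fully connected head. Accepts inputs of dim
#' `(side, side, 3, N)` and emits raw class scores of dim
#' `(num_classes, N)`.
#'
#' @param config A [model_config()].
#' @return A network module; `attr(, "config")`-equivalent metadata is kept
#'   in `$config`.
#' @export
assemble_model <- function(config) {
  stopifnot(inherits(config, "gh_model_config"))
  kids <- list(stem = build_stem(config$stem, pool = config$stem_pool))
  in_ch <- config$stem$out_channels
  for (i in 1:3) {
    st <- config$stages[[i]]
    if (st$entry$in_channels != in_ch)
      stop(sprintf("channel continuity violated entering stage %d (%d vs %d)",
                   i, in_ch, st$entry$in_channels))
    blocks <- list(entry = build_bottleneck(st$entry))
    for (j in seq_along(st$ghosts))
      blocks[[sprintf("ghost%d", j)]] <- build_ghost_bottleneck(st$ghosts[[j]])
    if (!is.null(st$exit)) blocks$exit <- build_bottleneck(st$exit)
    kids[[sprintf("stage%d", i)]] <- nn_sequential(blocks)
    if (!is.null(st$attention))
      kids[[sprintf("cbam%d", i)]] <- build_cbam(st$attention)
    in_ch <- st$out_channels
  }
  kids$gap <- nn_global_avgpool()
  kids$fc <- nn_linear(in_ch, config$num_classes, bias = TRUE)
  m <- nn_sequential(kids)
  m$config <- config
  class(m) <- c("gh_model", class(m))
  m
}

#' Build the canonical 4-stage 50-layer residual baseline
#'
#' The standard deep residual network: 7x7/stride-2 stem, 3x3 max pool,
#' four stages of (3, 4, 6, 3) bottlenecks at pre-expansion widths
#' (64, 128, 256, 512) with expansion 4, global average pool and a fully
#' connected head. Serves as the unmodified reference the lightweight model
#' is measured against.
#'
#' @param num_classes Size of the classification head.
#' @return A network module.
#' @export
build_reference_resnet50 <- function(num_classes = 13) {
  num_classes <- chk_posint(num_classes, "num_classes")
  kids <- list(stem = build_stem(conv_spec(7, 3, 64, stride = 2), pool = TRUE))
  widths <- c(64L, 128L, 256L, 512L)
  nblocks <- c(3L, 4L, 6L, 3L)
  in_ch <- 64L
  for (i in 1:4) {
    w <- widths[i]
    blocks <- list()
    for (b in seq_len(nblocks[i])) {
      stride <- if (b == 1L && i > 1L) 2L else 1L
      blocks[[sprintf("b%d", b)]] <- build_bottleneck(
        bottleneck_spec(in_ch, w, 4L * w, stride = stride))
      in_ch <- 4L * w
    }
    kids[[sprintf("stage%d", i)]] <- nn_sequential(blocks)
  }
  kids$gap <- nn_global_avgpool()
  kids$fc <- nn_linear(in_ch, num_classes, bias = TRUE)
  m <- nn_sequential(kids)
  m$config <- list(num_classes = num_classes, arch = "resnet50",
                   input_side = 224L)
  class(m) <- c("gh_model", class(m))
  m
}

#' Class probabilities for a batch
#'
#' Runs the model in evaluation mode and applies the softmax.
#'
#' @param model A network built by [assemble_model()] or
#'   [build_reference_resnet50()].
#' @param batch Array of dim `(side, side, 3, N)`.
#' @return An `N x num_classes` matrix; every row is non-negative and sums
#'   to 1.
#' @export
predict_proba <- function(model, batch) {
  if (length(dim(batch)) != 4 || dim(batch)[3] != 3)
    stop("batch must be an (H, W, 3, N) array")
  scores <- nn_forward(model, batch, training = FALSE)   # K x N
  t(softmax_cols(scores))
}

# column-wise softmax of a K x N score matrix, shift-invariant
softmax_cols <- function(z) {
  z <- z - rep(apply(z, 2, max), each = nrow(z))
  e <- exp(z)
  e / rep(colSums(e), each = nrow(z))
}
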