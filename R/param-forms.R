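# ---------------------------------------------------------------------------
# Closed-form parameter arithmetic.
#
# Every block's trainable-scalar count is expressed as plain integer
# arithmetic on its spec, so the configuration search can score thousands of
# candidate architectures without allocating a single weight. Parity with
# the counts of actually-built modules is enforced by tests.
# ---------------------------------------------------------------------------

pf_conv <- function(kernel, cin, cout, groups = 1, bias = FALSE) {
  kernel^2 * cin * cout / groups + if (bias) cout else 0
}

pf_bn <- function(channels) 2 * channels

#' Closed-form parameter counts per block specification
#'
#' Arithmetic equivalents of [count_parameters()] applied to a built block;
#' used by the configuration search and as its cross-check.
#'
#' @param spec The corresponding block specification.
#' @return Exact trainable-parameter count.
#' @export
params_stem <- function(spec) {
  pf_conv(spec$kernel, spec$in_channels, spec$out_channels, spec$groups,
          spec$has_bias) + pf_bn(spec$out_channels)
}

#' @rdname params_stem
#' @export
params_bottleneck <- function(spec) {
  p <- pf_conv(1, spec$in_channels, spec$mid_channels) + pf_bn(spec$mid_channels) +
    pf_conv(3, spec$mid_channels, spec$mid_channels) + pf_bn(spec$mid_channels) +
    pf_conv(1, spec$mid_channels, spec$out_channels) + pf_bn(spec$out_channels)
  if (spec$has_projection)
    p <- p + pf_conv(1, spec$in_channels, spec$out_channels) +
      pf_bn(spec$out_channels)
  p
}

#' @rdname params_stem
#' @export
params_ghost_module <- function(spec) {
  init <- spec$primary_channels
  cheap <- spec$out_channels - init
  pf_conv(1, spec$in_channels, init) + pf_bn(init) +
    pf_conv(spec$cheap_kernel_d, init, cheap, groups = init) + pf_bn(cheap)
}

#' @rdname params_stem
#' @export
params_ghost_bottleneck <- function(spec) {
  p <- params_ghost_module(spec$expand) + params_ghost_module(spec$project)
  if (spec$stride == 2)
    p <- p + pf_conv(3, spec$hidden_channels, spec$hidden_channels,
                     groups = spec$hidden_channels) + pf_bn(spec$hidden_channels)
  if (spec$shortcut == "projection") {
    if (spec$stride == 2)
      p <- p + pf_conv(3, spec$in_channels, spec$in_channels,
                       groups = spec$in_channels) + pf_bn(spec$in_channels)
    p <- p + pf_conv(1, spec$in_channels, spec$out_channels) +
      pf_bn(spec$out_channels)
  }
  p
}

#' @rdname params_stem
#' @export
params_cbam <- function(spec) {
  cr <- spec$channels %/% spec$reduction_r
  2 * spec$channels * cr + spec$spatial_kernel^2 * 2
}

#' Closed-form parameter count of a full model configuration
#'
#' @param config A [model_config()].
#' @return Exact trainable-parameter count of the model
#'   [assemble_model()] would build.
#' @export
config_param_count <- function(config) {
  stopifnot(inherits(config, "gh_model_config"))
  p <- params_stem(config$stem)
  for (st in config$stages) {
    p <- p + params_bottleneck(st$entry)
    for (g in st$ghosts) p <- p + params_ghost_bottleneck(g)
    if (!is.null(st$exit)) p <- p + params_bottleneck(st$exit)
    if (!is.null(st$attention)) p <- p + params_cbam(st$attention)
  }
  p + config$head_channels * config$num_classes + config$num_classes
}

#' Closed-form parameter count of the canonical 4-stage baseline
#'
#' @param num_classes Classification-head size.
#' @return Exact trainable-parameter count of
#'   [build_reference_resnet50()].
#' @export
resnet50_param_count <- function(num_classes = 13) {
  p <- pf_conv(7, 3, 64) + pf_bn(64)
  widths <- c(64, 128, 256, 512)
  nblocks <- c(3, 4, 6, 3)
  in_ch <- 64
  for (i in 1:4) {
    w <- widths[i]
    for (b in seq_len(nblocks[i])) {
      stride <- if (b == 1 && i > 1) 2 else 1
      p <- p + params_bottleneck(bottleneck_spec(in_ch, w, 4 * w,
                                                 stride = stride))
      in_ch <- 4 * w
    }
  }
  p + in_ch * num_classes + num_classes
}
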