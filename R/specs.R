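# ---------------------------------------------------------------------------
# Declarative block and model specifications.
#
# Every network block is described by a plain validated list before anything
# is built, so the same spec drives (a) weight allocation, (b) closed-form
# parameter accounting, and (c) the configuration search.
# ---------------------------------------------------------------------------

chk_posint <- function(x, nm) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 1 || x != floor(x))
    stop(sprintf("'%s' must be a positive integer", nm), call. = FALSE)
  as.integer(x)
}

#' Specification of a single convolution
#'
#' @param kernel Square kernel side (odd for 'same'-style padding).
#' @param in_channels,out_channels Channel counts; both must be divisible by
#'   `groups`.
#' @param stride,dilation,groups Convolution geometry (all >= 1).
#' @param has_bias Whether the convolution carries a bias vector. Convolutions
#'   followed by batch normalization conventionally do not.
#' @return A `conv_spec` list.
#' @export
conv_spec <- function(kernel, in_channels, out_channels, stride = 1,
                      dilation = 1, groups = 1, has_bias = FALSE) {
  s <- list(kernel = chk_posint(kernel, "kernel"),
            in_channels = chk_posint(in_channels, "in_channels"),
            out_channels = chk_posint(out_channels, "out_channels"),
            stride = chk_posint(stride, "stride"),
            dilation = chk_posint(dilation, "dilation"),
            groups = chk_posint(groups, "groups"),
            has_bias = isTRUE(has_bias))
  if (s$in_channels %% s$groups != 0 || s$out_channels %% s$groups != 0)
    stop("channel counts must be divisible by groups")
  structure(s, class = "conv_spec")
}

#' Specification of a standard residual bottleneck
#'
#' A 1x1 reduce -> 3x3 -> 1x1 expand block with batch normalization after each
#' convolution, an additive shortcut, and a trailing nonlinearity. The
#' shortcut is a 1x1 projection whenever the block changes shape.
#'
#' @param in_channels,mid_channels,out_channels Channel widths; `out_channels`
#'   must equal `expansion * mid_channels`.
#' @param stride Stride of the 3x3 convolution (and projection).
#' @param expansion Width multiplier tying `mid_channels` to `out_channels`.
#' @return A `bottleneck_spec` list with derived flag `has_projection`.
#' @export
bottleneck_spec <- function(in_channels, mid_channels, out_channels,
                            stride = 1, expansion = 4) {
  s <- list(in_channels = chk_posint(in_channels, "in_channels"),
            mid_channels = chk_posint(mid_channels, "mid_channels"),
            out_channels = chk_posint(out_channels, "out_channels"),
            stride = chk_posint(stride, "stride"),
            expansion = chk_posint(expansion, "expansion"))
  if (s$out_channels != s$expansion * s$mid_channels)
    stop("out_channels must equal expansion * mid_channels")
  s$has_projection <- s$stride != 1L || s$in_channels != s$out_channels
  structure(s, class = "bottleneck_spec")
}

#' Specification of a ghost module
#'
#' A ghost module computes only `out_channels / ratio_s` channels with a dense
#' pointwise convolution and synthesizes the remaining channels from them with
#' a cheap depthwise convolution, concatenating both halves.
#'
#' @param in_channels,out_channels Channel counts; `out_channels` must be
#'   divisible by `ratio_s`.
#' @param ratio_s Integer >= 2: fraction of channels produced by the primary
#'   convolution is `1 / ratio_s`.
#' @param cheap_kernel_d Odd depthwise kernel of the cheap operation.
#' @param stride Stride of the primary convolution.
#' @return A `ghost_module_spec` list.
#' @export
ghost_module_spec <- function(in_channels, out_channels, ratio_s = 2,
                              cheap_kernel_d = 3, stride = 1) {
  s <- list(in_channels = chk_posint(in_channels, "in_channels"),
            out_channels = chk_posint(out_channels, "out_channels"),
            ratio_s = chk_posint(ratio_s, "ratio_s"),
            cheap_kernel_d = chk_posint(cheap_kernel_d, "cheap_kernel_d"),
            stride = chk_posint(stride, "stride"))
  if (s$ratio_s < 2) stop("ratio_s must be at least 2")
  if (s$out_channels %% s$ratio_s != 0)
    stop("out_channels must be divisible by ratio_s")
  if (s$cheap_kernel_d %% 2 == 0) stop("cheap_kernel_d must be odd")
  s$primary_channels <- s$out_channels %/% s$ratio_s
  structure(s, class = "ghost_module_spec")
}

#' Specification of a GhostBottleneck
#'
#' Ghost expansion module -> optional strided depthwise step -> ghost
#' projection module, with an additive shortcut (identity when the shape is
#' preserved, otherwise a depthwise + pointwise projection).
#'
#' @param in_channels,hidden_channels,out_channels Channel widths of input,
#'   expanded interior and output.
#' @param stride 1 (shape preserving) or 2 (downsampling).
#' @param ratio_s,cheap_kernel_d Ghost-module parameters for both halves.
#' @return A `ghost_bottleneck_spec` list with derived `shortcut` kind.
#' @export
ghost_bottleneck_spec <- function(in_channels, hidden_channels, out_channels,
                                  stride = 1, ratio_s = 2, cheap_kernel_d = 3) {
  s <- list(in_channels = chk_posint(in_channels, "in_channels"),
            hidden_channels = chk_posint(hidden_channels, "hidden_channels"),
            out_channels = chk_posint(out_channels, "out_channels"),
            stride = chk_posint(stride, "stride"),
            ratio_s = chk_posint(ratio_s, "ratio_s"),
            cheap_kernel_d = chk_posint(cheap_kernel_d, "cheap_kernel_d"))
  if (!s$stride %in% c(1L, 2L)) stop("stride must be 1 or 2")
  s$expand <- ghost_module_spec(s$in_channels, s$hidden_channels,
                                s$ratio_s, s$cheap_kernel_d)
  s$project <- ghost_module_spec(s$hidden_channels, s$out_channels,
                                 s$ratio_s, s$cheap_kernel_d)
  s$shortcut <- if (s$stride == 1L && s$in_channels == s$out_channels)
    "identity" else "projection"
  structure(s, class = "ghost_bottleneck_spec")
}

#' Specification of a channel + spatial attention block (CBAM)
#'
#' @param channels Feature-map channels; must be divisible by `reduction_r`.
#' @param reduction_r Bottleneck reduction of the shared channel-attention
#'   mapping.
#' @param spatial_kernel Odd kernel of the spatial-attention convolution.
#' @return A `cbam_spec` list.
#' @export
cbam_spec <- function(channels, reduction_r = 16, spatial_kernel = 7) {
  s <- list(channels = chk_posint(channels, "channels"),
            reduction_r = chk_posint(reduction_r, "reduction_r"),
            spatial_kernel = chk_posint(spatial_kernel, "spatial_kernel"))
  if (s$channels %% s$reduction_r != 0)
    stop("channels must be divisible by reduction_r")
  if (s$spatial_kernel %% 2 == 0) stop("spatial_kernel must be odd")
  structure(s, class = "cbam_spec")
}

#' Specification of one trunk stage
#'
#' A stage is an entry bottleneck (which sets the stage width and, except in
#' the first stage, halves the spatial resolution), a run of shape-preserving
#' GhostBottlenecks, an optional identity-shaped exit bottleneck, and an
#' attention block applied to the stage output.
#'
#' @param in_channels Channels entering the stage.
#' @param width Pre-expansion width of the stage bottlenecks.
#' @param n_ghost Number of GhostBottlenecks between entry and exit.
#' @param stride Stride of the entry bottleneck.
#' @param expansion Bottleneck expansion factor.
#' @param keep_exit Whether the identity-shaped exit bottleneck is present.
#' @param ghost_ratio,ghost_kernel Ghost-module parameters.
#' @param attention A [cbam_spec()] or `NULL`.
#' @return A `stage_spec` list; `$out_channels` is the stage output width.
#' @export
stage_spec <- function(in_channels, width, n_ghost, stride = 2, expansion = 4,
                       keep_exit = TRUE, ghost_ratio = 2, ghost_kernel = 3,
                       attention = NULL) {
  out_ch <- chk_posint(width, "width") * chk_posint(expansion, "expansion")
  entry <- bottleneck_spec(in_channels, width, out_ch, stride = stride,
                           expansion = expansion)
  ghosts <- list()
  n_ghost <- as.integer(n_ghost)
  if (n_ghost < 0) stop("n_ghost must be >= 0")
  # the ghost interior contracts by half: with the stage already expanded
  # 4x by its entry bottleneck, a contracting hidden width keeps every
  # GhostBottleneck strictly cheaper than the standard mid-stage bottleneck
  # it stands in for, at every stage width
  if (n_ghost > 0)
    ghosts <- replicate(n_ghost, ghost_bottleneck_spec(
      out_ch, out_ch %/% 2L, out_ch, stride = 1,
      ratio_s = ghost_ratio, cheap_kernel_d = ghost_kernel),
      simplify = FALSE)
  exitb <- if (isTRUE(keep_exit))
    bottleneck_spec(out_ch, width, out_ch, stride = 1, expansion = expansion)
  if (!is.null(attention) && attention$channels != out_ch)
    stop("attention channels must equal stage output channels")
  structure(list(entry = entry, ghosts = ghosts, exit = exitb,
                 attention = attention, width = as.integer(width),
                 n_ghost = n_ghost, out_channels = out_ch),
            class = "stage_spec")
}

#' Full declarative model configuration
#'
#' Describes the three-stage reduced residual trunk: a stem convolution
#' (dilated in the final model), three stages of entry bottleneck +
#' GhostBottlenecks + optional exit bottleneck, per-stage attention, and a
#' global-average-pool + fully-connected head.
#'
#' Invariants enforced: exactly three stages, non-decreasing stage widths, and
#' non-decreasing ghost counts (ghost capacity is added incrementally with
#' depth, following the rule that later stages carry more feature maps).
#'
#' @param num_classes Number of identities in the classification head.
#' @param stage_widths Pre-expansion widths of the three stages
#'   (non-decreasing).
#' @param ghost_counts GhostBottlenecks per stage (non-decreasing).
#' @param expansion Bottleneck expansion factor.
#' @param stem_width Stem output channels (defaults to `stage_widths[1]`).
#' @param stem_kernel,stem_dilation Stem convolution geometry. The final model
#'   uses a 3x3 kernel with dilation 3 (effective receptive field 7); the
#'   plain variant uses a 7x7 kernel with dilation 1.
#' @param stem_pool Whether a 3x3/stride-2 max pool follows the stem.
#' @param keep_exit_bottleneck Keep the identity-shaped exit bottleneck in
#'   each stage.
#' @param ghost_ratio,ghost_kernel Ghost-module ratio `s` and cheap depthwise
#'   kernel `d`.
#' @param use_cbam Insert an attention block after every stage.
#' @param cbam_reduction,cbam_spatial_kernel Attention-block parameters.
#' @param input_side Expected input image side in pixels.
#' @return A `gh_model_config` object consumable by [assemble_model()].
#' @export
model_config <- function(num_classes = 13,
                         stage_widths = c(64, 128, 256),
                         ghost_counts = c(1, 2, 3),
                         expansion = 4,
                         stem_width = stage_widths[1],
                         stem_kernel = 3, stem_dilation = 3,
                         stem_pool = TRUE,
                         keep_exit_bottleneck = TRUE,
                         ghost_ratio = 2, ghost_kernel = 3,
                         use_cbam = TRUE,
                         cbam_reduction = 16, cbam_spatial_kernel = 7,
                         input_side = 224) {
  if (length(stage_widths) != 3 || length(ghost_counts) != 3)
    stop("the trunk has exactly three stages")
  if (any(diff(stage_widths) < 0))
    stop("stage widths must be non-decreasing")
  if (any(diff(ghost_counts) < 0))
    stop("ghost counts must be non-decreasing across stages")
  stem <- conv_spec(stem_kernel, 3, stem_width, stride = 2,
                    dilation = stem_dilation)
  stages <- vector("list", 3)
  in_ch <- as.integer(stem_width)
  for (i in 1:3) {
    att <- if (isTRUE(use_cbam))
      cbam_spec(stage_widths[i] * expansion, cbam_reduction,
                cbam_spatial_kernel)
    stages[[i]] <- stage_spec(in_ch, stage_widths[i], ghost_counts[i],
                              stride = if (i == 1) 1 else 2,
                              expansion = expansion,
                              keep_exit = keep_exit_bottleneck,
                              ghost_ratio = ghost_ratio,
                              ghost_kernel = ghost_kernel,
                              attention = att)
    in_ch <- stages[[i]]$out_channels
  }
  structure(list(stem = stem, stem_pool = isTRUE(stem_pool),
                 stages = stages,
                 num_classes = chk_posint(num_classes, "num_classes"),
                 head_channels = in_ch,
                 input_side = chk_posint(input_side, "input_side"),
                 options = list(stage_widths = as.integer(stage_widths),
                                ghost_counts = as.integer(ghost_counts),
                                expansion = as.integer(expansion),
                                stem_width = as.integer(stem_width),
                                stem_kernel = as.integer(stem_kernel),
                                stem_dilation = as.integer(stem_dilation),
                                stem_pool = isTRUE(stem_pool),
                                keep_exit_bottleneck = isTRUE(keep_exit_bottleneck),
                                ghost_ratio = as.integer(ghost_ratio),
                                ghost_kernel = as.integer(ghost_kernel),
                                use_cbam = isTRUE(use_cbam),
                                cbam_reduction = as.integer(cbam_reduction),
                                cbam_spatial_kernel = as.integer(cbam_spatial_kernel))),
            class = "gh_model_config")
}

#' Desk-scale model configuration
#'
#' A narrow preset of the same three-stage architecture (widths 16/32/64
#' pre-expansion, ghost counts 1/2/3, 48-pixel inputs) sized so that the full
#' training recipe runs end-to-end on one CPU core in minutes. Used for the
#' synthetic-herd sanity runs.
#'
#' @param num_classes Number of identities.
#' @return A `gh_model_config`.
#' @export
desk_model_config <- function(num_classes = 13) {
  model_config(num_classes = num_classes,
               stage_widths = c(16, 32, 64),
               ghost_counts = c(1, 2, 3),
               input_side = 48)
}

#' @export
print.gh_model_config <- function(x, ...) {
  o <- x$options
  cat(sprintf(
    "<gh_model_config> %d classes | stem %dx%d d=%d -> %d ch%s\n",
    x$num_classes, o$stem_kernel, o$stem_kernel, o$stem_dilation,
    o$stem_width, if (x$stem_pool) " + maxpool" else ""))
  for (i in 1:3) {
    st <- x$stages[[i]]
    cat(sprintf(
      "  stage%d: width %d (out %d), %d ghost block(s)%s%s\n",
      i, st$width, st$out_channels, st$n_ghost,
      if (!is.null(st$exit)) ", exit bottleneck" else "",
      if (!is.null(st$attention)) ", CBAM" else ""))
  }
  cat(sprintf("  head: global average pool -> fc %d -> %d\n",
              x$head_channels, x$num_classes))
  invisible(x)
}

#' Write / read a model configuration
#'
#' Configurations round-trip through JSON or YAML keyed by the
#' [model_config()] argument names.
#'
#' @param config A `gh_model_config`.
#' @param path Output file; format chosen by extension (`.json`, `.yaml`,
#'   `.yml`).
#' @return `path`, invisibly (writer); a `gh_model_config` (reader).
#' @export
write_model_config <- function(config, path) {
  stopifnot(inherits(config, "gh_model_config"))
  doc <- c(list(num_classes = config$num_classes,
                input_side = config$input_side),
           config$options)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(doc, path)
  else
    jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  doc <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::read_json(path, simplifyVector = TRUE)
  known <- union(names(formals(model_config)),
                 c("num_classes", "input_side"))
  doc <- doc[intersect(names(doc), known)]
  do.call(model_config, doc)
}
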