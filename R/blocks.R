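# ---------------------------------------------------------------------------
# The pyramid residual attention (PRA) block and its three sub-components.
#
# A PRA block processes a feature map along two branches:
#   (a) a residual unit: two (3x3 conv -> group norm -> ReLU) stages;
#   (b) 2x2/stride-2 max-pool -> multi-scale convolution pyramid (kernels
#       1/3/5/7 in parallel, channel-concatenated) -> channel attention with
#       summed global average/max pooled descriptors -> 2x2/stride-2
#       transposed convolution back to the input resolution.
# The block output is the elementwise sum of branch (b) (1x1-projected to the
# output width when needed), branch (a) (likewise projected) and an identity
# shortcut (1x1-projected when the input width differs).
# ---------------------------------------------------------------------------

#' Configuration of one PRA block
#'
#' Describes the channel plan of a single pyramid residual attention block.
#' The attention width is always `length(kernel_sizes) * branch_channels`
#' because the pyramid branches are channel-concatenated before attention.
#'
#' @param in_channels input feature-map width.
#' @param branch_channels output width of each pyramid branch.
#' @param residual_channels width of the residual unit (branch (a)).
#' @param out_channels block output width.
#' @param attention_reduction bottleneck divisor of the two attention dense
#'   layers; the hidden width is `attention_channels / attention_reduction`.
#' @param kernel_sizes odd kernel sizes of the pyramid branches.
#' @param gn_groups group count for group normalization; `NULL` picks 8 when
#'   divisible, otherwise the largest divisor not above 8.
#' @param internal_pool pooling factor of the compression inside branch (b).
#' @return a `pra_config` list.
#' @export
pra_config <- function(in_channels, branch_channels, residual_channels,
                       out_channels, attention_reduction = 2L,
                       kernel_sizes = c(1L, 3L, 5L, 7L), gn_groups = NULL,
                       internal_pool = 2L) {
  stopifnot(in_channels >= 1, branch_channels >= 1, residual_channels >= 1,
            out_channels >= 1, attention_reduction >= 1, internal_pool >= 1)
  att <- length(kernel_sizes) * branch_channels
  if (att %% attention_reduction != 0)
    stop("attention width ", att, " is not divisible by the reduction ",
         attention_reduction)
  structure(list(
    in_channels = as.integer(in_channels),
    branch_channels = as.integer(branch_channels),
    kernel_sizes = as.integer(kernel_sizes),
    attention_channels = as.integer(att),
    attention_reduction = as.integer(attention_reduction),
    residual_channels = as.integer(residual_channels),
    out_channels = as.integer(out_channels),
    gn_groups = gn_groups,
    internal_pool = as.integer(internal_pool)
  ), class = "pra_config")
}

#' @export
print.pra_config <- function(x, ...) {
  cat(sprintf(
    "<pra_config> in %d | pyramid %s -> %d | attention %d (r=%d) | residual %d | out %d\n",
    x$in_channels, paste(x$kernel_sizes, collapse = "/"),
    x$attention_channels, x$attention_channels, x$attention_reduction,
    x$residual_channels, x$out_channels))
  invisible(x)
}

as_feature_node <- function(x) {
  if (is_node(x)) return(x)
  if (is.null(dim(x)) || length(dim(x)) != 4L)
    stop("a feature map must be a 4-d (H, W, C, N) array")
  if (any(!is.finite(x))) stop("feature map contains non-finite values")
  pr_node(x)
}

maybe_value <- function(node, was_array) if (was_array) node$value else node

# --- multi-scale convolution pyramid -----------------------------------------

new_pyramid <- function(in_channels, branch_channels,
                        kernel_sizes = c(1L, 3L, 5L, 7L)) {
  convs <- lapply(kernel_sizes, function(k)
    layer_conv2d(in_channels, branch_channels, k))
  structure(list(convs = convs, in_channels = as.integer(in_channels),
                 branch_channels = as.integer(branch_channels),
                 kernel_sizes = as.integer(kernel_sizes)),
            class = "pra_pyramid")
}

#' Multi-scale convolution pyramid
#'
#' Runs the input through parallel stride-1 convolutions of kernel sizes
#' 1/3/5/7 (same-padded so the spatial size is preserved) and concatenates
#' the branch outputs channel-wise in kernel-size order.
#'
#' @param block a pyramid created inside a PRA block (or via the block
#'   builders); carries one convolution per kernel size.
#' @param x feature map, `(H, W, C, N)` array or internal graph node.
#' @return feature map with `length(kernel_sizes) * branch_channels` channels
#'   and the input spatial size; an array when `x` was an array.
#' @export
pyramid_conv <- function(block, x) {
  was_array <- !is_node(x)
  xn <- as_feature_node(x)
  d <- dim(xn$value)
  if (d[3] != block$in_channels)
    stop("pyramid expects ", block$in_channels, " input channels, got ", d[3])
  if (d[1] < 1 || d[2] < 1) stop("empty spatial dimensions")
  outs <- lapply(block$convs, function(cv) fwd_conv2d(cv, xn))
  out <- Reduce(op_concat_channels, outs)
  maybe_value(out, was_array)
}

# --- channel attention -------------------------------------------------------

new_channel_attention <- function(channels, reduction = 2L) {
  hidden <- channels %/% reduction
  stopifnot(hidden >= 1)
  structure(list(
    k1 = layer_linear(channels, hidden),
    k2 = layer_linear(hidden, channels),
    channels = as.integer(channels), reduction = as.integer(reduction)
  ), class = "pra_attention")
}

#' Channel attention with summed pooled descriptors
#'
#' Computes per-channel gates
#' `Y = sigmoid(k2 (k1 (P_gavg(x) + P_gmax(x)) + b1) + b2)`
#' — the global average-pooled and global max-pooled channel descriptors are
#' summed *before* the shared two-layer bottleneck — and returns
#' `Out = Y (x) x + x`, where `(x)` is per-channel broadcast multiplication.
#'
#' @param block a channel-attention block (`new_channel_attention`), holding
#'   the dense layers `k1`/`k2` with their biases.
#' @param x feature map whose channel width matches `block$channels`.
#' @return list with `weights` (a `(C, N)` matrix of gates, strictly inside
#'   (0, 1)) and `out` (the reweighted feature map plus the identity term).
#'   Arrays in, arrays out.
#' @export
channel_attention <- function(block, x) {
  was_array <- !is_node(x)
  xn <- as_feature_node(x)
  d <- dim(xn$value)
  if (d[3] != block$channels)
    stop("attention expects ", block$channels, " channels, got ", d[3])
  pooled <- op_add(op_gavg(xn), op_gmax(xn))
  y <- op_sigmoid(fwd_linear(block$k2, fwd_linear(block$k1, pooled)))
  out <- op_add(op_scale_channels(xn, y), xn)
  list(weights = maybe_value(y, was_array), out = maybe_value(out, was_array))
}

# --- residual unit -----------------------------------------------------------

new_residual_unit <- function(in_channels, out_channels, gn_groups = NULL) {
  g <- if (is.null(gn_groups)) gn_groups_for(out_channels) else as.integer(gn_groups)
  if (out_channels %% g != 0)
    stop("gn_groups ", g, " does not divide residual width ", out_channels)
  structure(list(
    conv1 = layer_conv2d(in_channels, out_channels, 3L, gain = 2),
    gn1 = layer_groupnorm(out_channels, g),
    conv2 = layer_conv2d(out_channels, out_channels, 3L, gain = 2),
    gn2 = layer_groupnorm(out_channels, g),
    in_channels = as.integer(in_channels), out_channels = as.integer(out_channels)
  ), class = "pra_residual_unit")
}

#' Group-normalized residual unit
#'
#' Two stages of (3x3 convolution, group normalization, ReLU); preserves the
#' spatial size and maps the input to `out_channels` channels.
#'
#' @param block a residual unit (`new_residual_unit`).
#' @param x feature map.
#' @return feature map of the unit's output width.
#' @export
residual_unit <- function(block, x) {
  was_array <- !is_node(x)
  xn <- as_feature_node(x)
  if (dim(xn$value)[3] != block$in_channels)
    stop("residual unit expects ", block$in_channels, " input channels, got ",
         dim(xn$value)[3])
  h <- op_relu(fwd_groupnorm(block$gn1, fwd_conv2d(block$conv1, xn)))
  h <- op_relu(fwd_groupnorm(block$gn2, fwd_conv2d(block$conv2, h)))
  maybe_value(h, was_array)
}

# --- the full PRA block ------------------------------------------------------

#' Build a pyramid residual attention block
#'
#' @param cfg a [pra_config()].
#' @param variant one of `"full"`, `"PM"`, `"CA"`, `"Res"`. The ablation
#'   variants replace the named sub-component with a plain 3x3 convolution of
#'   matching input/output widths: `"PM"` swaps the pyramid, `"CA"` swaps the
#'   attention gating (so no sigmoid gate remains), and `"Res"` swaps the
#'   two-stage residual unit *and* drops the identity shortcut around the
#'   block body.
#' @return a `pra_block` whose weights are freshly initialized from the
#'   current RNG stream.
#' @export
new_pra_block <- function(cfg, variant = c("full", "PM", "CA", "Res")) {
  variant <- match.arg(variant)
  A <- cfg$attention_channels
  blk <- list(cfg = cfg, variant = variant)
  blk$branch_a <- if (variant == "Res")
    layer_conv2d(cfg$in_channels, cfg$residual_channels, 3L)
  else
    new_residual_unit(cfg$in_channels, cfg$residual_channels, cfg$gn_groups)
  blk$pyramid <- if (variant == "PM")
    layer_conv2d(cfg$in_channels, A, 3L)
  else
    new_pyramid(cfg$in_channels, cfg$branch_channels, cfg$kernel_sizes)
  blk$attention <- if (variant == "CA")
    layer_conv2d(A, A, 3L)
  else
    new_channel_attention(A, cfg$attention_reduction)
  blk$deconv <- layer_convT(A, A, cfg$internal_pool)
  if (A != cfg$out_channels)
    blk$proj_b <- layer_conv2d(A, cfg$out_channels, 1L)
  if (cfg$residual_channels != cfg$out_channels)
    blk$proj_a <- layer_conv2d(cfg$residual_channels, cfg$out_channels, 1L)
  if (variant != "Res" && cfg$in_channels != cfg$out_channels)
    blk$shortcut <- layer_conv2d(cfg$in_channels, cfg$out_channels, 1L)
  structure(blk, class = "pra_block")
}

#' Forward pass of a PRA block
#'
#' @param block a [new_pra_block()].
#' @param x feature map with the block's input width; `H` and `W` must be
#'   divisible by the block's internal pooling factor.
#' @param return_attention also return branch (b)'s attention-weighted output
#'   after size recovery (the tensor the network's intra-level skip consumes).
#' @return the block output (same spatial size as the input, `out_channels`
#'   wide), or a list `(out, attention_out)` when `return_attention = TRUE`.
#' @export
pra_forward <- function(block, x, return_attention = FALSE) {
  was_array <- !is_node(x)
  xn <- as_feature_node(x)
  cfg <- block$cfg
  d <- dim(xn$value)
  if (d[3] != cfg$in_channels)
    stop("PRA block expects ", cfg$in_channels, " input channels, got ", d[3])
  if (d[1] %% cfg$internal_pool != 0 || d[2] %% cfg$internal_pool != 0)
    stop("spatial size ", d[1], "x", d[2], " is not divisible by the internal ",
         "pooling factor ", cfg$internal_pool, "; pad or resize the input")
  # branch (a)
  a <- if (block$variant == "Res") fwd_conv2d(block$branch_a, xn)
       else residual_unit(block$branch_a, xn)
  # branch (b)
  b <- op_maxpool(xn, cfg$internal_pool)
  b <- if (block$variant == "PM") fwd_conv2d(block$pyramid, b)
       else pyramid_conv(block$pyramid, b)
  b <- if (block$variant == "CA") fwd_conv2d(block$attention, b)
       else channel_attention(block$attention, b)$out
  b <- fwd_convT(block$deconv, b)
  att_out <- b
  if (!is.null(block$proj_b)) b <- fwd_conv2d(block$proj_b, b)
  if (!is.null(block$proj_a)) a <- fwd_conv2d(block$proj_a, a)
  out <- op_add(b, a)
  if (block$variant != "Res") {
    sc <- if (!is.null(block$shortcut)) fwd_conv2d(block$shortcut, xn) else xn
    out <- op_add(out, sc)
  }
  if (return_attention)
    list(out = maybe_value(out, was_array),
         attention_out = maybe_value(att_out, was_array))
  else maybe_value(out, was_array)
}

#' Build an ablation variant of the PRA block
#'
#' @param which which sub-component to replace: `"PM"` (pyramid module),
#'   `"CA"` (channel attention) or `"Res"` (residual mechanism).
#' @param cfg a [pra_config()].
#' @return a `pra_block` with the named sub-component replaced by a plain
#'   3x3 convolution of matching widths.
#' @export
make_ablation_variant <- function(which, cfg) {
  if (!is.character(which) || length(which) != 1L ||
      !(which %in% c("PM", "CA", "Res")))
    stop("unknown ablation variant; use one of \"PM\", \"CA\", \"Res\"")
  new_pra_block(cfg, variant = which)
}

#' Default channel plans of the five PRA positions
#'
#' One configuration per network position (left/right shallow, left/right
#' middle, deep). Pyramid branch widths follow the published plan
#' (8/16/32/64/128); residual and output widths are the package's calibrated
#' defaults. `width_scale` divides every width (used for CPU-scale networks).
#'
#' @param width_scale integer divisor applied to all widths.
#' @param in_channels width of the network input (3 for RGB).
#' @return named list of [pra_config()] objects.
#' @export
default_pra_configs <- function(width_scale = 1L, in_channels = 3L) {
  sc <- function(w) max(1L, as.integer(w / width_scale))
  list(
    left_shallow = pra_config(in_channels, sc(8), sc(96), sc(64)),
    right_shallow = pra_config(sc(64), sc(16), sc(192), sc(128)),
    left_middle = pra_config(5L * sc(32), sc(32), sc(192), sc(64)),
    right_middle = pra_config(sc(64), sc(64), sc(320), sc(384)),
    deep = pra_config(7L * sc(64), sc(128), sc(512), sc(512))
  )
}

#' Serialize / read block configurations
#'
#' Writes the per-position channel plan to a YAML file and reads it back.
#'
#' @param configs named list of [pra_config()] objects.
#' @param path file path.
#' @return `read_block_configs` returns the named list of configs.
#' @export
write_block_configs <- function(configs, path) {
  plain <- lapply(configs, function(cf)
    lapply(unclass(cf)[c("in_channels", "branch_channels", "kernel_sizes",
                         "attention_reduction", "residual_channels",
                         "out_channels", "internal_pool")], identity))
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_block_configs
#' @export
read_block_configs <- function(path) {
  plain <- yaml::read_yaml(path)
  lapply(plain, function(cf)
    pra_config(cf$in_channels, cf$branch_channels, cf$residual_channels,
               cf$out_channels, cf$attention_reduction,
               as.integer(unlist(cf$kernel_sizes)),
               internal_pool = cf$internal_pool))
}
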