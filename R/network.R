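# ---------------------------------------------------------------------------
# Assembly of PRA blocks into networks.
#
# The three-level PRAN: shallow and middle levels each chain two PRA blocks;
# the first block's attention-weighted branch output feeds an intra-level
# skip (3x3 conv) that is concatenated into the second block's output, the
# concatenation is reweighted by a channel-attention stage, and the result
# both descends to the next level (two stride-2 max-pools, a 4x per-dimension
# reduction) and waits for the lower level's output (4x transposed-conv
# upsample) to be fused back by the level's 3x3 post-process convolution.
# The deep level is a single PRA block. A 1x1 convolution plus sigmoid head
# emits a probability map at the input resolution.
# ---------------------------------------------------------------------------

scale_w <- function(w, width_scale) max(1L, as.integer(w / width_scale))

#' Network spec for the three-level PRAN
#'
#' Collects the five per-position PRA configurations plus the widths of the
#' glue layers (intra-level skip convolutions, post-process convolutions,
#' inter-level fusion upsamples) and the inter-level pooling factor.
#'
#' @param width_scale integer divisor applied to every width; 1 gives the
#'   full-size network, 8 the CPU-scale one used in tests.
#' @param in_channels network input width (3 for RGB).
#' @return a `pran_spec` list.
#' @export
pran_spec <- function(width_scale = 1L, in_channels = 3L) {
  sc <- function(w) scale_w(w, width_scale)
  cfgs <- default_pra_configs(width_scale, in_channels)
  structure(list(
    configs = cfgs,
    skip_shallow = sc(32), skip_middle = sc(64),
    up_deep = sc(384), up_middle = sc(192),
    post_middle = sc(256), post_shallow = sc(256),
    inter_level_pool = 4L, num_classes = 1L,
    width_scale = as.integer(width_scale), in_channels = as.integer(in_channels)
  ), class = "pran_spec")
}

#' Build the three-level PRAN
#'
#' @param spec a [pran_spec()].
#' @param seed integer seed for weight initialization.
#' @return a `praseg_net` of kind `"pran"`.
#' @export
build_pran <- function(spec = pran_spec(), seed = 1L) {
  set.seed(seed)
  cf <- spec$configs
  a_ls <- cf$left_shallow$attention_channels
  a_lm <- cf$left_middle$attention_channels
  o_rs <- cf$right_shallow$out_channels
  o_rm <- cf$right_middle$out_channels
  w2s_ch <- o_rs + spec$skip_shallow
  w2m_ch <- o_rm + spec$skip_middle
  net <- list(
    kind = "pran", spec = spec,
    blk_ls = new_pra_block(cf$left_shallow),
    blk_rs = new_pra_block(cf$right_shallow),
    skip_s = layer_conv2d(a_ls, spec$skip_shallow, 3L),
    att2_s = new_channel_attention(w2s_ch, cf$left_shallow$attention_reduction),
    blk_lm = new_pra_block(cf$left_middle),
    blk_rm = new_pra_block(cf$right_middle),
    skip_m = layer_conv2d(a_lm, spec$skip_middle, 3L),
    att2_m = new_channel_attention(w2m_ch, cf$left_middle$attention_reduction),
    blk_d = new_pra_block(cf$deep),
    up_dm = layer_convT(cf$deep$out_channels, spec$up_deep, 4L),
    post_m = layer_conv2d(w2m_ch + spec$up_deep, spec$post_middle, 3L),
    up_ms = layer_convT(spec$post_middle, spec$up_middle, 4L),
    post_s = layer_conv2d(w2s_ch + spec$up_middle, spec$post_shallow, 3L),
    head = layer_conv2d(spec$post_shallow, 1L, 1L, gain = 0.01),
    build_args = list(seed = seed)
  )
  if (w2s_ch != cf$left_middle$in_channels)
    stop("middle level expects ", cf$left_middle$in_channels,
         " input channels but the shallow level produces ", w2s_ch)
  if (w2m_ch != cf$deep$in_channels)
    stop("deep level expects ", cf$deep$in_channels,
         " input channels but the middle level produces ", w2m_ch)
  structure(net, class = "praseg_net")
}

# One level's two-block pass; returns the reweighted tensor feeding both the
# descent to the next level and the level's own post-processing.
level_pass <- function(blk_l, blk_r, skip_conv, att2, x) {
  r1 <- pra_forward(blk_l, x, return_attention = TRUE)
  skip <- fwd_conv2d(skip_conv, r1$attention_out)
  u2 <- pra_forward(blk_r, r1$out)
  channel_attention(att2, op_concat_channels(u2, skip))$out
}

pool4 <- function(x) op_maxpool(op_maxpool(x, 2L), 2L)

forward_pran <- function(net, xn) {
  d <- dim(xn$value)
  if (d[1] %% 16 != 0 || d[2] %% 16 != 0)
    stop("input spatial size ", d[1], "x", d[2], " is not divisible by 16")
  trace <- list(shallow = d[1:2])
  w2s <- level_pass(net$blk_ls, net$blk_rs, net$skip_s, net$att2_s, xn)
  m_in <- pool4(w2s)
  trace$middle <- dim(m_in$value)[1:2]
  w2m <- level_pass(net$blk_lm, net$blk_rm, net$skip_m, net$att2_m, m_in)
  d_in <- pool4(w2m)
  trace$deep <- dim(d_in$value)[1:2]
  d_out <- pra_forward(net$blk_d, d_in)
  m_out <- op_relu(fwd_conv2d(net$post_m,
                              op_concat_channels(w2m, fwd_convT(net$up_dm, d_out))))
  s_out <- op_relu(fwd_conv2d(net$post_s,
                              op_concat_channels(w2s, fwd_convT(net$up_ms, m_out))))
  prob <- op_sigmoid(fwd_conv2d(net$head, s_out))
  list(prob = prob, trace = trace)
}

#' Build the standalone shallow level
#'
#' The horizontally stacked pair of PRA blocks (the network's shallow level)
#' as a self-contained segmenter: two chained blocks, intra-level skip,
#' channel-attention reweighting, post-process convolution and sigmoid head.
#'
#' @param width_scale integer width divisor.
#' @param in_channels input width.
#' @param seed initialization seed.
#' @return a `praseg_net` of kind `"shallow"`.
#' @export
build_shallow_pran <- function(width_scale = 1L, in_channels = 3L, seed = 1L) {
  set.seed(seed)
  sc <- function(w) scale_w(w, width_scale)
  cf <- default_pra_configs(width_scale, in_channels)
  w2s_ch <- cf$right_shallow$out_channels + sc(32)
  net <- list(
    kind = "shallow",
    blk_ls = new_pra_block(cf$left_shallow),
    blk_rs = new_pra_block(cf$right_shallow),
    skip_s = layer_conv2d(cf$left_shallow$attention_channels, sc(32), 3L),
    att2_s = new_channel_attention(w2s_ch, 2L),
    post_s = layer_conv2d(w2s_ch, sc(256), 3L),
    head = layer_conv2d(sc(256), 1L, 1L, gain = 0.01),
    build_args = list(width_scale = width_scale, in_channels = in_channels,
                      seed = seed)
  )
  structure(net, class = "praseg_net")
}

forward_shallow <- function(net, xn) {
  d <- dim(xn$value)
  trace <- list(shallow = d[1:2])
  w2s <- level_pass(net$blk_ls, net$blk_rs, net$skip_s, net$att2_s, xn)
  prob <- op_sigmoid(fwd_conv2d(net$head, op_relu(fwd_conv2d(net$post_s, w2s))))
  list(prob = prob, trace = trace)
}

#' Build a standalone single-PRA segmenter
#'
#' One PRA block in the single-module ablation configuration (pyramid branch
#' width 32, residual width 48, output width 64, all divided by
#' `width_scale`) followed by a 1x1 convolution and sigmoid head.
#'
#' @param width_scale integer width divisor.
#' @param in_channels input width.
#' @param seed initialization seed.
#' @param variant `"full"` or an ablation variant (`"PM"`, `"CA"`, `"Res"`).
#' @return a `praseg_net` of kind `"pra_seg"`.
#' @export
build_pra_segmenter <- function(width_scale = 1L, in_channels = 3L, seed = 1L,
                                variant = "full") {
  set.seed(seed)
  sc <- function(w) scale_w(w, width_scale)
  cfg <- pra_config(in_channels, sc(32), sc(48), sc(64))
  net <- list(
    kind = "pra_seg",
    blk = new_pra_block(cfg, variant = variant),
    head = layer_conv2d(cfg$out_channels, 1L, 1L, gain = 0.01),
    build_args = list(width_scale = width_scale, in_channels = in_channels,
                      seed = seed, variant = variant)
  )
  structure(net, class = "praseg_net")
}

forward_pra_seg <- function(net, xn) {
  out <- pra_forward(net$blk, xn)
  list(prob = op_sigmoid(fwd_conv2d(net$head, out)),
       trace = list(shallow = dim(xn$value)[1:2]))
}

# --- U-Net and the PRA-bottleneck variant (PRAU) -----------------------------

double_conv <- function(in_ch, out_ch) {
  g <- gn_groups_for(out_ch)
  structure(list(
    conv1 = layer_conv2d(in_ch, out_ch, 3L, gain = 2),
    gn1 = layer_groupnorm(out_ch, g),
    conv2 = layer_conv2d(out_ch, out_ch, 3L, gain = 2),
    gn2 = layer_groupnorm(out_ch, g)
  ), class = "praseg_double_conv")
}

fwd_double_conv <- function(dc, x) {
  h <- op_relu(fwd_groupnorm(dc$gn1, fwd_conv2d(dc$conv1, x)))
  op_relu(fwd_groupnorm(dc$gn2, fwd_conv2d(dc$conv2, h)))
}

#' Build a plain 4-down/4-up U-Net or its PRA-bottleneck variant (PRAU)
#'
#' The encoder halves the resolution four times; the bottleneck is either a
#' two-convolution block (plain U-Net) or a PRA block (PRAU); the decoder
#' restores resolution with stride-2 transposed convolutions and encoder skip
#' concatenations. Head: 1x1 convolution + sigmoid.
#'
#' @param base first-level width; deeper levels double it.
#' @param in_channels input width.
#' @param seed initialization seed.
#' @param bottleneck `"conv"` for the plain U-Net, `"pra"` for PRAU.
#' @return a `praseg_net` of kind `"unet"` or `"prau"`.
#' @export
build_unet <- function(base = 16L, in_channels = 3L, seed = 1L,
                       bottleneck = c("conv", "pra")) {
  bottleneck <- match.arg(bottleneck)
  set.seed(seed)
  widths <- base * c(1L, 2L, 4L, 8L)
  bott_w <- base * 16L
  enc <- list(); inw <- in_channels
  for (i in seq_along(widths)) {
    enc[[i]] <- double_conv(inw, widths[i]); inw <- widths[i]
  }
  bott <- if (bottleneck == "conv") double_conv(inw, bott_w) else {
    cfg <- pra_config(inw, bott_w %/% 4L, bott_w, bott_w)
    if (cfg$attention_channels != bott_w)
      stop("PRA bottleneck width mismatch: attention width ",
           cfg$attention_channels, " vs bottleneck ", bott_w)
    new_pra_block(cfg)
  }
  dec <- list(); ups <- list(); inw <- bott_w
  for (i in rev(seq_along(widths))) {
    ups[[length(ups) + 1L]] <- layer_convT(inw, widths[i], 2L)
    dec[[length(dec) + 1L]] <- double_conv(widths[i] * 2L, widths[i])
    inw <- widths[i]
  }
  net <- list(
    kind = if (bottleneck == "conv") "unet" else "prau",
    enc = enc, bott = bott, ups = ups, dec = dec,
    head = layer_conv2d(widths[1], 1L, 1L, gain = 0.01),
    build_args = list(base = base, in_channels = in_channels, seed = seed,
                      bottleneck = bottleneck)
  )
  structure(net, class = "praseg_net")
}

#' @rdname build_unet
#' @export
build_prau <- function(base = 16L, in_channels = 3L, seed = 1L)
  build_unet(base, in_channels, seed, bottleneck = "pra")

forward_unet <- function(net, xn) {
  d <- dim(xn$value)
  if (d[1] %% 16 != 0 || d[2] %% 16 != 0)
    stop("input spatial size ", d[1], "x", d[2], " is not divisible by 16")
  skips <- list(); h <- xn
  for (i in seq_along(net$enc)) {
    h <- fwd_double_conv(net$enc[[i]], h)
    skips[[i]] <- h
    h <- op_maxpool(h, 2L)
  }
  trace <- list(shallow = d[1:2], deep = dim(h$value)[1:2])
  h <- if (identical(net$kind, "prau")) pra_forward(net$bott, h)
       else fwd_double_conv(net$bott, h)
  for (j in seq_along(net$ups)) {
    h <- fwd_convT(net$ups[[j]], h)
    h <- fwd_double_conv(net$dec[[j]],
                         op_concat_channels(skips[[length(skips) + 1L - j]], h))
  }
  list(prob = op_sigmoid(fwd_conv2d(net$head, h)), trace = trace)
}

#' Forward pass of any praseg network
#'
#' @param net a `praseg_net`.
#' @param x input feature map `(H, W, C, N)` array (or graph node during
#'   training).
#' @return list with `prob` — the probability map, values in (0, 1), same
#'   spatial size as the input — and `trace`, the per-level input spatial
#'   dimensions recorded during the pass.
#' @export
net_forward <- function(net, x) {
  was_array <- !is_node(x)
  xn <- as_feature_node(x)
  r <- switch(net$kind,
              pran = forward_pran(net, xn),
              shallow = forward_shallow(net, xn),
              pra_seg = forward_pra_seg(net, xn),
              unet = ,
              prau = forward_unet(net, xn),
              stop("unknown network kind: ", net$kind))
  if (was_array) r$prob <- r$prob$value
  r
}

#' Predict probability maps
#'
#' @param object a `praseg_net`.
#' @param x input array `(H, W, C, N)`.
#' @param ... unused.
#' @return probability map array `(H, W, 1, N)`.
#' @export
predict.praseg_net <- function(object, x, ...) net_forward(object, x)$prob

#' @export
print.praseg_net <- function(x, ...) {
  cat(sprintf("<praseg_net kind=%s, %s trainable parameters>\n", x$kind,
              format(count_trainable_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Architecture summary
#'
#' Per-component trainable-parameter table, mirroring the positions of the
#' published channel plan.
#'
#' @param net a `praseg_net`.
#' @return data frame with columns `component` and `parameters`, printed with
#'   a total row.
#' @export
network_summary <- function(net) {
  comps <- net[!(names(net) %in% c("kind", "spec", "build_args"))]
  comps <- comps[vapply(comps, is.list, logical(1))]
  rows <- data.frame(
    component = names(comps),
    parameters = vapply(comps, count_trainable_parameters, numeric(1)),
    row.names = NULL)
  rows <- rbind(rows, data.frame(component = "TOTAL",
                                 parameters = count_trainable_parameters(net)))
  rows
}

#' Serialize / read a PRAN network spec
#'
#' Writes the three-level assembly (per-position block configs plus glue
#' widths) to YAML, so alternative wirings can be swapped without code
#' changes.
#'
#' @param spec a [pran_spec()].
#' @param path YAML file path.
#' @return `read_pran_spec` returns the `pran_spec`.
#' @export
write_pran_spec <- function(spec, path) {
  plain <- unclass(spec)
  plain$configs <- lapply(plain$configs, function(cf)
    unclass(cf)[c("in_channels", "branch_channels", "kernel_sizes",
                  "attention_reduction", "residual_channels", "out_channels",
                  "internal_pool")])
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_pran_spec
#' @export
read_pran_spec <- function(path) {
  plain <- yaml::read_yaml(path)
  spec <- pran_spec(plain$width_scale, plain$in_channels)
  for (f in c("skip_shallow", "skip_middle", "up_deep", "up_middle",
              "post_middle", "post_shallow"))
    spec[[f]] <- as.integer(plain[[f]])
  spec$configs <- lapply(plain$configs, function(cf)
    pra_config(cf$in_channels, cf$branch_channels, cf$residual_channels,
               cf$out_channels, cf$attention_reduction,
               as.integer(unlist(cf$kernel_sizes)),
               internal_pool = cf$internal_pool))
  spec
}

#' Save / load network checkpoints
#'
#' A checkpoint stores the network kind, the arguments needed to rebuild its
#' architecture and every weight tensor. Loading rebuilds the architecture
#' and restores the weights, so a loaded network evaluates identically to the
#' saved one.
#'
#' @param net a `praseg_net`.
#' @param path file path (`.rds`).
#' @return `load_checkpoint` returns the rebuilt `praseg_net`.
#' @export
save_checkpoint <- function(net, path) {
  spec <- if (net$kind == "pran") net$spec else NULL
  saveRDS(list(kind = net$kind, build_args = net$build_args, spec = spec,
               state = state_dict(net)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  net <- switch(ck$kind,
    pran = build_pran(ck$spec, seed = ck$build_args$seed),
    shallow = do.call(build_shallow_pran, ck$build_args),
    pra_seg = do.call(build_pra_segmenter, ck$build_args),
    unet = ,
    prau = do.call(build_unet, ck$build_args),
    stop("unknown checkpoint kind: ", ck$kind))
  load_state_dict(net, ck$state)
  net
}
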