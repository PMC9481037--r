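# Layer constructors. A layer is a plain list tagged with a class; its weights
# are pr_param nodes (environments), so reference identity survives nesting.
# Initialization is Kaiming fan-in with zero biases, drawn from the current
# RNG stream so builders can seed once at network construction.

# He initialization (gain 2) ahead of rectifiers, Xavier-style gain 1 for
# purely linear layers, so activation variance stays bounded through the
# many additive recombinations.
kaiming <- function(dims, fan_in, gain = 1) {
  array(stats::rnorm(prod(dims), sd = sqrt(gain / fan_in)), dim = dims)
}

layer_conv2d <- function(in_ch, out_ch, k, pad = k %/% 2L, gain = 1) {
  structure(list(
    w = pr_param(kaiming(c(k, k, in_ch, out_ch), fan_in = k * k * in_ch,
                         gain = gain)),
    b = pr_param(numeric(out_ch)),
    k = as.integer(k), pad = as.integer(pad),
    in_ch = as.integer(in_ch), out_ch = as.integer(out_ch)
  ), class = "pr_conv2d")
}

layer_convT <- function(in_ch, out_ch, stride) {
  structure(list(
    w = pr_param(kaiming(c(stride, stride, in_ch, out_ch), fan_in = in_ch)),
    b = pr_param(numeric(out_ch)),
    stride = as.integer(stride),
    in_ch = as.integer(in_ch), out_ch = as.integer(out_ch)
  ), class = "pr_convT")
}

layer_linear <- function(in_f, out_f) {
  structure(list(
    w = pr_param(kaiming(c(out_f, in_f), fan_in = in_f)),
    b = pr_param(numeric(out_f)),
    in_f = as.integer(in_f), out_f = as.integer(out_f)
  ), class = "pr_linear")
}

# Group count: 8 when divisible, else the largest divisor of C not above 8.
gn_groups_for <- function(C, preferred = 8L) {
  g <- min(preferred, C)
  while (C %% g != 0L) g <- g - 1L
  as.integer(g)
}

layer_groupnorm <- function(C, groups = gn_groups_for(C), eps = 1e-5) {
  if (C %% groups != 0L)
    stop("group count ", groups, " does not divide channel width ", C)
  structure(list(
    gamma = pr_param(rep(1, C)),
    beta = pr_param(numeric(C)),
    groups = as.integer(groups), eps = eps, C = as.integer(C)
  ), class = "pr_groupnorm")
}

fwd_conv2d <- function(layer, x) op_conv2d(x, layer$w, layer$b, layer$pad)
fwd_convT <- function(layer, x) op_convT(x, layer$w, layer$b, layer$stride)
fwd_linear <- function(layer, x) op_linear(x, layer$w, layer$b)
fwd_groupnorm <- function(layer, x)
  op_groupnorm(x, layer$gamma, layer$beta, layer$groups, layer$eps)

# Recursively collect every pr_param inside a nested layer/network list.
collect_params <- function(obj) {
  out <- list()
  walk <- function(o) {
    if (is_node(o)) {
      if (isTRUE(o$requires_grad)) out[[length(out) + 1L]] <<- o
    } else if (is.list(o)) {
      for (el in o) walk(el)
    }
  }
  walk(obj)
  out
}

#' Count independently trainable scalar weights
#'
#' Walks a block or network and sums the lengths of every trainable weight
#' array (convolution kernels, biases, normalization affine parameters,
#' dense-layer matrices). Buffers and recorded statistics are not counted.
#' The count is purely structural: it does not depend on weight values or on
#' any forward pass having been run.
#'
#' @param block_or_network any praseg block or network object.
#' @return integer scalar, the number of trainable parameters.
#' @export
count_trainable_parameters <- function(block_or_network) {
  ps <- collect_params(block_or_network)
  ids <- vapply(ps, function(p) p$id, integer(1))
  ps <- ps[!duplicated(ids)]
  sum(vapply(ps, function(p) length(p$value), numeric(1)))
}

# Flatten parameter values to a named list (checkpointing) and restore them.
state_dict <- function(obj) {
  ps <- collect_params(obj)
  ids <- vapply(ps, function(p) p$id, integer(1))
  ps <- ps[!duplicated(ids)]
  lapply(ps, function(p) p$value)
}

load_state_dict <- function(obj, state) {
  ps <- collect_params(obj)
  ids <- vapply(ps, function(p) p$id, integer(1))
  ps <- ps[!duplicated(ids)]
  if (length(ps) != length(state))
    stop("checkpoint has ", length(state), " tensors but the model expects ",
         length(ps))
  for (i in seq_along(ps)) {
    if (length(ps[[i]]$value) != length(state[[i]]))
      stop("checkpoint tensor ", i, " has length ", length(state[[i]]),
           " but the model expects ", length(ps[[i]]$value))
    v <- state[[i]]
    dim(v) <- dim_or_len(ps[[i]]$value)
    if (is.null(dim(ps[[i]]$value))) v <- as.numeric(state[[i]])
    ps[[i]]$value <- v
  }
  invisible(obj)
}
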