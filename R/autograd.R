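#' @useDynLib praseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# Reverse-mode automatic differentiation on a dynamic graph.
#
# Every value flowing through a network is a `pr_node`: an environment holding
# the numeric array, an optional gradient, the parent nodes and a closure that
# maps the node's output gradient to a list of parent gradients. Environments
# give reference semantics, so parameter nodes stored inside layer lists keep
# their identity across forward passes and optimizer steps.
# ---------------------------------------------------------------------------

node_counter <- local({ i <- 0L; function() { i <<- i + 1L; i } })

pr_node <- function(value, parents = list(), backward = NULL,
                    requires_grad = FALSE) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$parents <- parents
  e$backward <- backward
  e$requires_grad <- requires_grad
  e$id <- node_counter()
  class(e) <- "pr_node"
  e
}

#' Create a trainable parameter node
#'
#' @param value numeric array holding the initial weights.
#' @return a `pr_node` with `requires_grad = TRUE`.
#' @keywords internal
pr_param <- function(value) pr_node(value, requires_grad = TRUE)

is_node <- function(x) inherits(x, "pr_node")

node_value <- function(x) if (is_node(x)) x$value else x

accumulate_grad <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

# Topological order by depth-first search over parents, then reverse sweep.
backward_pass <- function(loss) {
  stopifnot(is_node(loss), length(loss$value) == 1L)
  order <- list()
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = loss, stage = 1L))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nd <- top$node
    key <- as.character(nd$id)
    if (top$stage == 1L) {
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = nd, stage = 2L)
      for (p in nd$parents)
        if (is.null(seen[[as.character(p$id)]]))
          stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
    } else {
      order[[length(order) + 1L]] <- nd
    }
  }
  loss$grad <- array(1, dim = dim_or_len(loss$value))
  for (i in rev(seq_along(order))) {
    nd <- order[[i]]
    if (is.null(nd$backward) || is.null(nd$grad)) next
    gs <- nd$backward(nd$grad)
    for (j in seq_along(nd$parents)) {
      g <- gs[[j]]
      if (!is.null(g)) accumulate_grad(nd$parents[[j]], g)
    }
  }
  invisible(loss)
}

dim_or_len <- function(x) if (is.null(dim(x))) length(x) else dim(x)

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# ---------------------------------------------------------------------------
# Differentiable operations. Feature maps are (H, W, C, N) arrays; pooled
# channel descriptors are (C, N) matrices.
# ---------------------------------------------------------------------------

op_conv2d <- function(x, w, b, pad) {
  xv <- x$value; wv <- w$value; bv <- b$value
  out <- cpp_conv2d_fwd(xv, wv, bv, as.integer(pad))
  pr_node(out, parents = list(x, w, b), backward = function(g) {
    r <- cpp_conv2d_bwd(xv, wv, g, as.integer(pad))
    list(r$gx, r$gw, as.numeric(r$gb))
  })
}

op_convT <- function(x, w, b, stride) {
  xv <- x$value; wv <- w$value
  out <- cpp_convT_fwd(xv, wv, b$value, as.integer(stride))
  pr_node(out, parents = list(x, w, b), backward = function(g) {
    r <- cpp_convT_bwd(xv, wv, g, as.integer(stride))
    list(r$gx, r$gw, as.numeric(r$gb))
  })
}

op_maxpool <- function(x, k = 2L) {
  d <- dim(x$value)
  if (d[1] %% k != 0 || d[2] %% k != 0)
    stop("spatial dimensions (", d[1], "x", d[2],
         ") are not divisible by the pooling factor ", k)
  r <- cpp_maxpool_fwd(x$value, as.integer(k))
  pr_node(r$value, parents = list(x), backward = function(g) {
    list(cpp_maxpool_bwd(r$argmax, g, as.integer(d)))
  })
}

op_relu <- function(x) {
  mask <- x$value > 0
  pr_node(x$value * mask, parents = list(x),
          backward = function(g) list(g * mask))
}

op_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$value))
  pr_node(s, parents = list(x), backward = function(g) list(g * s * (1 - s)))
}

op_add <- function(x, y) {
  pr_node(x$value + y$value, parents = list(x, y),
          backward = function(g) list(g, g))
}

op_concat_channels <- function(x, y) {
  dx <- dim(x$value); dy <- dim(y$value)
  stopifnot(all(dx[c(1, 2, 4)] == dy[c(1, 2, 4)]))
  v <- array(0, dim = c(dx[1], dx[2], dx[3] + dy[3], dx[4]))
  v[, , seq_len(dx[3]), ] <- x$value
  v[, , dx[3] + seq_len(dy[3]), ] <- y$value
  pr_node(v, parents = list(x, y), backward = function(g) {
    list(g[, , seq_len(dx[3]), , drop = FALSE],
         g[, , dx[3] + seq_len(dy[3]), , drop = FALSE])
  })
}

# Global average pooling: (H,W,C,N) -> (C,N)
op_gavg <- function(x) {
  d <- dim(x$value)
  m <- matrix(x$value, nrow = d[1] * d[2])
  v <- matrix(colMeans(m), nrow = d[3], ncol = d[4])
  pr_node(v, parents = list(x), backward = function(g) {
    gr <- matrix(rep(as.numeric(g), each = d[1] * d[2]) / (d[1] * d[2]),
                 nrow = d[1] * d[2])
    list(array(gr, dim = d))
  })
}

# Global max pooling: (H,W,C,N) -> (C,N)
op_gmax <- function(x) {
  d <- dim(x$value)
  m <- matrix(x$value, nrow = d[1] * d[2])
  idx <- max.col(t(m), ties.method = "first")         # argmax per (c,n) column
  v <- matrix(m[cbind(idx, seq_len(ncol(m)))], nrow = d[3], ncol = d[4])
  pr_node(v, parents = list(x), backward = function(g) {
    gr <- matrix(0, nrow = d[1] * d[2], ncol = d[3] * d[4])
    gr[cbind(idx, seq_len(ncol(gr)))] <- as.numeric(g)
    list(array(gr, dim = d))
  })
}

# Dense layer on channel descriptors: x (Cin,N), w (Cout,Cin), b (Cout)
op_linear <- function(x, w, b) {
  xv <- x$value; wv <- w$value
  v <- wv %*% xv + b$value
  pr_node(v, parents = list(x, w, b), backward = function(g) {
    list(crossprod(wv, g), tcrossprod(g, xv), rowSums(g))
  })
}

# Per-channel broadcast multiplication: x (H,W,C,N) scaled by y (C,N)
op_scale_channels <- function(x, y) {
  d <- dim(x$value)
  hw <- d[1] * d[2]
  yb <- rep(as.numeric(y$value), each = hw)
  v <- array(as.numeric(x$value) * yb, dim = d)
  xv <- x$value
  pr_node(v, parents = list(x, y), backward = function(g) {
    gx <- array(as.numeric(g) * yb, dim = d)
    gy <- matrix(colSums(matrix(as.numeric(g) * as.numeric(xv), nrow = hw)),
                 nrow = d[3], ncol = d[4])
    list(gx, gy)
  })
}

# Group normalization with affine per-channel parameters.
# Statistics per (sample, group) over H*W*(C/groups) entries, population var.
op_groupnorm <- function(x, gamma, beta, groups, eps = 1e-5) {
  d <- dim(x$value)
  C <- d[3]
  if (C %% groups != 0)
    stop("group count ", groups, " does not divide channel width ", C)
  gs <- d[1] * d[2] * (C %/% groups)                 # entries per group
  ng <- groups * d[4]                                # (group, sample) columns
  m <- matrix(x$value, nrow = gs, ncol = ng)
  mu <- colMeans(m)
  va <- colMeans(m * m) - mu^2
  inv <- 1 / sqrt(va + eps)
  xhat_m <- (m - rep(mu, each = gs)) * rep(inv, each = gs)
  xhat <- array(xhat_m, dim = d)
  gb <- rep(as.numeric(gamma$value), each = d[1] * d[2])  # recycled over (C,N)
  bb <- rep(as.numeric(beta$value), each = d[1] * d[2])
  v <- array(as.numeric(xhat) * gb + bb, dim = d)
  hw <- d[1] * d[2]
  pr_node(v, parents = list(x, gamma, beta), backward = function(g) {
    gnum <- as.numeric(g)
    xh <- as.numeric(xhat)
    ggam <- rowSums(matrix(colSums(matrix(gnum * xh, nrow = hw)), nrow = C))
    gbet <- rowSums(matrix(colSums(matrix(gnum, nrow = hw)), nrow = C))
    dxh <- matrix(gnum * gb, nrow = gs, ncol = ng)
    m1 <- colMeans(dxh)
    m2 <- colMeans(dxh * xhat_m)
    gx <- (dxh - rep(m1, each = gs) - xhat_m * rep(m2, each = gs)) *
      rep(inv, each = gs)
    list(array(gx, dim = d), ggam, gbet)
  })
}

# Soft Dice loss over a batch: mean over samples of
#   1 - (2*sum(p*g) + eps) / (sum(p) + sum(g) + eps)
op_dice_loss <- function(p, gt, eps = 1e-6) {
  d <- dim(p$value)
  n <- d[4]
  per <- d[1] * d[2] * d[3]
  pm <- matrix(p$value, nrow = per, ncol = n)
  gm <- matrix(gt, nrow = per, ncol = n)
  num <- 2 * colSums(pm * gm) + eps
  den <- colSums(pm) + colSums(gm) + eps
  loss <- mean(1 - num / den)
  pr_node(loss, parents = list(p), backward = function(g) {
    # d/dp_i of -(num/den): -(2*g_i*den - num)/den^2, averaged over batch
    gp <- -(2 * gm * rep(den, each = per) - rep(num, each = per)) /
      rep(den^2, each = per) / n
    list(array(as.numeric(g) * gp, dim = d))
  })
}
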