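# Shared fixtures and independent oracles, all built in code at test time.

P <- asNamespace("praseg")

# Independent brute-force cross-correlation with zero padding; nested loops,
# no shared code with the package kernels.
naive_conv2d <- function(x, w, b, pad) {
  d <- dim(x); k <- dim(w)[1]; O <- dim(w)[4]
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  Ho <- H + 2 * pad - k + 1
  Wo <- W + 2 * pad - k + 1
  xp <- array(0, c(H + 2 * pad, W + 2 * pad, C, N))
  xp[pad + 1:H, pad + 1:W, , ] <- x
  y <- array(0, c(Ho, Wo, O, N))
  for (n in 1:N) for (o in 1:O) for (ho in 1:Ho) for (wo in 1:Wo) {
    acc <- b[o]
    for (c in 1:C) for (dy in 1:k) for (dx in 1:k)
      acc <- acc + xp[ho + dy - 1, wo + dx - 1, c, n] * w[dy, dx, c, o]
    y[ho, wo, o, n] <- acc
  }
  y
}

# Central finite differences of a scalar-valued function of an array.
numeric_grad <- function(f, v, eps = 1e-6) {
  g <- v * 0
  for (i in seq_along(v)) {
    v1 <- v; v2 <- v
    v1[i] <- v1[i] + eps
    v2[i] <- v2[i] - eps
    g[i] <- (f(v1) - f(v2)) / (2 * eps)
  }
  g
}

# Wrap an arbitrary node in a sum-of-squares scalar loss for gradient checks.
sumsq_loss <- function(node) {
  P$pr_node(sum(node$value^2), list(node),
            function(g) list(2 * node$value * as.numeric(g)))
}

# Deterministic random feature map.
rand_fmap <- function(H, W, C, N, seed = 1) {
  set.seed(seed)
  array(stats::rnorm(H * W * C * N), c(H, W, C, N))
}

# Circular 64x64 lesion-like mask fixture.
disk_mask <- function(size = 64L, r = 15) {
  yy <- matrix(seq_len(size), size, size)
  xx <- t(yy)
  c0 <- (size + 1) / 2
  ((yy - c0)^2 + (xx - c0)^2 <= r^2) * 1
}

flat_sample <- function(mask, value = 0.5) {
  P$new_sample(array(value, c(dim(mask), 3L)), mask)
}

# Small default-difficulty synthetic training setup shared across tests.
tiny_dataset <- function(n, size = 64L, seed = 11L) {
  p <- lesion_params(canvas = c(size, size), seed = seed)
  generate_dataset(p, n)$samples
}
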