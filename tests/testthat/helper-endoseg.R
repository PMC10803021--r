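# Shared fixtures and independent reference implementations used as oracles.

es <- asNamespace("endoseg")

# a deliberately tiny but structurally complete configuration
tiny_config <- function(...) {
  model_config(num_classes = 3L, stem_channels = 4L, growth = c(2L, 2L, 2L, 2L),
               depths = c(1L, 1L, 2L, 1L), fpn_channels = 8L,
               fused_channels = 8L, ccam_reduction = 4L, head_channels = 8L, ...)
}

rand_arr <- function(d, seed) {
  set.seed(seed)
  array(stats::rnorm(prod(d)), d)
}

# straight-line depthwise convolution: quadruple loop over output pixels and
# kernel taps, independent of the package's kernels
naive_dw_conv <- function(x, w, k, stride = 1L) {
  # x: C x H x W array; w: (k*k) x C matrix, tap t = ki + kj*k (0-based)
  cc <- dim(x)[1L]; h <- dim(x)[2L]; wd <- dim(x)[3L]
  pad <- (k - 1L) %/% 2L
  ho <- (h + 2L * pad - k) %/% stride + 1L
  wo <- (wd + 2L * pad - k) %/% stride + 1L
  y <- array(0, c(cc, ho, wo))
  for (c in seq_len(cc)) for (oi in seq_len(ho)) for (oj in seq_len(wo)) {
    acc <- 0
    for (ki in 0:(k - 1L)) for (kj in 0:(k - 1L)) {
      i <- (oi - 1L) * stride + ki - pad + 1L
      j <- (oj - 1L) * stride + kj - pad + 1L
      if (i >= 1L && i <= h && j >= 1L && j <= wd) {
        acc <- acc + x[c, i, j] * w[ki + kj * k + 1L, c]
      }
    }
    y[c, oi, oj] <- acc
  }
  y
}

# batch statistics normalisation as written in its definition
naive_bn_train <- function(x, gamma, beta, eps = 1e-5) {
  # x: N x C matrix
  sapply(seq_len(ncol(x)), function(c) {
    mu <- mean(x[, c]); v <- mean((x[, c] - mu)^2)
    gamma[c] * (x[, c] - mu) / sqrt(v + eps) + beta[c]
  })
}

in_memory_scenes <- function(n, seed0 = 100, size = 64L, k = 2L) {
  lapply(seq_len(n), function(i) {
    generate_scene(scene_config(image_size = size, instrument_classes = k,
                                min_width = max(4, size %/% 18),
                                max_width = max(7, size %/% 9),
                                seed = seed0 + i))
  })
}
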