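# Encoder: shape/channel bookkeeping, the dual-branch bottleneck against a
# straight-line composition of primitive operations, and structural audits.

test_that("bottleneck output channels are input + growth at fixed spatial size", {
  blk <- new_bottleneck(16, 24, seed = 1)
  x <- rand_arr(c(16, 32, 32), 1)
  y <- bottleneck_forward(x, blk)
  expect_equal(dim(y), c(40L, 32L, 32L))
  expect_error(bottleneck_forward(rand_arr(c(8, 32, 32), 1), blk), "channels")
})

test_that("bottleneck equals a hand-composed chain of primitive operations", {
  set.seed(33)
  cin <- 4L; g <- 3L; h <- 8L; w <- 8L
  blk <- new_bottleneck(cin, g, seed = 9)
  x <- rand_arr(c(cin, h, w), 2)
  got <- bottleneck_forward(x, blk)
  P <- blk$params
  branch <- function(k) {
    pre <- sprintf("bn.br%d", k)
    z1 <- naive_dw_conv(x, P[[paste0(pre, ".dw.w")]], k)
    m1 <- matrix(aperm(z1, c(2, 3, 1)), h * w, cin)
    r1 <- pmax(naive_bn_train(m1, P[[paste0(pre, ".bn1.gamma")]],
                              P[[paste0(pre, ".bn1.beta")]]), 0)
    z2 <- r1 %*% P[[paste0(pre, ".pw.w")]]
    pmax(naive_bn_train(z2, P[[paste0(pre, ".bn2.gamma")]],
                        P[[paste0(pre, ".bn2.beta")]]), 0)
  }
  s <- branch(7L) + branch(3L)
  ref <- array(0, c(cin + g, h, w))
  ref[seq_len(cin), , ] <- x
  ref[cin + seq_len(g), , ] <- aperm(array(s, c(h, w, g)), c(3, 1, 2))
  expect_equal(got, ref, tolerance = 1e-10)
})

test_that("zero input maps to zero output", {
  # a zero map normalises to zero (shift is zero at init), ReLU and the
  # pointwise convolution keep it zero, and the concatenated input is zero
  blk <- new_bottleneck(4, 3, seed = 2)
  x <- array(0, c(4, 6, 6))
  y <- bottleneck_forward(x, blk)
  expect_equal(y, array(0, c(7, 6, 6)))
})

test_that("dense stage accumulates depth x growth channels", {
  st <- new_dense_stage(32, depth = 2, growth = 16, seed = 1)
  y <- dense_stage_forward(rand_arr(c(32, 8, 8), 3), st)
  expect_equal(dim(y)[1], 64L)
  st6 <- new_dense_stage(24, depth = 6, growth = 12, seed = 1)
  y6 <- dense_stage_forward(rand_arr(c(24, 8, 8), 3), st6)
  expect_equal(dim(y6)[1], 96L)  # 24 + 6 * 12
})

test_that("a depth-1 stage is exactly one bottleneck", {
  st <- new_dense_stage(6, depth = 1, growth = 4, seed = 5)
  blk <- new_bottleneck(6, 4, seed = 5)
  x <- rand_arr(c(6, 8, 8), 4)
  # same seed initialises the same weights in the same order
  expect_equal(dense_stage_forward(x, st), bottleneck_forward(x, blk))
})

test_that("encoder emits the stride-4/8/16/32 pyramid with planned channels", {
  cfg <- tiny_config()
  m <- build_model(cfg, seed = 1)
  pl <- es$channel_plan(cfg)
  pyr <- encoder_forward(rand_arr(c(3, 64, 64), 1), m)
  expect_equal(sapply(pyr, function(p) dim(p)[2]), c(16L, 8L, 4L, 2L))
  expect_equal(sapply(pyr, function(p) dim(p)[1]), pl$pyramid)
  pyr256 <- encoder_forward(rand_arr(c(3, 96, 96), 2), m)
  expect_equal(sapply(pyr256, function(p) dim(p)[2]), c(24L, 12L, 6L, 3L))
  expect_error(encoder_forward(rand_arr(c(3, 60, 60), 1), m), "divisible")
})

test_that("reference channel plan matches the closed form at every stage", {
  cfg <- model_config()
  pl <- es$channel_plan(cfg)
  cin <- cfg$stem_channels
  for (s in 1:4) {
    expect_equal(pl$stages[[s]]$out, cin + cfg$depths[s] * cfg$growth[s])
    cin <- if (s < 4) floor(pl$stages[[s]]$out * cfg$compression) else pl$stages[[s]]$out
  }
})

test_that("encoder forward is deterministic in inference mode", {
  m <- build_model(tiny_config(), seed = 3)
  x <- rand_arr(c(3, 64, 64), 9)
  expect_identical(encoder_forward(x, m), encoder_forward(x, m))
})

test_that("every spatial convolution in the model is depthwise", {
  # structural audit over the parameter tree: any weight matrix with a
  # kernel dimension > 1 must be a .dw.w (depthwise) entry; everything else
  # is 1x1 (rows = input channels)
  m <- build_model(model_config(), seed = 1)
  units <- es$model_units(m$config)
  for (u in units) {
    if (!(u$kind %in% c("dwsep", "proj", "linear"))) next
    if (u$kind == "dwsep") {
      dw <- m$params[[paste0(u$pfx, ".dw.w")]]
      expect_equal(dim(dw), c(u$k^2, u$cin))  # one kernel per channel
      pw <- m$params[[paste0(u$pfx, ".pw.w")]]
      expect_equal(dim(pw), c(u$cin, u$cout))  # pointwise mixes channels
    } else {
      wkey <- if (u$kind == "linear") ".w" else ".pw.w"
      expect_equal(dim(m$params[[paste0(u$pfx, wkey)]]), c(u$cin, u$cout))
    }
  }
  # and no parameter tensor is a dense k x k x Cin x Cout kernel
  expect_true(all(vapply(m$params, function(p) is.null(dim(p)) || length(dim(p)) <= 2L,
                         logical(1))))
})
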