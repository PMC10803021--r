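# Decoder plumbing: upsample blocks, pyramid fusion, segmentation head,
# and the ablation toggles.

test_that("upsample block doubles spatial size at the requested width", {
  blk <- new_upsample_block(16, 8, seed = 1)
  y <- upsample_block(rand_arr(c(16, 8, 8), 1), blk)
  expect_equal(dim(y), c(8L, 16L, 16L))
})

test_that("upsample block keeps constant input constant away from borders", {
  # the padded 3x3 depthwise stage perturbs a one-pixel border; in the
  # interior the map stays constant and bilinear upsampling preserves it
  blk <- new_upsample_block(4, 4, seed = 2)
  x <- array(rep(c(1, -2, 0.5, 3), each = 64), c(64, 4))  # constant per channel
  xa <- aperm(array(x, c(8, 8, 4)), c(3, 1, 2))
  y <- upsample_block(xa, blk)
  for (c in 1:4) expect_lt(diff(range(y[c, 5:12, 5:12])), 1e-9)
})

test_that("upsample block equals hand-composed primitives", {
  cin <- 3L; cout <- 2L
  blk <- new_upsample_block(cin, cout, seed = 4)
  x <- rand_arr(c(cin, 4, 4), 6)
  got <- upsample_block(x, blk)
  P <- blk$params
  z1 <- naive_dw_conv(x, P[["ub.dw.w"]], 3L)
  m1 <- matrix(aperm(z1, c(2, 3, 1)), 16, cin)
  r1 <- pmax(naive_bn_train(m1, P[["ub.bn1.gamma"]], P[["ub.bn1.beta"]]), 0)
  r2 <- pmax(naive_bn_train(r1 %*% P[["ub.pw.w"]],
                            P[["ub.bn2.gamma"]], P[["ub.bn2.beta"]]), 0)
  up <- es$bilinear_fwd(r2, 1L, 4L, 4L, 8L, 8L)
  expect_equal(got, es$feature_array(up, 8L, 8L), tolerance = 1e-10)
})

test_that("fused map obeys the 64 x S/4 x S/4 contract across input sizes", {
  m <- build_model(model_config(num_classes = 3), seed = 1)
  for (s in c(64L, 128L, 256L)) {
    pyr <- encoder_forward(rand_arr(c(3, s, s), s), m)
    fused <- fpn_fuse(pyr, m)
    expect_equal(dim(fused), c(64L, s %/% 4L, s %/% 4L))
  }
})

test_that("zero lateral weights give an all-zero fused map", {
  m <- build_model(tiny_config(), seed = 2)
  for (l in 1:4) {
    m$params[[sprintf("dec.lat%d.w", l)]][] <- 0
    m$params[[sprintf("dec.lat%d.b", l)]][] <- 0
  }
  pyr <- encoder_forward(rand_arr(c(3, 64, 64), 3), m)
  fused <- fpn_fuse(pyr, m)
  expect_equal(max(abs(fused)), 0)
})

test_that("segmentation head emits full-resolution logits with softmax rows", {
  m <- build_model(model_config(num_classes = 3), seed = 1)
  x <- rand_arr(c(64, 16, 16), 5)
  lg <- segmentation_head(x, m, out_size = 64)
  expect_equal(dim(lg), c(3L, 64L, 64L))
  pm <- es$feature_matrix(lg)
  p <- exp(pm - log(rowSums(exp(pm))))  # softmax per pixel
  sm <- exp(pm); sm <- sm / rowSums(sm)
  expect_true(all(abs(rowSums(sm) - 1) < 1e-9))
})

test_that("argmax is equivariant to permuting classifier channels", {
  m <- build_model(tiny_config(), seed = 6)
  x <- rand_arr(c(8, 8, 8), 7)
  perm <- c(3L, 1L, 2L)
  lg1 <- segmentation_head(x, m, out_size = 32)
  m2 <- m
  m2$params[["head.cls.w"]] <- m$params[["head.cls.w"]][, perm]
  m2$params[["head.cls.b"]] <- m$params[["head.cls.b"]][perm]
  lg2 <- segmentation_head(x, m2, out_size = 32)
  a1 <- apply(lg1, c(2, 3), which.max)
  a2 <- apply(lg2, c(2, 3), which.max)
  # channel c of the permuted head carries original class perm[c]
  expect_equal(matrix(perm[a2], nrow(a2)), a1)
})

test_that("full model emits class logits at input resolution", {
  m <- build_model(model_config(num_classes = 3), seed = 1)
  lg <- model_forward(m, rand_arr(c(3, 64, 64), 8))
  expect_equal(dim(lg), c(3L, 64L, 64L))
  # repeated passes agree exactly
  expect_identical(lg, model_forward(m, rand_arr(c(3, 64, 64), 8)))
})

test_that("ablation toggles change the graph as specified", {
  x <- rand_arr(c(3, 64, 64), 9)
  base <- build_model(tiny_config(use_fpn = FALSE, use_ccam = FALSE), seed = 3)
  lg <- model_forward(base, x)
  expect_equal(dim(lg), c(3L, 64L, 64L))
  # without attention the forward is exactly encoder + FPN + head
  mf <- build_model(tiny_config(use_ccam = FALSE), seed = 3)
  pyr <- encoder_forward(x, mf)
  fused <- fpn_fuse(pyr, mf)
  direct <- segmentation_head(fused, mf, out_size = 64)
  expect_equal(model_forward(mf, x), direct, tolerance = 1e-12)
  # toggling attention on changes the output
  mc <- build_model(tiny_config(), seed = 3)
  expect_gt(max(abs(model_forward(mc, x) - model_forward(mf, x))), 1e-8)
})

test_that("predictions are invariant to batch composition", {
  m <- build_model(tiny_config(), seed = 11)
  a <- rand_arr(c(3, 64, 64), 21)
  b <- rand_arr(c(3, 64, 64), 22)
  sep <- predict_masks(m, a)
  joint <- predict_masks(m, list(a, b))
  expect_identical(sep, joint[[1]])
})
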