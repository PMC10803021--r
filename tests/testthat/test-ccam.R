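# Criss-cross attention: closed-form cases, the brute-force dense oracle,
# and the structural guarantees of the sparse path.

test_that("singleton grid gives weight 1 and a pure residual-plus-value", {
  cc <- new_ccam(4, reduction = 4, seed = 1)
  f <- rand_arr(c(4, 1, 1), 1)
  a <- criss_cross_affinity(rand_arr(c(1, 1, 1), 2), rand_arr(c(1, 1, 1), 3))
  expect_equal(dim(a), c(1L, 1L))
  expect_equal(as.vector(a), 1)
  # F' = V + F on a single position
  fm <- es$feature_matrix(f)
  v <- es$linear_fwd(fm, cc$params, "ccam.v")
  q <- es$linear_fwd(fm, cc$params, "ccam.q")
  k <- es$linear_fwd(fm, cc$params, "ccam.k")
  out <- ccam_forward(f, cc)
  expect_equal(es$feature_matrix(out), v + fm, tolerance = 1e-12)
})

test_that("constant keys give uniform attention weights", {
  h <- 3L; w <- 5L; bq <- 2L
  q <- rand_arr(c(bq, h, w), 4)
  k <- array(0.7, c(bq, h, w))
  a <- criss_cross_affinity(q, k)
  expect_equal(dim(a), c(h * w, h + w - 1L))
  expect_true(all(abs(a - 1 / (h + w - 1)) < 1e-12))
  expect_true(all(abs(rowSums(a) - 1) < 1e-6))
})

test_that("affinity equals explicitly gathered row/column dot products", {
  bq <- 4L; h <- 3L; w <- 5L
  q <- rand_arr(c(bq, h, w), 11)
  k <- rand_arr(c(bq, h, w), 12)
  a <- criss_cross_affinity(q, k)
  # double loop over (u, v) pairs, independent of the package's slot layout
  for (i in 1:h) for (j in 1:w) {
    d <- numeric(0)
    for (i2 in 1:h) d <- c(d, sum(q[, i, j] * k[, i2, j]))      # column of u
    for (j2 in setdiff(1:w, j)) d <- c(d, sum(q[, i, j] * k[, i, j2]))  # row
    expect_equal(a[i + (j - 1) * h, ], exp(d - max(d)) / sum(exp(d - max(d))),
                 tolerance = 1e-12)
  }
})

test_that("aggregation of a constant value map adds that constant", {
  h <- 4L; w <- 3L; cc <- 5L
  a <- criss_cross_affinity(rand_arr(c(2, h, w), 1), rand_arr(c(2, h, w), 2))
  cvec <- rnorm(cc)
  v <- array(rep(cvec, h * w), c(cc, h, w))
  f <- rand_arr(c(cc, h, w), 3)
  out <- criss_cross_aggregate(a, v, f)
  expect_equal(out, f + v, tolerance = 1e-12)  # weights sum to 1
})

test_that("aggregation equals the double-loop weighted sum", {
  cc_ch <- 4L; h <- 3L; w <- 5L
  a <- criss_cross_affinity(rand_arr(c(2, h, w), 21), rand_arr(c(2, h, w), 22))
  v <- rand_arr(c(cc_ch, h, w), 23)
  f <- rand_arr(c(cc_ch, h, w), 24)
  got <- criss_cross_aggregate(a, v, f)
  for (i in 1:h) for (j in 1:w) {
    vs <- cbind(sapply(1:h, function(i2) v[, i2, j]),
                sapply(setdiff(1:w, j), function(j2) v[, i, j2]))
    expect_equal(got[, i, j], as.vector(vs %*% a[i + (j - 1) * h, ]) + f[, i, j],
                 tolerance = 1e-12)
  }
})

test_that("efficient path matches the dense masked-attention oracle broadly", {
  set.seed(99)
  for (t in 1:22) {
    cch <- sample(2:12, 1)
    red <- sample(2:4, 1)
    if (max(1L, cch %/% red) >= cch) cch <- cch + red  # keep B < C
    h <- sample(1:12, 1); w <- sample(1:12, 1)
    cc <- new_ccam(cch, reduction = red, seed = t)
    f <- rand_arr(c(cch, h, w), 1000 + t)
    expect_lt(max(abs(ccam_forward(f, cc) - dense_attention_oracle(f, cc))), 1e-5)
  }
})

test_that("oracle mask has exactly H+W-1 admissible keys per query", {
  h <- 3L; w <- 5L
  n <- h * w
  i <- (seq_len(n) - 1L) %% h; j <- (seq_len(n) - 1L) %/% h
  mask <- outer(i, i, "==") | outer(j, j, "==")
  expect_true(all(rowSums(mask) == h + w - 1L))
})

test_that("zeroing the value projection reduces the module to identity", {
  cc <- new_ccam(6, reduction = 3, seed = 2)
  cc$params[["ccam.v.w"]][] <- 0
  cc$params[["ccam.v.b"]][] <- 0
  f <- rand_arr(c(6, 5, 4), 8)
  expect_identical(ccam_forward(f, cc), f + 0)  # exact residual
})

test_that("output minus input stays in the convex hull of cross values", {
  cc <- new_ccam(5, reduction = 4, seed = 3)
  f <- rand_arr(c(5, 4, 4), 12)
  fm <- es$feature_matrix(f)
  v <- es$linear_fwd(fm, cc$params, "ccam.v")
  delta <- es$feature_matrix(ccam_forward(f, cc)) - fm
  for (u in seq_len(16)) {
    i <- (u - 1) %% 4; j <- (u - 1) %/% 4
    cross <- which((seq_len(16) - 1) %% 4 == i | (seq_len(16) - 1) %/% 4 == j)
    lo <- apply(v[cross, , drop = FALSE], 2, min)
    hi <- apply(v[cross, , drop = FALSE], 2, max)
    expect_true(all(delta[u, ] >= lo - 1e-9 & delta[u, ] <= hi + 1e-9))
  }
})

test_that("transposing the grid transposes the attention output", {
  cc <- new_ccam(6, reduction = 3, seed = 5)
  f <- rand_arr(c(6, 3, 5), 31)
  ft <- aperm(f, c(1, 3, 2))
  out <- ccam_forward(f, cc)
  out_t <- ccam_forward(ft, cc)
  expect_equal(out_t, aperm(out, c(1, 3, 2)), tolerance = 1e-12)
})

test_that("attention gradients match finite differences", {
  set.seed(77)
  h <- 3L; w <- 4L; bq <- 2L; cch <- 3L
  q <- matrix(rnorm(h * w * bq), h * w, bq)
  k <- matrix(rnorm(h * w * bq), h * w, bq)
  v <- matrix(rnorm(h * w * cch), h * w, cch)
  dy <- matrix(rnorm(h * w * cch), h * w, cch)
  fw <- es$cc_attention_fwd(q, k, v, h, w)
  bw <- es$cc_attention_bwd(dy, q, k, v, fw$a, h, w)
  f_of <- function(qm, km, vm) sum(es$cc_attention_fwd(qm, km, vm, h, w)$out * dy)
  eps <- 1e-6
  for (i in sample(length(q), 4)) {
    qp <- q; qp[i] <- qp[i] + eps; qm <- q; qm[i] <- qm[i] - eps
    expect_equal(bw$dq[i], (f_of(qp, k, v) - f_of(qm, k, v)) / (2 * eps),
                 tolerance = 1e-4)
  }
  for (i in sample(length(k), 4)) {
    kp <- k; kp[i] <- kp[i] + eps; km <- k; km[i] <- km[i] - eps
    expect_equal(bw$dk[i], (f_of(q, kp, v) - f_of(q, km, v)) / (2 * eps),
                 tolerance = 1e-4)
  }
  for (i in sample(length(v), 4)) {
    vp <- v; vp[i] <- vp[i] + eps; vm <- v; vm[i] <- vm[i] - eps
    expect_equal(bw$dv[i], (f_of(q, k, vp) - f_of(q, k, vm)) / (2 * eps),
                 tolerance = 1e-4)
  }
})

test_that("B >= C reduction is rejected", {
  expect_error(new_ccam(4, reduction = 1), "B < C")
  expect_error(model_config(fused_channels = 8, ccam_reduction = 1), "B < C")
})
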