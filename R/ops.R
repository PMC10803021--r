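# Low-level tensor primitives.
#
# Every feature map travels as a dense (B*H*W) x C matrix, column-major, with
# spatial index p = i + j*H inside each image (i = row, fastest -- the order
# as.vector() yields on an R matrix). Image b occupies the contiguous row block
# b*H*W + 1 .. (b+1)*H*W. 1x1 (pointwise) convolutions are then plain matrix
# products handled by BLAS; depthwise convolutions call the compiled kernels;
# pooling and bilinear resampling are vectorised gathers with memoised index
# tables.

.memo <- new.env(parent = emptyenv())

memo_get <- function(key, make) {
  v <- .memo[[key]]
  if (is.null(v)) {
    v <- make()
    assign(key, v, envir = .memo)
  }
  v
}

feature_matrix <- function(a) {
  # C x H x W array -> (H*W) x C matrix
  stopifnot(length(dim(a)) == 3L)
  d <- dim(a)
  m <- matrix(aperm(a, c(2L, 3L, 1L)), nrow = d[2L] * d[3L], ncol = d[1L])
  attr(m, "hw") <- d[2:3]
  m
}

feature_array <- function(m, h, w) {
  # (H*W) x C matrix -> C x H x W array
  aperm(array(m, dim = c(h, w, ncol(m))), c(3L, 1L, 2L))
}

rowmax <- function(x) do.call(pmax, lapply(seq_len(ncol(x)), function(j) x[, j]))

col_rep <- function(v, n) rep(v, each = n)

# ---- pointwise (1x1) convolution ----

pw_fwd <- function(x, w, b = NULL) {
  y <- x %*% w
  if (!is.null(b)) y <- y + col_rep(b, nrow(y))
  y
}

pw_bwd <- function(dy, x, w, genv, pfx, bias = FALSE) {
  g_acc(genv, paste0(pfx, ".w"), crossprod(x, dy))
  if (bias) g_acc(genv, paste0(pfx, ".b"), colSums(dy))
  dy %*% t(w)
}

# ---- per-image (instance) affine normalisation ----
# Statistics are computed per image and channel over the spatial positions,
# identically in training and inference, so predictions do not depend on how
# images are batched and there are no running statistics to calibrate.

inorm_fwd <- function(x, gamma, beta, b, eps = 1e-5) {
  .inorm_fwd_cpp(x, gamma, beta, as.integer(b), eps)
}

inorm_bwd <- function(dy, cache, gamma, genv, pfx, b) {
  r <- .inorm_bwd_cpp(dy, cache$xhat, cache$invstd, gamma, as.integer(b))
  g_acc(genv, paste0(pfx, ".gamma"), r$dgamma)
  g_acc(genv, paste0(pfx, ".beta"), r$dbeta)
  r$dx
}

relu_fwd <- function(x) .relu_fwd_cpp(x)

relu_bwd <- function(dy, y) .relu_bwd_cpp(dy, y)

# ---- depthwise convolution (compiled kernels) ----

conv_out_size <- function(n, k, stride) (n + 2 * ((k - 1) %/% 2) - k) %/% stride + 1

dw_fwd <- function(x, w, b, h, wd, k, stride = 1L) {
  .dw_conv_fwd_cpp(x, w, as.integer(b), as.integer(h), as.integer(wd),
                   as.integer(k), as.integer(stride))
}

dw_bwd <- function(dy, x, w, b, h, wd, k, stride, genv, pfx) {
  r <- .dw_conv_bwd_cpp(x, w, dy, as.integer(b), as.integer(h), as.integer(wd),
                        as.integer(k), as.integer(stride))
  g_acc(genv, paste0(pfx, ".w"), r$dw)
  r$dx
}

# ---- 2x2 average pooling, stride 2 ----

avgpool_idx <- function(b, h, w) {
  key <- paste("ap", b, h, w, sep = "_")
  memo_get(key, function() {
    ho <- h %/% 2L; wo <- w %/% 2L
    oi <- 2L * (0:(ho - 1L)); oj <- 2L * (0:(wo - 1L))
    off <- as.vector(outer(rep(0L, ho * wo), (0:(b - 1L)) * h * w, "+"))
    lapply(list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L)), function(d) {
      base <- as.vector(outer(oi + d[1L], (oj + d[2L]) * h, "+"))
      rep(base, times = b) + off + 1L
    })
  })
}

avgpool_fwd <- function(x, b, h, w) {
  ix <- avgpool_idx(b, h, w)
  (x[ix[[1L]], , drop = FALSE] + x[ix[[2L]], , drop = FALSE] +
     x[ix[[3L]], , drop = FALSE] + x[ix[[4L]], , drop = FALSE]) / 4
}

avgpool_bwd <- function(dy, b, h, w) {
  ix <- avgpool_idx(b, h, w)
  dx <- matrix(0, b * h * w, ncol(dy))
  q <- dy / 4
  for (ii in ix) dx[ii, ] <- dx[ii, ] + q
  dx
}

# ---- bilinear resize (half-pixel convention, no corner alignment) ----

bilinear_plan <- function(b, h, w, ho, wo) {
  key <- paste("bl", b, h, w, ho, wo, sep = "_")
  memo_get(key, function() {
    axis <- function(n_in, n_out) {
      s <- pmin(pmax(((0:(n_out - 1L)) + 0.5) * n_in / n_out - 0.5, 0), n_in - 1L)
      i0 <- floor(s)
      list(i0 = as.integer(i0), i1 = as.integer(pmin(i0 + 1, n_in - 1L)), f = s - i0)
    }
    ai <- axis(h, ho); aj <- axis(w, wo)
    off <- rep((0:(b - 1L)) * h * w, each = ho * wo)
    comb <- function(iv, jv, wi, wj) {
      list(idx = rep(as.vector(outer(iv, jv * h, "+")) + 1L, times = b) + off,
           w = rep(as.vector(outer(wi, wj)), times = b))
    }
    list(
      comb(ai$i0, aj$i0, 1 - ai$f, 1 - aj$f),
      comb(ai$i1, aj$i0, ai$f, 1 - aj$f),
      comb(ai$i0, aj$i1, 1 - ai$f, aj$f),
      comb(ai$i1, aj$i1, ai$f, aj$f)
    )
  })
}

bilinear_fwd <- function(x, b, h, w, ho, wo) {
  pl <- bilinear_plan(b, h, w, ho, wo)
  y <- x[pl[[1L]]$idx, , drop = FALSE] * pl[[1L]]$w
  for (t in 2:4) y <- y + x[pl[[t]]$idx, , drop = FALSE] * pl[[t]]$w
  y
}

scatter_add <- function(dx, idx, m) {
  rs <- rowsum(m, group = idx, reorder = FALSE)
  rows <- as.integer(rownames(rs))
  dx[rows, ] <- dx[rows, , drop = FALSE] + rs
  dx
}

bilinear_bwd <- function(dy, b, h, w, ho, wo) {
  pl <- bilinear_plan(b, h, w, ho, wo)
  dx <- matrix(0, b * h * w, ncol(dy))
  for (t in 1:4) dx <- scatter_add(dx, pl[[t]]$idx, dy * pl[[t]]$w)
  dx
}

# ---- nearest-neighbour resize for label masks ----
# Convention: source index = floor((i_out + 0.5) * n_in / n_out), clamped.

nearest_resize <- function(mask, ho, wo) {
  h <- nrow(mask); w <- ncol(mask)
  ii <- pmin(floor(((0:(ho - 1L)) + 0.5) * h / ho), h - 1L) + 1L
  jj <- pmin(floor(((0:(wo - 1L)) + 0.5) * w / wo), w - 1L) + 1L
  mask[ii, jj, drop = FALSE]
}

# ---- gradient accumulation ----

g_acc <- function(genv, name, value) {
  cur <- genv[[name]]
  if (is.null(cur)) assign(name, value, envir = genv)
  else assign(name, cur + value, envir = genv)
  invisible(NULL)
}

grad_list <- function(genv, params) {
  g <- as.list(genv)
  missing <- setdiff(names(params), names(g))
  for (nm in missing) g[[nm]] <- array(0, dim = dim_or_len(params[[nm]]))
  g[names(params)]
}

dim_or_len <- function(x) if (is.null(dim(x))) length(x) else dim(x)
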