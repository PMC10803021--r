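# Criss-cross attention: each spatial position u attends to the H+W-1
# positions sharing its row or column (u itself counted once, via its
# column). Query/key projections reduce C channels to B < C; scores are raw
# dot products (no scaling, no positional encoding); softmax weights
# aggregate the value vectors and the input is added back as a residual.
#
# Slot layout of the (H*W) x (H+W-1) score/weight matrices: slots 1..H are
# the positions of u's column (ordered by row index, u itself at slot i+1);
# slots H+1..H+W-1 are the remaining positions of u's row, ordered by
# ascending column index with u's own column skipped.
#
# The efficient path never materialises an (H*W) x (H*W) matrix: per-column
# and per-row blocks are (H x H) / (W x W) matrix products, so the peak
# intermediate is the H*W x (H+W-1) score matrix itself.

cc_plan <- function(h, w) {
  memo_get(paste("cc", h, w, sep = "_"), function() {
    # off-diagonal mapping of a W x W row-score block, column-major order
    j2 <- rep(0:(w - 1L), each = w)  # key column
    j <- rep(0:(w - 1L), times = w)  # query column
    keep <- j != j2
    j <- j[keep]; j2 <- j2[keep]
    list(
      sel = which(keep),                      # linear idx into the W x W block
      slot = h + ifelse(j2 < j, j2 + 1L, j2), # target slot (1-based col of D)
      jq = j,                                 # query column of each element
      col_rows = lapply(0:(w - 1L), function(jj) jj * h + 1:h),
      row_rows = lapply(0:(h - 1L), function(ii) ii + seq(1L, by = h, length.out = w))
    )
  })
}

# Q, K: (H*W) x B; V: (H*W) x C -- single image.
cc_attention_fwd <- function(q, k, v, h, w) {
  pl <- cc_plan(h, w)
  L <- h + w - 1L
  d <- matrix(0, h * w, L)
  for (jj in seq_len(w)) {
    rows <- pl$col_rows[[jj]]
    d[rows, 1:h] <- q[rows, , drop = FALSE] %*% t(k[rows, , drop = FALSE])
  }
  if (w > 1L) {
    for (ii in seq_len(h)) {
      rows <- pl$row_rows[[ii]]
      dr <- q[rows, , drop = FALSE] %*% t(k[rows, , drop = FALSE])
      d[cbind(rows[pl$jq + 1L], pl$slot)] <- dr[pl$sel]
    }
  }
  a <- exp(d - rowmax(d))
  a <- a / rowSums(a)
  out <- matrix(0, h * w, ncol(v))
  for (jj in seq_len(w)) {
    rows <- pl$col_rows[[jj]]
    out[rows, ] <- a[rows, 1:h, drop = FALSE] %*% v[rows, , drop = FALSE]
  }
  if (w > 1L) {
    for (ii in seq_len(h)) {
      rows <- pl$row_rows[[ii]]
      ar <- matrix(0, w, w)
      ar[pl$sel] <- a[cbind(rows[pl$jq + 1L], pl$slot)]
      out[rows, ] <- out[rows, ] + ar %*% v[rows, , drop = FALSE]
    }
  }
  list(out = out, a = a)
}

cc_attention_bwd <- function(dout, q, k, v, a, h, w) {
  pl <- cc_plan(h, w)
  dv <- matrix(0, nrow(v), ncol(v))
  da <- matrix(0, nrow(a), ncol(a))
  for (jj in seq_len(w)) {
    rows <- pl$col_rows[[jj]]
    vv <- v[rows, , drop = FALSE]
    dv[rows, ] <- crossprod(a[rows, 1:h, drop = FALSE], dout[rows, , drop = FALSE])
    da[rows, 1:h] <- dout[rows, , drop = FALSE] %*% t(vv)
  }
  if (w > 1L) {
    for (ii in seq_len(h)) {
      rows <- pl$row_rows[[ii]]
      vv <- v[rows, , drop = FALSE]
      ar <- matrix(0, w, w)
      ix <- cbind(rows[pl$jq + 1L], pl$slot)
      ar[pl$sel] <- a[ix]
      dv[rows, ] <- dv[rows, ] + crossprod(ar, dout[rows, , drop = FALSE])
      dar <- dout[rows, , drop = FALSE] %*% t(vv)
      da[ix] <- dar[pl$sel]
    }
  }
  dd <- a * (da - rowSums(da * a))
  dq <- matrix(0, nrow(q), ncol(q))
  dk <- matrix(0, nrow(k), ncol(k))
  for (jj in seq_len(w)) {
    rows <- pl$col_rows[[jj]]
    dq[rows, ] <- dd[rows, 1:h, drop = FALSE] %*% k[rows, , drop = FALSE]
    dk[rows, ] <- crossprod(dd[rows, 1:h, drop = FALSE], q[rows, , drop = FALSE])
  }
  if (w > 1L) {
    for (ii in seq_len(h)) {
      rows <- pl$row_rows[[ii]]
      ddr <- matrix(0, w, w)
      ddr[pl$sel] <- dd[cbind(rows[pl$jq + 1L], pl$slot)]
      dq[rows, ] <- dq[rows, ] + ddr %*% k[rows, , drop = FALSE]
      dk[rows, ] <- dk[rows, ] + crossprod(ddr, q[rows, , drop = FALSE])
    }
  }
  list(dq = dq, dk = dk, dv = dv)
}

# Full module on one image's fused map (matrix form), with the 1x1 Q/K/V
# projections; out = attention(F) + F.
ccam_fwd_mat <- function(f, h, w, P) {
  q <- linear_fwd(f, P, "ccam.q")
  k <- linear_fwd(f, P, "ccam.k")
  v <- linear_fwd(f, P, "ccam.v")
  at <- cc_attention_fwd(q, k, v, h, w)
  list(out = at$out + f, cache = list(f = f, q = q, k = k, v = v, a = at$a, h = h, w = w))
}

ccam_bwd_mat <- function(dout, cache, P, genv) {
  bw <- cc_attention_bwd(dout, cache$q, cache$k, cache$v, cache$a, cache$h, cache$w)
  df <- dout  # residual
  df <- df + linear_bwd(bw$dq, cache$f, P, genv, "ccam.q")
  df <- df + linear_bwd(bw$dk, cache$f, P, genv, "ccam.k")
  df + linear_bwd(bw$dv, cache$f, P, genv, "ccam.v")
}

# ---- public API ----

#' Stand-alone criss-cross attention module
#'
#' Builds the attention block outside the full model: three 1x1 convolutions
#' produce queries and keys with `channels / reduction` channels and values
#' with `channels` channels; sparse row/column attention then refines the
#' input with a residual connection.
#'
#' @param channels input channel count C.
#' @param reduction channel reduction ratio; `B = max(1, C / reduction)` and
#'   B must stay below C.
#' @param seed integer seed for weight initialisation.
#' @return An `endoseg_ccam` object.
#' @export
new_ccam <- function(channels, reduction = 8L, seed = 1L) {
  channels <- as.integer(channels)
  bq <- max(1L, channels %/% as.integer(reduction))
  if (bq >= channels) stop("reduction must give B < C channels")
  old <- rng_snapshot(); on.exit(rng_restore(old))
  set.seed(seed)
  params <- list()
  for (nm in c("q", "k")) {
    params <- init_unit(list(pfx = paste0("ccam.", nm), kind = "linear",
                             cin = channels, cout = bq), params)
  }
  params <- init_unit(list(pfx = "ccam.v", kind = "linear",
                           cin = channels, cout = channels), params)
  structure(list(params = params, channels = channels, b_channels = bq),
            class = "endoseg_ccam")
}

#' Criss-cross attention forward pass
#'
#' @param f feature map, C x H x W array.
#' @param ccam an `endoseg_ccam` (or an `endoseg_model`, whose attention
#'   parameters are then used).
#' @return The refined C x H x W feature map (attention output plus residual).
#' @examples
#' cc <- new_ccam(8, reduction = 8, seed = 3)
#' f <- array(rnorm(8 * 4 * 4), c(8, 4, 4))
#' out <- ccam_forward(f, cc)
#' max(abs(out - dense_attention_oracle(f, cc)))  # < 1e-5
#' @export
ccam_forward <- function(f, ccam) {
  P <- if (inherits(ccam, "endoseg_model")) ccam$params else ccam$params
  stopifnot(length(dim(f)) == 3L)
  h <- dim(f)[2L]; w <- dim(f)[3L]
  if (h < 1L || w < 1L) stop("empty feature map")
  r <- ccam_fwd_mat(feature_matrix(f), h, w, P)
  feature_array(r$out, h, w)
}

#' Affinity and aggregation of criss-cross attention
#'
#' `criss_cross_affinity()` computes, for every position u, the softmax
#' weights over the H+W-1 positions of u's row and column (u counted once);
#' `criss_cross_aggregate()` applies those weights to the value map and adds
#' the residual input. Slot order of the weight matrix: the H positions of
#' u's column (by row index), then the remaining W-1 positions of u's row
#' (by ascending column index).
#'
#' @param q,k query and key maps, B x H x W arrays.
#' @return For `criss_cross_affinity()`: an (H*W) x (H+W-1) weight matrix of
#'   class `endoseg_ccattention` (rows sum to 1) with attribute `hw`.
#' @export
criss_cross_affinity <- function(q, k) {
  stopifnot(length(dim(q)) == 3L, all(dim(q) == dim(k)))
  h <- dim(q)[2L]; w <- dim(q)[3L]
  if (h < 1L || w < 1L) stop("empty feature map")
  qm <- feature_matrix(q); km <- feature_matrix(k)
  at <- cc_attention_fwd(qm, km, matrix(0, h * w, 1L), h, w)
  structure(at$a, hw = c(h, w), class = "endoseg_ccattention")
}

#' @rdname criss_cross_affinity
#' @param a weight matrix from `criss_cross_affinity()`.
#' @param v value map, C x H x W array.
#' @param f residual input, C x H x W array.
#' @return For `criss_cross_aggregate()`: the C x H x W output map.
#' @export
criss_cross_aggregate <- function(a, v, f) {
  hw <- attr(a, "hw")
  stopifnot(!is.null(hw), length(dim(v)) == 3L, all(dim(v) == dim(f)),
            all(dim(v)[2:3] == hw))
  h <- hw[1L]; w <- hw[2L]
  pl <- cc_plan(h, w)
  vm <- feature_matrix(v)
  out <- matrix(0, h * w, ncol(vm))
  for (jj in seq_len(w)) {
    rows <- pl$col_rows[[jj]]
    out[rows, ] <- a[rows, 1:h, drop = FALSE] %*% vm[rows, , drop = FALSE]
  }
  if (w > 1L) {
    for (ii in seq_len(h)) {
      rows <- pl$row_rows[[ii]]
      ar <- matrix(0, w, w)
      ar[pl$sel] <- a[cbind(rows[pl$jq + 1L], pl$slot)]
      out[rows, ] <- out[rows, ] + ar %*% vm[rows, , drop = FALSE]
    }
  }
  feature_array(out, h, w) + f
}

#' Brute-force dense-attention oracle
#'
#' Test oracle for the efficient criss-cross path: materialises the full
#' (H*W) x (H*W) score matrix Q_u . K_v, masks every pair that shares
#' neither row nor column to -Inf, softmaxes each row, aggregates the value
#' map and adds the residual. Intended for small inputs only (H*W <= 256);
#' it must agree with [ccam_forward()] to within 1e-5.
#'
#' @inheritParams ccam_forward
#' @return The C x H x W output map.
#' @export
dense_attention_oracle <- function(f, ccam) {
  P <- ccam$params
  stopifnot(length(dim(f)) == 3L)
  h <- dim(f)[2L]; w <- dim(f)[3L]
  if (h * w > 256L) stop("oracle is restricted to H*W <= 256")
  fm <- feature_matrix(f)
  q <- linear_fwd(fm, P, "ccam.q")
  k <- linear_fwd(fm, P, "ccam.k")
  v <- linear_fwd(fm, P, "ccam.v")
  n <- h * w
  i <- (seq_len(n) - 1L) %% h
  j <- (seq_len(n) - 1L) %/% h
  mask <- outer(i, i, "==") | outer(j, j, "==")
  s <- q %*% t(k)
  s[!mask] <- -Inf
  a <- exp(s - rowmax(s))
  a <- a / rowSums(a)
  feature_array(a %*% v + fm, h, w)
}

#' @export
print.endoseg_ccam <- function(x, ...) {
  cat(sprintf("<endoseg_ccam> C = %d, B = %d\n", x$channels, x$b_channels))
  invisible(x)
}
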