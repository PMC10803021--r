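# Decoder: lateral 1x1 convolutions bring the four pyramid levels to a
# common width, a top-down pathway adds each 2x-bilinearly-upsampled deeper
# level to the next lateral, and per-level upsample chains (0/1/2/3 blocks,
# deepest gets 3) bring every level to stride 4 at fused_channels/4 channels
# each; channel concatenation yields the fused map (64 x S/4 x S/4 for the
# reference widths). Criss-cross attention refines the fused map, and the
# head emits class logits at full resolution. FPN and attention are
# independently toggleable for the ablation; with the pyramid off, the
# stride-4 encoder level is merged by a single 1x1 convolution.

upblock_fwd <- function(x, b, h, w, P, pfx) {
  ds <- dwsep_fwd(x, b, h, w, P, pfx, 3L, 1L)
  up <- bilinear_fwd(ds$out, b, h, w, 2L * h, 2L * w)
  list(out = up, ho = 2L * h, wo = 2L * w,
       cache = list(ds = ds$cache, b = b, h = h, w = w))
}

upblock_bwd <- function(dout, cache, P, genv, pfx) {
  dds <- bilinear_bwd(dout, cache$b, cache$h, cache$w, 2L * cache$h, 2L * cache$w)
  dwsep_bwd(dds, cache$ds, P, genv, pfx)
}

fpn_fwd <- function(pyr, b, model) {
  P <- model$params
  lat <- lapply(1:4, function(l) linear_fwd(pyr[[l]]$x, P, sprintf("dec.lat%d", l)))
  # top-down: merged[4] = lat[4]; merged[l] = lat[l] + up2(merged[l+1])
  merged <- vector("list", 4L)
  merged[[4L]] <- lat[[4L]]
  for (l in 3:1) {
    merged[[l]] <- lat[[l]] + bilinear_fwd(merged[[l + 1L]], b,
                                           pyr[[l + 1L]]$h, pyr[[l + 1L]]$w,
                                           pyr[[l]]$h, pyr[[l]]$w)
  }
  red <- proj_fwd(merged[[1L]], b, P, "dec.red1")
  parts <- vector("list", 4L)
  parts[[1L]] <- red$out
  ccache <- vector("list", 4L)
  for (l in 2:4) {
    x <- merged[[l]]; hh <- pyr[[l]]$h; ww <- pyr[[l]]$w
    blocks <- vector("list", l - 1L)
    for (i in seq_len(l - 1L)) {
      r <- upblock_fwd(x, b, hh, ww, P, sprintf("dec.chain%d.u%d", l, i))
      x <- r$out; hh <- r$ho; ww <- r$wo
      blocks[[i]] <- r$cache
    }
    parts[[l]] <- x
    ccache[[l]] <- blocks
  }
  fused <- do.call(cbind, parts)
  list(out = fused,
       cache = list(pyr_dims = lapply(pyr, function(p) c(p$h, p$w)),
                    lat_in = lapply(pyr, `[[`, "x"),
                    red = red$cache, chains = ccache, b = b,
                    contrib = ncol(parts[[1L]])))
}

fpn_bwd <- function(dfused, cache, model, genv) {
  P <- model$params; b <- cache$b; ct <- cache$contrib
  dims <- cache$pyr_dims
  dparts <- lapply(0:3, function(l) dfused[, l * ct + seq_len(ct), drop = FALSE])
  dmerged <- vector("list", 4L)
  dmerged[[1L]] <- proj_bwd(dparts[[1L]], cache$red, P, genv, "dec.red1")
  for (l in 2:4) {
    dx <- dparts[[l]]
    for (i in rev(seq_len(l - 1L))) {
      dx <- upblock_bwd(dx, cache$chains[[l]][[i]], P, genv,
                        sprintf("dec.chain%d.u%d", l, i))
    }
    dmerged[[l]] <- dx
  }
  # top-down transpose: dlat[l] = dmerged[l]; dmerged[l+1] += up2^T(dmerged[l])
  for (l in 1:3) {
    dmerged[[l + 1L]] <- dmerged[[l + 1L]] +
      bilinear_bwd(dmerged[[l]], b, dims[[l + 1L]][1L], dims[[l + 1L]][2L],
                   dims[[l]][1L], dims[[l]][2L])
  }
  lapply(1:4, function(l) {
    linear_bwd(dmerged[[l]], cache$lat_in[[l]], P, genv, sprintf("dec.lat%d", l))
  })
}

head_fwd <- function(x, b, h, w, model, out_h, out_w) {
  P <- model$params
  ds <- dwsep_fwd(x, b, h, w, P, "head.conv", 3L, 1L)
  z <- linear_fwd(ds$out, P, "head.cls")
  logits <- bilinear_fwd(z, b, h, w, out_h, out_w)
  list(out = logits, cache = list(ds = ds$cache, z_in = ds$out, b = b,
                                  h = h, w = w, out_h = out_h, out_w = out_w))
}

head_bwd <- function(dlogits, cache, model, genv) {
  P <- model$params
  dz <- bilinear_bwd(dlogits, cache$b, cache$h, cache$w, cache$out_h, cache$out_w)
  dds <- linear_bwd(dz, cache$z_in, P, genv, "head.cls")
  dwsep_bwd(dds, cache$ds, P, genv, "head.conv")
}

# full network forward on a stacked batch matrix
net_fwd <- function(x, b, h, w, model) {
  cfg <- model$config
  enc <- enc_fwd(x, b, h, w, model)
  if (cfg$use_fpn) {
    fp <- fpn_fwd(enc$pyr, b, model)
    fused <- fp$out
  } else {
    fp <- proj_fwd(enc$pyr[[1L]]$x, b, model$params, "dec.merge")
    fused <- fp$out
  }
  h4 <- enc$pyr[[1L]]$h; w4 <- enc$pyr[[1L]]$w
  cc <- NULL
  if (cfg$use_ccam) {
    n4 <- h4 * w4
    cc <- vector("list", b)
    out <- fused
    for (bb in seq_len(b)) {
      rows <- (bb - 1L) * n4 + seq_len(n4)
      r <- ccam_fwd_mat(fused[rows, , drop = FALSE], h4, w4, model$params)
      out[rows, ] <- r$out
      cc[[bb]] <- r$cache
    }
    fused <- out
  }
  hd <- head_fwd(fused, b, h4, w4, model, h, w)
  list(logits = hd$out,
       cache = list(enc = enc$cache, fp = fp, cc = cc, hd = hd$cache,
                    b = b, h4 = h4, w4 = w4, use_fpn = cfg$use_fpn,
                    use_ccam = cfg$use_ccam))
}

net_bwd <- function(dlogits, cache, model, genv) {
  dfused <- head_bwd(dlogits, cache$hd, model, genv)
  if (cache$use_ccam) {
    n4 <- cache$h4 * cache$w4
    dout <- dfused
    for (bb in seq_len(cache$b)) {
      rows <- (bb - 1L) * n4 + seq_len(n4)
      dout[rows, ] <- ccam_bwd_mat(dfused[rows, , drop = FALSE],
                                   cache$cc[[bb]], model$params, genv)
    }
    dfused <- dout
  }
  if (cache$use_fpn) {
    dpyr <- fpn_bwd(dfused, cache$fp$cache, model, genv)
  } else {
    dpyr <- list(proj_bwd(dfused, cache$fp$cache, model$params, genv, "dec.merge"),
                 NULL, NULL, NULL)
  }
  enc_bwd(dpyr, cache$enc, model, genv)
  invisible(NULL)
}

# ---- public wrappers ----

#' Stand-alone decoder upsample block
#'
#' One block of the pyramid upsample chains: 3x3 depthwise convolution,
#' per-image norm, ReLU, 1x1 convolution, norm, ReLU, then 2x bilinear
#' upsampling.
#'
#' @param c_in,c_out input and output channel counts.
#' @param seed integer seed for weight initialisation.
#' @return An `endoseg_upblock` object.
#' @export
new_upsample_block <- function(c_in, c_out, seed = 1L) {
  old <- rng_snapshot(); on.exit(rng_restore(old))
  set.seed(seed)
  params <- init_unit(list(pfx = "ub", kind = "dwsep", k = 3L,
                           cin = as.integer(c_in), cout = as.integer(c_out)),
                      list())
  structure(list(params = params,
                 c_in = as.integer(c_in), c_out = as.integer(c_out)),
            class = "endoseg_upblock")
}

#' @rdname new_upsample_block
#' @param x feature map, `c_in` x H x W array.
#' @param block an `endoseg_upblock`.
#' @return `upsample_block()` returns a `c_out` x 2H x 2W array.
#' @export
upsample_block <- function(x, block) {
  stopifnot(inherits(block, "endoseg_upblock"), dim(x)[1L] == block$c_in)
  h <- dim(x)[2L]; w <- dim(x)[3L]
  r <- upblock_fwd(feature_matrix(x), 1L, h, w, block$params, "ub")
  feature_array(r$out, r$ho, r$wo)
}

#' Fuse the feature pyramid into the stride-4 map
#'
#' Applies the lateral 1x1 convolutions, the top-down pathway and the
#' per-level upsample chains of a built model to a four-level pyramid (as
#' returned by [encoder_forward()]) and concatenates the per-level
#' contributions into the fused map (`fused_channels` x S/4 x S/4).
#'
#' @param pyramid list of four C_l x H_l x W_l arrays at strides 4/8/16/32.
#' @param model an `endoseg_model` built with `use_fpn = TRUE`.
#' @return The fused feature map array.
#' @export
fpn_fuse <- function(pyramid, model) {
  stopifnot(inherits(model, "endoseg_model"), model$config$use_fpn)
  if (length(pyramid) != 4L) stop("pyramid must have exactly 4 levels")
  pyr <- lapply(pyramid, function(a) {
    list(x = feature_matrix(a), h = dim(a)[2L], w = dim(a)[3L])
  })
  r <- fpn_fwd(pyr, 1L, model)
  feature_array(r$out, pyr[[1L]]$h, pyr[[1L]]$w)
}

#' Segmentation head
#'
#' 3x3 depthwise-separable convolution, 1x1 convolution to the class count,
#' and bilinear upsampling to the output resolution; per-pixel class scores
#' are returned as logits.
#'
#' @param x fused feature map array (stride 4).
#' @param model an `endoseg_model`.
#' @param out_size output side length (typically 4x the input map).
#' @return A `num_classes` x out_size x out_size logits array.
#' @export
segmentation_head <- function(x, model, out_size = 4L * dim(x)[2L]) {
  stopifnot(inherits(model, "endoseg_model"))
  h <- dim(x)[2L]; w <- dim(x)[3L]
  out_w <- as.integer(round(out_size * w / h))
  r <- head_fwd(feature_matrix(x), 1L, h, w, model, as.integer(out_size), out_w)
  feature_array(r$out, as.integer(out_size), out_w)
}
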