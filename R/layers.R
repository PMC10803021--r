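# Parameter initialisation and the forward/backward pairs of the three
# repeated composite units:
#   dwsep : depthwise kxk conv -> norm -> ReLU -> 1x1 conv -> norm -> ReLU
#   proj  : 1x1 conv (no bias) -> norm -> ReLU
#   linear: 1x1 conv with bias (no norm, no activation)
# He-normal weight initialisation (fan-in of the kernel), norm scale 1
# shift 0. The norm is per-image affine normalisation (see ops.R).

init_unit <- function(u, params) {
  p <- u$pfx
  if (u$kind == "dwsep") {
    params[[paste0(p, ".dw.w")]] <-
      matrix(stats::rnorm(u$k^2 * u$cin, sd = sqrt(2 / u$k^2)), u$k^2, u$cin)
    params[[paste0(p, ".bn1.gamma")]] <- rep(1, u$cin)
    params[[paste0(p, ".bn1.beta")]] <- rep(0, u$cin)
    params[[paste0(p, ".pw.w")]] <-
      matrix(stats::rnorm(u$cin * u$cout, sd = sqrt(2 / u$cin)), u$cin, u$cout)
    params[[paste0(p, ".bn2.gamma")]] <- rep(1, u$cout)
    params[[paste0(p, ".bn2.beta")]] <- rep(0, u$cout)
  } else if (u$kind == "proj") {
    params[[paste0(p, ".pw.w")]] <-
      matrix(stats::rnorm(u$cin * u$cout, sd = sqrt(2 / u$cin)), u$cin, u$cout)
    params[[paste0(p, ".bn.gamma")]] <- rep(1, u$cout)
    params[[paste0(p, ".bn.beta")]] <- rep(0, u$cout)
  } else if (u$kind == "linear") {
    params[[paste0(p, ".w")]] <-
      matrix(stats::rnorm(u$cin * u$cout, sd = sqrt(2 / u$cin)), u$cin, u$cout)
    params[[paste0(p, ".b")]] <- rep(0, u$cout)
  }
  params
}

# x: (B*H*W) x cin. Returns out at (B*Ho*Wo) x cout with Ho = H/stride.
dwsep_fwd <- function(x, b, h, w, P, pfx, k, stride) {
  ho <- conv_out_size(h, k, stride); wo <- conv_out_size(w, k, stride)
  z1 <- dw_fwd(x, P[[paste0(pfx, ".dw.w")]], b, h, w, k, stride)
  c1 <- inorm_fwd(z1, P[[paste0(pfx, ".bn1.gamma")]], P[[paste0(pfx, ".bn1.beta")]], b)
  r1 <- relu_fwd(c1$y)
  z2 <- pw_fwd(r1, P[[paste0(pfx, ".pw.w")]])
  c2 <- inorm_fwd(z2, P[[paste0(pfx, ".bn2.gamma")]], P[[paste0(pfx, ".bn2.beta")]], b)
  out <- relu_fwd(c2$y)
  list(out = out, ho = ho, wo = wo,
       cache = list(x = x, c1 = c1, r1 = r1, c2 = c2, out = out,
                    b = b, h = h, w = w, k = k, stride = stride))
}

dwsep_bwd <- function(dout, cache, P, genv, pfx) {
  b <- cache$b
  dout <- relu_bwd(dout, cache$out)
  d2 <- inorm_bwd(dout, cache$c2, P[[paste0(pfx, ".bn2.gamma")]], genv,
                  paste0(pfx, ".bn2"), b)
  d1 <- pw_bwd(d2, cache$r1, P[[paste0(pfx, ".pw.w")]], genv, paste0(pfx, ".pw"))
  d1 <- relu_bwd(d1, cache$r1)
  d0 <- inorm_bwd(d1, cache$c1, P[[paste0(pfx, ".bn1.gamma")]], genv,
                  paste0(pfx, ".bn1"), b)
  dw_bwd(d0, cache$x, P[[paste0(pfx, ".dw.w")]],
         b, cache$h, cache$w, cache$k, cache$stride, genv, paste0(pfx, ".dw"))
}

proj_fwd <- function(x, b, P, pfx) {
  z <- pw_fwd(x, P[[paste0(pfx, ".pw.w")]])
  cb <- inorm_fwd(z, P[[paste0(pfx, ".bn.gamma")]], P[[paste0(pfx, ".bn.beta")]], b)
  out <- relu_fwd(cb$y)
  list(out = out, cache = list(x = x, cb = cb, out = out, b = b))
}

proj_bwd <- function(dout, cache, P, genv, pfx) {
  dout <- relu_bwd(dout, cache$out)
  dz <- inorm_bwd(dout, cache$cb, P[[paste0(pfx, ".bn.gamma")]], genv,
                  paste0(pfx, ".bn"), cache$b)
  pw_bwd(dz, cache$x, P[[paste0(pfx, ".pw.w")]], genv, paste0(pfx, ".pw"))
}

linear_fwd <- function(x, P, pfx) {
  pw_fwd(x, P[[paste0(pfx, ".w")]], P[[paste0(pfx, ".b")]])
}

linear_bwd <- function(dout, x, P, genv, pfx) {
  pw_bwd(dout, x, P[[paste0(pfx, ".w")]], genv, pfx, bias = TRUE)
}
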