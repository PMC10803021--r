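# The densely connected encoder: a stride-4 stem of two depthwise-separable
# stride-2 convolutions, then four dense stages of dual-branch bottlenecks
# (7x7 and 3x3 depthwise-separable branches summed and concatenated with the
# block input), with 1x1 compression + 2x2 average-pool transitions between
# stages. Emits the four-level feature pyramid at strides 4/8/16/32.
# Normalisation is per-image, so there is no training/inference mode split
# and every forward pass is deterministic.

bneck_fwd <- function(x, b, h, w, P, pfx) {
  f7 <- dwsep_fwd(x, b, h, w, P, paste0(pfx, ".br7"), 7L, 1L)
  f3 <- dwsep_fwd(x, b, h, w, P, paste0(pfx, ".br3"), 3L, 1L)
  out <- cbind(x, f7$out + f3$out)
  list(out = out, cache = list(f7 = f7$cache, f3 = f3$cache, cin = ncol(x)))
}

bneck_bwd <- function(dout, cache, P, genv, pfx) {
  cin <- cache$cin
  dx <- dout[, seq_len(cin), drop = FALSE]
  dsum <- dout[, -seq_len(cin), drop = FALSE]
  dx <- dx + dwsep_bwd(dsum, cache$f7, P, genv, paste0(pfx, ".br7"))
  dx + dwsep_bwd(dsum, cache$f3, P, genv, paste0(pfx, ".br3"))
}

stage_fwd <- function(x, b, h, w, P, pfx, depth) {
  caches <- vector("list", depth)
  for (d in seq_len(depth)) {
    r <- bneck_fwd(x, b, h, w, P, sprintf("%s.b%d", pfx, d))
    x <- r$out
    caches[[d]] <- r$cache
  }
  list(out = x, caches = caches)
}

stage_bwd <- function(dout, caches, P, genv, pfx) {
  for (d in rev(seq_along(caches))) {
    dout <- bneck_bwd(dout, caches[[d]], P, genv, sprintf("%s.b%d", pfx, d))
  }
  dout
}

enc_fwd <- function(x, b, h, w, model) {
  P <- model$params; cfg <- model$config
  s1 <- dwsep_fwd(x, b, h, w, P, "enc.stem1", 3L, 2L)
  s2 <- dwsep_fwd(s1$out, b, s1$ho, s1$wo, P, "enc.stem2", 3L, 2L)
  hh <- s2$ho; ww <- s2$wo
  pyr <- vector("list", 4L)
  stc <- vector("list", 4L); trc <- vector("list", 3L)
  cur <- s2$out
  for (s in 1:4) {
    st <- stage_fwd(cur, b, hh, ww, P, sprintf("enc.s%d", s), cfg$depths[s])
    pyr[[s]] <- list(x = st$out, h = hh, w = ww)
    stc[[s]] <- st$caches
    if (s < 4L) {
      tr <- proj_fwd(st$out, b, P, sprintf("enc.t%d", s))
      trc[[s]] <- list(cache = tr$cache, h = hh, w = ww)
      cur <- avgpool_fwd(tr$out, b, hh, ww)
      hh <- hh %/% 2L; ww <- ww %/% 2L
    }
  }
  list(pyr = pyr,
       cache = list(s1 = s1, s2 = s2, stc = stc, trc = trc, b = b))
}

# dpyr: list of 4 gradients w.r.t. the pyramid levels (any may be NULL).
# Stages whose outputs feed nothing (e.g. levels 2-4 when the pyramid
# decoder is off) receive no gradient and are skipped entirely.
enc_bwd <- function(dpyr, cache, model, genv, compute_dx = FALSE) {
  P <- model$params; b <- cache$b
  dcur <- NULL
  for (s in 4:1) {
    if (s < 4L && !is.null(dcur)) {
      tr <- cache$trc[[s]]
      dtr <- avgpool_bwd(dcur, b, tr$h, tr$w)
      dcur <- proj_bwd(dtr, tr$cache, P, genv, sprintf("enc.t%d", s))
    }
    if (!is.null(dpyr[[s]])) {
      dcur <- if (is.null(dcur)) dpyr[[s]] else dcur + dpyr[[s]]
    }
    if (is.null(dcur)) next
    dcur <- stage_bwd(dcur, cache$stc[[s]], P, genv, sprintf("enc.s%d", s))
  }
  d2 <- dwsep_bwd(dcur, cache$s2$cache, P, genv, "enc.stem2")
  d1 <- dwsep_bwd(d2, cache$s1$cache, P, genv, "enc.stem1")
  if (compute_dx) d1 else NULL
}

# ---- public mini-module wrappers (operate on C x H x W arrays) ----

#' Stand-alone dual-branch bottleneck block
#'
#' Builds one bottleneck of the encoder outside the full model: two parallel
#' depthwise-separable branches (7x7 and 3x3 kernels), each mapping the
#' `c_in` input channels to `growth` channels; the branch outputs are summed
#' and concatenated with the input, so the block emits `c_in + growth`
#' channels at unchanged spatial size.
#'
#' @param c_in input channel count.
#' @param growth channels added by the block.
#' @param seed integer seed for weight initialisation.
#' @return An `endoseg_bottleneck` object.
#' @examples
#' blk <- new_bottleneck(16, 24, seed = 1)
#' x <- array(rnorm(16 * 32 * 32), c(16, 32, 32))
#' dim(bottleneck_forward(x, blk))  # 40 x 32 x 32
#' @export
new_bottleneck <- function(c_in, growth, seed = 1L) {
  old <- rng_snapshot(); on.exit(rng_restore(old))
  set.seed(seed)
  params <- list()
  for (k in c(7L, 3L)) {
    params <- init_unit(list(pfx = sprintf("bn.br%d", k), kind = "dwsep", k = k,
                             cin = as.integer(c_in), cout = as.integer(growth)),
                        params)
  }
  structure(list(params = params,
                 c_in = as.integer(c_in), growth = as.integer(growth)),
            class = "endoseg_bottleneck")
}

#' @rdname new_bottleneck
#' @param x feature map, `c_in` x H x W array.
#' @param block an `endoseg_bottleneck`.
#' @export
bottleneck_forward <- function(x, block) {
  stopifnot(inherits(block, "endoseg_bottleneck"))
  if (dim(x)[1L] != block$c_in) {
    stop("input has ", dim(x)[1L], " channels, block expects ", block$c_in)
  }
  h <- dim(x)[2L]; w <- dim(x)[3L]
  r <- bneck_fwd(feature_matrix(x), 1L, h, w, block$params, "bn")
  feature_array(r$out, h, w)
}

#' Stand-alone dense encoder stage
#'
#' A sequence of `depth` dual-branch bottlenecks sharing one growth rate;
#' the stage output has `c_in + depth * growth` channels.
#'
#' @inheritParams new_bottleneck
#' @param depth number of bottlenecks.
#' @return An `endoseg_stage` object.
#' @export
new_dense_stage <- function(c_in, depth, growth, seed = 1L) {
  old <- rng_snapshot(); on.exit(rng_restore(old))
  set.seed(seed)
  params <- list()
  cin <- as.integer(c_in)
  for (d in seq_len(depth)) {
    for (k in c(7L, 3L)) {
      params <- init_unit(list(pfx = sprintf("st.b%d.br%d", d, k), kind = "dwsep",
                               k = k, cin = cin, cout = as.integer(growth)),
                          params)
    }
    cin <- cin + as.integer(growth)
  }
  structure(list(params = params, c_in = as.integer(c_in),
                 depth = as.integer(depth), growth = as.integer(growth)),
            class = "endoseg_stage")
}

#' @rdname new_dense_stage
#' @param x feature map, `c_in` x H x W array.
#' @param stage an `endoseg_stage`.
#' @export
dense_stage_forward <- function(x, stage) {
  stopifnot(inherits(stage, "endoseg_stage"))
  if (dim(x)[1L] != stage$c_in) {
    stop("input has ", dim(x)[1L], " channels, stage expects ", stage$c_in)
  }
  h <- dim(x)[2L]; w <- dim(x)[3L]
  r <- stage_fwd(feature_matrix(x), 1L, h, w, stage$params, "st", stage$depth)
  feature_array(r$out, h, w)
}

#' Encoder forward pass: the four-level feature pyramid
#'
#' Runs the stem and the four dense stages of a built model and returns the
#' pyramid features at strides 4, 8, 16 and 32 relative to the input (for a
#' 256 x 256 input: spatial sizes 64, 32, 16, 8).
#'
#' @param image a 3 x H x W array with H, W divisible by 32.
#' @param model an `endoseg_model` from [build_model()].
#' @return A list of four C_l x H_l x W_l arrays.
#' @export
encoder_forward <- function(image, model) {
  stopifnot(inherits(model, "endoseg_model"), length(dim(image)) == 3L,
            dim(image)[1L] == 3L)
  h <- dim(image)[2L]; w <- dim(image)[3L]
  if (h %% 32L != 0L || w %% 32L != 0L) stop("input size must be divisible by 32")
  r <- enc_fwd(feature_matrix(image), 1L, h, w, model)
  lapply(r$pyr, function(p) feature_array(p$x, p$h, p$w))
}

rng_snapshot <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

rng_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
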