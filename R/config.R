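#' Model configuration
#'
#' Assembles the full set of architectural hyperparameters for the lightweight
#' segmentation network: a four-stage densely connected encoder built from
#' dual-branch (7x7 / 3x3) depthwise-separable bottlenecks, a feature-pyramid
#' fusion decoder, a criss-cross attention block on the fused map, and a
#' depthwise-separable segmentation head. The defaults reproduce the reference
#' model: stage depths 2/2/6/2 and widths chosen so the trainable parameter
#' count rounds to 466 K and the forward pass at 3x256x256 costs 0.202 G
#' multiply-accumulates (see [count_parameters()] and [count_macs()]).
#'
#' @param num_classes integer, number of output classes including background
#'   (k instrument classes give `num_classes = k + 1`).
#' @param stem_channels width after the two stride-2 stem convolutions.
#' @param growth integer vector of length 4, channels added by each bottleneck
#'   in stages 1..4 (the dense growth rates).
#' @param depths integer vector of length 4, bottlenecks per stage; the
#'   reference stacking is `c(2, 2, 6, 2)`.
#' @param compression channel compression factor of the 1x1 transition
#'   convolutions between stages.
#' @param fpn_channels width of the lateral 1x1 convolutions in the pyramid
#'   decoder.
#' @param fused_channels channel count of the fused stride-4 map the decoder
#'   concatenates (each pyramid level contributes `fused_channels / 4`).
#' @param use_fpn logical, include the feature-pyramid fusion (ablation
#'   toggle); when `FALSE` the stride-4 encoder level is merged by a plain
#'   1x1 convolution.
#' @param use_ccam logical, include the criss-cross attention block.
#' @param ccam_reduction channel reduction ratio of the attention query/key
#'   projections (`B = fused_channels / ccam_reduction`, with `B < C`).
#' @param head_channels width of the segmentation head's depthwise-separable
#'   convolution.
#' @return An object of class `endoseg_config` (a validated list).
#' @examples
#' cfg <- model_config(num_classes = 3)
#' count_parameters(cfg)
#' @export
model_config <- function(num_classes = 3L,
                         stem_channels = 12L,
                         growth = c(12L, 20L, 52L, 128L),
                         depths = c(2L, 2L, 6L, 2L),
                         compression = 0.5,
                         fpn_channels = 64L,
                         fused_channels = 64L,
                         use_fpn = TRUE,
                         use_ccam = TRUE,
                         ccam_reduction = 8L,
                         head_channels = 64L) {
  cfg <- list(
    num_classes = as.integer(num_classes),
    stem_channels = as.integer(stem_channels),
    growth = as.integer(growth),
    depths = as.integer(depths),
    compression = compression,
    fpn_channels = as.integer(fpn_channels),
    fused_channels = as.integer(fused_channels),
    use_fpn = isTRUE(use_fpn),
    use_ccam = isTRUE(use_ccam),
    ccam_reduction = as.integer(ccam_reduction),
    head_channels = as.integer(head_channels)
  )
  if (cfg$num_classes < 2L) stop("num_classes must be >= 2 (background + instruments)")
  if (length(cfg$depths) != 4L || any(cfg$depths < 1L)) stop("depths must be 4 positive integers")
  if (length(cfg$growth) != 4L || any(cfg$growth < 1L)) stop("growth must be 4 positive integers")
  if (cfg$compression <= 0 || cfg$compression > 1) stop("compression must be in (0, 1]")
  if (cfg$fused_channels %% 4L != 0L) stop("fused_channels must be divisible by 4")
  bq <- max(1L, cfg$fused_channels %/% cfg$ccam_reduction)
  if (bq >= cfg$fused_channels) stop("ccam_reduction must give B < C")
  structure(cfg, class = "endoseg_config")
}

#' @export
print.endoseg_config <- function(x, ...) {
  cat("<endoseg_config>\n")
  cat("  classes:", x$num_classes,
      " stem:", x$stem_channels,
      " growth:", paste(x$growth, collapse = "/"),
      " depths:", paste(x$depths, collapse = "/"), "\n")
  cat("  fpn:", x$use_fpn, " ccam:", x$use_ccam,
      " fpn_channels:", x$fpn_channels,
      " fused:", x$fused_channels, "\n")
  invisible(x)
}

# channel bookkeeping shared by init, forward pass and profiler
channel_plan <- function(cfg) {
  stages <- vector("list", 4L)
  c_in <- cfg$stem_channels
  pyramid <- integer(4L)
  for (s in 1:4) {
    blocks <- c_in + cfg$growth[s] * (0:(cfg$depths[s] - 1L))  # input width of each block
    c_out <- c_in + cfg$depths[s] * cfg$growth[s]
    trans <- if (s < 4L) as.integer(floor(c_out * cfg$compression)) else NA_integer_
    stages[[s]] <- list(block_in = blocks, out = c_out, trans = trans)
    pyramid[s] <- c_out
    c_in <- if (s < 4L) trans else c_out
  }
  list(stages = stages, pyramid = pyramid,
       contrib = cfg$fused_channels %/% 4L,
       b_channels = max(1L, cfg$fused_channels %/% cfg$ccam_reduction))
}

# Flat enumeration of every parameterised unit plus the parameter-free
# compute entries (bilinear resizes, the attention gather). The same table
# drives parameter initialisation, the analytic parameter count and the MAC
# count, so the three can never drift apart; a structural walk of the built
# parameter list cross-checks it.
#
# kinds: dwsep (depthwise k x k + BN + ReLU + pointwise + BN + ReLU),
#        proj  (1x1 conv no bias + BN + ReLU),
#        linear (1x1 conv with bias),
#        bilinear / ccattn (compute only).
# div_in: input side divisor relative to the network input.
model_units <- function(cfg) {
  pl <- channel_plan(cfg)
  u <- list()
  add <- function(pfx, kind, k, cin, cout, stride, div_in) {
    u[[length(u) + 1L]] <<- list(pfx = pfx, kind = kind, k = k, cin = cin,
                                 cout = cout, stride = stride, div_in = div_in)
  }
  S <- cfg$stem_channels
  add("enc.stem1", "dwsep", 3L, 3L, S, 2L, 1L)
  add("enc.stem2", "dwsep", 3L, S, S, 2L, 2L)
  div <- c(4L, 8L, 16L, 32L)
  for (s in 1:4) {
    st <- pl$stages[[s]]
    for (d in seq_len(cfg$depths[s])) {
      cin <- st$block_in[d]
      add(sprintf("enc.s%d.b%d.br7", s, d), "dwsep", 7L, cin, cfg$growth[s], 1L, div[s])
      add(sprintf("enc.s%d.b%d.br3", s, d), "dwsep", 3L, cin, cfg$growth[s], 1L, div[s])
    }
    if (s < 4L) add(sprintf("enc.t%d", s), "proj", 1L, st$out, st$trans, 1L, div[s])
  }
  fp <- cfg$fpn_channels; ct <- pl$contrib
  if (cfg$use_fpn) {
    for (l in 1:4) add(sprintf("dec.lat%d", l), "linear", 1L, pl$pyramid[l], fp, 1L, div[l])
    # top-down merges: merged level l+1 upsampled 2x onto level l
    for (l in 3:1) add(sprintf("dec.td%d", l), "bilinear", NA, NA, fp, NA, div[l])
    add("dec.red1", "proj", 1L, fp, ct, 1L, 4L)
    for (l in 2:4) {
      nblk <- l - 1L
      for (i in seq_len(nblk)) {
        cout <- if (i == nblk) ct else fp
        d_in <- div[l] %/% (2L^(i - 1L))
        add(sprintf("dec.chain%d.u%d", l, i), "dwsep", 3L, fp, cout, 1L, d_in)
        add(sprintf("dec.chain%d.up%d", l, i), "bilinear", NA, NA, cout, NA, d_in %/% 2L)
      }
    }
  } else {
    add("dec.merge", "proj", 1L, pl$pyramid[1L], cfg$fused_channels, 1L, 4L)
  }
  if (cfg$use_ccam) {
    Cf <- cfg$fused_channels; Bq <- pl$b_channels
    add("ccam.q", "linear", 1L, Cf, Bq, 1L, 4L)
    add("ccam.k", "linear", 1L, Cf, Bq, 1L, 4L)
    add("ccam.v", "linear", 1L, Cf, Cf, 1L, 4L)
    add("ccam.attn", "ccattn", NA, Bq, Cf, NA, 4L)
  }
  add("head.conv", "dwsep", 3L, cfg$fused_channels, cfg$head_channels, 1L, 4L)
  add("head.cls", "linear", 1L, cfg$head_channels, cfg$num_classes, 1L, 4L)
  add("head.up", "bilinear", NA, NA, cfg$num_classes, NA, 1L)
  u
}

#' Read or write a model configuration as YAML
#'
#' @param path file path.
#' @return `read_model_config()` returns an `endoseg_config`;
#'   `write_model_config()` returns `path` invisibly.
#' @export
read_model_config <- function(path) {
  do.call(model_config, yaml::read_yaml(path))
}

#' @rdname read_model_config
#' @param cfg an `endoseg_config`.
#' @export
write_model_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
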