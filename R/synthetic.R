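# Synthetic endoscopy scenes: dark vignetted tissue backgrounds with one or
# more elongated metallic instruments entering from a frame edge, small
# rounded tips, specular highlights and sensor noise, plus the dataset
# preparation steps (seeded shuffle split with the 60/20/20 rounding rule,
# bilinear/nearest resize, PNG fixtures on disk). Everything is a pure
# function of the configuration seed.

#' Synthetic scene configuration
#'
#' Describes one endoscopy-like frame: a dark, vignetted, reddish tissue
#' background and `n_instruments` rotated-capsule instruments (shaft plus
#' semicircular tip) entering from the frame border, shaded like cylinders
#' with a brightness gradient along the shaft and a class-specific metallic
#' tint so the k instrument classes are visually distinguishable. Instrument
#' classes are assigned cyclically (instrument m gets class ((m-1) mod k)+1),
#' so every class 1..k occurs whenever `n_instruments >= instrument_classes`.
#'
#' @param image_size square frame side in pixels.
#' @param n_instruments number of instruments drawn (>= 0).
#' @param instrument_classes number of instrument classes k (>= 1).
#' @param min_width,max_width instrument shaft width range, pixels.
#' @param background_base_intensity mean tissue brightness in `[0, 1]`;
#'   endoscopic scenes are low-light, so the default is dark.
#' @param vignette_strength radial light falloff in `[0, 1]`.
#' @param specular_count number of specular highlight blobs.
#' @param noise_sigma standard deviation of additive Gaussian sensor noise.
#' @param seed integer seed; the scene is fully determined by it.
#' @return A `scene_config` list.
#' @export
scene_config <- function(image_size = 256L,
                         n_instruments = 2L,
                         instrument_classes = 2L,
                         min_width = 14,
                         max_width = 28,
                         background_base_intensity = 0.18,
                         vignette_strength = 0.6,
                         specular_count = 3L,
                         noise_sigma = 0.02,
                         seed = 1L) {
  cfg <- list(image_size = as.integer(image_size),
              n_instruments = as.integer(n_instruments),
              instrument_classes = as.integer(instrument_classes),
              min_width = min_width, max_width = max_width,
              background_base_intensity = background_base_intensity,
              vignette_strength = vignette_strength,
              specular_count = as.integer(specular_count),
              noise_sigma = noise_sigma, seed = as.integer(seed))
  if (cfg$image_size < 16L) stop("image_size must be >= 16")
  if (cfg$n_instruments < 0L) stop("n_instruments must be >= 0")
  if (cfg$n_instruments > 0L && cfg$instrument_classes < 1L) {
    stop("instrument_classes must be >= 1 when instruments are drawn")
  }
  if (cfg$min_width <= 0 || cfg$max_width < cfg$min_width) {
    stop("need 0 < min_width <= max_width")
  }
  if (cfg$background_base_intensity < 0 || cfg$background_base_intensity > 1) {
    stop("background_base_intensity must be in [0, 1]")
  }
  if (cfg$vignette_strength < 0 || cfg$vignette_strength > 1) {
    stop("vignette_strength must be in [0, 1]")
  }
  if (cfg$noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(cfg, class = "scene_config")
}

#' Generate one synthetic endoscopy scene
#'
#' @param config a [scene_config()].
#' @return List with `image` (3 x S x S array, values in `[0, 1]`) and
#'   `mask` (S x S integer matrix, 0 = background tissue, 1..k instrument
#'   classes).
#' @examples
#' sc <- generate_scene(scene_config(n_instruments = 2, seed = 3))
#' sort(unique(as.vector(sc$mask)))
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  old <- rng_snapshot(); on.exit(rng_restore(old))
  set.seed(config$seed)
  s <- config$image_size
  xg <- matrix(rep(seq_len(s), each = s), s)   # column index j
  yg <- matrix(rep(seq_len(s), times = s), s)  # row index i
  # smooth tissue field: low-resolution noise upsampled bilinearly
  lowres <- 8L
  field <- matrix(stats::rnorm(lowres^2, mean = 1, sd = 0.25), lowres)
  field <- matrix(bilinear_fwd(matrix(as.vector(field), ncol = 1L),
                               1L, lowres, lowres, s, s), s)
  field <- pmax(field, 0.3)
  cx <- s / 2 + stats::runif(1, -s / 10, s / 10)
  cy <- s / 2 + stats::runif(1, -s / 10, s / 10)
  r2 <- ((yg - cy)^2 + (xg - cx)^2) / (s / 2)^2
  vig <- pmax(1 - config$vignette_strength * r2, 0)
  base <- config$background_base_intensity * field * vig
  img <- array(0, c(3L, s, s))
  img[1L, , ] <- base * 1.45   # reddish tissue
  img[2L, , ] <- base * 0.62
  img[3L, , ] <- base * 0.55
  mask <- matrix(0L, s, s)
  k <- config$instrument_classes
  # class tints: cool metallic hues, distinct per class
  tint <- rbind(c(0.82, 0.88, 1.00), c(0.80, 1.00, 0.84),
                c(1.00, 0.95, 0.75))[rep(1:3, length.out = max(k, 1L)), , drop = FALSE]
  if (config$n_instruments > 0L) {
    for (m in seq_len(config$n_instruments)) {
      cls <- ((m - 1L) %% k) + 1L
      side <- sample.int(4L, 1L)  # 1 top, 2 bottom, 3 left, 4 right
      t0 <- stats::runif(1, 0.15, 0.85) * s
      entry <- switch(side, c(1, t0), c(s, t0), c(t0, 1), c(t0, s))
      inward <- switch(side, 0, pi, pi / 2, -pi / 2)  # angle of (di, dj)
      ang <- inward + stats::runif(1, -pi / 5, pi / 5)
      len <- stats::runif(1, 0.55, 1.05) * s
      wid <- stats::runif(1, config$min_width, config$max_width)
      tip <- entry + len * c(cos(ang), sin(ang))
      # distance from every pixel to the segment entry->tip
      vx <- tip[1] - entry[1]; vy <- tip[2] - entry[2]
      L2 <- vx^2 + vy^2
      tpar <- pmin(pmax(((yg - entry[1]) * vx + (xg - entry[2]) * vy) / L2, 0), 1)
      px <- entry[1] + tpar * vx; py <- entry[2] + tpar * vy
      d <- sqrt((yg - px)^2 + (xg - py)^2)
      inside <- d <= wid / 2
      if (!any(inside)) next
      mask[inside] <- cls
      # cylindrical shading x gradient along the shaft (brighter at the tip)
      shade <- sqrt(pmax(1 - (d / (wid / 2))^2, 0))
      grad <- 0.5 + 0.4 * tpar
      lum <- (0.45 + 0.4 * shade) * grad
      for (ch in 1:3) {
        plane <- img[ch, , ]
        plane[inside] <- (lum * tint[cls, ch])[inside]
        img[ch, , ] <- plane
      }
    }
  }
  for (sp in seq_len(config$specular_count)) {
    scx <- stats::runif(1, 1, s); scy <- stats::runif(1, 1, s)
    rad <- stats::runif(1, 2, 5)
    g <- exp(-((yg - scy)^2 + (xg - scx)^2) / (2 * rad^2))
    for (ch in 1:3) img[ch, , ] <- img[ch, , ] + 0.9 * g
  }
  if (config$noise_sigma > 0) {
    img <- img + array(stats::rnorm(length(img), sd = config$noise_sigma), dim(img))
  }
  img <- pmin(pmax(img, 0), 1)
  list(image = img, mask = mask)
}

#' Shuffled 60/20/20 dataset split
#'
#' Shuffles the indices 1..N with a seeded generator and assigns
#' `round(0.2 N)` of them to validation, `round(0.2 N)` to test (rounding
#' half up) and the remainder to training -- the rule that maps the 2,344
#' frames of the reference dataset to 1,406 / 469 / 469.
#'
#' @param n_total number of samples, >= 5.
#' @param fractions train/val/test fractions; must be `c(0.6, 0.2, 0.2)`.
#' @param seed integer shuffle seed.
#' @return An `endoseg_split`: list with integer index vectors `train`,
#'   `val`, `test` (1-based, pairwise disjoint, union 1..N), plus `seed` and
#'   `fractions`.
#' @examples
#' sp <- split_dataset(2344, seed = 1)
#' lengths(sp[c("train", "val", "test")])  # 1406 469 469
#' @export
split_dataset <- function(n_total, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  n_total <- as.integer(n_total)
  if (n_total < 5L) stop("n_total must be >= 5")
  if (length(fractions) != 3L || any(abs(fractions - c(0.6, 0.2, 0.2)) > 1e-12)) {
    stop("fractions must be c(0.6, 0.2, 0.2)")
  }
  n_val <- as.integer(floor(0.2 * n_total + 0.5))   # round half up
  n_test <- as.integer(floor(0.2 * n_total + 0.5))
  n_train <- n_total - n_val - n_test
  if (n_train < 1L || n_val < 1L || n_test < 1L) {
    stop("n_total too small for non-empty subsets")
  }
  old <- rng_snapshot(); on.exit(rng_restore(old))
  set.seed(seed)
  perm <- sample.int(n_total)
  structure(list(train = perm[seq_len(n_train)],
                 val = perm[n_train + seq_len(n_val)],
                 test = perm[n_train + n_val + seq_len(n_test)],
                 seed = as.integer(seed), fractions = fractions),
            class = "endoseg_split")
}

#' @export
print.endoseg_split <- function(x, ...) {
  cat(sprintf("<endoseg_split> train %d / val %d / test %d (seed %d)\n",
              length(x$train), length(x$val), length(x$test), x$seed))
  invisible(x)
}

#' Resize an image/mask pair
#'
#' The image is resampled bilinearly (half-pixel convention), the label mask
#' by nearest neighbour (source index `floor((i + 0.5) * n_in / n_out)`,
#' clamped), so no new labels can appear.
#'
#' @param image 3 x H x W array.
#' @param mask H x W integer matrix.
#' @param target_size output side length (square output).
#' @return List with resized `image` and `mask`.
#' @export
resize_pair <- function(image, mask, target_size) {
  stopifnot(length(dim(image)) == 3L)
  h <- dim(image)[2L]; w <- dim(image)[3L]
  if (nrow(mask) != h || ncol(mask) != w) stop("image and mask shapes differ")
  t <- as.integer(target_size)
  im <- bilinear_fwd(feature_matrix(image), 1L, h, w, t, t)
  list(image = feature_array(im, t, t),
       mask = nearest_resize(mask, t, t))
}

#' Write a synthetic dataset to disk
#'
#' Generates `n` scenes (frame i uses seed `scene_config$seed + i - 1`),
#' writes them as 8-bit PNG pairs (RGB image; grayscale mask whose pixel
#' value is the class label) and a two-column CSV manifest.
#'
#' @param n number of image/mask pairs.
#' @param config a [scene_config()]; its seed anchors the whole dataset.
#' @param out_dir output directory (created if missing).
#' @return The manifest data.frame (`image_path`, `mask_path`) with
#'   attributes `k` (class count) and `image_size`; also written to
#'   `manifest.csv` in `out_dir`.
#' @export
write_dataset <- function(n, config, out_dir) {
  stopifnot(inherits(config, "scene_config"), n >= 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  image_path <- file.path(out_dir, sprintf("img_%04d.png", seq_len(n)))
  mask_path <- file.path(out_dir, sprintf("mask_%04d.png", seq_len(n)))
  for (i in seq_len(n)) {
    ci <- config; ci$seed <- config$seed + i - 1L
    sc <- generate_scene(ci)
    png::writePNG(aperm(sc$image, c(2L, 3L, 1L)), image_path[i])
    png::writePNG(sc$mask / 255, mask_path[i])
  }
  man <- data.frame(image_path = image_path, mask_path = mask_path,
                    stringsAsFactors = FALSE)
  utils::write.csv(man, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  attr(man, "k") <- config$instrument_classes
  attr(man, "image_size") <- config$image_size
  man
}

#' Read a dataset manifest
#'
#' @param path path to a `manifest.csv` written by [write_dataset()] (or any
#'   CSV with `image_path`, `mask_path` columns).
#' @return The manifest data.frame; errors if a listed file is missing.
#' @export
read_manifest <- function(path) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("image_path", "mask_path") %in% names(man))) {
    stop("manifest must have image_path and mask_path columns")
  }
  missing <- c(man$image_path, man$mask_path)
  missing <- missing[!file.exists(missing)]
  if (length(missing)) stop("missing files: ", paste(missing, collapse = ", "))
  man
}

#' Load one image/mask pair from PNG files
#'
#' @param image_path 8-bit RGB PNG.
#' @param mask_path 8-bit grayscale PNG whose pixel value is the class label.
#' @return List with `image` (3 x H x W array) and `mask` (H x W integer
#'   matrix).
#' @export
load_pair <- function(image_path, mask_path) {
  im <- png::readPNG(image_path)
  if (length(dim(im)) == 2L) stop("image PNG must be RGB: ", image_path)
  mk <- png::readPNG(mask_path)
  if (length(dim(mk)) == 3L) mk <- mk[, , 1L]
  mask <- matrix(as.integer(round(mk * 255)), nrow(mk), ncol(mk))
  if (nrow(mask) != dim(im)[1L] || ncol(mask) != dim(im)[2L]) {
    stop("image and mask sizes differ for ", image_path)
  }
  list(image = aperm(im[, , 1:3], c(3L, 1L, 2L)), mask = mask)
}
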