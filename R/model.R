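#' Build the segmentation model
#'
#' Initialises all trainable parameters of the network described by a
#' configuration. Weights use He-normal initialisation seeded by `seed`, so
#' builds are reproducible. Normalisation layers carry only their affine
#' scale/shift parameters (statistics are recomputed per image), so the
#' parameter list is the complete model state.
#'
#' @param config an `endoseg_config` from [model_config()].
#' @param seed integer seed for weight initialisation.
#' @return An `endoseg_model`: list with `config` and the flat named
#'   `params` list.
#' @examples
#' m <- build_model(model_config(num_classes = 2), seed = 1)
#' count_parameters(m) == count_parameters(m$config)
#' @export
build_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "endoseg_config"))
  old <- rng_snapshot(); on.exit(rng_restore(old))
  set.seed(seed)
  params <- list()
  for (u in model_units(config)) {
    if (u$kind %in% c("bilinear", "ccattn")) next
    params <- init_unit(u, params)
  }
  structure(list(config = config, params = params), class = "endoseg_model")
}

#' @export
print.endoseg_model <- function(x, ...) {
  cat("<endoseg_model>", format(count_parameters(x), big.mark = ","),
      "trainable parameters\n")
  print(x$config)
  invisible(x)
}

# stack a list of 3 x H x W arrays into the batch matrix
stack_images <- function(images) {
  if (is.array(images) && length(dim(images)) == 3L) images <- list(images)
  d <- dim(images[[1L]])
  stopifnot(d[1L] == 3L)
  for (im in images) stopifnot(all(dim(im) == d))
  x <- do.call(rbind, lapply(images, feature_matrix))
  list(x = x, b = length(images), h = d[2L], w = d[3L])
}

#' Full model forward pass
#'
#' Encoder, pyramid fusion (or plain 1x1 merge when `use_fpn` is off),
#' criss-cross attention (when `use_ccam` is on) and segmentation head.
#' Deterministic: normalisation uses per-image statistics, so repeated
#' passes and different batchings give identical results.
#'
#' @param model an `endoseg_model`.
#' @param images a 3 x H x W array or a list of them (H, W divisible by 32).
#' @return A `num_classes` x H x W logits array, or a list of them for a
#'   list input.
#' @export
model_forward <- function(model, images) {
  stopifnot(inherits(model, "endoseg_model"))
  single <- is.array(images) && length(dim(images)) == 3L
  st <- stack_images(images)
  if (st$h %% 32L != 0L || st$w %% 32L != 0L) stop("input size must be divisible by 32")
  r <- net_fwd(st$x, st$b, st$h, st$w, model)
  n <- st$h * st$w
  out <- lapply(seq_len(st$b), function(bb) {
    feature_array(r$logits[(bb - 1L) * n + seq_len(n), , drop = FALSE], st$h, st$w)
  })
  if (single) out[[1L]] else out
}

#' Predict label masks
#'
#' Runs the model and takes the per-pixel argmax over the class logits.
#' Background is label 0.
#'
#' @inheritParams model_forward
#' @return An H x W integer mask, or a list of them for a list input.
#' @export
predict_masks <- function(model, images) {
  single <- is.array(images) && length(dim(images)) == 3L
  st <- stack_images(images)
  r <- net_fwd(st$x, st$b, st$h, st$w, model)
  n <- st$h * st$w
  out <- lapply(seq_len(st$b), function(bb) {
    lg <- r$logits[(bb - 1L) * n + seq_len(n), , drop = FALSE]
    matrix(max.col(lg, ties.method = "first") - 1L, st$h, st$w)
  })
  if (single) out[[1L]] else out
}

# one optimisation step's worth of gradients: forward, loss, backward.
# Returns list(loss, grads) with grads a flat list aligned with params.
net_loss_grads <- function(model, x, b, h, w, target, loss_cfg) {
  fw <- net_fwd(x, b, h, w, model)
  fl <- focal_fwd_bwd(fw$logits, target, loss_cfg)
  genv <- new.env(parent = emptyenv())
  net_bwd(fl$dlogits, fw$cache, model, genv)
  list(loss = fl$loss, grads = grad_list(genv, model$params))
}

# snapshot / restore of model state (the parameter list is the full state)
model_state <- function(model) {
  list(params = model$params)
}

model_load_state <- function(model, state) {
  model$params <- state$params
  model
}
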