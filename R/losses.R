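# Focal loss for multi-class pixel classification.
#
# Per pixel with true class t and softmax probability p_t:
#   FL = -alpha_t * (1 - p_t)^gamma * log(p_t)
# with alpha_t = alpha for instrument classes (label >= 1) and 1 - alpha for
# background (the positive/negative balancing of the binary formulation
# carried to the foreground/background axis). gamma down-weights
# well-classified pixels. Natural logarithm; mean reduction over pixels.
# All probabilities are taken from log-softmax, so the loss stays finite for
# p_t down to the underflow limit.

#' Focal loss configuration
#'
#' @param gamma focusing parameter, >= 0; `gamma = 0` with `alpha_t` forced
#'   to 1 recovers plain cross-entropy. Default 2.
#' @param alpha foreground balancing weight in (0, 1); background pixels get
#'   `1 - alpha`. Default 0.25.
#' @param ignore_index optional label excluded from the loss (e.g. unlabeled
#'   border pixels); `NULL` to use every pixel.
#' @return A `focal_config` list.
#' @export
focal_config <- function(gamma = 2, alpha = 0.25, ignore_index = NULL) {
  if (gamma < 0) stop("gamma must be >= 0")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  structure(list(gamma = gamma, alpha = alpha, ignore_index = ignore_index),
            class = "focal_config")
}

log_softmax <- function(z) {
  m <- rowmax(z)
  zs <- z - m
  zs - log(rowSums(exp(zs)))
}

# logits: N x K matrix, target: integer vector length N with labels 0..K-1
# (or ignore_index). Returns loss and gradient w.r.t. logits (already
# including the 1/N mean factor).
focal_fwd_bwd <- function(logits, target, cfg) {
  k <- ncol(logits)
  valid <- !is.na(target)
  if (!is.null(cfg$ignore_index)) valid <- valid & target != cfg$ignore_index
  if (any(target[valid] < 0L | target[valid] >= k)) {
    stop("target labels must lie in 0..", k - 1L)
  }
  n <- sum(valid)
  if (n == 0L) stop("no pixels left to evaluate the loss on")
  lp <- log_softmax(logits)
  p <- exp(lp)
  idx <- cbind(which(valid), target[valid] + 1L)
  lpt <- lp[idx]
  pt <- pmin(p[idx], 1)  # guard rounding above 1
  at <- ifelse(target[valid] >= 1L, cfg$alpha, 1 - cfg$alpha)
  omp <- 1 - pt
  loss <- sum(-at * omp^cfg$gamma * lpt) / n  # mean over valid pixels
  # dFL/dz_j = alpha_t (delta_tj - p_j) (gamma p_t (1-p_t)^(gamma-1) log p_t - (1-p_t)^gamma)
  gm <- cfg$gamma
  fac <- if (gm == 0) rep(-1, length(pt)) else {
    ompg1 <- ifelse(omp > 0, omp^(gm - 1), 0)
    gm * pt * ompg1 * lpt - omp^gm
  }
  dl <- matrix(0, nrow(logits), k)
  coef <- at * fac / n
  dl[valid, ] <- -p[valid, , drop = FALSE] * coef
  dl[idx] <- dl[idx] + coef
  list(loss = loss, dlogits = dl)
}

#' Focal loss
#'
#' Mean focal loss over the pixels of one image (or any logits/target pair).
#'
#' @param logits class scores: a `(k+1)` x H x W array or an N x (k+1)
#'   matrix.
#' @param target integer label mask: H x W matrix or length-N vector with
#'   values in 0..k (0 = background) or `ignore_index`.
#' @param config a [focal_config()].
#' @return Non-negative scalar loss.
#' @examples
#' lg <- array(0, c(2, 2, 2)); lg[2, , ] <- 3   # confident foreground
#' focal_loss(lg, matrix(1L, 2, 2))
#' @export
focal_loss <- function(logits, target, config = focal_config()) {
  if (is.array(logits) && length(dim(logits)) == 3L) logits <- feature_matrix(logits)
  target <- as.integer(target)
  if (length(target) != nrow(logits)) stop("logits and target sizes differ")
  focal_fwd_bwd(logits, target, config)$loss
}

#' Mean cross-entropy, the gamma = 0 / alpha_t = 1 degenerate focal loss
#'
#' @inheritParams focal_loss
#' @return Scalar mean negative log-likelihood.
#' @export
cross_entropy_loss <- function(logits, target) {
  if (is.array(logits) && length(dim(logits)) == 3L) logits <- feature_matrix(logits)
  target <- as.integer(target)
  lp <- log_softmax(logits)
  -mean(lp[cbind(seq_along(target), target + 1L)])
}
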