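# Model efficiency accounting: trainable parameters and multiply-accumulates.
#
# Counting conventions (stated, and used consistently everywhere):
#   * a convolution costs kernel_elements x output_elements MACs
#     (bias additions and batch-norm are not counted);
#   * the criss-cross attention gather costs B*(H+W-1) MACs per position for
#     the affinity dot products and C*(H+W-1) for the aggregation;
#   * a bilinear resize costs 4 MACs per output element;
#   * trainable parameters are convolution kernels, biases where present, and
#     the normalisation scale/shift pairs.

unit_params <- function(u) {
  switch(u$kind,
    dwsep = u$k^2 * u$cin + 2L * u$cin + u$cin * u$cout + 2L * u$cout,
    proj = u$cin * u$cout + 2L * u$cout,
    linear = u$cin * u$cout + u$cout,
    0L
  )
}

unit_macs <- function(u, input_size) {
  if (u$kind %in% c("dwsep", "proj", "linear")) {
    n_out <- (input_size %/% (u$div_in * u$stride))^2
    kk <- if (u$kind == "dwsep") u$k^2 * u$cin + u$cin * u$cout else u$cin * u$cout
    return(as.numeric(kk) * n_out)
  }
  if (u$kind == "bilinear") {
    n_out <- (input_size %/% u$div_in)^2
    return(4 * as.numeric(u$cout) * n_out)
  }
  if (u$kind == "ccattn") {
    n <- input_size %/% u$div_in
    hw <- as.numeric(n) * n
    return((u$cin + u$cout) * (2 * n - 1) * hw)  # affinity B + aggregation C per position
  }
  0
}

#' Count trainable parameters
#'
#' Analytic parameter count of the network described by a configuration, or a
#' structural walk over the parameter list of a built model. The two routes
#' agree exactly (this is asserted in the test suite); the analytic route
#' needs no weights and is instant.
#'
#' @param x an `endoseg_config` or an `endoseg_model`.
#' @return Integer parameter count.
#' @examples
#' count_parameters(model_config())  # reference model: rounds to 466 K
#' @export
count_parameters <- function(x) {
  if (inherits(x, "endoseg_model")) {
    return(sum(vapply(x$params, length, integer(1L))))
  }
  stopifnot(inherits(x, "endoseg_config"))
  sum(vapply(model_units(x), unit_params, numeric(1L)))
}

#' Count multiply-accumulate operations of one forward pass
#'
#' @param cfg an `endoseg_config`.
#' @param input_size input side length in pixels (square input, divisible
#'   by 32). Convolutional cost scales linearly with pixel count.
#' @return MAC count (numeric, exact integer value).
#' @examples
#' count_macs(model_config(), 256) / 1e9  # reference model: 0.202 G
#' @export
count_macs <- function(cfg, input_size = 256L) {
  stopifnot(inherits(cfg, "endoseg_config"))
  if (input_size %% 32L != 0L) stop("input_size must be divisible by 32")
  sum(vapply(model_units(cfg), unit_macs, numeric(1L), input_size = input_size))
}

#' Model efficiency report
#'
#' Parameter and compute budget of a configuration: raw counts plus the
#' conventional summary figures (parameters rounded half-up to the nearest
#' thousand; MACs in units of 1e9 to three decimals). Because some profilers
#' report 2 x MACs under the name FLOPs, the doubled figure is included for
#' transparency; the MAC figure is the comparison value.
#'
#' @param cfg an `endoseg_config`.
#' @param input_size input side length used for the MAC count.
#' @return An `endoseg_efficiency` list with fields `parameter_count`,
#'   `parameter_count_k`, `mac_count`, `mac_count_g`, `flops_2x_g`,
#'   `input_size`.
#' @export
efficiency_report <- function(cfg, input_size = 256L) {
  p <- count_parameters(cfg)
  m <- count_macs(cfg, input_size)
  structure(list(
    parameter_count = p,
    parameter_count_k = as.integer(floor(p / 1000 + 0.5)),  # round half up
    mac_count = m,
    mac_count_g = round(m / 1e9, 3L),
    flops_2x_g = round(2 * m / 1e9, 3L),
    input_size = as.integer(input_size)
  ), class = "endoseg_efficiency")
}

#' @export
print.endoseg_efficiency <- function(x, ...) {
  cat("<endoseg_efficiency>\n")
  cat(sprintf("  parameters : %d (%d K)\n", x$parameter_count, x$parameter_count_k))
  cat(sprintf("  MACs @ %dpx : %.0f (%.3f G; 2x = %.3f G)\n",
              x$input_size, x$mac_count, x$mac_count_g, x$flops_2x_g))
  invisible(x)
}
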