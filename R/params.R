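#' GUTS-RED parameter vectors
#'
#' The two reduced GUTS variants share the one-compartment toxicokinetic
#' with dominant rate constant `kd` (1/day) and a background hazard `hb`
#' (1/day), and differ in the death mechanism:
#'
#' * **SD** (stochastic death): all individuals share an internal threshold
#'   `z` (concentration units); above it the hazard increases linearly with
#'   the scaled damage at killing rate `bw` (1/(concentration x day)).
#' * **IT** (individual tolerance): thresholds vary between individuals
#'   following a log-logistic distribution with median `mw` (concentration
#'   units) and shape `beta`; death is immediate at the first exceedance of
#'   the individual threshold.
#'
#' @param kd dominant rate constant (1/day), `> 0`.
#' @param bw killing rate (1/(concentration x day)), `> 0` (SD only).
#' @param z internal threshold (concentration), `>= 0` (SD only).
#' @param mw median of the threshold distribution, `> 0` (IT only).
#' @param beta shape of the threshold distribution, `> 0` (IT only).
#' @param hb background hazard rate (1/day), `>= 0`.
#' @return A named list of class `sd_params` or `it_params` (both inherit
#'   from `guts_params`).
#' @examples
#' sd_params(kd = 0.8, bw = 0.5, z = 2, hb = 0.01)
#' it_params(kd = 0.8, mw = 2, beta = 2, hb = 0.01)
#' @export
sd_params <- function(kd, bw, z, hb = 0) {
  .check_pos(kd = kd, bw = bw)
  .check_nonneg(z = z, hb = hb)
  structure(list(kd = kd, bw = bw, z = z, hb = hb),
            class = c("sd_params", "guts_params"))
}

#' @rdname sd_params
#' @export
it_params <- function(kd, mw, beta, hb = 0) {
  .check_pos(kd = kd, mw = mw, beta = beta)
  .check_nonneg(hb = hb)
  structure(list(kd = kd, mw = mw, beta = beta, hb = hb),
            class = c("it_params", "guts_params"))
}

#' @export
print.guts_params <- function(x, ...) {
  tag <- if (inherits(x, "sd_params")) "GUTS-RED-SD" else "GUTS-RED-IT"
  cat(tag, "parameters:\n")
  print(unlist(x))
  invisible(x)
}

.check_pos <- function(...) {
  v <- list(...)
  for (nm in names(v))
    if (!is.numeric(v[[nm]]) || length(v[[nm]]) != 1L ||
        !is.finite(v[[nm]]) || v[[nm]] <= 0)
      stop("`", nm, "` must be a finite positive number")
  invisible(TRUE)
}

.check_nonneg <- function(...) {
  v <- list(...)
  for (nm in names(v))
    if (!is.numeric(v[[nm]]) || length(v[[nm]]) != 1L ||
        !is.finite(v[[nm]]) || v[[nm]] < 0)
      stop("`", nm, "` must be a finite non-negative number")
  invisible(TRUE)
}

.model_tag <- function(params) {
  if (inherits(params, "sd_params")) "SD"
  else if (inherits(params, "it_params")) "IT"
  else stop("`params` must be built with sd_params() or it_params()")
}
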