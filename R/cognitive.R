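#' Risk-attitude response curve
#'
#' The contact radius a susceptible individual chooses for the next step,
#' given the infection load it currently observes and its risk attitude:
#'
#'   r = r0 * sqrt(1 - I^alpha)
#'
#' where `I` is the infection load (infected neighbours / total neighbours in
#' the awareness neighbourhood, in `[0, 1]`) and `alpha > 0` is the risk
#' attitude. Lower `alpha` is more cautious: the radius falls faster as the
#' load rises. At `I = 0` the radius is the maximum `r0`; at `I = 1` it is 0.
#'
#' @param infection_load Observed infection load(s) in `[0, 1]`.
#' @param risk_attitude Positive risk attitude(s), `alpha`. `Inf` is accepted
#'   and means "no response": the radius stays at `r0` for any load below 1.
#' @param r0 Maximum contact radius (default 4).
#'
#' @return Radii in `[0, r0]`, vectorized over the inputs.
#' @seealso [infer_alpha()] for the exact inverse.
#' @examples
#' response_radius(0.25, 0.20753, 4)
#' @export
response_radius <- function(infection_load, risk_attitude, r0 = 4) {
  if (anyNA(infection_load) || any(infection_load < 0 | infection_load > 1)) {
    stop("`infection_load` must lie in [0, 1]", call. = FALSE)
  }
  if (anyNA(risk_attitude) || any(risk_attitude <= 0)) {
    stop("`risk_attitude` must be positive", call. = FALSE)
  }
  if (anyNA(r0) || any(r0 <= 0)) stop("`r0` must be positive", call. = FALSE)
  # I^Inf is NaN at I = 1 in IEEE arithmetic; the limit of the curve is 0 there
  powed <- infection_load^risk_attitude
  powed[is.nan(powed)] <- 1
  r0 * sqrt(1 - powed)
}

#' Effective risk attitude from an observed response
#'
#' Inverts the response curve: given the radius chosen for the next step and
#' the load that prompted it,
#'
#'   alpha = log(1 - (r / r0)^2) / log(I).
#'
#' The inverse is defined only when infection is present and contact was
#' actually reduced (`0 < I < 1` and `r < r0`); on all other steps the
#' effective risk attitude is not calculable and `NA` is returned. `NA` is
#' the typed "undefined" sentinel used throughout the inference pipeline;
#' such steps are excluded from analysis, never coerced to 0 or infinity.
#'
#' @param next_radius Chosen radius (or radii) in `[0, r0]`.
#' @param infection_load Observed infection load(s) in `[0, 1]`.
#' @param r0 Maximum contact radius (default 4).
#'
#' @return Effective risk attitude(s); `NA_real_` where undefined.
#'   Round-trips with [response_radius()] wherever defined.
#' @examples
#' infer_alpha(2, 0.25, 4)       # log(0.75)/log(0.25) = 0.20753...
#' infer_alpha(4, 0.3, 4)        # NA: no contact reduction
#' infer_alpha(3, 0, 4)          # NA: no infection present
#' @export
infer_alpha <- function(next_radius, infection_load, r0 = 4) {
  if (anyNA(next_radius) || any(next_radius < 0 | next_radius > r0)) {
    stop("`next_radius` must lie in [0, r0]", call. = FALSE)
  }
  if (anyNA(infection_load) || any(infection_load < 0 | infection_load > 1)) {
    stop("`infection_load` must lie in [0, 1]", call. = FALSE)
  }
  n <- max(length(next_radius), length(infection_load))
  r <- rep_len(next_radius, n)
  load <- rep_len(infection_load, n)
  out <- rep(NA_real_, n)
  ok <- load > 0 & load < 1 & r < r0
  out[ok] <- log(1 - (r[ok] / r0)^2) / log(load[ok])
  out
}
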