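#' Define the deterministic climate forcing of the landscape
#'
#' The landscape is a chain of `L` evenly spaced patches from the pole
#' (patch 1) to the equator (patch `L`). Local temperature is a linear
#' latitudinal baseline plus a latitude-specific warming increment that ramps
#' smoothly from 0 (at `t = 0`) to its full regional value (at `t = t_E`)
#' via the quintic smoothstep.
#'
#' Warming is polar-amplified: the pole warms by `C_max`, the equator by
#' `C_min <= C_max`, with linear interpolation in between. The default
#' magnitudes are configurable stand-ins consistent with intermediate-emission
#' projections extended to a multi-century horizon; they are plumbing, not
#' ground truth, and any application should set them explicitly.
#'
#' @param T_min Initial polar temperature (degrees C).
#' @param T_max Initial equatorial temperature (degrees C); must exceed `T_min`.
#' @param C_max Total polar temperature increase (degrees C).
#' @param C_min Total equatorial temperature increase (degrees C);
#'   `0 <= C_min <= C_max`.
#' @param t_E Duration of the warming period (years).
#' @param L Number of patches pole to equator.
#'
#' @return An object of class `ee_climate`: a list with the six fields above.
#' @examples
#' clim <- climate_profile()
#' local_temperature(50, 300, clim) # warmed equator
#' @export
climate_profile <- function(T_min = -10, T_max = 30, C_max = 8, C_min = 2,
                            t_E = 300, L = 50) {
  stopifnot(T_min < T_max, C_max >= C_min, C_min >= 0, t_E > 0, L >= 1)
  structure(
    list(T_min = T_min, T_max = T_max, C_max = C_max, C_min = C_min,
         t_E = t_E, L = as.integer(L)),
    class = "ee_climate"
  )
}

#' @export
print.ee_climate <- function(x, ...) {
  cat(sprintf(
    "<ee_climate> %d patches; baseline %g..%g degC; warming +%g (pole) to +%g (equator) degC over %g yr\n",
    x$L, x$T_min, x$T_max, x$C_max, x$C_min, x$t_E))
  invisible(x)
}

#' Quintic smoothstep ramp
#'
#' Evaluates the ramp used to interpolate the warming increment: 0 for
#' `tau < 0`, 1 for `tau > 1`, and `10 tau^3 - 15 tau^4 + 6 tau^5` in
#' between. Continuous with continuous first and second derivatives at both
#' ends, and monotone nondecreasing.
#'
#' @param tau Numeric vector of dimensionless times (typically `t / t_E`).
#' @return Numeric vector of ramp values in \[0, 1\].
#' @examples
#' smoothstep(c(-1, 0.5, 2)) # 0, 0.5, 1
#' @export
smoothstep <- function(tau) {
  q <- tau^3 * (10 + tau * (-15 + 6 * tau))
  q[tau < 0] <- 0
  q[tau > 1] <- 1
  q
}

#' Local temperature of a patch at a time
#'
#' @param k Patch index (vector allowed), 1 = pole, `L` = equator.
#' @param t Time in years (vector allowed); `t <= 0` gives the initial
#'   profile, `t >= t_E` the fully warmed profile.
#' @param profile An [climate_profile()] object.
#' @return Temperature(s) in degrees C, recycled over `k` and `t`.
#' @export
local_temperature <- function(k, t, profile) {
  if (any(k < 1 | k > profile$L)) {
    stop("patch index out of range 1..", profile$L, call. = FALSE)
  }
  frac <- k / profile$L
  baseline <- profile$T_min + (profile$T_max - profile$T_min) * frac
  warming <- profile$C_max + (profile$C_min - profile$C_max) * frac
  baseline + warming * smoothstep(t / profile$t_E)
}

#' Tabulate the temperature field on a time grid
#'
#' @param profile An [climate_profile()] object.
#' @param times Numeric vector of times (years).
#' @return A tibble with columns `time`, `patch`, `temperature`.
#' @examples
#' climate_table(climate_profile(L = 3), times = c(0, 150, 300))
#' @export
climate_table <- function(profile, times = seq(0, profile$t_E, by = 10)) {
  grid <- tidyr::expand_grid(time = times, patch = seq_len(profile$L))
  dplyr::mutate(grid,
    temperature = local_temperature(.data$patch, .data$time, profile))
}
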