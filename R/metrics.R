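#' Community-weighted trait dispersion of one local community
#'
#' The density-weighted variance of species' mean temperature optima:
#' `V = sum_i n_i (mu_i - mu_bar)^2` with relative densities
#' `n_i = N_i / sum_j N_j` and community-weighted mean
#' `mu_bar = sum_i n_i mu_i`. This is the community's standing "adaptive
#' raw material" with respect to temperature.
#'
#' @param density Species densities in the patch (`>= 0`).
#' @param trait_mean Species' local mean temperature optima (degrees C).
#' @return Dispersion in degrees C squared; `NA` for an empty community.
#' @examples
#' trait_dispersion(c(3, 1), c(0, 4)) # weighted variance = 3
#' @export
trait_dispersion <- function(density, trait_mean) {
  tot <- sum(density)
  if (!isTRUE(tot > 0)) return(NA_real_)
  n <- density / tot
  mu_bar <- sum(n * trait_mean)
  sum(n * (trait_mean - mu_bar)^2)
}

#' Community-weighted trait lag of one local community
#'
#' The difference between the local temperature and the community-weighted
#' mean temperature optimum, `A = T - mu_bar`. Positive under warming when
#' the community has not caught up (maladaptation); the signed value is the
#' default throughout the package.
#'
#' @inheritParams trait_dispersion
#' @param temperature Local temperature (degrees C).
#' @return Lag in degrees C; `NA` for an empty community.
#' @export
trait_lag <- function(density, trait_mean, temperature) {
  tot <- sum(density)
  if (!isTRUE(tot > 0)) return(NA_real_)
  temperature - sum(density / tot * trait_mean)
}

#' Per-patch trait moments of a trajectory
#'
#' @param trajectory An `ee_trajectory`.
#' @param level Trophic level(s) to include (default resources, which are
#'   present in every scenario).
#' @return Tibble with `time`, `patch`, `temperature`, `total_density`,
#'   `mean_trait`, `dispersion`, `lag` (empty patches yield `NA` moments).
#' @export
trait_moments <- function(trajectory, level = "resource") {
  clim <- trajectory$config$climate
  trajectory$states |>
    dplyr::filter(.data$level %in% {{ level }}) |>
    dplyr::summarise(
      total_density = sum(.data$density),
      mean_trait = ifelse(sum(.data$density) > 0,
                          sum(.data$density * .data$trait_mean) /
                            sum(.data$density), NA_real_),
      dispersion = trait_dispersion(.data$density, .data$trait_mean),
      .by = c("time", "patch")
    ) |>
    dplyr::mutate(
      temperature = local_temperature(.data$patch, .data$time, clim),
      lag = .data$temperature - .data$mean_trait
    ) |>
    dplyr::relocate("temperature", .after = "patch")
}

#' Integrated trait lag and dispersion of a realisation
#'
#' Averages the community-weighted trait lag and dispersion over all
#' non-empty patches at each snapshot, then trapezoidally over time across
#' the climate-change window, yielding a single (lag, dispersion) pair per
#' realisation. A lower integrated lag indicates a community that tracked
#' the moving temperature better.
#'
#' @param trajectory An `ee_trajectory` whose snapshots span the window.
#' @param window Time window (years), default the warming period.
#' @param level Trophic level(s) to include.
#' @param signed Use the signed lag (default); if `FALSE`, the absolute lag
#'   is averaged instead.
#' @return One-row tibble with `lag` (degrees C) and `dispersion`
#'   (degrees C squared).
#' @export
integrated_lag_dispersion <- function(trajectory,
                                      window = c(0, trajectory$config$times$t_E),
                                      level = "resource", signed = TRUE) {
  mom <- trait_moments(trajectory, level = level)
  mom <- dplyr::filter(mom, .data$time >= window[1], .data$time <= window[2])
  if (nrow(mom) == 0) {
    stop("trajectory snapshots do not cover the requested window",
         call. = FALSE)
  }
  per_time <- mom |>
    dplyr::mutate(lag_use = if (signed) .data$lag else abs(.data$lag)) |>
    dplyr::summarise(
      lag = mean(.data$lag_use[.data$total_density > 0]),
      dispersion = mean(.data$dispersion[.data$total_density > 0]),
      .by = "time"
    ) |>
    dplyr::arrange(.data$time)
  tibble::tibble(lag = trapezoid_mean(per_time$time, per_time$lag),
                 dispersion = trapezoid_mean(per_time$time, per_time$dispersion))
}

# time-average by the trapezoid rule; a single snapshot averages to itself
trapezoid_mean <- function(t, x) {
  if (length(t) == 1) return(x)
  w <- diff(t)
  sum((x[-1] + x[-length(x)]) / 2 * w) / sum(w)
}

#' Local species richness through time
#'
#' @param trajectory An `ee_trajectory`.
#' @param threshold Presence threshold on density.
#' @param level Trophic level(s) to count.
#' @return Tibble with `time`, `patch`, `richness`.
#' @export
local_richness <- function(trajectory,
                           threshold = trajectory$config$defaults$presence_threshold,
                           level = "resource") {
  trajectory$states |>
    dplyr::filter(.data$level %in% {{ level }}) |>
    dplyr::summarise(richness = sum(.data$density > threshold),
                     .by = c("time", "patch"))
}

#' Landscape summary of local richness (mean and SD over patches)
#'
#' @inheritParams local_richness
#' @return Tibble with `time`, `mean_richness`, `sd_richness`.
#' @export
richness_summary <- function(trajectory,
                             threshold = trajectory$config$defaults$presence_threshold,
                             level = "resource") {
  local_richness(trajectory, threshold, level) |>
    dplyr::summarise(mean_richness = mean(.data$richness),
                     sd_richness = stats::sd(.data$richness),
                     .by = "time")
}

#' Range breadth of each species
#'
#' The percentage of the landscape's patches in which a species' density
#' exceeds the presence threshold, reported at selected times (by default
#' the onset of warming, its end, and the end of the simulation).
#'
#' @inheritParams local_richness
#' @param times Snapshot times at which to report.
#' @return Tibble with `time`, `species`, `level`, `range_breadth` (percent
#'   of patches occupied).
#' @export
range_breadth <- function(trajectory,
                          times = c(0, trajectory$config$times$t_E,
                                    trajectory$config$times$t_end),
                          threshold = trajectory$config$defaults$presence_threshold) {
  L <- trajectory$config$L
  trajectory$states |>
    dplyr::filter(.data$time %in% times) |>
    dplyr::summarise(range_breadth = 100 * sum(.data$density > threshold) / L,
                     .by = c("time", "species", "level"))
}

#' Assign patches to latitudinal regions
#'
#' The landscape is split into three equal thirds: polar (lowest patch
#' indices), temperate, and tropical. When `L` is not divisible by 3 the
#' boundaries are placed by rounding `L/3` and `2L/3`.
#'
#' @param L Number of patches.
#' @return Character vector of length `L` with values `"polar"`,
#'   `"temperate"`, `"tropical"`.
#' @export
patch_regions <- function(L) {
  b1 <- round(L / 3)
  b2 <- round(2 * L / 3)
  rep(c("polar", "temperate", "tropical"), c(b1, b2 - b1, L - b2))
}

#' Compositional turnover of a region between two times
#'
#' Sums each species' density over the region's patches at the reference
#' and comparison times and computes an abundance-weighted dissimilarity
#' between the two community vectors (Bray-Curtis by default; Jaccard on
#' presence/absence as an alternative).
#'
#' @param trajectory An `ee_trajectory`.
#' @param region `"polar"`, `"temperate"`, `"tropical"`, or `"all"`.
#' @param t_ref,t_cmp The two snapshot times to compare.
#' @param method `"bray"` or `"jaccard"`.
#' @param level Trophic level(s) to include.
#' @return Dissimilarity in \[0, 1\]; `NA` if the region is empty at both
#'   times.
#' @export
turnover <- function(trajectory, region = "polar", t_ref = 0,
                     t_cmp = trajectory$config$times$t_end,
                     method = c("bray", "jaccard"), level = "resource") {
  method <- match.arg(method)
  regions <- patch_regions(trajectory$config$L)
  patches <- if (identical(region, "all")) seq_len(trajectory$config$L) else
    which(regions == region)
  pick <- function(tt) {
    trajectory$states |>
      dplyr::filter(.data$time == tt, .data$patch %in% patches,
                    .data$level %in% {{ level }}) |>
      dplyr::summarise(density = sum(.data$density), .by = "species") |>
      dplyr::arrange(.data$species)
  }
  a <- pick(t_ref); b <- pick(t_cmp)
  if (nrow(a) == 0 || nrow(b) == 0) {
    stop("requested times not present in the trajectory", call. = FALSE)
  }
  x <- rbind(a$density, b$density)
  if (sum(x) == 0) return(NA_real_)
  if (method == "jaccard") x <- (x > 0) * 1
  as.numeric(vegan::vegdist(x, method = method, binary = method == "jaccard"))
}

#' Relative change in species richness, global and by region
#'
#' For each snapshot, the number of species present (density above the
#' threshold in at least one patch of the scope) divided by the number
#' present at the onset of climate change (`t = 0`). Values below 1 after
#' the end of warming that keep declining indicate an extinction debt.
#'
#' @inheritParams local_richness
#' @return Tibble with `time`, `region` (`"global"` plus the three
#'   latitudinal regions), `richness`, `relative_richness`.
#' @export
global_richness_change <- function(trajectory,
                                   threshold = trajectory$config$defaults$presence_threshold,
                                   level = "resource") {
  regions <- patch_regions(trajectory$config$L)
  states <- trajectory$states |>
    dplyr::filter(.data$level %in% {{ level }}) |>
    dplyr::mutate(region = regions[.data$patch])
  per_region <- states |>
    dplyr::summarise(present = any(.data$density > threshold),
                     .by = c("time", "region", "species")) |>
    dplyr::summarise(richness = sum(.data$present), .by = c("time", "region"))
  global <- states |>
    dplyr::summarise(present = any(.data$density > threshold),
                     .by = c("time", "species")) |>
    dplyr::summarise(richness = sum(.data$present), .by = "time") |>
    dplyr::mutate(region = "global")
  out <- dplyr::bind_rows(global, per_region)
  ref <- out |>
    dplyr::filter(.data$time == 0) |>
    dplyr::select("region", richness0 = "richness")
  out |>
    dplyr::left_join(ref, by = "region") |>
    dplyr::mutate(relative_richness = .data$richness / .data$richness0) |>
    dplyr::select("time", "region", "richness", "relative_richness") |>
    dplyr::arrange(.data$time, .data$region)
}

#' Fit the trait lag vs. trait dispersion relationship
#'
#' Ordinary least squares of the integrated (time- and patch-averaged)
#' trait lag on the integrated trait dispersion across realisations,
#' typically within one scenario. A negative slope means communities with
#' more varied temperature strategies tracked the changing climate better.
#'
#' @param data A data frame with columns `lag` and `dispersion`, one row
#'   per realisation (e.g. rows of [integrated_lag_dispersion()] bound
#'   together).
#' @return An `ee_lag_fit` object wrapping the [stats::lm()] fit; see
#'   [tidy.ee_lag_fit()] and [glance.ee_lag_fit()].
#' @export
fit_lag_dispersion <- function(data) {
  stopifnot(all(c("lag", "dispersion") %in% names(data)))
  fit <- stats::lm(lag ~ dispersion, data = data)
  structure(list(fit = fit, n = nrow(data)), class = "ee_lag_fit")
}

#' @export
print.ee_lag_fit <- function(x, ...) {
  co <- stats::coef(x$fit)
  cat(sprintf("<ee_lag_fit> lag = %.4g %+.4g x dispersion  (n = %d, R^2 = %.3f)\n",
              co[1], co[2], x$n, summary(x$fit)$r.squared))
  invisible(x)
}

#' Tidy the lag-dispersion fit
#'
#' @param x An `ee_lag_fit`.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`.
#' @export
tidy.ee_lag_fit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(sm), estimate = sm[, 1],
                 std.error = sm[, 2], statistic = sm[, 3], p.value = sm[, 4])
}

#' One-row summary of the lag-dispersion fit
#'
#' @param x An `ee_lag_fit`.
#' @param ... Unused.
#' @return A tibble with `slope`, `intercept`, `r.squared`, `n`.
#' @export
glance.ee_lag_fit <- function(x, ...) {
  co <- stats::coef(x$fit)
  tibble::tibble(slope = unname(co[2]), intercept = unname(co[1]),
                 r.squared = summary(x$fit)$r.squared, n = x$n)
}
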