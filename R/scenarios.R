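#' Define a simulation scenario
#'
#' A scenario is one cell of the fully factorial design: the average
#' dispersal rate (high = 100 m/yr, low = 0.01 m/yr), the mean genetic
#' variance (high = 1e-1, low = 1e-3 degrees C squared), the number of
#' trophic levels (one = resources only, two = resources plus consumers),
#' and the competition mode (constant coefficients, or coefficients that
#' decline with the distance between two species' temperature optima).
#'
#' @param dispersal `"high"` or `"low"`.
#' @param variance `"high"` or `"low"`.
#' @param trophic `"one"` or `"two"`.
#' @param competition `"constant"` or `"temperature_dependent"`.
#' @return A list with class `ee_scenario`.
#' @examples
#' scenario("high", "low", "two", "temperature_dependent")
#' @export
scenario <- function(dispersal = c("high", "low"),
                     variance = c("high", "low"),
                     trophic = c("one", "two"),
                     competition = c("constant", "temperature_dependent")) {
  structure(
    list(
      dispersal = match.arg(dispersal),
      variance = match.arg(variance),
      trophic = match.arg(trophic),
      competition = match.arg(competition)
    ),
    class = "ee_scenario"
  )
}

#' @export
print.ee_scenario <- function(x, ...) {
  cat(sprintf("<ee_scenario> dispersal=%s variance=%s trophic=%s competition=%s\n",
              x$dispersal, x$variance, x$trophic, x$competition))
  invisible(x)
}

#' Enumerate the full factorial scenario grid
#'
#' @return A tibble with one row per scenario (16 rows) and columns
#'   `scenario_id`, `dispersal`, `variance`, `trophic`, `competition`.
#' @examples
#' nrow(scenario_grid()) # 16
#' @export
scenario_grid <- function() {
  grid <- tidyr::expand_grid(
    dispersal = c("high", "low"),
    variance = c("high", "low"),
    trophic = c("one", "two"),
    competition = c("constant", "temperature_dependent")
  )
  dplyr::mutate(grid,
    scenario_id = paste(substr(.data$dispersal, 1, 1),
                        substr(.data$variance, 1, 1),
                        .data$trophic, .data$competition, sep = "_"),
    .before = 1)
}

#' Mean dispersal rate of a scenario level (m/yr)
#' @noRd
dispersal_mean <- function(level) switch(level, high = 100, low = 0.01)

#' Mean genetic variance of a scenario level (degrees C squared)
#' @noRd
variance_mean <- function(level) switch(level, high = 1e-1, low = 1e-3)
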