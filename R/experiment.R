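#' Enumerate an experiment manifest
#'
#' Expands the full 16-scenario factorial grid over a set of replicate
#' seeds. With `R` replicates this yields `16 * R` planned realisations;
#' each run's random stream is keyed by its own `(scenario, seed)`, never
#' by execution order, so any subset can be (re)run in any order and still
#' reproduce the same results.
#'
#' @param replicates Number of replicates per scenario.
#' @param seeds Optional explicit integer seeds (length `replicates`);
#'   defaults to `base_seed + 0:(replicates-1)`.
#' @param base_seed First seed when `seeds` is not given.
#' @param S Species per trophic level.
#' @param L Number of patches.
#' @return A tibble with one row per planned realisation: the scenario
#'   columns plus `seed`, `S`, `L`.
#' @examples
#' nrow(experiment_manifest(replicates = 100)) # 1600
#' @export
experiment_manifest <- function(replicates, seeds = NULL, base_seed = 1,
                                S = 50, L = 50) {
  if (is.null(seeds)) seeds <- base_seed + seq_len(replicates) - 1
  stopifnot(length(seeds) == replicates)
  tidyr::expand_grid(scenario_grid(), seed = as.integer(seeds)) |>
    dplyr::mutate(S = S, L = L)
}

#' Run a batch of realisations and aggregate their metrics
#'
#' Draws, integrates, and summarises every row of a manifest. Each
#' realisation contributes one row of summary metrics: the integrated
#' trait lag and dispersion over the warming window, polar Bray-Curtis
#' turnover between the onset of warming and the end of the simulation,
#' and global resource richness at the three reference times.
#'
#' @param manifest A tibble as returned by [experiment_manifest()] (any
#'   subset of rows works).
#' @param climate Climate profile factory: a function of `L` returning an
#'   [climate_profile()]; defaults to the standard profile.
#' @param keep_trajectories Also return the full trajectories (memory-heavy
#'   at full size; default `FALSE`).
#' @param quiet Suppress per-run progress messages.
#' @param ... Passed on to [draw_replicate()] (e.g. `defaults`, `solver`).
#' @return A tibble with one row per completed realisation. Failed runs
#'   are skipped with a warning and reported in the `status` attribute.
#'   If `keep_trajectories` is `TRUE`, the trajectories are attached as a
#'   list column `trajectory`.
#' @export
run_experiment <- function(manifest, climate = function(L) climate_profile(L = L),
                           keep_trajectories = FALSE, quiet = TRUE, ...) {
  rows <- seq_len(nrow(manifest))
  out <- purrr::map(rows, function(r) {
    row <- manifest[r, ]
    scen <- scenario(row$dispersal, row$variance, row$trophic, row$competition)
    res <- tryCatch({
      cfg <- draw_replicate(scen, seed = row$seed, S = row$S, L = row$L,
                            climate = climate(row$L), ...)
      traj <- run_replicate(cfg)
      summ <- summarise_realisation(traj)
      if (!quiet) message(sprintf("done %s seed %d", row$scenario_id, row$seed))
      list(ok = TRUE,
           metrics = dplyr::bind_cols(row, summ),
           trajectory = if (keep_trajectories) traj else NULL)
    }, error = function(e) {
      warning(sprintf("run %s seed %d failed: %s", row$scenario_id, row$seed,
                      conditionMessage(e)), call. = FALSE)
      list(ok = FALSE, metrics = NULL, trajectory = NULL)
    })
    res
  })
  ok <- purrr::map_lgl(out, "ok")
  metrics <- purrr::map_dfr(out[ok], "metrics")
  if (keep_trajectories) {
    metrics$trajectory <- purrr::map(out[ok], "trajectory")
  }
  attr(metrics, "status") <- list(completed = sum(ok), failed = sum(!ok))
  metrics
}

#' One-row metric summary of a single realisation
#'
#' @param trajectory An `ee_trajectory`.
#' @return A one-row tibble: `lag`, `dispersion` (integrated over warming),
#'   `polar_turnover` (Bray-Curtis, t = 0 vs. end), `richness_t0`,
#'   `richness_tE`, `richness_end` (global resource richness), and
#'   `global_extinctions` (count of logged global losses).
#' @export
summarise_realisation <- function(trajectory) {
  tms <- trajectory$config$times
  ld <- integrated_lag_dispersion(trajectory)
  grc <- global_richness_change(trajectory)
  glob <- dplyr::filter(grc, .data$region == "global")
  rich_at <- function(tt) {
    r <- glob$richness[glob$time == tt]
    if (length(r)) r else NA_integer_
  }
  tibble::tibble(
    lag = ld$lag, dispersion = ld$dispersion,
    polar_turnover = turnover(trajectory, "polar", 0, tms$t_end),
    richness_t0 = rich_at(0),
    richness_tE = rich_at(tms$t_E),
    richness_end = rich_at(tms$t_end),
    global_extinctions = sum(trajectory$events$scope == "global" &
                               trajectory$events$time > tms$t0)
  )
}
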