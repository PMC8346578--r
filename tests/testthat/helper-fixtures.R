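# Small configurations and hand-built objects shared across tests.

# a tiny replicate configuration; any field can be overridden afterwards
tiny_config <- function(dispersal = "high", variance = "high",
                        trophic = "one", competition = "constant",
                        seed = 7, S = 6, L = 5, climate = NULL, ...) {
  if (is.null(climate)) climate <- climate_profile(L = L)
  draw_replicate(scenario(dispersal, variance, trophic, competition),
                 seed = seed, S = S, L = L, climate = climate, ...)
}

# freeze trait evolution: zero genetic variance => h^2 = 0
freeze_traits <- function(config) {
  config$species$sigma2_G[] <- 0
  config$species$h2[] <- 0
  config$species$sigma2 <- config$species$sigma2_G + config$species$sigma2_E
  config
}

# a constant-climate profile (no warming)
flat_climate <- function(L, T_min = -10, T_max = 30) {
  climate_profile(T_min = T_min, T_max = T_max, C_max = 0, C_min = 0, L = L)
}

# hand-built trajectory for the metrics layer: `states` is a long tibble
# with columns time, species, level, patch, density, trait_mean
fake_trajectory <- function(states, climate, t_E = climate$t_E,
                            t0 = min(states$time), t_end = max(states$time)) {
  structure(
    list(states = states, events = NULL,
         times = sort(unique(states$time)),
         config = list(climate = climate, L = climate$L,
                       times = list(t0 = t0, t_E = t_E, t_end = t_end,
                                    cadence = NA),
                       defaults = list(presence_threshold = 1e-3))),
    class = "ee_trajectory"
  )
}

# random tolerance parameters within the admissible range
random_tolerance <- function() {
  species_tolerance(rho = runif(1, 0.2, 2), b_w = runif(1, 3, 6),
                    a_w = runif(1, 0.01, 0.08), kappa = runif(1, 0, 0.3))
}
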