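#' Low-density regulation of genetic variance
#'
#' Scales the genetic variance smoothly to zero as local density falls,
#' preventing near-extinct populations from evolving rapidly: the effective
#' variance is `sigma2_G * s(N)` with the ramp `s(N) = N^2 / (N^2 + N_c^2)`
#' (so `s(0) = 0`, `s(N_c) = 1/2`, and `s -> 1` well above `N_c`).
#'
#' @param N Local density (vector or matrix), `>= 0`.
#' @param sigma2_G Genetic variance (degrees C squared).
#' @param N_c Half-saturation density of the ramp.
#' @return Effective genetic variance, same shape as the inputs.
#' @export
variance_regulation <- function(N, sigma2_G, N_c) {
  sigma2_G * N^2 / (N^2 + N_c^2)
}

#' Apply the extinction threshold to a state
#'
#' Local densities strictly below `threshold` are set to exactly zero; a
#' species at zero in every patch is flagged globally extinct. Applied at
#' snapshot times by [run_replicate()].
#'
#' @param state An `ee_state`.
#' @param threshold Extinction threshold (density units), `> 0`.
#' @param config An `ee_config` (for species labels).
#' @param already_global Integer vector of species already recorded as
#'   globally extinct (their repeat flags are suppressed).
#' @return A list with the updated `state`, an `events` tibble (columns
#'   `time`, `species`, `level`, `scope`, `patch`), and `global_extinct`,
#'   the updated vector of globally extinct species.
#' @export
apply_extinction_threshold <- function(state, threshold, config,
                                       already_global = integer(0)) {
  stopifnot(threshold > 0)
  N <- state$N
  below <- which(N > 0 & N < threshold, arr.ind = TRUE)
  N[N < threshold] <- 0
  state$N <- N
  events <- tibble::tibble(
    time = rep(state$t, nrow(below)),
    species = as.integer(below[, 1]),
    level = config$species$level[below[, 1]],
    scope = rep("local", nrow(below)),
    patch = as.integer(below[, 2])
  )
  gone <- which(rowSums(N) == 0)
  new_global <- setdiff(gone, already_global)
  if (length(new_global)) {
    events <- dplyr::bind_rows(events, tibble::tibble(
      time = state$t, species = as.integer(new_global),
      level = config$species$level[new_global],
      scope = "global", patch = NA_integer_
    ))
  }
  list(state = state, events = events,
       global_extinct = sort(union(already_global, gone)))
}

#' Flatten a configuration for the compiled right-hand side
#' @noRd
rhs_parms <- function(config, include_growth = TRUE) {
  sp <- config$species
  S_C <- config$S_C
  Wo <- if (S_C > 0) config$web$W * config$web$omega else matrix(0, 0, config$S_R)
  list(
    S_R = config$S_R, S_C = S_C, L = config$L,
    rho = sp$rho, kappa = sp$kappa, sigma2 = sp$sigma2,
    sigma2_G = sp$sigma2_G, m = sp$m, q = sp$q, H = sp$H, eps = sp$eps,
    b_w = config$b_w, a_w = config$a_w, eta = config$eta,
    sigma2_E = sp$sigma2_E[1], N_c = config$defaults$N_c,
    N_floor = config$defaults$N_floor,
    tempdep = config$scenario$competition == "temperature_dependent",
    growth_on = isTRUE(include_growth),
    a_matrix = config$a_matrix, W_omega = Wo,
    T_min = config$climate$T_min, T_max = config$climate$T_max,
    C_max = config$climate$C_max, C_min = config$climate$C_min,
    t_E = config$climate$t_E
  )
}

state_to_y <- function(state) c(state$N, state$mu)

y_to_state <- function(y, S, L, t) {
  structure(list(N = matrix(y[seq_len(S * L)], S, L),
                 mu = matrix(y[S * L + seq_len(S * L)], S, L),
                 t = t),
            class = "ee_state")
}

#' Integrate one model realisation
#'
#' Runs the coupled density/trait system from the start of the
#' establishment period to the end of the simulation with an adaptive
#' solver, recording snapshots at a fixed cadence. The climate forcing is
#' smooth, so the establishment, warming, and post-warming phases need no
#' solver restarts; at each snapshot the extinction threshold is applied
#' (local densities below it are zeroed, and global extinctions logged).
#'
#' @param config An `ee_config` from [draw_replicate()].
#' @param cadence Years between snapshots (default from the config; the
#'   snapshot grid always contains the onset and end of warming and the
#'   final time exactly).
#' @param include_growth Switch all growth/selection off (dispersal-only
#'   dynamics, for conservation checks).
#' @return An `ee_trajectory`: list with `states` (tibble: `time`,
#'   `species`, `level`, `patch`, `density`, `trait_mean`), `events`
#'   (extinction log), `times` (snapshot vector), and the `config`.
#' @export
run_replicate <- function(config, cadence = config$times$cadence,
                          include_growth = TRUE) {
  S <- config$S_R + config$S_C
  tms <- config$times
  times <- sort(unique(c(seq(tms$t0, tms$t_end, by = cadence),
                         0, tms$t_E, tms$t_end)))
  times <- times[times >= tms$t0 & times <= tms$t_end]
  if (S == 0) {
    return(structure(list(
      states = tibble::tibble(time = numeric(0), species = integer(0),
                              level = character(0), patch = integer(0),
                              density = numeric(0), trait_mean = numeric(0)),
      events = empty_events(), times = times, config = config
    ), class = "ee_trajectory"))
  }
  parms <- rhs_parms(config, include_growth = include_growth)
  deriv <- function(t, y, p) list(rhs_flat(t, y, p))
  solver <- config$solver
  state <- initial_state(config)
  thr <- config$defaults$extinction_threshold

  snapshots <- vector("list", length(times))
  events <- list(empty_events())
  global_extinct <- integer(0)

  chk <- apply_extinction_threshold(state, thr, config, global_extinct)
  state <- chk$state; global_extinct <- chk$global_extinct
  events[[length(events) + 1]] <- chk$events
  snapshots[[1]] <- state

  for (s in seq_len(length(times) - 1)) {
    sol <- deSolve::ode(
      y = state_to_y(state), times = times[c(s, s + 1)], func = deriv,
      parms = parms, method = solver$method,
      rtol = solver$rtol, atol = solver$atol
    )
    if (attr(sol, "istate")[1] < 0) {
      stop(sprintf("solver failed between t = %g and t = %g (istate %d); last good state at t = %g",
                   times[s], times[s + 1], attr(sol, "istate")[1], state$t),
           call. = FALSE)
    }
    y <- sol[nrow(sol), -1]
    Npart <- y[seq_len(S * config$L)]
    undershoot <- -min(0, min(Npart))
    # permissible undershoot: the solver's own local error scale
    if (undershoot > 100 * solver$atol + 10 * solver$rtol) {
      stop(sprintf("solver undershoot below zero density (%.3g) at t = %g",
                   -undershoot, times[s + 1]), call. = FALSE)
    }
    y[seq_len(S * config$L)] <- pmax(Npart, 0)
    state <- y_to_state(y, S, config$L, times[s + 1])
    chk <- apply_extinction_threshold(state, thr, config, global_extinct)
    state <- chk$state; global_extinct <- chk$global_extinct
    events[[length(events) + 1]] <- chk$events
    snapshots[[s + 1]] <- state
  }

  states <- purrr::map_dfr(snapshots, function(st) {
    tibble::tibble(
      time = st$t,
      species = rep(config$species$species, config$L),
      level = rep(config$species$level, config$L),
      patch = rep(seq_len(config$L), each = S),
      density = as.vector(st$N),
      trait_mean = as.vector(st$mu)
    )
  })
  structure(list(states = states, events = dplyr::bind_rows(events),
                 times = times, config = config),
            class = "ee_trajectory")
}

empty_events <- function() {
  tibble::tibble(time = numeric(0), species = integer(0),
                 level = character(0), scope = character(0),
                 patch = integer(0))
}

#' @export
print.ee_trajectory <- function(x, ...) {
  n_glob <- sum(x$events$scope == "global")
  cat(sprintf("<ee_trajectory> %d snapshots over t = %g..%g; %d species x %d patches; %d global extinction(s)\n",
              length(x$times), min(x$times), max(x$times),
              x$config$S_R + x$config$S_C, x$config$L, n_glob))
  invisible(x)
}
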