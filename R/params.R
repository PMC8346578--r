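#' Default parameter-draw settings
#'
#' One block holding every distribution from which replicate-level
#' parameters are drawn, plus the numerical constants of the model. The
#' values below are the package's own documented
#' defaults: log-normal draws with a 20% coefficient
#' of variation around the stated means, and uniform intervals for the
#' constant competition coefficients (intraspecific at least as strong as
#' interspecific, permitting baseline coexistence). Override any entry via
#' the `defaults` argument of [draw_replicate()].
#'
#' @return A nested list of defaults (documented inline).
#' @export
default_draws <- function() {
  list(
    cv = 0.2,                 # coefficient of variation of log-normal draws
    rho_mean = 1,             # resource growth scale (per yr degC)
    kappa_resource_mean = 0.1,   # resource mortality (per yr)
    kappa_consumer_mean = 0.05,  # consumer metabolic loss + mortality (per yr)
    consumer_rho_frac = 0.5,  # consumer peak growth as fraction of kappa (kept < 1)
    b_w_mean = 4,             # tolerance-width intercept (degC)
    a_w_mean = 0.05,          # tolerance-width slope (per degC)
    sigma2_E = 0.05,          # environmental trait variance (degC^2)
    q_mean = 2,               # attack rate
    H_mean = 0.2,             # handling time (yr)
    eps_mean = 0.5,           # conversion efficiency
    eta_mean = 2.5,           # competition width (degC), one draw per replicate
    a_intra = c(0.3, 0.4),    # constant-mode intraspecific coefficient range
    a_inter = c(0.02, 0.1),   # constant-mode interspecific coefficient range
    links_per_consumer = 5L,  # consumer out-degree in the bipartite web
    dx = 2e5,                 # patch spacing (m): 10,000 km pole-to-equator / 50
    N_floor = 1e-12,          # density floor inside per-capita ratios
    extinction_threshold = 1e-6,  # hard-zero below this at snapshots
    N_c = 0.1,                # half-saturation density of variance regulation
    presence_threshold = 1e-3 # default presence cutoff for richness/ranges
  )
}

lognormal_around <- function(n, mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Draw a full replicate parameterisation
#'
#' Builds everything a single model realisation needs, reproducibly from
#' `(scenario, seed)`: per-species tolerance, variance, dispersal, and
#' trophic parameters, the constant competition matrix, the competition
#' width, the bipartite feeding network, and all numerical settings.
#'
#' Draws are made in a fixed order independent of the scenario, with the
#' scenario's dispersal and variance levels entering only as multiplicative
#' means; replicates sharing a seed are therefore matched across scenarios
#' (identical species up to the scenario's level shifts), which makes
#' between-scenario contrasts paired comparisons.
#'
#' @param scen An [scenario()] object.
#' @param seed Integer seed; identical `(scenario, seed)` give identical
#'   configurations.
#' @param S Species per trophic level.
#' @param L Number of patches.
#' @param climate An [climate_profile()] (its `L` must match).
#' @param defaults Parameter-draw settings, see [default_draws()].
#' @param solver Solver settings: list with `method`, `rtol`, `atol`.
#' @param times List with `t0`, `t_end`, `cadence` (years); the warming
#'   window is taken from `climate`.
#' @return An `ee_config` object: a list with the scenario, a per-species
#'   parameter tibble, global parameters, the food web, and numerics.
#' @export
draw_replicate <- function(scen, seed, S = 50, L = 50,
                           climate = climate_profile(L = L),
                           defaults = default_draws(),
                           solver = list(method = "adams",
                                         rtol = 1e-6, atol = 1e-9),
                           times = list(t0 = -4000, t_end = 2500,
                                        cadence = 100)) {
  stopifnot(inherits(scen, "ee_scenario"), S >= 1, L >= 1)
  if (climate$L != L) stop("climate profile has L = ", climate$L,
                           " but L = ", L, " requested", call. = FALSE)
  d <- defaults
  with_seed(seed, {
    cv <- d$cv
    # tolerance tradeoff, redrawn until the width is positive over the full
    # admissible trait range (initial optima plus total warming plus margin)
    mu_max <- climate$T_max + climate$C_max + 5
    repeat {
      b_w <- lognormal_around(1, d$b_w_mean, cv / 2)
      a_w <- lognormal_around(1, d$a_w_mean, cv)
      if (b_w - a_w * mu_max > 0.2) break
    }
    w_min <- b_w - a_w * mu_max

    S_R <- S
    S_C <- if (scen$trophic == "two") S else 0L
    n_tot <- S_R + S

    rho_r <- lognormal_around(S_R, d$rho_mean, cv)
    kappa_r <- lognormal_around(S_R, d$kappa_resource_mean, cv)
    kappa_c <- lognormal_around(S, d$kappa_consumer_mean, cv)
    frac_c <- pmin(lognormal_around(S, d$consumer_rho_frac, cv), 0.9)
    rho_c <- frac_c * kappa_c * w_min  # guarantees max_z r0 < 0 for consumers

    sigma2_G <- lognormal_around(n_tot, variance_mean(scen$variance), cv)
    disp <- lognormal_around(n_tot, dispersal_mean(scen$dispersal), cv)
    q <- lognormal_around(n_tot, d$q_mean, cv)
    H <- lognormal_around(n_tot, d$H_mean, cv)
    eps <- pmin(lognormal_around(n_tot, d$eps_mean, cv), 1)

    # constant-mode competition among resources (intra >= inter)
    a_mat <- matrix(stats::runif(S_R^2, d$a_inter[1], d$a_inter[2]), S_R, S_R)
    diag(a_mat) <- stats::runif(S_R, d$a_intra[1], d$a_intra[2])
    eta <- lognormal_around(1, d$eta_mean, cv)

    mu0 <- initial_trait_means(S, climate)  # same spacing on both levels
    web <- if (S_C > 0) {
      build_foodweb(S_R, S_C, mu0_consumer = mu0, mu0_resource = mu0,
                    links = d$links_per_consumer)
    } else NULL

    idx_r <- seq_len(S_R)
    idx_c <- if (S_C > 0) S_R + seq_len(S_C) else integer(0)
    keep <- c(idx_r, idx_c)
    sigma2_G_k <- sigma2_G[keep]
    sigma2 <- sigma2_G_k + d$sigma2_E
    species <- tibble::tibble(
      species = seq_along(keep),
      level = rep(c("resource", "consumer"), c(S_R, S_C)),
      rho = c(rho_r, rho_c[seq_len(S_C)]),
      kappa = c(kappa_r, kappa_c[seq_len(S_C)]),
      sigma2_G = sigma2_G_k,
      sigma2_E = d$sigma2_E,
      sigma2 = sigma2,
      h2 = sigma2_G_k / sigma2,
      dispersal = disp[keep],
      m = disp[keep] / d$dx,
      q = q[keep],
      H = H[keep],
      eps = eps[keep],
      mu0 = rep(mu0, length.out = length(keep))
    )

    structure(
      list(
        scenario = scen, seed = as.integer(seed),
        S_R = as.integer(S_R), S_C = as.integer(S_C), L = as.integer(L),
        climate = climate, species = species,
        b_w = b_w, a_w = a_w, eta = eta, a_matrix = a_mat, web = web,
        defaults = d, solver = solver,
        times = list(t0 = times$t0, t_E = climate$t_E,
                     t_end = times$t_end, cadence = times$cadence)
      ),
      class = "ee_config"
    )
  })
}

#' @export
print.ee_config <- function(x, ...) {
  cat(sprintf(
    "<ee_config> %d resource + %d consumer species, %d patches; seed %d\n",
    x$S_R, x$S_C, x$L, x$seed))
  print(x$scenario)
  invisible(x)
}

# evaluate expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Initial trait means of equally spaced species
#'
#' Species are initially equally spaced along the thermal gradient:
#' `mu_i = (T_max - T_min) * i / S + T_min`, identical in every patch.
#'
#' @param S Species per trophic level.
#' @param climate An [climate_profile()].
#' @return Numeric vector of length `S` (degrees C), increasing in `i`.
#' @export
initial_trait_means <- function(S, climate) {
  (climate$T_max - climate$T_min) * seq_len(S) / S + climate$T_min
}

#' Build the bipartite consumer-resource feeding network
#'
#' Each consumer is linked to a fixed number of resource species (default
#' five): always the resource whose initial mean temperature optimum is
#' closest to the consumer's own (ties broken toward the lowest index), plus
#' the remaining links drawn uniformly at random without replacement.
#' Feeding effort is spread uniformly across a consumer's links.
#'
#' @param S_R,S_C Number of resource and consumer species; `S_R >= links`.
#' @param mu0_consumer,mu0_resource Initial mean temperature optima.
#' @param links Links per consumer.
#' @return A list with binary adjacency `W` (`S_C x S_R`) and effort matrix
#'   `omega` (rows summing to 1 over links).
#' @export
build_foodweb <- function(S_R, S_C, mu0_consumer, mu0_resource, links = 5L) {
  if (S_R < links) {
    stop("need at least ", links, " resource species to build the food web",
         call. = FALSE)
  }
  W <- matrix(0, S_C, S_R)
  for (i in seq_len(S_C)) {
    matched <- which.min(abs(mu0_resource - mu0_consumer[i]))
    others <- setdiff(seq_len(S_R), matched)
    extra <- if (links > 1L) sample(others, links - 1L) else integer(0)
    W[i, c(matched, extra)] <- 1
  }
  omega <- W / rowSums(W)
  list(W = W, omega = omega)
}

#' Initial model state
#'
#' At the start of the establishment period every species has its initial
#' trait mean in every patch, and a Gaussian initial abundance profile
#' centred on the patches whose (pre-warming) temperature matches that
#' mean: `N_i^k = exp(-(mu_i - T^k(0))^2 / 8)`.
#'
#' @param config An `ee_config` from [draw_replicate()].
#' @return A list with matrices `N` and `mu` (species x patches) and time
#'   `t = t0`; class `ee_state`.
#' @export
initial_state <- function(config) {
  L <- config$L
  mu0 <- config$species$mu0
  T0 <- local_temperature(seq_len(L), 0, config$climate)
  mu <- matrix(mu0, nrow = nrow(config$species), ncol = L)
  N <- exp(-(sweep(mu, 2, T0))^2 / 8)
  structure(list(N = N, mu = mu, t = config$times$t0), class = "ee_state")
}
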