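#' Holling type II feeding rates within one patch
#'
#' `F_ij = q_i W_ij omega_ij N_j / (1 + q_i H_i sum_s W_is omega_is N_s)`:
#' each consumer's intake of each prey saturates in its total
#' effort-weighted prey density. Rows are consumers (global species
#' indices), columns prey; entries are zero off the feeding network.
#'
#' @param N_col Density vector of all species in the patch (length
#'   `S_R + S_C`, resources first).
#' @param config An `ee_config`.
#' @return A square matrix `F` (species x species) of feeding rates.
#' @export
feeding_rates <- function(N_col, config) {
  S <- config$S_R + config$S_C
  if (any(N_col < 0)) stop("densities must be nonnegative", call. = FALSE)
  F_mat <- matrix(0, S, S)
  if (config$S_C == 0) return(F_mat)
  W <- config$web$W
  omega <- config$web$omega
  res <- seq_len(config$S_R)
  for (ci in seq_len(config$S_C)) {
    gi <- config$S_R + ci
    q <- config$species$q[gi]
    H <- config$species$H[gi]
    eff <- W[ci, ] * omega[ci, ] * N_col[res]
    denom <- 1 + q * H * sum(eff)
    F_mat[gi, res] <- q * eff / denom
  }
  F_mat
}

# effective heritability under low-density genetic-variance regulation:
# sigma2_G is scaled by s(N) = N^2 / (N^2 + N_c^2) before forming h^2
effective_h2 <- function(N, sigma2_G, sigma2_E, N_c) {
  g <- variance_regulation(N, sigma2_G, N_c)
  g / (g + sigma2_E)
}

#' Per-capita growth and selection integrals in one patch
#'
#' Evaluates, for every species in patch `k`, the phenotype-averaged
#' per-capita growth rate (intrinsic growth, minus competition, plus
#' consumption gains, minus predation losses) and the matching selection
#' differential (intrinsic and, in temperature-dependent mode,
#' competitive contributions only; trophic terms are independent of the
#' phenotype and therefore exert no direct selection on the trait mean).
#'
#' @param state An `ee_state` (matrices `N`, `mu`, time `t`).
#' @param k Patch index.
#' @param config An `ee_config`.
#' @param t Time (years), defaults to `state$t`; sets the local temperature.
#' @return A tibble with columns `species`, `level`, `growth` (per yr) and
#'   `selection` (degrees C per yr, before heritability).
#' @export
per_capita_growth_terms <- function(state, k, config, t = state$t) {
  N <- pmax(state$N[, k], 0)
  mu <- state$mu[, k]
  sp <- config$species
  T_k <- local_temperature(k, t, config$climate)
  S_R <- config$S_R
  res <- seq_len(S_R)

  v_tol <- (config$b_w - config$a_w * mu)^2 + sp$sigma2
  expn <- exp(-(T_k - mu)^2 / (2 * v_tol))
  growth <- sp$rho / sqrt(v_tol) * expn - sp$kappa
  selection <- sp$rho * sp$sigma2 * (T_k - mu) / v_tol^1.5 * expn

  # competition acts among resource species only
  if (config$scenario$competition == "constant") {
    growth[res] <- growth[res] - drop(config$a_matrix %*% N[res])
  } else {
    s2 <- sp$sigma2[res]
    v <- config$eta^2 / 2 + outer(s2, s2, "+")
    dmu <- outer(mu[res], mu[res], "-")
    alpha <- config$eta / sqrt(2 * v) * exp(-dmu^2 / (2 * v))
    growth[res] <- growth[res] - drop(alpha %*% N[res])
    selection[res] <- selection[res] +
      s2 * drop((alpha * dmu / v) %*% N[res])
  }

  if (config$S_C > 0) {
    cons <- S_R + seq_len(config$S_C)
    Wo <- config$web$W * config$web$omega
    tot <- drop(Wo %*% N[res])  # effort-weighted prey density per consumer
    denom <- 1 + sp$q[cons] * sp$H[cons] * tot
    growth[cons] <- growth[cons] + sp$eps[cons] * sp$q[cons] * tot / denom
    # resource per-capita loss sum_c N_c F_cj / N_j reduces algebraically to
    # sum_c N_c q_c W_cj omega_cj / denom_c, finite at N_j = 0
    growth[res] <- growth[res] -
      drop(crossprod(Wo, N[cons] * sp$q[cons] / denom))
  }

  tibble::tibble(species = sp$species, level = sp$level,
                 growth = growth, selection = selection)
}

#' Dispersal contributions to densities and trait means
#'
#' Nearest-neighbour migration on the patch chain at per-species rate
#' `m_i` (dispersal distance per year divided by patch spacing), with a
#' reflecting (zero-flux) boundary at the pole and a mirror-symmetric
#' boundary at the equator (patch `L` exchanges with its own image, so net
#' flux is also zero there). The trait contribution is mass-weighted:
#' `sum_l m (N^l / N^k)(mu^l - mu^k)`, with the local density floored to
#' keep the ratio finite in near-empty patches (heritability is applied by
#' the caller).
#'
#' @param state An `ee_state`.
#' @param config An `ee_config`.
#' @return A list of matrices `dN` and `dmu_raw` (species x patches);
#'   `dmu_raw` excludes the heritability factor.
#' @export
dispersal_terms <- function(state, config) {
  N <- pmax(state$N, 0)
  mu <- state$mu
  L <- config$L
  m <- config$species$m
  dN <- matrix(0, nrow(N), L)
  dmu <- matrix(0, nrow(N), L)
  if (L == 1) return(list(dN = dN, dmu_raw = dmu))
  floor_N <- config$defaults$N_floor
  for (k in seq_len(L)) {
    nb <- c(k - 1, k + 1)
    nb <- nb[nb >= 1 & nb <= L]  # boundary patches exchange with one neighbour
    Nk <- pmax(N[, k], floor_N)
    for (l in nb) {
      dN[, k] <- dN[, k] + m * (N[, l] - N[, k])
      dmu[, k] <- dmu[, k] + m * (N[, l] / Nk) * (mu[, l] - mu[, k])
    }
  }
  list(dN = dN, dmu_raw = dmu)
}

#' Full right-hand side of the coupled density and trait equations
#'
#' `dN_i^k/dt = N_i^k * (phenotype-averaged growth) + dispersal`;
#' `dmu_i^k/dt = h_i^2 * (selection differential + mass-weighted immigrant
#' trait mixing)`, with the heritability reduced smoothly at very low local
#' density by the genetic-variance regulation (see [variance_regulation()]).
#'
#' This is the reference implementation; [run_replicate()] uses a compiled
#' equivalent that is cross-checked against this one in the test suite.
#'
#' @param state An `ee_state`.
#' @param config An `ee_config`.
#' @param t Time (years); defaults to `state$t`.
#' @param include_growth If `FALSE`, all local growth and selection terms
#'   are switched off, leaving pure dispersal (used to verify mass
#'   conservation of the migration operator).
#' @return A list of matrices `dN` and `dmu` (species x patches, per year).
#' @export
assemble_rhs <- function(state, config, t = state$t, include_growth = TRUE) {
  S <- config$S_R + config$S_C
  disp <- dispersal_terms(state, config)
  if (include_growth) {
    growth <- matrix(0, S, config$L)
    selection <- matrix(0, S, config$L)
    for (k in seq_len(config$L)) {
      terms <- per_capita_growth_terms(state, k, config, t = t)
      growth[, k] <- terms$growth
      selection[, k] <- terms$selection
    }
  } else {
    growth <- selection <- matrix(0, S, config$L)
  }
  h2_eff <- effective_h2(pmax(state$N, 0),
                         matrix(config$species$sigma2_G, S, config$L),
                         config$species$sigma2_E[1],
                         config$defaults$N_c)
  dN <- pmax(state$N, 0) * growth + disp$dN
  dmu <- h2_eff * (selection + disp$dmu_raw)
  if (!all(is.finite(dN)) || !all(is.finite(dmu))) {
    bad <- which(!is.finite(dN) | !is.finite(dmu), arr.ind = TRUE)
    stop(sprintf("non-finite derivative at t = %g (species %d, patch %d)",
                 t, bad[1, 1], bad[1, 2]), call. = FALSE)
  }
  list(dN = dN, dmu = dmu)
}
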