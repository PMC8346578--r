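#' Phenotype-level intrinsic growth rate
#'
#' The intrinsic growth of a phenotype `z` (a temperature optimum, degrees C)
#' in a patch at temperature `T` is a Gaussian performance curve whose height
#' and width both depend on the species' local mean optimum `mu` through a
#' tolerance tradeoff: width `w = b_w - a_w * mu` and peak height `rho / w`,
#' so warm-adapted species grow faster at their optimum but tolerate a
#' narrower temperature range. A constant mortality `kappa` is subtracted;
#' far from the optimum the rate tends to `-kappa`.
#'
#' @param z Phenotype (temperature optimum, degrees C); vectorised.
#' @param T_loc Local temperature (degrees C).
#' @param tol List with fields `rho`, `b_w`, `a_w`, `kappa` (see
#'   [species_tolerance()]).
#' @param mu Species' local mean temperature optimum (degrees C), which sets
#'   the width/height of the curve.
#' @return Per-year growth rate(s).
#' @export
phenotype_growth <- function(z, T_loc, tol, mu) {
  w <- tolerance_width(tol, mu)
  (tol$rho / w) * exp(-(T_loc - z)^2 / (2 * w^2)) - tol$kappa
}

#' Tolerance parameters of a species
#'
#' Bundles the growth-tolerance tradeoff constants: growth scale `rho`
#' (per year x degree C), tolerance-width intercept `b_w` and slope `a_w`
#' (width `= b_w - a_w * mu`, degrees C), and mortality `kappa` (per year).
#'
#' @param rho Growth scale, `> 0`.
#' @param b_w Width intercept (degrees C).
#' @param a_w Width slope (dimensionless).
#' @param kappa Mortality rate, `>= 0`.
#' @return A list with class `ee_tolerance`.
#' @export
species_tolerance <- function(rho, b_w, a_w, kappa) {
  stopifnot(rho > 0, kappa >= 0)
  structure(list(rho = rho, b_w = b_w, a_w = a_w, kappa = kappa),
            class = "ee_tolerance")
}

tolerance_width <- function(tol, mu) {
  w <- tol$b_w - tol$a_w * mu
  if (any(w <= 0)) {
    stop("nonpositive tolerance width: trait mean outside admissible range",
         call. = FALSE)
  }
  w
}

#' Mean intrinsic growth over a normal phenotype distribution
#'
#' Closed form of the intrinsic-growth integral `int r0(z) p(z) dz` for a
#' normal phenotype distribution with mean `mu` and variance `sigma2`:
#' a Gaussian in `T - mu` with variance inflated by the phenotypic variance,
#' `rho / sqrt(w^2 + sigma2) * exp(-(T - mu)^2 / (2 (w^2 + sigma2))) - kappa`.
#'
#' @param mu Mean temperature optimum (degrees C).
#' @param sigma2 Phenotypic variance (degrees C squared), `> 0`.
#' @param T_loc Local temperature (degrees C).
#' @param tol Tolerance parameters ([species_tolerance()]).
#' @return Per-year mean growth rate.
#' @seealso [quadrature_oracle()] for the numerical cross-check used in the
#'   test suite.
#' @export
mean_intrinsic_growth <- function(mu, sigma2, T_loc, tol) {
  w <- tolerance_width(tol, mu)
  v <- w^2 + sigma2
  tol$rho / sqrt(v) * exp(-(T_loc - mu)^2 / (2 * v)) - tol$kappa
}

#' Selection differential from temperature-dependent intrinsic growth
#'
#' Closed form of `int (z - mu) r0(z) p(z) dz`, the directional-selection
#' contribution of the temperature performance curve to the rate of change
#' of the mean optimum. Its sign equals the sign of `T - mu`: selection
#' pushes the mean optimum toward the local temperature, vanishing when the
#' species is locally adapted.
#'
#' @inheritParams mean_intrinsic_growth
#' @return Selection differential (degrees C per year, before multiplication
#'   by heritability).
#' @export
selection_intrinsic <- function(mu, sigma2, T_loc, tol) {
  w <- tolerance_width(tol, mu)
  v <- w^2 + sigma2
  tol$rho * sigma2 * (T_loc - mu) / v^1.5 * exp(-(T_loc - mu)^2 / (2 * v))
}

#' Effective competition coefficient between two phenotype distributions
#'
#' Averages the Gaussian competition kernel `exp(-(z - z')^2 / eta^2)` over
#' both species' normal phenotype distributions. Closed form: with
#' `v = eta^2/2 + sigma2_i + sigma2_j`,
#' `alpha_ij = eta / sqrt(2 v) * exp(-(mu_i - mu_j)^2 / (2 v))`.
#' Symmetric in the two species, at most 1, strictly decreasing in the
#' distance between the two mean optima.
#'
#' @param mu_i,mu_j Mean temperature optima (degrees C).
#' @param sigma2_i,sigma2_j Phenotypic variances (degrees C squared).
#' @param eta Competition width (degrees C), `> 0`.
#' @return Dimensionless competition coefficient in (0, 1\].
#' @export
effective_competition <- function(mu_i, sigma2_i, mu_j, sigma2_j, eta) {
  if (any(eta <= 0)) stop("competition width eta must be positive", call. = FALSE)
  v <- eta^2 / 2 + sigma2_i + sigma2_j
  eta / sqrt(2 * v) * exp(-(mu_i - mu_j)^2 / (2 * v))
}

#' Selection differential from temperature-dependent competition
#'
#' Closed form of `-N_j int (z - mu_i) [int a(z, z') p_j(z') dz'] p_i(z) dz`,
#' the frequency-dependent selection a competitor exerts on species i's mean
#' optimum. It vanishes when the two optima coincide and otherwise pushes
#' `mu_i` away from `mu_j` (character displacement), with strength
#' proportional to the competitor's density:
#' `N_j * alpha_ij * sigma2_i * (mu_i - mu_j) / v`.
#'
#' @inheritParams effective_competition
#' @param N_j Competitor density, `>= 0`.
#' @return Selection differential (degrees C per year, before heritability).
#' @export
selection_competition <- function(mu_i, sigma2_i, mu_j, sigma2_j, eta, N_j) {
  if (any(N_j < 0)) stop("density must be nonnegative", call. = FALSE)
  v <- eta^2 / 2 + sigma2_i + sigma2_j
  N_j * effective_competition(mu_i, sigma2_i, mu_j, sigma2_j, eta) *
    sigma2_i * (mu_i - mu_j) / v
}

#' Adaptive-quadrature oracle for phenotype integrals
#'
#' Numerically integrates `integrand(z) * p(z)` for a normal phenotype
#' density `p` with mean `mu` and variance `sigma2`, over `mu +/- 10 sd`.
#' This is the independent reference against which every closed form above
#' is validated; it is not used on the production path.
#'
#' @param integrand Function of the phenotype `z`, vectorised.
#' @param mu,sigma2 Mean and variance of the phenotype distribution.
#' @param rel_tol Relative tolerance passed to [stats::integrate()].
#' @return The value of the integral.
#' @examples
#' quadrature_oracle(function(z) z, mu = 2, sigma2 = 0.5) # the mean, 2
#' @export
quadrature_oracle <- function(integrand, mu, sigma2, rel_tol = 1e-10) {
  sd <- sqrt(sigma2)
  res <- stats::integrate(
    function(z) integrand(z) * stats::dnorm(z, mu, sd),
    lower = mu - 10 * sd, upper = mu + 10 * sd,
    rel.tol = rel_tol, subdivisions = 500L
  )
  if (res$message != "OK") {
    stop("quadrature oracle failed to converge: ", res$message, call. = FALSE)
  }
  res$value
}
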