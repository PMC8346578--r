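# independent 2-D quadrature for the competition integrals
nested_oracle <- function(f_outer, mu_i, s2_i, mu_j, s2_j, eta) {
  inner <- function(z) {
    vapply(z, function(zz) {
      stats::integrate(function(zp) exp(-(zz - zp)^2 / eta^2) *
                         stats::dnorm(zp, mu_j, sqrt(s2_j)),
                       mu_j - 10 * sqrt(s2_j), mu_j + 10 * sqrt(s2_j),
                       rel.tol = 1e-11)$value
    }, numeric(1))
  }
  quadrature_oracle(function(z) f_outer(z) * inner(z), mu_i, s2_i,
                    rel_tol = 1e-10)
}

test_that("phenotype growth follows the width-height tradeoff", {
  tol <- species_tolerance(rho = 1, b_w = 4, a_w = 0.05, kappa = 0.1)
  w <- 4 - 0.05 * 10
  expect_equal(phenotype_growth(15, 15, tol, mu = 10), 1 / w - 0.1)
  expect_equal(phenotype_growth(80, 15, tol, mu = 10), -0.1, tolerance = 1e-10)
  # warm-adapted species: taller peak, narrower curve
  peak <- function(mu) phenotype_growth(mu, mu, tol, mu)
  expect_gt(peak(25), peak(-5))
  w_warm <- 4 - 0.05 * 25
  w_cold <- 4 - 0.05 * (-5)
  expect_lt(w_warm, w_cold)
  expect_error(phenotype_growth(0, 0, tol, mu = 90), "width")
})

test_that("closed forms match the quadrature oracle on random draws", {
  set.seed(421)
  for (i in 1:150) {
    tol <- random_tolerance()
    mu <- runif(1, -10, 30)
    s2 <- runif(1, 0.01, 3)
    T_loc <- mu + runif(1, -6, 6)
    r0 <- function(z) phenotype_growth(z, T_loc, tol, mu)
    expect_equal(mean_intrinsic_growth(mu, s2, T_loc, tol),
                 quadrature_oracle(r0, mu, s2),
                 tolerance = 1e-8)
    expect_equal(selection_intrinsic(mu, s2, T_loc, tol),
                 quadrature_oracle(function(z) (z - mu) * r0(z), mu, s2),
                 tolerance = 1e-8)
  }
})

test_that("competition closed forms match nested quadrature", {
  set.seed(422)
  for (i in 1:40) {
    mu_i <- runif(1, -10, 30); mu_j <- mu_i + runif(1, -4, 4)
    s2_i <- runif(1, 0.01, 2); s2_j <- runif(1, 0.01, 2)
    eta <- runif(1, 0.5, 4); N_j <- runif(1, 0, 3)
    expect_equal(effective_competition(mu_i, s2_i, mu_j, s2_j, eta),
                 nested_oracle(function(z) rep(1, length(z)),
                               mu_i, s2_i, mu_j, s2_j, eta),
                 tolerance = 1e-7)
    expect_equal(selection_competition(mu_i, s2_i, mu_j, s2_j, eta, N_j),
                 -N_j * nested_oracle(function(z) z - mu_i,
                                      mu_i, s2_i, mu_j, s2_j, eta),
                 tolerance = 1e-7)
  }
})

test_that("mean growth collapses to the point-phenotype rate as variance vanishes", {
  tol <- species_tolerance(rho = 1.2, b_w = 4, a_w = 0.05, kappa = 0.1)
  expect_equal(mean_intrinsic_growth(5, 1e-12, 9, tol),
               phenotype_growth(5, 9, tol, 5), tolerance = 1e-6)
  # phenotypic averaging lowers growth at the peak
  w2 <- (4 - 0.05 * 9)^2
  expect_lt(mean_intrinsic_growth(9, w2, 9, tol),
            phenotype_growth(9, 9, tol, 9))
})

test_that("directional selection points toward the local temperature", {
  tol <- species_tolerance(rho = 1, b_w = 4, a_w = 0.05, kappa = 0.1)
  expect_equal(selection_intrinsic(12, 0.5, 12, tol), 0)
  expect_gt(selection_intrinsic(12, 0.5, 15, tol), 0)
  expect_lt(selection_intrinsic(12, 0.5, 9, tol), 0)
})

test_that("effective competition is a bounded, symmetric, shift-invariant kernel", {
  expect_equal(effective_competition(5, 1e-14, 5, 1e-14, 2), 1)
  expect_equal(effective_competition(5, 1e-14, 7, 1e-14, 2), exp(-1),
               tolerance = 1e-10)
  set.seed(423)
  for (i in 1:25) {
    mu_i <- runif(1, -10, 30); mu_j <- runif(1, -10, 30)
    s2_i <- runif(1, 0.01, 2); s2_j <- runif(1, 0.01, 2)
    eta <- runif(1, 0.5, 4); shift <- runif(1, -20, 20)
    a_ij <- effective_competition(mu_i, s2_i, mu_j, s2_j, eta)
    expect_lte(a_ij, 1)
    expect_equal(a_ij, effective_competition(mu_j, s2_j, mu_i, s2_i, eta))
    expect_equal(a_ij, effective_competition(mu_i + shift, s2_i,
                                             mu_j + shift, s2_j, eta))
  }
  # strictly decreasing in trait distance
  d <- seq(0, 6, by = 0.5)
  vals <- effective_competition(d, 0.3, 0, 0.3, 2)
  expect_true(all(diff(vals) < 0))
  expect_error(effective_competition(0, 1, 0, 1, eta = 0), "eta")
})

test_that("competitive selection displaces traits away from the competitor", {
  expect_equal(selection_competition(10, 0.5, 10, 0.5, 2, N_j = 1), 0)
  # competitor with a warmer optimum pushes mu_i colder
  expect_lt(selection_competition(10, 0.5, 12, 0.5, 2, N_j = 1), 0)
  expect_gt(selection_competition(10, 0.5, 8, 0.5, 2, N_j = 1), 0)
  # no competitor density, no selection
  expect_equal(selection_competition(10, 0.5, 14, 0.5, 2, N_j = 0), 0)
})

test_that("the oracle reproduces normal moments and kills constant selection", {
  expect_equal(quadrature_oracle(function(z) rep(1, length(z)), 3, 0.7), 1)
  expect_equal(quadrature_oracle(function(z) z, 3, 0.7), 3)
  expect_equal(quadrature_oracle(function(z) (z - 3)^2, 3, 0.7), 0.7)
  # phenotype-independent growth terms contribute nothing to selection:
  # trophic gains/losses cannot directly move the trait mean
  expect_equal(quadrature_oracle(function(z) (z - 3) * 0.42, 3, 0.7), 0,
               tolerance = 1e-12)
})
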