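test_that("feeding rates saturate as a Holling type II response", {
  cfg <- tiny_config(trophic = "two", S = 6, L = 4)
  S <- 12
  gi <- 7  # first consumer
  N <- rep(0.5, S)
  F0 <- feeding_rates(N, cfg)
  # resources eat nothing; consumers feed only on linked prey
  expect_true(all(F0[1:6, ] == 0))
  linked <- cfg$web$W[1, ] > 0
  expect_true(all(F0[gi, c(linked, rep(FALSE, 6))] > 0))
  expect_true(all(F0[gi, c(!linked, rep(TRUE, 6))] == 0))
  # with zero handling time the response is linear in prey density
  cfg0 <- cfg
  cfg0$species$H[] <- 0
  F_lin <- feeding_rates(N, cfg0)
  q1 <- cfg0$species$q[gi]
  expect_equal(F_lin[gi, 1:6], q1 * cfg0$web$W[1, ] * cfg0$web$omega[1, ] * N[1:6])
  # a single linked prey growing dense saturates intake at 1/H
  cfg1 <- cfg
  cfg1$web$W <- matrix(0, 6, 6); cfg1$web$W[, 1] <- 1
  cfg1$web$omega <- cfg1$web$W
  N_big <- c(1e9, rep(0, 5), rep(1, 6))
  F_sat <- feeding_rates(N_big, cfg1)
  expect_equal(F_sat[gi, 1], 1 / cfg1$species$H[gi], tolerance = 1e-6)
  expect_error(feeding_rates(rep(-1, S), cfg), "nonnegative")
})

test_that("per-capita growth reduces to logistic form for a lone resource", {
  cfg <- tiny_config(S = 1, L = 3, competition = "constant")
  st <- initial_state(cfg)
  T2 <- local_temperature(2, st$t, cfg$climate)
  st$mu[1, ] <- T2     # locally adapted in patch 2
  st$N[1, ] <- 0.6
  terms <- per_capita_growth_terms(st, 2, cfg)
  tol <- species_tolerance(cfg$species$rho, cfg$b_w, cfg$a_w, cfg$species$kappa)
  expect_equal(terms$growth,
               mean_intrinsic_growth(T2, cfg$species$sigma2, T2, tol) -
                 cfg$a_matrix[1, 1] * 0.6)
  expect_equal(terms$selection, 0)
})

test_that("a consumer without prey declines", {
  cfg <- tiny_config(trophic = "two", S = 6, L = 4)
  st <- initial_state(cfg)
  st$N[1:6, ] <- 0  # no resources anywhere
  terms <- per_capita_growth_terms(st, 2, cfg)
  expect_true(all(terms$growth[terms$level == "consumer"] < 0))
})

test_that("identical coexisting phenotypes compete at full kernel strength", {
  cfg <- tiny_config(S = 2, L = 3, competition = "temperature_dependent")
  cfg$species$sigma2[] <- 1e-12
  st <- initial_state(cfg)
  st$mu[, 2] <- 10; st$N[, 2] <- c(0.4, 0.7)
  terms <- per_capita_growth_terms(st, 2, cfg)
  tol1 <- species_tolerance(cfg$species$rho[1], cfg$b_w, cfg$a_w,
                            cfg$species$kappa[1])
  T2 <- local_temperature(2, st$t, cfg$climate)
  intrinsic <- mean_intrinsic_growth(10, 1e-12, T2, tol1)
  # competition coefficient is 1 against itself and its identical competitor
  expect_equal(terms$growth[1], intrinsic - (0.4 + 0.7), tolerance = 1e-6)
})

test_that("trophic interactions exert no direct selection on trait means", {
  cfg <- tiny_config(trophic = "two", S = 6, L = 4, seed = 9)
  st <- initial_state(cfg)
  st$N <- st$N + 0.2
  with_web <- per_capita_growth_terms(st, 3, cfg)
  cfg_noweb <- cfg
  cfg_noweb$web$W[] <- 0
  cfg_noweb$web$omega[] <- 0
  without_web <- per_capita_growth_terms(st, 3, cfg_noweb)
  expect_equal(with_web$selection, without_web$selection)
  expect_false(isTRUE(all.equal(with_web$growth, without_web$growth)))
})

test_that("dispersal vanishes on homogeneous landscapes and conserves mass", {
  cfg <- tiny_config(S = 4, L = 6)
  st <- initial_state(cfg)
  st$N[] <- 0.8
  st$mu[] <- 12
  d <- dispersal_terms(st, cfg)
  expect_equal(d$dN, matrix(0, 4, 6))
  expect_equal(d$dmu_raw, matrix(0, 4, 6))
  # heterogeneous densities: reflecting/mirror boundaries conserve totals
  set.seed(31)
  st$N <- matrix(runif(24, 0.1, 2), 4, 6)
  d2 <- dispersal_terms(st, cfg)
  expect_equal(rowSums(d2$dN), rep(0, 4), tolerance = 1e-14)
  # equal trait means: no trait flux regardless of density differences
  expect_equal(d2$dmu_raw, matrix(0, 4, 6))
})

test_that("heritability zero freezes trait means entirely", {
  cfg <- freeze_traits(tiny_config(S = 4, L = 5, seed = 13))
  st <- initial_state(cfg)
  st$N <- st$N + 0.3
  st$mu <- st$mu + matrix(rnorm(20, 0, 0.5), 4, 5)
  rhs <- assemble_rhs(st, cfg, t = 100)
  expect_equal(rhs$dmu, matrix(0, 4, 5))
  expect_false(isTRUE(all.equal(rhs$dN, matrix(0, 4, 5))))
})

test_that("the compiled right-hand side matches the reference implementation", {
  set.seed(77)
  for (case in list(list(trophic = "one", competition = "constant"),
                    list(trophic = "two", competition = "constant"),
                    list(trophic = "one", competition = "temperature_dependent"),
                    list(trophic = "two", competition = "temperature_dependent"))) {
    cfg <- tiny_config(trophic = case$trophic, competition = case$competition,
                       S = 7, L = 6, seed = 21)
    st <- initial_state(cfg)
    st$N <- st$N * matrix(runif(length(st$N), 0, 1.5), nrow(st$N))
    st$mu <- st$mu + matrix(rnorm(length(st$mu), 0, 1), nrow(st$mu))
    for (t in c(-1000, 150, 1000)) {
      ref <- assemble_rhs(st, cfg, t = t)
      out <- ecoevoclim:::rhs_flat(t, c(st$N, st$mu),
                                   ecoevoclim:::rhs_parms(cfg))
      n <- length(st$N)
      expect_equal(out[seq_len(n)], as.vector(ref$dN), tolerance = 1e-12)
      expect_equal(out[n + seq_len(n)], as.vector(ref$dmu), tolerance = 1e-12)
    }
  }
})

test_that("small Lotka-Volterra equilibria match the linear-algebra solution", {
  # two resources, one patch, frozen traits, constant competition:
  # at equilibrium A N* = g  (both species locally adapted)
  cfg <- freeze_traits(tiny_config(S = 2, L = 1, seed = 17,
                                   climate = flat_climate(1)))
  cfg$species$m[] <- 0
  T1 <- local_temperature(1, 0, cfg$climate)
  cfg$species$mu0 <- c(T1, T1)
  g <- vapply(1:2, function(i) {
    tol <- species_tolerance(cfg$species$rho[i], cfg$b_w, cfg$a_w,
                             cfg$species$kappa[i])
    mean_intrinsic_growth(T1, cfg$species$sigma2[i], T1, tol)
  }, numeric(1))
  N_star <- solve(cfg$a_matrix, g)
  expect_true(all(N_star > 0))  # feasible interior equilibrium for this draw
  cfg$times <- list(t0 = 0, t_end = 3000, cadence = 500)
  cfg$solver$rtol <- 1e-10; cfg$solver$atol <- 1e-12
  traj <- run_replicate(cfg)
  final <- dplyr::filter(traj$states, time == 3000)
  expect_equal(final$density, N_star, tolerance = 1e-6)
})
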