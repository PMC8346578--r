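test_that("trait dispersion is the density-weighted trait variance", {
  expect_equal(trait_dispersion(5, 12), 0)           # single species
  expect_equal(trait_dispersion(c(1, 1), c(17, 19)), 1)
  expect_equal(trait_dispersion(c(3, 1), c(0, 4)), 3)
  expect_true(is.na(trait_dispersion(c(0, 0), c(1, 2))))
  # brute-force two-pass weighted variance on random communities
  set.seed(101)
  for (i in 1:50) {
    n <- sample(2:12, 1)
    dens <- runif(n); mu <- rnorm(n, 10, 5)
    w <- dens / sum(dens)
    brute <- sum(w * (mu - sum(w * mu))^2)
    expect_equal(trait_dispersion(dens, mu), brute, tolerance = 1e-12)
    expect_gte(trait_dispersion(dens, mu), 0)
    # invariant under a common shift of all optima
    expect_equal(trait_dispersion(dens, mu + 7.3),
                 trait_dispersion(dens, mu), tolerance = 1e-9)
  }
})

test_that("trait lag is temperature minus the community-weighted mean optimum", {
  expect_equal(trait_lag(c(1, 1), c(10, 20), 18), 3)
  expect_equal(trait_lag(c(2, 3), c(10, 10), 10), 0)
  expect_true(is.na(trait_lag(numeric(0), numeric(0), 5)))
})

test_that("integrated lag and dispersion average over patches and time", {
  clim <- flat_climate(L = 2, T_min = 10, T_max = 20)
  # static two-patch community perfectly tracking a constant climate
  states <- tidyr::expand_grid(time = c(0, 150, 300), patch = 1:2,
                               species = 1:2) |>
    dplyr::mutate(level = "resource", density = 1,
                  trait_mean = local_temperature(patch, 0, clim) +
                    ifelse(species == 1, -1, 1))
  traj <- fake_trajectory(states, clim, t_E = 300)
  out <- integrated_lag_dispersion(traj)
  expect_equal(out$lag, 0)
  expect_equal(out$dispersion, 1)  # two equal-density species at T +/- 1
  # a single-snapshot window degenerates to that snapshot's patch average
  out1 <- integrated_lag_dispersion(traj, window = c(150, 150))
  expect_equal(out1, out)
  expect_error(integrated_lag_dispersion(traj, window = c(4000, 5000)),
               "window")
})

test_that("richness and range breadth count presences above the threshold", {
  clim <- flat_climate(L = 3)
  states <- tidyr::expand_grid(time = c(0, 300, 2500), patch = 1:3,
                               species = 1:4) |>
    dplyr::mutate(level = "resource", density = 1, trait_mean = 10)
  traj <- fake_trajectory(states, clim, t_E = 300)
  lr <- local_richness(traj)
  expect_true(all(lr$richness == 4))
  rs <- richness_summary(traj)
  expect_equal(rs$mean_richness, rep(4, 3))
  expect_equal(rs$sd_richness, rep(0, 3))
  rb <- range_breadth(traj)
  expect_true(all(rb$range_breadth == 100))
  # an empty landscape has zero richness and breadth
  empty <- traj
  empty$states$density <- 0
  expect_true(all(local_richness(empty)$richness == 0))
  expect_true(all(range_breadth(empty)$range_breadth == 0))
})

test_that("patches split into polar, temperate and tropical thirds", {
  expect_equal(patch_regions(9), rep(c("polar", "temperate", "tropical"), each = 3))
  r50 <- patch_regions(50)
  expect_equal(as.vector(table(factor(r50, levels = c("polar", "temperate", "tropical")))),
               c(17, 16, 17))
  expect_equal(r50[1], "polar")
  expect_equal(r50[50], "tropical")
})

test_that("turnover is a bounded Bray-Curtis dissimilarity on region sums", {
  clim <- flat_climate(L = 3)
  base <- tidyr::expand_grid(time = c(0, 2500), patch = 1:3, species = 1:3) |>
    dplyr::mutate(level = "resource", trait_mean = 10)
  same <- dplyr::mutate(base, density = species)
  traj_same <- fake_trajectory(same, clim)
  expect_equal(turnover(traj_same, "all", 0, 2500), 0)
  # disjoint compositions are maximally dissimilar
  disj <- dplyr::mutate(base, density = ifelse(xor(time == 0, species > 1), 1, 0))
  traj_disj <- fake_trajectory(disj, clim)
  expect_equal(turnover(traj_disj, "all", 0, 2500), 1)
  expect_equal(turnover(traj_disj, "all", 0, 2500, method = "jaccard"), 1)
  # bounds on random abundance vectors
  set.seed(202)
  for (i in 1:20) {
    rnd <- dplyr::mutate(base, density = runif(dplyr::n()))
    d <- turnover(fake_trajectory(rnd, clim), "all", 0, 2500)
    expect_gte(d, 0); expect_lte(d, 1)
  }
})

test_that("relative global richness tracks extinctions", {
  clim <- flat_climate(L = 3)
  states <- tidyr::expand_grid(time = c(0, 300, 2500), patch = 1:3,
                               species = 1:10) |>
    dplyr::mutate(level = "resource", trait_mean = 10,
                  density = ifelse(time == 2500 & species == 1, 0, 1))
  traj <- fake_trajectory(states, clim)
  grc <- global_richness_change(traj)
  glob <- dplyr::filter(grc, region == "global")
  expect_equal(glob$relative_richness[glob$time == 0], 1)
  expect_equal(glob$relative_richness[glob$time == 300], 1)
  expect_equal(glob$relative_richness[glob$time == 2500], 0.9)
})

test_that("the lag-dispersion fit exposes tidy and glance summaries", {
  set.seed(303)
  df <- tibble::tibble(dispersion = runif(30, 0.5, 3))
  df$lag <- 2 - 0.4 * df$dispersion + rnorm(30, 0, 0.05)
  fit <- fit_lag_dispersion(df)
  td <- tidy(fit)
  expect_equal(td$term, c("(Intercept)", "dispersion"))
  gl <- glance(fit)
  expect_equal(gl$n, 30)
  expect_lt(gl$slope, 0)
  expect_equal(gl$slope, unname(coef(fit$fit)[2]))
  expect_gt(gl$r.squared, 0.9)
})
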