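small_obs <- function(lambda = 1.5, N = 500, seed = 77)
  sample_counts(zipf_model(lambda), N, seed = seed)$counts

test_that("rejection with infinite tolerance recovers the uniform prior", {
  obs <- small_obs()
  rejections <- 0L
  for (s in 1:20) {
    cfg <- abc_config(n_particles = 80, seed = 100 + s)
    pop <- abc_rejection(obs, "zipf", cfg, epsilon = Inf)
    pv <- suppressWarnings(stats::ks.test(
      pop$particles[, 1], "punif", cfg$prior_lambda[1],
      cfg$prior_lambda[2])$p.value)
    if (pv < 0.001) rejections <- rejections + 1L
  }
  expect_lte(rejections, 1L)
})

test_that("ABC runs are deterministic given a seed", {
  obs <- small_obs()
  cfg <- abc_config(n_particles = 40, n_generations = 3, seed = 9)
  a <- abc_rejection(obs, "zipf", cfg, epsilon = Inf)
  b <- abc_rejection(obs, "zipf", cfg, epsilon = Inf)
  expect_identical(a$particles, b$particles)
  p1 <- abc_pmc(obs, "zipf", cfg)
  p2 <- abc_pmc(obs, "zipf", cfg)
  expect_identical(p1$population$particles, p2$population$particles)
  expect_identical(p1$posterior$map_estimate, p2$posterior$map_estimate)
})

test_that("rejection at a small prior-predictive tolerance recovers lambda", {
  obs <- small_obs(lambda = 1.5, N = 2000, seed = 13)
  # prior-predictive distance scale from a pilot run
  pilot <- abc_rejection(obs, "zipf",
                         abc_config(n_particles = 300, seed = 14), Inf)
  eps <- unname(quantile(pilot$distances, 0.02))
  cfg <- abc_config(n_particles = 30, seed = 15,
                    max_draws_per_generation = 30000)
  pop <- abc_rejection(obs, "zipf", cfg, epsilon = eps)
  expect_true(all(pop$distances < eps))
  expect_lt(abs(weighted.mean(pop$particles[, 1], pop$weights) - 1.5), 0.15)
})

test_that("rejection errors when the draw cap is exhausted", {
  obs <- small_obs()
  cfg <- abc_config(n_particles = 50, max_draws_per_generation = 60, seed = 4)
  expect_error(abc_rejection(obs, "zipf", cfg, epsilon = 1e-9), "acceptances")
})

test_that("PMC tolerance schedule is non-increasing and posterior concentrates", {
  obs <- small_obs(lambda = 1.4, N = 2000, seed = 23)
  cfg <- abc_config(n_particles = 80, n_generations = 5, seed = 24)
  res <- abc_pmc(obs, "zipf", cfg)
  expect_true(all(diff(res$tolerances) <= 0))
  expect_true(all(res$population$distances < res$population$tolerance))
  expect_equal(sum(res$population$weights), 1, tolerance = 1e-12)
  expect_lt(abs(res$posterior$map_estimate[["lambda"]] - 1.4), 0.2)
})

test_that("posterior densities are proper and the MAP matches a grid oracle", {
  obs <- small_obs(N = 1000)
  res <- abc_pmc(obs, "zipf",
                 abc_config(n_particles = 60, n_generations = 4, seed = 31))
  post <- res$posterior
  dx <- diff(post$support)
  integral <- sum(dx * (head(post$density, -1) + post$density[-1]) / 2)
  expect_equal(integral, 1, tolerance = 1e-6)
  expect_true(all(post$density >= 0))
  # direct grid evaluation of the weighted KDE reproduces the MAP
  pop <- res$population
  h <- post$bandwidth
  dens <- vapply(post$support, function(g)
    sum(pop$weights * dnorm(g, pop$particles[, 1], h)), numeric(1))
  expect_equal(post$map_estimate[["lambda"]],
               post$support[which.max(dens)], tolerance = 1e-9)
})

test_that("map_estimate behaves on degenerate particle populations", {
  cfg <- abc_config(n_particles = 5, seed = 1)
  mk_pop <- function(lams, w) structure(
    list(particles = matrix(lams, ncol = 1, dimnames = list(NULL, "lambda")),
         weights = w / sum(w), distances = numeric(length(lams)),
         tolerance = Inf, generation = 0L, family = "zipf", config = cfg,
         n_draws = length(lams), acceptance_rate = 1),
    class = "abc_population")
  expect_equal(map_estimate(mk_pop(rep(1.3, 5), rep(1, 5)))[["lambda"]], 1.3,
               tolerance = 1e-3)
  conc <- mk_pop(c(1.8, 2.4, 2.41, 2.39, 2.42), c(0.99, rep(0.0025, 4)))
  expect_lt(abs(map_estimate(conc)[["lambda"]] - 1.8), 0.05)
})

test_that("mean log count summary statistic", {
  expect_equal(mean_log_counts(rank_counts(c(1, 1, 1))), 0)
  expect_equal(mean_log_counts(rank_counts(c(7, 7))), log(7))
})

test_that("ABC regression recovers the exponent and reports a proper posterior", {
  obs <- small_obs(lambda = 1.5, N = 2000, seed = 55)
  cfg <- abc_config(n_prior_draws = 2000, seed = 56)
  post <- abc_regression(obs, "zipf", cfg)
  expect_lt(abs(post$point_estimate - 1.5), 0.1)
  dx <- diff(post$support)
  integral <- sum(dx * (head(post$density, -1) + post$density[-1]) / 2)
  expect_equal(integral, 1, tolerance = 1e-6)
  expect_error(abc_regression(obs, "zipf_mandelbrot", cfg), "one-parameter")
})

test_that("two-parameter inference with q fixed at 0 matches one-parameter", {
  obs <- small_obs(lambda = 1.4, N = 2000, seed = 61)
  cfg1 <- abc_config(n_particles = 60, n_generations = 4, seed = 62)
  cfg2 <- abc_config(n_particles = 60, n_generations = 4, seed = 62,
                     prior_q = c(0, 0))
  m1 <- abc_pmc(obs, "zipf", cfg1)$posterior$map_estimate[["lambda"]]
  res2 <- abc_pmc(obs, "zipf_mandelbrot", cfg2)
  m2 <- res2$posterior$map_estimate
  expect_equal(m2[["q"]], 0)
  expect_lt(abs(m2[["lambda"]] - m1), 0.15)
  # 2-D posterior mass sums to 1
  expect_equal(sum(res2$posterior$q_marginal), 1, tolerance = 1e-6)
})

test_that("empty observations are rejected", {
  cfg <- abc_config(seed = 1)
  expect_error(abc_rejection(rank_counts(integer(0)), "zipf", cfg), "empty")
  expect_error(abc_pmc(rank_counts(integer(0)), "zipf", cfg), "empty")
})
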