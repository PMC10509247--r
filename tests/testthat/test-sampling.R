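test_that("truncated-normal draws respect their support exactly", {
  d <- sample_truncated_normal(1e4, 0.85, 0.05, 0.8, 0.95, seed = 1)
  expect_gte(min(d), 0.8)
  expect_lte(max(d), 0.95)
  expect_error(sample_truncated_normal(10, 0, 1, 2, 1), "lower")
})

test_that("untruncated limit recovers the plain normal mean", {
  n <- 1e4
  d <- sample_truncated_normal(n, 0, 1, -1e9, 1e9, seed = 2)
  expect_lt(abs(mean(d)), 4 / sqrt(n))
})

test_that("truncated-normal mean matches a quadrature oracle", {
  # E[X | 1 < X < 5], X ~ N(3, 0.6), by numerical integration
  z <- stats::pnorm(5, 3, 0.6) - stats::pnorm(1, 3, 0.6)
  oracle <- stats::integrate(function(x) x * stats::dnorm(x, 3, 0.6),
                             1, 5)$value / z
  d <- sample_truncated_normal(1e5, 3, 0.6, 1, 5, seed = 3)
  expect_lt(abs(mean(d) - oracle), 0.02)
})

test_that("zero-sd truncated normal degenerates to the clamped mean", {
  expect_identical(sample_truncated_normal(5, 0.85, 0, 0.8, 0.95),
                   rep(0.85, 5))
})

test_that("lognormal moment matching is exact", {
  p <- lognormal_params_from_mean_cv(100, 0)
  expect_equal(unname(p), c(log(100), 0))
  p <- lognormal_params_from_mean_cv(100, 0.3)
  expect_equal(exp(p[["mu"]] + p[["sigma"]]^2 / 2), 100)
  # lognormal CV = sqrt(exp(sigma^2) - 1)
  expect_equal(sqrt(exp(p[["sigma"]]^2) - 1), 0.3)
  expect_error(lognormal_params_from_mean_cv(0, 0.3), "mean_a")
})

test_that("abundance draws recover the survey mean and CV", {
  n <- 1e5
  d <- sample_abundance(n, 2500, 0.45, seed = 4)
  expect_lt(abs(mean(d) / 2500 - 1), 0.02)
  expect_lt(abs(sd(d) / mean(d) / 0.45 - 1), 0.03)
  expect_identical(sample_abundance(5, 0, 0.3), rep(0, 5))
  expect_identical(sample_abundance(5, 100, 0), rep(100, 5))
})

test_that("abundance moment recovery holds across random (mean, cv) pairs", {
  n <- 1e4
  set.seed(5)
  pairs <- data.frame(mean = runif(20, 50, 1e5), cv = runif(20, 0.1, 0.8))
  for (i in seq_len(20)) {
    m <- pairs$mean[i]; cv <- pairs$cv[i]
    d <- sample_abundance(n, m, cv, seed = 100 + i)
    # MC standard error of the sample mean is sd/sqrt(n)
    se_mean <- m * cv / sqrt(n)
    expect_lt(abs(mean(d) - m), 3 * se_mean)
  }
})

test_that("release-rate rules follow the migratory fasting context", {
  cfg <- simulation_config(n_sim = 1e4, seed = 6)
  humpback <- make_species(taxon = "baleen_whale", migratory = TRUE)
  r <- sample_release_rates(1e4, humpback, "breeding", cfg, seed = 7)
  for (nm in c("Fe", "Cu", "Mn", "Se", "Zn", "Co")) {
    expect_identical(unname(r[, nm]), rep(0, 1e4))
  }
  expect_gte(min(r[, c("N", "P")]), 0.2)
  expect_lte(max(r[, c("N", "P")]), 0.4)

  # same species feeding: everything U(0.7, 0.9)
  r <- sample_release_rates(1e4, humpback, "feeding", cfg, seed = 8)
  expect_gte(min(r), 0.7)
  expect_lte(max(r), 0.9)

  # resident small cetacean: all nutrients U(0.7, 0.9), mean ~ 0.8
  dolphin <- make_species()
  r <- sample_release_rates(1e4, dolphin, "resident", cfg, seed = 9)
  expect_gte(min(r), 0.7)
  expect_lte(max(r), 0.9)
  expect_lt(abs(mean(r) - 0.8), 0.005)
})

test_that("days of presence: migrants are seasonal, residents year-round", {
  cfg <- simulation_config(n_sim = 1e4, seed = 10)
  dolphin <- make_species()
  expect_identical(sample_days_present(100, dolphin, "feeding", cfg),
                   rep(365, 100))
  fin <- make_species(taxon = "baleen_whale", migratory = TRUE)
  for (ground in c("feeding", "breeding")) {
    t <- sample_days_present(1e4, fin, ground, cfg, seed = 11)
    expect_gte(min(t), 120)
    expect_lte(max(t), 240)
  }
  t <- sample_days_present(1e4, fin, "feeding", cfg, seed = 12)
  expect_lt(abs(mean(t) - 180), 2)
})

test_that("block aggregation combines means and CVs as independent errors", {
  expect_equal(aggregate_abundance_blocks(1000, 0.3),
               list(mean = 1000, cv = 0.3))
  # oracle: sqrt((0.2*500)^2 + (0.2*500)^2) / 1000 = sqrt(2)*100/1000
  got <- aggregate_abundance_blocks(c(500, 500), c(0.2, 0.2))
  expect_equal(got$mean, 1000)
  expect_equal(got$cv, sqrt(100^2 + 100^2) / 1000)
  expect_equal(got$cv, 0.1414214, tolerance = 1e-6)
  expect_equal(aggregate_abundance_blocks(c(0, 800), c(0, 0.5)),
               list(mean = 800, cv = 0.5))
  expect_warning(z <- aggregate_abundance_blocks(c(0, 0), c(0, 0)),
                 "zero")
  expect_equal(z, list(mean = 0, cv = 0))
})

test_that("parameter draws are reproducible and respect every support", {
  cfg <- tiny_config(n_sim = 1e3)
  sp <- make_species(taxon = "baleen_whale", migratory = TRUE,
                     bm = 50, beta = 4.5)
  ab <- make_abundance(mean_abundance = 2000, cv = 0.4)
  diet <- constant_diet(1e3)
  d1 <- build_parameter_draws(sp, ab, "feeding", cfg, diet)
  d2 <- build_parameter_draws(sp, ab, "feeding", cfg, diet)
  expect_identical(d1, d2)

  expect_true(all(d1$beta >= 1 & d1$beta <= 5))
  expect_true(all(d1$ae >= 0.8 & d1$ae <= 0.95))
  expect_true(all(d1$bm > 0))
  expect_true(all(d1$r >= 0.7 & d1$r <= 0.9))
  expect_true(all(d1$t >= 120 & d1$t <= 240))
  expect_true(all(d1$a >= 0))

  # body-mass spread: sd ~ 20% of the mean
  cfg2 <- tiny_config(n_sim = 1e4)
  d3 <- build_parameter_draws(make_species(bm = 50), make_abundance(),
                              "resident", cfg2, constant_diet(1e4))
  expect_lt(abs(sd(d3$bm) / 10 - 1), 0.05)
})

test_that("sub-streams are keyed by identity, not iteration order", {
  cfg <- tiny_config(n_sim = 500)
  diet <- constant_diet(500)
  spA <- make_species(id = "spA")
  spB <- make_species(id = "spB")
  abA <- make_abundance(id = "spA")
  abB <- make_abundance(id = "spB")
  # draws for A alone...
  a_alone <- build_parameter_draws(spA, abA, "resident", cfg, diet)
  # ...and for A after B has consumed RNG in between
  invisible(build_parameter_draws(spB, abB, "resident", cfg, diet))
  set.seed(777)  # perturb the global RNG state too
  a_again <- build_parameter_draws(spA, abA, "resident", cfg, diet)
  expect_identical(a_alone, a_again)
  # different species get different draws
  b <- build_parameter_draws(spB, abB, "resident", cfg, diet)
  expect_false(identical(a_alone$bm, b$bm))
})

test_that("configuration round-trips through YAML", {
  cfg <- simulation_config(n_sim = 123, seed = 9L)
  path <- tempfile(fileext = ".yaml")
  write_config(cfg, path)
  expect_equal(read_config(path), cfg)
  expect_error(simulation_config(n_sim = 1), "n_sim")
  expect_error(simulation_config(beta_bounds = c(5, 1)), "ordered")
})
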