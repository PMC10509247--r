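test_that("additive model: S1 equals analytic variance shares", {
  # y = z1 + 2*z2, independent standard normals: shares 1/5 and 4/5
  model <- function(m) m[, "z1"] + 2 * m[, "z2"]
  sam <- list(z1 = function(n) rnorm(n), z2 = function(n) rnorm(n))
  res <- sobol_indices(model, sam, n_base = 2^14, seed = 90)
  s1 <- setNames(res$S1$S1, res$S1$parameter)
  expect_lt(abs(s1[["z1"]] - 0.2), 0.02)
  expect_lt(abs(s1[["z2"]] - 0.8), 0.02)
  # additive: second-order interaction ~ 0
  expect_lt(abs(res$S2$S2), 0.05)
  expect_equal(res$n_evaluations, 2^14 * 6)
})

test_that("constant model yields zero indices with a warning", {
  model <- function(m) rep(3, nrow(m))
  sam <- list(a = function(n) rnorm(n), b = function(n) rnorm(n))
  expect_warning(res <- sobol_indices(model, sam, 256, seed = 91),
                 "zero output variance")
  expect_identical(unique(res$S1$S1), 0)
  expect_identical(unique(res$S2$S2), 0)
})

test_that("Ishigami indices match the analytic decomposition", {
  a <- 7; b <- 0.1
  model <- function(m) {
    sin(m[, "x1"]) + a * sin(m[, "x2"])^2 + b * m[, "x3"]^4 * sin(m[, "x1"])
  }
  sam <- list(x1 = function(n) runif(n, -pi, pi),
              x2 = function(n) runif(n, -pi, pi),
              x3 = function(n) runif(n, -pi, pi))
  # closed-form variance decomposition
  V <- a^2 / 8 + b * pi^4 / 5 + b^2 * pi^8 / 18 + 0.5
  s1_true <- c(x1 = 0.5 * (1 + b * pi^4 / 5)^2 / V,
               x2 = (a^2 / 8) / V,
               x3 = 0)
  s2_13_true <- (8 * b^2 * pi^8 / 225) / V
  res <- sobol_indices(model, sam, n_base = 2^14, seed = 92)
  s1 <- setNames(res$S1$S1, res$S1$parameter)
  for (p in names(s1_true)) {
    expect_lt(abs(s1[[p]] - s1_true[[p]]), 0.02)
  }
  s2 <- res$S2
  got_13 <- s2$S2[s2$parameter_1 == "x1" & s2$parameter_2 == "x3"]
  expect_lt(abs(got_13 - s2_13_true), 0.05)
})

test_that("multiplicative lognormal model matches the closed form", {
  # y = prod(z_i), z_i independent lognormal(0, s_i):
  # S1_i = (exp(s_i^2) - 1) / (exp(sum(s^2)) - 1)
  set.seed(93)
  for (rep in 1:3) {
    s <- runif(3, 0.2, 0.7)
    model <- local({
      function(m) m[, 1] * m[, 2] * m[, 3]
    })
    sam <- setNames(lapply(1:3, function(i) {
      force(i); function(n) rlnorm(n, 0, s[i])
    }), paste0("z", 1:3))
    res <- sobol_indices(model, sam, n_base = 2^14, seed = 93 + rep,
                         second_order = FALSE)
    truth <- (exp(s^2) - 1) / (exp(sum(s^2)) - 1)
    expect_lt(max(abs(res$S1$S1 - truth)), 0.03)
  }
})

test_that("fixing every parameter but one concentrates S1 on it", {
  model <- function(m) m[, "a"] + m[, "b"] + m[, "c"]
  sam <- list(a = function(n) rnorm(n),
              b = function(n) rep(1, n),
              c = function(n) rep(2, n))
  res <- sobol_indices(model, sam, 2^12, seed = 94, second_order = FALSE)
  s1 <- setNames(res$S1$S1, res$S1$parameter)
  expect_lt(abs(s1[["a"]] - 1), 0.02)
  expect_lt(abs(s1[["b"]]), 0.02)
})

test_that("release-model samplers tie Sobol to the study context", {
  cfg <- tiny_config(n_sim = 500)
  sp <- make_species(taxon = "baleen_whale", migratory = TRUE, bm = 3e4,
                     beta = 3)
  diet <- constant_diet(500, energy = 4000,
                        x = setNames(rep(50, 8), nutrient_set()$nutrient))
  model <- release_model_fn()
  # zero abundance CV: abundance contributes no variance
  ab0 <- make_abundance(mean_abundance = 5000, cv = 0)
  sam <- release_model_samplers(sp, ab0, "feeding", cfg, diet, "N")
  res <- sobol_indices(model, sam, 2^11, seed = 95, second_order = FALSE)
  s1 <- setNames(res$S1$S1, res$S1$parameter)
  expect_lt(abs(s1[["A"]]), 0.02)
  # constant diet: E and x contribute nothing either
  expect_lt(abs(s1[["E"]]), 0.02)
  # huge abundance CV dominates every other source of variance
  ab1 <- make_abundance(mean_abundance = 5000, cv = 2.5)
  sam <- release_model_samplers(sp, ab1, "feeding", cfg, diet, "N")
  res <- sobol_indices(model, sam, 2^12, seed = 96, second_order = FALSE)
  s1 <- setNames(res$S1$S1, res$S1$parameter)
  expect_identical(names(which.max(s1)), "A")
  expect_gt(s1[["A"]], 0.5)
  # fasting migrant, trace nutrient: r is constant 0, output is 0
  samf <- release_model_samplers(sp, ab1, "breeding", cfg, diet, "Fe")
  expect_warning(resf <- sobol_indices(model, samf, 256, seed = 97),
                 "zero output variance")
  expect_identical(unique(resf$S1$S1), 0)
})

test_that("sweep summarizes per-cell indices across the study", {
  st <- generate_study(tiny_spec())
  cfg <- tiny_config(n_sim = 300)
  sw <- model_sensitivity_sweep(st, cfg, nutrients = "N", cells = 1:4,
                                n_base = 2^10, second_order = FALSE)
  expect_identical(sort(unique(sw$cells$parameter)),
                   sort(c("BM", "beta", "E", "x", "AE", "r", "A", "t")))
  expect_identical(nrow(sw$summary), 8L)
  expect_true(all(sw$cells$S1 > -0.05 & sw$cells$S1 < 1.05))
  # doubling n_base leaves estimates within a few standard errors
  sw2 <- model_sensitivity_sweep(st, cfg, nutrients = "N", cells = 1:4,
                                 n_base = 2^11, second_order = FALSE)
  m <- merge(sw$cells, sw2$cells,
             by = c("parameter", "species_id", "area_id", "habitat",
                    "nutrient"))
  expect_gt(mean(abs(m$S1.x - m$S1.y) <= 3 * (m$se.x + m$se.y) + 0.02),
            0.9)
})
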