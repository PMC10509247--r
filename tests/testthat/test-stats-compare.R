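test_that("binary relation test reproduces the directional convention", {
  # 9900 of 10000 paired draws favour group 1 -> p = 0.01, significant
  n <- 1e4
  a <- rep(1, n)
  b <- c(rep(0, 9900), rep(2, 100))
  res <- binary_relation_test(a, b)
  expect_equal(res$fraction_greater, 0.99)
  expect_equal(res$p, 0.01)
  expect_true(res$significant)
  expect_identical(res$direction, "group1")
})

test_that("ties and degenerate comparisons", {
  v <- rnorm(100)
  res <- binary_relation_test(v, v)   # all ties
  expect_equal(res$fraction_greater, 0.5)
  expect_equal(res$p, 0.5)
  expect_false(res$significant)
  expect_identical(res$direction, "none")

  res <- binary_relation_test(v + 1, v)
  expect_equal(res$fraction_greater, 1)
  expect_equal(res$p, 1 / 100)  # floored, never exactly 0
  expect_true(res$significant)
  expect_error(binary_relation_test(1:3, 1:4), "equal length")
})

test_that("antisymmetry and monotone invariance", {
  set.seed(80)
  for (i in 1:10) {
    a <- rnorm(500, mean = runif(1, -1, 1))
    b <- rnorm(500)
    f_ab <- binary_relation_test(a, b)$fraction_greater
    f_ba <- binary_relation_test(b, a)$fraction_greater
    expect_equal(f_ab, 1 - f_ba)
    # strictly monotone transform of both vectors leaves the fraction
    g <- function(x) exp(2 * x) + 5
    expect_equal(binary_relation_test(g(a), g(b))$fraction_greater, f_ab)
  }
})

test_that("all-pairs variant agrees with the Mann-Whitney statistic", {
  set.seed(81)
  a <- rnorm(60, 0.5); b <- rnorm(40)
  res <- binary_relation_test(a, b, all_pairs = TRUE)
  oracle <- mean(outer(a, b, `>`)) + 0.5 * mean(outer(a, b, `==`))
  expect_equal(res$fraction_greater, oracle)
})

test_that("under an exact null the paired test almost never fires", {
  # with independent iid draws the fraction concentrates at 0.5 with
  # sd = 0.5/sqrt(n); at n = 1e3 the 0.95/0.05 rule is then essentially
  # unreachable, i.e. Monte-Carlo noise alone does not trigger it
  set.seed(82)
  hits <- 0
  fracs <- replicate(1000, {
    r <- binary_relation_test(rnorm(1000), rnorm(1000))
    hits <<- hits + r$significant
    r$fraction_greater
  })
  expect_lt(hits / 1000, 0.01)
  expect_lt(abs(mean(fracs) - 0.5), 0.005)
  expect_lt(abs(sd(fracs) - 0.5 / sqrt(1000)), 0.005)
})

test_that("stoichiometry profile is x * r per kg ingested", {
  n <- 1e4
  nut <- nutrient_set()$nutrient
  x10 <- constant_diet(n, x = setNames(rep(10, 8), nut))
  r <- matrix(0.8, n, 8, dimnames = list(NULL, nut))
  p <- stoichiometry_profile(x10, r)
  expect_identical(unique(as.vector(p$draws)), 8)
  expect_identical(unique(p$summary$mean), 8)
  p0 <- stoichiometry_profile(x10, r * 0)
  expect_identical(unique(as.vector(p0$draws)), 0)
  # uniform release rate on [0.7, 0.9] with x = 100: mean 80
  set.seed(83)
  x100 <- constant_diet(n, x = setNames(rep(100, 8), nut))
  ru <- matrix(runif(n * 8, 0.7, 0.9), n, 8, dimnames = list(NULL, nut))
  p <- stoichiometry_profile(x100, ru)
  se <- 100 * (0.2 / sqrt(12)) / sqrt(n)
  expect_lt(max(abs(p$summary$mean - 80)), 4 * se)
  expect_true(all(p$summary$q2.5 <= p$summary$mean &
                  p$summary$mean <= p$summary$q97.5))
})

test_that("stoichiometry PCA has the standard spectral properties", {
  set.seed(84)
  # rank-2 construction: 24 columns from 2 latent factors
  z <- matrix(rnorm(20 * 2), 20, 2)
  load <- matrix(rnorm(2 * 24), 2, 24)
  m <- z %*% load
  colnames(m) <- paste0("v", 1:24)
  fit <- pca_stoichiometry(m)
  expect_lt(sum(fit$eig[-(1:2)]) / sum(fit$eig), 1e-9)
  # component variances sum to the number of standardized columns
  expect_equal(sum(fit$eig), 24)
  # duplicated rows score identically
  m2 <- rbind(m, m[3, ])
  fit2 <- pca_stoichiometry(m2)
  expect_equal(fit2$scores[3, ], fit2$scores[21, ])
  # full-rank reconstruction identity
  r <- matrix(rnorm(12 * 6), 12, 6, dimnames = list(NULL, paste0("v", 1:6)))
  fr <- pca_stoichiometry(r)
  rec <- fr$scores %*% t(fr$loadings)
  expect_equal(rec, scale(r), ignore_attr = TRUE, tolerance = 1e-9)
  # constant columns are dropped with a warning
  rc <- cbind(r, const = 1)
  expect_warning(fc <- pca_stoichiometry(rc), "const")
  expect_identical(fc$dropped, "const")
  expect_error(pca_stoichiometry(r[1:2, ]), "3 species")
})

test_that("productivity regressions recover known and null slopes", {
  areas <- sprintf("a%02d", 1:14)
  covs <- data.frame(area_id = areas,
                     mean_chlorophyll = seq(0.1, 1.4, length.out = 14),
                     mean_sst = seq(28, 7, length.out = 14),
                     chlorophyll_outlier = c(rep(FALSE, 13), TRUE))
  # exact line y = 2x on the non-excluded areas
  y <- matrix(2 * covs$mean_chlorophyll, 14, 2,
              dimnames = list(areas, c("N", "Fe")))
  # (suppress lm's "essentially perfect fit" warning for the exact line)
  fit <- suppressWarnings(productivity_regression(y, covs, "chlorophyll"))
  expect_equal(fit$slope, c(2, 2))
  expect_equal(fit$r_squared, c(1, 1))
  # the flagged turbidity area is excluded from chlorophyll fits only
  expect_identical(unique(fit$n_areas), 13L)
  fit_sst <- suppressWarnings(productivity_regression(y, covs, "sst"))
  expect_identical(unique(fit_sst$n_areas), 14L)
  # pure noise: slope near 0, R^2 near 0
  set.seed(85)
  yn <- matrix(rnorm(14, 5), 14, 1, dimnames = list(areas, "N"))
  fn <- productivity_regression(yn, covs, "sst")
  expect_gt(fn$p_value, 0.05)
  expect_lt(fn$r_squared, 0.3)
  expect_error(productivity_regression(y[1:2, , drop = FALSE], covs,
                                       "sst"), "3 areas")
})
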