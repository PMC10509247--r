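#' Monte-Carlo simulation settings
#'
#' Defaults encode the study design: 1e4 draws; body mass and metabolic
#' multiplier with 20% coefficients of variation (the latter truncated to
#' [1, 5]); assimilation efficiency truncated-normal N(0.85, 0.05) on
#' [0.80, 0.95]; nutrient release rates U(0.7, 0.9) generally and
#' U(0.2, 0.4) for N and P (0 for trace nutrients) for migratory baleen
#' whales fasting in breeding grounds; days of presence U(120, 240) for
#' migratory species away from residency, 365 otherwise; abundance
#' lognormal moment-matched to the survey mean and CV.
#'
#' @param n_sim Number of Monte-Carlo draws (>= 2).
#' @param seed Integer root seed for all sub-streams.
#' @param feeding_days_range Days of presence for migratory species in
#'   feeding/breeding grounds.
#' @param release_rate_range General nutrient release-rate range.
#' @param breeding_np_release_range N/P release-rate range for migratory
#'   baleen whales in breeding grounds (urine only).
#' @param bm_sd_fraction SD of body mass as a fraction of its mean.
#' @param beta_sd_fraction SD of beta as a fraction of its base value.
#' @param beta_bounds Truncation bounds for beta.
#' @param ae_mean,ae_sd,ae_bounds Assimilation-efficiency distribution.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_sim = 1e4, seed = 1L,
                              feeding_days_range = c(120, 240),
                              release_rate_range = c(0.7, 0.9),
                              breeding_np_release_range = c(0.2, 0.4),
                              bm_sd_fraction = 0.2,
                              beta_sd_fraction = 0.2,
                              beta_bounds = c(1, 5),
                              ae_mean = 0.85, ae_sd = 0.05,
                              ae_bounds = c(0.8, 0.95)) {
  if (n_sim < 2) stop("n_sim must be >= 2")
  for (rng in list(feeding_days_range, release_rate_range,
                   breeding_np_release_range, beta_bounds, ae_bounds)) {
    if (length(rng) != 2 || rng[1] > rng[2]) {
      stop("ranges must be ordered pairs (lower <= upper)")
    }
  }
  if (bm_sd_fraction < 0 || bm_sd_fraction >= 1) {
    stop("bm_sd_fraction must be in [0, 1)")
  }
  if (beta_sd_fraction < 0 || beta_sd_fraction >= 1) {
    stop("beta_sd_fraction must be in [0, 1)")
  }
  structure(
    list(n_sim = as.integer(n_sim), seed = as.integer(seed),
         feeding_days_range = feeding_days_range,
         release_rate_range = release_rate_range,
         breeding_np_release_range = breeding_np_release_range,
         bm_sd_fraction = bm_sd_fraction,
         beta_sd_fraction = beta_sd_fraction,
         beta_bounds = beta_bounds,
         ae_mean = ae_mean, ae_sd = ae_sd, ae_bounds = ae_bounds),
    class = "simulation_config"
  )
}

#' Read / write a simulation configuration as YAML
#'
#' @param path File path.
#' @return For `read_config`, a `simulation_config`; for `write_config`,
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(simulation_config, raw)
}

#' @rdname read_config
#' @param config A `simulation_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Sample a truncated normal by inverse-CDF
#'
#' Draws are mapped from uniforms on the truncated quantile range, so the
#' support is respected exactly and sampling is deterministic given the
#' stream (no rejection loop). A zero `sd` returns the (clamped) mean.
#'
#' @param n Number of draws.
#' @param mean,sd Location and scale of the parent normal.
#' @param lower,upper Truncation bounds.
#' @param seed Optional sub-stream seed (see [with_stream()]).
#' @return Numeric vector of `n` draws strictly inside `[lower, upper]`.
#' @export
sample_truncated_normal <- function(n, mean, sd, lower = -Inf, upper = Inf,
                                    seed = NULL) {
  if (lower >= upper) stop("lower must be < upper")
  if (sd < 0) stop("sd must be >= 0")
  if (sd == 0) {
    return(rep(min(max(mean, lower), upper), n))
  }
  with_stream(seed, {
    plo <- stats::pnorm(lower, mean, sd)
    phi <- stats::pnorm(upper, mean, sd)
    u <- stats::runif(n, plo, phi)
    stats::qnorm(u, mean, sd)
  })
}

#' Lognormal parameters from a mean and coefficient of variation
#'
#' Moment matching: `mu = log(mean / sqrt(1 + cv^2))`,
#' `sigma = sqrt(log(1 + cv^2))`, so that `exp(mu + sigma^2/2) = mean` and
#' the lognormal CV equals `cv` exactly.
#'
#' @param mean_a Target mean (> 0).
#' @param cv Target coefficient of variation (>= 0).
#' @return Named numeric vector `c(mu =, sigma =)`.
#' @export
lognormal_params_from_mean_cv <- function(mean_a, cv) {
  if (mean_a <= 0) stop("mean_a must be > 0")
  if (cv < 0) stop("cv must be >= 0")
  c(mu = log(mean_a / sqrt(1 + cv^2)), sigma = sqrt(log(1 + cv^2)))
}

#' Sample population abundance draws from a survey mean and CV
#'
#' Lognormal with moment-matched parameters; a zero mean yields all-zero
#' draws (species absent), a zero CV a point mass at the mean.
#'
#' @param n Number of draws.
#' @param mean_a Survey mean abundance (>= 0).
#' @param cv Survey coefficient of variation (>= 0).
#' @param seed Optional sub-stream seed.
#' @return Numeric vector of `n` non-negative draws.
#' @export
sample_abundance <- function(n, mean_a, cv, seed = NULL) {
  if (mean_a < 0) stop("mean_a must be >= 0")
  if (mean_a == 0) return(rep(0, n))
  if (cv == 0) return(rep(mean_a, n))
  p <- lognormal_params_from_mean_cv(mean_a, cv)
  with_stream(seed, stats::rlnorm(n, p[["mu"]], p[["sigma"]]))
}

#' Sample per-nutrient release rates for one species in one ground context
#'
#' Migratory baleen whales fast in their breeding grounds and only urinate
#' there: N and P release follows U(0.2, 0.4) and trace-nutrient release is
#' exactly 0. In every other context all eight nutrients follow U(0.7, 0.9).
#'
#' @param n Number of draws.
#' @param species One-row species record (list or data.frame row) with
#'   fields `taxon` and `migratory`.
#' @param ground Context of the area for this species: `"feeding"`,
#'   `"breeding"` or `"resident"`.
#' @param config A [simulation_config()].
#' @param seed Optional sub-stream seed.
#' @return `n` x 8 matrix of release rates, columns named by nutrient.
#' @export
sample_release_rates <- function(n, species, ground,
                                 config = simulation_config(), seed = NULL) {
  ground <- match.arg(ground, c("feeding", "breeding", "resident"))
  out <- matrix(0, n, length(NUTRIENTS), dimnames = list(NULL, NUTRIENTS))
  breeding_faster <- isTRUE(as.logical(species$migratory)) &&
    identical(as.character(species$taxon), "baleen_whale") &&
    ground == "breeding"
  with_stream(seed, {
    if (breeding_faster) {
      rng <- config$breeding_np_release_range
      for (nm in MAJOR_NUTRIENTS) out[, nm] <- stats::runif(n, rng[1], rng[2])
      # trace nutrients stay exactly 0: negligible in urine
    } else {
      rng <- config$release_rate_range
      for (nm in NUTRIENTS) out[, nm] <- stats::runif(n, rng[1], rng[2])
    }
    out
  })
}

#' Sample days of presence for one species in one ground context
#'
#' Migratory species spend four to eight months (U(120, 240) days) in both
#' their feeding and breeding grounds; everyone else is present year-round
#' (constant 365).
#'
#' @inheritParams sample_release_rates
#' @return Numeric vector of `n` draws of t, days.
#' @export
sample_days_present <- function(n, species, ground,
                                config = simulation_config(), seed = NULL) {
  ground <- match.arg(ground, c("feeding", "breeding", "resident"))
  if (isTRUE(as.logical(species$migratory)) && ground != "resident") {
    rng <- config$feeding_days_range
    with_stream(seed, stats::runif(n, rng[1], rng[2]))
  } else {
    rep(365, n)
  }
}

#' Combine survey-block abundance estimates into one area estimate
#'
#' Means add; assuming independent block errors, the combined CV is
#' `sqrt(sum((cv_i * mean_i)^2)) / sum(mean_i)`.
#'
#' @param means Block mean abundances (>= 0).
#' @param cvs Block coefficients of variation (>= 0), same length.
#' @return List with `mean` and `cv`; all-zero means give `(0, 0)` with a
#'   warning.
#' @export
aggregate_abundance_blocks <- function(means, cvs) {
  if (length(means) < 1 || length(means) != length(cvs)) {
    stop("means and cvs must be non-empty and of equal length")
  }
  if (any(means < 0) || any(cvs < 0)) stop("means and cvs must be >= 0")
  total <- sum(means)
  if (total == 0) {
    warning("all block means are zero; CV undefined, returning (0, 0)")
    return(list(mean = 0, cv = 0))
  }
  list(mean = total, cv = sqrt(sum((cvs * means)^2)) / total)
}

#' Build aligned Monte-Carlo parameter draws for one species x area x habitat
#'
#' Samples `BM ~ N(mean, 0.2 mean)` (truncated just above 0),
#' `beta ~ truncN(base, 0.2 base, 1, 5)`, `AE ~ truncN(0.85, 0.05, 0.8,
#' 0.95)`, abundance lognormal from the survey mean and CV, release rates
#' and days of presence per the ground-context rules, and attaches the
#' species' diet draws of E and x. Every parameter uses its own named
#' sub-stream derived from `config$seed` and (species, area, habitat), so
#' draws are reproducible and invariant to what else is simulated.
#'
#' @param species One-row species record with `species_id`, `taxon`,
#'   `mean_body_mass`, `beta_base`, `migratory`.
#' @param abundance One-row abundance record with `area_id`, `habitat`,
#'   `mean_abundance`, `cv`.
#' @param ground Ground context of the area for this species.
#' @param config A [simulation_config()].
#' @param diet_draws The species' [diet_mixture()] output (`energy` vector
#'   of length `n_sim`, `x` matrix `n_sim` x 8).
#' @return List of class `parameter_draws` with aligned fields
#'   `bm`, `beta`, `ae`, `e`, `x`, `r`, `t`, `a`.
#' @export
build_parameter_draws <- function(species, abundance, ground, config,
                                  diet_draws) {
  if (is.null(diet_draws) || is.null(diet_draws$energy)) {
    stop("diet_draws missing for species ", species$species_id)
  }
  n <- config$n_sim
  if (length(diet_draws$energy) != n || nrow(diet_draws$x) != n) {
    stop("diet draws length does not match n_sim")
  }
  key <- function(param) {
    substream_seed(config$seed, species$species_id, abundance$area_id,
                   abundance$habitat, param)
  }
  bm_mean <- species$mean_body_mass
  beta_base <- species$beta_base
  structure(list(
    species_id = species$species_id,
    area_id = abundance$area_id,
    habitat = abundance$habitat,
    n_sim = n,
    bm = sample_truncated_normal(n, bm_mean, config$bm_sd_fraction * bm_mean,
                                 lower = 1e-6 * bm_mean, upper = Inf,
                                 seed = key("bm")),
    beta = sample_truncated_normal(n, beta_base,
                                   config$beta_sd_fraction * beta_base,
                                   config$beta_bounds[1],
                                   config$beta_bounds[2],
                                   seed = key("beta")),
    ae = sample_truncated_normal(n, config$ae_mean, config$ae_sd,
                                 config$ae_bounds[1], config$ae_bounds[2],
                                 seed = key("ae")),
    e = diet_draws$energy,
    x = diet_draws$x,
    r = sample_release_rates(n, species, ground, config, seed = key("r")),
    t = sample_days_present(n, species, ground, config, seed = key("t")),
    a = sample_abundance(n, abundance$mean_abundance, abundance$cv,
                         seed = key("a"))
  ), class = "parameter_draws")
}
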