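# Diet composition: prey-group draws of energy density and nutrient
# concentrations, mixed into species-level E and x_n by diet weights.

DIET_VARS <- c("energy", NUTRIENTS)

#' Silverman's rule-of-thumb bandwidth
#'
#' `0.9 * min(sd, IQR/1.34) * n^(-1/5)`; returns 0 for samples with no
#' spread (no smoothing is added to constant data, keeping degenerate
#' fixtures exact).
#'
#' @param x Numeric sample.
#' @return Bandwidth (>= 0).
#' @export
silverman_bw <- function(x) {
  n <- length(x)
  if (n < 2) return(0)
  s <- stats::sd(x)
  iqr <- stats::IQR(x) / 1.34
  spread <- if (iqr > 0) min(s, iqr) else s
  0.9 * spread * n^(-1 / 5)
}

#' Smoothed bootstrap of one prey group's composition samples
#'
#' Whole analytical sample records are resampled with replacement (so
#' between-variable correlation within a sample is preserved), then
#' per-variable Gaussian kernel noise with Silverman's bandwidth is added;
#' draws are reflected at 0 so concentrations stay non-negative while the
#' sample mean is preserved better than by clipping.
#'
#' @param samples data.frame of composition samples with columns `energy`
#'   and the eight nutrients (extra columns ignored); >= 2 rows.
#' @param n Number of draws.
#' @param seed Optional sub-stream seed.
#' @param bandwidth Optional named bandwidth override per variable (mainly
#'   for the degenerate `bandwidth = 0` limit in validation).
#' @return List with `energy` (length `n`) and `x` (`n` x 8 matrix).
#' @export
bootstrap_prey_group <- function(samples, n, seed = NULL, bandwidth = NULL) {
  if (is.null(samples) || nrow(samples) == 0) {
    stop("no composition samples supplied")
  }
  if (nrow(samples) < 2) {
    stop("smoothed bootstrap needs >= 2 samples; ",
         "use zooplankton_special_case for single-sample groups")
  }
  miss <- setdiff(DIET_VARS, names(samples))
  if (length(miss)) stop("missing composition columns: ",
                         paste(miss, collapse = ", "))
  m <- as.matrix(samples[DIET_VARS])
  if (any(m < 0)) stop("composition values must be >= 0")
  if (any(m[, "energy"] <= 0)) stop("energy density must be > 0")
  with_stream(seed, {
    idx <- sample.int(nrow(m), n, replace = TRUE)
    draws <- m[idx, , drop = FALSE]
    for (v in DIET_VARS) {
      bw <- if (!is.null(bandwidth)) {
        if (length(bandwidth) == 1 && is.null(names(bandwidth))) bandwidth
        else bandwidth[[v]]
      } else {
        silverman_bw(m[, v])
      }
      if (bw > 0) draws[, v] <- abs(draws[, v] + stats::rnorm(n, 0, bw))
    }
    list(energy = draws[, "energy"],
         x = draws[, NUTRIENTS, drop = FALSE])
  })
}

#' Single-sample prey group: parametric variation around the one analysis
#'
#' When a prey group (zooplankton in the study data) has a single
#' analytical sample, variation is simulated as normal around the sample
#' value with a standard deviation of 20% of the value for energy and the
#' major nutrients (N, P) and 40% for the trace nutrients, reflected at 0.
#'
#' @param sample One-row data.frame (or named list) with `energy` and the
#'   eight nutrient columns.
#' @param n Number of draws.
#' @param seed Optional sub-stream seed.
#' @return List with `energy` (length `n`) and `x` (`n` x 8 matrix).
#' @export
zooplankton_special_case <- function(sample, n, seed = NULL) {
  vals <- vapply(DIET_VARS, function(v) as.numeric(sample[[v]]), 0)
  if (any(is.na(vals)) || any(vals < 0)) {
    stop("sample must provide non-negative energy and nutrient values")
  }
  sd_frac <- c(energy = 0.2,
               stats::setNames(ifelse(NUTRIENTS %in% MAJOR_NUTRIENTS,
                                      0.2, 0.4), NUTRIENTS))
  with_stream(seed, {
    draws <- vapply(DIET_VARS, function(v) {
      s <- sd_frac[[v]] * vals[[v]]
      if (s == 0) rep(vals[[v]], n) else abs(stats::rnorm(n, vals[[v]], s))
    }, numeric(n))
    list(energy = draws[, "energy"],
         x = draws[, NUTRIENTS, drop = FALSE])
  })
}

#' Draw composition vectors for every prey group
#'
#' Groups with two or more samples go through the smoothed bootstrap;
#' single-sample groups through the parametric special case. One pool of
#' draws is produced per group and shared by all species (mirroring a
#' single artificially extended composition data set per group).
#'
#' @param prey_samples data.frame with a `group` column plus `energy` and
#'   nutrient columns, one row per analytical sample.
#' @param n Number of draws per group.
#' @param seed Root seed; each group gets a named sub-stream.
#' @return Named list: group -> list(`energy`, `x`).
#' @export
build_prey_group_draws <- function(prey_samples, n, seed = NULL) {
  groups <- unique(as.character(prey_samples$group))
  out <- lapply(groups, function(g) {
    rows <- prey_samples[prey_samples$group == g, , drop = FALSE]
    s <- if (is.null(seed)) NULL else substream_seed(seed, "prey", g)
    if (nrow(rows) >= 2) {
      bootstrap_prey_group(rows, n, seed = s)
    } else {
      zooplankton_special_case(rows[1, ], n, seed = s)
    }
  })
  stats::setNames(out, groups)
}

#' Mix prey-group draws into species-level diet draws
#'
#' Diet-weighted sums, per draw index:
#' `E = sum_pg W_pg * E_pg` and `x_n = sum_pg W_pg * x_{n,pg}`.
#'
#' @param weights Named numeric vector of diet weights (fractions of
#'   ingested biomass per prey group), summing to 1 within 1e-9.
#' @param group_draws Named list from [build_prey_group_draws()]; must
#'   cover every positively weighted group, all with equal draw counts.
#' @return List of class `diet_draws` with `energy` and `x`.
#' @export
diet_mixture <- function(weights, group_draws) {
  weights <- weights[weights != 0]
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("diet weights must sum to 1 (got ", sum(weights), ")")
  }
  miss <- setdiff(names(weights), names(group_draws))
  if (length(miss)) {
    stop("no composition draws for prey group(s): ",
         paste(miss, collapse = ", "))
  }
  lens <- vapply(group_draws[names(weights)],
                 function(g) length(g$energy), 0L)
  if (length(unique(lens)) != 1) stop("group draws have unequal lengths")
  n <- lens[[1]]
  energy <- numeric(n)
  x <- matrix(0, n, length(NUTRIENTS), dimnames = list(NULL, NUTRIENTS))
  for (g in names(weights)) {
    energy <- energy + weights[[g]] * group_draws[[g]]$energy
    x <- x + weights[[g]] * group_draws[[g]]$x
  }
  structure(list(energy = energy, x = x), class = "diet_draws")
}
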