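# Draw-based significance testing, waste stoichiometry, PCA, and
# productivity regressions.

#' Unilateral binary-relation test between two draw vectors
#'
#' With full Monte-Carlo output distributions in hand, classical tests do
#' not apply; instead the fraction of paired draws in which group 1 exceeds
#' group 2 is computed (ties counted 0.5, preserving antisymmetry exactly).
#' The difference is called significant when that fraction is >= 0.95 or
#' <= 0.05, and the reported p-value is `min(fraction, 1 - fraction)`
#' (floored at `1/n`: a Monte-Carlo p of exactly 0 is not defensible).
#' A fraction of 0.99, for instance, reports p = 0.01 in favour of group 1.
#'
#' No multiple-testing correction is applied anywhere in the pipeline.
#'
#' @param draws_a,draws_b Draw vectors. Index-paired comparison (the
#'   default) requires equal lengths.
#' @param all_pairs If `TRUE`, computes the all-vs-all fraction (the
#'   Mann-Whitney statistic scaled to `[0, 1]`) instead of pairing draws by
#'   index; lengths may then differ.
#' @return List of class `comparison_result`: `fraction_greater`, `p`,
#'   `direction` (`"group1"`, `"group2"` or `"none"`), `significant`, `n`.
#' @export
binary_relation_test <- function(draws_a, draws_b, all_pairs = FALSE) {
  na <- length(draws_a); nb <- length(draws_b)
  if (!all_pairs) {
    if (na != nb) stop("draw vectors must have equal length when paired")
    frac <- (sum(draws_a > draws_b) + 0.5 * sum(draws_a == draws_b)) / na
    n <- na
  } else {
    r <- rank(c(draws_a, draws_b))  # midranks count ties as 0.5
    u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
    frac <- u / (na * nb)
    n <- na * nb
  }
  p <- max(min(frac, 1 - frac), 1 / n)
  structure(list(
    fraction_greater = frac,
    p = p,
    direction = if (frac > 0.5) "group1" else if (frac < 0.5) "group2"
                else "none",
    significant = frac >= 0.95 || frac <= 0.05,
    n = n
  ), class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf(
    "binary relation: fraction(group1 > group2) = %.4f, p = %.4g%s\n",
    x$fraction_greater, x$p,
    if (x$significant) sprintf(" (significant, %s greater)", x$direction)
    else " (not significant)"))
  invisible(x)
}

#' Waste stoichiometry: nutrient released per kilogram of food ingested
#'
#' Per draw and nutrient, `x_n * r_n` gives the milligrams of nutrient
#' released per kg of food ingested, independent of how much the species
#' eats or how abundant it is; summarized by the 2.5% quantile, mean and
#' 97.5% quantile.
#'
#' @param diet_draws A `diet_draws` object (or any list with an `x`
#'   draws-by-nutrient matrix).
#' @param release_rate_draws Aligned release-rate matrix (draws x
#'   nutrients).
#' @param species_id Optional label.
#' @return List of class `stoichiometry_profile` with `draws`
#'   (draws x nutrients, mg/kg ingested) and `summary` (data.frame with
#'   `nutrient`, `q2.5`, `mean`, `q97.5`).
#' @export
stoichiometry_profile <- function(diet_draws, release_rate_draws,
                                  species_id = NA_character_) {
  x <- as.matrix(diet_draws$x)
  r <- as.matrix(release_rate_draws)
  if (!all(dim(x) == dim(r))) stop("diet and release-rate draws not aligned")
  d <- x * r
  q <- apply(d, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  structure(list(
    species_id = species_id,
    draws = d,
    summary = data.frame(nutrient = colnames(d),
                         q2.5 = q[1, ], mean = colMeans(d), q97.5 = q[2, ],
                         row.names = NULL, stringsAsFactors = FALSE)
  ), class = "stoichiometry_profile")
}

#' Assemble the species x (quantile, nutrient) stoichiometry matrix
#'
#' Binds per-species summaries into the 24-column matrix (q2.5, mean,
#' q97.5 for each of the eight nutrients) and normalizes each nutrient's
#' three columns jointly by the nutrient's maximum across all entries, so
#' species are compared on relative composition.
#'
#' @param profiles Named list of `stoichiometry_profile`s (names = species).
#' @return Numeric matrix, species x 24, columns like `"N_mean"`.
#' @export
stoichiometry_matrix <- function(profiles) {
  rows <- t(vapply(profiles, function(p) {
    s <- p$summary
    stats::setNames(c(rbind(s$q2.5, s$mean, s$q97.5)),
                    c(rbind(paste0(s$nutrient, "_q2.5"),
                            paste0(s$nutrient, "_mean"),
                            paste0(s$nutrient, "_q97.5"))))
  }, numeric(3 * length(NUTRIENTS))))
  # normalize per nutrient (all three summary columns of a nutrient share
  # one scale) so trace and major nutrients are comparable
  for (nm in NUTRIENTS) {
    cols <- grep(paste0("^", nm, "_"), colnames(rows))
    mx <- max(rows[, cols])
    if (mx > 0) rows[, cols] <- rows[, cols] / mx
  }
  rows
}

#' PCA of species waste-stoichiometry profiles
#'
#' Columns are centred and scaled to unit variance; constant columns are
#' dropped with a warning. Variable cos2 on the first two components flags
#' which variables the biplot would display (`cos2 > 0.5` by convention);
#' all loadings are retained regardless.
#'
#' @param profile_matrix Species x variable matrix (e.g. from
#'   [stoichiometry_matrix()]); >= 3 rows.
#' @param cos2_cutoff Reporting threshold on first-two-component cos2.
#' @return List of class `stoichiometry_pca`: `scores`, `loadings`,
#'   `sdev`, `eig` (component variances), `var_coords` (variable
#'   coordinates), `cos2` (on PC1-2), `displayed` (logical per variable),
#'   `dropped` (names of constant columns).
#' @export
pca_stoichiometry <- function(profile_matrix, cos2_cutoff = 0.5) {
  m <- as.matrix(profile_matrix)
  if (nrow(m) < 3) stop("PCA needs at least 3 species")
  sds <- apply(m, 2, stats::sd)
  dropped <- colnames(m)[sds == 0]
  if (length(dropped)) {
    warning("dropping constant column(s): ", paste(dropped, collapse = ", "))
    m <- m[, sds > 0, drop = FALSE]
  }
  fit <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  coords <- fit$rotation %*% diag(fit$sdev, length(fit$sdev))
  colnames(coords) <- colnames(fit$rotation)
  cos2 <- rowSums(coords[, 1:2, drop = FALSE]^2) /
    rowSums(coords^2)
  structure(list(
    scores = fit$x,
    loadings = fit$rotation,
    sdev = fit$sdev,
    eig = fit$sdev^2,
    var_coords = coords,
    cos2 = cos2,
    displayed = cos2 > cos2_cutoff,
    dropped = dropped
  ), class = "stoichiometry_pca")
}

#' Linear regression of nutrient release on a productivity covariate
#'
#' Ordinary least squares of per-area mean release (normalized per
#' nutrient) on mean surface chlorophyll or SST, one fit per nutrient.
#' Areas whose chlorophyll estimate is flagged as an outlier (e.g. driven
#' by river-plume turbidity) are excluded from chlorophyll fits only.
#'
#' @param release_means Matrix, areas x nutrients, of normalized mean
#'   release (rownames = area ids).
#' @param covariates data.frame with `area_id`, `mean_chlorophyll`,
#'   `mean_sst` and logical `chlorophyll_outlier`.
#' @param covariate `"chlorophyll"` or `"sst"`.
#' @return data.frame with one row per nutrient: `nutrient`, `covariate`,
#'   `slope`, `r_squared`, `p_value`, `n_areas`.
#' @export
productivity_regression <- function(release_means, covariates,
                                    covariate = c("chlorophyll", "sst")) {
  covariate <- match.arg(covariate)
  release_means <- as.matrix(release_means)
  covariates <- unique(covariates[, intersect(
    c("area_id", "mean_chlorophyll", "mean_sst", "chlorophyll_outlier"),
    names(covariates))])
  rownames(covariates) <- covariates$area_id
  areas <- intersect(rownames(release_means), covariates$area_id)
  if (covariate == "chlorophyll" &&
      "chlorophyll_outlier" %in% names(covariates)) {
    areas <- areas[!as.logical(covariates[areas, "chlorophyll_outlier"])]
  }
  if (length(areas) < 3) stop("need at least 3 areas after exclusions")
  xcol <- if (covariate == "chlorophyll") "mean_chlorophyll" else "mean_sst"
  xv <- covariates[areas, xcol]
  out <- lapply(colnames(release_means), function(nm) {
    fit <- stats::lm(release_means[areas, nm] ~ xv)
    sm <- summary(fit)
    data.frame(nutrient = nm, covariate = covariate,
               slope = unname(stats::coef(fit)[2]),
               r_squared = sm$r.squared,
               p_value = sm$coefficients[2, 4],
               n_areas = length(areas), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
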