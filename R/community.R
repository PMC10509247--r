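# Community-level aggregation of species release draws: totals, densities,
# fold-changes versus a baseline area, taxa contributions, normalization.

#' Sum species release draws into community draws
#'
#' @param release_list List of aligned release matrices (draws x nutrients),
#'   one per species.
#' @return A matrix of the per-draw community totals.
#' @export
community_totals <- function(release_list) {
  if (length(release_list) == 0) stop("empty community")
  dims <- vapply(release_list, function(m) dim(as.matrix(m)), integer(2))
  if (length(unique(dims[1, ])) != 1 || length(unique(dims[2, ])) != 1) {
    stop("release draws have mismatched dimensions")
  }
  Reduce(`+`, lapply(release_list, as.matrix))
}

#' Fold-change of area nutrient-release densities versus a baseline area
#'
#' Ratio of mean release densities, area over baseline, per nutrient. The
#' baseline area's fold-change is exactly 1 for every nutrient.
#'
#' @param density_means Matrix of mean densities, areas x nutrients, with
#'   rownames identifying areas.
#' @param baseline Baseline area id (a rowname).
#' @return Matrix of fold-change ratios, same shape; nutrients whose
#'   baseline mean is zero are `NA`.
#' @export
fold_change <- function(density_means, baseline) {
  density_means <- as.matrix(density_means)
  if (!baseline %in% rownames(density_means)) {
    stop("baseline area '", baseline, "' not found")
  }
  base <- density_means[baseline, ]
  out <- sweep(density_means, 2, base, `/`)
  out[, base == 0] <- NA_real_
  out
}

#' Percentage contribution of each cetacean taxon to community release
#'
#' Per draw and nutrient, each taxon's share is its summed release divided
#' by the community total, in percent; the headline summary is the mean of
#' per-draw shares. Draws with a zero community total are excluded from the
#' mean and counted.
#'
#' @param taxon_draws Named list: taxon -> aligned release matrix
#'   (draws x nutrients) already summed over that taxon's species.
#' @return List with `mean` (taxon x nutrient matrix of mean percentage
#'   shares), `draws` (per-taxon share matrices, %), `share_of_means`
#'   (the alternative summary: share of summed means, %), and
#'   `n_excluded` (per-nutrient count of zero-total draws).
#' @export
taxa_contributions <- function(taxon_draws) {
  if (length(taxon_draws) == 0) stop("no taxa supplied")
  total <- community_totals(taxon_draws)
  share_draws <- lapply(taxon_draws, function(m) {
    # divide before scaling so a taxon equal to the whole community gets
    # a share of exactly 100
    s <- 100 * (as.matrix(m) / total)
    s[total == 0] <- NA_real_
    s
  })
  mean_tab <- t(vapply(share_draws, function(s) colMeans(s, na.rm = TRUE),
                       numeric(ncol(total))))
  som <- t(vapply(taxon_draws, function(m) {
    100 * colMeans(as.matrix(m)) / colMeans(total)
  }, numeric(ncol(total))))
  rownames(mean_tab) <- rownames(som) <- names(taxon_draws)
  list(mean = mean_tab, draws = share_draws, share_of_means = som,
       n_excluded = colSums(total == 0))
}

#' Normalize a value table per nutrient by its column maximum
#'
#' Each nutrient column is divided by its maximum across entities (areas or
#' species), mapping values into (0, 1] with the largest entity at exactly
#' 1; zeros and ratios are preserved and ordering is unchanged.
#'
#' @param values Matrix or data.frame, entities x nutrients, non-negative.
#' @return Matrix of normalized values.
#' @export
normalize_per_nutrient <- function(values) {
  values <- as.matrix(values)
  if (nrow(values) < 2) stop("need at least two entities to normalize")
  if (any(values < 0)) stop("values must be non-negative")
  mx <- apply(values, 2, max)
  if (any(mx == 0)) {
    stop("all-zero nutrient column(s): ",
         paste(colnames(values)[mx == 0], collapse = ", "))
  }
  sweep(values, 2, mx, `/`)
}

#' Neritic vs oceanic difference in release density for one area
#'
#' For each nutrient the two habitat means are normalized by their maximum
#' (per nutrient, per area) and the difference `oceanic - neritic` is
#' reported on that [-1, 1] scale: negative values mean greater release in
#' neritic waters. Significance comes from the draw-based binary-relation
#' test on the density draws themselves.
#'
#' @param neritic_draws,oceanic_draws Aligned density draw matrices
#'   (draws x nutrients) for the two habitats of one area.
#' @return data.frame with columns `nutrient`, `difference`,
#'   `fraction_greater` (oceanic > neritic), `p`, `significant`.
#' @export
habitat_difference <- function(neritic_draws, oceanic_draws) {
  neritic_draws <- as.matrix(neritic_draws)
  oceanic_draws <- as.matrix(oceanic_draws)
  if (!all(dim(neritic_draws) == dim(oceanic_draws))) {
    stop("habitat draws must be aligned")
  }
  nut <- colnames(neritic_draws)
  res <- lapply(seq_along(nut), function(j) {
    mn <- mean(neritic_draws[, j])
    mo <- mean(oceanic_draws[, j])
    mx <- max(mn, mo)
    d <- if (mx == 0) 0 else (mo - mn) / mx
    bt <- binary_relation_test(oceanic_draws[, j], neritic_draws[, j])
    data.frame(nutrient = nut[j], difference = d,
               fraction_greater = bt$fraction_greater, p = bt$p,
               significant = bt$significant, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
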