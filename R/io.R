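# Input loading/validation, results writing, and the end-to-end pipeline.

.require_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(what, ": missing column(s) ", paste(miss, collapse = ", "))
  }
}

#' Validate (and lightly repair) a study input bundle
#'
#' Checks schemas and cross-references: every species has diet weights
#' over known prey groups (renormalized when off by < 1e-6, rejected
#' otherwise), every abundance row references a known species and a known
#' area x habitat, no duplicated abundance cells, exactly one baseline
#' area, and all numeric invariants.
#'
#' @param inputs List with data.frames `species`, `diet_weights`,
#'   `prey_samples`, `abundance`, `areas`.
#' @return The validated bundle, classed `study_inputs`.
#' @export
validate_study_inputs <- function(inputs) {
  sp <- inputs$species
  .require_cols(sp, c("species_id", "taxon", "mean_body_mass", "beta_base",
                      "lunge_feeder", "migratory"), "species")
  if (anyDuplicated(sp$species_id)) stop("species: duplicated species_id")
  if (!all(sp$taxon %in% TAXA)) {
    stop("species: unknown taxon value(s): ",
         paste(setdiff(sp$taxon, TAXA), collapse = ", "))
  }
  if (any(sp$mean_body_mass <= 0)) stop("species: mean_body_mass must be > 0")
  if (any(sp$beta_base < 2 | sp$beta_base > 4.5)) {
    stop("species: beta_base must be in [2, 4.5]")
  }

  dw <- inputs$diet_weights
  .require_cols(dw, c("species_id", "group", "weight"), "diet_weights")
  ps <- inputs$prey_samples
  .require_cols(ps, c("group", "energy", NUTRIENTS), "prey_samples")
  if (any(ps$energy <= 0)) stop("prey_samples: energy must be > 0")
  if (any(as.matrix(ps[NUTRIENTS]) < 0)) {
    stop("prey_samples: nutrient concentrations must be >= 0")
  }
  bad_grp <- setdiff(dw$group[dw$weight > 0], unique(ps$group))
  if (length(bad_grp)) {
    stop("diet_weights: prey group(s) without composition samples: ",
         paste(bad_grp, collapse = ", "))
  }
  for (id in sp$species_id) {
    w <- dw$weight[dw$species_id == id]
    if (length(w) == 0) stop("diet_weights: no diet for species ", id)
    s <- sum(w)
    if (abs(s - 1) > 1e-6) {
      stop("diet_weights: weights for species ", id, " sum to ", s)
    }
    if (abs(s - 1) > 0) {
      dw$weight[dw$species_id == id] <- w / s
    }
  }
  inputs$diet_weights <- dw

  ar <- inputs$areas
  .require_cols(ar, c("area_id", "habitat", "surface_km2", "ground_status",
                      "mean_chlorophyll", "mean_sst", "chlorophyll_outlier",
                      "is_baseline"), "areas")
  if (any(ar$surface_km2 <= 0)) stop("areas: surface_km2 must be > 0")
  if (!all(ar$ground_status %in% c("feeding", "breeding", "resident"))) {
    stop("areas: ground_status must be feeding/breeding/resident")
  }
  if (anyDuplicated(ar[c("area_id", "habitat")])) {
    stop("areas: duplicated (area_id, habitat) row")
  }
  baseline <- unique(ar$area_id[as.logical(ar$is_baseline)])
  if (length(baseline) != 1) {
    stop("areas: exactly one baseline area required, found ",
         length(baseline))
  }

  ab <- inputs$abundance
  .require_cols(ab, c("area_id", "habitat", "species_id", "mean_abundance",
                      "cv"), "abundance")
  if (any(ab$mean_abundance < 0) || any(ab$cv < 0)) {
    stop("abundance: mean_abundance and cv must be >= 0")
  }
  if (anyDuplicated(ab[c("area_id", "habitat", "species_id")])) {
    stop("abundance: duplicated (area_id, habitat, species_id) row")
  }
  dangling <- setdiff(ab$species_id, sp$species_id)
  if (length(dangling)) {
    stop("abundance: unknown species_id: ", paste(dangling, collapse = ", "))
  }
  key_ab <- paste(ab$area_id, ab$habitat)
  key_ar <- paste(ar$area_id, ar$habitat)
  if (!all(key_ab %in% key_ar)) {
    stop("abundance: unknown (area, habitat): ",
         paste(unique(setdiff(key_ab, key_ar)), collapse = ", "))
  }
  structure(inputs, class = "study_inputs")
}

#' Load study inputs from CSV files
#'
#' @param dir Directory containing `species.csv`, `diet_weights.csv`,
#'   `prey_samples.csv`, `abundance.csv`, `areas.csv` (as written by
#'   [write_study_inputs()]); alternatively pass named `paths`.
#' @param paths Optional named list/vector of the five file paths.
#' @return A validated `study_inputs` bundle.
#' @export
load_study_inputs <- function(dir = NULL, paths = NULL) {
  parts <- c("species", "diet_weights", "prey_samples", "abundance", "areas")
  if (is.null(paths)) {
    paths <- stats::setNames(file.path(dir, paste0(parts, ".csv")), parts)
  }
  missing <- !file.exists(unlist(paths[parts]))
  if (any(missing)) {
    stop("input file(s) not found: ",
         paste(unlist(paths[parts])[missing], collapse = ", "))
  }
  inputs <- lapply(stats::setNames(parts, parts), function(p) {
    utils::read.csv(paths[[p]], stringsAsFactors = FALSE)
  })
  validate_study_inputs(inputs)
}

#' Write a study input bundle as CSV files
#'
#' @param inputs A `study_inputs` bundle.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_inputs <- function(inputs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (p in c("species", "diet_weights", "prey_samples", "abundance",
              "areas")) {
    utils::write.csv(inputs[[p]], file.path(dir, paste0(p, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Species-level diet draws from shared prey-group draw pools
#'
#' @param inputs A `study_inputs` bundle.
#' @param group_draws Output of [build_prey_group_draws()].
#' @return Named list species_id -> `diet_draws`.
#' @export
species_diet_draws <- function(inputs, group_draws) {
  dw <- inputs$diet_weights
  out <- lapply(inputs$species$species_id, function(id) {
    d <- dw[dw$species_id == id & dw$weight > 0, ]
    diet_mixture(stats::setNames(d$weight, d$group), group_draws)
  })
  stats::setNames(out, inputs$species$species_id)
}

.summ <- function(m) {
  q <- apply(m, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  data.frame(nutrient = colnames(m), mean = colMeans(m),
             q2.5 = q[1, ], q97.5 = q[2, ], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Run the full release pipeline on a study input bundle
#'
#' Draws prey-group composition pools, species diet draws and per-cell
#' parameter draws; evaluates the release model; and aggregates to
#' community totals and densities per area x habitat, whole-area fold
#' changes versus the baseline area, taxa contributions, habitat
#' differences, per-species waste stoichiometry with PCA, and
#' productivity regressions. Deterministic given `config$seed`.
#'
#' @param inputs A validated `study_inputs` bundle.
#' @param config A [simulation_config()].
#' @param out_dir Optional directory; when given, tidy result CSVs and a
#'   JSON run manifest are written there.
#' @param keep_draws Keep draw-level community/taxon matrices in the
#'   result (needed for draw-based comparisons; default `TRUE`).
#' @return List of class `cetapump_result`.
#' @export
run_pipeline <- function(inputs, config = simulation_config(),
                         out_dir = NULL, keep_draws = TRUE) {
  inputs <- validate_study_inputs(inputs)
  n <- config$n_sim
  nk <- length(NUTRIENTS)
  sp <- inputs$species
  rownames(sp) <- sp$species_id
  ar <- inputs$areas
  area_ground <- unique(ar[, c("area_id", "ground_status")])
  ground_of <- stats::setNames(area_ground$ground_status,
                               area_ground$area_id)
  surf <- stats::setNames(ar$surface_km2, paste(ar$area_id, ar$habitat))

  group_draws <- build_prey_group_draws(
    inputs$prey_samples, n, seed = substream_seed(config$seed, "prey_pool"))
  diets <- species_diet_draws(inputs, group_draws)

  ab <- inputs$abundance
  cell_keys <- unique(paste(ab$area_id, ab$habitat))
  zero <- function() matrix(0, n, nk, dimnames = list(NULL, NUTRIENTS))
  taxa <- stats::setNames(
    lapply(cell_keys, function(k) {
      stats::setNames(lapply(TAXA, function(t) zero()), TAXA)
    }), cell_keys)
  species_rows <- vector("list", nrow(ab))
  skipped <- character(0)

  for (i in seq_len(nrow(ab))) {
    row <- ab[i, ]
    s <- sp[row$species_id, ]
    ground <- ground_of[[row$area_id]]
    pd <- build_parameter_draws(s, row, ground, config,
                                diets[[row$species_id]])
    q <- compute_annual_release(pd)
    key <- paste(row$area_id, row$habitat)
    taxa[[key]][[s$taxon]] <- taxa[[key]][[s$taxon]] + q
    sm <- .summ(q)
    sm$area_id <- row$area_id; sm$habitat <- row$habitat
    sm$species_id <- row$species_id; sm$taxon <- s$taxon
    species_rows[[i]] <- sm
  }
  species_summary <- do.call(rbind, species_rows)

  # community totals as the sum of per-taxon accumulators, so the
  # taxon/community conservation law holds exactly, draw by draw
  comm <- stats::setNames(lapply(cell_keys, function(k) {
    Reduce(`+`, taxa[[k]])
  }), cell_keys)

  ## per area x habitat totals and densities -------------------------
  cell_df <- do.call(rbind, lapply(cell_keys, function(k) {
    parts <- strsplit(k, " ")[[1]]
    sm <- .summ(comm[[k]])
    sm$area_id <- parts[1]; sm$habitat <- parts[2]
    sm$surface_km2 <- unname(surf[[k]])
    sm$density_mean <- 1000 * sm$mean / sm$surface_km2  # kg/km2/yr
    sm
  }))

  ## whole-area totals (habitats summed) -----------------------------
  area_ids <- unique(ab$area_id)
  whole <- stats::setNames(lapply(area_ids, function(a) {
    ks <- cell_keys[startsWith(cell_keys, paste0(a, " "))]
    Reduce(`+`, comm[ks])
  }), area_ids)
  area_surface <- vapply(area_ids, function(a) {
    sum(ar$surface_km2[ar$area_id == a])
  }, 0)
  area_df <- do.call(rbind, lapply(area_ids, function(a) {
    sm <- .summ(whole[[a]])
    sm$area_id <- a
    sm$surface_km2 <- area_surface[[a]]
    sm$density_mean <- 1000 * sm$mean / sm$surface_km2
    sm
  }))
  density_means <- do.call(rbind, lapply(area_ids, function(a) {
    1000 * colMeans(whole[[a]]) / area_surface[[a]]
  }))
  rownames(density_means) <- area_ids

  baseline <- ar$area_id[as.logical(ar$is_baseline)][1]
  fc <- fold_change(density_means, baseline)

  ## taxa contributions per whole area -------------------------------
  contrib <- lapply(stats::setNames(area_ids, area_ids), function(a) {
    ks <- cell_keys[startsWith(cell_keys, paste0(a, " "))]
    td <- stats::setNames(lapply(TAXA, function(t) {
      Reduce(`+`, lapply(ks, function(k) taxa[[k]][[t]]))
    }), TAXA)
    td <- td[vapply(td, function(m) any(m > 0), TRUE)]
    taxa_contributions(td)
  })
  contrib_df <- do.call(rbind, lapply(area_ids, function(a) {
    m <- contrib[[a]]$mean
    do.call(rbind, lapply(rownames(m), function(t) {
      data.frame(area_id = a, taxon = t, nutrient = colnames(m),
                 contribution_pct = m[t, ], row.names = NULL,
                 stringsAsFactors = FALSE)
    }))
  }))

  ## habitat differences ---------------------------------------------
  hd <- list()
  for (a in area_ids) {
    kn <- paste(a, "neritic"); ko <- paste(a, "oceanic")
    if (kn %in% cell_keys && ko %in% cell_keys) {
      d <- habitat_difference(1000 * comm[[kn]] / surf[[kn]],
                              1000 * comm[[ko]] / surf[[ko]])
      d$area_id <- a
      hd[[a]] <- d
    } else {
      skipped <- c(skipped, paste0("habitat_difference:", a,
                                   " (single habitat)"))
    }
  }
  habitat_diff <- if (length(hd)) do.call(rbind, hd) else NULL

  ## waste stoichiometry + PCA ---------------------------------------
  profiles <- lapply(stats::setNames(sp$species_id, sp$species_id),
    function(id) {
      r <- with_stream(substream_seed(config$seed, id, "stoich"), {
        matrix(stats::runif(n * nk, config$release_rate_range[1],
                            config$release_rate_range[2]),
               n, nk, dimnames = list(NULL, NUTRIENTS))
      })
      p <- stoichiometry_profile(diets[[id]], r, species_id = id)
      p$draws <- NULL  # summaries suffice downstream
      p
    })
  stoich_df <- do.call(rbind, lapply(profiles, function(p) {
    cbind(species_id = p$species_id, p$summary)
  }))
  rownames(stoich_df) <- NULL
  pca <- if (nrow(sp) >= 3) {
    tryCatch(pca_stoichiometry(stoichiometry_matrix(profiles)),
             error = function(e) {
               skipped <<- c(skipped, paste0("pca: ", conditionMessage(e)))
               NULL
             })
  }

  ## productivity regressions ----------------------------------------
  covs <- unique(ar[, c("area_id", "mean_chlorophyll", "mean_sst",
                        "chlorophyll_outlier")])
  regressions <- if (length(area_ids) >= 4) {
    norm_dens <- normalize_per_nutrient(density_means)
    rbind(productivity_regression(norm_dens, covs, "chlorophyll"),
          productivity_regression(norm_dens, covs, "sst"))
  }

  result <- structure(list(
    species_summary = species_summary,
    cell_summary = cell_df,
    area_summary = area_df,
    density_means = density_means,
    fold_change = fc,
    baseline_area = baseline,
    contributions = contrib_df,
    contribution_detail = contrib,
    habitat_differences = habitat_diff,
    stoichiometry = stoich_df,
    stoichiometry_profiles = profiles,
    pca = pca,
    regressions = regressions,
    community_draws = if (keep_draws) comm,
    taxon_draws = if (keep_draws) taxa,
    area_draws = if (keep_draws) whole,
    skipped = skipped,
    config = config
  ), class = "cetapump_result")

  if (!is.null(out_dir)) write_results(result, inputs, out_dir)
  result
}

#' @export
print.cetapump_result <- function(x, ...) {
  cat("cetapump pipeline result\n")
  cat("  areas:", nrow(x$density_means),
      " species:", length(unique(x$species_summary$species_id)),
      " n_sim:", x$config$n_sim, "\n")
  cat("  baseline area:", x$baseline_area, "\n")
  if (length(x$skipped)) {
    cat("  skipped:", paste(x$skipped, collapse = "; "), "\n")
  }
  invisible(x)
}

# Small deterministic content hash (same scheme as substream_seed) used in
# the run manifest.
.content_hash <- function(x) {
  substream_seed(0L, paste(utils::capture.output(utils::str(x)),
                           collapse = "\n"))
}

#' Write pipeline results and a run manifest to a directory
#'
#' @param result A `cetapump_result`.
#' @param inputs The `study_inputs` bundle the result came from.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_results <- function(result, inputs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    if (!is.null(df)) {
      utils::write.csv(df, file.path(dir, paste0(name, ".csv")),
                       row.names = FALSE)
    }
  }
  wr(result$species_summary, "species_release")
  wr(result$cell_summary, "community_release")
  wr(result$area_summary, "area_release")
  fc <- as.data.frame(result$fold_change)
  fc <- cbind(area_id = rownames(fc), fc)
  wr(fc, "fold_change")
  wr(result$contributions, "taxa_contributions")
  wr(result$habitat_differences, "habitat_differences")
  wr(result$stoichiometry, "stoichiometry")
  wr(result$regressions, "regressions")
  manifest <- list(
    package = "cetapump",
    version = as.character(utils::packageVersion("cetapump")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = result$config$seed,
    n_sim = result$config$n_sim,
    config_hash = .content_hash(unclass(result$config)),
    input_checksums = lapply(
      inputs[c("species", "diet_weights", "prey_samples", "abundance",
               "areas")], .content_hash),
    skipped = result$skipped
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Compare release draws between two areas (or habitats) for one nutrient
#'
#' Convenience wrapper around [binary_relation_test()] on whole-area draw
#' vectors kept in a pipeline result (`keep_draws = TRUE`).
#'
#' @param result A `cetapump_result`.
#' @param area_a,area_b Area ids.
#' @param nutrient Nutrient name.
#' @return A `comparison_result`.
#' @export
compare_areas <- function(result, area_a, area_b, nutrient = "N") {
  if (is.null(result$area_draws)) stop("result was run with keep_draws = FALSE")
  binary_relation_test(result$area_draws[[area_a]][, nutrient],
                       result$area_draws[[area_b]][, nutrient])
}
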