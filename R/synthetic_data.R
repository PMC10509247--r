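# Synthetic study generator: complete input bundles with known ground
# truth, emulating the statistical structure the analysis assumes (species
# in three taxa, functional prey groups with multi-sample composition
# profiles, area x habitat abundance estimates with survey CVs, and a
# latent productivity gradient that drives both abundances and the
# chlorophyll / SST covariates).

PREY_GROUPS <- c("zooplankton", "small_pelagic_fish", "mesopelagic_fish",
                 "demersal_fish", "large_pelagic_fish",
                 "muscular_cephalopod", "gelatinous_cephalopod",
                 "benthic_crustacean", "miscellaneous")

# Group-level geometric means of composition (fresh-weight basis):
# energy kJ/kg, nutrients mg/kg. Documentation values in realistic ranges,
# not measurements.
PREY_GROUP_MEANS <- local({
  m <- rbind(
    #            energy     N     P    Fe   Cu   Mn   Se   Zn    Co
    zooplankton        = c(3800, 22000, 4500, 40, 4.0, 3.0, 1.0, 25, 0.10),
    small_pelagic_fish = c(6500, 28000, 6500, 25, 2.0, 1.5, 1.2, 20, 0.05),
    mesopelagic_fish   = c(5500, 26000, 6000, 60, 4.5, 2.0, 1.5, 35, 0.08),
    demersal_fish      = c(4200, 30000, 7000, 15, 1.5, 1.0, 1.0, 18, 0.03),
    large_pelagic_fish = c(6000, 29000, 6800, 30, 2.5, 1.2, 1.8, 22, 0.04),
    muscular_cephalopod   = c(4500, 25000, 5500, 20, 15.0, 1.0, 1.2, 30, 0.06),
    gelatinous_cephalopod = c(3000, 20000, 4000, 18, 10.0, 0.8, 0.8, 25, 0.05),
    benthic_crustacean = c(3500, 24000, 5000, 35, 8.0, 5.0, 1.5, 40, 0.12),
    miscellaneous      = c(4000, 25000, 5500, 30, 4.0, 2.0, 1.2, 25, 0.06)
  )
  colnames(m) <- c("energy", NUTRIENTS)
  m
})

#' Specification of a synthetic study
#'
#' Defaults mirror the dimensions of the study design: 14 areas, 38
#' species across three taxa, 9 functional prey groups with ~17
#' composition samples each (one group forced to a single sample to
#' exercise the parametric branch), survey CVs in 0.1-0.8, and a 10x
#' latent productivity gradient across areas.
#'
#' @param n_areas Number of areas.
#' @param n_species Number of species.
#' @param taxon_props Proportions of species per taxon (sum to 1).
#' @param samples_per_group Composition samples per multi-sample group.
#' @param cv_range Range of survey abundance CVs.
#' @param productivity_gradient Ratio of richest to poorest area's latent
#'   productivity.
#' @param prop_both_habitats Fraction of areas surveyed in both neritic
#'   and oceanic habitats.
#' @param presence_prob Probability a species occurs in a given area.
#' @param seed Integer seed; generation is deterministic given it.
#' @return List of class `synthetic_study_spec`.
#' @export
synthetic_study_spec <- function(n_areas = 14, n_species = 38,
                                 taxon_props = c(small_cetacean = 0.50,
                                                 deep_diver = 0.29,
                                                 baleen_whale = 0.21),
                                 samples_per_group = 17,
                                 cv_range = c(0.1, 0.8),
                                 productivity_gradient = 10,
                                 prop_both_habitats = 0.7,
                                 presence_prob = 0.55,
                                 seed = 1L) {
  if (n_areas < 2 || n_species < 3) stop("need >= 2 areas and >= 3 species")
  if (abs(sum(taxon_props) - 1) > 1e-9) stop("taxon_props must sum to 1")
  if (any(taxon_props <= 0)) stop("every taxon needs a positive share")
  if (productivity_gradient < 1) stop("productivity_gradient must be >= 1")
  structure(list(n_areas = n_areas, n_species = n_species,
                 taxon_props = taxon_props,
                 n_prey_groups = length(PREY_GROUPS),
                 samples_per_group = samples_per_group,
                 cv_range = cv_range,
                 productivity_gradient = productivity_gradient,
                 prop_both_habitats = prop_both_habitats,
                 presence_prob = presence_prob,
                 seed = as.integer(seed)),
            class = "synthetic_study_spec")
}

# Dirichlet diet weights via normalized gammas; taxon-specific prey focus.
.diet_alpha <- function(taxon) {
  a <- stats::setNames(rep(0.15, length(PREY_GROUPS)), PREY_GROUPS)
  if (taxon == "baleen_whale") {
    a["zooplankton"] <- 8; a["small_pelagic_fish"] <- 3
    a["mesopelagic_fish"] <- 1.5
  } else if (taxon == "deep_diver") {
    a["muscular_cephalopod"] <- 5; a["gelatinous_cephalopod"] <- 3
    a["mesopelagic_fish"] <- 2.5; a["demersal_fish"] <- 1
  } else {
    a["small_pelagic_fish"] <- 5; a["demersal_fish"] <- 3
    a["muscular_cephalopod"] <- 1.5; a["benthic_crustacean"] <- 1
  }
  a
}

#' Generate a complete synthetic study input bundle with ground truth
#'
#' Areas receive a latent productivity scale `g` log-spaced over
#' `[1, productivity_gradient]`; chlorophyll is proportional to `g` (with
#' one flagged turbidity-outlier area) and SST decreases with `log(g)`.
#' Species abundances scale with `g`, habitat surface and taxon-specific
#' density, with multiplicative lognormal noise — so the
#' productivity-release correlation is a real, recoverable signal rather
#' than being baked into outputs. Migratory baleen whales make high-`g`
#' areas feeding grounds and low-`g` areas breeding grounds; the poorest
#' area is the fold-change baseline.
#'
#' @param spec A [synthetic_study_spec()].
#' @return List of class `study_inputs` with data.frames `species`,
#'   `diet_weights`, `prey_samples`, `abundance`, `areas`, plus
#'   `ground_truth` (latent gradient, expected plug-in release densities
#'   and taxon shares, baseline area) and `spec`.
#' @export
generate_study <- function(spec = synthetic_study_spec()) {
  with_stream(substream_seed(spec$seed, "study"), {
    ## --- species ----------------------------------------------------
    n_tax <- pmax(1, round(spec$n_species * spec$taxon_props))
    while (sum(n_tax) > spec$n_species) n_tax[which.max(n_tax)] <-
      n_tax[which.max(n_tax)] - 1
    while (sum(n_tax) < spec$n_species) n_tax[which.min(n_tax)] <-
      n_tax[which.min(n_tax)] + 1
    taxon <- rep(names(spec$taxon_props), n_tax)
    ns <- spec$n_species
    mass_range <- list(small_cetacean = c(30, 300),
                       deep_diver = c(300, 40000),
                       baleen_whale = c(5000, 120000))
    mean_bm <- vapply(taxon, function(tx) {
      r <- mass_range[[tx]]
      exp(stats::runif(1, log(r[1]), log(r[2])))
    }, 0)
    lunge <- taxon == "baleen_whale" & stats::runif(ns) < 0.7
    migratory <- taxon == "baleen_whale" & stats::runif(ns) < 0.65
    if (any(taxon == "baleen_whale") && !any(migratory)) {
      migratory[which(taxon == "baleen_whale")[1]] <- TRUE
    }
    beta_base <- c(small_cetacean = 4, deep_diver = 2,
                   baleen_whale = 3)[taxon] + 0.5 * lunge
    species <- data.frame(
      species_id = sprintf("sp%02d", seq_len(ns)),
      taxon = taxon, mean_body_mass = round(mean_bm, 1),
      beta_base = unname(beta_base), lunge_feeder = lunge,
      migratory = migratory, stringsAsFactors = FALSE)

    ## --- diets ------------------------------------------------------
    diet_weights <- do.call(rbind, lapply(seq_len(ns), function(i) {
      a <- .diet_alpha(taxon[i])
      w <- stats::rgamma(length(a), shape = a)
      w <- w / sum(w)
      data.frame(species_id = species$species_id[i], group = PREY_GROUPS,
                 weight = w, stringsAsFactors = FALSE)
    }))

    ## --- prey composition samples ----------------------------------
    prey_samples <- do.call(rbind, lapply(PREY_GROUPS, function(g) {
      k <- if (g == "zooplankton") 1L else spec$samples_per_group
      mu <- PREY_GROUP_MEANS[g, ]
      vals <- vapply(names(mu), function(v) {
        sdlog <- if (v == "energy") 0.12 else 0.25
        mu[[v]] * exp(stats::rnorm(k, 0, sdlog))
      }, numeric(k))
      if (k == 1) vals <- matrix(vals, 1, dimnames = list(NULL, names(mu)))
      cbind(data.frame(group = g, sample_id = sprintf("%s_%02d", g, 1:k),
                       stringsAsFactors = FALSE),
            as.data.frame(vals))
    }))

    ## --- areas ------------------------------------------------------
    na <- spec$n_areas
    g <- spec$productivity_gradient^((seq_len(na) - 1) / (na - 1))
    g <- sample(g)  # latent productivity, order randomized across ids
    area_id <- sprintf("area%02d", seq_len(na))
    rel_g <- log(g) / log(max(spec$productivity_gradient, exp(1)))
    chl <- 0.08 * g * exp(stats::rnorm(na, 0, 0.12))
    sst <- 30 - 23 * rel_g + stats::rnorm(na, 0, 0.8)
    outlier <- rep(FALSE, na)
    outlier[which.min(abs(rel_g - 0.5))] <- TRUE  # turbidity-driven chl
    chl[outlier] <- chl[outlier] * 6
    tert <- cut(rank(g, ties.method = "first"), 3, labels = FALSE)
    ground <- c("breeding", "resident", "feeding")[tert]
    both <- rep(FALSE, na)
    both[sample.int(na, round(spec$prop_both_habitats * na))] <- TRUE
    areas <- do.call(rbind, lapply(seq_len(na), function(i) {
      habs <- if (both[i]) c("neritic", "oceanic") else "oceanic"
      surf <- vapply(habs, function(h) {
        base <- if (h == "neritic") 1.5e5 else 5e5
        base * exp(stats::rnorm(1, 0, 0.4))
      }, 0)
      data.frame(area_id = area_id[i], habitat = habs,
                 surface_km2 = round(unname(surf)),
                 ground_status = ground[i],
                 mean_chlorophyll = round(chl[i], 4),
                 mean_sst = round(sst[i], 2),
                 chlorophyll_outlier = outlier[i],
                 is_baseline = g[i] == min(g),
                 stringsAsFactors = FALSE)
    }))

    ## --- abundances -------------------------------------------------
    dens0 <- c(small_cetacean = 0.02, deep_diver = 0.004,
               baleen_whale = 0.0008)  # individuals per km^2 at g = 1
    present <- matrix(stats::runif(ns * na) < spec$presence_prob, ns, na)
    for (j in seq_len(na)) if (sum(present[, j]) < 5) {
      present[sample.int(ns, 5), j] <- TRUE
    }
    for (i in seq_len(ns)) if (!any(present[i, ])) {
      present[i, sample.int(na, 1)] <- TRUE
    }
    abundance <- do.call(rbind, lapply(seq_len(na), function(j) {
      rows_a <- areas[areas$area_id == area_id[j], ]
      do.call(rbind, lapply(which(present[, j]), function(i) {
        tot_surf <- sum(rows_a$surface_km2)
        mean_tot <- dens0[[taxon[i]]] * g[j] * tot_surf *
          exp(stats::rnorm(1, 0, 0.3))
        split <- rows_a$surface_km2 / tot_surf *
          exp(stats::rnorm(nrow(rows_a), 0, 0.2))
        split <- split / sum(split)
        data.frame(area_id = area_id[j], habitat = rows_a$habitat,
                   species_id = species$species_id[i],
                   mean_abundance = round(mean_tot * split, 1),
                   cv = round(stats::runif(nrow(rows_a), spec$cv_range[1],
                                           spec$cv_range[2]), 3),
                   stringsAsFactors = FALSE)
      }))
    }))

    inputs <- structure(list(species = species, diet_weights = diet_weights,
                             prey_samples = prey_samples,
                             abundance = abundance, areas = areas),
                        class = "study_inputs")
    gt <- .ground_truth(inputs, g)
    inputs$ground_truth <- gt
    inputs$spec <- spec
    inputs
  })
}

# Deterministic plug-in expectation of each area's release density and
# taxon shares, from parameter means only (no Monte-Carlo): the generator's
# own record of what the pipeline should recover.
.ground_truth <- function(inputs, g) {
  sp <- inputs$species
  rownames(sp) <- sp$species_id
  grp_mean <- do.call(rbind, lapply(split(inputs$prey_samples,
                                          inputs$prey_samples$group),
    function(d) colMeans(d[, c("energy", NUTRIENTS)])))
  w <- inputs$diet_weights
  diet_mean <- do.call(rbind, lapply(split(w, w$species_id), function(d) {
    colSums(d$weight * grp_mean[d$group, , drop = FALSE])
  }))
  area_ground <- unique(inputs$areas[, c("area_id", "ground_status")])
  rownames(area_ground) <- area_ground$area_id
  ab <- inputs$abundance
  q_n <- vapply(seq_len(nrow(ab)), function(i) {
    s <- sp[ab$species_id[i], ]
    ground <- area_ground[ab$area_id[i], "ground_status"]
    mig_away <- s$migratory && ground != "resident"
    fasting <- s$migratory && s$taxon == "baleen_whale" &&
      ground == "breeding"
    ration <- compute_bmr(s$mean_body_mass, s$beta_base) /
      (0.85 * diet_mean[ab$species_id[i], "energy"])
    r_mean <- if (fasting) 0.3 else 0.8
    t_mean <- if (mig_away) 180 else 365
    ration * diet_mean[ab$species_id[i], "N"] * r_mean * t_mean *
      ab$mean_abundance[i] / 1e9
  }, 0)
  surf <- stats::aggregate(surface_km2 ~ area_id, inputs$areas, sum)
  tot <- stats::aggregate(q_n, list(area_id = ab$area_id), sum)
  dens <- merge(tot, surf)
  expected_density <- stats::setNames(1000 * dens$x / dens$surface_km2,
                                      dens$area_id)  # kg/km2/yr of N
  taxon_tot <- stats::aggregate(
    q_n, list(area_id = ab$area_id, taxon = sp[ab$species_id, "taxon"]), sum)
  shares <- do.call(rbind, lapply(split(taxon_tot, taxon_tot$area_id),
    function(d) {
      s <- stats::setNames(rep(0, length(TAXA)), TAXA)
      s[d$taxon] <- 100 * d$x / sum(d$x)
      s
    }))
  list(latent_g = stats::setNames(g, sort(unique(inputs$areas$area_id))),
       baseline_area = inputs$areas$area_id[inputs$areas$is_baseline][1],
       expected_density_N = expected_density,
       expected_taxon_share_N = shares)
}

#' Minimal degenerate worked example with closed-form expected outputs
#'
#' Two species, one single-habitat area, two prey groups with constant
#' composition, and a configuration in which every sampled distribution is
#' degenerate (zero variance), so every pipeline output is a hand-checkable
#' number. The expected values shipped in `$expected` are computed from the
#' unit chain written out independently of the model code.
#'
#' @return List with `inputs` (a `study_inputs` bundle), `config` (the
#'   degenerate [simulation_config()]), and `expected` (named closed-form
#'   values: per-species N release in t/yr, community totals per nutrient,
#'   densities, taxa shares, fold-change).
#' @export
generate_worked_example <- function() {
  comp <- rbind(
    grp_fish = c(energy = 5000, N = 25000, P = 6000, Fe = 100, Cu = 10,
                 Mn = 5, Se = 2, Zn = 50, Co = 0.1),
    grp_squid = c(energy = 4000, N = 20000, P = 5000, Fe = 50, Cu = 15,
                  Mn = 2, Se = 1, Zn = 40, Co = 0.05))
  prey_samples <- do.call(rbind, lapply(rownames(comp), function(g) {
    cbind(data.frame(group = g, sample_id = paste0(g, "_", 1:3),
                     stringsAsFactors = FALSE),
          as.data.frame(matrix(rep(comp[g, ], each = 3), 3,
                               dimnames = list(NULL, colnames(comp)))))
  }))
  species <- data.frame(
    species_id = c("dolphin", "beaked_whale"),
    taxon = c("small_cetacean", "deep_diver"),
    mean_body_mass = c(100, 2000), beta_base = c(3, 2),
    lunge_feeder = FALSE, migratory = FALSE, stringsAsFactors = FALSE)
  diet_weights <- data.frame(
    species_id = c("dolphin", "beaked_whale"),
    group = c("grp_fish", "grp_squid"), weight = 1,
    stringsAsFactors = FALSE)
  areas <- data.frame(area_id = "area01", habitat = "oceanic",
                      surface_km2 = 1000, ground_status = "resident",
                      mean_chlorophyll = 0.5, mean_sst = 15,
                      chlorophyll_outlier = FALSE, is_baseline = TRUE,
                      stringsAsFactors = FALSE)
  abundance <- data.frame(area_id = "area01", habitat = "oceanic",
                          species_id = c("dolphin", "beaked_whale"),
                          mean_abundance = c(1000, 200), cv = 0,
                          stringsAsFactors = FALSE)
  config <- simulation_config(n_sim = 50, seed = 1L,
                              release_rate_range = c(0.8, 0.8),
                              breeding_np_release_range = c(0.3, 0.3),
                              bm_sd_fraction = 0, beta_sd_fraction = 0,
                              ae_sd = 0)
  # closed-form expectation, written as the unit chain:
  # kJ/day -> kg food/day -> mg nutrient/day -> mg/yr -> t/yr
  expected_q <- sapply(c("dolphin", "beaked_whale"), function(id) {
    i <- match(id, species$species_id)
    grp <- diet_weights$group[diet_weights$species_id == id]
    bmr <- species$beta_base[i] * 293.1 * species$mean_body_mass[i]^0.75
    ration <- bmr / (0.85 * comp[grp, "energy"])
    mg_per_day <- ration * comp[grp, NUTRIENTS]
    mg_per_day * 0.8 * 365 * abundance$mean_abundance[i] / 1e9
  })  # 8 x 2 matrix (nutrient x species)
  totals <- rowSums(expected_q)
  expected <- list(
    per_species_t_yr = t(expected_q),
    community_total_t_yr = totals,
    density_kg_km2_yr = 1000 * totals / areas$surface_km2,
    taxon_share_pct = 100 * t(expected_q) / rep(totals, each = 2),
    fold_change = stats::setNames(rep(1, length(NUTRIENTS)), NUTRIENTS))
  inputs <- structure(list(species = species, diet_weights = diet_weights,
                           prey_samples = prey_samples,
                           abundance = abundance, areas = areas),
                      class = "study_inputs")
  list(inputs = inputs, config = config, expected = expected)
}
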