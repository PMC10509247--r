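# Shared fixtures: a reduced synthetic study and configuration used where a
# test only needs structure, not the full study dimensions.

tiny_spec <- function(seed = 42L) {
  synthetic_study_spec(n_areas = 6, n_species = 9,
                       samples_per_group = 6, seed = seed)
}

tiny_config <- function(seed = 42L, n_sim = 400) {
  simulation_config(n_sim = n_sim, seed = seed)
}

# A one-row species record for sampler tests.
make_species <- function(taxon = "small_cetacean", migratory = FALSE,
                         bm = 100, beta = 3, id = "spX") {
  data.frame(species_id = id, taxon = taxon, mean_body_mass = bm,
             beta_base = beta, lunge_feeder = FALSE, migratory = migratory,
             stringsAsFactors = FALSE)
}

make_abundance <- function(mean_abundance = 1000, cv = 0.3,
                           area = "areaA", habitat = "oceanic",
                           id = "spX") {
  data.frame(area_id = area, habitat = habitat, species_id = id,
             mean_abundance = mean_abundance, cv = cv,
             stringsAsFactors = FALSE)
}

# Constant diet draws (degenerate pools) for a given energy and nutrient
# concentration vector.
constant_diet <- function(n, energy = 5000, x = NULL) {
  if (is.null(x)) x <- stats::setNames(rep(10, 8), cetapump::nutrient_set()$nutrient)
  structure(list(energy = rep(energy, n),
                 x = matrix(rep(x, each = n), n,
                            dimnames = list(NULL, names(x)))),
            class = "diet_draws")
}
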