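# Variance-based global sensitivity analysis of the release model.

#' Sobol first- and second-order sensitivity indices
#'
#' Saltelli-type paired-matrix design: two independent base matrices A and
#' B of `n_base` rows are drawn from the parameter distributions, plus the
#' 2k cross matrices AB_i (A with column i from B) and BA_i. First-order
#' indices use the Jansen estimator
#' `S1_i = 1 - mean((f(B) - f(AB_i))^2) / (2 V)`; closed second-order
#' variances use the Saltelli (2002) cross-products
#' `V_ij = mean(f(BA_i) * f(AB_j)) - mean(f(A)) * mean(f(B))`, from which
#' `S2_ij = V_ij / V - S1_i - S1_j`. Total cost is `n_base * (2k + 2)`
#' model evaluations.
#'
#' @param model Function mapping an `n x k` parameter matrix (columns named
#'   after the parameters) to a numeric vector of `n` outputs; must be
#'   deterministic.
#' @param samplers Named list of functions `f(n)` drawing `n` independent
#'   values of each parameter.
#' @param n_base Base sample size per matrix (rows of A and B).
#' @param seed Optional sub-stream seed controlling all draws.
#' @param second_order Compute second-order indices (doubles the number of
#'   cross matrices).
#' @return List of class `sobol_result`: `S1` (data.frame `parameter`,
#'   `S1`, `se`), `S2` (data.frame `parameter_1`, `parameter_2`, `S2`, or
#'   `NULL`), `variance`, `n_base`, `n_evaluations`.
#' @export
sobol_indices <- function(model, samplers, n_base, seed = NULL,
                          second_order = TRUE) {
  k <- length(samplers)
  pars <- names(samplers)
  if (is.null(pars) || any(pars == "")) stop("samplers must be named")
  draw_matrix <- function() {
    m <- vapply(samplers, function(s) s(n_base), numeric(n_base))
    colnames(m) <- pars
    m
  }
  with_stream(seed, {
    A <- draw_matrix()
    B <- draw_matrix()
    fA <- model(A)
    fB <- model(B)
    V <- stats::var(c(fA, fB))
    n_eval <- 2 * n_base
    if (!is.finite(V) || V == 0) {
      warning("zero output variance; all indices defined as 0")
      s1 <- data.frame(parameter = pars, S1 = 0, se = 0,
                       stringsAsFactors = FALSE)
      s2 <- if (second_order && k >= 2) {
        idx <- utils::combn(pars, 2)
        data.frame(parameter_1 = idx[1, ], parameter_2 = idx[2, ], S2 = 0,
                   stringsAsFactors = FALSE)
      }
      return(structure(list(S1 = s1, S2 = s2, variance = 0, n_base = n_base,
                            n_evaluations = n_eval), class = "sobol_result"))
    }
    fAB <- matrix(NA_real_, n_base, k)
    for (i in seq_len(k)) {
      Ai <- A; Ai[, i] <- B[, i]
      fAB[, i] <- model(Ai)
    }
    n_eval <- n_eval + n_base * k
    d2 <- (fB - fAB)^2
    S1 <- 1 - colMeans(d2) / (2 * V)
    se <- apply(d2, 2, stats::sd) / (2 * V * sqrt(n_base))
    s1 <- data.frame(parameter = pars, S1 = unname(S1), se = unname(se),
                     stringsAsFactors = FALSE)
    s2 <- NULL
    if (second_order && k >= 2) {
      fBA <- matrix(NA_real_, n_base, k)
      for (i in seq_len(k)) {
        Bi <- B; Bi[, i] <- A[, i]
        fBA[, i] <- model(Bi)
      }
      n_eval <- n_eval + n_base * k
      f02 <- mean(fA) * mean(fB)
      idx <- utils::combn(seq_len(k), 2)
      s2 <- data.frame(
        parameter_1 = pars[idx[1, ]],
        parameter_2 = pars[idx[2, ]],
        S2 = apply(idx, 2, function(ij) {
          vij <- mean(fBA[, ij[1]] * fAB[, ij[2]]) - f02
          vij / V - S1[ij[1]] - S1[ij[2]]
        }),
        stringsAsFactors = FALSE
      )
    }
    structure(list(S1 = s1, S2 = s2, variance = V, n_base = n_base,
                   n_evaluations = n_eval), class = "sobol_result")
  })
}

#' Parameter samplers for the release model of one species in one context
#'
#' Builds the eight independent samplers (BM, beta, E, x, AE, r, A, t)
#' matching the study distributions: E and x are resampled from the
#' species' bootstrap diet-draw pools (treated as one scalar factor each
#' for the analysed nutrient), the rest follow their parametric forms.
#' Context-degenerate parameters (e.g. t = 365 for residents, r = 0 for
#' trace nutrients of fasting migrants) become constant samplers and
#' contribute no variance.
#'
#' @param species,abundance,ground,config As in [build_parameter_draws()].
#' @param diet_draws The species' diet draws pool.
#' @param nutrient Which nutrient's release to analyse.
#' @return Named list of 8 sampler functions.
#' @export
release_model_samplers <- function(species, abundance, ground, config,
                                   diet_draws, nutrient = "N") {
  bm_mean <- species$mean_body_mass
  beta_base <- species$beta_base
  e_pool <- diet_draws$energy
  x_pool <- diet_draws$x[, nutrient]
  breeding_faster <- isTRUE(as.logical(species$migratory)) &&
    identical(as.character(species$taxon), "baleen_whale") &&
    ground == "breeding"
  r_range <- if (!breeding_faster) config$release_rate_range
             else if (nutrient %in% MAJOR_NUTRIENTS)
               config$breeding_np_release_range
             else c(0, 0)
  migratory_away <- isTRUE(as.logical(species$migratory)) &&
    ground != "resident"
  list(
    BM = function(n) sample_truncated_normal(
      n, bm_mean, config$bm_sd_fraction * bm_mean, 1e-6 * bm_mean, Inf),
    beta = function(n) sample_truncated_normal(
      n, beta_base, config$beta_sd_fraction * beta_base,
      config$beta_bounds[1], config$beta_bounds[2]),
    E = function(n) sample(e_pool, n, replace = TRUE),
    x = function(n) sample(x_pool, n, replace = TRUE),
    AE = function(n) sample_truncated_normal(
      n, config$ae_mean, config$ae_sd, config$ae_bounds[1],
      config$ae_bounds[2]),
    r = function(n) if (r_range[1] == r_range[2]) rep(r_range[1], n)
        else stats::runif(n, r_range[1], r_range[2]),
    A = function(n) sample_abundance(n, abundance$mean_abundance,
                                     abundance$cv),
    t = function(n) if (migratory_away)
          stats::runif(n, config$feeding_days_range[1],
                       config$feeding_days_range[2])
        else rep(365, n)
  )
}

#' The release model as a function of its 8-column parameter matrix
#'
#' @param constants A [model_constants()] list.
#' @return Function suitable as the `model` argument of [sobol_indices()].
#' @export
release_model_fn <- function(constants = model_constants()) {
  function(m) {
    compute_annual_release(list(
      bm = m[, "BM"], beta = m[, "beta"], ae = m[, "AE"], e = m[, "E"],
      x = m[, "x"], r = m[, "r"], t = m[, "t"], a = m[, "A"]
    ), constants)
  }
}

#' Sobol sensitivity sweep over study cells
#'
#' Runs [sobol_indices()] on the release model for each
#' species x area x habitat cell (optionally a subset) and each requested
#' nutrient, and summarizes the distribution of each parameter's
#' first-order index across cells.
#'
#' @param inputs A validated study input bundle (see
#'   [load_study_inputs()] / [generate_study()]).
#' @param config A [simulation_config()].
#' @param nutrients Nutrients to analyse (default `"N"`).
#' @param cells Optional integer vector of rows of `inputs$abundance` to
#'   analyse (default all).
#' @param n_base Base sample size per cell.
#' @param second_order Also estimate second-order indices.
#' @return List with `cells` (long data.frame of S1 per cell x parameter),
#'   `S2_cells` (long data.frame or NULL), and `summary` (quantiles of S1
#'   per parameter across cells).
#' @export
model_sensitivity_sweep <- function(inputs, config, nutrients = "N",
                                    cells = NULL, n_base = 2^12,
                                    second_order = TRUE) {
  ab <- inputs$abundance
  if (is.null(cells)) cells <- seq_len(nrow(ab))
  species_tab <- inputs$species
  areas <- unique(inputs$areas[, c("area_id", "ground_status")])
  group_draws <- build_prey_group_draws(inputs$prey_samples, config$n_sim,
                                        seed = substream_seed(config$seed,
                                                              "prey_pool"))
  diet_by_species <- species_diet_draws(inputs, group_draws)
  model <- release_model_fn()
  rows <- list(); s2rows <- list()
  for (i in cells) {
    row <- ab[i, ]
    sp <- species_tab[species_tab$species_id == row$species_id, ]
    ground <- areas$ground_status[areas$area_id == row$area_id][1]
    for (nm in nutrients) {
      sam <- release_model_samplers(sp, row, ground, config,
                                    diet_by_species[[sp$species_id]], nm)
      seed_i <- substream_seed(config$seed, "sobol", row$species_id,
                               row$area_id, row$habitat, nm)
      res <- tryCatch(
        sobol_indices(model, sam, n_base, seed = seed_i,
                      second_order = second_order),
        error = function(e) NULL)
      if (is.null(res)) next
      s1 <- res$S1
      s1$species_id <- row$species_id; s1$area_id <- row$area_id
      s1$habitat <- row$habitat; s1$nutrient <- nm
      rows[[length(rows) + 1]] <- s1
      if (!is.null(res$S2)) {
        s2 <- res$S2
        s2$species_id <- row$species_id; s2$area_id <- row$area_id
        s2$habitat <- row$habitat; s2$nutrient <- nm
        s2rows[[length(s2rows) + 1]] <- s2
      }
    }
  }
  cells_df <- do.call(rbind, rows)
  summary_df <- do.call(rbind, lapply(split(cells_df, cells_df$parameter),
    function(d) {
      q <- stats::quantile(d$S1, c(0.025, 0.25, 0.5, 0.75, 0.975))
      data.frame(parameter = d$parameter[1], median = q[[3]],
                 q2.5 = q[[1]], q25 = q[[2]], q75 = q[[4]], q97.5 = q[[5]],
                 n_cells = nrow(d), stringsAsFactors = FALSE)
    }))
  rownames(summary_df) <- NULL
  list(cells = cells_df,
       S2_cells = if (length(s2rows)) do.call(rbind, s2rows) else NULL,
       summary = summary_df)
}
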