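#' Basal metabolic rate from Kleiber allometry
#'
#' `BMR = beta * 293.1 * BM^(3/4)` in kJ/day. `beta` is a species-specific
#' metabolic multiplier scaling basal metabolism to field energy needs
#' ("cost of living"); typical base values are 2 (low, e.g. sperm whale),
#' 3, and 4 (high, e.g. harbour porpoise), + 0.5 for lunge feeders.
#'
#' @param bm Body mass in kg (vectorised).
#' @param beta Metabolic multiplier, dimensionless (vectorised).
#' @param constants A [model_constants()] list.
#' @return Metabolic rate in kJ/day.
#' @export
#' @examples
#' compute_bmr(1, 1)      # 293.1
#' compute_bmr(16, 1)     # 8 * 293.1
compute_bmr <- function(bm, beta, constants = model_constants()) {
  if (any(!is.finite(bm)) || any(bm <= 0)) {
    stop("bm: body mass must be finite and > 0")
  }
  if (any(!is.finite(beta)) || any(beta <= 0)) {
    stop("beta: metabolic multiplier must be finite and > 0")
  }
  beta * constants$kleiber_coefficient * bm^constants$kleiber_exponent
}

#' Daily ration from energy balance
#'
#' Food intake needed to meet a metabolic rate given the assimilation
#' efficiency and mean diet energy density:
#' `ration = BMR / (AE * E)` in kg food/day.
#'
#' @param bmr Metabolic rate, kJ/day.
#' @param ae Assimilation efficiency, fraction in (0, 1].
#' @param e Mean diet energy density, kJ/kg fresh weight.
#' @return Ingestion rate, kg food/day.
#' @export
compute_daily_ration <- function(bmr, ae, e) {
  if (any(!is.finite(ae)) || any(ae <= 0) || any(ae > 1)) {
    stop("ae: assimilation efficiency must be in (0, 1]")
  }
  if (any(!is.finite(e)) || any(e <= 0)) {
    stop("e: diet energy density must be finite and > 0")
  }
  bmr / (ae * e)
}

#' Annual nutrient release for one parameter vector (or aligned draws)
#'
#' The full consumption-egestion chain: an individual's ration
#' `BMR / (AE * E)` (kg food/day) carries nutrient `x_n` (mg/kg fresh
#' weight), of which a fraction `r_n` is released; scaled by days of
#' presence `t` and abundance `A`, and converted mg -> tonnes:
#'
#' `Q_n = ration * x_n * r_n * t * A / mg_per_tonne`  (tonnes/year)
#'
#' All scalar fields may be length-`n` vectors of aligned Monte-Carlo draws;
#' `x` and `r` may be `n x k` matrices (one column per nutrient, all sharing
#' the one ration per draw).
#'
#' @param params List with fields `bm` (kg), `beta`, `ae` (fraction),
#'   `e` (kJ/kg), `x` (mg/kg; vector or n-by-nutrient matrix),
#'   `r` (fraction in `[0,1]`; same shape as `x`), `t` (days in `[0,365]`),
#'   `a` (abundance, >= 0).
#' @param constants A [model_constants()] list.
#' @return Annual release in tonnes/year, same shape as `params$x`.
#' @export
compute_annual_release <- function(params, constants = model_constants()) {
  x <- params$x
  r <- params$r
  if (any(x < 0)) stop("x: nutrient concentrations must be >= 0")
  if (any(r < 0) || any(r > 1)) stop("r: release rates must be in [0, 1]")
  if (any(params$t < 0) || any(params$t > 365)) {
    stop("t: days of presence must be in [0, 365]")
  }
  if (any(params$a < 0)) stop("a: abundance must be >= 0")

  bmr <- compute_bmr(params$bm, params$beta, constants)
  ration <- compute_daily_ration(bmr, params$ae, params$e)
  # elementwise; a matrix x recycles the per-draw scalars down each column
  q_mg <- ration * x * r * params$t * params$a
  q_mg / constants$mg_per_tonne
}
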