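#' Fixed physical and allometric constants of the bioenergetic model
#'
#' The basal metabolic rate follows Kleiber's allometry,
#' `BMR = beta * 293.1 * BM^(3/4)` in kJ/day for body mass `BM` in kg.
#' `mg_per_tonne` carries the unit chain from nutrient concentrations in
#' mg per kg fresh weight to annual release in tonnes.
#'
#' @param kleiber_coefficient Energy-rate coefficient, kJ day^-1 kg^-0.75.
#' @param kleiber_exponent Allometric exponent, fixed at 3/4.
#' @param mg_per_tonne Milligrams per tonne (1e9).
#' @return A list of class `model_constants`.
#' @export
#' @examples
#' model_constants()$kleiber_coefficient
model_constants <- function(kleiber_coefficient = 293.1,
                            kleiber_exponent = 0.75,
                            mg_per_tonne = 1e9) {
  if (kleiber_coefficient <= 0) stop("kleiber_coefficient must be > 0")
  if (kleiber_exponent != 0.75) stop("kleiber_exponent is fixed at 3/4")
  if (mg_per_tonne <= 0) stop("mg_per_tonne must be > 0")
  structure(
    list(kleiber_coefficient = kleiber_coefficient,
         kleiber_exponent = kleiber_exponent,
         mg_per_tonne = mg_per_tonne),
    class = "model_constants"
  )
}

# Fixed nutrient order used everywhere in the pipeline.
NUTRIENTS <- c("N", "P", "Fe", "Cu", "Mn", "Se", "Zn", "Co")
MAJOR_NUTRIENTS <- c("N", "P")
TRACE_NUTRIENTS <- c("Fe", "Cu", "Mn", "Se", "Zn", "Co")

TAXA <- c("small_cetacean", "deep_diver", "baleen_whale")

#' The eight nutrients tracked by the model
#'
#' Two major nutrients (N, P) and six trace nutrients (Fe, Cu, Mn, Se, Zn,
#' Co), in the fixed order used across the whole pipeline.
#'
#' @return A data.frame with columns `nutrient` and `class`
#'   (`"major"` or `"trace"`).
#' @export
nutrient_set <- function() {
  data.frame(
    nutrient = NUTRIENTS,
    class = ifelse(NUTRIENTS %in% MAJOR_NUTRIENTS, "major", "trace"),
    stringsAsFactors = FALSE
  )
}
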