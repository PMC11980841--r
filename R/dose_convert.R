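#' Weight-proportional mouse-equivalent cell dose
#'
#' Translates a human clinical cell dose expressed per kilogram of body
#' weight into the proportional per-animal dose for a mouse model, by simple
#' linear (per-kg) scaling: `cells_per_mouse = cells_per_kg * mouse_mass`.
#' The default mouse mass is 0.02 kg (a 20 g adult immunodeficient mouse).
#'
#' @param cells_per_kg Human dose, cells per kg body weight (> 0).
#' @param mouse_mass Mouse body mass in kg (> 0; default 0.02).
#' @return Cells per mouse (exact product).
#' @export
#' @examples
#' mouse_equivalent_dose(1e6) # 2e4 cells per mouse
#' mouse_equivalent_dose(0.5e6) # 1e4 cells per mouse
mouse_equivalent_dose <- function(cells_per_kg, mouse_mass = 0.02) {
  stopifnot(is.numeric(cells_per_kg), is.numeric(mouse_mass))
  if (any(!(cells_per_kg > 0)) || any(!(mouse_mass > 0))) {
    stop("doses and masses must be positive", call. = FALSE)
  }
  cells_per_kg * mouse_mass
}

#' Fold excess of a model dose over a proportional dose
#'
#' Ratio of the cell dose used in an animal model (e.g. the lowest dose that
#' controls leukemia in a xenograft) to the weight-proportional equivalent of
#' a human clinical dose — the factor by which the model dose exceeds what
#' could proportionally be given to a patient.
#'
#' @param model_dose Cells per mouse used in the model (>= 0).
#' @param proportional_dose Weight-proportional clinical-equivalent dose,
#'   cells per mouse (> 0).
#' @return `model_dose / proportional_dose`.
#' @export
#' @examples
#' fold_excess(5e6, 2e4) # 250
#' fold_excess(5e6, 1e4) # 500
fold_excess <- function(model_dose, proportional_dose) {
  stopifnot(is.numeric(model_dose), is.numeric(proportional_dose))
  if (any(model_dose < 0)) stop("model_dose must be nonnegative", call. = FALSE)
  if (any(!(proportional_dose > 0))) {
    stop("proportional_dose must be positive", call. = FALSE)
  }
  model_dose / proportional_dose
}
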