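#' Du Bois body surface area
#'
#' Classical Du Bois & Du Bois estimate of body surface area from weight and
#' height, `0.007184 * weight^0.425 * height^0.725`.
#'
#' @param weight_kg Body weight in kilograms. Must be strictly positive.
#' @param height_cm Standing height in centimetres. Must be strictly positive.
#' @return Body surface area in square metres. Vectorised over both arguments.
#' @examples
#' du_bois_bsa(70, 170)
#' @export
du_bois_bsa <- function(weight_kg, height_cm) {
  if (any(!is.finite(weight_kg)) || any(!is.finite(height_cm)) ||
      any(weight_kg <= 0) || any(height_cm <= 0)) {
    stop("du_bois_bsa(): weight_kg and height_cm must be finite and > 0",
         call. = FALSE)
  }
  0.007184 * weight_kg^0.425 * height_cm^0.725
}

#' Body mass index
#'
#' @inheritParams du_bois_bsa
#' @return BMI in kg per square metre.
#' @export
bmi <- function(weight_kg, height_cm) {
  if (any(weight_kg <= 0) || any(height_cm <= 0)) {
    stop("bmi(): inputs must be > 0", call. = FALSE)
  }
  weight_kg / (height_cm / 100)^2
}

#' Body surface area to mass ratio
#'
#' Surface available for heat exchange per kilogram of body mass,
#' in cm^2 per kg. This is the "BSA/M" index of thermoregulation studies:
#' small-bodied subjects carry more exchange surface per unit mass.
#'
#' @param bsa_m2 Body surface area in square metres.
#' @param weight_kg Body weight in kilograms.
#' @return BSA/M in cm^2 per kg.
#' @export
bsa_per_mass <- function(bsa_m2, weight_kg) {
  if (any(bsa_m2 <= 0) || any(weight_kg <= 0)) {
    stop("bsa_per_mass(): inputs must be > 0", call. = FALSE)
  }
  bsa_m2 * 1e4 / weight_kg
}

#' Join derived anthropometric indices onto a participant table
#'
#' Adds `bsa_m2`, `bsa_per_mass_cm2_kg` and `bmi_kg_m2` columns computed from
#' `weight_kg` and `height_cm`.
#'
#' @param participants A data frame with `weight_kg` and `height_cm` columns.
#' @return The participant table with three additional columns.
#' @export
add_anthropometry <- function(participants) {
  stopifnot(all(c("weight_kg", "height_cm") %in% names(participants)))
  participants$bsa_m2 <- du_bois_bsa(participants$weight_kg, participants$height_cm)
  participants$bsa_per_mass_cm2_kg <- bsa_per_mass(participants$bsa_m2, participants$weight_kg)
  participants$bmi_kg_m2 <- bmi(participants$weight_kg, participants$height_cm)
  participants
}
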