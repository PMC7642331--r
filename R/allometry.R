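#' Maximum running speed from body mass
#'
#' Allometric maximum running speed for terrestrial mammals,
#' \deqn{V_{max} = 25.5\, M^{0.26} (1 - e^{-22 M^{-0.6}})}
#' with \eqn{M} the body mass in kg and the result in km/h, converted here to
#' m/s. The curve is unimodal: speed rises with mass for small animals and
#' falls again for very heavy ones, peaking at intermediate (roughly
#' 100 kg) body masses.
#'
#' @param mass_kg body mass in kilograms; positive, finite. Vectorised.
#' @return maximum running speed in m/s, full precision.
#' @examples
#' vmax_from_mass(65)    # chital, ~17.50 m/s
#' vmax_from_mass(825)   # gaur, ~13.15 m/s
#' @seealso [traverse_speed()], [species_traits()]
#' @export
vmax_from_mass <- function(mass_kg) {
  check_number(mass_kg, "mass_kg")
  v_kmh <- 25.5 * mass_kg^0.26 * (1 - exp(-22 * mass_kg^-0.6))
  v_kmh / 3.6
}

#' Traversing (road-crossing) speed from maximum running speed
#'
#' Animals cross roads at a walking pace far below their top running speed;
#' field-measured crossing speeds for large Indian mammals are close to one
#' sixth of the allometric maximum, which is the default used here.
#'
#' @param vmax_ms maximum running speed in m/s; positive. Vectorised.
#' @return traversing speed `vmax_ms / 6` in m/s, full precision.
#' @examples
#' traverse_speed(17.0815)  # tiger, ~2.85 m/s
#' @export
traverse_speed <- function(vmax_ms) {
  check_number(vmax_ms, "vmax_ms")
  vmax_ms / 6
}
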