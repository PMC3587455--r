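# Unit conversions between mass concentration and mixing ratio.

#' Molar masses of the species handled by the model (g mol-1)
#' @keywords internal
MOLAR_MASS <- c(NO = 30.006, NO2 = 46.0055, O3 = 47.998, NOx = 46.0055)

#' Universal gas constant, J mol-1 K-1
#' @keywords internal
R_GAS <- 8.314462618

#' Convert a mass concentration to a volume mixing ratio
#'
#' Ideal-gas conversion of micrograms per cubic metre to parts per billion
#' by volume at a stated temperature and pressure. NOx is treated on the
#' NO2-equivalent mass basis used by emission inventories, so it converts
#' with the NO2 molar mass.
#'
#' @param value mass concentration, ug m-3 (vectorised)
#' @param species one of "NO", "NO2", "O3", "NOx"
#' @param temp air temperature, K
#' @param pressure air pressure, Pa
#' @return mixing ratio in ppb
#' @examples
#' ugm3_to_ppb(1.9125, "NO2", temp = 293.15) # ~1 ppb
#' @export
ugm3_to_ppb <- function(value, species, temp = 293.15, pressure = 101325) {
  m <- molar_mass(species)
  stopifnot(all(temp > 0), all(pressure > 0))
  value * (R_GAS * temp) / (pressure * m) * 1e3
}

#' Convert a volume mixing ratio to a mass concentration
#'
#' Exact inverse of [ugm3_to_ppb()].
#'
#' @inheritParams ugm3_to_ppb
#' @param value mixing ratio, ppb
#' @return mass concentration in ug m-3
#' @export
ppb_to_ugm3 <- function(value, species, temp = 293.15, pressure = 101325) {
  m <- molar_mass(species)
  stopifnot(all(temp > 0), all(pressure > 0))
  value * (pressure * m) / (R_GAS * temp) * 1e-3
}

molar_mass <- function(species) {
  species <- as.character(species)
  if (!all(species %in% names(MOLAR_MASS))) {
    stop("unknown species: ", paste(setdiff(species, names(MOLAR_MASS)), collapse = ", "))
  }
  unname(MOLAR_MASS[species])
}
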