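# Whole-community energy consumption from abundances and mass-scaled field
# metabolic rates, and year-over-year compensation ratios.

#' Mass-specific field metabolic rate
#'
#' Scales a reference species' field metabolic rate linearly by body mass:
#' \code{(fmr_ref / mass_ref) * mass_target}.  Used to transfer an FMR
#' measured on a reference species (e.g. an 8.2 g common shrew) to the
#' focal species' mean body mass in each year.
#'
#' @param fmr_ref reference FMR, kJ/day (> 0).
#' @param mass_ref reference body mass, g (> 0).
#' @param mass_target focal body mass, g (> 0).
#' @return FMR in kJ/day at the target mass.
#' @examples
#' mass_specific_fmr(90, 8.2, 4.1)  # 45
#' @export
mass_specific_fmr <- function(fmr_ref, mass_ref, mass_target) {
  if (any(c(fmr_ref, mass_ref, mass_target) <= 0)) {
    stop_invalid("all FMR inputs must be > 0")
  }
  (fmr_ref / mass_ref) * mass_target
}

#' Community energy consumption
#'
#' Total daily energy flux through the community:
#' \code{sum(abundance * FMR)} over species, with per-species components
#' retained.
#'
#' @param abundances named per-species abundances (>= 0).
#' @param fmrs per-species FMR values, kJ/day, aligned with
#'   \code{abundances}.
#' @return list with \code{species} (per-species kJ/day) and \code{total}.
#' @examples
#' community_energy(c(mouse = 100, shrew = 50), c(mouse = 30, shrew = 10))
#' @export
community_energy <- function(abundances, fmrs) {
  if (length(abundances) != length(fmrs)) {
    stop_invalid("abundances and fmrs must be aligned")
  }
  if (any(abundances < 0)) stop_invalid("abundances must be non-negative")
  if (any(fmrs < 0)) stop_invalid("FMR values must be non-negative")
  comp <- abundances * fmrs
  list(species = comp, total = sum(comp))
}

#' Energy compensation ratio
#'
#' Percent of a reference year's community energy consumption reached in a
#' later year: \code{100 * E_t / E_ref}.  100 percent is the zero-sum
#' expectation (the released competitor fully replaces the lost energy
#' flux); values below 100 indicate partial compensation.
#'
#' @param e_t community energy in the focal year, kJ/day.
#' @param e_ref community energy in the reference year, kJ/day (> 0 for a
#'   defined ratio; 0 yields \code{NA} with a warning).
#' @return percent.
#' @examples
#' compensation(690, 1000)  # 69
#' @export
compensation <- function(e_t, e_ref) {
  if (e_ref <= 0) {
    warning("zero reference energy: compensation undefined")
    return(NA_real_)
  }
  100 * e_t / e_ref
}
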