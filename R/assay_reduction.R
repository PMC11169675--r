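.round_half_away_int <- function(x) as.integer(sign(x) * floor(abs(x) + 0.5))

#' Inner circumference of a pore ring
#'
#' `pi * inner_diameter`, rounded half away from zero to the nearest
#' integer nanometre (a ~20 nm inner diameter gives ~63 nm).
#'
#' @param inner_diameter Inner ring diameter in nm (> 0).
#' @return Integer circumference in nm.
#' @export
ring_circumference <- function(inner_diameter) {
  if (!is.finite(inner_diameter) || inner_diameter <= 0) {
    stop("inner_diameter must be positive")
  }
  .round_half_away_int(pi * inner_diameter)
}

#' Estimated monomer count of an oligomeric ring
#'
#' Circumference divided by the per-monomer width of the twin transmembrane
#' beta-hairpins (~2.1 nm), rounded half away from zero (63 nm / 2.1 nm
#' gives 30 monomers).
#'
#' @param circumference Inner circumference in nm (> 0).
#' @param hairpin_width Combined width of one monomer's two transmembrane
#'   beta-hairpins in nm (> 0).
#' @return Integer monomer count.
#' @export
estimate_monomer_count <- function(circumference, hairpin_width) {
  stopifnot(circumference > 0, hairpin_width > 0)
  .round_half_away_int(circumference / hairpin_width)
}

#' Background-corrected FRET donor quench
#'
#' Corrects the donor+unlabeled (DU) emission by subtracting the unlabeled
#' (U) background, corrects the donor+acceptor (DA) emission by subtracting
#' the unlabeled+acceptor (UA) background, and expresses the corrected DA
#' as a percentage of the corrected DU. 100 means no quenching; smaller
#' values mean the acceptor quenches donor emission (the two labeled
#' proteins interact).
#'
#' @param E_DU,E_U,E_DA,E_UA Fluorescence emissions (arbitrary units).
#' @return Percent donor emission retained.
#' @export
fret_quench <- function(E_DU, E_U, E_DA, E_UA) {
  stopifnot(is.finite(E_DU), is.finite(E_U), is.finite(E_DA), is.finite(E_UA))
  denom <- E_DU - E_U
  if (denom <= 0) stop("donor signal not above background")
  100 * (E_DA - E_UA) / denom
}

#' Normalize a kinetic emission trace to a positive control
#'
#' Scales emissions so the positive-control emission equals 100 arbitrary
#' units.
#'
#' @param emissions Numeric vector of emissions.
#' @param positive_control_emission Positive-control emission (> 0).
#' @param times Optional strictly increasing time vector (validated only).
#' @return Numeric vector of normalized emissions.
#' @export
normalize_trace <- function(emissions, positive_control_emission,
                            times = NULL) {
  if (!is.finite(positive_control_emission) ||
      positive_control_emission <= 0) {
    stop("positive control emission must be positive")
  }
  if (!is.null(times) && any(diff(times) <= 0)) {
    stop("times must be strictly increasing")
  }
  emissions * (100 / positive_control_emission)
}

#' Fraction of PI-positive cells
#'
#' A cell is propidium-iodide positive when its mean red-channel intensity
#' is strictly above the background level (default 7498 a.u.).
#'
#' @param intensities Per-cell mean red-channel intensities (>= 0).
#' @param background Background intensity threshold (default 7498).
#' @return Fraction of positive cells in \[0, 1\].
#' @export
call_pi_positive <- function(intensities, background = 7498) {
  if (length(intensities) == 0L) stop("no cells in intensity table")
  stopifnot(all(intensities >= 0))
  mean(intensities > background)
}
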