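#' Analytic pencil-beam dose model configuration
#'
#' Parameters of the closed-form proton depth-dose and lateral-spread
#' model. The range-energy relation is Bragg-Kleeman, R = alpha * E^p (R in
#' cm water, E in MeV) with standard water constants. The depth-dose is a
#' Gaussian Bragg peak of width `bragg_width_mm` on top of a flat proximal
#' plateau (`plateau_frac` of the peak Gaussian amplitude) that is cut off
#' sigmoidally at the range; dose is identically zero beyond
#' R + 3 * bragg_width. The lateral profile is a single Gaussian whose
#' sigma grows with normalized depth,
#' sigma(z)^2 = sigma0^2 + sigma_shifter^2 + (mcs_coeff * z * z/R)^2,
#' which reproduces the clinically relevant penumbra ordering: a range
#' shifter widens the beam at every depth, and a high-energy transmission
#' spot (Bragg peak far beyond the patient) stays narrower than an
#' in-target spot at the same depth. Doses are weighted by a constant RBE
#' factor of 1.1.
#'
#' @param alpha Bragg-Kleeman coefficient (cm MeV^-p), default 0.0022.
#' @param p Bragg-Kleeman exponent, default 1.77.
#' @param sigma0_mm spot sigma at the patient surface (mm).
#' @param shifter_sigma_mm added sigma (mm, in quadrature) for a 3 cm
#'   range shifter; scaled linearly for other thicknesses.
#' @param mcs_coeff multiple-Coulomb-scattering lateral growth coefficient
#'   (dimensionless; multiplies z * z/R with z in mm).
#' @param bragg_width_mm Gaussian sigma of the Bragg peak (mm water).
#' @param plateau_frac plateau level relative to the peak Gaussian.
#' @param rbe relative biological effectiveness factor, default 1.1.
#' @param lateral_cutoff_sigma deposit dose within this many sigma of the
#'   spot axis (sparsity cutoff), default 3.5.
#' @return list of class "dose_model_config"
#' @export
doseModelConfig <- function(alpha = 0.0022, p = 1.77,
                            sigma0_mm = 10, shifter_sigma_mm = 4,
                            mcs_coeff = 0.045, bragg_width_mm = 12,
                            plateau_frac = 0.35, rbe = 1.1,
                            lateral_cutoff_sigma = 3.0) {
  vals <- c(alpha = alpha, p = p, sigma0_mm = sigma0_mm,
            shifter_sigma_mm = shifter_sigma_mm, mcs_coeff = mcs_coeff,
            bragg_width_mm = bragg_width_mm, plateau_frac = plateau_frac,
            rbe = rbe, lateral_cutoff_sigma = lateral_cutoff_sigma)
  if (any(vals <= 0)) .stopf("all dose model parameters must be positive")
  structure(as.list(vals), class = "dose_model_config")
}

#' Proton range in water from energy (Bragg-Kleeman)
#'
#' @param energy beam energy in MeV (vectorized).
#' @param cfg a [doseModelConfig()].
#' @return range in cm water. Strictly increasing in energy; subtract the
#'   water-equivalent shifter thickness to get the residual range in the
#'   patient.
#' @export
rangeFromEnergy <- function(energy, cfg = doseModelConfig()) {
  if (any(energy <= 0)) .stopf("energy must be positive")
  cfg$alpha * energy^cfg$p
}

#' Relative depth-dose of a pencil beam
#'
#' @param energy MeV.
#' @param wet_depth water-equivalent depth in cm (vectorized); for a
#'   range-shifted spot pass patient WET + shifter WET.
#' @param cfg a [doseModelConfig()].
#' @return dimensionless relative dose: a flat proximal plateau, a Bragg
#'   peak with maximum within one peak-width of the range, and exactly zero
#'   beyond R + 3 peak-widths.
#' @export
depthDose <- function(energy, wet_depth, cfg = doseModelConfig()) {
  if (any(wet_depth < 0)) .stopf("wet_depth must be >= 0")
  R <- rangeFromEnergy(energy, cfg)
  sB <- cfg$bragg_width_mm / 10     # cm
  plateau <- cfg$plateau_frac * stats::plogis((R - wet_depth) / sB)
  peak <- exp(-(wet_depth - R)^2 / (2 * sB^2))
  d <- plateau + peak
  d[wet_depth > R + 3 * sB] <- 0
  d
}

#' Lateral Gaussian sigma of a pencil beam at depth
#'
#' @param energy MeV.
#' @param wet_depth water-equivalent depth in the patient, cm (vectorized).
#' @param shifter_wet_cm water-equivalent range-shifter thickness (cm).
#' @param cfg a [doseModelConfig()].
#' @return sigma in mm. Non-decreasing in depth; a shifter strictly widens
#'   the beam at every depth; at equal depth a transmission-energy spot is
#'   never wider than a spot whose Bragg peak sits at that depth.
#' @export
lateralSigma <- function(energy, wet_depth, shifter_wet_cm = 0,
                         cfg = doseModelConfig()) {
  R_res <- rangeFromEnergy(energy, cfg) - shifter_wet_cm   # cm in patient
  if (any(R_res <= 0)) .stopf("shifter absorbs the full range")
  z <- wet_depth * 10                                     # mm
  growth <- cfg$mcs_coeff * z * (z / (R_res * 10))
  sh <- cfg$shifter_sigma_mm * (shifter_wet_cm / 3)
  sqrt(cfg$sigma0_mm^2 + sh^2 + growth^2)
}

#' 80-20 lateral penumbra width of a spot at depth
#'
#' Distance between the 80% and 20% levels of the lateral profile,
#' evaluated numerically from the Gaussian lateral model (erf-free,
#' profile-based): for a Gaussian this is (z80 - z20) of the normalized
#' profile exp(-x^2 / 2 sigma^2).
#'
#' @inheritParams lateralSigma
#' @return penumbra width in mm.
#' @export
penumbra8020 <- function(energy, wet_depth, shifter_wet_cm = 0,
                         cfg = doseModelConfig()) {
  s <- lateralSigma(energy, wet_depth, shifter_wet_cm, cfg)
  x <- seq(0, 6, by = 1e-3)            # in units of sigma
  prof <- exp(-x^2 / 2)
  x80 <- x[which.max(prof <= 0.8)]
  x20 <- x[which.max(prof <= 0.2)]
  (x20 - x80) * s
}
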