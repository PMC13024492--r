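#' @include constructors.R
NULL

# Coerce the load argument: numeric is total mass in ug.
.as_load <- function(load, area_cm2 = NA) {
  if (is(load, "MassLoad")) return(load)
  if (is.numeric(load) && length(load) == 1L) {
    if (is.na(load) || load < 0) stop("mass load must be a nonnegative number (ug)")
    return(massLoad(delta_m_ug = load, area_cm2 = area_cm2))
  }
  stop("load must be a MassLoad or a single nonnegative number (ug)")
}

.need <- function(spec, fields) {
  miss <- fields[vapply(fields, function(f) is.na(slot(spec, f)), logical(1))]
  if (length(miss)) {
    stop(sprintf("ResonatorSpec is missing required field(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
}

#' Sauerbrey frequency shift of a loaded resonator
#'
#' For rigid, thin, uniform loading the resonant-frequency shift is
#' \deqn{\Delta f = -\frac{2 f_0^2}{A\sqrt{\rho_q \mu_q}}\,\Delta m,}
#' with \eqn{f_0} the unloaded resonance (Hz), \eqn{A} the active area
#' (cm^2), \eqn{\rho_q} and \eqn{\mu_q} the substrate density (g/cm^3) and
#' shear modulus (g cm^-1 s^-2), and \eqn{\Delta m} the added mass (grams
#' internally; the interface takes micrograms). The shift is nonpositive
#' and exactly linear in the load.
#'
#' @param spec a \linkS4class{ResonatorSpec} with \code{f0}, \code{A},
#'   \code{rho_q} and \code{mu_q} set.
#' @param load a \linkS4class{MassLoad} or a single nonnegative mass in ug.
#' @return frequency shift, Hz (<= 0).
#' @examples
#' qz <- resonatorSpec(f0_hz = 5e6, area_cm2 = 1, rho_q = 2.648, mu_q = 2.947e11)
#' sauerbreyShift(qz, 1) # about -56.6 Hz for 1 ug on a 5 MHz quartz device
#' @seealso \code{\link{theoreticalSensitivity}}, \code{\link{filmShift}}
#' @export
sauerbreyShift <- function(spec, load) {
  .need(spec, c("f0", "A", "rho_q", "mu_q"))
  load <- .as_load(load, area_cm2 = spec@A)
  if (is.na(load@delta_m)) stop("load must carry a total mass delta_m")
  dm_g <- load@delta_m * 1e-6
  -2 * spec@f0^2 * dm_g / (spec@A * sqrt(spec@rho_q * spec@mu_q))
}

#' Theoretical mass sensitivity from device constants
#'
#' \deqn{S_M = \frac{2 f_0^2}{A\sqrt{\rho_q \mu_q}},} the magnitude of
#' frequency shift per unit mass; it scales quadratically with \eqn{f_0}
#' and inversely with active area and substrate acoustic impedance. By
#' construction \code{sauerbreyShift(spec, dm) == -S_M * dm} to machine
#' precision.
#'
#' @inheritParams sauerbreyShift
#' @param per_ug logical; if TRUE (default) return Hz/ug for total mass on
#'   area A, else Hz per unit areal loading (g/cm^2).
#' @return a \linkS4class{SensitivityResult} with \code{S_M} set.
#' @export
theoreticalSensitivity <- function(spec, per_ug = TRUE) {
  .need(spec, c("f0", "A", "rho_q", "mu_q"))
  s_areal <- 2 * spec@f0^2 / (spec@A * sqrt(spec@rho_q * spec@mu_q)) # per g on A
  if (per_ug) {
    new("SensitivityResult", S_M = s_areal * 1e-6, S_M_unit = "Hz/ug")
  } else {
    new("SensitivityResult", S_M = s_areal * spec@A, S_M_unit = "Hz per g/cm2")
  }
}

#' Empirically calibrated mass sensitivity
#'
#' \deqn{S_m = -\Delta f / \Delta m} from a measured shift/mass pair.
#'
#' @param delta_f measured frequency shift, Hz.
#' @param delta_m added mass, ug; must be nonzero.
#' @return a \linkS4class{SensitivityResult} with \code{S_m} set (Hz/ug).
#' @export
empiricalSensitivity <- function(delta_f, delta_m) {
  if (length(delta_m) != 1L || is.na(delta_m) || delta_m == 0) {
    stop("delta_m must be a single nonzero mass (ug)")
  }
  new("SensitivityResult", S_m = -delta_f / delta_m, S_M_unit = "Hz/ug")
}

#' Thin-film frequency shift under areal mass loading
#'
#' For a thin piezoelectric film of density \eqn{\rho} and thickness
#' \eqn{t}, an areal mass loading \eqn{\Delta m_A} much smaller than the
#' areal density \eqn{\rho t} shifts the resonance by
#' \deqn{\Delta f = -\frac{f_0}{2 \rho t}\,\Delta m_A:} direct in
#' \eqn{f_0}, inverse in both \eqn{\rho} and \eqn{t}. A warning is issued
#' when \eqn{\Delta m_A \ge 0.1\,\rho t}, where the small-load assumption
#' becomes questionable.
#'
#' @param spec a \linkS4class{ResonatorSpec} with \code{f0}, \code{rho} and
#'   \code{thickness} set.
#' @param load a \linkS4class{MassLoad} carrying \code{delta_mA} (or a total
#'   mass in ug, converted through the spec's active area).
#' @return frequency shift, Hz (<= 0).
#' @examples
#' filmShift(pvdfSpec(), massLoad(delta_mA = 1e-6)) # about -0.853 Hz
#' @export
filmShift <- function(spec, load) {
  .need(spec, c("f0", "rho", "thickness"))
  load <- .as_load(load, area_cm2 = spec@A)
  if (is.na(load@delta_mA)) {
    stop("load must carry an areal loading delta_mA ",
         "(give the spec an area to convert total mass)")
  }
  rt <- spec@rho * spec@thickness
  if (rt == 0) stop("rho * thickness must be nonzero")
  if (load@delta_mA >= 0.1 * rt) {
    warning(sprintf(
      "areal loading %.3g g/cm^2 is not small against rho*t = %.3g g/cm^2; ",
      load@delta_mA, rt), "the linear thin-film model may be inaccurate")
  }
  -spec@f0 * load@delta_mA / (2 * rt)
}

#' Quality factor from the half-power bandwidth (and back)
#'
#' \code{qualityFactor} computes \eqn{Q = f_0 / \mathrm{BW}};
#' \code{bandwidthFromQ} inverts it. Both require strictly positive inputs
#' and round-trip exactly.
#'
#' @param f0 resonant frequency, Hz.
#' @param bandwidth half-power (-3 dB) bandwidth, Hz.
#' @param q quality factor.
#' @return numeric scalar (dimensionless Q, or bandwidth in Hz).
#' @examples
#' round(qualityFactor(8500, 308), 1) # 27.6
#' @export
qualityFactor <- function(f0, bandwidth) {
  if (any(f0 <= 0) || any(bandwidth <= 0)) {
    stop("f0 and bandwidth must be > 0")
  }
  f0 / bandwidth
}

#' @rdname qualityFactor
#' @export
bandwidthFromQ <- function(f0, q) {
  if (any(f0 <= 0) || any(q <= 0)) stop("f0 and q must be > 0")
  f0 / q
}

#' Invert a frequency shift to a mass estimate
#'
#' Given a calibrated sensitivity \eqn{S_m > 0} (Hz/ug), the adsorbed mass
#' is \eqn{\Delta m = -\Delta f / S_m}.
#'
#' @param delta_f measured frequency shift, Hz.
#' @param sensitivity empirical sensitivity \eqn{S_m}, Hz/ug (positive), or
#'   a \linkS4class{SensitivityResult}.
#' @return mass, ug.
#' @export
invertMass <- function(delta_f, sensitivity) {
  if (is(sensitivity, "SensitivityResult")) {
    sensitivity <- if (!is.na(sensitivity@S_m)) sensitivity@S_m else sensitivity@S_M
  }
  if (length(sensitivity) != 1L || is.na(sensitivity) || sensitivity <= 0) {
    stop("sensitivity must be a single positive value (Hz/ug)")
  }
  -delta_f / sensitivity
}
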