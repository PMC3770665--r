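#' Maximal wall shear stress under orbital shaking
#'
#' First-order estimate of the maximal wall shear stress generated at the
#' bottom of a culture well by an orbital shaker,
#' `tau = a * sqrt(rho * eta * (2 * pi * f)^3)`. Inputs are accepted in the
#' units the assay is usually described in (cm, poise, g/ml, Hz) and
#' converted to SI internally; the result is in Pa. The relation ignores
#' fluid height and well radius, so it brackets rather than pinpoints the
#' true peak shear. `tau` scales linearly in the orbital radius and as
#' `f^(3/2)` in the frequency.
#'
#' @param frequency_hz orbital frequency f in Hz.
#' @param orbital_radius_cm orbital radius a in cm.
#' @param viscosity_poise dynamic viscosity eta in poise (1 P = 0.1 Pa s).
#' @param density_g_ml fluid density rho in g/ml.
#' @return Shear stress in Pa.
#' @examples
#' estimateMaxShear(2.2, 0.95, 0.01, 1.0)  # ~0.49 Pa
#' @export
estimateMaxShear <- function(frequency_hz, orbital_radius_cm,
                             viscosity_poise, density_g_ml) {
  pars <- c(frequency_hz, orbital_radius_cm, viscosity_poise, density_g_ml)
  if (any(!is.finite(pars)) || any(pars < 0))
    stop("all parameters must be finite and non-negative")
  if (any(pars[-2] <= 0))
    stop("frequency, viscosity and density must be positive")
  a <- orbital_radius_cm / 100          # cm   -> m
  eta <- viscosity_poise * 0.1          # P    -> Pa s
  rho <- density_g_ml * 1000            # g/ml -> kg/m^3
  a * sqrt(rho * eta * (2 * pi * frequency_hz)^3)
}

#' Relative expression by the 2^(-ddCt) method
#'
#' Standard relative quantification for real-time PCR: the target gene's
#' cycle threshold is normalized to a housekeeping gene within each
#' condition (`dCt = Ct_target - Ct_housekeeping`), the treated condition is
#' referenced to control (`ddCt = dCt_treated - dCt_control`), and the fold
#' change is `2^(-ddCt)`. Swapping treated and control returns the
#' reciprocal.
#'
#' @param ct_target_treated,ct_housekeeping_treated Ct values (cycles) in
#'   the treated condition.
#' @param ct_target_control,ct_housekeeping_control Ct values in the
#'   control condition.
#' @return Fold change (dimensionless).
#' @examples
#' ddctFoldChange(20, 15, 22, 15)  # 4
#' @export
ddctFoldChange <- function(ct_target_treated, ct_housekeeping_treated,
                           ct_target_control, ct_housekeeping_control) {
  cts <- c(ct_target_treated, ct_housekeeping_treated,
           ct_target_control, ct_housekeeping_control)
  if (any(!is.finite(cts)) || any(cts <= 0))
    stop("all Ct values must be finite and positive")
  ddct <- (ct_target_treated - ct_housekeeping_treated) -
    (ct_target_control - ct_housekeeping_control)
  2^(-ddct)
}
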