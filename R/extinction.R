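#' Hemoglobin extinction coefficients
#'
#' Molar extinction coefficients of oxy- (HbO) and deoxy-hemoglobin (HbR) at
#' the wavelengths used by common continuous-wave fNIRS devices, in
#' cm^-1/(moles/liter) (the HOMER \code{GetExtinctions} convention). These
#' constants scale the modified Beer-Lambert law that maps optical-density
#' changes to concentration changes.
#'
#' @return data frame with columns \code{wavelength}, \code{eps_hbo},
#'   \code{eps_hbr}; all entries positive.
#' @export
extinction_table <- function() {
  data.frame(
    wavelength = c(760, 785, 808, 830, 850),
    eps_hbo    = c(645, 787, 903, 1008, 1097),
    eps_hbr    = c(1669, 996.65, 804, 778, 781)
  )
}

extinction_for <- function(wavelengths, table = extinction_table()) {
  i <- match(wavelengths, table$wavelength)
  if (anyNA(i))
    abort_nirsisc(sprintf("extinction table lacks wavelength(s): %s",
                          paste(wavelengths[is.na(i)], collapse = ", ")),
                  "nirsisc_validation")
  table[i, , drop = FALSE]
}

#' Differential pathlength factor model
#'
#' Coefficients of the general age- and wavelength-dependent differential
#' pathlength factor (DPF) equation of Scholkmann and Wolf (2013),
#' \deqn{DPF(\lambda, A) = \alpha + \beta A^{\gamma} + \delta\lambda^3 +
#'   \epsilon\lambda^2 + \zeta\lambda}
#' with age \eqn{A} in years and wavelength \eqn{\lambda} in nm. The DPF
#' multiplies the geometric source-detector distance to account for the
#' longer scattered photon path through tissue. Stored as a plain list so
#' alternative fitted coefficient sets can be plugged in.
#'
#' @return list of coefficients \code{alpha}..\code{zeta}.
#' @references Scholkmann, F., & Wolf, M. (2013). General equation for the
#'   differential pathlength factor of the frontal human head depending on
#'   wavelength and age. Journal of Biomedical Optics, 18(10), 105004.
#' @export
dpf_model <- function() {
  list(alpha = 223.3, beta = 0.05624, gamma = 0.8493,
       delta = -5.723e-7, epsilon = 0.001245, zeta = -0.9025)
}

#' Compute the differential pathlength factor
#'
#' @param age participant age in years (0 < age < 120).
#' @param wavelength wavelength in nm (600 < wavelength < 1000).
#' @param model coefficient list from \code{\link{dpf_model}}.
#' @return positive dimensionless scalar (vectorized over inputs).
#' @examples
#' compute_dpf(23.3, 760)  # about 6.1
#' @export
compute_dpf <- function(age, wavelength, model = dpf_model()) {
  if (any(age <= 0) || any(age >= 120))
    abort_nirsisc("age must be in (0, 120) years", "nirsisc_parameter")
  if (any(wavelength <= 600) || any(wavelength >= 1000))
    abort_nirsisc("wavelength must be in (600, 1000) nm", "nirsisc_parameter")
  with(model,
       alpha + beta * age^gamma + delta * wavelength^3 +
         epsilon * wavelength^2 + zeta * wavelength)
}
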