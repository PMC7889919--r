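#' Physical and physiological constants registry
#'
#' Every constant used by the solvers lives here, so that a run can override
#' any of them through a single named list. Electromagnetic constants are
#' CODATA values; blood properties, the air-skin heat transfer coefficient and
#' the reference temperatures are the values standard in millimetre-wave skin
#' dosimetry models.
#'
#' @param overrides named list replacing individual defaults.
#' @return named list of constants:
#' \describe{
#'   \item{c0}{speed of light in vacuum, m s-1}
#'   \item{eps0}{vacuum permittivity, F m-1}
#'   \item{eta0}{free-space wave impedance, Ohm}
#'   \item{rho_blood}{blood mass density, kg m-3}
#'   \item{c_blood}{blood specific heat, J kg-1 degC-1}
#'   \item{h_conv}{air-skin convective heat transfer coefficient, W m-2 degC-1}
#'   \item{T_air}{ambient air temperature, degC}
#'   \item{T_blood}{arterial blood temperature, degC}
#'   \item{adult_age}{reference adult age, years, at which tissue hydration
#'     equals its adult value}
#'   \item{tbw_adult}{total body water at the reference adult age, L kg-1}
#'   \item{water_debye}{single-Debye parameters of liquid water at 37 degC
#'     (eps_s, eps_inf, tau_s) used for the free-water permittivity}
#' }
#' @export
dosimetry_constants <- function(overrides = list()) {
  const <- list(
    c0        = 299792458,
    eps0      = 8.8541878128e-12,
    eta0      = 376.730313668,
    rho_blood = 1050,
    c_blood   = 3617,
    h_conv    = 7,
    T_air     = 20,
    T_blood   = 37,
    adult_age = 35,
    tbw_adult = 0.60,
    water_debye = list(eps_s = 73.2, eps_inf = 5.2, tau_s = 6.5e-12)
  )
  if (length(overrides)) {
    stopifnot(is.list(overrides), !is.null(names(overrides)))
    unknown <- setdiff(names(overrides), names(const))
    if (length(unknown)) {
      stop("unknown constant override(s): ", paste(unknown, collapse = ", "))
    }
    const[names(overrides)] <- overrides
  }
  const
}

#' Real part of the free-water permittivity
#'
#' Single-Debye model eps'(f) = eps_inf + (eps_s - eps_inf) / (1 + (2*pi*f*tau)^2)
#' evaluated with the water parameters of the constants registry (37 degC).
#' This supplies the eps'_W entering the Lichtenecker hydration model; any
#' caller may override it with tabulated values instead.
#'
#' @param frequency Hz.
#' @param const constants registry, see [dosimetry_constants()].
#' @return dimensionless eps'_W.
#' @export
water_permittivity_real <- function(frequency, const = dosimetry_constants()) {
  stopifnot(is.numeric(frequency), all(frequency > 0))
  p <- const$water_debye
  wt <- 2 * pi * frequency * p$tau_s
  p$eps_inf + (p$eps_s - p$eps_inf) / (1 + wt^2)
}
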