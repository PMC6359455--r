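# Physical constants and model coefficients, collected in one place.
# All energies J/mol, volumes cm^3/mol unless noted.
.psp_const <- list(
  R          = 8.314,    # gas constant, J/(mol K)
  T_std      = 298.15,   # default temperature for bulk properties, K
  T_igc      = 303.15,   # 30 C column temperature used for IGC work, K
  T_ice      = 273.15,   # reference temperature for carrier-gas flow, K
  seg_vol    = 0.213,    # McGowan volume of one lattice segment, (cm^3/mol)/100
  disp_slope = 3.1,      # dispersion contribution per unit McGowan volume
  E_HB_coef  = 30450,    # J/mol per sqrt(A*B): hydrogen-bond energy scale
  S_HB_coef  = 35.1,     # J/(K mol) per sqrt(A*B): hydrogen-bond entropy scale
  psp_scale  = 100,      # sqrt(J/cm^3 per descriptor/Vm) -> MPa^0.5
  res_scale  = 10000     # prefactor of the quadratic residual terms, J/cm^3 scale
)

#' Model constants
#'
#' Returns the registry of physical constants and model coefficients used
#' throughout the package (gas constant, segment volume 0.213, the
#' hydrogen-bond energy/entropy coefficients 30450 and 35.1, default
#' temperatures).
#'
#' @return A named list.
#' @export
#' @examples
#' psp_constants()$seg_vol
psp_constants <- function() .psp_const
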