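#' Convert wavelengths to Raman shifts (Stokes lines)
#'
#' Converts scattered wavelengths (nm) to Raman shifts (cm^-1) relative to
#' the excitation line: `shift = 1e7 * (1/excitation_nm - 1/lambda)`.
#' Wavelengths longer than the excitation give positive (Stokes) shifts.
#' The transform is strictly increasing, so band ordering is preserved.
#'
#' @param wavelength_nm Numeric vector of wavelengths, nm (all positive).
#' @param excitation_nm Excitation laser wavelength, nm.
#' @return Numeric vector of Raman shifts, cm^-1.
#' @examples
#' to_raman_shift(785, 785)      # 0 at the excitation line
#' to_raman_shift(823.8, 785)    # ~600 cm^-1
#' @export
to_raman_shift <- function(wavelength_nm, excitation_nm = 785) {
  if (any(!is.finite(wavelength_nm)) || any(wavelength_nm <= 0)) {
    abort("wavelengths must be positive and finite",
          class = "sors_input_error")
  }
  if (length(excitation_nm) != 1L || excitation_nm <= 0) {
    abort("`excitation_nm` must be a single positive value",
          class = "sors_input_error")
  }
  1e7 * (1 / excitation_nm - 1 / wavelength_nm)
}

#' Convert Raman shifts back to wavelengths
#'
#' Inverse of [to_raman_shift()]: `lambda = 1 / (1/excitation_nm -
#' shift * 1e-7)` nm. Used by the simulator to lay its native bands on a
#' wavelength axis so the shift conversion step is genuinely exercised.
#'
#' @param shift_cm1 Numeric vector of Raman shifts, cm^-1.
#' @param excitation_nm Excitation laser wavelength, nm.
#' @return Numeric vector of wavelengths, nm.
#' @export
shift_to_wavelength <- function(shift_cm1, excitation_nm = 785) {
  inv <- 1 / excitation_nm - shift_cm1 * 1e-7
  if (any(inv <= 0)) {
    abort("shift too large for this excitation wavelength",
          class = "sors_input_error")
  }
  1 / inv
}
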