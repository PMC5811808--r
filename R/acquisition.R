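#' Acquisition parameters for a simulated dimension
#'
#' Collects everything the simulator needs to turn a line list into a
#' digitised spectrum: the spectral width (which fixes the dwell time
#' `dw = 1/sw_hz`), the number of complex points, the decay rate `r2`
#' (full width at half maximum = `r2 / pi` Hz for the resulting Lorentzian),
#' the carrier position and spectrometer frequency of the simulated nucleus
#' (for ppm conversion), and the splitting-enhancement multipliers.
#'
#' The enhancement multipliers `k_cc` and `k_cn` count the extra spin-echo
#' increments appended per t1 increment; because those delays are multiples
#' of the dwell time they are restricted to non-negative integers, and the
#' apparent couplings become `(1 + k) * J` while chemical shifts are
#' unchanged. `k_cn` scales carbon-nitrogen couplings independently of
#' `k_cc` (the 15N refocusing pulse is optional in the experiment).
#'
#' @param sw_hz Spectral width in Hz.
#' @param n_points Number of complex time-domain points (>= 64).
#' @param r2 Decay rate in Hz (`FWHM = r2/pi`).
#' @param carrier_ppm Carrier (centre of the spectrum) in ppm.
#' @param field_mhz Larmor frequency of the simulated nucleus in MHz
#'   (converts ppm to Hz).
#' @param nucleus One of `"13C"`, `"1H"`, `"15N"`.
#' @param k_cc,k_cn Non-negative integer enhancement multipliers for C-C and
#'   C-N couplings.
#' @param zero_fill Zero-filling factor (>= 1); the frequency grid has
#'   `n_points * zero_fill` points.
#' @param dispersive_fraction Lineshape admixture in 0-1: 0 gives a pure
#'   absorptive Lorentzian, larger values mix in the dispersive component
#'   (a calibration knob for gradient quadrature lineshape effects).
#' @return An object of class `acq_params`.
#' @examples
#' acq_params(sw_hz = 2000, n_points = 1024, r2 = 3,
#'            carrier_ppm = 18.8, field_mhz = 150.9)
#' @export
acq_params <- function(sw_hz, n_points, r2 = 3, carrier_ppm = 0,
                       field_mhz = 150.9, nucleus = c("13C", "1H", "15N"),
                       k_cc = 0L, k_cn = 0L, zero_fill = 2L,
                       dispersive_fraction = 0) {
  nucleus <- match.arg(nucleus)
  if (!is_number(sw_hz) || sw_hz <= 0) stop_validation("`sw_hz` must be a positive number")
  if (!is_count(n_points) || n_points < 64) {
    stop_validation("`n_points` must be an integer >= 64")
  }
  if (!is_number(r2) || r2 <= 0) stop_validation("`r2` must be > 0")
  if (!is_count(k_cc) || !is_count(k_cn)) {
    stop_validation("`k_cc` and `k_cn` must be non-negative integers (extra echo increments per dwell)")
  }
  if (!is_count(zero_fill) || zero_fill < 1) stop_validation("`zero_fill` must be an integer >= 1")
  if (!is_number(dispersive_fraction) || dispersive_fraction < 0 || dispersive_fraction > 1) {
    stop_validation("`dispersive_fraction` must be in [0, 1]")
  }
  structure(
    list(sw_hz = sw_hz, n_points = as.integer(n_points), r2 = r2,
         carrier_ppm = carrier_ppm, field_mhz = field_mhz, nucleus = nucleus,
         k_cc = as.integer(k_cc), k_cn = as.integer(k_cn),
         zero_fill = as.integer(zero_fill),
         dispersive_fraction = dispersive_fraction),
    class = "acq_params"
  )
}

#' @export
print.acq_params <- function(x, ...) {
  cat(sprintf(
    "<acq_params> %s: sw %.6g Hz, %d pts (x%d zero-fill), r2 %.3g Hz (FWHM %.3g Hz)\n",
    x$nucleus, x$sw_hz, x$n_points, x$zero_fill, x$r2, x$r2 / pi))
  cat(sprintf("  carrier %.4g ppm at %.6g MHz; k_cc %d (E=%d), k_cn %d (E=%d)\n",
              x$carrier_ppm, x$field_mhz, x$k_cc, x$k_cc + 1L, x$k_cn, x$k_cn + 1L))
  if (x$dispersive_fraction > 0) {
    cat(sprintf("  dispersive fraction %.3g\n", x$dispersive_fraction))
  }
  invisible(x)
}

#' Modify acquisition parameters
#'
#' Returns a copy of `acq` with the named fields replaced (re-validated).
#' @param acq An [acq_params()].
#' @param ... Fields to replace, e.g. `k_cc = 3`, `n_points = 512`.
#' @return An `acq_params` object.
#' @export
update_acq <- function(acq, ...) {
  stopifnot(inherits(acq, "acq_params"))
  fields <- utils::modifyList(unclass(acq), list(...))
  do.call(acq_params, fields)
}

dwell_time <- function(acq) 1 / acq$sw_hz
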