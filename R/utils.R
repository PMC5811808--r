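#' @importFrom rlang abort warn .data %||%
#' @importFrom tibble tibble as_tibble
#' @keywords internal
"_PACKAGE"

# consistent error class so the CLI can map validation vs numerical failures
stop_validation <- function(msg) {
  abort(msg, class = "hsqctracer_validation")
}

stop_numerical <- function(msg) {
  abort(msg, class = "hsqctracer_numerical")
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

is_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# fftshift for even or odd length n: maps DFT bin order to ascending frequency
fft_shift <- function(x) {
  n <- length(x)
  h <- ceiling(n / 2)
  c(x[(h + 1L):n], x[1:h])
}

# ascending frequency axis (Hz, relative to carrier) for an n-point grid
shifted_freq_axis <- function(n, sw_hz) {
  df <- sw_hz / n
  h <- ceiling(n / 2)
  df * c(seq.int(h - n, -1L), seq.int(0L, h - 1L))
}
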