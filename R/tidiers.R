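#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an isotopomer fit
#'
#' @param x An `isotopomer_fit` from [fit_fractions()].
#' @param ... Unused.
#' @return One row per candidate isotopomer: `name`, `percent`, `sigma`,
#'   `coef`.
#' @export
tidy.isotopomer_fit <- function(x, ...) {
  x$fractions
}

#' One-row summary of an isotopomer fit
#'
#' @param x An `isotopomer_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the overall scale, residual RMS, nuisance
#'   parameters, enhancement multipliers and problem size.
#' @export
glance.isotopomer_fit <- function(x, ...) {
  tibble(
    scale = x$scale,
    residual_rms = x$residual_rms,
    r2 = x$nuisance$r2,
    offset_hz = x$nuisance$offset_hz,
    k_cc = x$k_cc,
    k_cn = x$k_cn,
    n_points = x$n,
    n_candidates = nrow(x$fractions)
  )
}
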