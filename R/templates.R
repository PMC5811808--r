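#' Built-in metabolite templates
#'
#' Ready-made spin-system templates for the metabolites most used in
#' 13C/15N tracer work. Chemical shifts are typical literature values for
#' aqueous metabolite extracts near pH 7 and the coupling constants are
#' typical one-bond / long-range magnitudes; both are starting points meant
#' to be edited for a given sample, not measured constants of this package.
#'
#' * `template_alanine()` - C1 (carboxyl, no attached proton), C2 (Halpha),
#'   C3 (methyl) and the amino nitrogen; 1J(C2,C3) = 34.9 Hz,
#'   1J(C1,C2) = 54 Hz, 1J(C2,N) = 5.5 Hz, 2J(C3,N) = 0.
#' * `template_lactate()` - C2 and C3 (methyl); 1J(C2,C3) = 37 Hz.
#' * `template_glucose_c456()` - the C4/C5/C6 fragment of glucose;
#'   1J(C5,C6) = 43 Hz, 1J(C4,C5) = 38 Hz and the long-range
#'   J(C4,C6) = 4 Hz that becomes visible under splitting enhancement.
#'
#' @return A [spin_system()].
#' @name builtin_templates
NULL

#' @rdname builtin_templates
#' @export
template_alanine <- function() {
  spin_system(
    name = "alanine",
    carbons = tibble(
      site = c(1L, 2L, 3L),
      carbon_ppm = c(176.5, 53.2, 18.8),
      proton_ppm = c(NA_real_, 3.77, 1.47),
      n_h = c(0L, 1L, 3L),
      j_ch = c(145, 145, 130)
    ),
    nitrogens = tibble(site = "N", nitrogen_ppm = 40.0, j_hn2 = 1.5),
    j_cc = tibble(site_a = c(1L, 2L), site_b = c(2L, 3L), hz = c(54, 34.9)),
    j_cn = tibble(carbon = c(2L, 3L), nitrogen = c("N", "N"), hz = c(5.5, 0))
  )
}

#' @rdname builtin_templates
#' @export
template_lactate <- function() {
  spin_system(
    name = "lactate",
    carbons = tibble(
      site = c(2L, 3L),
      carbon_ppm = c(69.3, 22.9),
      proton_ppm = c(4.11, 1.32),
      n_h = c(1L, 3L),
      j_ch = c(145, 128)
    ),
    j_cc = tibble(site_a = 2L, site_b = 3L, hz = 37)
  )
}

#' @rdname builtin_templates
#' @export
template_glucose_c456 <- function() {
  spin_system(
    name = "glucose_c456",
    carbons = tibble(
      site = c(4L, 5L, 6L),
      carbon_ppm = c(70.9, 72.1, 63.2),
      proton_ppm = c(3.40, 3.45, 3.72),
      n_h = c(1L, 1L, 2L),
      j_ch = c(145, 145, 143)
    ),
    j_cc = tibble(site_a = c(4L, 5L, 4L), site_b = c(5L, 6L, 6L),
                  hz = c(38, 43, 4))
  )
}

#' Look up a built-in template by name
#' @param name One of `"alanine"`, `"lactate"`, `"glucose_c456"`.
#' @return A [spin_system()].
#' @export
builtin_template <- function(name) {
  switch(name,
    alanine = template_alanine(),
    lactate = template_lactate(),
    glucose_c456 = template_glucose_c456(),
    stop_validation(sprintf("unknown built-in template '%s'", name))
  )
}
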