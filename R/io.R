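#' Serialise spin systems and mixtures to JSON
#'
#' Templates are stored as
#' `{name, carbons[], nitrogens[], j_cc[], j_cn[]}` where the coupling
#' tables are arrays of `{site_a, site_b, hz}` / `{carbon, nitrogen, hz}`
#' triples. Mixtures are stored as
#' `{template, entries: [{name, carbons[], nitrogens[], fraction,
#' cn_active}]}` with the labelled site numbers listed explicitly.
#'
#' @param template A [spin_system()].
#' @param path Output file.
#' @return `write_spin_system()`/`write_mixture()` return `path` invisibly;
#'   the readers return the reconstructed object.
#' @export
write_spin_system <- function(template, path) {
  assert_spin_system(template)
  jsonlite::write_json(list(
    name = template$name,
    carbons = template$carbons,
    nitrogens = template$nitrogens,
    j_cc = template$j_cc,
    j_cn = template$j_cn
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_spin_system
#' @export
read_spin_system <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  none <- function(tbl) is.null(tbl) || !NROW(tbl)
  spin_system(
    name = x$name,
    carbons = x$carbons,
    nitrogens = if (none(x$nitrogens)) NULL else x$nitrogens,
    j_cc = if (none(x$j_cc)) NULL else x$j_cc,
    j_cn = if (none(x$j_cn)) NULL else x$j_cn
  )
}

#' @rdname write_spin_system
#' @param mixture An [isotopomer_mixture()].
#' @export
write_mixture <- function(mixture, path) {
  template <- mixture_template(mixture)
  cs <- template$carbons
  ns <- template$nitrogens
  entries <- purrr::map(seq_len(nrow(mixture)), function(r) {
    list(
      name = mixture$name[r],
      carbons = cs$site[mixture$carbon_labels[[r]]],
      nitrogens = ns$site[mixture$nitrogen_labels[[r]]],
      fraction = mixture$fraction[r],
      cn_active = mixture$cn_active[r]
    )
  })
  jsonlite::write_json(list(template = template$name, entries = entries),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_spin_system
#' @export
read_mixture <- function(path, template) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(x$template, template$name)) {
    warn(sprintf("mixture file was written for template '%s', reading against '%s'",
                 x$template, template$name))
  }
  entries <- purrr::map(x$entries, function(e) {
    mix_entry(e$fraction,
              carbons = unlist(e$carbons) %||% integer(),
              nitrogens = unlist(e$nitrogens) %||% character(),
              cn_active = e$cn_active %||% TRUE)
  })
  isotopomer_mixture(template, entries)
}
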