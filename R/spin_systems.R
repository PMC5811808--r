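#' Define a metabolite spin-system template
#'
#' A spin system describes the NMR-relevant part of a metabolite fragment:
#' its carbon sites (chemical shifts of the carbon and of the attached
#' proton(s), proton multiplicity, one-bond C-H coupling), optional nitrogen
#' sites, and the scalar coupling network between sites. Templates are the
#' static input shared by the simulator, the fitting routines and the
#' synthetic-data generators.
#'
#' Site numbering follows IUPAC metabolite carbon numbering (C1 = carboxyl /
#' anomeric carbon), so e.g. the alanine methyl carbon is site 3. Carbon
#' sites without attached protons (`n_h = 0`) give no direct HSQC signal;
#' they contribute only through couplings to protonated neighbours.
#' Coupling constants are stored signed but only their magnitude enters the
#' simulation (signs are unobservable in this experiment class).
#'
#' @param name Template name (e.g. `"alanine"`).
#' @param carbons Data frame with one row per carbon site and columns
#'   `site` (positive integer), `carbon_ppm`, `proton_ppm`, `n_h`
#'   (0-3 attached protons) and optionally `j_ch` (one-bond 1H-13C coupling
#'   in Hz, default 145).
#' @param nitrogens Optional data frame with columns `site` (character
#'   label), `nitrogen_ppm`, and optionally `j_hn2` (long-range 2J(H,N)
#'   coupling in Hz used for long-range 1H,15N detection).
#' @param j_cc Optional data frame of carbon-carbon couplings with columns
#'   `site_a`, `site_b`, `hz` (one row per unordered pair).
#' @param j_cn Optional data frame of carbon-nitrogen couplings with columns
#'   `carbon`, `nitrogen`, `hz`.
#'
#' @return An object of class `spin_system`: a list with tibble fields
#'   `carbons`, `nitrogens`, `j_cc`, `j_cn` plus `name`.
#' @seealso [validate_spin_system()], [isotopomer_mixture()],
#'   [template_alanine()]
#' @examples
#' ala <- template_alanine()
#' validate_spin_system(ala)
#' @export
spin_system <- function(name, carbons, nitrogens = NULL, j_cc = NULL, j_cn = NULL) {
  carbons <- as_tibble(carbons)
  if (!"j_ch" %in% names(carbons)) carbons$j_ch <- 145
  carbons <- carbons[, c("site", "carbon_ppm", "proton_ppm", "n_h", "j_ch")]
  carbons$site <- as.integer(carbons$site)
  carbons$n_h <- as.integer(carbons$n_h)

  if (is.null(nitrogens)) {
    nitrogens <- tibble(site = character(), nitrogen_ppm = double(), j_hn2 = double())
  } else {
    nitrogens <- as_tibble(nitrogens)
    if (!"j_hn2" %in% names(nitrogens)) nitrogens$j_hn2 <- 0
    nitrogens$site <- as.character(nitrogens$site)
    nitrogens <- nitrogens[, c("site", "nitrogen_ppm", "j_hn2")]
  }
  if (is.null(j_cc)) {
    j_cc <- tibble(site_a = integer(), site_b = integer(), hz = double())
  } else {
    j_cc <- as_tibble(j_cc)
    j_cc$site_a <- as.integer(j_cc$site_a)
    j_cc$site_b <- as.integer(j_cc$site_b)
  }
  if (is.null(j_cn)) {
    j_cn <- tibble(carbon = integer(), nitrogen = character(), hz = double())
  } else {
    j_cn <- as_tibble(j_cn)
    j_cn$carbon <- as.integer(j_cn$carbon)
    j_cn$nitrogen <- as.character(j_cn$nitrogen)
  }
  structure(
    list(name = name, carbons = carbons, nitrogens = nitrogens,
         j_cc = j_cc, j_cn = j_cn),
    class = "spin_system"
  )
}

#' @export
print.spin_system <- function(x, ...) {
  cat("<spin_system> ", x$name, "\n", sep = "")
  cat(" carbons:\n")
  print(x$carbons, n = Inf)
  if (nrow(x$nitrogens)) {
    cat(" nitrogens:\n")
    print(x$nitrogens, n = Inf)
  }
  if (nrow(x$j_cc)) {
    cat(" J(C,C) [Hz]:\n")
    print(x$j_cc, n = Inf)
  }
  if (nrow(x$j_cn)) {
    cat(" J(C,N) [Hz]:\n")
    print(x$j_cn, n = Inf)
  }
  invisible(x)
}

#' Check a spin-system template against its invariants
#'
#' Reports (never throws) all violations of the template contract:
#' positive site ids, proton counts in 0-3, positive one-bond C-H couplings,
#' a symmetric C-C coupling map without self-couplings, finite coupling
#' values, and coupling entries that only reference existing sites.
#'
#' @param template A [spin_system()].
#' @return A character vector of human-readable violations; empty when the
#'   template is well formed.
#' @export
validate_spin_system <- function(template) {
  v <- character()
  cs <- template$carbons
  ns <- template$nitrogens
  if (!nrow(cs)) v <- c(v, "template has no carbon sites")
  if (anyDuplicated(cs$site)) v <- c(v, "duplicate carbon site ids")
  if (any(cs$site < 1, na.rm = TRUE)) v <- c(v, "carbon site ids must be positive")
  if (any(cs$n_h < 0 | cs$n_h > 3, na.rm = TRUE)) {
    v <- c(v, "n_h (attached protons) must be between 0 and 3")
  }
  if (any(cs$j_ch <= 0, na.rm = TRUE)) v <- c(v, "j_ch must be > 0")
  if (anyDuplicated(ns$site)) v <- c(v, "duplicate nitrogen site ids")

  jcc <- template$j_cc
  if (nrow(jcc)) {
    if (any(!is.finite(jcc$hz))) v <- c(v, "non-finite J(C,C) coupling")
    self <- jcc$site_a == jcc$site_b
    if (any(self)) {
      v <- c(v, sprintf("J(C,C) self-coupling on site %d", jcc$site_a[self][1]))
    }
    missing <- !(jcc$site_a %in% cs$site) | !(jcc$site_b %in% cs$site)
    if (any(missing)) {
      v <- c(v, sprintf("J(C,C) entry (%d,%d) references a missing carbon site",
                        jcc$site_a[missing][1], jcc$site_b[missing][1]))
    }
    # symmetry: if both orientations of a pair are present they must agree
    key <- paste(pmin(jcc$site_a, jcc$site_b), pmax(jcc$site_a, jcc$site_b))
    for (k in unique(key[duplicated(key)])) {
      hz <- jcc$hz[key == k]
      if (length(unique(hz)) > 1L) {
        v <- c(v, sprintf("asymmetric J(C,C) map for site pair (%s)",
                          gsub(" ", ",", k)))
      }
    }
  }
  jcn <- template$j_cn
  if (nrow(jcn)) {
    if (any(!is.finite(jcn$hz))) v <- c(v, "non-finite J(C,N) coupling")
    if (any(!(jcn$carbon %in% cs$site))) {
      v <- c(v, "J(C,N) entry references a missing carbon site")
    }
    if (any(!(jcn$nitrogen %in% ns$site))) {
      v <- c(v, "J(C,N) entry references a missing nitrogen site")
    }
  }
  v
}

assert_spin_system <- function(template) {
  if (!inherits(template, "spin_system")) {
    stop_validation("`template` must be a spin_system object")
  }
  v <- validate_spin_system(template)
  if (length(v)) {
    stop_validation(c("invalid spin system:", stats::setNames(v, rep("x", length(v)))))
  }
  invisible(template)
}

# |J(C,C)| between two carbon sites (0 when uncoupled)
j_cc_between <- function(template, i, j) {
  jcc <- template$j_cc
  hit <- (jcc$site_a == i & jcc$site_b == j) | (jcc$site_a == j & jcc$site_b == i)
  if (!any(hit)) return(0)
  jcc$hz[which(hit)[1]]
}

# |J(C,N)| between a carbon site and a nitrogen site (0 when uncoupled)
j_cn_between <- function(template, carbon, nitrogen) {
  jcn <- template$j_cn
  hit <- jcn$carbon == carbon & jcn$nitrogen == nitrogen
  if (!any(hit)) return(0)
  jcn$hz[which(hit)[1]]
}

#' Canonical bracket name for an isotopomer
#'
#' Produces the deterministic, sorted-position bracket notation used
#' throughout tracer NMR, e.g. `"[3-13C]"`, `"[2,3-13C]"`, `"[U-13C]"`,
#' `"[U-13C,15N]"`. Uniform labelling of an element collapses to the `U-`
#' form; when every carbon and every nitrogen is labelled the combined
#' `[U-13C,15N]` form is used. A fully unlabelled species is named
#' `"[unlabelled]"`. The name is a pure function of the label vectors, and
#' distinct label vectors always map to distinct names.
#'
#' @param carbon_labels Logical vector, `TRUE` for 13C, one per carbon site
#'   of `template` (in template row order).
#' @param nitrogen_labels Logical vector, `TRUE` for 15N, one per nitrogen
#'   site (may be omitted for carbon-only templates).
#' @param template A [spin_system()].
#' @return A single character string.
#' @examples
#' ala <- template_alanine()
#' canonical_isotopomer_name(c(FALSE, FALSE, TRUE), FALSE, ala)
#' @export
canonical_isotopomer_name <- function(carbon_labels, nitrogen_labels = NULL, template) {
  cs <- template$carbons
  ns <- template$nitrogens
  if (is.null(nitrogen_labels)) nitrogen_labels <- rep(FALSE, nrow(ns))
  carbon_labels <- as.logical(carbon_labels)
  nitrogen_labels <- as.logical(nitrogen_labels)
  if (length(carbon_labels) != nrow(cs)) {
    stop_validation("`carbon_labels` length does not match the template's carbon sites")
  }
  if (length(nitrogen_labels) != nrow(ns)) {
    stop_validation("`nitrogen_labels` length does not match the template's nitrogen sites")
  }
  if (!any(carbon_labels) && !any(nitrogen_labels)) return("[unlabelled]")

  all_c <- nrow(cs) > 0 && all(carbon_labels)
  all_n <- nrow(ns) > 0 && all(nitrogen_labels)
  if (all_c && all_n) return("[U-13C,15N]")

  parts <- character()
  if (any(carbon_labels)) {
    parts <- c(parts, if (all_c) "U-13C" else {
      paste0(paste(sort(cs$site[carbon_labels]), collapse = ","), "-13C")
    })
  }
  if (any(nitrogen_labels)) {
    parts <- c(parts, if (all_n) "U-15N" else {
      paste0(paste(sort(ns$site[nitrogen_labels]), collapse = ","), "-15N")
    })
  }
  paste0("[", paste(parts, collapse = ","), "]")
}

#' Enumerate all isotopomers of a template
#'
#' Generates every label pattern over the scoped element(s) - the candidate
#' basis for isotopomer fitting. With `n` scoped sites the result has
#' exactly `2^n` rows, in a deterministic order (the first scoped site
#' toggles fastest). Refuses more than 20 scoped sites.
#'
#' @param template A [spin_system()].
#' @param elements Which elements to enumerate over: subset of
#'   `c("carbon", "nitrogen")`.
#' @return A tibble with columns `name`, `carbon_labels`, `nitrogen_labels`
#'   (the label columns are list-columns of logical vectors).
#' @examples
#' enumerate_isotopomers(template_alanine(), "carbon")
#' @export
enumerate_isotopomers <- function(template, elements = c("carbon", "nitrogen")) {
  assert_spin_system(template)
  elements <- match.arg(elements, c("carbon", "nitrogen"), several.ok = TRUE)
  n_c <- nrow(template$carbons)
  n_n <- nrow(template$nitrogens)
  scope_c <- if ("carbon" %in% elements) n_c else 0L
  scope_n <- if ("nitrogen" %in% elements) n_n else 0L
  n_scoped <- scope_c + scope_n
  if (n_scoped > 20L) {
    stop_validation(sprintf(
      "refusing to enumerate 2^%d isotopomers (more than 20 scoped sites)", n_scoped))
  }
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), n_scoped), KEEP.OUT.ATTRS = FALSE)
  if (n_scoped == 0L) grid <- data.frame(row.names = 1L)
  rows <- purrr::map(seq_len(nrow(grid)), function(r) {
    flags <- as.logical(grid[r, , drop = TRUE])
    cl <- rep(FALSE, n_c)
    nl <- rep(FALSE, n_n)
    if (scope_c) cl <- flags[seq_len(scope_c)]
    if (scope_n) nl <- flags[scope_c + seq_len(scope_n)]
    tibble(
      name = canonical_isotopomer_name(cl, nl, template),
      carbon_labels = list(cl),
      nitrogen_labels = list(nl)
    )
  })
  dplyr::bind_rows(rows)
}

#' Build one mixture entry
#'
#' Convenience constructor for [isotopomer_mixture()]: identifies an
#' isotopomer by the site numbers that carry the label.
#'
#' @param fraction Molar fraction of this species (0-1).
#' @param carbons Integer vector of 13C-labelled carbon site numbers
#'   (empty for none).
#' @param nitrogens Character (or integer) vector of 15N-labelled nitrogen
#'   site labels.
#' @param cn_active Whether this species' C-N couplings are resolvable
#'   (`FALSE` models a sub-population whose C-N splitting is below the
#'   linewidth; it only affects nitrogen-coupled simulations).
#' @return A list consumed by [isotopomer_mixture()].
#' @export
mix_entry <- function(fraction, carbons = integer(), nitrogens = character(),
                      cn_active = TRUE) {
  list(fraction = fraction, carbons = as.integer(carbons),
       nitrogens = as.character(nitrogens), cn_active = isTRUE(cn_active))
}

#' Define an isotopomer mixture
#'
#' A mixture is the ground-truth labelling state of a metabolite: a set of
#' isotopomers with molar fractions that sum to 1. It is represented as a
#' tibble (one row per species) carrying the template as an attribute, so
#' it pipes directly into the simulators and fitters.
#'
#' @param template A [spin_system()].
#' @param ... [mix_entry()] objects (or a single list of them).
#' @return A tibble of class `isotopomer_mixture` with columns `name`,
#'   `fraction`, `carbon_labels`, `nitrogen_labels`, `cn_active`.
#' @examples
#' ala <- template_alanine()
#' isotopomer_mixture(ala, mix_entry(0.121, carbons = 3),
#'                    mix_entry(0.879, carbons = 2:3))
#' @export
isotopomer_mixture <- function(template, ...) {
  assert_spin_system(template)
  entries <- list(...)
  if (length(entries) == 1L && is.list(entries[[1]]) && is.null(entries[[1]]$fraction)) {
    entries <- entries[[1]]
  }
  if (!length(entries)) stop_validation("a mixture needs at least one entry")
  cs <- template$carbons
  ns <- template$nitrogens
  rows <- purrr::map(entries, function(e) {
    if (!all(e$carbons %in% cs$site)) {
      stop_validation("mixture entry labels a carbon site not in the template")
    }
    if (!all(e$nitrogens %in% ns$site)) {
      stop_validation("mixture entry labels a nitrogen site not in the template")
    }
    cl <- cs$site %in% e$carbons
    nl <- ns$site %in% e$nitrogens
    tibble(
      name = canonical_isotopomer_name(cl, nl, template),
      fraction = as.numeric(e$fraction),
      carbon_labels = list(cl),
      nitrogen_labels = list(nl),
      cn_active = e$cn_active %||% TRUE
    )
  })
  out <- dplyr::bind_rows(rows)
  if (any(out$fraction < 0)) stop_validation("mixture fractions must be >= 0")
  if (abs(sum(out$fraction) - 1) > 1e-9) {
    stop_validation(sprintf("mixture fractions must sum to 1 (got %.12g)",
                            sum(out$fraction)))
  }
  if (anyDuplicated(paste(out$name, out$cn_active))) {
    stop_validation("mixture isotopomers must be unique")
  }
  new_mixture(out, template)
}

new_mixture <- function(tbl, template) {
  structure(as_tibble(tbl),
            template = template,
            class = c("isotopomer_mixture", class(as_tibble(tbl))))
}

#' Extract the spin-system template attached to an object
#' @param x An `isotopomer_mixture` or `basis_set`.
#' @return The [spin_system()] the object was built from.
#' @export
mixture_template <- function(x) attr(x, "template", exact = TRUE)
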