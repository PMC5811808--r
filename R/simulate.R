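#' Apparent splitting under J-coupling splitting enhancement
#'
#' Appending a spin echo whose delays grow by `k` dwell times per t1
#' increment lets the coupling evolve `1 + k` times faster than the chemical
#' shift, so a coupling `J` appears as `(1 + k) * J` in the transformed
#' spectrum (a delay of `3*dw` gives a four-fold enhancement).
#'
#' @param j Coupling constant in Hz (>= 0).
#' @param k Non-negative integer echo increment per dwell time.
#' @return Apparent splitting in Hz.
#' @examples
#' apparent_splitting(35, 3) # 140
#' @export
apparent_splitting <- function(j, k) {
  if (any(j < 0)) stop_validation("`j` must be >= 0")
  if (!all(vapply(k, is_count, logical(1)))) {
    stop_validation("`k` must be a non-negative integer")
  }
  (1 + k) * j
}

# assemble the line list for one carbon trace
carbon_trace_lines <- function(template, mixture, observed_site, acq) {
  cs <- template$carbons
  row <- which(cs$site == observed_site)
  if (!length(row)) {
    stop_validation(sprintf("site %s is not a carbon site of '%s'",
                            observed_site, template$name))
  }
  if (cs$n_h[row] < 1) {
    stop_validation(sprintf(
      "HSQC-invisible site: carbon %d of '%s' has no attached protons",
      observed_site, template$name))
  }
  omega <- (cs$carbon_ppm[row] - acq$carrier_ppm) * acq$field_mhz
  e_cc <- 1 + acq$k_cc
  e_cn <- 1 + acq$k_cn
  ns <- template$nitrogens
  lines <- list()
  for (r in seq_len(nrow(mixture))) {
    cl <- mixture$carbon_labels[[r]]
    if (!cl[row]) next  # 12C at the observed site: invisible in the HSQC
    nl <- mixture$nitrogen_labels[[r]]
    cn_active <- if ("cn_active" %in% names(mixture)) mixture$cn_active[r] else TRUE
    mods <- list()
    for (p in seq_len(nrow(cs))) {
      if (p == row || !cl[p]) next
      j <- j_cc_between(template, observed_site, cs$site[p])
      if (abs(j) > 0) mods[[length(mods) + 1L]] <- c(abs(j), e_cc)
    }
    if (cn_active && nrow(ns)) {
      for (q in seq_len(nrow(ns))) {
        if (!nl[q]) next
        j <- j_cn_between(template, observed_site, ns$site[q])
        if (abs(j) > 0) mods[[length(mods) + 1L]] <- c(abs(j), e_cn)
      }
    }
    mods <- if (length(mods)) {
      as.data.frame(do.call(rbind, mods)) |> stats::setNames(c("j_hz", "e"))
    } else NULL
    lines[[length(lines) + 1L]] <- list(freq_hz = omega,
                                        amp = mixture$fraction[r],
                                        mods = mods)
  }
  lines
}

#' Simulate the 13C trace of a splitting-enhanced HSQC multiplet
#'
#' Simulates the indirect-dimension (13C) signal of a 1H,13C-HSQC experiment
#' at the observed carbon site under the weak-coupling spin-echo model: each
#' isotopomer that carries 13C at the observed site contributes a
#' time-domain component with amplitude equal to its molar fraction,
#' frequency equal to the site's offset from the carrier, cosine amplitude
#' modulation `cos(pi * J * (1 + k) * t)` for every coupled 13C-labelled
#' carbon (and `cos(pi * J_CN * (1 + k_cn) * t)` for every coupled
#' 15N-labelled nitrogen), and exponential decay `exp(-r2 t)`. The summed
#' FID is first-point corrected, zero-filled and Fourier transformed to an
#' absorptive (or dispersive-admixed) spectrum.
#'
#' Isotopomers with 12C at the observed site contribute nothing (the HSQC's
#' implicit 12C filter), so the total spectral integral is proportional to
#' the summed fractions of contributing species and is independent of the
#' enhancement multipliers. The 1H dimension is assumed ideally decoupled
#' during acquisition, so no one-bond C-H splitting appears. A warning is
#' raised when the enhanced multiplet would extend beyond the spectral
#' window (folding is not simulated).
#'
#' @param template A [spin_system()].
#' @param mixture An [isotopomer_mixture()].
#' @param observed_site Carbon site number to observe (must bear >= 1
#'   proton).
#' @param acq An [acq_params()] for the 13C dimension.
#' @return An `nmr_spectrum` tibble.
#' @examples
#' ala <- template_alanine()
#' mx <- isotopomer_mixture(ala, mix_entry(0.121, carbons = 3),
#'                          mix_entry(0.879, carbons = 2:3))
#' acq <- acq_params(2000, 1024, r2 = 3, carrier_ppm = 18.8, field_mhz = 150.9,
#'                   k_cc = 3)
#' sp <- simulate_carbon_trace(ala, mx, observed_site = 3, acq = acq)
#' @export
simulate_carbon_trace <- function(template, mixture, observed_site, acq) {
  assert_spin_system(template)
  stopifnot(inherits(acq, "acq_params"))
  lines <- carbon_trace_lines(template, mixture, observed_site, acq)
  check_aliasing(lines, acq)
  simulate_lines_1d(lines, acq, meta = list(
    template = template$name, observed_site = observed_site,
    kind = "carbon_trace", k_cc = acq$k_cc, k_cn = acq$k_cn))
}

#' Simulate a 1D 1H resonance with 13C satellites
#'
#' A proton resonance from a site whose carbon is 13C with probability
#' `fraction_13c` splits into a central line of weight `1 - fraction_13c`
#' (12C-bound protons) flanked by two satellites of weight
#' `fraction_13c / 2` at `+/- j_ch / 2`, all with equal linewidths. At
#' natural abundance (`fraction_13c = 0.0107`) each satellite is about 0.5%
#' of the central peak height. With `decouple_13c = TRUE` the satellites
#' collapse onto the central line (ideal 13C decoupling during acquisition)
#' and a single full-weight peak results.
#'
#' @param template A [spin_system()].
#' @param observed_site Carbon site whose attached proton(s) are observed.
#' @param fraction_13c 13C fraction at the site, 0-1.
#' @param acq An [acq_params()] for the 1H dimension (`nucleus = "1H"`).
#' @param decouple_13c Collapse the satellites (13C decoupling on)?
#' @return An `nmr_spectrum`.
#' @export
simulate_satellite_spectrum <- function(template, observed_site, fraction_13c,
                                        acq, decouple_13c = FALSE) {
  assert_spin_system(template)
  stopifnot(inherits(acq, "acq_params"))
  if (!is_number(fraction_13c) || fraction_13c < 0 || fraction_13c > 1) {
    stop_validation("`fraction_13c` must be in [0, 1]")
  }
  cs <- template$carbons
  row <- which(cs$site == observed_site)
  if (!length(row)) stop_validation("`observed_site` is not a carbon site of the template")
  if (cs$n_h[row] < 1) stop_validation("site has no attached protons to observe")
  omega <- (cs$proton_ppm[row] - acq$carrier_ppm) * acq$field_mhz
  jch <- cs$j_ch[row]
  lines <- if (decouple_13c) {
    list(list(freq_hz = omega, amp = 1, mods = NULL))
  } else {
    list(
      list(freq_hz = omega, amp = 1 - fraction_13c, mods = NULL),
      list(freq_hz = omega - jch / 2, amp = fraction_13c / 2, mods = NULL),
      list(freq_hz = omega + jch / 2, amp = fraction_13c / 2, mods = NULL)
    )
  }
  simulate_lines_1d(lines, acq, meta = list(
    template = template$name, observed_site = observed_site,
    kind = "satellite_1h", fraction_13c = fraction_13c,
    decoupled = decouple_13c))
}

#' Filter a mixture by isotope species
#'
#' Emulates the species selection of spectral-filter experiments on the
#' mixture itself. `mode = "require_15N_neighbour"` keeps only species in
#' which some nitrogen coupled to the observed carbon (`J_CN != 0`) is
#' 15N-labelled - the 15N filter of the filtered 2D HSQC. Fractions are
#' *not* renormalised: the filter removes signal, it does not rescale the
#' survivors.
#'
#' @param mixture An [isotopomer_mixture()].
#' @param observed_site Carbon site the experiment observes.
#' @param mode `"none"` (identity) or `"require_15N_neighbour"`.
#' @return An `isotopomer_mixture` (possibly with zero rows and fractions
#'   summing to less than 1).
#' @export
apply_species_filter <- function(mixture, observed_site,
                                 mode = c("none", "require_15N_neighbour")) {
  mode <- match.arg(mode)
  template <- mixture_template(mixture)
  if (!observed_site %in% template$carbons$site) {
    stop_validation("`observed_site` is not a carbon site of the mixture's template")
  }
  if (mode == "none") return(mixture)
  ns <- template$nitrogens
  keep <- vapply(seq_len(nrow(mixture)), function(r) {
    nl <- mixture$nitrogen_labels[[r]]
    if (!nrow(ns)) return(FALSE)
    any(vapply(seq_len(nrow(ns)), function(q) {
      nl[q] && abs(j_cn_between(template, observed_site, ns$site[q])) > 0
    }, logical(1)))
  }, logical(1))
  new_mixture(mixture[keep, ], template)
}

#' Simulate a long-range 1H,15N-HSQC 2D multiplet
#'
#' In the long-range experiment, proton magnetisation is transferred from a
#' carbon-bound proton (typically Halpha) to the nitrogen via the two-bond
#' H-N coupling, so only 15N-containing species contribute. For each
#' contributing species the F2 (1H) position is the proton shift of
#' `proton_site`, split into a doublet by that carbon's one-bond C-H
#' coupling iff it is 13C-labelled; the F1 (15N) position is the nitrogen
#' shift, split by `(1 + k_cn) * J_CN` for every 13C-labelled coupled
#' carbon with a non-zero (and active) C-N coupling. Each 2D component is
#' the outer product of Lorentzian lines in the two dimensions, so a species
#' of fraction `f` with `m` active splittings contributes lines of weight
#' `f * 2^-m`.
#'
#' @param template A [spin_system()] with at least one nitrogen site.
#' @param mixture An [isotopomer_mixture()].
#' @param acq_f1 [acq_params()] for the 15N dimension (carries `k_cn`).
#' @param acq_f2 [acq_params()] for the 1H dimension.
#' @param proton_site Carbon site whose proton is detected; defaults to the
#'   protonated carbon with the largest |J_CN|.
#' @return An `nmr_spectrum2d`. If no species contains 15N the spectrum is
#'   all zero and a warning is raised.
#' @export
simulate_long_range_nh_2d <- function(template, mixture, acq_f1, acq_f2,
                                      proton_site = NULL) {
  assert_spin_system(template)
  stopifnot(inherits(acq_f1, "acq_params"), inherits(acq_f2, "acq_params"))
  ns <- template$nitrogens
  if (!nrow(ns)) stop_validation("template has no nitrogen site")
  cs <- template$carbons
  if (is.null(proton_site)) {
    cand <- cs$site[cs$n_h >= 1]
    jmax <- vapply(cand, function(s) {
      max(abs(vapply(ns$site, function(n) j_cn_between(template, s, n), numeric(1))))
    }, numeric(1))
    proton_site <- cand[which.max(jmax)]
  }
  prow <- which(cs$site == proton_site)
  if (!length(prow) || cs$n_h[prow] < 1) {
    stop_validation("`proton_site` must be a protonated carbon site")
  }
  n1 <- acq_f1$n_points * acq_f1$zero_fill
  n2 <- acq_f2$n_points * acq_f2$zero_fill
  m <- matrix(0, n1, n2)
  e_cn <- 1 + acq_f1$k_cn
  any_15n <- FALSE
  for (r in seq_len(nrow(mixture))) {
    nl <- mixture$nitrogen_labels[[r]]
    if (!any(nl)) next
    any_15n <- TRUE
    cl <- mixture$carbon_labels[[r]]
    cn_active <- if ("cn_active" %in% names(mixture)) mixture$cn_active[r] else TRUE
    for (q in which(nl)) {
      omega_n <- (ns$nitrogen_ppm[q] - acq_f1$carrier_ppm) * acq_f1$field_mhz
      mods <- list()
      if (cn_active) {
        for (p in seq_len(nrow(cs))) {
          if (!cl[p]) next
          j <- j_cn_between(template, cs$site[p], ns$site[q])
          if (abs(j) > 0) mods[[length(mods) + 1L]] <- c(abs(j), e_cn)
        }
      }
      mods <- if (length(mods)) {
        as.data.frame(do.call(rbind, mods)) |> stats::setNames(c("j_hz", "e"))
      } else NULL
      f1 <- process_fid(simulate_fid(
        list(list(freq_hz = omega_n, amp = 1, mods = mods)), acq_f1), acq_f1)

      omega_h <- (cs$proton_ppm[prow] - acq_f2$carrier_ppm) * acq_f2$field_mhz
      jch <- cs$j_ch[prow]
      f2_lines <- if (cl[prow]) {
        list(list(freq_hz = omega_h - jch / 2, amp = 0.5, mods = NULL),
             list(freq_hz = omega_h + jch / 2, amp = 0.5, mods = NULL))
      } else {
        list(list(freq_hz = omega_h, amp = 1, mods = NULL))
      }
      f2 <- process_fid(simulate_fid(f2_lines, acq_f2), acq_f2)
      m <- m + mixture$fraction[r] * outer(f1, f2)
    }
  }
  if (!any_15n) {
    warn("no 15N-containing species in the mixture: spectrum is all zero")
  }
  new_spectrum2d(m, acq_f1, acq_f2, meta = list(
    template = template$name, kind = "long_range_nh",
    proton_site = proton_site, k_cn = acq_f1$k_cn))
}
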