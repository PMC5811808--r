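# shared helpers: small acquisition grids and randomised spin systems

quick_acq <- function(...) {
  defaults <- list(sw_hz = 2000, n_points = 512, r2 = 3, carrier_ppm = 18.8,
                   field_mhz = 150.9)
  do.call(acq_params, utils::modifyList(defaults, list(...)))
}

# a minimal two-carbon system with a single coupling J, sites 1-2, proton on
# site 2 (used wherever an isolated doublet is needed)
two_spin_system <- function(j_hz = 35) {
  spin_system(
    name = "two_spin",
    carbons = tibble::tibble(
      site = c(1L, 2L),
      carbon_ppm = c(30, 20),
      proton_ppm = c(2.5, 1.5),
      n_h = c(1L, 1L),
      j_ch = 145
    ),
    j_cc = tibble::tibble(site_a = 1L, site_b = 2L, hz = j_hz)
  )
}

# randomised small spin system for property-style tests; the observed site is
# always site 1 and carries a proton
random_spin_system <- function(n_carbons = sample(2:4, 1), with_nitrogen = FALSE) {
  sites <- seq_len(n_carbons)
  carbons <- tibble::tibble(
    site = as.integer(sites),
    carbon_ppm = 20 + stats::runif(n_carbons, -1.5, 1.5),  # within +-230 Hz of carrier
    proton_ppm = stats::runif(n_carbons, 1, 4),
    n_h = c(1L, sample(0:3, n_carbons - 1, replace = TRUE)),
    j_ch = 145
  )
  pairs <- utils::combn(sites, 2)
  keep <- stats::runif(ncol(pairs)) < 0.7
  j_cc <- tibble::tibble(
    site_a = as.integer(pairs[1, keep]),
    site_b = as.integer(pairs[2, keep]),
    hz = stats::runif(sum(keep), 2, 60)
  )
  nitrogens <- NULL
  j_cn <- NULL
  if (with_nitrogen) {
    nitrogens <- tibble::tibble(site = "N", nitrogen_ppm = 40, j_hn2 = 1.5)
    j_cn <- tibble::tibble(carbon = 1L, nitrogen = "N", hz = stats::runif(1, 2, 8))
  }
  spin_system("random", carbons, nitrogens, j_cc, j_cn)
}

# random mixture over all isotopomers that label site 1 (so every species is
# visible in the observed trace)
random_visible_mixture <- function(template, n_species = 2) {
  iso <- enumerate_isotopomers(template, "carbon")
  vis <- iso[vapply(iso$carbon_labels, function(cl) cl[1], logical(1)), ]
  pick <- vis[sample(nrow(vis), n_species), ]
  f <- stats::runif(n_species)
  f <- f / sum(f)
  entries <- lapply(seq_len(n_species), function(i) {
    mix_entry(f[i], carbons = template$carbons$site[pick$carbon_labels[[i]]])
  })
  isotopomer_mixture(template, entries)
}
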