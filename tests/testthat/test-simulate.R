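test_that("apparent splitting is (1 + k) * J", {
  expect_equal(apparent_splitting(35, 0), 35)
  expect_equal(apparent_splitting(35, 3), 140)
  expect_equal(apparent_splitting(0, 7), 0)
  expect_error(apparent_splitting(35, -1), "non-negative")
  expect_error(apparent_splitting(-3, 1), ">= 0")
  for (j in c(4.2, 34.9, 53)) {
    for (k in c(0L, 1L, 3L, 7L)) {
      expect_equal(apparent_splitting(j, k), (1 + k) * j)
    }
  }
})

test_that("a species without labelled neighbours gives an enhancement-invariant singlet", {
  ala <- template_alanine()
  mx <- isotopomer_mixture(ala, mix_entry(1, carbons = 3))
  sp0 <- simulate_carbon_trace(ala, mx, 3, quick_acq(k_cc = 0))
  sp7 <- simulate_carbon_trace(ala, mx, 3, quick_acq(k_cc = 7))
  expect_identical(sp0$intensity, sp7$intensity)
  pk <- find_peaks(sp0, rel_threshold = 0.5)
  expect_equal(nrow(pk), 1L)
  # the singlet sits at the C3 offset from the carrier
  expect_equal(pk$freq_hz, (18.8 - 18.8) * 150.9, tolerance = 1e-6)
})

test_that("a 13C,13C pair shows the enhanced splitting", {
  ala <- template_alanine()
  mx <- isotopomer_mixture(ala, mix_entry(1, carbons = 2:3))
  acq <- quick_acq(n_points = 2048, k_cc = 3, zero_fill = 4, r2 = 1)
  sp <- simulate_carbon_trace(ala, mx, 3, acq)
  grid_step <- acq$sw_hz / (acq$n_points * acq$zero_fill)
  expect_lt(abs(measured_splitting(sp) - 4 * 34.9), grid_step)
})

test_that("a zero C-N coupling makes the trace independent of k_cn", {
  ala <- template_alanine()  # 2J(C3,N) = 0 in the template
  mx <- isotopomer_mixture(ala, mix_entry(1, carbons = 3, nitrogens = "N"))
  sp0 <- simulate_carbon_trace(ala, mx, 3, quick_acq(k_cn = 0))
  sp3 <- simulate_carbon_trace(ala, mx, 3, quick_acq(k_cn = 3))
  expect_lt(max(abs(sp0$intensity - sp3$intensity)), 1e-10)
  # while C2, which has 1J(C2,N) = 5.5 Hz, does depend on k_cn
  acq2 <- acq_params(2000, 2048, r2 = 1, carrier_ppm = 53.2, field_mhz = 150.9)
  mx2 <- isotopomer_mixture(ala, mix_entry(1, carbons = 2, nitrogens = "N"))
  c2_0 <- simulate_carbon_trace(ala, mx2, 2, acq2)
  c2_3 <- simulate_carbon_trace(ala, mx2, 2, update_acq(acq2, k_cn = 3))
  expect_gt(max(abs(c2_0$intensity - c2_3$intensity)), 1e-3 * max(c2_0$intensity))
})

test_that("HSQC-invisible and unknown sites are rejected; aliasing warns", {
  ala <- template_alanine()
  mx <- isotopomer_mixture(ala, mix_entry(1, carbons = 1:3))
  expect_error(simulate_carbon_trace(ala, mx, 1, quick_acq()), "HSQC-invisible")
  expect_error(simulate_carbon_trace(ala, mx, 9, quick_acq()), "not a carbon site")
  narrow <- acq_params(sw_hz = 120, n_points = 256, r2 = 3, carrier_ppm = 18.8,
                       field_mhz = 150.9, k_cc = 3)
  expect_warning(simulate_carbon_trace(ala, mx, 3, narrow), "alias")
})

test_that("natural-abundance satellites have the expected height ratio", {
  lac <- template_lactate()
  acq <- acq_params(1200, 4096, r2 = 2, carrier_ppm = 1.32, field_mhz = 600.2,
                    nucleus = "1H")
  sp <- simulate_satellite_spectrum(lac, 3, 0.0107, acq)
  pk <- find_peaks(sp, rel_threshold = 0.001)
  expect_equal(nrow(pk), 3L)
  # satellites sit +- j_ch/2 around the centre line
  expect_equal(sort(pk$freq_hz[2:3]), c(-64, 64), tolerance = 1e-3)
  ratio <- pk$intensity[2] / pk$intensity[1]
  expect_equal(ratio, (0.0107 / 2) / (1 - 0.0107), tolerance = 0.02)

  # degenerate fractions
  sp0 <- simulate_satellite_spectrum(lac, 3, 0, acq)
  expect_equal(nrow(find_peaks(sp0, rel_threshold = 0.001)), 1L)
  spd <- simulate_satellite_spectrum(lac, 3, 1, acq, decouple_13c = TRUE)
  pkd <- find_peaks(spd, rel_threshold = 0.5)
  expect_equal(nrow(pkd), 1L)
  expect_equal(pkd$intensity, find_peaks(sp0, rel_threshold = 0.5)$intensity,
               tolerance = 1e-9)
})

test_that("multiplet integral is conserved under enhancement", {
  set.seed(11)
  for (rep in 1:10) {
    tpl <- random_spin_system()
    mx <- random_visible_mixture(tpl)
    acq0 <- acq_params(2000, 512, r2 = 3, carrier_ppm = 20, field_mhz = 150.9)
    i0 <- spec_integral(simulate_carbon_trace(tpl, mx, 1, acq0))
    k <- sample(1:7, 1)
    ik <- spec_integral(suppressWarnings(
      simulate_carbon_trace(tpl, mx, 1, update_acq(acq0, k_cc = k))))
    expect_equal(ik, i0, tolerance = 1e-6)
  }
})

test_that("the simulator is linear in the mixture", {
  ala <- template_alanine()
  acq <- quick_acq(k_cc = 3)
  mx <- isotopomer_mixture(ala, mix_entry(0.3, carbons = 3),
                           mix_entry(0.7, carbons = 2:3))
  combined <- simulate_carbon_trace(ala, mx, 3, acq)
  a <- simulate_carbon_trace(ala, isotopomer_mixture(ala, mix_entry(1, carbons = 3)),
                             3, acq)
  b <- simulate_carbon_trace(ala, isotopomer_mixture(ala, mix_entry(1, carbons = 2:3)),
                             3, acq)
  expect_equal(combined$intensity, 0.3 * a$intensity + 0.7 * b$intensity,
               tolerance = 1e-12)
})

test_that("the central singlet is unchanged by enhancement within a multiplet", {
  ala <- template_alanine()
  mx <- isotopomer_mixture(ala, mix_entry(0.4, carbons = 3),
                           mix_entry(0.6, carbons = 2:3))
  acq <- quick_acq(n_points = 2048, r2 = 3, zero_fill = 2)
  centre <- function(sp) {
    pk <- find_peaks(sp, rel_threshold = 0.2)
    pk[which.min(abs(pk$freq_hz)), ]
  }
  c0 <- centre(simulate_carbon_trace(ala, mx, 3, acq))
  c7 <- centre(simulate_carbon_trace(ala, mx, 3, update_acq(acq, k_cc = 7)))
  grid_step <- acq$sw_hz / (acq$n_points * acq$zero_fill)
  expect_lt(abs(c0$freq_hz - c7$freq_hz), grid_step)
  expect_equal(c7$intensity, c0$intensity, tolerance = 1e-3)
})

test_that("peak positions match the analytic line list for well-resolved couplings", {
  glc <- template_glucose_c456()
  mx <- isotopomer_mixture(glc, mix_entry(1, carbons = c(4, 5, 6)))
  acq <- acq_params(2000, 4096, r2 = 1, carrier_ppm = 63.2, field_mhz = 150.9,
                    k_cc = 3, zero_fill = 2)
  sp <- simulate_carbon_trace(glc, mx, 6, acq)
  pk <- find_peaks(sp, rel_threshold = 0.3)
  # doublet of doublets: +-E*J56/2 +- E*J46/2 around the C6 offset (carrier)
  want <- sort(c(outer(c(-1, 1) * 4 * 43 / 2, c(-1, 1) * 4 * 4 / 2, "+")))
  grid_step <- acq$sw_hz / (acq$n_points * acq$zero_fill)
  expect_equal(nrow(pk), 4L)
  expect_true(all(abs(sort(pk$freq_hz) - want) < grid_step))
})

test_that("enhancement resolves couplings hidden below the linewidth", {
  glc <- template_glucose_c456()
  mx <- isotopomer_mixture(glc, mix_entry(1, carbons = c(4, 5, 6)))
  # FWHM = r2/pi = 7.5 Hz: two equal Lorentzians merge into one maximum when
  # their separation is below FWHM/sqrt(3) = 4.3 Hz, so the 4 Hz long-range
  # J(C4,C6) is unresolved at k = 0 and resolved (16 Hz) at k = 3
  acq <- acq_params(2000, 4096, r2 = 23.5, carrier_ppm = 63.2, field_mhz = 150.9,
                    zero_fill = 2)
  n0 <- nrow(find_peaks(simulate_carbon_trace(glc, mx, 6, acq), rel_threshold = 0.2))
  n3 <- nrow(find_peaks(simulate_carbon_trace(glc, mx, 6, update_acq(acq, k_cc = 3)),
                        rel_threshold = 0.2))
  expect_equal(n0, 2L)   # only the 43 Hz doublet
  expect_equal(n3, 4L)   # 4 * 4 Hz = 16 Hz > 2 * FWHM: now resolved
  expect_gt(n3, n0)
})

test_that("species filtering keeps only 15N-coupled species without renormalising", {
  ala <- template_alanine()
  mx <- isotopomer_mixture(ala,
    mix_entry(0.5, carbons = 2:3),                  # 14N species
    mix_entry(0.5, carbons = 2:3, nitrogens = "N")) # 15N species
  kept <- apply_species_filter(mx, 2, mode = "require_15N_neighbour")
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$fraction, 0.5)  # not rescaled to 1

  all15 <- isotopomer_mixture(ala, mix_entry(1, carbons = 2:3, nitrogens = "N"))
  expect_equal(nrow(apply_species_filter(all15, 2, "require_15N_neighbour")), 1L)
  expect_identical(apply_species_filter(mx, 2, "none"), mx)

  lac_mx <- isotopomer_mixture(template_lactate(), mix_entry(1, carbons = 2:3))
  expect_equal(nrow(apply_species_filter(lac_mx, 2, "require_15N_neighbour")), 0L)
  expect_error(apply_species_filter(mx, 9, "none"), "not a carbon site")
})

test_that("long-range 1H,15N multiplets have the expected component counts", {
  ala <- template_alanine()
  fx <- fixture_library()$fig7_alanine_NH
  acq_f1 <- fx$acq
  acq_f2 <- fx$acq_f2

  one <- isotopomer_mixture(ala, mix_entry(1, nitrogens = "N"))
  sp1 <- simulate_long_range_nh_2d(ala, one, acq_f1, acq_f2)
  expect_equal(count_components(sp1, 0.05, 3), 1L)

  four <- isotopomer_mixture(ala, mix_entry(1, carbons = 1:3, nitrogens = "N"))
  sp4 <- simulate_long_range_nh_2d(ala, four, acq_f1, acq_f2)
  expect_equal(count_components(sp4, 0.05, 3), 4L)

  sp7 <- simulate_long_range_nh_2d(ala, fx$mixture, acq_f1, acq_f2)
  expect_equal(count_components(sp7, 0.05, 3), 7L)

  no_n <- isotopomer_mixture(ala, mix_entry(1, carbons = 2:3))
  expect_warning(sp0 <- simulate_long_range_nh_2d(ala, no_n, acq_f1, acq_f2),
                 "all zero")
  expect_equal(count_components(sp0, 0.05, 3), 0L)
})
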