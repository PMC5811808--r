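ala <- template_alanine()
glc <- template_glucose_c456()
fig5_candidates <- isotopomer_set(ala, list(3, c(2, 3)))
fig5_mix <- isotopomer_mixture(ala, mix_entry(0.121, carbons = 3),
                               mix_entry(0.879, carbons = 2:3))

test_that("basis columns are the expected multiplet shapes", {
  acq <- quick_acq(k_cc = 3)
  bs <- build_basis(ala, 3, fig5_candidates, acq)
  expect_equal(ncol(bs$B), 2L)
  n_pk <- function(col) {
    sp <- simulate_carbon_trace(ala, isotopomer_mixture(ala, mix_entry(1, carbons = 3)),
                                3, acq)  # reuse the axis
    sp$intensity <- col
    nrow(find_peaks(sp, rel_threshold = 0.3))
  }
  expect_equal(n_pk(bs$B[, 1]), 1L)  # [3-13C]: singlet
  expect_equal(n_pk(bs$B[, 2]), 2L)  # [2,3-13C]: doublet

  glc_cand <- isotopomer_set(glc, list(6, c(5, 6), c(4, 5, 6)))
  acq_glc <- acq_params(2000, 512, r2 = 3, carrier_ppm = 63.2, field_mhz = 150.9)
  expect_equal(ncol(build_basis(glc, 6, glc_cand, acq_glc)$B), 3L)

  # a singlet candidate's column is enhancement-invariant
  b0 <- build_basis(ala, 3, fig5_candidates[1, ], quick_acq(k_cc = 0))
  b7 <- build_basis(ala, 3, fig5_candidates[1, ], quick_acq(k_cc = 7))
  expect_identical(b0$B, b7$B)

  expect_error(build_basis(ala, 3, fig5_candidates[0, ], acq), "empty")
  expect_error(build_basis(ala, 3, isotopomer_set(ala, list(2)), acq),
               "does not label the observed site")
})

test_that("degenerate candidate pairs are flagged and refused", {
  # C1 has no coupling path to C3 in the template, so [1,3-13C] and [3-13C]
  # give identical C3 traces
  tpl <- template_alanine()
  tpl$j_cc <- tpl$j_cc[tpl$j_cc$site_a != 1, ]
  cand <- isotopomer_set(tpl, list(3, c(1, 3)))
  bs <- build_basis(tpl, 3, cand, quick_acq())
  expect_equal(nrow(bs$degenerate), 1L)
  obs <- simulate_carbon_trace(tpl, isotopomer_mixture(tpl, mix_entry(1, carbons = 3)),
                               3, quick_acq())
  expect_error(fit_fractions(obs, bs), "indistinguishable")
})

test_that("noiseless fractions are recovered exactly across enhancements", {
  for (k in c(0L, 1L, 3L, 7L)) {
    acq <- quick_acq(k_cc = k)
    bs <- build_basis(ala, 3, fig5_candidates, acq)
    obs <- simulate_carbon_trace(ala, fig5_mix, 3, acq)
    ft <- fit_fractions(obs, bs)
    expect_equal(ft$fractions$percent, c(12.1, 87.9), tolerance = 1e-8)
    expect_equal(sum(ft$fractions$percent), 100, tolerance = 1e-6)

    # a pure basis trace maps to a 100/0 split
    pure <- obs
    pure$intensity <- bs$B[, 2]
    expect_equal(fit_fractions(pure, bs)$fractions$percent, c(0, 100),
                 tolerance = 1e-8)
  }
})

test_that("fractions are invariant under observation rescaling", {
  acq <- quick_acq(k_cc = 3)
  bs <- build_basis(ala, 3, fig5_candidates, acq)
  obs <- simulate_carbon_trace(ala, fig5_mix, 3, acq)
  ft1 <- fit_fractions(obs, bs)
  obs$intensity <- 5.7 * obs$intensity
  ft2 <- fit_fractions(obs, bs)
  expect_equal(ft2$fractions$percent, ft1$fractions$percent, tolerance = 1e-10)
  expect_equal(ft2$scale, 5.7 * ft1$scale, tolerance = 1e-10)
  obs$intensity <- 0 * obs$intensity
  expect_error(fit_fractions(obs, bs), "identically zero")
})

test_that("nuisance refinement recovers a perturbed linewidth", {
  acq_true <- quick_acq(n_points = 1024, r2 = 4.5)
  acq_assumed <- update_acq(acq_true, r2 = 3)
  obs <- simulate_carbon_trace(ala, fig5_mix, 3, acq_true)
  obs_assumed <- obs
  attr(obs_assumed, "acq") <- acq_assumed
  bs <- build_basis(ala, 3, fig5_candidates, acq_assumed)
  ft <- fit_fractions(obs_assumed, bs, refine_nuisance = TRUE)
  expect_equal(ft$nuisance$r2, 4.5, tolerance = 0.05)
  expect_equal(ft$fractions$percent, c(12.1, 87.9), tolerance = 1e-3)
  expect_lt(ft$residual_rms, 1e-4 * max(obs$intensity))
})

test_that("grid oracle agrees with NNLS and flags non-unique optima", {
  acq <- quick_acq(k_cc = 3)
  bs <- build_basis(ala, 3, fig5_candidates, acq)
  obs <- simulate_carbon_trace(ala, fig5_mix, 3, acq)
  gr <- grid_oracle(obs, bs, step = 0.001)
  expect_equal(gr$percent, c(12.1, 87.9), tolerance = 1e-9)

  coarse <- grid_oracle(obs, bs, step = 0.5)
  expect_true(all(coarse$percent %in% c(0, 50, 100)))

  zero <- obs
  zero$intensity <- 0 * zero$intensity
  gr0 <- grid_oracle(zero, bs, step = 0.5)
  expect_true(attr(gr0, "non_unique"))

  glc_cand <- isotopomer_set(glc, list(6, c(5, 6), c(4, 5, 6)))
  acq_glc <- acq_params(2000, 512, r2 = 3, carrier_ppm = 63.2, field_mhz = 150.9)
  bs4 <- build_basis(glc, 6, glc_cand, acq_glc)
  expect_error(grid_oracle(obs, bs, step = 1e-4), "0.001")
  big <- isotopomer_set(glc, list(6, c(5, 6), c(4, 6), c(4, 5, 6)))
  expect_error(grid_oracle(obs, build_basis(glc, 6, big, acq_glc)),
               "more than 3")
})

test_that("NNLS and the grid oracle find the same minimiser on noisy problems", {
  set.seed(42)
  acq <- quick_acq(n_points = 256, zero_fill = 2)
  for (rep in 1:20) {
    k <- sample(c(0L, 1L, 3L, 7L), 1)
    acq_k <- update_acq(acq, k_cc = k)
    f <- runif(2)
    f <- f / sum(f)
    mx <- isotopomer_mixture(ala, mix_entry(f[1], carbons = 3),
                             mix_entry(f[2], carbons = 2:3))
    obs <- simulate_carbon_trace(ala, mx, 3, acq_k)
    obs <- add_time_noise(obs, noise_spec(max(obs$intensity) / (200 * sqrt(256)),
                                          seed = rep))
    bs <- build_basis(ala, 3, fig5_candidates, acq_k)
    ft <- fit_fractions(obs, bs)
    gr <- grid_oracle(obs, bs, step = 0.01)
    expect_lt(max(abs(ft$fractions$percent - gr$percent)), 1.0)
  }
})

test_that("recovered fractions are stable across enhancement levels", {
  acq <- quick_acq(n_points = 2048)
  rep_noiseless <- enhancement_consistency(ala, 3, fig5_mix, c(0L, 1L, 3L, 7L), acq)
  expect_lt(attr(rep_noiseless, "max_spread_pp"), 0.05)
  expect_equal(unique(rep_noiseless$n_points), c(2048L, 1024L, 512L, 256L))

  mix5050 <- isotopomer_mixture(ala, mix_entry(0.5, carbons = 3),
                                mix_entry(0.5, carbons = 2:3))
  rep50 <- enhancement_consistency(ala, 3, mix5050, c(0L, 1L, 3L, 7L), acq)
  expect_equal(rep50$percent, rep(50, 8), tolerance = 1e-8)

  # noisy at the SNR of a short eight-fold-enhanced acquisition
  sigma <- noise_sigma_for_snr(ala, fig5_mix, 3, update_acq(acq, k_cc = 7L,
                                                            n_points = 256),
                               snr = 280)
  rep_noisy <- enhancement_consistency(ala, 3, fig5_mix, c(0L, 1L, 3L, 7L), acq,
                                       noise_sigma = sigma, seed = 9L)
  truth <- c(12.1, 87.9)
  err <- abs(rep_noisy$percent - rep(truth, 4))
  expect_lt(max(err), 1.0)
})

test_that("reported sigmas calibrate the noise-driven scatter", {
  acq <- quick_acq(n_points = 512)
  bs <- build_basis(ala, 3, fig5_candidates, acq)
  noiseless <- simulate_carbon_trace(ala, fig5_mix, 3, acq)
  sigma_t <- max(noiseless$intensity) / (100 * sqrt(acq$n_points))  # SNR 100
  recovered <- matrix(NA_real_, 200, 2)
  sig_rep <- matrix(NA_real_, 200, 2)
  for (r in 1:200) {
    obs <- add_time_noise(noiseless, noise_spec(sigma_t, seed = 1000 + r))
    ft <- fit_fractions(obs, bs)
    recovered[r, ] <- ft$fractions$percent
    sig_rep[r, ] <- ft$fractions$sigma
  }
  truth <- c(12.1, 87.9)
  emp_sd <- apply(recovered, 2, sd)
  bias <- colMeans(recovered) - truth
  # unbiased within 2 reported sigmas (and within 3 standard errors)
  expect_true(all(abs(bias) < 2 * colMeans(sig_rep)))
  expect_true(all(abs(bias) < 3 * emp_sd / sqrt(200)))
  # reported sigma tracks the empirical scatter to within a factor of 2
  expect_true(all(colMeans(sig_rep) / emp_sd > 0.5 &
                  colMeans(sig_rep) / emp_sd < 2))
})

test_that("tidy, glance and reports expose the fit", {
  acq <- quick_acq(k_cc = 7)
  bs <- build_basis(ala, 3, fig5_candidates, acq)
  ft <- fit_fractions(simulate_carbon_trace(ala, fig5_mix, 3, acq), bs)
  td <- tidy(ft)
  expect_named(td, c("name", "percent", "sigma", "coef"))
  gl <- glance(ft)
  expect_equal(gl$n_candidates, 2L)
  expect_equal(gl$k_cc, 7L)

  out <- withr::local_tempdir()
  files <- write_fit_report(ft, file.path(out, "fit"))
  expect_true(all(file.exists(file.path(out, c("fit.csv", "fit.json")))))
  back <- utils::read.csv(file.path(out, "fit.csv"))
  expect_equal(back$percent, td$percent, tolerance = 1e-12)
})
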