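#' Time-domain noise specification
#'
#' Synthetic noise is injected in the time domain, where spectrometer noise
#' enters, as independent complex Gaussian samples of standard deviation
#' `sigma` per real/imaginary component, then carried through exactly the
#' same processing (first-point scaling, zero-filling, Fourier transform,
#' lineshape mixing) as the signal. The same seed and parameters always
#' reproduce the same noise realisation.
#'
#' @param sigma Standard deviation (intensity units), >= 0.
#' @param seed Integer seed.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(sigma, seed = 1L) {
  if (!is_number(sigma) || sigma < 0) stop_validation("`sigma` must be >= 0")
  structure(list(sigma = sigma, seed = as.integer(seed)), class = "noise_spec")
}

# frequency-domain realisation of time-domain complex Gaussian noise,
# processed identically to the signal FID
frequency_noise <- function(acq, noise) {
  n_total <- acq$n_points * acq$zero_fill
  if (noise$sigma == 0) return(numeric(n_total))
  fid <- withr::with_seed(noise$seed, complex(
    real = stats::rnorm(acq$n_points, sd = noise$sigma),
    imaginary = stats::rnorm(acq$n_points, sd = noise$sigma)))
  process_fid(fid, acq)
}

#' Add seeded time-domain noise to a simulated spectrum
#'
#' @param spectrum An `nmr_spectrum` produced by the simulator.
#' @param noise A [noise_spec()].
#' @return The spectrum with noise added; the noise spec is recorded in the
#'   metadata.
#' @export
add_time_noise <- function(spectrum, noise) {
  stopifnot(inherits(noise, "noise_spec"))
  acq <- spectrum_acq(spectrum)
  spectrum$intensity <- spectrum$intensity + frequency_noise(acq, noise)
  attr(spectrum, "meta") <- c(spectrum_meta(spectrum),
                              list(noise_sigma = noise$sigma,
                                   noise_seed = noise$seed))
  spectrum
}

#' Noise level matching a target signal-to-noise ratio
#'
#' Computes the time-domain sigma that makes the tallest peak of the
#' noiseless simulation stand at approximately `snr` times the baseline
#' noise RMS (SNR in the peak-height / noise-RMS sense used for spectrometer
#' comparisons). The frequency-domain noise RMS of an `n`-point complex
#' Gaussian FID is `sigma * sqrt(n)`.
#'
#' @param template,mixture,observed_site,acq Simulation inputs as in
#'   [simulate_carbon_trace()].
#' @param snr Target signal-to-noise ratio.
#' @return Time-domain sigma.
#' @export
noise_sigma_for_snr <- function(template, mixture, observed_site, acq, snr) {
  sp <- simulate_carbon_trace(template, mixture, observed_site, acq)
  max(sp$intensity) / (snr * sqrt(acq$n_points))
}

new_fixture_case <- function(name, template, mixture, observed_site, acq,
                             noise, extra = list()) {
  structure(c(list(name = name, template = template, mixture = mixture,
                   observed_site = observed_site, acq = acq, noise = noise),
              extra),
            class = "fixture_case")
}

#' @export
print.fixture_case <- function(x, ...) {
  cat(sprintf("<fixture_case> %s (%s, site %s)\n", x$name, x$template$name,
              paste(x$observed_site, collapse = "/")))
  print(as_tibble(x$mixture)[, c("name", "fraction")], n = Inf)
  invisible(x)
}

#' Library of synthetic ground-truth cases
#'
#' Named fixture cases covering every analysis path of the package, each
#' with a known isotopomer mixture, acquisition parameters and a seeded
#' noise level:
#'
#' * `fig4_glucoseC6` - glucose C6 with 6.8% \[6-13C\], 41.2% \[5,6-13C\]
#'   and 52.0% \[U-13C\], the mixture against which the splitting-enhanced
#'   fitting is exercised. Noise set for SNR about 800 (full-length
#'   acquisition).
#' * `fig5_alanineC3` - alanine C3 with 12.1% \[3-13C\] / 87.9%
#'   \[2,3-13C\]; noise set for SNR about 280, the level of a short
#'   eight-fold-enhanced acquisition.
#' * `fig7_alanine_NH` - equal thirds of 15N-only alanine, \[U-13C,15N\]
#'   alanine with resolvable C-N coupling, and a \[U-13C,15N\] species
#'   whose C-N splitting is below the linewidth; input for the long-range
#'   1H,15N 2D multiplet whose component count is 7.
#' * `fig2_filter_lactate` - lactate methyl group at 40% 13C with an actual
#'   one-bond coupling of 130 Hz, for the paired-filter quantification
#'   round trip.
#'
#' @return A named list of `fixture_case` objects.
#' @export
fixture_library <- function() {
  glc <- template_glucose_c456()
  ala <- template_alanine()
  lac <- template_lactate()

  acq_glc <- acq_params(sw_hz = 2000, n_points = 2048, r2 = 3,
                        carrier_ppm = 63.2, field_mhz = 150.9, nucleus = "13C")
  mix_glc <- isotopomer_mixture(
    glc,
    mix_entry(0.068, carbons = 6),
    mix_entry(0.412, carbons = c(5, 6)),
    mix_entry(0.520, carbons = c(4, 5, 6))
  )
  sig_glc <- noise_sigma_for_snr(glc, mix_glc, 6, acq_glc, snr = 800)

  acq_ala <- acq_params(sw_hz = 2000, n_points = 2048, r2 = 3,
                        carrier_ppm = 18.8, field_mhz = 150.9, nucleus = "13C")
  mix_ala <- isotopomer_mixture(
    ala,
    mix_entry(0.121, carbons = 3),
    mix_entry(0.879, carbons = c(2, 3))
  )
  sig_ala <- noise_sigma_for_snr(ala, mix_ala, 3, acq_ala, snr = 280)

  mix_nh <- isotopomer_mixture(
    ala,
    mix_entry(1 / 3, nitrogens = "N"),
    mix_entry(1 / 3, carbons = 1:3, nitrogens = "N"),
    mix_entry(1 / 3, carbons = 1:3, nitrogens = "N", cn_active = FALSE)
  )
  # decay rates chosen so the FID has decayed out at truncation (r2 * T > 5);
  # otherwise sinc ringing would create spurious local maxima in the 2D grid
  acq_f1 <- acq_params(sw_hz = 240, n_points = 256, r2 = 5, carrier_ppm = 40,
                       field_mhz = 60.8, nucleus = "15N", k_cn = 3,
                       zero_fill = 2)
  acq_f2 <- acq_params(sw_hz = 1200, n_points = 512, r2 = 12, carrier_ppm = 3.77,
                       field_mhz = 600.2, nucleus = "1H", zero_fill = 2)

  acq_1h <- acq_params(sw_hz = 1200, n_points = 2048, r2 = 2, carrier_ppm = 1.32,
                       field_mhz = 600.2, nucleus = "1H")

  list(
    fig4_glucoseC6 = new_fixture_case(
      "fig4_glucoseC6", glc, mix_glc, 6L, acq_glc, noise_spec(sig_glc, 401L)),
    fig5_alanineC3 = new_fixture_case(
      "fig5_alanineC3", ala, mix_ala, 3L, acq_ala, noise_spec(sig_ala, 501L)),
    fig7_alanine_NH = new_fixture_case(
      "fig7_alanine_NH", ala, mix_nh, 2L, acq_f1, noise_spec(0, 701L),
      extra = list(acq_f2 = acq_f2)),
    fig2_filter_lactate = new_fixture_case(
      "fig2_filter_lactate", lac, NULL, 3L, acq_1h, noise_spec(0, 201L),
      extra = list(percent_13c = 40, j_ch_actual = 130,
                   delta = filter_delay(145)))
  )
}

#' Simulate a noisy observation from a fixture case
#'
#' Runs the deterministic simulator for the case's template/mixture/site,
#' then adds the case's seeded time-domain noise. The ground truth (mixture
#' fractions, acquisition, noise parameters) is attached as the `truth`
#' attribute and serialised alongside the spectrum by [write_fixture_tree()].
#'
#' @param case A `fixture_case` from [fixture_library()].
#' @param k_cc,k_cn Enhancement multipliers overriding the case acquisition.
#' @return An `nmr_spectrum` with a `truth` attribute.
#' @export
make_noisy_trace <- function(case, k_cc = NULL, k_cn = NULL) {
  stopifnot(inherits(case, "fixture_case"))
  acq <- case$acq
  if (!is.null(k_cc)) acq <- update_acq(acq, k_cc = k_cc)
  if (!is.null(k_cn)) acq <- update_acq(acq, k_cn = k_cn)
  sp <- simulate_carbon_trace(case$template, case$mixture, case$observed_site, acq)
  if (case$noise$sigma > 0) sp <- add_time_noise(sp, case$noise)
  attr(sp, "truth") <- list(
    case = case$name,
    template = case$template$name,
    observed_site = case$observed_site,
    fractions = stats::setNames(as.list(case$mixture$fraction), case$mixture$name),
    k_cc = acq$k_cc, k_cn = acq$k_cn,
    noise_sigma = case$noise$sigma, noise_seed = case$noise$seed
  )
  sp
}

#' Generate a paired all-1H / 13C-filtered spectrum with known truth
#'
#' The all-1H spectrum carries the full-weight resonance (central line plus
#' 13C satellites in proportion to the labelled fraction); the filtered
#' spectrum carries the labelled fraction scaled by the J-dependent
#' [attenuation_factor()], 13C-decoupled so the satellites collapse. Noise,
#' when requested, is seeded independently for the two spectra.
#'
#' @param case A `fixture_case` whose template/site describe the resonance
#'   (e.g. `fixture_library()$fig2_filter_lactate`).
#' @param percent_13c Ground-truth percent 13C (0-100); defaults to the
#'   case's value.
#' @param j_ch_actual Actual one-bond coupling of the resonance (Hz).
#' @param delta Filter delay in seconds.
#' @param noise Optional [noise_spec()] (defaults to the case's).
#' @return A [filter_pair()] with a `truth` attribute.
#' @export
make_filter_pair <- function(case, percent_13c = NULL, j_ch_actual = NULL,
                             delta = NULL, noise = NULL) {
  stopifnot(inherits(case, "fixture_case"))
  percent_13c <- percent_13c %||% case$percent_13c
  j_ch_actual <- j_ch_actual %||% case$j_ch_actual
  delta <- delta %||% case$delta
  noise <- noise %||% case$noise
  if (!is_number(percent_13c) || percent_13c < 0 || percent_13c > 100) {
    stop_validation("`percent_13c` must be in [0, 100]")
  }
  f <- percent_13c / 100
  template <- case$template
  site <- case$observed_site
  # the satellite doublet uses the actual coupling of this resonance
  template$carbons$j_ch[template$carbons$site == site] <- j_ch_actual
  acq <- case$acq
  sp_all <- simulate_satellite_spectrum(template, site, f, acq)
  fac <- attenuation_factor(j_ch_actual, delta)
  sp_filt <- simulate_satellite_spectrum(template, site, f, acq,
                                         decouple_13c = TRUE)
  sp_filt$intensity <- f * fac * sp_filt$intensity
  if (noise$sigma > 0) {
    sp_all <- add_time_noise(sp_all, noise)
    sp_filt <- add_time_noise(sp_filt, noise_spec(noise$sigma, noise$seed + 1L))
  }
  pair <- filter_pair(sp_all, sp_filt, delta = delta)
  attr(pair, "truth") <- list(
    case = case$name, percent_13c = percent_13c, j_ch_actual = j_ch_actual,
    delta = delta, attenuation = fac,
    noise_sigma = noise$sigma, noise_seed = noise$seed
  )
  pair
}

#' Write the fixture tree to disk
#'
#' Materialises every case of [fixture_library()] as native-container
#' spectra plus a JSON truth sidecar per case.
#'
#' @param dir Output directory (created if needed).
#' @param cases Fixture cases (default: the full library).
#' @return Invisibly, the paths written.
#' @export
write_fixture_tree <- function(dir, cases = fixture_library()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  for (case in cases) {
    base <- file.path(dir, case$name)
    if (case$name == "fig2_filter_lactate") {
      pair <- make_filter_pair(case)
      write_spectrum(pair$spectrum_all, paste0(base, "_all"))
      write_spectrum(pair$spectrum_filtered, paste0(base, "_filtered"))
      truth <- attr(pair, "truth")
      written <- c(written, paste0(base, c("_all.csv", "_filtered.csv")))
    } else if (case$name == "fig7_alanine_NH") {
      sp <- simulate_long_range_nh_2d(case$template, case$mixture,
                                      case$acq, case$acq_f2)
      write_spectrum(sp, base)
      truth <- list(case = case$name,
                    fractions = stats::setNames(as.list(case$mixture$fraction),
                                                case$mixture$name),
                    cn_active = case$mixture$cn_active,
                    k_cn = case$acq$k_cn)
      written <- c(written, paste0(base, ".csv"))
    } else {
      sp <- make_noisy_trace(case)
      write_spectrum(sp, base)
      truth <- attr(sp, "truth")
      written <- c(written, paste0(base, ".csv"))
    }
    tf <- paste0(base, "_truth.json")
    jsonlite::write_json(truth, tf, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <- c(written, tf)
  }
  invisible(written)
}
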