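#' Spectrum containers
#'
#' One-dimensional spectra are tibbles of class `nmr_spectrum` with columns
#' `freq_hz` (offset from the carrier, ascending), `ppm` and `intensity`,
#' carrying the generating [acq_params()] and a provenance list as
#' attributes. Two-dimensional spectra (`nmr_spectrum2d`) are long tibbles
#' with columns `f1_hz`, `f1_ppm`, `f2_hz`, `f2_ppm`, `intensity`.
#' The ppm axis follows the NMR plotting convention (decreasing left to
#' right) in [ggplot2::autoplot()] displays; the stored tibble is ordered by
#' ascending frequency.
#'
#' @name spectrum_containers
NULL

new_spectrum1d <- function(intensity, acq, meta = list()) {
  n <- acq$n_points * acq$zero_fill
  stopifnot(length(intensity) == n)
  freq <- shifted_freq_axis(n, acq$sw_hz)
  out <- tibble(
    freq_hz = freq,
    ppm = acq$carrier_ppm + freq / acq$field_mhz,
    intensity = as.numeric(intensity)
  )
  structure(out, acq = acq, nucleus = acq$nucleus, meta = meta,
            class = c("nmr_spectrum", class(out)))
}

new_spectrum2d <- function(intensity_matrix, acq_f1, acq_f2, meta = list()) {
  n1 <- acq_f1$n_points * acq_f1$zero_fill
  n2 <- acq_f2$n_points * acq_f2$zero_fill
  stopifnot(nrow(intensity_matrix) == n1, ncol(intensity_matrix) == n2)
  f1 <- shifted_freq_axis(n1, acq_f1$sw_hz)
  f2 <- shifted_freq_axis(n2, acq_f2$sw_hz)
  out <- tibble(
    f1_hz = rep(f1, times = n2),
    f1_ppm = acq_f1$carrier_ppm + rep(f1, times = n2) / acq_f1$field_mhz,
    f2_hz = rep(f2, each = n1),
    f2_ppm = acq_f2$carrier_ppm + rep(f2, each = n1) / acq_f2$field_mhz,
    intensity = as.numeric(intensity_matrix)
  )
  structure(out, acq_f1 = acq_f1, acq_f2 = acq_f2, meta = meta,
            n1 = n1, n2 = n2,
            class = c("nmr_spectrum2d", class(out)))
}

spectrum_acq <- function(spectrum) attr(spectrum, "acq", exact = TRUE)

#' Retrieve provenance metadata attached to a spectrum
#' @param spectrum An `nmr_spectrum` or `nmr_spectrum2d`.
#' @return A list.
#' @export
spectrum_meta <- function(spectrum) attr(spectrum, "meta", exact = TRUE)

as_matrix_2d <- function(spectrum2d) {
  matrix(spectrum2d$intensity, nrow = attr(spectrum2d, "n1", exact = TRUE))
}

# ---- core line-list -> spectrum engine (deterministic; noise lives in the
# synthetic-data module) -----------------------------------------------------

# lines: list of components, each
#   list(freq_hz =, amp =, mods = data.frame(j_hz, e))
# where each mod contributes a factor cos(pi * j * e * t) to the FID
# (weak-coupling spin-echo model: couplings evolve, shifts are refocused
# except for the t1 chemical-shift evolution itself).
simulate_fid <- function(lines, acq) {
  n <- acq$n_points
  t <- (seq_len(n) - 1) * dwell_time(acq)
  fid <- complex(n)
  for (ln in lines) {
    if (ln$amp == 0) next
    sig <- ln$amp * exp((2i * pi * ln$freq_hz - acq$r2) * t)
    mods <- ln$mods
    if (!is.null(mods) && nrow(mods)) {
      for (m in seq_len(nrow(mods))) {
        j <- abs(mods$j_hz[m])
        if (j > 0) sig <- sig * cos(pi * j * mods$e[m] * t)
      }
    }
    fid <- fid + sig
  }
  fid
}

process_fid <- function(fid, acq) {
  fid[1] <- fid[1] / 2  # first-point scaling for a flat baseline / exact integral
  n_total <- acq$n_points * acq$zero_fill
  fid <- c(fid, complex(n_total - length(fid)))
  sp <- fft_shift(stats::fft(fid))
  d <- acq$dispersive_fraction
  (1 - d) * Re(sp) + d * Im(sp)
}

simulate_lines_1d <- function(lines, acq, meta = list()) {
  new_spectrum1d(process_fid(simulate_fid(lines, acq), acq), acq, meta)
}

# warn when an enhanced multiplet would exceed the spectral window
check_aliasing <- function(lines, acq) {
  if (!length(lines)) return(invisible(FALSE))
  extent <- vapply(lines, function(ln) {
    half_mult <- if (!is.null(ln$mods) && nrow(ln$mods)) {
      sum(abs(ln$mods$j_hz) * ln$mods$e) / 2
    } else 0
    abs(ln$freq_hz) + half_mult
  }, numeric(1))
  if (max(extent) > acq$sw_hz / 2) {
    warn(sprintf(
      "multiplet extends to %.1f Hz, beyond half the spectral width (%.1f Hz): peaks will alias",
      max(extent), acq$sw_hz / 2))
    return(invisible(TRUE))
  }
  invisible(FALSE)
}

# ---- spectrum arithmetic & summaries ---------------------------------------

#' Numerical integral of a 1D spectrum
#'
#' Riemann sum `sum(intensity) * df` over the full axis. For the simulator's
#' output this equals `sw/2` times the summed component amplitudes and is
#' invariant under splitting enhancement.
#'
#' @param spectrum An `nmr_spectrum`.
#' @return A number (intensity x Hz).
#' @export
spec_integral <- function(spectrum) {
  df <- spectrum$freq_hz[2] - spectrum$freq_hz[1]
  sum(spectrum$intensity) * df
}

#' Locate peaks in a 1D spectrum
#'
#' Finds local maxima above `rel_threshold` times the global maximum.
#' With `refine = TRUE` each peak position is refined by a three-point
#' parabolic interpolation, giving sub-grid frequency estimates for
#' symmetric lineshapes.
#'
#' @param spectrum An `nmr_spectrum`.
#' @param rel_threshold Minimum peak height relative to the global maximum.
#' @param refine Parabolic sub-grid refinement of peak positions.
#' @return A tibble with columns `freq_hz`, `ppm`, `intensity`, ordered by
#'   decreasing intensity.
#' @export
find_peaks <- function(spectrum, rel_threshold = 0.1, refine = TRUE) {
  y <- spectrum$intensity
  n <- length(y)
  if (n < 3 || max(y) <= 0) {
    return(tibble(freq_hz = double(), ppm = double(), intensity = double()))
  }
  thr <- rel_threshold * max(y)
  i <- 2:(n - 1)
  is_max <- y[i] >= y[i - 1] & y[i] > y[i + 1] & y[i] >= thr
  idx <- i[is_max]
  if (!length(idx)) {
    return(tibble(freq_hz = double(), ppm = double(), intensity = double()))
  }
  df <- spectrum$freq_hz[2] - spectrum$freq_hz[1]
  freq <- spectrum$freq_hz[idx]
  height <- y[idx]
  if (refine) {
    ym <- y[idx - 1]; y0 <- y[idx]; yp <- y[idx + 1]
    denom <- ym - 2 * y0 + yp
    delta <- ifelse(abs(denom) > 0, 0.5 * (ym - yp) / denom, 0)
    freq <- freq + delta * df
    height <- y0 - 0.25 * (ym - yp) * delta
  }
  acq <- spectrum_acq(spectrum)
  field <- if (!is.null(acq)) acq$field_mhz else {
    (spectrum$freq_hz[n] - spectrum$freq_hz[1]) / (spectrum$ppm[n] - spectrum$ppm[1])
  }
  carrier <- if (!is.null(acq)) acq$carrier_ppm else 0
  out <- tibble(freq_hz = freq, ppm = carrier + freq / field, intensity = height)
  dplyr::arrange(out, dplyr::desc(.data$intensity))
}

#' Measured splitting of a doublet
#'
#' Frequency separation (Hz) of the two tallest peaks of a 1D spectrum,
#' using parabolic peak-position refinement.
#'
#' @inheritParams find_peaks
#' @return Separation in Hz.
#' @export
measured_splitting <- function(spectrum, rel_threshold = 0.2) {
  pk <- find_peaks(spectrum, rel_threshold = rel_threshold, refine = TRUE)
  if (nrow(pk) < 2) {
    stop_numerical("fewer than two peaks found; cannot measure a splitting")
  }
  abs(pk$freq_hz[1] - pk$freq_hz[2])
}

#' Count resolved components of a 2D multiplet
#'
#' Operationalises "number of resolved 2D components": local maxima of the
#' intensity grid (8-neighbourhood) with height at least
#' `rel_threshold` times the global maximum; candidate maxima closer than
#' `min_separation` grid points in *both* axes are merged (the tallest is
#' kept; processing order is by decreasing intensity, so the result is
#' deterministic). An all-zero spectrum has 0 components.
#'
#' @param spectrum2d An `nmr_spectrum2d`.
#' @param rel_threshold Relative height threshold in (0, 1).
#' @param min_separation Minimum separation in grid points.
#' @return Integer component count.
#' @export
count_components <- function(spectrum2d, rel_threshold = 0.05, min_separation = 3L) {
  if (!(rel_threshold > 0 && rel_threshold < 1)) {
    stop_validation("`rel_threshold` must be in (0, 1)")
  }
  m <- as_matrix_2d(spectrum2d)
  mx <- max(m)
  if (mx <= 0) return(0L)
  n1 <- nrow(m); n2 <- ncol(m)
  pad <- matrix(-Inf, n1 + 2, n2 + 2)
  pad[2:(n1 + 1), 2:(n2 + 1)] <- m
  ctr <- pad[2:(n1 + 1), 2:(n2 + 1)]
  is_max <- ctr >= pad[1:n1, 2:(n2 + 1)] & ctr > pad[3:(n1 + 2), 2:(n2 + 1)] &
    ctr >= pad[2:(n1 + 1), 1:n2] & ctr > pad[2:(n1 + 1), 3:(n2 + 2)] &
    ctr >= pad[1:n1, 1:n2] & ctr >= pad[1:n1, 3:(n2 + 2)] &
    ctr > pad[3:(n1 + 2), 1:n2] & ctr >= pad[3:(n1 + 2), 3:(n2 + 2)] &
    ctr >= rel_threshold * mx
  cand <- which(is_max, arr.ind = TRUE)
  if (!nrow(cand)) return(0L)
  ord <- order(m[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  kept <- matrix(numeric(0), ncol = 2)
  for (r in seq_len(nrow(cand))) {
    p <- cand[r, ]
    if (nrow(kept)) {
      close_both <- abs(kept[, 1] - p[1]) < min_separation &
        abs(kept[, 2] - p[2]) < min_separation
      if (any(close_both)) next
    }
    kept <- rbind(kept, p)
  }
  nrow(kept)
}

# ---- native container I/O ---------------------------------------------------

#' Write / read the native spectrum container
#'
#' A spectrum is stored as `<prefix>.csv` (columns `freq_hz`, `ppm`,
#' `intensity`) plus a `<prefix>.json` sidecar holding the axis nucleus,
#' acquisition parameters and provenance metadata. 2D spectra use the long
#' format with columns `f1_hz`, `f1_ppm`, `f2_hz`, `f2_ppm`, `intensity`.
#'
#' @param spectrum An `nmr_spectrum` or `nmr_spectrum2d`.
#' @param prefix Path prefix (without extension).
#' @return `write_spectrum()` returns the prefix invisibly;
#'   `read_spectrum()` returns the spectrum.
#' @export
write_spectrum <- function(spectrum, prefix) {
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(spectrum), paste0(prefix, ".csv"), row.names = FALSE)
  if (inherits(spectrum, "nmr_spectrum2d")) {
    side <- list(kind = "spectrum2d",
                 acq_f1 = unclass(attr(spectrum, "acq_f1")),
                 acq_f2 = unclass(attr(spectrum, "acq_f2")),
                 meta = spectrum_meta(spectrum))
  } else {
    side <- list(kind = "spectrum1d",
                 acq = unclass(spectrum_acq(spectrum)),
                 meta = spectrum_meta(spectrum))
  }
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(prefix)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  tbl <- utils::read.csv(paste0(prefix, ".csv"))
  if (identical(side$kind, "spectrum2d")) {
    acq1 <- do.call(acq_params, side$acq_f1)
    acq2 <- do.call(acq_params, side$acq_f2)
    m <- matrix(tbl$intensity, nrow = acq1$n_points * acq1$zero_fill)
    new_spectrum2d(m, acq1, acq2, meta = as.list(side$meta))
  } else {
    acq <- do.call(acq_params, side$acq)
    new_spectrum1d(tbl$intensity, acq, meta = as.list(side$meta))
  }
}

#' Read a bare two-column trace
#'
#' Imports a `(freq_hz, intensity)` CSV as an `nmr_spectrum`, attaching the
#' acquisition parameters the caller knows it was recorded with. The file's
#' frequency grid must match the grid implied by `acq`.
#'
#' @param path CSV file with columns `freq_hz` and `intensity` (a `ppm`
#'   column is ignored).
#' @param acq The [acq_params()] describing the trace.
#' @return An `nmr_spectrum`.
#' @export
read_trace_csv <- function(path, acq) {
  tbl <- utils::read.csv(path)
  if (!all(c("freq_hz", "intensity") %in% names(tbl))) {
    stop_validation("trace CSV must have columns `freq_hz` and `intensity`")
  }
  tbl <- tbl[order(tbl$freq_hz), ]
  n <- acq$n_points * acq$zero_fill
  if (nrow(tbl) != n ||
      max(abs(tbl$freq_hz - shifted_freq_axis(n, acq$sw_hz))) > 1e-6 * acq$sw_hz) {
    stop_validation("trace CSV grid does not match the supplied acquisition parameters")
  }
  new_spectrum1d(tbl$intensity, acq, meta = list(source = path))
}
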