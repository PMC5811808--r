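#' Candidate isotopomer set for basis building
#'
#' Convenience wrapper turning a list of labelled-carbon site vectors into
#' the candidate tibble consumed by [build_basis()].
#'
#' @param template A [spin_system()].
#' @param carbons List of integer vectors of 13C-labelled carbon sites, one
#'   per candidate (e.g. `list(3, c(2, 3))`).
#' @param nitrogens Optional list of 15N-labelled nitrogen site vectors
#'   (recycled empty when omitted).
#' @return A tibble with columns `name`, `carbon_labels`, `nitrogen_labels`.
#' @export
isotopomer_set <- function(template, carbons, nitrogens = NULL) {
  assert_spin_system(template)
  cs <- template$carbons
  ns <- template$nitrogens
  rows <- purrr::map(seq_along(carbons), function(i) {
    cl <- cs$site %in% as.integer(carbons[[i]])
    nl <- if (is.null(nitrogens)) rep(FALSE, nrow(ns)) else {
      ns$site %in% as.character(nitrogens[[i]])
    }
    tibble(name = canonical_isotopomer_name(cl, nl, template),
           carbon_labels = list(cl), nitrogen_labels = list(nl))
  })
  dplyr::bind_rows(rows)
}

# one unit-fraction trace per candidate, with an optional global frequency
# offset and r2 override (used by the nuisance refinement)
basis_matrix <- function(template, observed_site, candidates, acq,
                         r2 = acq$r2, offset_hz = 0) {
  acq_use <- if (r2 != acq$r2) update_acq(acq, r2 = r2) else acq
  n <- acq_use$n_points * acq_use$zero_fill
  B <- matrix(0, n, nrow(candidates))
  for (j in seq_len(nrow(candidates))) {
    mx <- new_mixture(tibble(
      name = candidates$name[j], fraction = 1,
      carbon_labels = candidates$carbon_labels[j],
      nitrogen_labels = candidates$nitrogen_labels[j],
      cn_active = if ("cn_active" %in% names(candidates)) candidates$cn_active[j] else TRUE
    ), template)
    lines <- carbon_trace_lines(template, mx, observed_site, acq_use)
    for (i in seq_along(lines)) lines[[i]]$freq_hz <- lines[[i]]$freq_hz + offset_hz
    B[, j] <- process_fid(simulate_fid(lines, acq_use), acq_use)
  }
  B
}

#' Build a simulated multiplet basis for isotopomer fitting
#'
#' Simulates one unit-fraction 13C trace per candidate isotopomer, on the
#' same frequency grid and with the same enhancement multipliers as the
#' observation to be fitted. Every candidate must carry 13C at the observed
#' site (species without it are invisible there and cannot be fitted).
#' Candidate pairs whose traces are nearly collinear (normalised inner
#' product > 0.999) are flagged as degenerate; [fit_fractions()] refuses
#' degenerate bases.
#'
#' @param template A [spin_system()].
#' @param observed_site Carbon site observed.
#' @param candidates Candidate tibble from [isotopomer_set()],
#'   [enumerate_isotopomers()] or an [isotopomer_mixture()] (fractions are
#'   ignored).
#' @param acq The observation's [acq_params()].
#' @return An object of class `basis_set` with fields `B` (matrix, one
#'   column per candidate), `candidates`, `template`, `observed_site`,
#'   `acq`, `axis` and `degenerate` (tibble of flagged pairs).
#' @export
build_basis <- function(template, observed_site, candidates, acq) {
  assert_spin_system(template)
  stopifnot(inherits(acq, "acq_params"))
  candidates <- as_tibble(candidates)[, intersect(
    c("name", "carbon_labels", "nitrogen_labels", "cn_active"),
    names(as_tibble(candidates))), drop = FALSE]
  if (!nrow(candidates)) stop_validation("empty candidate list")
  row <- which(template$carbons$site == observed_site)
  ok <- vapply(candidates$carbon_labels, function(cl) isTRUE(cl[row]), logical(1))
  if (!all(ok)) {
    stop_validation(sprintf(
      "candidate %s does not label the observed site and would be invisible",
      candidates$name[!ok][1]))
  }
  B <- basis_matrix(template, observed_site, candidates, acq)
  df <- acq$sw_hz / (acq$n_points * acq$zero_fill)
  integrals <- colSums(B) * df
  if (any(integrals <= 0)) stop_numerical("a basis column has non-positive integral")
  # degeneracy scan
  K <- ncol(B)
  deg <- tibble(name_a = character(), name_b = character(), similarity = double())
  if (K > 1) {
    Bn <- sweep(B, 2, sqrt(colSums(B^2)), "/")
    G <- crossprod(Bn)
    for (a in 1:(K - 1)) for (b in (a + 1):K) {
      if (G[a, b] > 0.999) {
        deg <- dplyr::bind_rows(deg, tibble(
          name_a = candidates$name[a], name_b = candidates$name[b],
          similarity = G[a, b]))
      }
    }
  }
  structure(list(B = B, candidates = candidates, template = template,
                 observed_site = observed_site, acq = acq,
                 axis = shifted_freq_axis(nrow(B), acq$sw_hz),
                 degenerate = deg),
            class = "basis_set")
}

#' @export
print.basis_set <- function(x, ...) {
  cat(sprintf("<basis_set> %s site %d: %d candidates on %d points (k_cc %d, k_cn %d)\n",
              x$template$name, x$observed_site, ncol(x$B), nrow(x$B),
              x$acq$k_cc, x$acq$k_cn))
  cat(" ", paste(x$candidates$name, collapse = ", "), "\n")
  if (nrow(x$degenerate)) {
    cat("  degenerate pairs:\n")
    print(x$degenerate)
  }
  invisible(x)
}

nnls_solve <- function(B, y) {
  sol <- pracma::lsqnonneg(B, y)
  sol$x
}

fit_objective <- function(B, y) {
  x <- nnls_solve(B, y)
  list(x = x, rss = sum((y - B %*% x)^2))
}

#' Fit isotopomer fractions to an observed multiplet
#'
#' Solves `min || observed - sum_i c_i basis_i ||^2` with `c_i >= 0`
#' (Lawson-Hanson non-negative least squares) and reports the fractions
#' `100 * c_i / sum(c)`. With `refine_nuisance = TRUE` the linear solve
#' alternates with one-dimensional refinement of the decay rate `r2` and a
#' global frequency offset of the basis (coordinate descent, at most 20
#' outer iterations, relative residual tolerance 1e-8). Uncertainties come
#' from the linearised covariance of the active coefficient set propagated
#' through the normalisation (delta method).
#'
#' @param observed An `nmr_spectrum` on exactly the basis' frequency grid.
#' @param basis A [build_basis()] result.
#' @param refine_nuisance Refine `r2` and a global frequency offset?
#' @return An object of class `isotopomer_fit`; see [tidy()][generics::tidy]
#'   and [glance()][generics::glance] methods.
#' @examples
#' ala <- template_alanine()
#' acq <- acq_params(2000, 512, r2 = 3, carrier_ppm = 18.8, field_mhz = 150.9,
#'                   k_cc = 7)
#' mx <- isotopomer_mixture(ala, mix_entry(0.121, carbons = 3),
#'                          mix_entry(0.879, carbons = 2:3))
#' obs <- simulate_carbon_trace(ala, mx, 3, acq)
#' bs <- build_basis(ala, 3, isotopomer_set(ala, list(3, c(2, 3))), acq)
#' fit_fractions(obs, bs)
#' @export
fit_fractions <- function(observed, basis, refine_nuisance = FALSE) {
  stopifnot(inherits(basis, "basis_set"))
  if (nrow(observed) != nrow(basis$B) ||
      max(abs(observed$freq_hz - basis$axis)) > 1e-9 * basis$acq$sw_hz) {
    stop_validation("observed axis does not equal the basis axis")
  }
  if (nrow(basis$degenerate)) {
    d <- basis$degenerate[1, ]
    stop_numerical(sprintf(
      "degenerate basis: %s and %s are indistinguishable (similarity %.5f)",
      d$name_a, d$name_b, d$similarity))
  }
  y <- observed$intensity
  if (all(y == 0)) stop_validation("observation is identically zero")

  r2 <- basis$acq$r2
  offset <- 0
  B <- basis$B
  sol <- fit_objective(B, y)
  if (refine_nuisance) {
    df <- basis$acq$sw_hz / nrow(B)
    for (iter in seq_len(20L)) {
      rss_prev <- sol$rss
      opt_r2 <- stats::optimize(function(v) {
        fit_objective(basis_matrix(basis$template, basis$observed_site,
                                   basis$candidates, basis$acq,
                                   r2 = v, offset_hz = offset), y)$rss
      }, interval = c(0.2 * basis$acq$r2, 5 * basis$acq$r2))
      r2 <- opt_r2$minimum
      opt_off <- stats::optimize(function(v) {
        fit_objective(basis_matrix(basis$template, basis$observed_site,
                                   basis$candidates, basis$acq,
                                   r2 = r2, offset_hz = v), y)$rss
      }, interval = c(-2 * df, 2 * df))
      offset <- opt_off$minimum
      B <- basis_matrix(basis$template, basis$observed_site, basis$candidates,
                        basis$acq, r2 = r2, offset_hz = offset)
      sol <- fit_objective(B, y)
      if (abs(rss_prev - sol$rss) <= 1e-8 * max(rss_prev, .Machine$double.eps)) break
    }
  }
  x <- sol$x
  s <- sum(x)
  if (s <= 0) stop_numerical("all fitted coefficients are zero; nothing to normalise")
  pct <- 100 * x / s

  # delta-method sigma on the normalised fractions, from the NNLS active set
  n <- length(y)
  K <- ncol(B)
  active <- which(x > 0)
  dof <- max(n - length(active), 1L)
  s2 <- sol$rss / dof
  cov_c <- matrix(0, K, K)
  if (length(active)) {
    cov_c[active, active] <- s2 * solve(crossprod(B[, active, drop = FALSE]))
  }
  J <- (diag(K) * s - matrix(x, K, K, byrow = FALSE)) * (100 / s^2)
  sig <- sqrt(pmax(diag(J %*% cov_c %*% t(J)), 0))

  structure(list(
    fractions = tibble(name = basis$candidates$name, percent = pct,
                       sigma = sig, coef = x),
    scale = s,
    residual_rms = sqrt(sol$rss / n),
    rss = sol$rss,
    nuisance = list(r2 = r2, offset_hz = offset, refined = refine_nuisance),
    observed_site = basis$observed_site,
    template = basis$template$name,
    k_cc = basis$acq$k_cc, k_cn = basis$acq$k_cn,
    n = n
  ), class = "isotopomer_fit")
}

#' @export
print.isotopomer_fit <- function(x, ...) {
  cat(sprintf("<isotopomer_fit> %s site %d (k_cc %d, k_cn %d)\n",
              x$template, x$observed_site, x$k_cc, x$k_cn))
  fr <- x$fractions
  for (i in seq_len(nrow(fr))) {
    cat(sprintf("  %-14s %6.2f %% (sigma %.3g)\n", fr$name[i], fr$percent[i],
                fr$sigma[i]))
  }
  cat(sprintf("  residual rms %.4g; scale %.4g", x$residual_rms, x$scale))
  if (isTRUE(x$nuisance$refined)) {
    cat(sprintf("; refined r2 %.3g Hz, offset %.3g Hz",
                x$nuisance$r2, x$nuisance$offset_hz))
  }
  cat("\n")
  invisible(x)
}

#' Exhaustive simplex-grid oracle for small fitting problems
#'
#' Brute-force reference minimiser: walks the fraction simplex on a regular
#' grid (at most 3 candidates), finds the best overall scale for each grid
#' point in closed form, and returns the grid point with the smallest
#' residual. Intended as an independent check of [fit_fractions()] in tests,
#' not for production fitting.
#'
#' @param observed An `nmr_spectrum` on the basis grid.
#' @param basis A [build_basis()] result with <= 3 candidates.
#' @param step Grid step on the fraction scale (>= 0.001).
#' @return A tibble `name`, `percent` with attributes `residual` (residual
#'   sum of squares at the optimum) and `non_unique` (TRUE when several grid
#'   points tie within floating tolerance).
#' @export
grid_oracle <- function(observed, basis, step = 0.01) {
  stopifnot(inherits(basis, "basis_set"))
  K <- ncol(basis$B)
  if (K > 3) stop_validation("grid_oracle refuses more than 3 candidates")
  if (step < 0.001) stop_validation("`step` must be >= 0.001")
  y <- observed$intensity
  B <- basis$B
  G <- crossprod(B)
  b <- drop(crossprod(B, y))
  yy <- sum(y^2)
  g <- seq(0, 1, by = step)
  if (K == 1) {
    P <- matrix(1, 1, 1)
  } else if (K == 2) {
    P <- rbind(g, 1 - g)
  } else {
    grid2 <- expand.grid(p1 = g, p2 = g)
    grid2 <- grid2[grid2$p1 + grid2$p2 <= 1 + 1e-12, ]
    P <- rbind(grid2$p1, grid2$p2, pmax(1 - grid2$p1 - grid2$p2, 0))
  }
  num <- drop(crossprod(P, b))            # <y, B p>
  den <- colSums(P * (G %*% P))           # <B p, B p>
  s <- pmax(num, 0) / pmax(den, .Machine$double.eps)
  resid <- yy - 2 * s * num + s^2 * den
  best <- which.min(resid)
  ties <- sum(resid <= resid[best] + 1e-9 * max(yy, 1))
  out <- tibble(name = basis$candidates$name,
                percent = as.numeric(100 * P[, best]))
  attr(out, "residual") <- resid[best]
  attr(out, "scale") <- s[best]
  attr(out, "non_unique") <- ties > 1L
  out
}

#' Consistency of recovered fractions across enhancement levels
#'
#' Simulates the same mixture at several enhancement multipliers - reducing
#' the number of acquired points in proportion, as one would shorten the
#' acquisition when splittings grow - fits each simulated observation
#' against a matched basis, and reports the recovered fractions per level
#' together with the maximum spread across levels. Optional time-domain
#' Gaussian noise (seeded) can be injected to emulate measured data.
#'
#' @param template A [spin_system()].
#' @param observed_site Carbon site observed.
#' @param mixture Ground-truth [isotopomer_mixture()]; its isotopomers are
#'   also the fit candidates.
#' @param k_list Integer vector of enhancement multipliers `k` (apparent
#'   couplings are `(1+k) * J`). `n_points` is divided by `1+k` per level.
#' @param acq Base [acq_params()] (its `k_cc` is ignored; `n_points` should
#'   be divisible by `max(1 + k_list)`).
#' @param noise_sigma Time-domain noise standard deviation (0 = noiseless).
#' @param seed Seed for the noise (one independent stream per level).
#' @return An object of class `enhancement_report`: a tibble
#'   (`k`, `enhancement`, `n_points`, `name`, `percent`, `sigma`) with
#'   attribute `max_spread_pp` (largest per-species range across levels, in
#'   percentage points).
#' @export
enhancement_consistency <- function(template, observed_site, mixture, k_list,
                                    acq, noise_sigma = 0, seed = NULL) {
  if (!length(k_list)) stop_validation("`k_list` must be non-empty")
  # only species labelling the observed site are visible and fittable there
  row <- which(template$carbons$site == observed_site)
  visible <- vapply(mixture$carbon_labels, function(cl) isTRUE(cl[row]), logical(1))
  candidates <- as_tibble(mixture)[visible, ]
  rows <- purrr::map(seq_along(k_list), function(i) {
    k <- k_list[i]
    n_k <- max(64L, as.integer(round(acq$n_points / (1 + k))))
    acq_k <- update_acq(acq, k_cc = k, n_points = n_k)
    obs <- simulate_carbon_trace(template, mixture, observed_site, acq_k)
    if (noise_sigma > 0) {
      obs <- add_time_noise(obs, noise_spec(noise_sigma,
                                            seed = (seed %||% 0L) + i))
    }
    bs <- build_basis(template, observed_site, candidates, acq_k)
    ft <- fit_fractions(obs, bs)
    dplyr::mutate(ft$fractions[, c("name", "percent", "sigma")],
                  k = k, enhancement = 1L + k, n_points = n_k,
                  .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  spread <- out |>
    dplyr::group_by(.data$name) |>
    dplyr::summarise(spread = max(.data$percent) - min(.data$percent)) |>
    dplyr::pull(.data$spread) |>
    max()
  structure(out, max_spread_pp = spread,
            class = c("enhancement_report", class(out)))
}

#' @export
print.enhancement_report <- function(x, ...) {
  cat("<enhancement_report>\n")
  NextMethod()
  cat(sprintf("max spread across enhancement levels: %.3g percentage points\n",
              attr(x, "max_spread_pp", exact = TRUE)))
  invisible(x)
}

#' Write a fit report
#'
#' Exports an [fit_fractions()] result as CSV (per-candidate percent, sigma,
#' coefficient) and/or JSON (adding residual and nuisance metadata).
#'
#' @param fit An `isotopomer_fit`.
#' @param path Output path without extension.
#' @param format `"csv"`, `"json"` or both.
#' @return The paths written, invisibly.
#' @export
write_fit_report <- function(fit, path, format = c("csv", "json")) {
  format <- match.arg(format, c("csv", "json"), several.ok = TRUE)
  written <- character()
  if ("csv" %in% format) {
    f <- paste0(path, ".csv")
    utils::write.csv(as.data.frame(fit$fractions), f, row.names = FALSE)
    written <- c(written, f)
  }
  if ("json" %in% format) {
    f <- paste0(path, ".json")
    jsonlite::write_json(list(
      template = fit$template, observed_site = fit$observed_site,
      k_cc = fit$k_cc, k_cn = fit$k_cn,
      fractions = fit$fractions, scale = fit$scale,
      residual_rms = fit$residual_rms, nuisance = fit$nuisance,
      n = fit$n), f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <- c(written, f)
  }
  invisible(written)
}
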