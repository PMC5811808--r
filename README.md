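# hsqctracer

Simulation and quantification tools for **stable-isotope tracer NMR of
metabolism**: splitting-enhanced ¹H,¹³C-HSQC multiplets, quantitative
¹²C/¹³C spectral filters, and isotopomer-fraction fitting — with a
synthetic-data module that provides known ground truth for every analysis
path.

## The problem

Feeding cells or organs a ¹³C- or ¹⁵N-enriched nutrient (e.g.
[1,2-¹³C]glucose, [U-¹³C,¹⁵N]glutamine) imprints pathway-specific labelling
patterns on downstream metabolites. NMR resolves those patterns at atomic
resolution: in the indirect (¹³C) dimension of a ¹H,¹³C-HSQC spectrum, each
¹³C–¹³C (or ¹³C–¹⁵N) scalar coupling splits the resonance, so the multiplet
fine structure encodes *which* neighbouring atoms are labelled, and the
relative multiplet component areas encode the molar fractions of the
positional isotopomers. Two acquisition tricks make this fast and
quantitative on a single sample:

1. **Quantitative spectral filters.** Two 1D ¹H spectra are acquired with
   identical scaling — one from all protons, one only from ¹³C-bound
   protons. The filtered spectrum is attenuated by
   `sin²(2πδJ_CH)`, where δ is the filter spin-echo delay (tuned as
   δ = 1/(4·J_CH), J_CH = 145 Hz). Dividing region integrals, after
   correcting each resonance for its actual one-bond coupling, yields the
   absolute percent ¹³C incorporation: over the physiological coupling
   range 120–165 Hz the maximum correction is 7.2 %.

2. **J-coupling splitting enhancement.** A spin echo appended after the t₁
   evolution, whose delays grow by *k* dwell times per increment, lets
   homonuclear (and optionally C–N) couplings evolve `1 + k` times faster
   than the chemical shift: apparent splittings become `(1 + k)·J` while
   shifts stay put. Couplings can then be resolved with `1/(1+k)` as many
   increments — an 8× enhancement turns a 233-minute acquisition into a
   24-minute one — and sub-linewidth couplings (long-range ¹³C–¹³C, ¹J_CN)
   become visible.

`hsqctracer` implements the computational side of this workflow: a
weak-coupling spin-echo simulator for the ¹³C (and ¹⁵N) dimension
(cosine amplitude modulation `cos(πJ(1+k)t)` per coupled labelled
neighbour, Lorentzian decay, ¹H-decoupled acquisition), satellite and
filter-pair 1D simulation, and recovery of isotopomer fractions by
non-negative least squares against simulated basis multiplets
(`min ‖y − Σcᵢbᵢ‖², cᵢ ≥ 0`, fractions `100·cᵢ/Σc`).

## Worked example

Fit the isotopomer composition of the alanine methyl (C3) multiplet at
eight-fold splitting enhancement, from a mixture of 12.1 % [3-¹³C] and
87.9 % [2,3-¹³C] alanine:

```r
library(hsqctracer)

ala <- template_alanine()
mix <- isotopomer_mixture(ala,
  mix_entry(0.121, carbons = 3),
  mix_entry(0.879, carbons = c(2, 3)))

# eight-fold enhancement (k = 7): 34.9 Hz doublet appears at 279.2 Hz,
# so 256 complex points suffice
acq <- acq_params(sw_hz = 2000, n_points = 256, r2 = 3,
                  carrier_ppm = 18.8, field_mhz = 150.9, k_cc = 7)
obs   <- simulate_carbon_trace(ala, mix, observed_site = 3, acq = acq)
basis <- build_basis(ala, 3, isotopomer_set(ala, list(3, c(2, 3))), acq)
fit_fractions(obs, basis)
#> <isotopomer_fit> alanine site 3 (k_cc 7, k_cn 0)
#>   [3-13C]         12.10 % (sigma 1.28e-15)
#>   [2,3-13C]       87.90 % (sigma 1.28e-15)
#>   residual rms 3.052e-15; scale 1
```

The two percentages are the recovered molar fractions of the two
isotopomers (they sum to 100); `sigma` is the linearised 1-σ uncertainty —
essentially zero here because the observation is noiseless. The recovery is
stable across enhancement levels even as the acquisition is shortened in
proportion:

```r
enhancement_consistency(ala, 3, mix, k_list = c(0, 1, 3, 7),
                        acq = update_acq(acq, k_cc = 0, n_points = 2048))
#> # A tibble: 8 x 6
#>       k enhancement n_points name      percent    sigma
#>   <dbl>       <dbl>    <int> <chr>       <dbl>    <dbl>
#> 1     0           1     2048 [3-13C]      12.1 3.89e-16
#> 2     0           1     2048 [2,3-13C]    87.9 3.89e-16
#> ...
#> max spread across enhancement levels: 4.26e-14 percentage points
```

and the filter-correction arithmetic is available directly:

```r
round(max_downscaling(120, 165, filter_delay(145)), 1)
#> [1] 7.2
```

`tidy()` / `glance()` return the fit as tibbles, `autoplot()` plots spectra
and fits, and the `inst/cli/hsqctracer` script exposes `simulate`, `fit`,
`filter-quant` and `fixtures` subcommands (JSON configs; exit codes 0/2/3).

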