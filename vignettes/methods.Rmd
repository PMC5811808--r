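---
title: "Models and methods behind hsqctracer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hsqctracer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsqctracer)
```

# Scope

`hsqctracer` models the quantitative core of stable-isotope tracer analysis
by NMR: how positional isotopomer mixtures of a metabolite appear in the
indirect dimension of (optionally splitting-enhanced) ¹H,¹³C-HSQC spectra
and in paired ¹²C/¹³C-filtered 1D ¹H spectra, and how isotopomer fractions
and percent ¹³C incorporation are recovered from those spectra. Hardware
concerns — pulse programs, phase cycles, gradients, decoupling waveforms,
non-uniform sampling and its reconstruction — are out of scope; only their
idealised *effects* are modelled (a ¹H-decoupled ¹³C dimension, species
selection by spectral filters, echo/anti-echo lineshape perturbations as a
single admixture parameter).

# The simulation model

## Weak-coupling spin-echo evolution

The indirect-dimension signal of each isotopomer that carries ¹³C at the
observed carbon site is modelled as

$$ s(t) \;=\; f \cdot e^{\,i 2\pi \Omega t}\; e^{-R_2 t}
   \prod_{j \in \text{coupled }^{13}\text{C}} \cos\!\big(\pi J_{ij} (1+k_{cc})\, t\big)
   \prod_{N \in \text{coupled }^{15}\text{N}} \cos\!\big(\pi J_{iN} (1+k_{cn})\, t\big), $$

where $f$ is the species' molar fraction, $\Omega$ the offset of the site's
carbon shift from the carrier, and $R_2$ the decay rate (Lorentzian
FWHM $= R_2/\pi$). This is the weak-coupling limit: each coupling
contributes an independent cosine; strong-coupling (second-order) effects
are not modelled. The splitting-enhancement spin echo refocuses chemical
shift and ¹H couplings while letting the C–C (and, with the optional ¹⁵N
refocusing pulse, C–N) couplings evolve $1+k$ times per dwell time, hence
the $(1+k)J$ apparent splittings; because the extra delays are multiples of
the dwell time, $k$ is restricted to non-negative integers. Species with
¹²C at the observed site contribute nothing (the HSQC's implicit ¹²C
filter), and the ¹H dimension is treated as ideally decoupled, so no
one-bond C–H splitting appears in the ¹³C dimension.

The summed FID is first-point-halved (flat baseline, exact integral),
zero-filled, and discrete-Fourier-transformed; the displayed intensity is
$(1-d)\,\mathrm{Re} + d\,\mathrm{Im}$ with `dispersive_fraction` $d$
(default 0, a pure absorptive Lorentzian). $d$ exists as a calibration knob
for the predictable lineshape perturbation of gradient echo/anti-echo
quadrature; it is applied identically to simulated observations and fitting
bases, so fits are consistent whichever value is used.

Two consequences of this construction are load-bearing and tested as
invariants: the spectral integral equals half the spectral width times the
summed contributing fractions — independent of $k$, enhancement moves
intensity but never creates it — and the simulation is exactly linear in
the mixture.

## 2D long-range ¹H,¹⁵N spectra

The long-range experiment transfers proton magnetisation from a
carbon-bound proton (Hα for alanine) to the nitrogen through the two-bond
H–N coupling, so only ¹⁵N species contribute. Each contributing species is
an outer product of two 1D traces: F1 (¹⁵N) at the nitrogen shift,
cosine-modulated by $(1+k_{cn}) J_{CN}$ for every ¹³C-labelled coupled
carbon; F2 (¹H) at the proton shift, split into a ±$J_{CH}/2$ doublet iff
the proton-bearing carbon is ¹³C. A species of fraction $f$ with $m$ active
splittings therefore contributes $2^m$ components of weight $f\,2^{-m}$. No
t₂ relaxation model is applied beyond the F2 trace's own $R_2$.

Component counting is operationalised deterministically: local maxima of
the intensity grid (8-neighbourhood, ties broken toward the
lower-index cell) above a relative threshold (default 5 % of the global
maximum), with candidates closer than `min_separation` grid points in
*both* axes merged into the taller one, processed in order of decreasing
intensity.

One modelling decision was genuinely open here. The three-species alanine
mixture that produces the 7-component long-range multiplet contains two
¹³C/¹⁵N species that differ only in whether their one-bond C–N splitting is
resolvable. Coupling constants live on the shared template, so mixtures
carry a per-species `cn_active` flag (default `TRUE`); setting it to
`FALSE` models a sub-population whose C–N splitting is below the linewidth
(for instance because the relevant coupling partner is unlabelled in a way
the template cannot express, or the coupling is effectively averaged).
This keeps the template single-valued while letting fixtures express the
published three-species composition: one ¹⁵N species with unlabelled
carbons (1 central component), one ¹³C/¹⁵N species with resolvable C–N
coupling (4 components), one ¹³C/¹⁵N species without (2 components).

## 1D filter pairs and satellites

A proton resonance whose carbon is ¹³C with probability $p$ is simulated as
a central line of weight $1-p$ flanked by satellites of weight $p/2$ at
±$J_{CH}/2$, all with equal linewidths (at natural abundance,
$p = 0.0107$, each satellite stands at
$(p/2)/(1-p) \approx 0.54\%$ of the parent height). Whether satellite and
parent widths are truly equal in measured spectra is not knowable from the
data the model is built on; equal widths are assumed and the 0.5 % figure
should be read at that assumption.

The ¹²C/¹³C filter attenuates ¹³C-bound-proton signal by
$\sin^2(2\pi\delta J_{CH})$; the proportionality constant is taken as
exactly 1 at the tuned coupling $J = 1/(4\delta)$, which is the reading
consistent with a 7.2 % maximum downscaling over 120–165 Hz.
`incorporation_percent()` integrates user-specified ppm regions by the
trapezoidal rule on the common grid (no peak fitting — region
quantification upstream of this package is assumed), corrects the filtered
integral by the attenuation factor of the region's *actual* coupling, and
propagates a single-σ Gaussian uncertainty from the RMS of a
user-designated signal-free region. The reported percentage includes the
~1.07 % natural abundance; subtracting it is an explicit, default-off
option because the source methodology does not state a subtraction.

# Fitting

`fit_fractions()` solves the non-negative least-squares problem with the
Lawson–Hanson algorithm (`pracma::lsqnonneg`) on the real absorptive trace,
against basis multiplets simulated with the observation's own acquisition
parameters; fractions are the normalised coefficients. Design choices:

* **Degeneracy.** Basis columns with normalised inner product > 0.999 are
  declared indistinguishable and the fit refuses to run, rather than
  silently splitting a fraction between collinear candidates. The
  threshold is deliberately conservative; near-degenerate candidate pairs
  (e.g. species differing only by a sub-linewidth long-range coupling at
  $k=0$) pass it but carry large reported sigmas — and are exactly the
  cases splitting enhancement is designed to separate.
* **Nuisance refinement** (optional): coordinate descent alternating NNLS
  with golden-section refinement of $R_2$ (within 0.2–5× the nominal
  value) and a global frequency offset (within ±2 grid steps), at most 20
  outer iterations, relative residual tolerance 1e-8. Whether measured
  fits should float linewidth and phase is an open question in the source
  methodology; both knobs default off.
* **Uncertainty.** Delta-method propagation of the OLS covariance of the
  NNLS active set through the normalisation; inactive (zero) coefficients
  get zero variance. Against 300 simulated replicates this tracks the
  empirical scatter to within ~10 %; zero-filling correlates neighbouring
  frequency bins, which the residual-based variance estimate largely
  absorbs.
* **The grid oracle** (`grid_oracle()`) is an independent brute-force
  minimiser that walks the fraction simplex at a fixed step with the scale
  optimised in closed form per point. It exists for verification, capped
  at 3 candidates; under near-degeneracy its discretised minimiser can sit
  more than one step from the NNLS solution while the residuals differ
  by less than 1e-6 of the signal power, so equivalence is asserted up to
  residual ties at the grid's resolution.

`enhancement_consistency()` mirrors how the experiment is actually run
faster at higher enhancement: the number of complex points is divided by
$1+k$ (8192 → 1024 in the motivating acquisitions; 2048 → 256 at the test
scale, chosen to keep the full suite under a minute while leaving every
multiplet well-resolved on its grid), and the same mixture is simulated and
refitted at each level.

# The synthetic-data module

Fixtures are the package's stand-in for measured perfusate and cell-extract
samples. Noise is injected in the time domain (complex Gaussian,
independent per point, seeded), then processed identically to signal — so
the frequency-domain noise is exactly what a spectrometer's would be after
the same processing. Noise levels are set via `noise_sigma_for_snr()` in
the peak-height / baseline-RMS sense used in acquisition comparisons:
SNR ≈ 800 for the glucose C6 fixture (a full-length acquisition) and
SNR ≈ 280 for the alanine C3 fixture (the level of a short eight-fold
enhanced acquisition). Chemical shifts in the built-in templates are
typical literature values for aqueous extracts, and the default couplings
(alanine ¹J(C2,C3) = 34.9 Hz, lactate 37 Hz, glucose ¹J(C5,C6) = 43 Hz and
long-range J(C4,C6) = 4 Hz, ¹J_CH = 145 Hz, alanine ¹J(C2,N) = 5.5 Hz) are
typical magnitudes, configurable per template — they are inputs, not
measured constants of this package.

What the generator deliberately does **not** emulate: non-uniform sampling
masks and reconstruction artefacts, solvent/presaturation residuals,
baseline distortion, strong coupling, relaxation during transfer periods,
and sample-to-sample variation of shifts and couplings. Passing tests
therefore demonstrate that the *analysis* is correct and calibrated under
the stated spectral model — not that the model captures every feature of
measured spectra.

# Numerical choices and degenerate inputs

* Dwell time $= 1/\mathrm{sw}$; frequency grids are fftshifted with the
  carrier at the centre; ppm axes are plotted right-to-left.
* Aliasing is warned about (when the enhanced multiplet extent exceeds half
  the spectral width), not folded.
* Fixture acquisition lengths keep $R_2 T \gtrsim 5$ so truncation ringing
  stays below peak-counting thresholds; this matters for the 2D component
  counter, whose 5 % threshold would otherwise pick up sinc lobes.
* Peak positions are refined by three-point parabolic interpolation, giving
  sub-grid accuracy for symmetric lines.
* Degenerate inputs fail loudly and early: observations that are
  identically zero, empty candidate lists, HSQC-invisible (proton-less)
  observed sites, empty reference regions, and mixtures whose fractions do
  not sum to 1 within 1e-9 are all errors; species filters return
  un-renormalised survivors because a filter removes signal rather than
  rescaling what remains.
* Coupling signs are stored but only magnitudes enter the simulation
  (signs are unobservable in this experiment class). Site numbering follows
  IUPAC metabolite numbering (C1 = carboxyl/anomeric).

# Known limitations

* Weak coupling only; multiplets of strongly coupled spin pairs
  (shift difference comparable to $J$) will be wrong.
* Fitting operates on a single multiplet trace; joint multi-peak or
  whole-spectrum fitting is not implemented.
* The 2D model is a separable outer product; tilted or sheared 2D
  lineshapes are not representable.
* No vendor-format reader is included: spectra enter through the native
  CSV + JSON container or a plain two-column CSV with caller-supplied
  acquisition parameters.
* The `cn_active` species flag is a modelling convenience, not a physical
  parameter; where real data demand per-species couplings, the honest fix
  is separate templates.
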