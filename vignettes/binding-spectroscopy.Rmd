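---
title: "Quantifying protein–ligand binding from steady-state spectroscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying protein–ligand binding from steady-state spectroscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specbind)
```

specbind implements the standard steady-state-spectroscopy workflow for
characterising the interaction of a small molecule (here motivated by
flavonoid inhibitors such as quercetin, hyperoside, luteolin and
luteoloside) with a fluorescent protein target (motivated by porcine
pancreatic elastase, whose intrinsic Trp/Tyr fluorescence reports ligand
binding). This vignette explains the models behind each stage, the
parameters that matter, what the synthetic-data generator does and does
not emulate, and the numerical and design choices the package makes.

## Enzyme inhibition and IC50

The inhibition rate of an activity assay read out in relative
fluorescence units (RFU) is

$$\mathrm{inhibition}\,(\%) =
  100\,\frac{\mathrm{RFU}_{\mathrm{enzyme}} -
             \mathrm{RFU}_{\mathrm{enzyme+drug}}}
            {\mathrm{RFU}_{\mathrm{enzyme}}}.$$

`inhibition_rate()` never clips: a drug that *raises* fluorescence
produces a negative rate with a warning, because silently clipping to
zero would hide assay interference.

`fit_ic50()` fits the two-parameter logistic
$y(c) = 100\,c^h/(c^h + \mathrm{IC}_{50}^h)$ with the floor fixed at 0 %
and the ceiling at 100 %. The scale is fixed by the definition of the
inhibition rate, and on the 5–8-point curves typical of these assays two
parameters are all the data support; a 4-parameter option
(`four_param = TRUE`) exists for assays with incomplete inhibition. The
concentration axis is handled as $\log_{10} c$, which makes the problem
well-conditioned across the micromolar decades; zero-concentration rows
have no logarithm and are used only to check the floor. The fit is
Levenberg–Marquardt least squares (via minpack.lm) with the Hill slope
constrained positive, so the fitted curve is always monotone. The IC50
standard error is obtained from the asymptotic error of
$\log_{10}\mathrm{IC}_{50}$ by the delta method. When every response lies
on one side of 50 % the IC50 is an extrapolation; the fit proceeds but
carries an `extrapolated` flag and a warning.

## Quenching analysis

Fluorescence intensities can first be corrected for the inner-filter
effect, $F_{\mathrm{corr}} = F_{\mathrm{obs}}\,
10^{(A_{\mathrm{ex}}+A_{\mathrm{em}})/2}$ (`inner_filter_correct()`,
`correct_titration()`). The correction assumes a centred 1 cm cuvette
and degrades at high absorbance; above $A_{\mathrm{ex}}+A_{\mathrm{em}}
= 0.6$ a warning is attached. Because instruments and workflows differ
in whether exported intensities are already corrected, the titration
file format carries optional `a_ex`/`a_em` columns and both corrected
and uncorrected paths are supported.

`stern_volmer_fit()` regresses $F_0/F$ on the quencher concentration
$[Q]$:

$$F_0/F = 1 + K_{SV}[Q] = 1 + K_q \tau_0 [Q].$$

One deliberate deviation from the textbook form: the intercept is left
free rather than forced to 1. A forced unit intercept folds any baseline
error into the slope; a free intercept leaves the slope unbiased and
turns $|{\rm intercept} - 1|$ into a useful diagnostic, reported on the
fit object. The default fluorescence lifetime is $\tau_0 = 10^{-8}$ s,
the customary value for biological macromolecules; `kq = ksv/tau0` holds
exactly by construction.

`classify_quenching()` applies the standard two-signature rule table
over fits at two or more temperatures: static quenching (ground-state
complex) shows $K_{SV}$ non-increasing with temperature *and* apparent
$K_q$ above the diffusion-controlled limit of about
$2\times10^{10}$ L mol$^{-1}$ s$^{-1}$; collisional (dynamic) quenching
shows the opposite pattern. Profiles satisfying neither conjunction are
reported `ambiguous` together with the individual rule outcomes, rather
than being forced into a verdict.

`double_log_binding_fit()` estimates the association constant and
stoichiometry from the ligand-depletion-corrected double-log relation

$$\lg\frac{F_0-F}{F} = n \lg K_a +
  n \lg\!\left([Q_0] - [P_0]\frac{F_0-F}{F_0}\right),$$

where $[Q_0] - [P_0](F_0-F)/F_0$ is the free-ligand concentration
implied by the fraction of complexed protein. Base-10 logarithms are
used here (matching the conventional "lg" form); natural logarithms
appear only in the van't Hoff analysis. Points with $F \ge F_0$ or a
non-positive free-ligand estimate have no logarithm; the convention here
is explicit: they are excluded and their indices reported, never
silently dropped. Fits are always per temperature; the package never
pools titrations across temperatures.

Published tables for such systems sometimes report $n$ well away from 1
(e.g. 1.58) while concluding 1:1 binding; `double_log_binding_fit()`
reports $n$ exactly as fitted and leaves interpretation to the caller.

## Van't Hoff thermodynamics and force classification

`vant_hoff_regression()` performs least squares of $\ln K$ on $1/T$
($\ln K = -\Delta H/RT + \Delta S/R$), giving $\Delta H = -R\,b$ and
$\Delta S = R\,a$ for slope $b$ and intercept $a$, with
$R = 8.314$ J mol$^{-1}$ K$^{-1}$ exactly. With three temperatures the
regression is the default; the closed two-point form
(`vant_hoff_two_point()`) is retained and is algebraically identical on
two points. Units follow the mixed convention of the field's tables —
$\Delta H$, $\Delta G$ in kJ/mol, $\Delta S$ in J/(mol K) — with the
conversions centralised.

Two Gibbs routes exist and are never silently interchanged:
`gibbs_from_HS()` ($\Delta G = \Delta H - T\Delta S$, the default used
in reports) and `gibbs_from_K()` ($\Delta G = -RT\ln K$). They agree
whenever $K$ itself obeys the van't Hoff relation; on published tables
they can disagree because the printed $\Delta H/\Delta S$ and $K_a$
columns are not always mutually consistent. Indeed, for the motivating
four-flavonoid dataset only the quercetin and luteoloside rows close
under $\Delta G = \Delta H - T\Delta S$ at the printed precision; the
hyperoside and luteolin $\Delta G$ entries cannot be reproduced from
their printed $\Delta H/\Delta S$ by either route, and the package's
desk-level checks therefore use only the internally consistent rows.
This discrepancy is surfaced here deliberately instead of being
reconciled by hidden rescaling.

`ross_classify()` encodes the sign rules for the dominant binding
force: hydrophobic for $(\Delta H > 0, \Delta S > 0)$, hydrogen
bonding / van der Waals for $(-,-)$, electrostatic for $(-,+)$. Two
safeguards extend the strict-sign table: values inside a near-zero band
(defaults $|\Delta H| < 1$ kJ/mol, $|\Delta S| < 1$ J/(mol K)) return
`indeterminate`, because a sign call on a value statistically
indistinguishable from zero would flip under noise; and the $(+,-)$
quadrant, which the rule table does not cover, also maps to
`indeterminate`.

## Förster energy transfer

The transfer efficiency is $E = 1 - F/F_0$ from donor fluorescence with
and without the acceptor. The overlap integral is the donor-normalised,
$\lambda^4$-weighted discrete sum

$$J = \frac{\sum F_D(\lambda)\,\varepsilon_A(\lambda)\,\lambda^4\,
  \Delta\lambda}{\sum F_D(\lambda)\,\Delta\lambda},$$

computed after linear interpolation of both spectra onto the union grid
of the overlapping axis region (extrapolation is forbidden; disjoint
spectra give $J = 0$). Midpoint quadrature widths make the sum correct
on non-uniform grids, and halving the grid step changes $J$ by well
under 0.1 % for Gaussian bands.

Units are fixed once and hard-coded: with $\lambda$ in nm and
$\varepsilon$ in L mol$^{-1}$ cm$^{-1}$ the nm$^4$-basis sum converts to
M$^{-1}$ cm$^3$ by $10^{-28}$, and
$R_0^6 = 8.8\times10^{-25}\,\kappa^2\,\phi\,n^{-4}\,J$ then yields
$R_0^6$ in cm$^6$, reported in nm. This is the only unit assignment
under which the $8.8\times10^{-25}$ prefactor produces nm-scale Förster
radii for protein–ligand pairs. Defaults: $\kappa^2 = 2/3$ (isotropic
dynamic averaging), $\phi = 0.15$ (protein Trp emission),
$n = 1.336$ (water/organic average; the literature phrase "average of
water and organic matter" is not a number, so 1.336 was fixed once and
made configurable). The efficiency relation is implemented as
$E = R_0^6/(R_0^6 + r^6)$ — the standard Förster form with the actual
donor–acceptor distance $r$ in the denominator, the only reading
consistent with published $(E, R_0, r)$ triples — and
`binding_distance()` inverts it exactly. `assess_validity()` reports
the two conventional plausibility windows ($r < 7$ nm for non-radiative
transfer, $2 \le r \le 8$ nm for static quenching) plus an advisory
$0.5 R_0 \le r \le 1.5 R_0$ band where distance estimates are most
reliable.

## Conformational evidence

`peak_position()` locates band maxima with optional windowing (default
amide I window 1600–1700 cm$^{-1}$ on FT-IR axes) and, by default,
refines the argmax by a parabola through the maximum and its two
neighbours — on a 1 nm grid this recovers a noiseless Gaussian centre to
well under 0.01 grid steps. Plain argmax remains available for coarse
instrument grids. Ties on flat maxima break to the smallest axis value
and are flagged; maxima on a window edge cannot be refined and warn.

`peak_shift()` reports `complex - free` with an explicit sign
convention: positive means longer wavelength (red shift) on nm axes and
higher wavenumber on cm$^{-1}$ axes. The convention is attached per
channel (synchronous-fluorescence Tyr at $\Delta\lambda = 15$ nm, Trp at
60 nm, UV–vis, amide I) because real studies report red shifts in one
channel and blue shifts in another.

`uv_additivity()` implements the absorbance additivity test
($A_{\mathrm{free}} + A_{\mathrm{ligand}} > A_{\mathrm{complex}}$
indicates ground-state association). `cd_fractions()` /`cd_change()` do
the secondary-structure bookkeeping on deconvolved CD fractions — the
ellipticity-to-fraction deconvolution itself is out of scope, since it
belongs to dedicated external tools, and this package consumes their
output. Fraction rows must sum to 100 within ±1 percentage point
(published rows close to 99.6 motivated the band width); rows outside
the band are flagged, not rejected. `rank_by_random_coil()` orders
ligands by induced disorder, the quantity that tracks inhibitory potency
in the motivating study, with lexicographic tie-breaking.

## The synthetic-data generator

Raw fluorescence tables behind published binding studies are rarely
deposited, so every fitting stage is validated against
`gen_titration()`, `gen_dose_response()`, `gen_band_spectrum()` and
`gen_fret_pair()`, whose defaults encode a realistic study design:
protein at 2 μM, ligand at 0/10/30/40/50/70/80 μM, temperatures
298/303/310 K, unquenched amplitude 1000 a.u., and ground-truth
thermodynamics $\Delta H = -27.511$ kJ/mol, $\Delta S = -4.108$
J/(mol K) — an enthalpy-driven binder with
$K_a(298\,\mathrm{K}) \approx 4.05\times10^4$ L/mol, typical of a
flavonoid–protein complex.

The forward model is static quenching by 1:1 ground-state complex
formation: only free protein fluoresces, $F = F_0/(1 + K_a[Q])$, with
$K_a(T) = \exp(-\Delta H \cdot 1000/RT + \Delta S/R)$. In the default
`approx` mode $[Q]$ is total ligand (ligand in excess over protein), so
$F_0/F$ is exactly linear with slope $K_a$ — the regime Stern–Volmer
analysis assumes, and the mode on which noiseless Stern–Volmer recovery
is exact. In `exact` mode the free-ligand concentration solves the 1:1
equilibrium quadratic; this is the mode the double-log plot linearises
exactly (free ligand equals $[Q_0]$ minus complexed protein), and it is
what makes noiseless double-log recovery of $(K_a, n{=}1)$ exact. A
`dynamic` mode with $K_{SV}(T) \propto T$ exists solely so the
classifier can be exercised against a known collisional ground truth.
The generator deliberately simulates only $n = 1$: non-integer fitted
$n$ is treated as a fit outcome, not a generative mechanism.

Noise is multiplicative Gaussian, $x(1 + c_v z)$ with $z$ truncated at
±5σ, because fluorescence noise scales with signal and truncation keeps
intensities positive at realistic $c_v$. Seeded generation is
bit-reproducible and restores the caller's RNG state.

What passing these tests shows — and does not show. Exact recovery at
$c_v = 0$ (≤ 0.1 % for $K_{SV}$, $K_a$, $n$, $\Delta H$, $\Delta S$,
IC50) verifies that each fit inverts its own forward model; statistical
recovery at $c_v = 0.01$ over 200 seeds (Stern–Volmer bias < 1 %, SD
< 5 %) verifies noise behaviour. Real instruments add effects the
generator omits: baseline drift, scatter peaks, wavelength-dependent
detector response, ligand self-absorption beyond the inner-filter
model, partial dynamic quenching, and non-1:1 binding. Green tests
therefore certify the estimators, not any particular real dataset.

## Numerical choices and problem sizes

Degenerate inputs fail loudly with typed conditions
(`duplicate_axis`, `missing_reference`, `mixed_series`, `fit_failure`,
`insufficient_data`, ...), and warnings are attached as flags on the
returned objects so downstream report code can render them as
footnotes. All concentrations are mol/L internally; file columns
declared `_uM` convert on read; the Unicode minus is normalised before
parsing. JSON result envelopes serialise numbers at full precision so
round trips are bit-exact, and each envelope carries an MD5 content
digest of its inputs.

Test and validation problem sizes were chosen so the whole suite runs
in seconds on a laptop: 7-point titrations at 3 temperatures, 7–8-point
dose curves, 200-seed Monte Carlo batches, spectra of a few hundred
points, and a 21,501-point refined grid for the overlap-integral
oracle. These sizes are comfortably representative of real instrument
output, which is similarly small.

## Known limitations

* Only the linear Stern–Volmer form is implemented; combined
  static+dynamic (sphere-of-action) models are out of scope.
* No enzyme kinetics (no $K_m$/$k_{cat}$, no inhibition-type analysis)
  and no heat-capacity extension of the van't Hoff model.
* CD deconvolution and FT-IR sub-band fitting are consumed, not
  performed.
* The FRET treatment uses a scalar $\kappa^2$ and intensity-based
  efficiencies; lifetime-based efficiencies are not modelled.
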