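---
title: "Measuring intrachain dynamics of disordered proteins with syndyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring intrachain dynamics of disordered proteins with syndyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syndyn)
```

## The measurement problem

The synucleins (alpha, beta, gamma) are intrinsically disordered proteins:
they have no stable tertiary structure, so their behaviour is governed by
the statistics and kinetics of a fluctuating conformational ensemble. Two
single-molecule observables characterize a ~25-residue segment of such a
chain:

* **End-to-end contact kinetics.** A segment double-labeled with
  tetramethylrhodamine (TMR) self-quenches when the two dyes stack. The
  fluorescence fluctuations of freely diffusing molecules, autocorrelated
  over lag times from below a microsecond to seconds (FCS), show a fast
  relaxation component with time constant $\tau_R$ — the timescale on which
  the chain brings its ends together — superimposed on the translational
  diffusion decay $\tau_D$.
* **Ensemble dimensions.** The same segment labeled with a FRET donor and
  acceptor gives a mean transfer efficiency from burst histograms, which a
  polymer model converts into an RMS end-to-end distance and a radius of
  gyration $R_g$.

Combining the two yields an intrachain diffusion coefficient: how fast the
segment explores an ensemble of the size it actually occupies. `syndyn`
implements this full chain of analysis, together with the sequence
physico-chemical profiles used to interpret it, and a synthetic-data
generator that stands in for raw instrument data (which were never
deposited for this system).

## FCS model

The autocorrelation of a species diffusing through a 3D-Gaussian
observation volume, with up to two multiplicative kinetic relaxations, is

$$G(\tau) = \frac{1}{N}\,\prod_i\left(1 + A_i e^{-\tau/\tau_{R,i}}\right)
\left(1+\frac{\tau}{\tau_D}\right)^{-1}
\left(1+\frac{s^2\tau}{\tau_D}\right)^{-1/2},$$

with $N$ the mean occupancy, $s$ the radial/axial ratio of the volume
(calibrated once from a free-dye measurement and then held fixed;
`calibrate_s()`), and $A_i$ the kinetic amplitude. For a two-state
bright/dark process, $A = F/(1-F)$ where $F$ is the equilibrium dark-state
fraction; `quenched_fraction()` converts between the two
parameterizations. We fix the multiplicative $(1 + A e^{-\tau/\tau_R})$
form; the alternative normalization $(1-F+Fe^{-\tau/\tau_R})/(1-F)$ is the
same curve up to the mapping above, so nothing downstream depends on the
choice.

Fitting (`fit_fcs_curve()`) is weighted Levenberg–Marquardt on
log-parameters (which enforces positivity without constrained
optimization), with weights $1/\sigma^2$ from the per-lag variance across
replicate acquisitions — the weighting used in the original measurement
protocol. Numerical choices worth knowing:

* **Variance floor.** Sparse lag bins can show zero sample variance across
  10–15 acquisitions by accident; raw inverse-variance weights would make
  those points infinitely credible. Weights use
  $\max(\sigma^2, 10^{-3}\,\mathrm{median}(\sigma^2))$. All-zero variance
  falls back to unit weights with a warning.
* **Multi-start initialization.** The default initial guesses ($N$ from
  $1/G(\tau_1)$, $\tau_D$ from the half-decay lag, $\tau_R = 1\,\mu s$,
  $A = 0.3$) fail when the kinetic amplitude is large, because the
  half-decay point then lies inside the kinetic decay. The fitter therefore
  also tries a small grid of alternative starts and keeps the lowest
  weighted residual sum. Two-component fits additionally restart from the
  converged one-component solution, which guarantees the nested model never
  fits worse.
* **No triplet term.** Laser-power controls in the source measurements
  ruled out triplet photophysics on the $\tau_R$ timescale, so the model
  deliberately has no triplet factor.
* Model comparison is by $R^2$ and reduced $\chi^2$; no automatic F-test,
  mirroring how one- versus two-component fits were compared qualitatively.

## FRET histograms

Burst events (donor counts $I_D$, acceptor counts $I_A$) are thresholded
on the summed channel at `buffer_mean + k * buffer_sd` (default $k = 5$;
whether the original threshold was per channel or on the sum is not
recorded, so `apply_threshold()` makes it configurable). Corrected
efficiencies use

$$ET_{\mathrm{eff}} = \frac{I_A - \beta I_D}{(I_A - \beta I_D) + \gamma I_D},$$

the standard corrected-ratio form consistent with the stated roles of the
bleed-through ($\beta = 0.6$) and detection/quantum-yield ($\gamma = 1.2$)
factors. Efficiencies slightly outside $[0,1]$ are genuine shot-noise
outcomes and are retained; events with a non-positive corrected
denominator are excluded and counted.

Histograms use 70 bins on $[-0.2, 1.2]$, which resolves both the
donor-only peak near zero and a FRET peak at the few-thousand-event scale
typical of these measurements. The double-Gaussian fit is
area-parameterized; the component with the larger center is always the
FRET ("data") peak — a deterministic assignment that makes the fit
invariant to initialization order. Collapsed peaks (centers closer than a
bin width) flag the fit rather than silently reporting a center.

## Gaussian-chain inversion

The mean efficiency of a Gaussian chain with RMS end-to-end distance $r$
is the Forster average over the end-to-end density,
$$\langle E\rangle = \int_0^\infty 4\pi x^2
\left(\tfrac{3}{2\pi}\right)^{3/2} e^{-3x^2/2}
\frac{1}{1+(x\,r/R_0)^6}\,dx,$$
which depends only on $r/R_0$. `invert_efficiency()` solves for that ratio
by bracketed root finding to $10^{-9}$; round-trip error in efficiency is
below $10^{-8}$ across $(0.05, 0.95)$. The integrand is evaluated on the
scale-free variable with an upper limit of 10 RMS units — the neglected
tail mass is below $10^{-15}$.

Parameter choices:

* $R_0 = 54$ Å for the Alexa 488/594 pair is a literature value — the
  source analysis never states its $R_0$. This only sets the absolute
  distance scale. Everything relative (and all headline results are
  relative) cancels $R_0$ exactly, which the test suite asserts to
  $10^{-10}$.
* The published chain dimensions were corrected for dye linkers by an
  unstated amount; `gaussian_chain(linker_mode = "subtract_fixed")`
  implements a fixed subtraction (floored at 1 Å) but the default is no
  correction, and the relative-diffusion pipeline uses raw RMS precisely
  so this unknown drops out.
* `ideal_coil_rms()` uses $b = 3.8$ Å and characteristic ratio $C = 2.8$,
  chosen so a 25-residue ideal coil comes out at ~32 Å, the standard
  benchmark scale for short disordered polypeptides. This is a calibration
  convention, not a fitted quantity.

## Intrachain diffusion coefficients

With $\tau_R$ and $R_g$ in hand, the Szabo–Schulten–Schulten-type relation
gives $D = 3.545\,R_g^3/(a\,\tau_R)$, with $a$ the dye-contact distance
(default 4 Å, the TMR stacking scale; never stated in the source). Because
neither $a$, nor the 3.545 prefactor, nor $R_0$ survives normalization,
all reported diffusion coefficients are relative to a reference record —
the LF construct of alpha-synuclein at pH 7.4 — which is defined to have
$D_{rel} = 1$ with zero error.

Error propagation follows the printed prescription exactly:
$\delta_{R_g^3} = 3R_g^2\sigma_{R_g}$ and
$\delta_D = (3.545/a)\,\delta_{R_g^3}/\tau_R$. That expression contains no
$\sigma_{\tau_R}$ term even though the accompanying text mentions
propagating it; we implement the printed formula as the default and
provide `dynamics_config(error_mode = "quadrature")` to fold in the
relative $\tau_R$ error for users who want the fuller estimate.
$\sigma_{R_g}$ comes from the efficiency SD through the numerical
derivative of the inversion.

Reconfiguration times default to $\tau_{rec} = \langle r^2\rangle/(6D)$,
the mean-square displacement convention; the defining equation in the
source's supplement is unavailable, so the formula is pluggable
(`tau_rec_formula`) and never asserted against published values.

With the bundled measurement tables, the recomputed relative diffusion
coefficients land within twice the published standard error of all 24
published values — as close as is possible without knowing the linker
correction.

## Group comparison

`mann_whitney_exact()` enumerates all $\binom{n_1+n_2}{n_1}$ labelings for
pooled sizes up to 16 (the measurement groups had $4 \le n \le 12$, so the
exact path covers every real comparison), with mid-rank tie handling and a
two-tailed p of twice the smaller tail, capped at 1. Larger pools use the
tie-corrected normal approximation with continuity correction. The exact
path is validated against an independent pair-counting enumeration oracle,
and its type-I error is conservative because the U statistic is discrete.
No multiple-testing correction is applied, matching the source protocol.
`significance_table()` reproduces the annotation convention: `*` against
the alpha-synuclein cell of the same construct and pH, `+` against the
pH 7.4 cell of the same protein and construct.

## What the synthetic data emulate — and what they do not

Raw instrument data for this system were never deposited, so the package
generates its own inputs with the statistical structure the analysis
assumes:

* `simulate_photon_trace()` performs discrete-step Brownian motion of
  point molecules in a periodic box, detection-weighted by a 3D-Gaussian
  PSF with the calibrated axial ratio, with per-molecule two-state
  bright/dark telegraph kinetics (the exact two-state propagator per bin,
  so the state autocorrelation is exactly exponential), Poisson photon
  statistics, and a binomial 50/50 channel split emulating the
  beamsplitter used for pseudo-crosscorrelation.
* `multi_tau_correlate()` is a digital multi-tau correlator (16 linear
  lags per level, factor-2 coarsening, 12 levels by default) with
  symmetric normalization, exact against a brute-force correlation oracle
  to $10^{-10}$.
* `simulate_bursts()` draws per-event photon totals from a Poisson and
  splits them binomially with an acceptor probability constructed so the
  corrected-efficiency estimator recovers the true efficiency in
  expectation, plus a donor-only subpopulation and per-channel background.
* `simulate_fcs_curve()` is the fast path: the analytical model plus
  per-lag Gaussian noise scaled as `noise_level * (g + 1/sqrt(T/lag))`,
  matching the statistics of averaged curves at 10–15 acquisitions.

The defaults encode the study conditions: occupancy of order unity,
sub-millisecond diffusion, microsecond quenching kinetics with dark
fractions in the 0.2–0.5 range, $s = 0.175$, thousands of burst events
with a donor-only fraction, $\beta = 0.6$, $\gamma = 1.2$.

Deliberate simplifications, and hence limits on what passing tests show
about real data: quenching is modeled as a telegraph process *decoupled*
from chain configuration, which reproduces the separable fitted model but
not true polymer dynamics; there is no detector afterpulsing or dead time
(pseudo-crosscorrelation is assumed to have removed afterpulsing); no
triplet photophysics; no photobleaching; and the per-molecule brightness
used in validation runs is higher than a real TMR measurement so that
seconds of simulated trace carry the information content of minutes of
real acquisition. Validation problem sizes are chosen accordingly: the
end-to-end correlator-and-fit checks use 12 chunks of 0.25 s at 0.5 µs
bins per seed (mirroring the 10–15-acquisition protocol), three seeds,
with the box at 6 PSF waists (detection weight at the edge below
$2\times10^{-8}$), and a diffusion time of 100 µs so the slow axial tail
of the correlation stays short relative to the chunk length.

Two small estimator effects matter at this scale and are handled
explicitly. First, a periodic box holding $M$ molecules cannot exchange
molecules with a reservoir, so its normalized correlation sits exactly
$f_{sig}^2/M$ below the open-volume model; `multi_tau_correlate()` adds
this known constant back for simulated traces
(`correct_finite_box = TRUE`). Second, mean-normalized correlation
estimates from finite chunks carry an additional small baseline deficit
(the finite-window bias, order $-10^{-3}$ here), and inverse-variance
weights estimated from the same dozen chunks being fit correlate with the
residuals — together these distorted the fitted kinetic time by ~10% if
ignored. The validation fits therefore enable the fitter's additive
baseline term and use unit weights
(`fit_fcs_curve(..., fit_offset = TRUE, weighting = "unit")`), after
which the telegraph relaxation time is recovered to within a few percent
on average (per-group scatter ~6%).

## Degenerate inputs and tie-breaks

* All-zero variance curves fit with unit weights (warned).
* Non-converged fits return flagged results, not exceptions.
* Double-Gaussian peak assignment is by center order, never by
  initialization order; collapse within one bin width flags the fit.
* Efficiency inversion refuses $ET \le 0$ or $\ge 1$; corrected-ratio
  events with non-positive denominators are excluded and counted.
* All-tied group comparisons return $p = 1$ with a warning.
* Linker subtraction floors the corrected RMS at 1 Å.

## Interfaces

The package's functions are the interface: tables come in and go out as
schema-validated CSV (`read_table_csv()`, `write_table_csv()`), sequences
as FASTA, fit results and provenance as JSON, and `syn_report()` runs the
whole derivation from the bundled measurement tables to the
relative-diffusion table and the property-versus-dynamics long tables.
The bundled relaxation-time and efficiency tables are *inputs* — measured
summary data transcribed from the published tables — not computed outputs;
the published relative-diffusion table is bundled separately purely for
comparison.
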