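# syndyn

Intrachain dynamics and conformations of disordered protein segments from
fluorescence correlation spectroscopy (FCS) and single-molecule FRET, built
around the human synuclein family (α-, β- and γ-synuclein).

Intrinsically disordered proteins such as the synucleins have no fixed
structure; what characterizes a segment is how large its conformational
ensemble is and how fast the chain explores it. `syndyn` implements the
complete analysis chain that turns two single-molecule measurements into a
per-segment intrachain diffusion coefficient, for people analysing (or
simulating) dye-quenching FCS and burst-mode FRET experiments on IDPs:

1. **FCS with self-quenching kinetics.** Autocorrelation curves of
   TMR-double-labeled segments are fit with

   G(τ) = (1/N) · Π_i (1 + A_i e^(−τ/τ_R,i)) · (1 + τ/τ_D)^(−1) · (1 + s²τ/τ_D)^(−1/2)

   giving the end-to-end contact relaxation time τ_R (microseconds) on top
   of translational diffusion τ_D; `calibrate_s()` fixes the
   observation-volume ratio s from a free-dye measurement.
2. **smFRET histograms.** Burst counts are thresholded against buffer
   statistics, converted to corrected efficiencies
   ET = (I_A − βI_D)/((I_A − βI_D) + γI_D), histogrammed, and fit with a
   double Gaussian (donor-only peak + FRET peak); the FRET-peak center is
   the mean ET_eff.
3. **Gaussian-chain inversion.** Mean ET_eff ↦ RMS end-to-end distance ↦
   radius of gyration R_g = RMS/√6, by numerically inverting the Förster
   average over the Gaussian-chain end-to-end distribution.
4. **Intrachain diffusion.** D = 3.545·R_g³/(a·τ_R)
   (Szabo–Schulten–Schulten form), reported relative to a reference
   construct so that the contact distance a, the prefactor and the Förster
   radius R₀ all cancel; errors propagated as δ_D = (3.545/a)·3R_g²σ_Rg/τ_R,
   plus reconfiguration times τ_rec = ⟨r²⟩/(6D).
5. **Sequence profiles and statistics.** Per-residue net charge
   (Henderson–Hasselbalch), Zimmerman bulkiness (glycine-normalized) and
   Kyte–Doolittle hydrophobicity for the labeled constructs; exact
   two-tailed Mann–Whitney U comparisons with the */+ annotation scheme of
   the source tables.

Because the raw instrument data for this system were never deposited, the
package ships (a) the published summary tables as typed fixture inputs and
(b) a first-class synthetic-data generator: Brownian photon-trace
simulation with two-state dark-state kinetics, a multi-tau digital
correlator, and FRET burst streams — used throughout the tests to validate
every fitting route against known ground truth.

## Worked example

Derive the relative diffusion table from the bundled measurement tables:

```r
library(syndyn)
dyn <- derive_dynamics(syn_relaxation_times(), syn_transfer_efficiencies())
dyn[dyn$ph == 7.4, c("protein", "construct", "d_rel_2dp", "delta_d_rel_2dp")]
#> # A tibble: 12 × 4
#>    protein construct d_rel_2dp delta_d_rel_2dp
#>    <chr>   <chr>         <dbl>           <dbl>
#>  1 alphaS  AH             0.68            0
#>  2 alphaS  CT             1.03            0.06
#>  3 alphaS  LF             1               0
#>  4 alphaS  NAC            1.29            0
#>  5 betaS   AH             0.76            0.04
#>  6 betaS   CT             1.47            0.06
#>  7 betaS   LF             1.01            0.07
#>  8 betaS   NAC            1.4             0
#>  9 gammaS  AH             0.49            0.03
#> 10 gammaS  CT             1.62            0.08
#> 11 gammaS  LF             1.24            0.07
#> 12 gammaS  NAC            1.13            0.05
```

Each row is one labeled segment at pH 7.4: `d_rel` is its intrachain
diffusion coefficient relative to the αS LF reference (1.00 by
definition). The AH constructs are slowest in all three proteins; βS NAC
and the γS CT are among the fastest. Zero error bars correspond to table
rows whose efficiency SD is printed as 0 (the default error propagation
implements the published formula, which carries only the R_g³ term;
`dynamics_config(error_mode = "quadrature")` folds in the τ_R error too).

Fit a simulated FCS curve and recover its kinetics:

```r
p <- fcs_params(N = 2, tau_D = 4e-4, s = 0.175,
                kinetic = list(c(A = 0.3, tau_R = 1.2e-6)))
avg <- average_curves(simulate_fcs_curve(p, seed = 42))
fit_fcs_curve(avg, n_kinetic = 1, s_fixed = 0.175)
#> <fcs_fit> N = 2.001, tau_D = 0.0004002 s, s = 0.175
#>   kinetic: A = 0.2977 (F = 0.229), tau_R = 1.23e-06 s
#>   R^2 = 0.999926, reduced chi^2 = 0.08832
```

The fitted relaxation time (1.23 µs) recovers the generating 1.2 µs within
a few percent; `F` is the equivalent dark-state fraction A/(1+A).

Sequence profiling:

```r
mean_scale(get_segment("betaS", "NAC"), residue_scale("bulkiness"))
#> [1] 3.674
percent_identity(get_segment("alphaS", "AH"), get_segment("betaS", "AH"))
#> [1] 88
```

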