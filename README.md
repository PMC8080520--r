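# photolaccase

Deterministic kinetic and photophysical modelling of a hybrid photoredox
system: a tris-bipyridine ruthenium sensitizer coupled to a fungal
multicopper laccase (LAC3), with methyl viologen (MV²⁺) as electron relay,
EDTA as sacrificial donor and dioxygen as terminal electron acceptor. The
package is written for photochemists and enzymologists who want to simulate,
fit and interrogate the elementary steps of such systems: why direct
photoreduction of the enzyme is inefficient (Förster energy transfer
outcompeting electron transfer), how a viologen relay fixes it, how the
enzyme's internal T1 → trinuclear-cluster electron transfer shapes
continuous-illumination kinetics, and how superoxide routes electrons into
the enzyme under air.

## What it implements

* **Mass-action reaction networks** (`build_network`, `simulate`): species +
  order-≤2 reactions, stiff ODE integration (deSolve/lsoda), automatic
  conserved-moiety detection by null-space analysis, optional cumulative
  reaction-flux ledgers for electron/oxygen bookkeeping.
* **Observables** (`absorbance_trace`, `emission_trace`, `o2_trace`):
  Beer–Lambert difference absorbance at 395/450/605/610 nm, excited-state
  emission, Clark-electrode oxygen readout with first-order response lag.
* **Closed-form photophysics** (`driving_force`, `quench_fraction`,
  `stern_volmer_fit`, `forster_rate`, `marcus_rate`, `marcus_fit_lambda`,
  `marcus_infer_distance`, `equilibrium_delta_g`,
  `rate_crossing_distance`): the classical nonadiabatic Marcus expression

  k(ΔG, r) = (2π/ħ) H²(r) (4πλk_BT)^(-1/2) exp[−(ΔG+λ)²/(4λk_BT)],
  H(r) = V₀ e^(−β(r−r₀)/2)

  together with the coupling-independent pairwise inversion for the
  reorganization energy λ, Förster transfer k(r) = (1/τ₀)(R₀/r)⁶, and
  Stern–Volmer quenching analysis.
* **Four experimental regimes**: direct flash (association complex,
  `run_direct_scheme`), viologen-relay flash (`run_relay_scheme`),
  anaerobic continuous photoreduction over the eight-state
  T1(ox/red) × TNC⁰…³ redox ladder (`run_photoreduction`), and aerobic
  photocatalysis with superoxide dismutation versus reversible
  superoxide–enzyme adduct routing (`run_aerobic`), plus yield, rate-scan
  and pathway-ablation analyses.
* **Global fitting** (`global_fit`): multi-experiment weighted least squares
  with shared parameters, log-scale Levenberg–Marquardt, Latin-hypercube
  multi-start and identifiability screening.
* **Synthetic data** (`generate_dataset`, `recovery_report`): seeded noisy
  trace generation with manifests, and generate-and-refit recovery studies.

## Worked example

Simulate the direct laser-flash experiment (15 µM sensitizer, 37 µM laccase,
9.7 µM excited by the flash) and extract the charge-separation yield:

```r
library(photolaccase)

p     <- direct_scheme_params()        # Ka = 4.75 mM^-1, k_cs = 8.5e6 s^-1, ...
pulse <- flash_pulse(9.7e-6)
tg    <- c(0, 10^seq(-8, -3, length.out = 200))
run   <- run_direct_scheme(p, pulse, tg)

tail(run$a450, 1)                      # -0.000824  : long-lived 450 nm plateau
css_yield(run$trajectory, pulse)       # 0.674      : % of the flash stored as Ru(III)
branch_yield(p$k_off, p$k_br)          # 6.25       : % escape from the CS complex
```

The plateau of −0.8 × 10⁻³ absorbance corresponds to ~0.065 µM of oxidized
sensitizer surviving recombination, i.e. a charge-separation quantum yield
of ~0.7% — the quantitative statement of why the direct pathway needs a
relay. The Marcus layer then condenses the four intra-complex rates into one
reorganization energy:

```r
marcus_fit_lambda(c(8.5e6, 6.6e6, 1.8e6, 1.2e6),
                  c(-1.52, -0.55, -0.58, -1.55),
                  class = c("cs", "cs", "br", "br"))$lambda
# 1.045835   (prints as 1.05 eV)
```

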