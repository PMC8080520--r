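---
title: "Modelling photoinduced electron transfer to a multicopper laccase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling photoinduced electron transfer to a multicopper laccase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photolaccase)
```

## The system

A photosensitizer ([Ru(bpy)₃]²⁺, MLCT band at 450 nm, ε = 14,600 M⁻¹cm⁻¹,
excited-state lifetime τ₀ = 600 ns) is mixed with a fungal laccase whose
oxidized T1 copper absorbs at 610 nm (ε = 5,600 M⁻¹cm⁻¹). Light-driven
reduction of the enzyme — and with it the accumulation of the strong oxidant
Ru(III) — can proceed directly from the excited sensitizer, or through a
methyl-viologen relay, or, under air, through superoxide. This package
models all of these as deterministic mass-action reaction networks plus a
closed-form photophysics layer, and provides the fitting and synthetic-data
machinery to interrogate them.

Everything is expressed in molar, seconds and centimetres; energies in eV,
distances in Å (Förster radii in nm, as that literature does). Config
values may carry unit tags (`"15 uM"`, `"600 ns"`) normalized on load.

## Core network engine

A `reaction_network` is a species list plus elementary reactions of total
reactant order 1 or 2 with mass-action rate laws. Higher-order chemistry is
deliberately excluded: the one nominally higher-order process here,
superoxide dismutation `2 O₂·⁻ + 2H⁺ → O₂ + H₂O₂`, is encoded as second
order in superoxide with protons implicit, because the medium is buffered
and all constants are effective values at the working pH. Conserved pools
(total sensitizer, total enzyme, total viologen, total oxygen atoms) are
found automatically from the left null space of the stoichiometry matrix
and checked after every integration: relative drift above 10⁻⁶ is an error,
not a warning.

Integration uses `deSolve::lsoda` (automatic stiff/non-stiff switching)
with defaults rtol = 10⁻⁸ and atol = 10⁻¹⁵ M; the flash regimes span nine
decades of time (ns excitation to ms observation) and the continuous
regimes couple nanosecond photophysics to minutes-scale enzyme kinetics, so
a stiff-capable method is not optional. Solutions are dense-output
interpolated to the requested grid — halving the grid spacing changes
reported concentrations only at the solver-tolerance level. Round-off
negatives are clipped at reporting, never during integration. Optionally
the integrator carries cumulative reaction fluxes as extra states; all
electron- and oxygen-bookkeeping analyses (donor-electron balance,
H₂O₂ yield, route shares) read these exact ledgers rather than
re-differentiating traces.

## The photophysics layer

`driving_force` uses ΔG = −(E_acceptor − E_donor), negative = exergonic;
the stored couples are the printed potentials (−0.84, +1.26, +0.68, +0.13,
+2.23 V vs NHE; the viologen couple defaults to the standard −0.45 V).
`marcus_rate` is the classical nonadiabatic expression with distance-decaying
coupling. Two properties matter for the analyses built on it: the rate is
maximal (activationless) at ΔG = −λ and symmetric about that apex, which is
what lets two rates of one reaction class pin λ in closed form
(`marcus_fit_lambda`); and because the electronic coupling cancels within a
class, that inference is coupling-independent by construction. Applied to
the four intra-complex rates of the two sensitizers (charge separation
8.5 × 10⁶ and 6.6 × 10⁶ s⁻¹ at driving forces 1.52 and 0.55 eV;
recombination 1.8 × 10⁶ and 1.2 × 10⁶ s⁻¹ at 0.58 and 1.55 eV) the two
per-class solutions are 1.049 and 1.043 eV, mean 1.05 eV — placing the
high-driving-force reactions in the inverted region.

Distance inference (`marcus_infer_distance`) does depend on the coupling.
The documented defaults V₀ = 0.02 eV, β = 1.1 Å⁻¹, r₀ = 3 Å are a
calibration, chosen once so that the charge-separation rate at ΔG = −1.52 eV
maps into the 12.5–13.5 Å window consistent with the docking distance of
11.2 Å; they are not ground truth, and tests treat them as such. With these
defaults the Förster curve (R₀ = 2.6 nm, τ₀ = 600 ns) crosses the Marcus
curve near 9 Å — below the docking distance, which is exactly why a simple
rate-crossing argument cannot explain electron transfer beating energy
transfer inside the complex; an optional spin-statistics factor (< 1) on
the Förster rate is exposed for exploring the multiplicity-based
explanation, defaulting to 1.

## Direct flash regime

Ground-state sensitizer and enzyme pre-associate with Ka = 4.75 mM⁻¹; the
pre-flash state is the exact root of the binding quadratic. At 15 µM
sensitizer and 37 µM enzyme the quadratic gives 2.13 µM complexed (14.2%),
slightly above the 12.5% (1.9 µM) quoted alongside the same Ka — the
arithmetic in the source appears to use a free-ligand approximation; the
exact quadratic is used here, which propagates into simulated plateau
amplitudes a few percent above the printed ones. The nanosecond flash is
treated as a delta pulse partitioned over free and complexed sensitizer in
proportion to their ground-state populations (the pulse is short against
every subsequent rate).

Free excited sensitizer decays (k₀ = 1/τ₀) or is quenched by the enzyme at
the diffusional 6.1 × 10⁹ M⁻¹s⁻¹ — modelled as pure energy transfer with no
product channel, which is the mechanistic conclusion of the flash analysis;
the whole productive pathway lives in the complex: charge separation k_cs
against k₀, then recombination k_br against dissociation k_off (escape
yield k_off/(k_off+k_br) = 6.25%), with re-association of the
charge-separated pair at k_off·Ka_cs (Ka_cs = 8.5 mM⁻¹) and bimolecular
recombination of the escaped products at 4.6 × 10⁸ M⁻¹s⁻¹. The ground-pair
association rate is not separately identifiable from the data the defaults
describe; it is fixed at a diffusional 10⁹ M⁻¹s⁻¹ with the dissociation
rate set by Ka. Intra-complex energy transfer is exposed but defaults to
zero — no such reaction was needed to describe the data.

Simulated with the default parameters, the T1 bleach rises and decays with
apparent biexponential rates ≈ 10⁷ and ≈ 2 × 10⁶ s⁻¹, the 450 nm trace
settles at ≈ −0.8 × 10⁻³, and the charge-separation yield is ≈ 0.67%
(printed: 0.65%, the small excess being the complexed-fraction discrepancy
above).

## Relay flash regime

Oxidative quenching by the viologen shortens the excited-state lifetime
from 600 to 110 ns at 10 mM, fixing kq = 7.4 × 10⁸ M⁻¹s⁻¹. Cage escape is a
branching probability on the quench event, not an explicit encounter
complex — the data constrain only the escape yield. The default
φ_ce = 0.239 is fixed by the printed radical quantum yield (19.5%) divided
by the quench fraction (1 − 110/600), consistent with the ~20% cage-escape
yields quoted for this couple. The escaped radical then partitions between
recombination with Ru(III) (3.1 × 10⁹ M⁻¹s⁻¹) and T1 reduction
(3.8 × 10⁸ M⁻¹s⁻¹), reduced T1 recombining with Ru(III) at
4.6 × 10⁸ M⁻¹s⁻¹. Enzyme-free, radical and oxidized sensitizer are exact
stoichiometric mirrors (a test asserts this to solver tolerance). Enzyme
quenching of the excited state is exposed (`kq_EnT`) but defaults to zero
in this regime: at mM viologen the enzyme channel is outcompeted and the
measured lifetime is insensitive to the enzyme.

## Anaerobic continuous illumination

Under continuous light the sensitizer is excited at an effective rate k_exc
per ground-state molecule — a single constant absorbing lamp spectrum,
extinction and geometry. It is calibrated (closed form, `calibrate_k_exc`)
so the radical production rate is 2 µM/s in the 300 µM-viologen reference
configuration, giving k_exc = 2.6 s⁻¹. EDTA (single-electron, irreversible,
inert product) resets Ru(III).

The resting-oxidized enzyme is an eight-state ladder, T1(ox/red) crossed
with 0–3 electrons on the TNC. Electrons enter exclusively at T1 (from the
radical at 3.8 × 10⁸ M⁻¹s⁻¹ for any T1-oxidized state, or from the excited
sensitizer through a low-yield direct branch); internal transfer moves them
to the TNC. The first two internal steps default to k₊ = k₋ = 1 s⁻¹
("close to equilibrium"; the fits that motivated them are insensitive above
~0.1 s⁻¹); the third is endergonic with k₊/k₋ = 1/4500, i.e.
ΔG = +0.216 eV by detailed balance. That one number generates the
characteristic phenomenology: without mediator the enzyme stalls at three
electrons (T1 stays reduced, the fourth electron cannot pass), and with
mediator the 610 nm trace decays to zero, waits — the lag during which the
long-lived radical slowly pushes the fourth electron uphill — and only then
does the radical accumulate (610 and 395 nm rising together). A 1:1
irreversible viologen adduct on the fully reduced enzyme
(k_sink = 10⁴ M⁻¹s⁻¹) withholds roughly one enzyme equivalent of mediator
from the photoactive pool, reproducing the "missing" radical amplitude;
below the enzyme stoichiometry (e.g. 25 µM viologen against 30 µM enzyme)
this sink sequesters the entire mediator pool, so lag read-outs are only
meaningful above it — the lag tests therefore scan 50–300 µM.

The direct branch is parameterized as a productive fraction
φ_direct = 0.0075 per enzyme quench event. The printed overall direct yield
(0.75% per absorbed photon) would correspond to a several-times-larger
per-quench fraction; the smaller value is kept because it is the only
choice consistent with the >10-fold acceleration of T1 reduction by 300 µM
viologen that the continuous-illumination data show (see Limitations).

The radical-accumulation detector (`mv_lag_time`) triggers at baseline +
max(3σ, 5% of the trace excursion): during fourth-electron uptake the
radical sits at a small production-limited plateau that a bare 3σ rule
would misread as accumulation on noiseless traces.

## Aerobic regime

With oxygen present, internal transfer is fast and nearly isoenergetic, so
the enzyme collapses to an electron counter E⁰…E⁴; E⁴ + O₂ → E⁰ + 2 H₂O
closes the catalytic cycle. The radical is intercepted by O₂
(6.6 × 10⁸ M⁻¹s⁻¹, a literature-magnitude default) to give superoxide,
which either dismutates (effective 10⁷ M⁻¹s⁻¹, second order) to O₂ + H₂O₂
or reduces the enzyme through a reversible adduct: fast association
(10⁸ M⁻¹s⁻¹), fast dissociation (10⁴ s⁻¹), slow internal transfer
returning O₂ (k_iet = 100 s⁻¹). The steady-state effective bimolecular
rate k_ad·k_iet/(k_mad + k_iet) ≈ 10⁶ M⁻¹s⁻¹ then sits well under the
5 × 10⁶ M⁻¹s⁻¹ ceiling the oxygen-consumption kinetics allow, about two
orders below the mediator route — slow enough that superoxide-mediated T1
reduction contributes < 5% of the mediator-route amplitude on a 1 ms flash
window (invisible in transient absorption) yet fast enough to dominate
enzyme reduction under continuous illumination, where the flux ledgers
attribute ~80% of enzyme-reduction events to the superoxide route and
zeroing it perturbs the O₂ trace far more than zeroing the mediator route.
A single-constant bimolecular mode (`adduct_mode = FALSE`) is retained as a
config switch and agrees with the adduct mechanism to a few percent at
trace superoxide.

Stoichiometry anchors the regime: enzyme-free, two radicals are oxidized
and one H₂O₂ made per O₂ consumed; fully enzyme-routed (dismutation off),
four electrons per O₂ give exactly half the laccase-free consumption rate
at equal radical flux. Adding 10–20 µM enzyme to the reference
configuration cuts the initial O₂ consumption well below the laccase-free
rate and suppresses the H₂O₂ yield from ~1 to ~0.02.

`initial_o2_rate` fits a least-squares slope on a window, by default from
light-on until 10% of the initial oxygen is depleted; scans accept an
explicit window because the informative regime differs between
configurations (the no-mediator scans, whose fluxes are tiny, are read in
the light-limited quasi-steady segment after the enzyme pool has loaded).

## Synthetic data and recovery

The generator simulates a regime at its ground-truth parameters and adds
independent Gaussian noise: 5 × 10⁻⁴ absorbance on flash traces (the
scatter of µs transient records), 2 × 10⁻³ on steady-state absorbance,
1 µM on oxygen, optional linear drift. A dataset is pinned by its manifest
(parameters, seed, md5 per file); the same seed is byte-identical.
Replicate seeds derive from the master seed by a plain counter.
What the generator does *not* emulate: instrument response functions,
photon-counting statistics, baseline wander beyond linear drift, and
model error — the generating model is the fitting model. Passing recovery
tests therefore demonstrate identifiability and estimator correctness
under the stated noise, not robustness to mechanistic misspecification.

Recovery studies at the default noise recover the direct-scheme triplet
(k_cs, k_br, k_off) and the relay triplet (k_rec_MV, k2, k_rec_T1) with
biases well under 10% from three replicates; fitting works on log₁₀
parameters (rates span decades) inside box bounds, with a
finite-difference sensitivity-rank screen at the start point that warns,
naming the null directions, when a parameter set is not identifiable —
e.g. attempting to fit the T1 rates from an enzyme-free experiment.

## Problem sizes and numerical choices

The test and acceptance simulations use: flash grids of ~100–200
log-spaced points over 10 ns–1 ms; continuous runs of 300–800 s at 0.5–1 s
resolution (12,000 s at 20 s resolution for the mediator-free stall);
recovery studies of 3 replicates × 3 experiments × ~280 points. These sizes
were chosen so each closed-form comparison resolves its fastest relevant
rate by at least an order of magnitude in grid density while keeping any
single study in seconds of compute. Ties and degenerate inputs are
rejected loudly (equal driving forces with unequal rates, zero pulse
yields, empty crossing brackets return an empty result rather than an
error, zero denominators raise typed conditions).

## Limitations

* The continuous-illumination and aerobic modules simplify the direct
  excited-state reduction of the enzyme to a low-yield bimolecular branch
  (φ_direct per quench event) instead of the association-complex mechanism
  of the flash module. Two printed observations cannot be reconciled under
  this simplification: the >10× acceleration by 300 µM viologen forces a
  small direct flux, while the recovery of the aerobic O₂-consumption rate
  at high enzyme loads (above the low-enzyme dip) requires a direct flux
  several times larger — in the source system that recovery is carried by
  the association-complex flux, which grows with enzyme concentration. With
  the small default, simulations reproduce the dip but not the
  high-enzyme recovery; the corresponding test documents this as a known
  model limitation rather than loosening its assertion.
* Rate constants are effective values at the working pH; no proton
  bookkeeping, no pH dependence, no temperature dependence outside the
  Marcus layer.
* The discrete channels 395/450/605/610 nm only; no full spectral
  reconstruction, inner-filter or photobleaching corrections.
* The viologen–enzyme sink is one admissible realization (1:1,
  irreversible on the experiment timescale) of a feature the source could
  only attribute tentatively; its rate constant is order-of-magnitude.
* Distance inference and the Förster/Marcus crossing depend on the
  documented default couplings and are calibrations, not measurements.
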