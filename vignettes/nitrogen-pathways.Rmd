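---
title: "Nitrogen pathways in anammox-based treatment: stoichiometry, mass balances, and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nitrogen pathways in anammox-based treatment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitropath)
```

## 1. The stoichiometric engine

Every reaction in `nitropath` is a signed molar coefficient vector over a
species registry (reactants negative, products positive). The five
built-in half-reactions are the conventional ones for the nitrogen cycle
around anammox:

```{r}
rx <- builtin_reactions()
for (r in rx) print(r)
```

Four of the five balance exactly in C, H, O, N and charge
(`element_balance()` returns residuals below 1e-9 mol). The anammox
equation as conventionally written omits the biomass-synthesis term, so it
does *not* balance: its residuals are N -0.02, O +0.14, H 0 and charge
+0.06 mol per mol NH3. Rather than loosening the global balance tolerance,
the reaction carries an `empirical = TRUE` flag that routes it through a
relaxed check (`assert_balanced()`); the 0.02 mol N deficit is carried
through the simulator as nitrogen incorporated into biomass, which keeps
the simulated nitrogen balance closed.

### Closure weights

A *process case* is a triple of half-reactions combined so that the net
nitrite and nitrate coefficients vanish while exactly 1 mol NH3 is
consumed. These three conditions are linear in the weights, so
`solve_case_weights()` solves a 3x3 system (errors report the rank when
the system is singular, and negative solutions are rejected as
infeasible). For the three built-in cases the solved weights are, up to
the common NH3 normalization:

* Case I (PN/A + denitrification): 1.32 : 1 : 0.26, normalized by 2.32;
* Case II (complete nitrification + PD/A): 1.06 : 1.32 : 1, normalized by 2.06;
* Case III (PN/A + PD/A): 1.06 : 1 : 0.26, normalized by 2.06.

A by-product of the same machinery: without a denitrification step,
partial nitritation + anammox with nitrite closure routes
0.26/2.32 = 11 % of the influent ammonium to nitrate
(`pna_nitrate_yield()`), which is why a PN/A reactor needs a polishing
step at all.

### Demands and the rounding convention

`demands()` prices a combined reaction per mg NH3-N: oxygen as
`|O2| * 32/14`, organics as `sum |coeff| * ThOD / 14` over carbonaceous
reactants. ThOD uses the electron-equivalent rule, 8 g O2 per equivalent
with ionic charge correction (`8 * (4C + H - 2O - charge)`); acetate gives
64 g O2/mol. Nitrogen-containing organics are rejected — acetate is the
only organic in scope and a general nitrogenous-ThOD model would be a
different package.

One numerical subtlety: published demand tables for these cases are
computed from molar coefficients that were themselves rounded to two
decimals. Case I is the visible instance: the full-precision O2
coefficient is 1.98/2.32 = 0.8534, giving 1.95 mg O2/mg N, while the
published 1.94 equals `round(0.85 * 32/14, 2)`. `demands()` therefore
reports full precision by default and offers `table_rounding = TRUE`,
which rounds the molar coefficients first and reproduces the published
cells exactly; `reproduce_table2()` compares all twelve cells under that
convention.

## 2. Endpoint mass-balance apportionment

`apportion_phase1()` (nitrifying, carbon-free operation) and
`apportion_phase2()` (strictly anoxic, carbon-dosed operation) implement
the standard two-point balances documented in `?apportion_phase1`. Both
are linear in the concentration differences, which gives two useful
properties (both tested): apportionments are additive over sub-intervals
of a cycle, and the phase-2 identity
`tn_anammox + tn_denitritation = delta_n` holds exactly by construction.

Design choices made here:

* **The 2.04 vs 2.06 constant.** The mass-balance tradition uses 2.04 mg
  TN removed per mg NH4-N removed by anammox, while the reaction vector
  itself implies 1 + 1.32 - 0.26 = 2.06. The package keeps both:
  `stoich_params()` defaults to the traditional 2.04 (used exactly where
  that tradition uses it), and `stoich_params("closed")` recomputes the
  constant from the configured reaction. The mismatch is small but
  visible: apportioning a *perfect* anammox conversion with 2.04 yields a
  spurious NH4_AOB of -0.98 % of the ammonium; closed mode returns
  exactly zero. Simulation-validation tests use closed mode so the oracle
  comparison is not polluted by this constant.
* **Operator grouping.** The phase-2 anammox term is
  `(NH4_i - NH4_f) * 2.04` — the difference is multiplied, not the final
  concentration alone, which is the only reading that produces sensible
  (non-negative) results on real cycle data.
* **Negative components are information.** A negative `nh4_aob`,
  `no3_nob` or `no3_denitratation` means a pathway the balance ignores
  was active. Components are reported as computed and flagged in
  `warnings`; `clamp = TRUE` floors them at zero *after* flagging.
  Silent clamping would hide exactly the diagnostic these balances exist
  to provide.
* **Endpoint convention.** "Initial" means immediately after feed mixing
  (`mix_feed()`, concentration-weighted by the volume exchange ratio);
  "final" means the end of the anoxic react phase. Settling and decant
  are treated as reaction-free.

### Batch statistics

`nitrate_to_nitrite_transformation()` computes
`NTR(t) = (NO2(t) - NO2(0)) / (NO3(0) - NO3(t)) * 100` and its maximum
over the trace (the maximum can occur mid-test when nitrite later drains
to N2, so the whole series is scanned). The denominator is guarded by
eps = 0.1 mg N/L — typical analytical precision — to avoid ratio blow-up
at the start of a trace; if nitrate is never reduced beyond the guard the
result is flagged undefined rather than returning a junk maximum. NTR is
invariant under uniform scaling of all concentrations.

`phase_summary()` reports per-phase mean, *sample* (n-1) standard
deviation and n — the convention is not universal in the field, so it is
stated here and in the docs. `nitrogen_removal_efficiency()` is provided
for both per-day series and campaign means; note that "mean of daily
efficiencies" and "efficiency of mean concentrations" differ for variable
influent, and the package computes whichever the caller asks for rather
than asserting one of them.

## 3. The SBR cycle simulator (synthetic-data generator)

`simulate_cycle()` integrates six processes — anammox, aerobic ammonium
oxidation, nitrite oxidation, denitratation, denitritation and aerobic
COD oxidation — with dual-Monod rate laws
`mu * X * S1/(K1+S1) * S2/(K2+S2)`, an oxygen Monod term for aerobic
guilds and an oxygen inhibition switch `Ki/(Ki+DO)` for anoxic guilds.
The stoichiometric couplings are shared with the reaction module
(1.32 NO2-N consumed and 0.26 NO3-N produced per NH4-N by anammox;
16/14 and 24/14 mg COD per mg N for the two heterotrophic steps by
acetate electron bookkeeping). Alongside the concentrations, the
integrator accumulates each process rate, so every simulated cycle
carries exact ground-truth pathway integrals (`$truth`) — the oracle
against which the endpoint balances are validated.

**What the generator emulates.** The default schedule is 10 min feed at
50 % volume exchange (treated as instantaneous mixing, since feed is
short against the 360-min react phase), 360 min anoxic react, 30 min
settle, 10 min decant, 70 min idle, three cycles per day. The built-in
influent specifications are zero-truncated normals: phase I
(14.3 ± 2.5 / 14.1 ± 2.4 / 1.2 ± 0.8 mg N/L of NH4/NO2/NO3, no
biodegradable organics) and phase II (12.5 ± 1.8 / 12.3 ± 1.4 /
2.0 ± 0.6 mg N/L plus 24.2 mg COD/L acetate, an rbCOD/TN ratio of 0.9).
The acetate sd is set to 2.4 mg/L (~10 % relative), a realistic dosing
variability for a bypass stream; the source tables state only the mean.
DO is prescribed constant by default — 0.07 mg/L for the organics-free
regime and 0.03 mg/L for the carbon-dosed regime, the midpoints of the
reported operating ranges — because bulk DO in such reactors is reported
as a measured near-constant range; a dynamic `kLa` mass-transfer mode is
available. Campaigns sample one influent batch per day (a daily feed
tank) and report the last cycle's endpoint as the daily effluent; that
choice is recorded in the output metadata.

**What it does not emulate.** Total biomass defaults to 4.9 g VSS/L, but
the rate constants are order-of-magnitude literature values chosen once
so that a default cycle removes most of its ammonium and nitrite within
the react phase — they are illustrative, not fitted to any particular
reactor. No granule diffusion limitation, washout selection, community
dynamics, temperature dependence or free-ammonia/nitrous-acid inhibition
is modelled, and heterotrophs consume acetate directly (no
storage-polymer mechanism). A green validation test therefore
establishes that the mass-balance *method* is correct under its own
assumptions and degrades predictably when they are violated — not that
the kinetic parameters describe any physical reactor.

**Numerical choices.** Integration uses an adaptive Dormand-Prince 5(4)
pair (written in-package; no ODE solver package is available in the
target environment) at rtol 1e-8 / atol 1e-10. Monod terms are evaluated
at `max(S, 0)`, so rates vanish smoothly as substrates deplete and
concentrations cannot go negative beyond integrator error; outputs are
floored at zero. Because the ground-truth integrals are integrated as
additional states of the same system, nitrogen closure — TIN removed
equals N2-N produced plus biomass-incorporated N — and the analogous COD
closure hold to integrator accuracy (tested at 1e-6 relative, observed
near machine precision).

**Validation scenario.** The oracle-recovery tests use a single anoxic
cycle with nitrifiers disabled, an ammonium/nitrite/acetate-rich feed
(8/25/5 mg N/L + 60 mg COD/L over a residual of 1/8/3 + 5), chosen *a
priori* so that the anammox, denitratation and denitritation integrals
are each several mg N/L — well above the 0.2 mg/L analytical noise used
in the robustness check. Noise robustness is assessed by drawing 100
seeded noise realizations of the endpoint measurements of that one
noise-free cycle (the quantity under test is measurement noise, not
process stochasticity). All randomness in a campaign flows from a single
seed set once at campaign start; reruns are bit-identical.

## 4. Input/output and configuration

Cycle and batch profiles use a fixed CSV schema
(`time_min,nh4_mgN_L,no2_mgN_L,no3_mgN_L[,cod_mg_L,do_mg_L]`; header
mandatory, '.' decimal separator); campaigns use
`day,phase,inf_*,eff_*` with TN derived as NH4+NO2+NO3. Readers validate
the schema and name the offending row/column on error; writes round-trip
to 1e-9. Configurations are plain R lists (`default_config()`)
serializable to JSON (`write_config()` / `read_config()`); JSON rather
than YAML because the target environment provides jsonlite.
`make_fixtures()` writes a deterministic set of small example files —
pure-anammox, nitrifying and carbon-dosed cycles, anoxic batch tests at
COD/NO3-N ratios 0.5-2.0 with 15 mg NO3-N/L (and 10 mg NH4-N/L in the
variants where anammox participates), and a 20-day campaign — plus a
manifest with file digests.

## 5. Known limitations

* The endpoint balances ignore N2O and DNRA entirely, as does the
  simulator; apportionment sums to total inorganic N by construction.
* The traditional 2.04 constant and the 2.06 implied by the reaction
  vector cannot both be "right"; the package's position is to expose
  both and default to tradition for field comparability.
* Kinetic defaults are illustrative (see above); quantitative statements
  about any real reactor require calibrated parameters.
* Figure-scale observations from operating reactors (e.g. a cycle ratio
  of 0.92, campaign efficiencies) are qualitative behaviours the
  simulator can display, not quantities the package asserts.
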