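---
title: "Screening canonical-loop inhibitor variants: hydrogen-bond networks, loop rigidity, and binding kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening canonical-loop inhibitor variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(looprigor)
library(dplyr)
```

## The scientific problem

Canonical (standard-mechanism) serine protease inhibitors — the Bowman–Birk
family and its relatives — bind their target protease through a rigid,
extended loop. Rigidity is what makes the mechanism work: the scissile bond
can be cleaved and re-ligated while the inhibitor stays bound, and a loop
that holds its conformation pays less entropy on binding and keeps the P1′
amine positioned for religation. The loop is held rigid by an internal
hydrogen-bond network (plus disulfides), so when the loop is re-engineered
for a new target — as when the 14-residue cyclic sunflower trypsin inhibitor
SFTI was redirected from trypsin to kallikrein-related peptidase 4 (KLK4) —
substitutions that disrupt that network can cost potency even when the
protease contacts improve.

`looprigor` implements the analysis half of an in-silico screen built on
this idea: molecular-dynamics (MD) ensembles of inhibitor–protease complexes
are reduced to per-bond hydrogen-bond occupancies and Cα-RMSD rigidity
profiles; variants are ranked by their mean internal hydrogen-bond count;
and the ranking is compared against measured inhibition constants from
tight-binding and slow-binding enzymology. The MD itself (GPU-scale,
explicit solvent) and the wet-lab assays are out of scope — synthetic-data
generators emulate both, so every stage of the analysis is testable on a
desktop.

## Hydrogen-bond occupancy analysis

A hydrogen bond is detected geometrically, per frame, for every
donor-heavy/acceptor pair on different residues:

* donor–acceptor distance ≤ 3.3 Å, and
* at least one donor hydrogen with a D–H···A angle within 40° of linear
  (i.e. ≥ 140°).

These defaults follow the convention used by trajectory post-processing
tools for explicit-hydrogen MD; both cutoffs are configurable through
`hbond_criteria()`. The bond's identity across frames is the directed
(donor-heavy, acceptor) pair — which hydrogen satisfied the test does not
matter, and a pair counts once per frame no matter how many hydrogens pass.
Adjacent-residue backbone pairs are deliberately *not* excluded; only
intra-residue pairs are. A `require_hydrogens = FALSE` mode accepts on
distance alone for hydrogen-free toy structures; summaries flag it.

Bonds are classified by chain role: *internal* (both endpoints on the
inhibitor), *intermolecular* (one inhibitor, one protease endpoint), or
*other* (excluded from summaries). **Occupancy** is the fraction of frames
in which a bond is present; the persistent network keeps bonds with
occupancy strictly above 0.5 ("more than half of frames"). Per-residue
frequencies sum the occupancies of every bond a residue participates in,
with each bond crediting both of its residues; values are stored unrounded
and displayed to one decimal with half-up rounding (`round_half_up()`),
matching tabulation convention.

Replicate statistics follow the study design they emulate: the per-run mean
per-frame count is averaged over runs, and the SEM is the standard deviation
of run means divided by √(number of runs). Within-run frame autocorrelation
is deliberately ignored — the replicate, not the frame, is the unit of
inference. With a single run the SEM is reported as `NA`. No burn-in is
discarded by default (the frames analysed are production frames); a
`burn_in` argument exists.

Which atoms count as donors and acceptors is chemistry the detection needs
but trajectory tools differ on; `default_donor_acceptor_table()` covers the
standard amino acids (backbone amide/carbonyl everywhere except proline's
nitrogen, side chains from the arginine guanidino nitrogens to the serine
hydroxyl, which is both donor and acceptor) and is replaceable. Unknown
residues fall back to backbone-only chemistry with a warning.

```{r hbond-demo}
bonds <- tibble::tibble(
  donor_resno    = c(2L, 4L, 6L, 8L, 1L),
  acceptor_resno = c(5L, 9L, 12L, 3L, 7L),
  class          = c(rep("internal", 4), "intermolecular"),
  occupancy      = c(1.0, 0.9, 0.6, 0.2, 0.8)
)
spec <- trajectory_spec(programmed_bonds = bonds, n_frames = 400,
                        n_runs = 3, seed = 7)
traj <- make_trajectory(spec)$trajectory
summary <- summarize_hbonds(traj)
summary$class_summary
```

The mean internal count approaches the sum of the programmed internal
occupancies (here 2.7), the mean-count identity that also serves as a test
invariant.

## Loop rigidity: superposition and Cα RMSD

Rigidity is read from Cα RMSD after optimal rigid-body superposition
(`kabsch_superpose()`, the standard SVD solution with the reflection
excluded). Two references answer two questions:

* **against the starting structure** (`rmsd_profile(..., reference =
  "start")`): does the loop hold its initial conformation?
* **against the trajectory-average structure** (`reference = "average"`):
  whatever conformation it adopted, is it stable?

A variant can drift from its start yet be rigid about a new conformation;
comparing the two profiles separates the drift from the wobble.
`per_residue_rmsd()` reads the same global fits out per residue, the
quantity used to colour structures from rigid to mobile.

The average structure is computed single-pass by default: superpose every
frame onto frame 1, then take the per-atom mean. Single-pass is
deterministic and adequate at this scale, but it imprints the reference
frame's own noise on the average; `iterate = TRUE` re-superposes against
the running average until it moves less than 1 Å × 10⁻⁴, which removes that
bias and is what the convergence tests use. Fitting and readout both default
to the inhibitor's Cα atoms and are configurable independently. Multi-run
sets give per-run profiles plus a pooled mean; both are reported because
published RMSD traces rarely state which was plotted.

## Inhibition kinetics

The enzymology module covers the four regimes the screen's validation used.
Units are explicit in every signature (substrate and Km in µM, inhibitor and
Ki in nM, rates in s⁻¹), and conversions to molar happen internally —
silent unit mismatch is the dominant bug class in this arithmetic.

**Competitive inhibition** — `v = Vmax·S / (Km(1 + I/Ki) + S)`, fitted by
`fit_competitive()` with Km free or fixed.

**Morrison tight binding** — when inhibitor potency approaches the enzyme
concentration, depletion of free inhibitor by the enzyme is not negligible
and the classical isotherm misestimates Ki. The Morrison equation is the
closed-form quadratic for the fractional velocity at total concentrations;
`fit_morrison()` fits the apparent constant and converts via
`Ki = Ki_app / (1 + S/Km)` with Km fixed at its supplied value. Km
uncertainty is not propagated by default (matching how such fits are
usually reported); `propagate_km = TRUE` enables first-order propagation.
As the enzyme concentration tends to zero the model collapses to the
classical isotherm — a tested limit.

**IC50** — a four-parameter logistic on log10 concentration with
constrainable asymptotes (`fit_ic50()`). Under tight binding the IC50
depends on enzyme concentration (≈ E/2 + Ki_app), so the package treats
IC50 as descriptive and Ki as mechanistic.

**Slow binding** — progress curves with a lag,
`P(t) = vs·t + (v0 − vs)(1 − e^(−k_obs·t))/k_obs`. `fit_koff()` analyses
the standard three-curve design (uninhibited; substrate and inhibitor added
together; preformed complex diluted into substrate). The primary estimator
is the slow-binding relation `k_off = k_obs · vs/v0` from the co-addition
curve. Because "read the steady states back to the time axis" is a
plausible alternative reading of graphical k_off extraction, a secondary
estimator from the back-extrapolated steady-state intercepts of the two
inhibited curves, `k_off = vs / |Δintercept|`, is also reported; on clean
curves the two agree. The association rate follows as
`k_on = k_off / Ki` (`second_order_kon()`), and values near 10⁹ M⁻¹s⁻¹
indicate diffusion-limited binding.

**Stability** — `fit_half_life()` fits `A(t) = A0·e^(−λt)` and reports
`t½ = ln 2 / λ` with a delta-method standard error; non-decaying series
warn and return an undefined half-life rather than a spurious number.

All fitters run Levenberg–Marquardt least squares with data-derived starting
values (Vmax ≈ max rate, IC50 ≈ the half-maximal concentration, k_obs ≈
3/t_max), zero lower bounds, and tight convergence tolerances; they are
deterministic given the data. Non-convergence and unidentifiable designs
(no inhibitor variation, no transition in range, no measurable inhibition)
are reported as errors or `converged = FALSE`, never silently. Results are
`kin_fit` objects with `tidy()`/`glance()` methods.

```{r kinetics-demo}
spec_ki <- kinetics_spec(
  "morrison",
  true_params = list(Ki_nM = 0.0386, enzyme_nM = 0.15,
                     substrate_uM = 500, Km_uM = 679.9),
  design = list(inhibitor_nM = 0.15 * 10^seq(-2, 1, length.out = 8))
)
fit <- fit_morrison(make_kinetics(spec_ki)$data,
                    enzyme_nM = 0.15, substrate_uM = 500, Km_uM = 679.9)
tidy(fit)
```

## The variant screen and the rigidity–potency correlation

`build_screen_report()` assembles per-variant summaries into the screen
table: variants sorted by mean internal bond count (descending, with a
deterministic name-order tie-break), percent change of each class mean
against a designated reference variant, and joined potencies. Variants
without potency data remain first-class rows — in a real screen most
variants are never synthesised. The correlation block reports Spearman's ρ
plus Pearson's r on Ki and on log10 Ki, for internal, intermolecular and
total counts. Spearman is the claim the data actually supports: potencies
span three orders of magnitude, so any parametric correlation is dominated
by the extremes, while the rank correlation is invariant to monotone
rescaling (a tested property). All three bond measures are reported without
asserting significance for any; on the bundled reference data the internal
count is the one that ranks potency perfectly.

```{r screen-demo}
report <- build_screen_report(
  sfti_hbond_table(), reference = "SFTI-FCQR Asp14",
  potencies = transmute(sfti_potency_table(), variant, ki_nM, ic50_nM)
)
glance(report)
```

The bundled tables (`sfti_hbond_table()`, `sfti_potency_table()`) carry the
literature-reported values for the nineteen-variant SFTI-FCQR residue-14
screen and its seven assayed variants, so the join and the correlation can
be reproduced without any trajectory data.

## What the synthetic generators emulate — and what they do not

`make_trajectory()` stands in for MD. It builds a poly-alanine-like
two-chain topology (14-residue inhibitor, 20-residue dummy protease by
default) and, for each programmed bond and frame, either places the acceptor
carbonyl oxygen collinear with the donor N–H at 2.9 Å (satisfying the
criteria with margin) or parks it beyond 5 Å of any donor, independently
per frame with the programmed probability. Gaussian jitter (default
σ = 0.05 Å) is added everywhere as a minimal stand-in for thermal motion —
small enough that programmed geometry stays inside the cutoffs, large
enough that exact-coordinate shortcuts would fail. Cα positions are
staggered off the backbone line so superposition is well-conditioned.
Defaults mirror the emulated study conditions: three replicate runs of 5000
frames (tests use a few hundred frames except where the binomial bounds
require the full count). Every run and variant derives its seed
deterministically (`derive_seed()`), and the realised truth (per-bond
occupancy, per-frame class counts) is returned alongside so checks never
re-derive it.

What this deliberately does **not** emulate: force-field energetics,
solvent, side-chain rotamers, correlated motions, or frame-to-frame
autocorrelation. Passing tests therefore demonstrate that the *analysis* —
detection, classification, occupancy statistics, replicate aggregation,
ranking — is correct, not that MD of a real complex would reproduce any
particular bond network. The published per-variant bond counts derive from
~28,000-atom explicit-solvent simulations and are not reproducible at desk
scale; they enter the package only as printed reference values.

`make_kinetics()` similarly evaluates the named rate law on a stated design
and adds optional seeded Gaussian noise (as a fraction of the uninhibited
signal). Noiseless generation followed by fitting is an inverse-crime
closure test — it validates the fitter against its own model, which is
exactly what is wanted for verifying the regression machinery, and nothing
more.

## Numerical choices and degenerate inputs

* Persistence filtering is strictly greater-than at the threshold
  (occupancy exactly 0.5 is excluded by "more than 50%").
* The Morrison discriminant is clamped at zero before the square root and
  the fraction clamped to [0, 1]; both guards only ever absorb rounding.
* Kabsch superposition rejects reflections by sign-correcting the smallest
  singular vector; fewer than 3 points or mismatched dimensions are errors.
* The slow-binding curve is linear when `v0 = vs`; a fit with
  `k_obs · t_max < 1` (no visible lag in the window) warns, and
  steady-state ≈ initial rate makes k_off undefined (error).
* PDB I/O stores coordinates to 3 decimals; round trips are exact at that
  precision. Insertion codes are rejected, first alternate locations kept,
  and inconsistent atom sets across MODEL blocks are a topology error.
* Ranking ties break on variant name so reports are reproducible
  byte-for-byte.

## Problem sizes

The test-suite defaults were chosen to keep the full suite around half a
minute: synthetic trajectories of 120–500 frames for behavioural tests, the
full 5000-frame single-run case where occupancy-recovery bounds are the
point, twenty-frame round trips for I/O, and 20–24 random frames for the
brute-force detector equivalence. The acceptance script fits three kinetic
datasets of 8–30 points and runs in seconds.

## Known limitations

* Only multi-model PDB input is supported; binary trajectory formats
  (DCD/XTC) would need conversion upstream.
* Hydrogen-bond detection is geometric; no energy scoring, water-mediated
  bridges, or salt-bridge special-casing.
* The donor/acceptor table covers standard amino acids; non-standard
  residues get backbone-only chemistry unless a custom table is supplied.
* `fit_koff()` assumes the three curves share a time base and that enzyme
  and substrate depletion are negligible over the window.
* The correlation block is descriptive; with seven assayed variants no
  significance testing is attempted.
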