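---
title: "Methods: chemical-potential landscapes and loop repair"
author: "gibbscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chemical-potential landscapes and loop repair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gibbscape)
```

## The model

A metabolic network at steady state is described by its M × N
stoichiometric matrix S (substrates negative, products positive) and a
direction assignment σ_r ∈ {+1, −1, 0} per reaction (0 = no constraint,
e.g. a reaction treated as not operating). The second law of thermodynamics
requires every operating reaction to dissipate Gibbs energy:

σ_r ΔG_r ≤ −ε  for all constrained r, with ΔG_r = Σ_i S_ir μ_i.

The unknowns are the chemical potentials μ_i (kJ/mol). The system is a set
of homogeneous linear inequalities; its solution set is a convex cone. Two
consequences shape everything in the package:

* **Loop law.** For any steady-state flux vector v (S v = 0), Σ_r v_r ΔG_r
  = μᵀ S v = 0 identically. Energy dissipated along any closed flux pattern
  must vanish, which is why directed loops are fatal.
* **Farkas/Gordan alternative.** Exactly one of the following holds: the
  strict system has a solution, or there are weights γ ≥ 0, γ ≠ 0 with
  Σ_r γ_r σ_r S^(r) = 0. The latter identifies an *infeasible loop*; the
  weights are a checkable certificate (`verify_loop_certificate()`).

The margin ε (default 10⁻⁶ kJ/mol) exists because floating point cannot
certify strict inequalities and because the MinOver convergence guarantee
assumes a solution with positive margin. It is far below any chemically
meaningful energy difference, so it does not distort results.

## Solvers

**MinOver** (`minover_solve`). Repeat: find the least satisfied constraint
r₀ = argmax σ_r ΔG_r (ties broken at the lowest reaction index so reruns
are deterministic); if its value is ≤ −ε, stop; otherwise update
μ ← μ − λ σ_{r₀} S^(r₀) on unclamped metabolites. The step constant λ
(default 0.1 kJ/mol) is scale-sensitive relative to the prior spread;
convergence, when a positive-margin solution exists, holds for any λ > 0,
with an iteration bound that degrades as the margin shrinks. The hot loop
is implemented in C++ with a precomputed Gram matrix so each iteration
costs O(N) rather than O(MN); constraint values are refreshed from scratch
every 8192 iterations to cancel floating-point drift, and the final
reported violations are always recomputed exactly.

**Relaxation** (`relaxation_solve`, Agmon–Motzkin). The same sweep with a
violation-proportional step, α (σ ΔG + 2ε)/‖S^(r₀)‖² along the constraint
normal, α ∈ (0, 2). The classical method aims at the constraint boundary;
we aim at −2ε so that the satisfaction test at −ε is crossed in finitely
many visits even for under-relaxed α < 1 (at ε = 0 the step is exactly the
classical one, and α = 1 lands the constraint on its boundary).

**Penalty** (`penalty_solve`). Subgradient descent on
‖μ − μ₀‖² + β Σ_{violated r} σ_r ΔG_r, with β raised by `beta_step` each
time an inner minimum is reached while violations remain (defaults: η =
10⁻³, β₀ = 1, step 1, inner tolerance 10⁻⁸ on the step norm). For large
enough β the minimizer is the Euclidean projection of the prior center onto
the feasible region — the distance-optimal feasible landscape, used as the
benchmark for MinOver's distances. The cost is piecewise smooth: at its
minimum the active (violated) set generically chatters, and a constant step
would oscillate forever. The step is therefore halved whenever the active
set changes between iterations — a standard diminishing-step subgradient
schedule — which makes the iterate converge to the projection; the
half-space test case matches the analytic projection to ~10⁻⁸.

**Clamps and bounds.** Clamped potentials (e.g. water) are held bit-exactly
fixed by every solver; they set the energy scale and can bound the solution
cone. Box bounds L_i ≤ μ_i ≤ U_i are encoded as synthetic single-variable
constraint columns tied to a reference metabolite clamped at 1, so all
solvers handle them with their unmodified update rule — one code path.
`boundedness_check()` decides whether the recession cone of the constrained
system is {0} by maximizing each coordinate under an ℓ∞ cap, returning a
recession ray as a witness when it is not; a rank test would miss
inequality-only rays.

## Priors

`build_prior()` turns a table of standard formation energies and
concentration ranges into per-metabolite uniform boxes for the chemical
potentials, via the dilute-solution relation μ = ΔG_f° + RT ln(c / 1 M)
with RT = 2.4790 kJ/mol at 298.15 K (temperature configurable):

* concentration data (center c, standard deviation s): the box endpoints
  are the images of c ± 2s. The span is symmetric in *concentration* — the
  physically stated quantity — and the asymmetric μ-interval is then
  symmetrized (center at μ(c), halfwidth = half the mapped width); a policy
  flag switches to symmetric-in-μ for sensitivity checks. c − 2s ≤ 0 is
  rejected as degenerate.
* formation energy only: centered at μ(ΔG_f°, 10⁻³ M) and spanning four
  orders of magnitude of concentration uniformly on the μ scale
  (halfwidth 2 RT ln 10 ≈ 11.42 kJ/mol). The default concentration for
  such metabolites, 10⁻³ M, is a typical intracellular metabolite level
  and is configurable.
* clamped metabolites: halfwidth 0, fixed at their center.

`sample_prior()` draws each unclamped μ_i independently and uniformly from
its box; the prior is a product measure, so any correlation in the fitted
ensembles is created by the solver dynamics, not the initialization. The
prior only initializes the solver: solutions may leave the boxes, and no
post-hoc re-boxing is applied.

## Loop identification and repair

On an infeasible assignment MinOver cannot converge: the least satisfied
constraint travels along a loop and the dynamics becomes (almost) periodic.
`minover_solve` therefore records the tail of least-satisfied indices
(window default min(10⁴, max_iters)) and per-reaction visit counts.
`find_loop()` then works in two stages:

1. **Visit-count shortcut.** Over one period the number of updates per
   constraint is itself a valid weight vector, so the counts restricted to
   the candidates are tried as γ and verified directly — cheap and often
   exact when a single cycle dominates.
2. **Subset enumeration.** Subsets of the candidate set are enumerated by
   increasing size k = 2..k_max (lexicographic within k) and tested for a
   strictly positive vanishing combination of their signed columns: a
   one-dimensional nullspace is inspected directly, higher-dimensional
   cases go to a small LP. The first hit — smallest k, lexicographically
   first — is returned, which also makes the returned certificate minimal
   within the candidate set. k_max defaults to 8 (covering the short cycles
   that dominate real networks, with headroom) and the enumeration carries
   an explicit budget (2 × 10⁶ subsets) because the search is exponential
   in the worst case; exhausting it raises a budget error distinct from
   "no loop found".

`remove_loop()` flips exactly one reversible loop member chosen uniformly
(seeded, so runs replay); a loop with no reversible member is reported as
an unrepairable error carrying its certificate — under the annotation, such
an assignment cannot be made thermodynamically consistent.
`correct_directions()` iterates solve → find → flip until feasible,
escalating the candidate set once (to every constraint that was ever least
satisfied) before giving up, and `catalogue_loops()` aggregates repairs
over an ensemble of random direction draws, deduplicating loops by reaction
set and sign pattern up to global inversion (a cycle and its reverse are
the same physical loop).

## The exact oracle

`lp_feasibility_oracle()` is the independent referee the heuristics are
validated against. For the homogeneous case it solves
min ‖Σ_r γ_r σ_r S^(r)‖² over the probability simplex (quadprog, ridge
10⁻¹⁰ for strict convexity) and decides the Gordan alternative *by
construction plus exact verification*: either the weights polish — via an
exact nullspace projection of their support — into a certificate whose
columns cancel to 10⁻⁸, or the induced witness μ = −Σ γ_r σ_r S^(r) has
strictly positive margin on every constraint (a KKT identity). Clamps and
bounds are handled by homogenizing with a slack coordinate. A dense-simplex
LP route (pracma) remains as a fallback for numerically ambiguous cases;
its pivot tie-breaking is randomized upstream, so it runs under fixed local
RNG streams with deterministic retries. Certificates returned for clamped
systems cancel on the unclamped subsystem (the clamped part enters the
homogenized system's slack row).

## Synthetic study conditions

The generator module defines the conditions under which every claim is
tested; its defaults are fixed once:

* `generate_network`: sparse S with coefficients in {−2, −1, 1, 2} (small
  integers, so certificates verify exactly and TSV round-trips are
  lossless), expected column density 0.3, every column nonzero,
  reversibility Bernoulli(0.5).
* `plant_feasible_directions`: witness μ* uniform on ±10 kJ/mol, reactions
  oriented downhill of μ*, coordinates resampled until every |ΔG_r| ≥ c.
  The margin c defaults to 1 kJ/mol; the oracle-agreement studies mix
  c ∈ {0.1, 1}.
* `plant_loop`: k fresh metabolites and k unit-coefficient cycle reactions,
  so the planted certificate (γ = 1) is the unique minimal loop through the
  new reactions — recovery tests are exact, not approximate.
* `random_instance`: 8–20 metabolites, 10–25 reactions; `hrbc_scale_fixture`:
  35 metabolites, 40 reactions, density 0.12, 10% reversible, half the
  metabolites with measured concentration ranges (log-uniform centers
  10⁻⁵–10⁻² M, sd = center/4), half with formation energies only, water-like
  clamp on one metabolite, directions planted downhill of a prior draw
  sharpened to margin 0.5 kJ/mol.

Validation problem sizes (500 mixed instances for oracle agreement, 200
each for loop recovery and repair soundness, 50 prior-equipped fixtures for
the distance comparison, 100 instances per step size for convergence) keep
each study well resolved while the whole suite runs in minutes.

What the synthetic conditions do *not* emulate: realistic degree
distributions and compartments, flux magnitudes (directions only),
correlated priors, and thermodynamically ambiguous annotations. Passing
these studies shows the algorithms are correct and calibrated on networks
with known ground truth; it does not by itself validate biological
conclusions on any particular reconstruction.

## Numerical choices and edge cases

* Feasibility is always re-verified on returned solutions
  (σ_r ΔG_r ≤ −ε + 10⁻⁹); solver status never stands alone.
* Tie-breaks: argmax at the lowest index; LP/QP pivot randomness is locked
  to fixed local RNG streams; all user-facing randomness flows through
  explicit seeds, and RNG state is restored around internal draws.
* Degenerate inputs: all-zero reaction columns, duplicate identifiers,
  non-numeric cells, directions on the wrong side of an irreversibility
  flag (error in strict mode, warning in lenient mode), all-unassigned
  assignments, and constraints touching only clamped metabolites (a stall —
  reported as such, since no update can improve them) are rejected with
  classed errors.
* The iteration cap defaults to 10 · N · 1000 and the solver reports
  MAX_ITERS rather than guessing; classification of an instance as
  infeasible additionally requires a verified certificate.

## Known limitations

* The margin/iteration relationship is weak at desk scale: deeper planted
  margins reduce iteration counts on average (the paired effect is
  consistently negative), but medians over 100 instances can tie, so the
  median comparison is a coarse check rather than a sharp law.
* Certified infeasibility searches are limited to loops of length ≤ k_max
  within the candidates the dynamics implicates; a pathological assignment
  whose shortest loop exceeds k_max would exhaust the search budget and be
  reported as undecided, not misclassified.
* Uniform sampling of the solution cone is out of scope: ensembles of
  solutions characterize the neighborhood of the prior, not the full
  solution space, and no claim of uniformity is made.
* Ensemble covariances (`potential_correlations`) are an empirical
  diagnostic. On minimal fixtures the sign of a covariance can differ from
  leading-order intuition about same-side/opposite-side metabolites,
  because update counts are strongly coupled to the initial draw when one
  constraint dominates; the diagnostic reports what the ensemble actually
  does.
* Repaired direction assignments are thermodynamically consistent but are
  not guaranteed to admit a steady-state flux vector; mass balance is not
  re-checked because flux values are never consumed.
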