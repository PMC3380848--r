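# gibbscape

Thermodynamic feasibility analysis and Gibbs energy landscapes for
metabolic networks at steady state.

## The problem

In a constraint-based model of metabolism, a steady-state flux configuration
fixes a direction σ_r ∈ {+1, −1} for every operating reaction. The second
law requires each reaction to run downhill in Gibbs energy,

    σ_r ΔG_r < 0,   with   ΔG_r = Σ_i S_ir μ_i ,

where S is the M × N stoichiometric matrix (substrates negative, products
positive) and μ_i is the chemical potential of metabolite i (kJ/mol). Two
questions follow:

1. **Landscape reconstruction.** Given feasible directions and a biochemical
   prior — standard formation energies ΔG_f° and concentration ranges,
   mapped through the dilute-solution relation μ = ΔG_f° + RT ln c — find
   chemical potential vectors that satisfy every inequality and stay close
   to the prior. The solutions bound metabolite log-concentrations and
   reaction affinities using stoichiometric information alone.
2. **Loop finding and repair.** A random or inferred direction assignment is
   usually *infeasible*: by the Farkas–Minkowski lemma this happens exactly
   when some reaction subset L admits strictly positive weights γ with
   Σ_{r∈L} γ_r σ_r S^(r) = 0 — a directed loop that would be a perpetual
   free-energy machine. The package certifies such loops, locates them, and
   repairs the assignment by flipping one reversible loop member at a time.

The workhorse is **MinOver**, a perceptron-style relaxation: repeatedly find
the least satisfied constraint r₀ = argmax σ_r ΔG_r and push the potentials
against it, μ ← μ − λ σ_{r₀} S^(r₀). Convergence is guaranteed whenever a
solution with positive margin exists; on an infeasible assignment the least
satisfied constraint cycles along a loop, and the visited-constraint tail
hands the loop to the detector. An Agmon–Motzkin relaxation solver
(violation-proportional steps), a distance-minimizing penalty solver (the
Euclidean projection of the prior onto the feasible region), and an exact
QP/LP oracle with Farkas certificates provide independent routes for
cross-validation. A seeded synthetic module generates networks with planted
feasible directions (known margin) and planted loops (known certificates),
so every claim is testable against ground truth.

## Worked example

A 35-metabolite, 40-reaction network with a realistic prior (half the
metabolites carry measured concentration ranges, the rest formation
energies only, water clamped), feasible directions, and one prior draw that
starts off thermodynamically inconsistent:

```r
library(gibbscape)

fx  <- hrbc_scale_fixture(3)                 # network + priors + directions
fit <- fit_potentials(fx$network, fx$sigma, prior = fx$priors, seed = 110)
summary(fit)
#> Thermodynamic potential fit (minover)
#>   status: FEASIBLE after 29 iterations
#>   constrained reactions: 40; worst sigma*dG: -0.594015 kJ/mol (target <= -1e-06)
#>   potentials in [-424, -24.03] kJ/mol; distance to prior 8.543 kJ/mol
```

The prior draw violated several constraints; 29 reinforcement steps deform
it into a consistent landscape 8.5 kJ/mol away (the true projection, from
`penalty_solve`, is 8.3 kJ/mol away — MinOver lands within a few percent of
the distance minimizer). Fitted potentials convert back to concentrations:

```r
mu <- coef(fit)
concentration_from_mu(fx$prior_table$dGf0[7], mu[7])
#> [1] 0.01278616
```

For that metabolite the fitted potential of −94.2 kJ/mol implies a
concentration of 1.3 × 10⁻² M, against a measured prior center of
3.7 × 10⁻³ M: reconciling the directions with the rest of the network
pushed this level above its prior box. The prior only initializes the
solver — solutions are free to leave the boxes when stoichiometry demands
it, and how far they move is exactly the information the landscape carries.

Loop repair on a planted 3-cycle:

```r
net     <- generate_network(8, 10, reversible_fraction = 0.4, seed = 11)
planted <- plant_feasible_directions(net, margin = 1, seed = 12)
aug     <- plant_loop(net, planted$sigma, k = 3,
                      reversible = c(TRUE, FALSE, FALSE))

lp_feasibility_oracle(aug$network, aug$sigma)$status
#> [1] "INFEASIBLE"
correct_directions(aug$network, aug$sigma, seed = 5)
#> direction_repair: FEASIBLE after 2 round(s), 1 loop(s) removed
```

The removed loop's certificate (reactions, signs, γ weights) is retained and
verifiable with `verify_loop_certificate()`; the repaired assignment differs
from the input only on the loop's one reversible member.

A command-line interface (`exec/gibbscape`) exposes the same workflows as
`check`, `solve`, `fix-loops` and `simulate` subcommands over plain TSV/JSON
files.

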