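# tatkit — transferability assessment for linear density functional approximations

Data-driven density functional approximations (DFAs) are trained by fitting a
handful of parameters to benchmark sets of chemical reaction energies. The
training error on the set you optimized is almost meaningless: flexibility can
always drive it down. What matters is whether the trained functional
*transfers* — whether it still predicts chemistry it was not trained on.
`tatkit` implements a transferability assessment toolkit around a controllable
family of double-hybrid DFAs, for method developers and benchmark curators who
want to quantify (and then engineer) that property.

## The model and the metrics

The functional family is linear in seven precomputed per-species energy
components (HF exchange, two semilocal exchange slots, two correlation slots,
and same-/opposite-spin MP2 correlation):

    E(a) = a1*E_x^HF + a2*E_x^aux + a3*E_x^GGA + a4*E_c^aux + a5*E_c^GGA
         + a6*E_c^MP2,ss + a7*E_c^MP2,os

A nested hierarchy XYG_p (p = 1…7 free parameters) is carved out of this form
by fixed reduction rules — e.g. p = 1 keeps only the exact-exchange fraction
α with a = (α, 0, 1−α, 0, 1−α², α², α²) — so the level of empiricism is a
dial. Training minimizes the mean absolute deviation (MAD, kcal/mol) over a
benchmark set ("benchset") of stoichiometric processes; because the model is
linear in `a` and every p ≥ 2 rule is affine, this least-absolute-deviations
problem is solved *exactly* as a linear program.

Cross-set performance is summarized by two quantities, both built from the
two-set error `MAD_B@A` (error on test set **B** of the model trained on
**A**):

* transferability matrix `T_B@A = (MAD_B@A + η) / (MAD_B@B + η)` with
  η = 0.01 kcal/mol: unitless, 1 on the diagonal, ≥ 1 whenever training
  finds the global optimum; larger is worse;
* transfer energy `ΔMAD_B@A = MAD_B@A − MAD_B@B`: the kcal/mol cost of
  training on the "wrong" set.

On top sit curation tools: a genetic algorithm that breeds fixed-size,
highly transferable subsets of a process pool, and a selection score
`N_el / mean_p T̄_p` that balances average transferability (over
p ∈ {1, 4, 7}) against the number of unique chemical elements covered.
A seeded synthetic-benchset generator with planted parameter vectors, noise,
regime structure and landscape-flatness controls makes every piece testable
without any quantum-chemistry input.

## Worked example

Two synthetic regimes share a species table: "sharp" (reference energies
sensitive to all parameters) and "flat" (MP2-type components damped, so its
error landscape is flat along the MP2-fraction direction), planted at
different optima:

```r
library(tatkit)
pair <- generate_two_regime(synthetic_spec(seed = 0))
fit_xyg(pair$sharp, 2)
#> xyg_fit: p = 2 trained on 'sharp'  (MAD = 0.376062 kcal/mol, status: global)
#> free: alpha = 0.649824, beta = 0.69988
#> a   : 0.649824 0 0.350176 0 0.30012 0.69988 0.69988
```

The planted sharp-regime parameters (α = 0.65, β = 0.7) are recovered to
three digits, and the training MAD sits at the noise floor of the σ = 0.5
kcal/mol reference noise. The transferability matrix makes the asymmetry
between the two regimes quantitative:

```r
tat_matrix(pair, 2)
#> tat_matrix: p = 2, eta = 0.01 kcal/mol  (rows = test set B, cols = training set A)
#> T_B@A:
#>        train
#> test     sharp    flat
#>   sharp 1.0000 41.9296
#>   flat  5.2328  1.0000
```

Training on the sharp set and testing on the flat one costs a factor 5.2
over the flat set's own accuracy limit; the reverse direction costs a factor
41.9 — the flat set never learned to pin down its weakly constrained MP2
fraction, so its model collapses on the sharp chemistry. In energy terms
(`transfer_energy_matrix(pair, 2)`) those factors are 1.54 and 15.80
kcal/mol of excess error, and the error-class summary shows what that means
per process:

```r
error_summary(fit_xyg(pair$sharp, 2), pair$flat)
#> errors on 'flat' (trained on 'sharp'): good 35.0%, ok 65.0%, bad 0.0%
```

The accuracy limit (`MAD_A@A`) of the family on the sharp set falls
monotonically with model size, from 7.54 kcal/mol at p = 1 to 0.356 at
p = 7 — adding parameters always helps the set you train on, which is
exactly why transferability, not training error, has to be the criterion.

A shell front end wraps the same functions
(`inst/scripts/tatkit simulate|validate|expand|fit|tat|curate`), reading and
writing the two-file CSV benchset layout documented in `?read_benchset`.

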