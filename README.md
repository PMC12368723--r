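# ibuopt

Kinetic simulation and surrogate-based multiobjective optimization of
the Pd-catalyzed carbonylation route to ibuprofen.

Process chemists optimizing a multistep catalytic synthesis face three
competing goals — short reaction time (RT), high conversion (CR), low
production cost — over a design space too large to explore by direct
simulation alone.  `ibuopt` implements the full workflow for the
ibuprofen batch process:

1. **Kinetics engine** — a mechanism-file-driven mass-action ODE system
   (12 integrated species, 9 reactions: dehydration,
   hydrohalogenation, dehydrohalogenation, catalyst activation,
   oxidative addition, carbonylation, hydrolysis, and reversible
   esterification), integrated with a compiled right-hand side under
   `deSolve::lsoda`.  RT is the time to reach θ = 0.99 of the terminal
   ibuprofen concentration; CR is the ibuprofen-to-substrate ratio at
   that point.
2. **Economics** — a seven-component batch cost
   `Cost = 8000·x5^1.2 + (40x1+20x2+30x3+10x4) + 200 + 15√y1 +
   10(1+0.05·y1^1.5) + 500(1−y2)^1.5 + (150+5y1)`.
3. **Dataset generation** — independent log-uniform sampling of the 14
   design variables (5 initial concentrations, 9 rate constants, each
   spanning 0.1×–10× its reference value), labeled by the simulator.
4. **Surrogates** — one gradient-boosted regressor per output, tuned by
   a snow ablation metaheuristic (population 15, 20 iterations,
   validation-MSE objective) over depth, learning rate, L2
   regularization, and iterations.
5. **Sensitivity** — exact TreeSHAP attributions, global importance
   ranking, and 2-D partial-dependence interaction surfaces.
6. **Optimization** — constrained NSGA-II (feasibility dominance, SBX +
   polynomial mutation) over surrogate-predicted (RT, CR, Cost) with
   RT ∈ [0.5, 72] h, CR ∈ [0.85, 0.98], Cost ≤ 800, yielding a Pareto
   front and four named strategies (balanced, max output, max yield,
   min cost).
7. **Uncertainty** — Monte Carlo perturbation (δ ~ N(0, (σ|x|)²))
   with percentile confidence intervals, RBF sensitivity surfaces, and
   a robustness score per strategy.

The methods vignette (`vignettes/ibuopt-methods.Rmd`) documents every
model, default, and numerical choice, and what the synthetic-data study
does and does not show.

## Worked example

```r
library(ibuopt)

# one batch at the reference design point (10x the lower bounds)
x <- reference_input()
traj <- simulate_batch(x)
m <- extract_metrics(traj, x)
cat(sprintf("RT = %.2f h, CR = %.3f\n", m$rt_h, m$cr))
#> RT = 2.92 h, CR = 0.990
compute_cost(x, m$rt_h, m$cr)
#> <cost_breakdown> total = 487.223 units
#>   C_catalyst     40.0343
#>   C_reagent      44.0000
#>   C_fixed       200.0000
#>   C_energy       25.6161
#>   C_maint        12.4902
#>   C_purif         0.5000
#>   C_labor       164.5819

# label a small design, tune and evaluate an RT surrogate
ds <- generate_dataset(sampling_config(n_samples = 2000, seed = 1))
sp <- split_dataset(ds, seed = 1)
tuned <- tune_hyperparameters(sp$train, sp$validation, outcome = "y1",
                              cfg = sao_config(n_pop = 6, n_iter = 5, seed = 1))
model <- train_surrogate(sp$train, "y1", tuned$hyperparameters, seed = 1)
evaluate_surrogate(model, sp$test)
#> <eval_report> n=300  RMSE=12.809  MAE=9.681  R2=0.736604  MAPE=270.7%
#>   fit line: y = 1.0191 yhat + -1.405  (t=29.01, p=8.78e-89)
```

The reference batch converts essentially completely (CR ≈ 0.99, capped
by the θ = 0.99 plateau definition) in about three hours, and its cost
is dominated by the fixed, labor, and reagent terms.  At this reduced
2,000-row scale the RT surrogate explains about 74 % of the held-out
variance; the large MAPE is expected for a label spanning minutes to
days (small-RT rows dominate a relative error).  Accuracy rises with
sample size and the full tuning budget — see below.

The full pipeline, from sampling to robustness scoring, runs from one
config:

```r
cfg <- pipeline_config(seed = 1, out_dir = "artifacts",
                       sampling = list(n_samples = 2000, law = "log-uniform"))
run_pipeline(cfg)
```

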