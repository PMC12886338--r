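# neurofact

Structural brain images confound two slow processes: normal aging and
neurodegenerative disease. `neurofact` implements a dual-pathway variational
encoder–decoder that disentangles them — an anatomy code `z_a` for
age-related variation and a disease code `z_d` for diagnosis-related
alterations — trained with a causal disease-aware alignment objective, and
validated end-to-end on longitudinal brain phantoms with fully known
generative factors.

## The model

Each scan `x` is encoded into two Gaussian posteriors and reparameterized,
`z_k = mu_k(x) + exp(logvar_k(x)/2) * eps_k`, `k ∈ {a, d}`, and decoded
jointly, `x̂ = g(z_a, z_d)`. Pathway-isolated reconstructions
`x̂_a = g(z_a, 0)` and `x̂_d = g(0, z_d)` support an additive-composition
constraint `||x̂ − x̂_a − x̂_d||²` and counterfactual synthesis
`g(z_a, z_d + δ)` with `δ = μ_target − μ_source` taken from
exponential-moving-average class centers of `z_d`.

The training objective is

```
L = L_task + λ1·L_MMD + λ2·L_cond + λ3·L_contrastive + λ4·L_inv + λ5·L_cf
```

where `L_task` bundles reconstruction, KL to the `N(0, I)` priors, the
additive constraint, diagnosis classification from `z_d`, age regression
from `z_a`, temporal coherence across visits, and code-decoupling penalties;
`L_MMD`/`L_cond` are marginal and class-conditional RBF-kernel maximum mean
discrepancies of `z_d` across imaging sites (median-heuristic bandwidths,
subgroup-size reweighting, plus a Fisher subgroup-separability penalty in
the same group); `L_contrastive` is a supervised contrastive family
(temperature-scaled cosine similarities, perturbation stability,
hard-negative mining, EMA center loss); `L_inv` is the closed-form Gaussian
KL between per-(class, site) and per-class running statistics with shrinkage
covariances; and `L_cf` is a counterfactual consistency term. Everything
runs on a small reverse-mode autodiff engine included in the package; no
external deep-learning framework is required.

The phantom simulator generates longitudinal cohorts
`x = template + age_score·A + severity·D_class + S_site + noise` with
Gaussian-process age/severity trajectories, class/site structure, and a
tunable age–diagnosis confound, so factor recovery, leakage, site
invariance, and counterfactual quality can all be scored against ground
truth.

## Worked example

```r
library(neurofact)

cfg  <- run_config(seed = 7)              # standard phantom + default objective
ds   <- sample_cohort(cfg$phantom)        # 300 subjects, 3 classes, 2 sites, 1-4 visits
ckpt <- train(ds, cfg$model, cfg$cdaa, cfg$optim, seed = 7)
report <- evaluate(ckpt, ds, "test")
round(unlist(unclass(report)), 3)
#>  age_pearson_r class_accuracy            auc             f1    sensitivity
#>          0.907          0.982          1.000          0.987          0.974
#>    specificity leakage_age_from_zd leakage_class_from_za      site_mmd2
#>          1.000               0.121                 0.344          0.035
#> stratum_probe_accuracy counterfactual_success_rate mean_adjacent_displacement
#>                  0.451                       1.000                      0.317
#> n_scans
#> 113
```

Reading the numbers: held-out age is recovered from the anatomy code with
Pearson r = 0.91 and the diagnosis from the disease code with 98% accuracy;
the reverse probes sit near chance (a ridge probe reads age from `z_d` at
r = 0.12; an LDA probe reads diagnosis from `z_a` at 0.34 balanced accuracy
against a 1/3 chance level), the site probe on `z_d` is at its 0.5 chance
level, and every held-out control scan, shifted by the control-to-disease
center difference and decoded, lands closer to the disease-class mean image
than to the control mean.

`write_dataset()`/`read_dataset()` persist cohorts (RDS archive plus a CSV
metadata sibling), `save_checkpoint()`/`load_checkpoint()` persist trained
models, and a command-line entry point wraps the same functions:

```sh
Rscript inst/cli/neurofact.R simulate --config cfg.yaml --out cohort.rds
Rscript inst/cli/neurofact.R train    --data cohort.rds --config cfg.yaml --out run/
Rscript inst/cli/neurofact.R eval     --ckpt run/checkpoint.rds --data cohort.rds \
                                      --split test --report report.json
Rscript inst/cli/neurofact.R counterfactual --ckpt run/checkpoint.rds \
                                      --data cohort.rds --source 0 --target 1 --out cf/
```

YAML configs are parsed strictly (unknown keys are errors); every run
directory contains the resolved config, the seed, a per-step CSV of every
loss term, and a JSON report, which together reproduce the run
bit-identically.

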