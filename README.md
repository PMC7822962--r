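# crowdmix

Mixture models of misreport errors in visual crowding, for analysts of
continuous-report (estimation) psychophysics data.

## The problem

In peripheral vision, a target surrounded by nearby flankers is hard to
identify — *crowding*. When observers reproduce the orientation of a
crowded Gabor on a continuous wheel, their signed errors
`theta = response − target` (wrapped to the 180°-periodic interval
`(−90°, +90°]`) mix three sources: von Mises report noise around the
target, uniform guessing, and *misreports* — trials where a flanker's
orientation is reproduced instead of the target's. Fitting mixture models
with one misreport weight per flanker turns the error distribution into a
per-item report-rate profile, and in radial displays that profile is
asymmetric: the flanker just outside the target captures far more reports
than the one just inside.

## The models

Six nested mixtures of the error density (per degree, shared variability
`σ`, flanker offsets `θ*_i = flanker_i − target`):

| model | density | free parameters |
|---|---|---|
| S  | `(1−γ) f(θ) + γ/180` | γ, σ |
| M  | S + `β (1/m) Σᵢ f(θ − θ*ᵢ)` | γ, σ, β |
| 2M | S + `β₁I f(θ − θ*₁I) + β₁O f(θ − θ*₁O)` | γ, σ, β₁I, β₁O |
| 2B | 2M with target mean bias μ (on outward-realigned errors) | + μ |
| 4M | independent β₂I, β₁I, β₁O, β₂O | γ, σ, 4 β's |
| 4B | 4M with target mean bias μ | + μ |

`f` is a von Mises on the angle-doubled circle; the target-report rate is
`P_T = 1 − γ − Σβ`. Models are fitted per observer and condition by
multi-start maximum likelihood (softmax-reparameterised simplex, Latin
hypercube starts, Nelder–Mead + BFGS) and compared by AICc. A synthetic
generator reproduces the radial two-/four-flanker designs (200 trials per
condition, 180-value orientation space, ≥ 15° target–flanker separation,
eccentricities 4–10° at 1.5° spacing) so the whole pipeline is validated by
parameter- and model-recovery simulation. See
`vignettes/crowding-mixture-models.Rmd` for the full account.

## Worked example

Simulate four observers from known mixtures and run the full analysis
(errors → precision → candidate fits → AICc comparison → report rates):

```r
library(crowdmix)

cfg <- design_config("exp1", n_observers = 4, trials_per_condition = 200,
                     seed = 7)
sc <- scenario(
  uncrowded    = list(model = "standard",
                      params = mixture_params(0.05, 12)),
  two_flanker  = list(model = "two_misreport",
                      params = mixture_params(0.05, 15,
                                              c("1I" = 0.05, "1O" = 0.25))),
  four_flanker = list(model = "four_misreport",
                      params = mixture_params(0.05, 15,
                                              c("2I" = 0.07, "1I" = 0.07,
                                                "1O" = 0.24, "2O" = 0.07))),
  seed = 8)

res <- run_pipeline(config = cfg, scen = sc, n_starts = 20, seed = 9)
print(res$group, digits = 4)
```

```
     condition               model mean_aicc delta_mean_aicc is_best
1 four_flanker      four_misreport      1960           0.000    TRUE
2 four_flanker four_misreport_bias      1961           1.774   FALSE
3 four_flanker           misreport      1971          11.882   FALSE
4 four_flanker            standard      2001          41.033   FALSE
5  two_flanker       two_misreport      1899           0.000    TRUE
6  two_flanker  two_misreport_bias      1899           0.475   FALSE
7  two_flanker           misreport      1909          10.502   FALSE
8  two_flanker            standard      1951          52.447   FALSE
9    uncrowded            standard      1616           0.000    TRUE
```

In each crowded condition the generating independent-misreport model wins
the group mean-AICc comparison, the pooled misreport model trails by ~10–12
points (the signature of unequal flanker weights), and adding a bias
parameter buys nothing. The fitted per-item report rates recover the
generating asymmetry:

```r
print(res$rates$group, digits = 3)
```

```
      condition   role   mean      sd n
1  four_flanker     1I 0.0612 0.06121 4
2  four_flanker     1O 0.2533 0.04385 4
3  four_flanker     2I 0.0622 0.01653 4
4  four_flanker     2O 0.0641 0.04629 4
5  four_flanker  guess 0.0498 0.05267 4
6  four_flanker target 0.5095 0.06495 4
...
```

The first-outer flanker's fitted weight (`0.25`) dominates the other three
(`~0.06`), matching the generating truth `0.24` vs `0.07`; `target` rows
are `P_T`. Per-observer summaries (`res$summary`) carry mean error,
precision (inverse variance of the errors in radians), best model, and the
fitted parameters.

A thin CLI over the same functions lives in `inst/cli/crowdmix.R`
(`simulate`, `fit`, `compare`, `pipeline`, `recover` subcommands).

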