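# kaedekin

Kinetic modelling of photoconvertible-reporter (Kaede) fate-mapping time
courses of dendritic-cell trafficking from an immunization site in the skin
to its draining lymph node.

Exposing the injection site to violet light at time $t_{pc}$ labels every
cell present there; red cells found later in the draining lymph node must
have migrated from the site.  `kaedekin` turns such photoswitch/harvest
count data into rates and residence times via a two-compartment delay
model: labelled skin cells $X(t)$ emigrate with hazard

$$\mu_{\text{saline}}(t) = \mu_0, \qquad
\mu_{\text{alum}}(t) = \mu_0 + \alpha\,t\,e^{-mt},$$

take a fixed lymphatic transit time $\tau$, and are then lost from the
lymph-node pool $Y(t)$ at a condition-specific first-order rate
$\delta$:

$$Y(t) = \int_{t_{pc}}^{t-\tau} \mu(s)\,X(s)\,e^{-\delta(t-s-\tau)}\,ds,
\qquad X(t) = x_0 e^{-\int_{t_{pc}}^{t}\mu(s)\,ds}.$$

The package provides

* a deterministic solver (closed forms plus a compiled quadrature
  convolution for the pulsed case),
* a synthetic-experiment generator emulating the standard photoswitch
  schedules with multiplicative lognormal noise,
* simultaneous multistart nonlinear least-squares fitting across
  conditions, sites and photoswitch strategies (per-design initial pools
  profiled out by variable projection),
* AIC selection over a nested family of migration-rate laws,
* case-resampling bootstrap confidence intervals, and
* derived summaries: half-lives, residence and transit times, and the
  timing/magnitude of the inflammation-driven migration peak.

See the vignette (`vignettes/trafficking-kinetics.Rmd`) for the model,
its assumptions and the numerical choices.

## Worked example

Simulate the standard schedules under the canonical parameter set (skin
residence 5.5 d, transit 2.6 h, lymph-node half-lives 9.5/3.8 h, migration
pulse peaking 26 h post-challenge at 10-fold basal), then fit and compare
the candidate models:

```r
library(kaedekin)

ds  <- simulate_dataset(study_designs(), canonical_parameters(), seed = 1)
tab <- compare_models(ds, settings = optimizer_settings(n_starts = 3,
                                                        reltol = 1e-8,
                                                        dt = 0.1))
tab
#> Model comparison (least-squares AIC)
#>   model  k      rss       aic delta_aic      weight
#> 1    M3 24   7.7995 -843.7246     0.000  1.0000e+00
#> 2    M2 23  10.3722 -772.7495    70.975  3.8720e-16
#> 3    M1 22  45.8354 -394.3510   449.374  2.6287e-98
#> 4    M0 21 216.3463    0.9159   844.641 3.8783e-184
#> winner: M3

kinetic_summary(attr(tab, "fits")$M3)
#> Kinetic summary
#>   dLN half-life: alum 9.49 h, saline 3.43 h
#>   dLN mean residence: alum 13.7 h, saline 4.95 h
#>   skin mean residence: 111.2 h (4.63 d)
#>   transit delay: 3.1 h
#>   migration pulse: peak at 25.8 h, 8.41-fold over basal
```

The pulsed-migration model with per-condition loss (M3) wins decisively,
and the refitted summaries sit close to the generating truth: labelled
cells linger about a day in an inflamed-site lymph node versus hours under
control, spend days in the skin, and transit the lymphatics in a few
hours.  On these sparse schedules the transit delay is weakly identified
(no lymph-node harvest within 12 h of the switch) — `fit_model()` flags
this, and `dense_designs()` provides the 2-h harvest grid that pins it
down.  `run_pipeline()` wires simulate → fit → select → report into one
configurable call (YAML-able; see `inst/scripts/kaedekin-cli.R` for the
shell front end), and `bootstrap_cis()` supplies percentile intervals.

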