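# mfrelease

Multifractal hydrodynamic modelling of controlled-release kinetics.

`mfrelease` is for researchers analysing long-term cumulative release
profiles of a payload (a fertilizer such as urea, or a drug) from a polymer
matrix. It implements a multifractal hydrodynamic release model alongside
the five classical dissolution-kinetics models, a mass-balance correction
for withdrawal/replacement sampling protocols, and a synthetic
release-experiment generator so the whole pipeline is testable without any
external data.

## The model

The dynamics of the polymer–payload structural units are treated as motion
on continuous, non-differentiable (multifractal) curves. Averaged over
scale resolutions this yields Madelung-type hydrodynamic equations whose
closed-form solution is a normalized Gaussian density pulse

$$\rho(x,t) = \frac{\pi^{-1/2}}{\sqrt{\alpha^2+(\sigma/\alpha)^2 t^2}}
  \exp\left[-\frac{(x-V_0t)^2}{\alpha^2+(\sigma/\alpha)^2 t^2}\right]$$

translating at $V_0$ and spreading at a rate set by the diffusion-like
coefficient $\sigma = \lambda\,(dt)^{2/f(\alpha)-1}$, where $f(\alpha)$ is
an effective fractal dimension of the motion curves. In nondimensional
variables the model has two shape parameters, $\mu = \sigma\tau_0/\alpha^2$
(the fractality-degree parameter) and $\phi = \alpha/(V_0\tau_0)$, and the
cumulative release law is the relative depletion of the local density at
the matrix position,

$$\bar M(\eta) = \bar m_0\,\left[1 - \bar\rho(0,\eta)\right],
\qquad
\bar\rho(0,\eta) = (1+\mu^2\eta^2)^{-1/2}
 e^{-\eta^2/[\phi^2(1+\mu^2\eta^2)]},$$

so $\bar m_0$ is the asymptotic released fraction. `fit_release()`
segments a profile into the three release stages observed for these
systems (burst to ~46% in 5 h; slower release to ~75% by 269 h; slow
erosion-driven release to near-complete by 840 h), calibrates
$(\mu, \phi, \bar m_0)$ per stage by bounded multi-start
Levenberg–Marquardt least squares, and converts each fitted $\mu$ into a
fractality degree $f(\alpha)$. The headline science: the fractality is
high in the burst stage and decreases as the release advances, and in the
final stage it no longer depends on the initial payload percentage.

## Worked example

```r
library(mfrelease)

panel <- generate_panel(generator_config(), seed = 1)  # synthetic experiment
prof  <- panel$profiles[panel$profiles$formulation == "2-U1", ]

fit <- fit_release(prof)
fit
#> Stage-wise multifractal release model
#> Formulation: 2-U1
#> Stage boundaries (h): 5, 269, 840
#>               mu phi   m0_bar  f_alpha      rmse
#> stage1 0.5822910 100 0.660852 1.619620 0.0197754
#> stage2 0.0519325 100 0.248492 0.875442 0.0228058
#> stage3 0.0167094 100 0.242357 0.720191 0.0140951
#> Fractality trajectory: decreasing
```

The fitted fractality-degree parameter `mu` falls by a factor of ~35 from
the burst stage to the erosion stage, and the derived fractality degree
`f_alpha` (under the default scale constants) decreases strictly —
the energetic burst is the most fractal regime. `m0_bar` is each stage's
incremental releasable fraction; `rmse` is in cumulative-fraction units.

The classical models tell the complementary story. In the erosion stage
only Korsmeyer–Peppas (and, marginally, Higuchi) remain adequate:

```r
rep <- stagewise_model_report(prof)
rep[rep$stage == 3, c("model", "r_squared", "adequate")]
#>             model r_squared adequate
#>        zero_order     0.876    FALSE
#>       first_order     0.735    FALSE
#>           higuchi     0.967     TRUE
#>  korsmeyer_peppas     0.981     TRUE
#>    hixson_crowell     0.889    FALSE
```

And across the six urea-bearing formulations the stage-3 fractality is
essentially load-independent:

```r
fits <- fit_release_panel(panel$profiles)
load_independence_stage3(fits)
#> stage-3 f(alpha): 0.729 0.720 0.723 0.734 0.720 0.730
#> CV: 0.0075  independent: TRUE
```

Real data enter through `read_release_csv()` (long format: formulation,
replicate, time in hours, and either cumulative fractions or measured
concentrations, which are routed through the withdrawal/replacement
mass-balance correction `correct_sampling()`).

## Package layout

* `R/scale.R`, `R/fields.R`, `R/pde.R` — scale relation, closed-form
  fields, release law, and the finite-difference oracle for the governing
  equations.
* `R/kinetics.R` — the five classical models (linearization, fitting,
  prediction, stage-wise adequacy report).
* `R/pipeline.R`, `R/mfr_fit-methods.R` — stage segmentation, sampling
  correction, the stage-wise multifractal calibration (`fit_release()`,
  an S3 model object with `print`/`summary`/`coef`/`predict`/`plot`/
  `residuals` methods), fractality trajectory and load-independence
  summaries.
* `R/synthetic.R` — formulation table, protocol simulation, panel
  generator.
* `R/io.R` — CSV/JSON input and output, run configuration and reports.
* `vignettes/multifractal-release-model.Rmd` — the model, its
  assumptions, all tunable parameters and the design choices behind the
  synthetic experiment.
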