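---
title: "Modelling non-linear creep of soft viscoelastic foods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling non-linear creep of soft viscoelastic foods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(creepfit)
```

## The creep test and the models

In a creep test a constant stress is applied to a specimen and the growing
strain is recorded over time. Soft foods tested at large deformation
(engineering strain well above 5 %) behave as non-linear viscoelastic
materials: the classical spring–dashpot (Kelvin–Voigt, Burgers) networks
built for the linear regime no longer superpose, and compact empirical
models are used instead. `creepfit` implements three of them for
constant-stress traces:

* **Peleg (two parameters)** — linear in transformed coordinates:
  $t/\varepsilon(t) = k_1 + k_2 t$, i.e.
  $\varepsilon(t) = t/(k_1 + k_2 t)$. $k_1$ is the *degree of solidity*
  (large $k_1$: slow initial creep, more solid-like), $1/k_2$ the
  asymptotic strain. The model forces $\varepsilon(0) = 0$, so it cannot
  represent an instantaneous elastic strain.
* **Purkayastha (four parameters)** —
  $Y(t) = k_0 + k_1 t + t/(k_2 + k_3 t)$: an instantaneous term $k_0$,
  unbounded steady flow $k_1 t$, and a retarded hyperbolic term. When
  fitted to strain traces $Y(t)$ is read as $\varepsilon(t)$, so that all
  three models compete on the same data.
* **Three-parameter power-law model** (`"powerlaw"`) —
  $$\varepsilon(t) = \varepsilon_0\left(1 + \frac{t^n}{k_1 + k_2
  t^n}\right),$$
  the package's primary model. $\varepsilon_0$ is the initial strain at
  load application; dividing by the constant stress $\sigma_0$ gives the
  compliance form with initial modulus $E_0 = \sigma_0/\varepsilon_0$.
  $k_1$ (units $\mathrm{s}^n$) governs the initial creep rate; $1/k_2$
  sets the relative asymptotic creep, $\varepsilon(\infty) =
  \varepsilon_0(1 + 1/k_2)$, so $k_2 \to \infty$ is ideal elasticity and
  $k_2 \to 0$ ideal liquid flow; the rate exponent $n > 0$ controls how
  fast the equilibrium strain is approached and provably does not move the
  asymptote. At $t = 0$ both $t^n$ and its $n$-derivative $t^n \ln t$ are
  taken at their limits (0), which keeps the grid origin well defined for
  $n < 1$.

The units of $k_1$ are nowhere standardised for this family; the package
treats $k_1$ as $\mathrm{s}^n$ so that $t^n/(k_1 + k_2 t^n)$ is
dimensionless, and $k_2$, $n$ as dimensionless. Rescaling time from
seconds to minutes therefore divides a fitted $k_1$ by $60^n$ and leaves
$\varepsilon_0$, $k_2$ and $n$ unchanged — a property the test suite
checks.

Whether $\varepsilon_0$ should be estimated jointly or pinned to the first
observed strain is a genuinely open choice; both are supported through
`creep_model("powerlaw", fixed = c(eps0 = ...))`. Joint estimation is well
conditioned on clean data (the $\varepsilon_0$ column of the Jacobian is
$1 + t^n/(k_1+k_2t^n)$, far from collinear with the others), but fixing
$\varepsilon_0$ is the natural mode when the instantaneous strain is known
from the instrument record.

## Fitting: Gauss-Newton with safeguards

The solver is the classical Gauss-Newton iteration on the residual sum of
squares $S = \sum_j r_j^2$, $r_j = y_j - f(t_j, \beta)$: form the Jacobian
$Z$, solve the normal equations $(Z^\top Z)\lambda = -Z^\top r$ (via a QR
factorization of $Z$, never an explicit inverse) and update $\beta$. Three
safeguards make the textbook iteration dependable:

* **Step halving** (up to 20 times per iteration) whenever a candidate
  update increases $S$ or leaves the positive orthant, so the objective is
  non-increasing across accepted iterations while Gauss-Newton fixed
  points are preserved. No Levenberg–Marquardt damping schedule or trust
  region is used — the halving line search is the whole globalization.
* **Parameter scaling**: Jacobian columns are scaled by the current
  parameter magnitudes, which makes the step unit-free. This matters for
  the four-parameter model, whose fitted constants span six orders of
  magnitude ($k_1 \approx 10^{-4}$ vs $k_2 \approx 10^{2}$).
* **Bounds by back-halving**: parameters are kept strictly positive (the
  Purkayastha flow term may sit at zero) by halving violating candidates
  back into the feasible region rather than reparameterizing, so reported
  parameters stay in their natural units.

Convergence is declared when the relative drop in $S$ falls below
$10^{-12}$ or the largest relative parameter step falls below $10^{-8}$,
within 200 iterations by default; non-convergence is reported in the
result object, not thrown. A rank-deficient Jacobian raises an error
naming the degenerate parameter. Overflowing trial evaluations (e.g. an
extreme exponent candidate making $t^n$ infinite) are treated like ascent
steps and halved away, and the power-law evaluation itself is guarded so
that $t^n \to \infty$ returns the exact asymptote instead of `NaN`.

Starting values are deterministic (`creep_init`): the Peleg model starts
— and, being linear after transformation, effectively ends — at its
closed-form OLS solution of $t/\varepsilon$ on $t$; the power-law model
reads $\varepsilon_0$ off the first sample, $k_2$ off the terminal strain
ratio, fixes $n = 0.5$ and solves for $k_1$ at the mid-grid point; the
four-parameter model uses the first sample, the terminal slope and a
two-point solve on the de-trended tail. The Peleg fit excludes $t = 0$,
where $t/\varepsilon$ is undefined.

## Goodness of fit and replicate comparison

`residual_standard_error` is $\sqrt{S/(N-p)}$ and `r_squared` is the
centred convention $1 - SS_{res}/SS_{tot}$; for non-linear fits the
centred choice is a convention, stated here because alternatives
(uncentred $R^2$) differ materially. For the Peleg model both the
strain-space statistics (from the back-transformed model) and the
linearized-space statistics are reported, since published tables built on
the linear form are ambiguous about the reporting space.

Replicate fits are aggregated into a group table (mean ± SD per parameter)
and compared with **Duncan's multiple range test**: a one-way ANOVA error
mean square per parameter (pooled across all groups, the standard usage),
ranked means, and least significant ranges
$R_p = q^*(\alpha_p, p, df)\sqrt{MSE/n_h}$ with protection level
$\alpha_p = 1-(1-\alpha)^{p-1}$. Critical values come from the
studentized-range distribution (`qtukey`) rather than the historical
printed tables, which reproduces those tables to two decimals at any
degrees of freedom; unequal group sizes use the harmonic mean $n_h$ (an
extension — the motivating design is balanced with nine replicates).
Means share a letter when their ranked span's range does not exceed
$R_p$; with a zero error mean square, equal means share and unequal means
split, which is the consistent limit of that rule.

## What the synthetic generator emulates — and what it does not

No raw creep traces are publicly deposited for the motivating study, so
the package ships a seeded generator instead of data. It emulates the
measurement protocol: a 120-s constant-stress hold sampled at 1 Hz
(121 points), additive i.i.d. Gaussian strain noise (SD 0.002 by default
— chosen so that post-fit residual errors land on the $10^{-4}$–$10^{-3}$
scale typical of published fits), nine replicates per group, and
between-replicate biological spread as mean-preserving lognormal jitter of
the generating parameters (CV 0.1, the scale suggested by published
replicate SDs). `rice_fixtures()` freezes three noiseless curves at the
published replicate-mean parameters for white, brown and germinated brown
cooked rice, with $(k_1, k_2, n)$ = (41.88, 6.24, 0.59),
(35.00, 7.07, 0.60) and (41.60, 6.76, 0.65); the initial strain is not
published, so the fixtures document an assumed $\varepsilon_0 = 0.6$, and
recovery checks target only the printed $k_1, k_2, n$.

The generator does **not** emulate: the force-controlled loading ramp and
its servo dynamics (curves start at the hold), heteroscedastic or
autocorrelated instrument noise, slip or sample rearrangement under the
probe, or the bulk nature of a scooped-rice specimen. Passing recovery
tests therefore demonstrate correctness of the estimation machinery under
the stated noise model, not robustness to every artefact of a real
texture-analyzer trace.

Strain is engineering strain $\delta/h_0$ throughout (the deformation
normalization basis must be supplied explicitly when converting raw
force/deformation traces); at the large deformations this package targets,
engineering and true (Hencky) strain diverge, and no conversion is
attempted.

## Verification problem sizes

The test suite runs entirely on generated data: noiseless roundtrips on
121-point grids for all printed parameter rows (recovery to $10^{-4}$
relative or better), 20 seeded noisy curves per model cross-checked
against an independent Levenberg–Marquardt reference fit, 50-replicate
noisy-recovery means, 1000 null simulations for Duncan type-I calibration
and 200 for power, all chosen to keep the suite in the tens of seconds
while leaving Monte-Carlo margins comfortably wide.

## Known limitations

* Gauss-Newton with step halving is a local method; the deterministic
  initializer makes the shipped models converge reliably on creep-shaped
  data, but there is no global multistart.
* The four-parameter model is near-degenerate when the flow term is
  negligible ($k_1 \to 0$): its column of the Jacobian can become
  rank-deficient mid-iteration, which is reported as an error rather than
  silently regularized.
* Duncan's test is the only post-hoc procedure provided (no Tukey or
  Scheffé), and only one-way, balanced-or-harmonic designs are supported.
* The Exponent instrument export is not parsed natively; traces must be
  exported to delimited text first.
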