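---
title: "Model-based analysis of xenograft tumour growth inhibition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based analysis of xenograft tumour growth inhibition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xenopower)
```

## The problem

Two-arm xenograft experiments are the workhorse of preclinical oncology: a
human tumour — either from an established cell line (CDX) or engrafted from a
patient (PDX) — grows in the flank of immunocompromised mice, and calliper
measurements of tumour volume are taken every few days after the animals are
randomised to a treated or a control arm. The conventional analysis discards
most of those measurements: it computes the percent tumour growth inhibition

$$\%\mathrm{TGI} = 100\,\frac{\bar V_c(T) - \bar V_t(T)}
                             {\bar V_c(T) - \bar V_c(0)}$$

from the arm mean volumes on the final day $T$ and reports an unpaired,
two-tailed t-test on the final-day volumes. `xenopower` implements that
conventional analysis alongside a model-based alternative that uses every
measurement in the time series, and a simulation engine for comparing the
statistical power of the two under PDX-like and CDX-like variability.

## The growth model

Treating the tumour as a sphere, volume converts to radius via
$R = (3V/4\pi)^{1/3}$. The model says each animal's radius grows linearly in
time — the behaviour expected when proliferation is confined to a thin outer
shell of the tumour, and an empirically good description of xenograft series:

$$R_{ij} = (a_i + b_i t_{ij})(1 + e_{ij}),$$

with, for animal $i$ and measurement $j$,

* $a_i$ the radius at randomisation (mm), $\log a_i \sim N(\mu_1, \sigma_1^2)$;
* $b_i$ the radius growth rate (mm/day), $\log b_i \sim N(\mu_2 + c\,T_i,
  \sigma_2^2)$, where $T_i$ is 1 for treated animals and 0 for controls and
  $c$ is the population treatment effect;
* $e_{ij} \sim N(0, \sigma_3^2)$ a proportional residual — the spread of
  calliper measurements grows with the tumour, so the error multiplies the
  predicted size rather than adding to it.

A volume-scale variant cubes the same latent line through the sphere formula,
$V_{ij} = \tfrac{4\pi}{3}(a_i + b_i t_{ij})^3 (1 + e_{ij})$, for users who
prefer to regress on the measured volume directly. Since calliper errors are
made on lengths, the radius scale is the default.

### The treatment effect and its scale

The package supports two readings of "the treated growth rate is shifted
by $c$":

* `log_shift` (default): $c$ shifts the mean of $\log b_i$, consistent with
  the lognormal control distribution. The treated rate stays positive, so
  expected TGI approaches 100% only as $c \to -\infty$; `calibrate_c()`
  returns a floor ($c = -20$, flagged `limit`) for a TGI-100 target.
* `natural_shift`: the treated rate is Normal with the control's
  moment-matched natural-scale mean shifted by $c$ and the same
  natural-scale variance. This attains TGI = 100 exactly (zero mean growth)
  at the price of allowing negative per-animal rates, i.e. shrinking
  tumours.

Both are provided because complete growth inhibition is a standard simulation
scenario while the lognormal model cannot represent it exactly; which scale a
given published simulation used is generally not recoverable, so neither is
asserted as canonical. Under `natural_shift` a strongly negative drawn rate
can push the mean radius through zero at late measurement days; the simulator
floors the noise-free radius at $10^{-3}$ mm so volumes stay positive. The
floor slightly biases natural-shift arm means at long horizons and deep
effects; the closed-form moments used for calibration ignore it.

### Expected volumes and effect calibration

Because $a_i \perp b_i$ and both are lognormal, the population mean volume
has the closed form

$$E[V(t)] = \frac{4\pi}{3}\sum_{k=0}^{3}\binom{3}{k} E[a^k]\,E[b^{3-k}]\,t^{3-k},
\qquad E[X^k] = e^{k\mu + k^2\sigma^2/2},$$

implemented by `expected_volume()` and verified in the tests against a
$10^6$-draw Monte-Carlo oracle. This is the noise-free mean: the residual
would inflate volumes on every arm and at baseline by the common factor
$E[(1+e)^3]$, which cancels from the TGI ratio. `expected_tgi()` plugs these
means into the TGI formula, and `calibrate_c()` inverts the monotone map
$c \mapsto \mathrm{TGI}(c)$ by root-finding to an absolute tolerance of
$10^{-6}$ TGI points — this is how a simulation targeting "50% TGI at day
21" chooses its effect size.

## Simulating studies

`simulate_study()` draws per-animal $(a_i, b_i)$, evaluates the line on the
measurement schedule and multiplies by the truncated proportional error
($1 + e > 0.01$, resampled otherwise, so measured sizes stay positive). The
default schedule takes measurements every 3–4 days — days 0, 3, 7, 10, 14,
then 17, 21, then 24, 28 — matching common practice for 14/21/28-day studies.
Every animal consumes its own substream derived from the study seed by an
integer hash, so studies are bit-reproducible and unaffected by the number of
animals simulated before them.

What the generator deliberately does **not** emulate: dropout (welfare-limit
sacrifice of large-tumour animals), measurement-day jitter between animals,
non-linear (plateauing) growth, and correlation between baseline size and
growth rate. Passing tests therefore demonstrate correctness of the methods
under the model's own assumptions, not robustness of the model to real-data
violations of them.

## Fitting and testing

### Mixed-effects fit

`fit_mixed()` maximises the marginal likelihood, integrating the two random
effects $u_i = (\log a_i, \log b_i)$ out of each animal's proportional-error
Gaussian likelihood. The per-animal 2-D integral is approximated by a
Laplace expansion at the posterior mode, located by a damped Newton iteration
with analytic gradient and Hessian (compiled code); `method = "agq"` replaces
the Laplace value with 5×5 adaptive Gauss–Hermite quadrature centred at the
same mode, and serves as the accuracy cross-check. Population parameters are
optimised by `nlminb` with the three SDs on the log scale (positivity by
construction; a floor of $10^{-6}$, hits flagged as `boundary`), starting
values taken from per-animal least-squares lines: medians of log intercepts
and slopes for $\mu_1, \mu_2$, their spread for $\sigma_1, \sigma_2$,
relative residuals for $\sigma_3$, and $c = 0$.

### Pooled fit and the LRT

`fit_pooled()` is the naive fixed-effects version — one $(a, b)$ for all
animals, the treatment effect still shifting $\log b$ — fitted by direct
maximum likelihood. `lrt()` compares a fit with the treatment effect to the
nested fit without it: $\Lambda = 2(\ell_1 - \ell_0)$, clipped at zero,
referred to $\chi^2_1$ ($c$ is an interior parameter, so the plain
chi-square rather than a boundary mixture applies). `model_test()` wraps the
pair of fits, starting the alternative at the null optimum so that nesting
($\ell_1 \ge \ell_0$) holds by construction, then re-polishing the null from
the alternative's optimum.

### Small-sample behaviour, measured

With $n$ animals in total, the $\chi^2_1$ reference behaves like a $z$-test
where a $t_{n-2}$-test is due, and the ML variance estimate lacks the
REML-type correction: the LRT statistic is roughly $\tfrac{n}{n-2}
F_{1,n-2}$-distributed, which at $\alpha = 0.05$ and 10 animals per arm gives
a true size near 8% rather than 5%. The package's own simulations (see
`tests/testthat/test-acceptance.R` and `scripts/acceptance.R`) measure
exactly this, and the adaptive-quadrature cross-check shows it is a property
of the test, not of the Laplace approximation. The pooled-LRT is far worse —
near 40% under PDX-like heterogeneity — because treating correlated
within-animal measurements as independent is pseudo-replication; it is
retained as a comparator, not recommended for inference. The empirical
t-test holds its nominal size. Users wanting calibrated small-sample
model-based inference should interpret mixed-LRT p-values near 0.05 with
care at these sample sizes.

## The power engine

`run_power_cell()` calibrates $c$ to a TGI target, simulates `reps` studies
and reports the percentage with $p < 0.05$ plus its binomial Monte-Carlo
standard error; `run_power_table()` maps this over a TGI × sample-size ×
horizon × method grid (defaults: TGI 50/100; 5, 8, 10, 12, 15 animals per
arm; 14/21/28 days; empirical and mixed-LRT), deriving one hashed seed per
cell so the grid is reproducible cell by cell. `significance_curve()`
summarises a batch-analysed database as the cumulative fraction of
significant studies among those with observed TGI at or below each value —
the curve stays higher at small TGI for the analysis with more power, which
is how the smallest reliably detectable effect size is read off.
`generate_database()` plus `batch_analyze()` produce and analyse a synthetic
multi-study database with per-study effects drawn from a TGI-target
distribution, emulating the structure of a large public PDX drug screen.

```{r, eval = FALSE}
pdx <- read_params_yaml(system.file("extdata", "pdx_params_synthetic.yaml",
                                    package = "xenopower"))
run_power_table(pdx, reps = 1000, seed = 1)
```

## Parameter sets and other defaults

The shipped YAML configs (`inst/extdata/*_synthetic.yaml`) are illustrative,
not fitted to any dataset (their filenames say so): baseline radius
$e^{1.28} \approx 3.6$ mm ($\approx 230$ mm³, a typical randomisation
volume), growth of roughly a volume doubling per two weeks for the PDX-like
set and faster for the CDX-like set, and a growth-rate log-SD of 0.65 (PDX)
versus 0.25 (CDX) to express the much larger between-animal heterogeneity of
patient-derived models. Power tables computed from them show the expected
qualitative structure — model-based power above empirical power at TGI 50
everywhere, the advantage largest where heterogeneity is high — but their
absolute values are specific to these parameter choices.

Other defaults, and why:

* **Student rather than Welch** t-test: the classical unpaired test is the
  field's convention; Welch is available via `variant = "welch"`.
* **Last measurement at or before the horizon** stands in for a missing
  final-day measurement in real data (the simulator always measures on the
  final day, so this rule only affects ingested data).
* **Integer days**: fractional days in ingested files are floored with a
  warning; arm labels are normalised case-insensitively and anything other
  than control/treated is an error rather than a guess.
* **Optimiser settings**: relative tolerance $10^{-10}$, at most 500
  iterations; inner Newton tolerance $10^{-9}$ on the gradient.
* **Problem sizes in the shipped tests**: recovery uses 300–500 animals
  (relative errors under 10%); power properties use 250–1000 replicates per
  cell with 3-Monte-Carlo-SE slack — sizes chosen to make the statistical
  assertions sharp at interactive runtimes.

## Known limitations

* The linear-radius model has no plateau; very long studies or very small
  residual tumours will strain the linearity and sphericity assumptions.
* Mixed-LRT p-values are mildly anticonservative below ~15 animals per arm
  (measured above); the pooled-LRT is anticonservative everywhere under
  between-animal heterogeneity.
* The simulator's independence of $a_i$ and $b_i$, fixed schedule and
  absence of dropout idealise real studies; power numbers are
  model-conditions numbers.
* TGI above 100 (regression) is representable in the data and the empirical
  summary, but the lognormal (`log_shift`) effect cannot generate mean
  regression; use `natural_shift` to simulate it.
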