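---
title: "Methods: mutual invasibility, sensitivity to interaction, and coexistence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mutual invasibility, sensitivity to interaction, and coexistence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invadyn)
```

## The experimental statistic

Mutual invasibility experiments measure interspecific interactions
directly from population dynamics.  Each species is grown alone from a
low-density inoculum to estimate its per-capita growth rate when alone,
$\mu_{i,\mathrm{alone}}$, and introduced at a low density into a culture
of a second species that has been grown to steady state, giving
$\mu_{i,\mathrm{invading}}$.  The sensitivity to interaction is

$$S_i = \frac{\mu_{i,\mathrm{alone}} - \mu_{i,\mathrm{invading}}}
             {\mu_{i,\mathrm{alone}}}.$$

$S_i > 0$ means the established species depresses the invader's growth
(competition); $S_i < 0$ means it enhances it (facilitation); $S_i = 1$
means invader growth is fully suppressed.  `compute_sensitivity()` is this
formula, exactly; it is scale-invariant in the two rates, so any common
miscalibration of the density scale cancels.

For a species pair with both directional sensitivities positive, modern
coexistence theory partitions the interaction into a niche difference and
a relative fitness difference,

$$ND = 1 - \sqrt{S_A S_B}, \qquad RFD = \sqrt{S_A / S_B}
\quad (S_A \ge S_B),$$

and predicts competitive exclusion when $RFD > 1/(1 - ND)$ and
coexistence when $RFD < 1/(1 - ND)$.  Algebraically this threshold
comparison reduces to comparing $S_A$ with 1, which the test suite
verifies on a dense grid; the package still evaluates the $ND$/$RFD$ form
because those two axes are what the field interprets.  Both quantities
are defined only for $S_A, S_B > 0$: nonpositive sensitivities
(facilitation) are outside current theory, and the package returns a
flagged undefined value rather than clipping — pairs without
consistently positive sensitivities are excluded from the coexistence
stage and counted, never coerced.

A relative tolerance `eps` (default $10^{-9}$) brackets the exclusion
threshold so that values within floating-point noise of the boundary are
labelled `"boundary"` deterministically rather than flipping between
classifications across platforms.

## Growth-rate estimation

Rates are estimated from cell-count density series (cells per ml) by
three routes, matching standard practice for batch growth curves:

* `two_point_rate()`: $\mu = \ln(D_T/D_0)/T$ between two samples.
* `easylinear_rate()`: ordinary least squares of $\ln$ density on time
  over every contiguous window of `h` observations, returning the
  steepest window (earliest on ties, for determinism).  The default
  `h = 3` with the standard post-invasion schedule
  $\{0, 19, 26, 74, 96\}$ h makes the estimate the log-linear slope of
  the first three samples — the first 26 h, before growth visibly
  decelerates.  With `h` equal to the series length the estimator
  reduces to a single whole-series fit.
* `fit_logistic()`: Levenberg–Marquardt nonlinear least squares of
  $N(t) = K/(1 + ((K - N_0)/N_0)e^{-\mu t})$ over $(\mu, K, N_0)$,
  initialized at $K_0 = 1.05\max N$, $N_{0,0} = N(t_1)$ and the
  easylinear slope, with relative tolerances of $10^{-14}$.  A fitted
  $K$ outside $[\max N/2,\, 10 \max N]$ is flagged as unidentified
  (`k_in_range = FALSE`), the typical symptom of a series still in
  exponential phase; non-convergence returns a flagged fit with `NA`
  estimates, never silent defaults.

Zero densities are a hard error in log-space estimators.  Invaders start
at 1,000 cells per ml, so a true zero count indicates a detection
failure that the analyst must resolve; a silent $+1$ pseudo-count would
bias $\mu$ exactly where the statistic is most sensitive (low
densities).

`select_polynomial_order()` reproduces the descriptive model-selection
step used on count trajectories: nested Gaussian likelihood-ratio tests
of polynomial trend order 1 vs 2 vs 3 (1 df each, stop at the first
non-significant improvement), with the LR statistic equal to
$n\ln(RSS_k/RSS_{k+1})$.

Fluorescence series (relative fluorescence units) are accepted by all
estimators but carry a `measurement = "fluorescence"` flag, and
`sensitivity_table()` refuses fluorescence-derived rates unless
explicitly overridden: fluorescence responds to cell size and condition
as well as density, so sensitivities are computed from counts only.

## Replicate pairing and the test layer

The design does not dictate how monoculture replicates pair with
invasion replicates when forming $S_i$.  The default is full
cross-pairing within treatment — every monoculture replicate with every
invasion replicate, $3 \times 3 = 9$ records per directed pair and
treatment — because only this choice gives the treatment ANOVA on
$ND$/$RFD$ its canonical $(1, 16)$ degrees of freedom from $9 + 9$
observations per treatment.  A `pairing = "matched"` mode (3 matched
pairs) is available.  $ND$ and $RFD$ are computed per replicate pairing
and then analyzed, not computed once from mean sensitivities: the
per-pairing spread is what the treatment ANOVA needs.

The treatment contrast per directed pair (`delta_sensitivity()`) is the
difference of mean $S_i$, xenic minus axenic, tested by default with a
one-sample t test on the differences between records with matching
pairing ids; a Welch two-sample option exists.  Welch is also the
default for the per-combination growth-rate t tests (pooled optional)
— the convention of the analysis environment this workflow comes from,
recorded in output metadata.  With a single pairing the contrast is
still reported but the test is refused with an explicit flag (zero
degrees of freedom) rather than returning a meaningless p value.  The
growth-rate linear model (`two_way_anova()`) uses sequential (Type I)
sums of squares in the order status, species-combination, interaction;
the synthetic designs are balanced, where sequential, Type II and
Type III coincide.  With a complete 16-combination $\times$ 2-status
$\times$ 3-replicate layout the residual df is $96 - 32 = 64$; published
analyses of comparable experiments sometimes report smaller residual dfs
(e.g. 57), consistent with lost flasks — the package books dfs from the
data it is given and surfaces them rather than forcing a target.

No multiple-testing correction is applied by default (per-combination p
values are reported raw, with significance flagged at $p < 0.05$ and a
weak trend at $p < 0.10$); `p.adjust()` can be applied downstream.

## The synthetic-data generator

The simulator exists so every stage is verifiable by parameter recovery.
Latent dynamics are two-species Lotka–Volterra competition with logistic
self-limitation,

$$\frac{dN_i}{dt} = \mu_i N_i
  \left(1 - \frac{N_i + \alpha_{ij} N_j}{K_i}\right),$$

with $\alpha_{ij} < 0$ encoding facilitation.  This form is chosen
because monocultures reduce exactly to logistic growth and the true
sensitivity has a closed form: with resident $j$ at carrying capacity
and invader $i$ rare, the invader's initial per-capita rate is
$\mu_i(1 - \alpha_{ij}K_j/K_i)$, so $S_i = \alpha_{ij}K_j/K_i$.  The
microbiome is phenomenological: the xenic treatment multiplies $\mu$,
$K$ and $\alpha$ elementwise by modifiers ($m_\mu$, $m_K$,
$m_\alpha$).  No bacterial taxa, nutrient pools or mechanisms are
modelled; the multiplier structure is a stand-in for unknown biology,
not a claim about it.

Coupled trajectories are integrated with fixed-step fourth-order
Runge–Kutta (step 0.1 h; the system is non-stiff at these rates).
Single-species phases — monoculture growth and the resident's 528-h
(22-day) pre-invasion growth — use the exact closed-form logistic
solution of the same model, so the resident enters the invasion at its
simulated 528-h density, near but not pinned to $K$.  The integrator
and the closed form agree to $10^{-8}$ in tests.

Observation noise models hemocytometer counting: counts are Poisson
with mean density $\times$ counted volume, and the counted volume
follows the bench rule of scoring at least 1.8 µl and continuing until
about 200 cells have been counted (capped at 1 ml), which keeps the
coefficient of variation of a count near $1/\sqrt{200} \approx 7\%$
across the density range.  `observe_counts()` itself is the plain
Poisson observation at a stated volume; the adaptive-volume rule lives
in the generator.  Fluorescence, used only by the isolate-panel
generator, is density $\times$ gain $\times$ lognormal error
(`sigma` default 0.05).

Reproducibility: one master seed per `generate_experiment()` call;
per-flask sub-streams are derived by a stable string hash of the flask
id, so any subset of flasks regenerates identically regardless of
generation order, and the full dataset is a pure function of
`(truth, design, seed)`.

### Default community

`default_truth()` defines the community the examples and verification
runs use: four species with growth rates 0.09–0.12 h$^{-1}$ (similar
rates, as in the algal systems this emulates), carrying capacities
1.5–3 $\times 10^6$ cells ml$^{-1}$ (dense batch cultures), and a
mixture of competitive ($\alpha$ 0.25–0.9) and facilitative
($\alpha$ −0.1, −0.15) interactions, so both interaction types flow
through the pipeline.  The xenic treatment raises rates by 5–15% and
carrying capacities by 20–40% and damps most sensitivities by 15%
($m_\alpha = 0.85$), with one invasion direction damped strongly
($m_\alpha = 0.35$): this reproduces the qualitative study conditions —
bacteria frequently reduce their host's sensitivity, exactly one
species pair has consistently positive sensitivities in both directions
and treatments, and that pair's niche difference increases under
bacteria while its classification stays "coexistence".  These values
were fixed once as a realistic configuration; they are conditions, not
tuning knobs.

## What the tests show, and what they cannot

The verification suite checks: exact recovery of $(\mu, K)$ from
noiseless curves ($10^{-6}$ relative); equivalence of window selection
with brute-force enumeration and of the ANOVA/t statistics with direct
matrix least squares ($10^{-10}$ relative, 50 random fixtures);
the coexistence classification against its algebraic identity on a
$100 \times 100$ sensitivity grid; recovery of
$S_i = \alpha_{ij}K_j/K_i$ through the full noisy pipeline to within
0.1 absolute over $\alpha \in \{-0.5, 0, 0.3, 0.8\}$ (20 seeds each);
type-I error of the treatment contrast within $[0.03, 0.07]$ at
$\alpha = 0.05$ over 2,000 null draws; and the design bookkeeping (72
invasion flasks, 9 records per direction and treatment, ANOVA df
$(1, 16)$) emerging from the default design.  Problem sizes (20 seeds,
2,000 null draws, 40–60 power-study runs) keep the whole suite around
half a minute while leaving Monte-Carlo margins wide relative to the
asserted bounds.

Passing these tests shows the machinery is correct for data that obey
the generator's assumptions.  Real experiments differ in ways the
generator deliberately omits: latent dynamics are not exactly
Lotka–Volterra; replicate flasks share no biological variance here
(only counting noise), whereas real replicates vary in inocula and
micro-environment; counts can be over-dispersed relative to Poisson
(clumping, counting error); and cross-paired records are not
statistically independent, so the $(1, 16)$-df ANOVA inherits the same
pseudo-replication the field's convention does.  The package reproduces
the convention and documents it rather than silently "fixing" it.

## Interfaces

The functions are the interface: `generate_experiment()` →
`fit_growth()` → `sensitivity_table()` → `delta_sensitivity()` /
`nd_rfd_table()`, or `run_pipeline()` end to end, with
`write_experiment()` / `read_tidy_csv()` / `write_bundle()` for the
tidy-CSV dialect (one row per flask, species and time; an explicit
column mapping adapts foreign headers).  `pipeline_config()`
round-trips through JSON and every run's manifest records the config,
its hash, the seed and the package version, so any output bundle is
regenerable.  `scripts/acceptance.R` is the scripted end-to-end run.
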