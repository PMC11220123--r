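---
title: "Three-stage DEA with Malmquist decomposition and spatial diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-stage DEA with Malmquist decomposition and spatial diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tridea)
```

## The problem

Benchmarking studies of public-service systems — here the motivating case
is provincial primary-healthcare delivery — ask how much input (facilities,
staff, beds) a unit *needs* to produce its observed service volume
(consultations, admissions), relative to the best practice visible in the
data. Plain data envelopment analysis (DEA) answers that question, but its
scores confound three things: genuine managerial inefficiency, the
operating environment (wealth, density, urbanisation, funding policy), and
luck. The three-stage procedure separates them: DEA, then a
stochastic-frontier regression of the DEA slacks on the environment, then
DEA again on environment- and noise-adjusted inputs.

## Stage 1: radial DEA

For DMU $o$ in a given year, the input-oriented envelopment program under
constant returns (CCR) is

$$\min_{\theta,\lambda}\ \theta \quad \text{s.t.}\quad
X'\lambda \le \theta x_o,\quad Y'\lambda \ge y_o,\quad \lambda \ge 0,$$

and the BCC program adds $\sum_j \lambda_j = 1$. TE is the CCR score, PTE
the BCC score, and SE $=$ TE/PTE, so TE $=$ PTE $\times$ SE by
construction. A second phase fixes $\theta^\*$ and maximises the slack sum,
which resolves the non-uniqueness of phase-1 solutions; a radially
efficient unit is strongly efficient exactly when all phase-2 slacks
vanish. Returns to scale come from the CCR weight sum with a tolerance
band of $10^{-6}$ around 1, and scores within $10^{-6}$ of 1 are reported
as exactly 1.

Frontiers are contemporaneous: each year is evaluated against its own
cross-section, the convention consistent with the Malmquist machinery
(a pooled all-years frontier is available via
`frontier_scope = "pooled"`, and is what the truth-recovery checks use,
since pooled scores are comparable across years).

The LPs are solved by an internal dense two-phase simplex with Bland's
anti-cycling rule. Envelopment programs are tiny (a handful of rows) but
routinely degenerate — many ties at the optimum — and Bland's rule makes
termination unconditional. Columns are rescaled by their means before
solving; radial DEA is units-invariant, so this is pure conditioning.
During development the solver was cross-checked against an independent
LP implementation on hundreds of random 31-DMU instances (agreement to
$3\times10^{-12}$); in the test suite it is held against closed-form
single-ratio scores and a brute-force $\lambda$-grid oracle.

## Stage 2: what the slacks are and how they are modelled

The dependent variable for input $n$ is the *total* input excess
$(1-\theta_{VRS})x + s^-$ — the radial shortfall plus the phase-2 slack —
the quantity that measures how much of the input could be shed. A
`slack_only` option restricts to the phase-2 component.

The regression is $S = Z'\beta + \nu + \mu$ with Gaussian noise $\nu$ and
half-normal inefficiency $\mu \ge 0$. Because slack is a "bad", the
one-sided term enters with a positive sign (cost-frontier orientation).
Estimation maximises the composed-error likelihood in the
parameterisation $(\beta, \log\sigma^2, \mathrm{logit}\,\gamma)$, where
$\sigma^2 = \sigma_\nu^2 + \sigma_\mu^2$ and
$\gamma = \sigma_\mu^2/\sigma^2$; the transform enforces the bounds, and
multi-start from OLS with a $\gamma$ grid ($0.05$ to $0.95$) guards
against the likelihood's known flat ridges. Because $\gamma = 0$ lies in
the closure of the parameter space, the fitted likelihood is floored at
the OLS likelihood; the LR statistic for $\gamma = 0$ is referred to the
50:50 mixture $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ (5% critical value
2.706). A positive coefficient is read as slack-increasing, hence
efficiency-decreasing, and conversely.

Residuals are split by the JLMS conditional expectation
$E[\mu|\varepsilon] = \mu_* + \sigma_*\phi(\mu_*/\sigma_*)/\Phi(\mu_*/\sigma_*)$
with $\mu_* = \varepsilon\sigma_\mu^2/\sigma^2$ and
$\sigma_*^2 = \sigma_\mu^2\sigma_\nu^2/\sigma^2$, computed on the log
scale for stability in the far tail, and $\hat\nu = \hat\varepsilon -
E[\mu|\hat\varepsilon]$. The adjustment

$$X^A = X + [\max f - f] + [\max\hat\nu - \hat\nu]$$

levels every DMU-year to the least favourable observed environment and
the worst observed draw, with maxima over the pooled DMU-year sample per
input. By construction $X^A \ge X$; equality holds exactly at an
observation attaining both maxima — which need not exist, since the two
maxima generally occur at different observations.

Three design points were genuinely open and decided here: the $\mu$
distribution is half-normal (a zero-mode truncated normal; free-mode
truncated normal and exponential variants are out of scope); $f(Z;\beta)$
is linear with intercept, one regression per input, pooled over all
DMU-years without year effects; and a constant slack vector (every unit
exactly efficient) short-circuits to a degenerate no-adjustment fit
rather than a failed likelihood.

## Stage 3 and the Malmquist index

Stage 3 re-runs both DEA models on $X^A$ with the original outputs. On
synthetic panels with a strong favourable-environment effect, favoured
DMUs lose ground relative to unfavoured ones and the between-group TE gap
narrows — scores are relative, so the clean diagnostic is the contrast,
not each unit's level.

Dynamics use the geometric-mean Malmquist index between adjacent years,
computed on the adjusted inputs by default (`malmquist_source = "raw"`
switches to the originals). With $D^a(b)$ the CRS distance of the
period-$b$ observation to the period-$a$ frontier:

$$\mathrm{EFFCH} = \frac{D^{t+1}(t+1)}{D^{t}(t)},\qquad
\mathrm{TECHCH} = \sqrt{\frac{D^{t}(t+1)}{D^{t+1}(t+1)}\cdot
\frac{D^{t}(t)}{D^{t+1}(t)}},$$

$\mathrm{TFPCH} = \mathrm{EFFCH}\times\mathrm{TECHCH}$, PECH is the VRS
own-period ratio and SECH $=$ EFFCH/PECH. The identities hold record-wise
to $10^{-9}$ and are asserted on every pipeline run. Summaries are
geometric means — the only aggregation under which the identities survive;
arithmetic means of the bundled published year-pair table fail to
reproduce its printed mean row, while geometric means reproduce it for
TFPCH, TECHCH, PECH and SECH (the published EFFCH mean of 0.983 is
evidently computed from unrounded per-DMU indices: the geometric mean of
the rounded column is 0.984, so EFFCH is excluded from the exact checks).
Cross-period VRS programs can be infeasible (a known DEA pathology); such
components are reported missing and excluded from summaries with a
message, never silently replaced by a CRS value.

## Spatial diagnostics

Global Moran's I uses the variance scaling $S^2 = n^{-1}\sum_i (x_i -
\bar x)^2$, under which the local values satisfy $\sum_i I_i = I \cdot
\sum_{ij} w_{ij}$ exactly (asserted to $10^{-12}$). Inference is two-sided
by default: analytically via the randomisation variance, and by
permutation with $p = (1 + \#\{|I_b - E[I]| \ge |I - E[I]|\})/(B+1)$,
seeded and reproducible. Local quadrants come from the signs of the
centred value and its centred spatial lag.

The neighbour structure for the 31-unit fixture is land-border contiguity
with Hainan joined to Guangdong so the graph is connected (Taiwan is
outside the 31-unit frame); k-nearest-neighbour weights (default
$k = 5$) on the bundled capital coordinates are the alternative. Both are
row-standardised by default. Which construction a published study used is
rarely stated; contiguity is the default here because it is the most
common choice for administrative units. A practical power note: on a
31-unit graph, a strongly autocorrelated surface (SAR $\rho = 0.8$)
is detected at the 1% permutation level about 90% of the time, and at
the 5% level about 95% — small maps cannot do better, which matters when
reading per-year significance tables.

## The synthetic generator

`generate_panel()` draws panels with exactly the separability the
three-stage method assumes: environmental covariates influence
inefficiency but not the frontier. Outputs are lognormal per-DMU scales
with mild growth; the efficient input bundle inverts a frontier built
from a convex CES output aggregate $Q = \sqrt{0.6\,C^2 + 0.4\,(30A)^2}$
(consultations and admissions weighted to comparable magnitude) with a
U-shaped scale term $g(Q) \propto 0.15 + 0.85q + 0.15q^2$, $q = Q/5000$ —
most productive scale at $q = 1$, increasing returns below, decreasing
above. Convexity is essential: a log-linear (concave) input requirement
would put large mixed-output DMUs strictly inside the convexified DEA
frontier even with zero inefficiency, breaking the no-inefficiency limit
in which every unit should have PTE $= 1$.

Inefficiency is input-oriented and multiplicative,
$x = x^{eff}e^{u+\nu}$, with
$u = \max\!\big(0,\ \delta'Z_{std} + s + |N(0,\sigma_\mu)|\big)$: a linear
effect of the standardised covariates, a spatial SAR field
$s = (I - \rho W)^{-1}\epsilon$ over the neighbour graph (drawn once per
panel, as a persistent regional effect), and an i.i.d. half-normal
component. Per-input noise $\nu$ plays the stochastic-disturbance role.
Defaults — 31 DMUs, 9 years from 2012, $\sigma_\mu = 0.3$,
$\sigma_\nu = 0.1$, $\rho = 0.4$ with innovation scale 0.1,
$\delta = (-0.08, -0.05, +0.08, +0.05)$ for GDP per capita, density,
urbanisation and health expenditure, static frontier $g = 1$ — produce
stage-1 mean TE near 0.79 with a realistic IRS/DRS mix, and covariate
signs matching the published direction pattern (wealth and density
efficiency-increasing, urbanisation and expenditure slack-increasing).
Covariate scales mimic yearbook magnitudes (GDP per capita in yuan,
lognormal around 50k; urbanisation bounded in [20, 95]%).

What the generator does *not* emulate: real panels have serially
persistent DMU-level inefficiency, measurement conventions that change
across yearbook editions, and environment–frontier dependence (richer
provinces may genuinely operate a different technology). Passing
recovery tests here therefore validates the machinery under the method's
own assumptions, not the assumptions themselves. One calibration fact
worth stating: the spatial *share* of inefficiency variance, not $\rho$
alone, controls whether true efficiency shows positive global Moran's I;
at the default innovation scale 0.1 the sign is positive only ~60% of
the time even at $\rho = 0.8$, while at scale 0.25 it is ~97% — the
spatial property tests run in that regime.

## Numerical choices and limitations

* LP pivot tolerance $10^{-9}$; phase-1 feasibility residual $10^{-7}$;
  scores snapped to 1 within $10^{-6}$; RTS band $10^{-6}$.
* SFA multi-start BFGS, relative tolerance $10^{-12}$, 500 iterations per
  start; standard errors from the numerical Hessian via the delta method
  (suppressed when the Hessian is singular, as happens at the $\gamma \to 1$
  boundary that heavily one-sided slack data produce).
* Competition ranking ("1, 1, 1, 4, ...") on unrounded TE; reported
  tables round to 3 decimals.
* Wilcoxon signed-rank on identical vectors returns $p = 1$ with a flag;
  a constant paired shift reports Cohen's $d = \pm\infty$ (zero spread)
  rather than erroring.
* Problem sizes in the test suite are chosen for tight oracles, not
  realism: grid oracles at 3 DMUs, recovery at $n = 2000$, calibration at
  $n \in \{9, 20\}$ with 100–150 replicates, full pipeline at 8–31 DMUs.
* Out of scope: output-oriented and non-radial (SBM, super-efficiency)
  models, DEA bootstrap confidence intervals, time-varying inefficiency
  panels, exponential/gamma inefficiency, biennial/global Malmquist
  variants, Geary's C / Getis–Ord, spatial regression, and map rendering.

```{r example}
sim <- generate_panel(sim_config(seed = 42))
res <- run_three_stage(sim$panel, weights = sim$weights,
                       config = list(n_perm = 199, seed = 43))
res
```
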