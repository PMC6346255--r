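---
title: "Contrast-based network meta-analysis: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contrast-based network meta-analysis: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contrastnma)
```

## Why contrast-based

Trials of targeted therapies in triple-negative breast cancer publish
hazard ratios (OS, PFS) or risk ratios (ORR, pCR) with 95% confidence
intervals; patient-level or arm-level counts are rarely recoverable.
The package therefore models the *published contrast* of each two-arm
trial.  A ratio estimate with interval (L, U) becomes a log-scale
observation `y = log(estimate)` with standard error
`se = (log U - log L) / (2 z)`, `z = 1.959964`.  This is the only
quantity the publications identify; arm sizes are carried as metadata
and never enter the likelihood.  A consequence worth stating: model
descriptions that include study-specific baseline (intercept)
parameters are not identifiable from contrasts, so the likelihood here
is written directly on the contrasts — the estimates and intervals are
unaffected by this reading.

Some printed intervals are not symmetric about the estimate on the log
scale (rounding, or non-Wald intervals; two records in the packaged
table, Carey 2012 PFS and Kummar 2016 PFS, are clearly off-centre).
These are accepted with a warning: the standard error is taken from the
interval width and the point estimate is left untouched.  Recentring
would silently contradict the printed estimate; dropping the records
would discard real evidence.

## The evidence networks

Treatment labels are canonicalized to the *targeted agent plus backbone
class*: all chemotherapy backbones collapse to `CT` because the source
trials varied them freely and the analysis deliberately does not
distinguish chemotherapy composition.  `CT + Placebo` stays a separate
node: placebo-controlled trials were double-blinded while the rest were
open label, and the two control conditions do not estimate the same
thing.  Two publications (Robert 2011, Sikov 2015) each randomized two
different backbones separately and are treated as two independent
sub-studies; a monotherapy comparator described as "standard therapy"
(Robson 2017) maps to the `CT` node.  Gray 2009 printed only a combined
arm total (232), which is stored once so the 6924-patient total is
exact.

Inference requires a connected network containing the reference.
Disconnected inputs raise an error naming the stranded regimens — this
is the same rule that excluded one onartuzumab trial from the original
dataset.  One structural detail surprised us: the PFS network as
printed contains a single closed quadrilateral loop
(CT – bevacizumab + CT – CT + placebo – veliparib + CT), although the
source analysis described its networks as loop-free.  Nothing in the
estimation changes (weighted least squares and the Bayesian model
handle loops natively), but two funnel-plot identities that are exact
on trees hold only approximately on the four loop edges, and the
package's tests check them accordingly.

## Bayesian engine

The fixed-effects model is

    y_i ~ Normal(d[a_i] - d[b_i], se_i^2),   d[ref] = 0,
    d[k] ~ Normal(0, 1e6)

and the random-effects model interposes study effects
`delta_i ~ Normal(d[a_i] - d[b_i], tau^2)`.  All full conditionals of
`d` and `delta` are normal, so sampling is a component-wise Gibbs
sweep, implemented in C++; `tau` gets a Uniform(0, 2) prior and a slice
sampling step (its conditional is not a standard family under a
uniform-on-sd prior).  Uniform(0, 2) on a log-ratio sd is effectively
unbounded: tau = 2 corresponds to studies whose true hazard ratios span
a 50-fold range.  The prior is a configurable argument (`tau_max`) so
sensitivity to it can be checked directly.

The default schedule — 2 chains, 40 000 burn-in, 200 000 iterations
per chain thinned every 20th, giving 20 000 retained draws — is the
conventional WinBUGS-era reporting schedule for this model class; with
the compiled sampler it runs in about a second per endpoint.  One
master seed deterministically derives per-chain seeds, so identical
configurations give identical retained draws.

Point estimates are posterior medians with central 95% credible
intervals.  League tables are computed per draw, which makes them
exactly antisymmetric on the log scale.  Rankings are computed by
ranking the `d` draws under the endpoint's direction of benefit (HR
endpoints: lower is better; RR endpoints: higher), giving rank
probabilities, cumulative rankograms and SUCRA
`= (n - mean rank)/(n - 1)`.

Convergence is reported as the split-chain potential scale reduction
factor (threshold 1.05) plus the batch-means Monte-Carlo error as a
fraction of the posterior sd (threshold 5%).  DIC uses the exact normal
deviance including its `log(2 pi se^2)` constants; because those
constants differ between implementations, DIC should only ever be
compared *within* this package, as differences.  The automatic model
choice keeps fixed effects unless the random-effects DIC is better by
more than 2 *and* its diagnostics pass — on these data that never
happens, matching the published choice of the fixed-effects model.

Because the fixed-effects model is fully conjugate, the package also
exposes the exact multivariate-normal posterior
(`conjugate_fixed_posterior()`).  It is used as an oracle in the test
suite: sampled means must sit within three Monte-Carlo standard errors
of the exact means on every packaged endpoint.

## Frequentist engine

The sensitivity analysis solves the same fixed-effects problem by
weighted least squares on the comparison graph: records on one edge are
pre-pooled by inverse variance (algebraically identical to stacking),
the Laplacian `L = B' W B` is pseudo-inverted, and node potentials give
every contrast with `var = L+_AA + L+_BB - 2 L+_AB`.  With a vague
prior the Bayesian posterior mean coincides with this solution; the two
engines agree to ~1e-7 on the packaged data, and that cross-engine
equality is a standing test.

P-scores are means of one-sided normal probabilities over the oriented
z matrix — the resampling-free analogue of SUCRA; ties (`theta = 0`,
`se = 0`) resolve to 0.5.  The contribution matrix uses the normalized
absolute hat-matrix row: the flow-decomposition algorithm used by some
plotting routines can differ on loopy networks, but on loop-free
comparisons both reduce to path weights and are identical; exact
replication of third-party contribution percentages is therefore not
claimed.  Comparison-adjusted funnel coordinates centre each study on
its comparison's network estimate, oriented by a configurable
assumed order (experimental regimens first, comparators last), matching
the convention that small-study effects would favour the newer agent.

## Synthetic data and what the tests show

The generator draws `delta ~ N(d_a - d_b, tau^2)`, `y ~ N(delta,
se^2)` over a user-specified edge design and re-expresses each `y` as a
ratio with a log-symmetric 95% interval, so ingest inverts generation
exactly (the CSV writer emits 17 significant digits, making the loop
bit-for-bit).  Standard errors are either fixed or derived from
simulated per-arm event counts via `sqrt(1/e_a + 1/e_b)`.

This emulates exactly the statistical structure the model assumes —
normal log-effects with known standard errors and, optionally, additive
heterogeneity.  It does *not* emulate the ways real published evidence
departs from that structure: selective reporting, interval asymmetry,
correlated multi-arm contrasts, non-proportional hazards, or
chemotherapy backbones that differ in efficacy.  Passing
parameter-recovery tests therefore demonstrates correctness of the
estimation machinery, not robustness to those real-world violations.

Problem sizes in the shipped tests were chosen to keep the full suite
in the low minutes while leaving Monte-Carlo noise far below the
asserted tolerances: the packaged endpoints are fitted at the full
reporting schedule; recovery experiments use 200 replicates of a
21-node, 20-edge network (se 0.1) with a shortened schedule (4 000
burn-in, 40 000 iterations thinned by 20), since interval coverage is
insensitive to Monte-Carlo error that is an order of magnitude below
the interval width; tau recovery uses 40 studies at tau = 0.3.

## Known limitations

* Two-arm records only; a study contributing more than one pair to an
  endpoint is rejected rather than modelled with multi-arm correlation
  (the packaged dataset has none after sub-study splitting).
* No node-splitting / inconsistency model: with a single closed loop
  carried by four edges there is essentially no replicate indirect
  evidence to test against, so consistency is reported descriptively
  (direct pooled versus network, for comparisons observed at least
  twice).
* The frequentist engine is fixed-effects only, mirroring its role as
  a sensitivity analysis.
* DIC values are implementation-specific up to constants; only
  differences are meaningful, and the package never interprets
  absolute DIC.
* Funnel coordinates are descriptive; no small-study regression test
  is attached, as visual assessment was the intended use.
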