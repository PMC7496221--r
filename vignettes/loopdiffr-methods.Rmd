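---
title: "Statistical methods for differential chromatin loop calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for differential chromatin loop calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopdiffr)
```

loopdiffr identifies chromatin looping interactions whose strength differs
between two or three biological conditions, for two very different assay
geometries: genome-wide binned Hi-C contact matrices, and dense
fragment-level 5C matrices covering a few megabase-scale regions. The two
branches share a philosophy — borrow strength across the enormous number
of pixels to stabilize variance estimates from two or three replicates —
but use different machinery, described in turn below.

## The Hi-C model

The raw count for the interaction between bins $i$ and $j$ in replicate
$r$ of condition $c(r)$ is modeled as negative binomial,

$$X_{r,i,j} \sim \mathrm{NB}\!\left(\mu_{c(r),i,j}\, b_{r,i}\, b_{r,j}\,
s_{r,j-i},\ \alpha_{c(r),j-i}\right),$$

with mean/dispersion parameterization
$\mathrm{Var}[X] = \mu + \alpha\mu^2$. Here $\mu_{c,i,j}$ is the true,
replicate-independent interaction strength; $b_{r,\cdot}$ is a
locus-specific bias vector absorbing GC content, mappability and fragment
effects; $s_{r,d}$ is a *distance-dependent* library size factor (a single
scalar per library demonstrably fails to align depth differences across
distance scales); and $\alpha_{c,d}$ is a condition- and
distance-specific dispersion.

**Bias vectors** come from Knight–Ruiz matrix balancing after removing
rows with fewer than 25 nonzero entries within 300 bins of the diagonal;
bias factors outside $[0.1, 10]$ (on the mean-1 scale) are excluded and
the vector re-normalized. The balancing itself is the Newton iteration
with an inner conjugate-gradient solve; we stop when the residual of the
balanced row sums falls below $10^{-6}$ (row-sum variance of order
$10^{-12}$), with a cap of 3000 outer iterations.

**Size factors** are a distance-dependent median-of-ratios: balanced
counts for pixels that are nonzero in every replicate and closer than the
distance cap are split into 100 equal-count distance groups; each group's
factor is the median ratio of the replicate's balanced count to the
geometric mean across replicates, and per-distance factors are the
piecewise-linear interpolation of the group factors against group mean
distance, held constant beyond the outermost anchors. For a replicate
scaled by a constant $k$ in a two-replicate design this yields exactly
$\sqrt{k}$ and $1/\sqrt{k}$ — a property the test suite checks exactly.

**The distance–dispersion relationship (DDR).** Pixels whose normalized
condition mean falls below 1 in any condition are excluded (we are
underpowered there), as are pixels with a zero count in any replicate. At
each distance $d$, pooling pixels across chromosomes, the dispersion is
estimated by quantile-adjusted conditional maximum likelihood: iterate
(1) per-pixel maximum-likelihood fits of $\mu$ with the current $\alpha$
and the fixed combined scaling factors, (2) quantile mapping of counts to
pseudocounts on the geometric-mean scaling scale, and (3) maximization of
the conditional likelihood of the pseudocounts over
$\alpha \in [10^{-7}, 10]$, until $|\Delta\alpha| < 10^{-4}$ from an
initial guess of 0.01. The quantile map is mid-p piecewise-linear CDF
matching between the source and target negative binomials: continuous
output (consumed through log-Gamma terms), and exactly the identity when
all scaling factors agree. The per-pixel $\mu$ fit solves the score
equation by vectorized bisection, bracketed by the min and max of
$x_r/k_r$, which is robust for all dispersions and exact in the Poisson
limit.

The raw per-distance estimates are precise at short range and noisy at
long range, so the final curve is a precision-weighted LOWESS: a centered
rolling sample variance of window 20 (left edge filled with the first
interior value, right edge with the interior maximum; for the default
range 4–500 bins the interior is 14–491, and the fills generalize as
`min_dist + 10` and `max_dist - 9`), weights $w = v^{-1/4}$, integer
duplication weights $\lfloor w/\min w\rfloor$, and a single-pass locally
weighted linear fit on the duplicated points with fraction
$15/(\max \tilde w \cdot \mathrm{mean}\, w)$ (clamped to $(0,1]$ and
overridable via `lowess_frac`). Because dispersion genuinely falls over
the first few distances, the raw estimates are kept up to the first
distance at which they increase, and the smoothed curve is used beyond.
Distances with no tested pixels are linearly interpolated before
smoothing and carry zero duplication weight. We fit the LOWESS on the
natural scale of the raw estimates, matching their direct substitution
into the final curve.

**Testing.** Loop pixels (the union of externally supplied per-condition
loop calls; the simulator provides its planted loops) are tested with a
likelihood-ratio test: a null fit with one shared $\mu_0$ versus an
alternative with one $\mu_c$ per condition, all nuisance parameters held
fixed; $-2\log\lambda$ is referred to $\chi^2_{|C|-1}$ (right tail).
Benjamini–Hochberg control is applied to the loop-pixel p values pooled
across chromosomes. Significant pixels at the chosen FDR (default 1%) are
clustered by 4-connectivity (strictest reading of direct adjacency;
corners do not touch) and clusters below 3 pixels are set to
`unclassified` rather than dropped from the table; the same clustering is
applied symmetrically to the insignificant pixels, whose retained members
become `constitutive`. Retained significant pixels are labeled with the
condition of their largest normalized mean, ties broken by design order
and flagged. Designs beyond two conditions use the same argmax rule;
richer labeling is out of scope.

Three deliberately simplified dispersion providers support benchmarking:
Poisson ($\alpha=0$), a single global qCML dispersion per condition over
all loop pixels, and per-pixel sample-variance dispersions
$\max(10^{-7}, (\hat\sigma^2-\bar z)/\bar z^2)$. On overdispersed null
simulations the Poisson model is anti-conservative, and the global model
concentrates its low p values wherever the true dispersion lies below the
global value — with dispersion rising over the bulk of the tested range
this is the long-distance stratum, while the short stratum is depleted;
the pooled DDR model stays calibrated. These are the signatures the
acceptance suite reproduces.

## The Hi-C simulator

The simulator is first-class code, because it defines the conditions
under which every quantitative claim is checked. A synthetic baseline
mean field follows a power law in distance, $z = S\,(j-i)^{-\gamma}$ with
defaults $S = 1000$, $\gamma = 1$ over 2000 bins, with 200 (tests use up
to 500) non-overlapping 2×2-pixel loop foci multiplied by an enrichment
of 4 — chosen so that loop pixels sit comfortably above the mean filter
across the whole distance range while long-range background approaches
realistic single-digit counts. Loops are labeled constitutive with
probability $1-p_\mathrm{diff}$ and otherwise split evenly among four
categories (up in A, down in A, up in B, down in B). The label assignment
is *balanced*: exactly `round(p_diff * n_loops)` loops are differential,
divided as evenly as possible among the categories, with the assignment
itself randomized by the seed. The marginal probabilities are unchanged,
but the realized differential fraction is pinned at $p_\mathrm{diff}$, so
desk-scale runs measure the estimator rather than label-sampling noise.
Loop pixels of an up-in-A loop get $\mu_A = (1+\beta)z$; non-member
pixels 4-adjacent to a perturbed loop receive half the effect in the
matching condition and carry truth label 0 (they are perturbed but not
part of the loop). Counts are drawn per pseudoreplicate as
$\mathrm{NB}(\mu\, b_i b_j s_d, \alpha(d))$ with identity biases by
default and a dispersion curve that decays from 0.30 at the shortest
tested distance to 0.05 (`sim_ddr_default`). One master seed fans out to
named substreams (labels; one per pseudoreplicate), so adding a replicate
never changes existing draws.

What the simulator does *not* emulate: TADs and compartments, bias
structure unless supplied, interchromosomal contacts, and read-level
artifacts. Passing tests therefore demonstrate correctness of the
estimators under the stated generative model, not robustness to every
property of real Hi-C libraries.

## Evaluation harness

The score $1-q$ is assessed against the planted truth by ROC/AUROC
(rank-based, tie-averaged), observed-FDR curves
($\mathrm{FP}/(\mathrm{FP+TP})$ among pixels called at each q threshold;
0 when nothing is called), and power curves. Distance strata are
left-closed: $[0,400)$, $[400,800)$, $[800,\infty)$ kb on the loop anchor
distance; within each stratum BH is re-run on that stratum's p values
before curves are drawn, so lower long-range power does not masquerade as
FDR inflation. The low-p bias diagnostic computes, on a null simulation,
the per-stratum proportion of loop pixels below the global 5th percentile
of p values; an unbiased model gives about 0.05 everywhere.

## The 5C branch

5C counts arrive quantile-normalized (normalization of raw 5C counts is
upstream of this package); they are modeled and simulated at fragment
resolution. Within each condition the per-interaction sample mean and
unbiased variance are pooled across regions into overlapping distance
windows (12 kb windows / 4 kb step to 150 kb, 24 kb / 8 kb to 600 kb,
60 kb / 24 kb to 1 Mb; windows straddling a regime boundary belong to the
regime of their start) and the mean-variance relationship
$\sigma^2 = A_w\mu^2 + \mu$ is fitted per window by non-negative least
squares on $(\sigma^2-\mu) \sim \mu^2$, after dropping interactions with
mean at most 1 or more than 2.5 SD above the window's mean of means.
LOWESS smoothing (fraction 0.5) of $A_w$ against the window median
distance gives $\bar A_w$; interactions beyond 1 Mb reuse the last
window. Simulated pseudoreplicates draw
$\mathrm{NB}(\mu, \bar\sigma^2)$ with
$\bar\sigma^2 = \tfrac12\hat\sigma^2 + \tfrac12\sigma^2$ blending the
model prediction and the observed variance — the equal weights reproduce
real-replicate correlation levels — clamped to $\mu(1+10^{-9})$ so the NB
exists (the clamp degenerates to Poisson). The NB is parameterized from
its two moments: size $\mu^2/(\bar\sigma^2-\mu)$.

Interaction scores are produced by a deliberately simplified re-creation
of the 5C scoring pipeline, applied identically to real and simulated
counts: Knight–Ruiz balancing of each region (zero rows masked, total
signal preserved), binning onto a 4 kb grid with a 16 kb smoothing window
(arithmetic mean of balanced fragment-pair counts; self pairs and the
diagonal excluded), a local expected from the elementwise maximum of a
donut annulus ($p=2$, $w=6$, same-row/column bands removed) and a
lower-left quadrant, both scaled by the region's per-distance decay; bins
within 20 kb are masked before model fitting and never reappear. The
obs/exp ratios of a region are fitted with a two-parameter log-logistic
by maximum likelihood (a logistic fit on the log scale via BFGS), giving
right-tail p values, and $\mathrm{IS} = -10\log_2 p$,
$Z = \Phi^{-1}(1-p)$. Cells whose footprint is more than half masked, or
whose fit inputs number fewer than 50, are refused rather than guessed.

**Empirical FDR classification.** Pixels with all replicate scores below
$b = -10\log_2 0.8$ are background; candidates need all replicates of at
least one condition above $g = -10\log_2 0.165$. For conditions $t,u$,
$\Delta(t,u) = \min_s \mathrm{IS}_{t_s} - \max_{s'} \mathrm{IS}_{u_{s'}}$
is the worst-case replicate-pair difference. Class $\{t\}$ requires
$\Delta(t,u)\ge d$ against both other conditions; class $\{t,t'\}$
requires both members to beat the remaining condition by $d$. Each clause
tightens as $d$ grows, so per-class call counts are non-increasing along
the sweep — the property that makes threshold selection well behaved. A
pixel meeting both a single and a dual predicate keeps the single
(more specific) label in the final assignment. Pixels strong everywhere
with no separation are constitutive; candidates fitting nothing are
`other`. The empirical FDR of class $h$ at threshold $d$ is the (mean)
number of class-$h$ calls on null replicate sets — same-condition
simulated replicates wearing the experimental condition labels — divided
by the experimental calls, defined 0 when nothing is called; each class
selects the threshold whose eFDR is closest to the target
$\tau = 0.02$ from below (ties to the smaller threshold, i.e. the less
stringent of equally safe choices). The default null condition should be
the most dispersed one, giving the most conservative eFDR; the sweep
defaults to IS 0.5–40 in steps of 0.5. Final calls are clustered per
class by 4-connectivity with a minimum size of 3.

**Benchmarks.** Classical one-way fixed-effects ANOVA (with BH) over IS
or z-scores — classical rather than Welch, matching the unqualified use
of the term — and a likelihood-ratio test on z-scores under unit-variance
normal shifts, whose statistic reduces to
$\sum_c n_c(\bar z_c - \bar z)^2$ with $\chi^2_{|C|-1}$ reference
(2 degrees of freedom for three conditions: three alternative parameters
minus one null parameter). The implementation evaluates the likelihood
ratio from the normal densities; the closed form serves as an independent
oracle in the tests. Significant pixels rank their condition means
$\hat\mu_{A'}>\hat\mu_{B'}>\hat\mu_{C'}$ and are labeled $\{A'\}$ when
the top gap exceeds the bottom gap, else $\{A',B'\}$. Degenerate ANOVA
pixels are flagged: zero within-group variance with real separation gives
p = 0, all-identical values give p = 1, so no NaN reaches the BH step.

## Numerical choices and degenerate inputs

* All-zero pixels sit at the boundary: $\hat\mu = 0$, statistic 0,
  p = 1.
* `nb_logpmf` dispatches to the Poisson pmf below $\alpha = 10^{-8}$,
  where the log-Gamma form loses precision; above that the log-Gamma
  form agrees with `dnbinom` to machine precision.
* The LRT statistic is clipped at 0 (it can be $-10^{-9}$ from finite
  optimization tolerance).
* Bisection on $\mu$ runs 60 halvings, giving relative precision far
  below the $10^{-4}$ dispersion stopping rule that consumes it.
* The sparse-row filter re-applies its rule until no bin fails, making
  it idempotent; the first pass is exactly the stated 25-in-300 rule.
* eFDR 0/0 is defined as 0: no discoveries imply no false discoveries.
* Exact classification ties (argmax of condition means, LRT ranking) are
  broken by design condition order and flagged, never silently.

## Problem sizes used by the checks

The acceptance-style studies run at: 2000 bins / 500 loops for the
headline FDR-endpoint simulation ($p_\mathrm{diff}=0.4$, $\beta=0.3$,
two pseudoreplicates per condition); twenty seeded 500-bin null runs for
specificity; four 1000-bin runs across $\beta \in \{0, 0.15, 0.3, 0.6\}$
for effect-size monotonicity; one 1000-bin overdispersed null for the
alternative-model signatures; and a 500-fragment synthetic region for
the 5C mean-variance recovery. These sizes were chosen so each study
measures its estimator with comfortable statistical margin on a single
CPU.

## Known limitations

The dual-condition 5C classes rest on a membership predicate chosen for
monotonicity along the threshold sweep; other readings of the class
definitions exist and the predicate is isolated in one function. The 5C
scoring pipeline is a simplified re-creation, not a numerical replica of
the published fragment-level pipeline, so absolute IS values differ even
though the downstream classification logic is faithful. The Hi-C branch
tests only intrachromosomal pixels within the configured distance range,
takes loop lists as input rather than discovering loops, and its
simulator omits domain structure. Designs with more than three
conditions are not supported in the 5C branch, and more than two are
untested in the Hi-C classification beyond the argmax rule.
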