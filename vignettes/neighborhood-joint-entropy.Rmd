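---
title: "Feature selection by neighborhood joint entropy: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature selection by neighborhood joint entropy: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bonje)
```

## The problem

High-dimensional tables with continuous measurements and few samples — the
tumor-microarray regime, where thousands of gene-expression features describe
a few dozen biopsies — defeat classifiers unless most features are discarded
first. Rough set reducts do this for *discrete* attributes by asking which
attributes are needed to discern the decision classes. For continuous
attributes, the equivalence classes of classical rough sets are replaced by
**neighborhood granules**: sample $x_i$'s granule on attribute subset $B$ is

$$n_B^\delta(x_i) = \{\, x_j : d_B(x_i, x_j) \le \delta \,\},$$

with $d_B$ the Minkowski distance restricted to $B$ (order $p$, default
$p = 2$) and $\delta$ a radius in the min–max-normalized $[0,1]$ feature
space. The decision class $[x_i]_D$ is the set of samples sharing $x_i$'s
label.

## The selection criterion

Two classical views measure how well $B$ determines the decision $D$:

* **Algebraic view** — the *approximate precision*
  $P_B(D) = |\underline{N}_B D| / |\overline{N}_B D|$, the size ratio of the
  union of lower approximations of the decision classes (samples whose whole
  granule is pure) to the union of upper approximations (always the whole
  universe, since each granule contains its own sample).
* **Information view** — entropies of the granulation. Per sample, define the
  *joint granule* $n_{B,D}(x_i) = n_B^\delta(x_i) \cup [x_i]_D$, the
  *credibility* $n\alpha_i = |n_B^\delta(x_i) \cap [x_i]_D| / |n_{B,D}(x_i)|$
  and the *coverage* $n\kappa_i = |n_B^\delta(x_i) \cap [x_i]_D| / |[x_i]_D|$.

The package's selection criterion fuses the two views in the **neighborhood
joint entropy**

$$H_\delta(D, B) \;=\; -\frac{P_B(D)}{|U|} \sum_{i}
  \log \frac{|n_B^\delta(x_i) \cap [x_i]_D|^2}{|n_{B,D}(x_i)|\,|[x_i]_D|}
  \;=\; -\frac{P_B(D)}{|U|} \sum_i \log (n\alpha_i \, n\kappa_i),$$

together with the marginal entropy
$H_\delta(B) = -(P_B(D)/|U|)\sum_i \log(|n_B^\delta(x_i)|/|n_{B,D}(x_i)|)$
and the conditional entropy satisfying the chain rule
$H_\delta(D|B) = H_\delta(D,B) - H_\delta(B)$. Both identities — the
credibility/coverage form and the chain rule — are exercised as equalities
(tolerance $10^{-12}$) over hundreds of random small systems in the test
suite, alongside the monotonicity of $P_B(D)$ under growing $B$.

$H_\delta(D,\cdot)$ itself is **not** monotone under subset growth: shrinking
granules change the per-sample log terms in either direction even as the
precision weight grows. The test suite freezes a random witness where adding
an attribute strictly decreases the joint entropy. Non-monotonicity dictates
the stopping rule below.

## The greedy search

`bonje()` starts from $B = \emptyset$, scores every remaining attribute $b$
by $H_\delta(D, B \cup \{b\})$, adds the argmax, and stops at the first step
whose best candidate no longer *strictly* improves the current value (its
significance $\mathrm{Sig}(b, B, D) = H_\delta(D, B\cup\{b\}) - H_\delta(D,B)$
is $\le 0$). Because the criterion is non-monotonic, this is a stop rule, not
a saturation test. Three numerical choices matter:

* **Strict improvement with tolerance.** Two float pipelines can produce the
  same entropy down to rounding; the comparison uses an absolute tolerance of
  $10^{-12}$, so an exact tie stops the search (on the worked 4-sample table
  this is precisely what terminates it: adding the last attribute leaves the
  entropy unchanged at 0.345).
* **Tie-break.** Equal-best candidates resolve to the lowest feature index —
  deterministic and reproducible; no reference convention exists.
* **Inclusive boundary, no epsilon.** Granule membership uses
  $d \le \delta$ compared directly in floating point. On the embedded
  4-sample table the boundary pair at distance exactly $0.3$ evaluates just
  below $0.3$ in IEEE doubles, so the worked example reproduces without any
  slack term, and no slack is added that could silently grow granules
  elsewhere.

`verify_feature_subset()` reports the two reduct conditions — the subset
preserves the full set's joint entropy, and no member is redundant — but the
greedy pass does not enforce the first (non-monotonicity can leave the greedy
result above or below the full set) and implements no repair sweep for late
redundancy; the reference procedure defines none, and the report makes the
condition auditable instead.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `delta` | 0.3 | neighborhood radius in the normalized $[0,1]$ space; governs granularity. Profiles are produced over `seq(0.05, 1, 0.05)` by `radius_sweep()`; radii beyond ~0.5 merge most granules and select little. |
| `p` | 2 | Minkowski order (2 = Euclidean, the worked-example convention) |
| `log_base` | 10 | entropy logarithm base; 10 reproduces the worked example's printed values, base 2 is common elsewhere. All measures rescale exactly by $\log_{b_1} b_2$. |
| `tol` | 1e-12 | absolute tolerance of the strict-improvement and reduct comparisons |
| `k` (folds) | 10 | cross-validation folds in the evaluation harness |
| `alpha` | 0.10 | significance level of the Friedman/Nemenyi comparison |

Normalization statistics are computed once on the full table (the standard
protocol for this method family). The evaluation harness therefore selects on
the full table before cross-validating — optimistic relative to nested
selection, and documented as such; `cross_validate()` itself stratifies folds
within classes, falling back to plain folds with a warning when a class is
smaller than the fold count.

## Degenerate inputs

Constant columns normalize to all zeros (inert) rather than erroring. A
single-class decision yields an empty selection with a warning: every
entropy is degenerate. $P_B(D) = 0$ short-circuits every entropy to exactly
0 — each log term is finite anyway (intersections contain the sample itself),
but the short-circuit documents the multiplicative-zero intent. An empty
attribute subset is an error everywhere: distance over no attributes is
undefined.

## What the synthetic generator emulates — and what it does not

`generate_table()` produces the regime the selector targets at desk scale:
a few relevant features (class-conditional Gaussians whose per-class means
sit `class_separation` within-class standard deviations apart), optional
redundant features (jittered affine copies of relevant ones), and many
class-independent uniform noise features, all min–max normalized, labels
balanced. Defaults (80 samples, 2 relevant + 20 noise features, separation 5,
within-class SD 0.05) keep the greedy search in the sub-second range while
leaving noise features genuinely uninformative.

Real microarray data differ in ways the generator does not imitate:
feature counts in the thousands, heavy-tailed and correlated expression
noise, batch effects, and unbalanced classes. Passing recovery tests
therefore shows the selector finds planted low-dimensional signal among
independent noise — not that it reproduces published accuracies on external
benchmark datasets, which are deliberately out of scope (they depend on
specific external classifiers and are not bundled).

Gaussian class-conditional signal was chosen because neighborhood granules
behave predictably under it: at small radii, granules within a class stay
dense while cross-class granules empty out, which is the mechanism the
criterion rewards.

## Algorithm comparison statistics

`compare_algorithms()` implements the rank-based comparison of M algorithms
over N datasets: midranks per dataset (rank 1 = highest accuracy; ties share
averaged positions, so each dataset's ranks sum to $M(M+1)/2$), the Friedman
statistic

$$\chi_F^2 = \frac{12N}{M(M+1)} \sum_i R_i^2 - 3N(M+1),$$

the Iman–Davenport correction
$F_F = (N-1)\chi_F^2 / (N(M-1) - \chi_F^2)$ referred to the
$F(M-1, (M-1)(N-1))$ distribution (critical values from `qf`, so any degrees
of freedom are supported), and the Nemenyi critical distance
$CD = q_\alpha \sqrt{M(M+1)/(6N)}$. The $q_\alpha$ values (two-tailed
studentized range at infinite df over $\sqrt 2$, $M = 2..20$,
$\alpha \in \{0.05, 0.10\}$) are embedded with their numeric source noted
in-code and cross-checked in the tests against `qtukey(1-\alpha, M, Inf)/sqrt(2)`.
Rank matrices can be supplied directly, so published rank tables can be
replayed verbatim even where they disagree with their accuracy tables.

## Worked example

```{r toy}
nds <- neighborhood_system(toy_decision_table(), delta = 0.3,
                           normalize = FALSE)
explain_subset(nds, "a")
fit <- bonje(nds)
summary(fit)
```

## Problem sizes used by the checks

The test suite and the reproduction script run entirely on embedded or
generated data: the 4-sample worked example; 200 random systems of up to 10
samples and 4 features for the entropy identities; brute-force oracle
comparisons at up to 8 samples; recovery runs at 80 samples and 22 features
over five seeds; and the published rank tables (5×4, 5×5, 11×3) for the
comparison statistics. These sizes were chosen so the whole suite completes
in well under a minute on a laptop while still exercising every code path at
the scale where exhaustive oracles are feasible.

## Known limitations

* Complexity is $O(n^2 |B|)$ per candidate evaluation and the greedy pass
  evaluates $O(|C|^2)$ candidates; tables with thousands of features are
  feasible but slow, and no accelerator structure is implemented.
* Only continuous condition attributes are supported; mixed or nominal
  distances are out of scope.
* The whole-table normalization and selection protocol leaks marginal
  information across cross-validation folds (documented above).
* The greedy pass may return a subset violating the entropy-preservation
  condition of a reduct; `verify_feature_subset()` makes this visible but no
  repair is attempted.
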