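---
title: "Differential coexpression networks: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential coexpression networks: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcnet)
```

## The model

Two sample groups — a disease group (here chronic myelogenous leukemia,
CML) and a normal group — are compared not gene by gene but *pair by pair*.
For genes $i$ and $j$ with expression profiles $x_i$, $x_j$ within one
group, the coexpression level is

$$C(i,j) = \lvert \mathrm{cor}(x_i, x_j) \rvert \in [0, 1],$$

the absolute Pearson correlation across that group's samples. The absolute
value is deliberate: a strong negative correlation (an inhibiting
relationship, e.g. degradation of an anti-apoptotic regulator) is as much a
functional link as a strong positive one, so the sign is erased. Pearson
correlation is scale- and shift-invariant, so normalization constants and
baselines cancel. Each unordered pair gets two levels, $C_d$ (disease
samples only) and $C_n$ (normal samples only); a 20-gene panel yields
$\binom{20}{2} = 190$ pairs per group.

### Threshold selection

A single threshold $C^*$ dichotomizes pairs into *strong* and *weak*
coexpression classes so that the classes separate the two groups as well as
possible. Because interest is in strong coexpression, the comparison uses
inverted empirical CDFs (survival fractions)

$$F_d(C) = \mathrm{Prob}(C_d \ge C), \qquad F_n(C) = \mathrm{Prob}(C_n \ge C),$$

and the threshold is placed where the two curves deviate most:

$$D = \max_C \lvert F_d(C) - F_n(C) \rvert,$$

the two-sample Kolmogorov–Smirnov statistic. The inequality is inclusive
($\ge$), so a pair sitting exactly at $C^*$ is strong. An asymptotic KS
p-value is attached via the Kolmogorov tail function
$Q(\lambda) = 2\sum_{k\ge1}(-1)^{k-1}e^{-2k^2\lambda^2}$ with
$\lambda = \sqrt{nm/(n+m)}\,D$, and the strong/weak $\times$
disease/normal contingency table is verified with a Pearson chi-square test
**without** continuity correction (the uncorrected statistic is what the
dichotomy verification reproduces exactly; on the counts 45, 98 / 145, 92
it equals 31.4957).

A caveat worth stating plainly: the two "samples" entering the KS test are
the 190 per-pair levels of the *same* gene panel, which are dependent
statistics (pairs share genes). The p-value is therefore a reference
figure on the conventional asymptotic scale, not an exact test level; the
package reports it as such.

### Networks and signatures

Strong pairs are partitioned into *common* (strong in both groups),
*normal-specific* and *disease-specific* (strong in one group, common pairs
removed) edge sets. By construction
$|\text{common}| + |\text{group-specific}| = $ number of that group's
strong pairs. For display, levels within each network are mapped linearly
from $[C^*, C_{\max}]$ to thicknesses $[1, 6]$, where $C_{\max}$ is that
network's own maximum level, and written as Pajek `.net` files.

Given regulator→target annotation tables (miRNA 3′-UTR targets, TF 5′-UTR
binding sites), a regulator's *signature* is the set of network pairs whose
**both** endpoints it targets. A regulator is kept if it covers at least
`min_pairs = 4` pairs (inclusive), signatures of one class that share
covered genes are merged (connected components of the gene-overlap
relation), and the composite signature (CRS) is the pair-set intersection
of a merged miRNA network (MRS) and a merged TF network (TRS), carrying the
regulators whose target sets contain every CRS gene.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `grid` | `"observed"` | Thresholds at which the curves are evaluated. The observed grid (union of all $C_d$, $C_n$ values plus 0 and 1) is exact because the step functions only change there; `"uniform"` with `step = 1e-4` mimics scanning "every possible threshold" and is provided for comparison. |
| `collapse` | `"max_mean"` | Probe-to-gene collapse. `max_mean` (keep the probe with highest mean expression) is a common deterministic convention; `mean` averages probes. The choice is exposed because array designs differ. |
| `min_pairs` | 4 | Minimum covered pairs for a regulatory signature; the selection rule counts *pairs*, while gene counts are reported alongside for description. |
| `rule` | `"both"` | Pair-coverage rule. A pair is covered when both endpoints are targets; `"any"` (one endpoint) is available but dilutes the coordinate-regulation interpretation. |
| `log2` (pipeline) | `FALSE` | Apply `log2(x+1)` for raw-scale inputs. Values are otherwise used exactly as provided. |

## Numerical and degenerate-input choices

* **Tie at the threshold**: $C \ge C^*$ is strong — inclusive, matching the
  survival-fraction definition.
* **Tie in $D$ across thresholds**: the *largest* achieving threshold is
  reported. When the deviation plateaus — which happens routinely when many
  pairs are near-null — the smallest achieving threshold can land inside
  the weak-coexpression noise floor whenever the noise region happens to
  touch the plateau value, sweeping dozens of null pairs into the strong
  class; the largest achieving threshold instead reports the most stringent
  strong class and is stable in exactly those situations. Both rules are
  deterministic and coincide when the maximum is unique.
* **Undefined correlations** (a gene constant within a group, or missing
  values inside a group): the pair keeps its row, flagged `NA`, is counted
  in a message, and is excluded from curves, contingency counts and
  networks. Degenerate profiles abort nothing.
* **Degenerate thickness** ($C_{\max} = C^*$): all edges get thickness 1
  with a message.
* **KS tail series**: truncated when terms drop below `1e-16`; at the pair
  counts involved ($\ge 190$ per side) the asymptotic regime is
  comfortable.
* **Chi-square**: `stats::chisq.test(correct = FALSE)`; the continuity
  correction is off by design (see above) and a zero marginal is an error,
  not a silent 0.

## The synthetic generator

`simulate_expression()` draws each group independently from a multivariate
normal with unit variances and a block-structured correlation matrix:
within a `correlation_block()` every pair has the target correlation, all
other pairs are independent, and blocks may apply to one or both groups.
Disjointness of blocks within a group is enforced so the implied matrix is
unambiguous, and each block's own positive semi-definiteness is checked
(`r >= -1/(k-1)` for a uniform block of `k` genes — strongly negative
blocks are necessarily pairs). Optional iid measurement noise
(`noise_sd`) attenuates planted correlations by $1/(1+\sigma^2)$; the
default is 0 so planted values are exact population values. A constant
baseline of 8 mimics log2 array intensities and affects nothing.

`simulate_planted_fixture()` is the study-shaped instance: 20 genes,
16 disease + 8 normal samples by default, with planted categories spanning
everything the partition must recover —

* `g01..g12` pairwise $r = 0.9$ in the normal group only (66
  normal-specific pairs),
* `g13..g15` pairwise $r = 0.95$ in both groups (3 common pairs),
* `g16, g17` $r = -0.95$ in the disease group only (1 disease-specific
  pair; negative on purpose, so sign erasure is exercised),
* `g18..g20` independent; their 3 mutual pairs are labelled `absent` as
  controls.

Only planted block pairs and the designated control pairs carry labels.
The remaining background cross pairs are genuinely null, but at a finite
sample size their sample correlations crowd the region just below any
sensible threshold; whether one of them grazes $C^*$ is boundary noise,
not planted truth, so the fixture does not assert their fate.

**What the generator does and does not emulate.** It reproduces the
two-group design, the panel size, per-group correlation structure of both
signs, and exact seeded reproducibility. It does not emulate probe-level
structure, normalization artifacts, heavy-tailed intensity distributions,
cell-cycle-fraction substructure within groups, or correlated measurement
error — so passing recovery tests demonstrates the estimator's correctness
under its stated sampling model, not robustness to real microarray
pathology. The study's pooling of cell-cycle fractions into one disease
group is likewise taken at face value: fraction is not modelled as a
covariate.

## Problem sizes used in validation

Parameter-recovery checks run the full pipeline at 200 samples per group
(where sampling error keeps planted $|r| \in \{0.9, 0.95\}$ pairs above
0.8 and null pairs far below), threshold-optimizer equivalence against a
brute-force scan uses 200 random tables of up to 45 pairs, and the
convergence and independence checks use up to 5000 samples per group for
tight Fisher-z bounds. These sizes make every property sharp while keeping
the whole suite around ten seconds.

## Known limitations

* The KS p-value's dependence caveat above; no permutation alternative is
  provided because the method's contract is the asymptotic formula.
* No multiple-testing control across pairs is applied anywhere — the
  threshold is a single global decision, not 190 tests.
* Regulator annotations are taken as input tables; the package neither
  predicts miRNA targets nor scans TF binding sites, and the shipped
  annotation files are synthetic demonstrations of the rules, not curated
  biology.
* Probe collapse supports `max_mean` and `mean` only; model-based
  summarization is out of scope.
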