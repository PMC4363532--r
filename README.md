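# dcnet — differential gene coexpression networks

`dcnet` contrasts the gene-pair coexpression structure of two sample
groups — a disease group and a normal group — to find which functional
links between genes are shared, which exist only in health, and which are
disease-specific. It was built for small curated gene panels (the
motivating use case is a 20-gene apoptosis/autophagy panel in chronic
myelogenous leukemia profiled on expression arrays, 16 disease vs 8 normal
samples), where pairwise structure is informative even when single-gene
differential expression is not.

## The method

For genes *i*, *j* with profiles *x<sub>i</sub>*, *x<sub>j</sub>* inside
one group, the **coexpression level** is the absolute Pearson correlation

&nbsp;&nbsp;&nbsp;&nbsp;*C*(*i*, *j*) = |cor(*x<sub>i</sub>*, *x<sub>j</sub>*)| ∈ [0, 1],

computed separately over the disease samples (*C<sub>d</sub>*) and the
normal samples (*C<sub>n</sub>*); the sign is erased so inhibiting
relationships count as links. The strong/weak dichotomy threshold *C\** is
chosen where the inverted empirical CDFs
*F<sub>d</sub>*(*C*) = Prob(*C<sub>d</sub>* ≥ *C*) and
*F<sub>n</sub>*(*C*) = Prob(*C<sub>n</sub>* ≥ *C*) deviate most,

&nbsp;&nbsp;&nbsp;&nbsp;*D* = max<sub>*C*</sub> |*F<sub>d</sub>*(*C*) − *F<sub>n</sub>*(*C*)|,

the two-sample Kolmogorov–Smirnov statistic (with its asymptotic p-value),
and the resulting strong/weak × disease/normal contingency table is
verified with an uncorrected Pearson chi-square test. Strong pairs are then
partitioned into **common**, **normal-specific** and **disease-specific**
networks, edge thicknesses are mapped linearly from [*C\**, *C*<sub>max</sub>]
to [1, 6], and each network is written as a Pajek `.net` file. Optional
regulator→target tables (miRNA targets, TF binding sites) yield regulatory
signatures: a regulator covering ≥ 4 strong pairs (both endpoints
targeted) forms an MRS/TRS, signatures sharing genes merge, and the
MRS∩TRS pair intersection is the composite signature (CRS).

See the methods vignette
(`vignettes/differential-coexpression.Rmd`) for assumptions, parameter
rationale and limitations.

## Worked example

The package ships a seeded generator whose planted correlation blocks
emulate the study design (20 genes, 16 disease + 8 normal samples; 66
normal-specific, 3 common and 1 negative disease-specific planted pairs):

```r
library(dcnet)
fx  <- simulate_planted_fixture(seed = 1)
fit <- dcn(fx$dataset)
fit
#> Differential coexpression network fit
#>   20 genes, 190 pairs (16 disease / 8 normal samples)
#>   C* = 0.4118   D = 0.5158   KS p = 2.23e-22
#>   chi-square = 106.8236 (p = 4.87e-25), no continuity correction
#>   edges: 16 common, 106 normal-specific, 8 disease-specific
```

Reading: of the 190 gene pairs, the fraction strongly coexpressed (level ≥
*C\** = 0.4118) differs between groups by *D* = 0.5158 at the optimum — far
more strong pairs in the normal group (122) than in the disease group (24),
as the contingency table shows:

```r
fit$contingency
#>         group
#> class    disease normal
#>   strong      24    122
#>   weak       166     68
```

That asymmetry is exactly what was planted (the normal-only block dominates),
and the chi-square of 106.8 confirms the class–group association. At only 8
normal samples the null pairs are noisy, so some background pairs cross the
threshold alongside the planted ones; at 200 samples per group the pipeline
recovers every planted category exactly (that recovery is an automated
test). Hubs are read off the degree report:

```r
head(degree_report(fit$partition$normal_specific), 3)
#>   gene degree
#> 1  g04     15
#> 2  g01     14
#> 3  g05     14
```

`plot(fit)` draws the two inverted CDFs with *C\** marked;
`run_pipeline()` (or `Rscript inst/scripts/dcnet.R run config.yaml`) runs
the same analysis file-to-file, writing the pair table, survival curves, a
threshold report, the three Pajek networks and, when an annotation table is
supplied, the signature reports.

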