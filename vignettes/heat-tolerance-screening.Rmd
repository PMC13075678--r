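---
title: "Screening wheat for terminal heat tolerance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening wheat for terminal heat tolerance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heattol)
```

## The screening problem

Terminal heat stress — high temperature during flowering and grain filling —
is a dominant yield constraint for spring wheat in warm environments. A
standard field protocol screens a genotype panel by sowing the same material
twice: at the normal date (fall), and late (spring), so that reproductive
development runs into summer heat. Comparing each genotype's grain yield
under the two sowing dates, relative to the panel as a whole, separates
genotypes that merely yield well from genotypes that *hold* their yield under
heat.

`heattol` implements the full analysis chain for such trials: plot-level data
handling, balanced combined ANOVA with variance components and broad-sense
heritability, the ten yield-based stress tolerance/sensitivity indices with
HSI classification and composite ranking, trait/index correlation matrices,
and PCA of standardized genotype means. A synthetic-trial generator with the
same variance-component structure makes every stage testable without field
data.

## Data model

The unit of observation is the plot: genotype $i$, sowing-date condition $j
\in \{\text{normal}, \text{stress}\}$, year $k$, replicate $l$, one numeric
value per trait. `trial_data()` holds these in long format and checks key
uniqueness; `read_trial_csv()`/`write_trial_csv()` move them through a plain
UTF-8 CSV (`genotype,condition,year,rep,block,trait,value`, with
`fall`/`spring` accepted as condition aliases and a column-mapping `dialect`
for wide files). Yields arrive as grams per harvested plot area and are put
on a g/m² basis by `standardize_yield()` (for the 0.40 m² harvested area of
a two-row plot this is the familiar ×2.5). Harvest index is computed per
plot as $100\,GY/BY$ and then averaged; the per-plot mean differs from the
ratio of condition means whenever plots vary (Jensen's inequality), and the
per-plot convention is the one that matches published panel tables.

Missing values are handled by complete-case analysis per trait. A genotype
missing an entire condition is listed in an exclusion report rather than
silently dropped, because every downstream index needs both condition means.

## The combined ANOVA

With genotype (G) and sowing date (SD) fixed, and year (Y) and replication
nested in SD×Y random, the balanced combined analysis under an RCBD framework
partitions the total sum of squares into Y, SD, SD×Y, Rep(SD×Y), G, G×SD,
G×Y, G×SD×Y and Residual. `combined_anova()` computes this partition through
a sequential linear-model fit, which under balance coincides exactly with the
textbook marginal/cell-mean decomposition — the test suite verifies this
against an explicit mean-decomposition oracle to 10⁻⁹ relative, and asserts
SS and df conservation on every run.

The F denominators deserve care because mixed designs admit several
conventions. The package tests each fixed effect against its interaction
with the random year factor — SD and Y against SD×Y, G against G×Y, G×SD
against G×SD×Y — and the random interactions and Rep(SD×Y) against the
residual. With only two years the SD test has a single denominator df, which
is why an enormous SD mean square can still earn only p < 0.05 in this kind
of trial. The assignment is overridable per source via `error_terms =`, e.g.
`list(G = "Residual")`, since some analysts prefer residual-based tests when
the G×Y mean square is not significant. No multiplicity correction is
applied to the ANOVA p-values; significance is flagged at 0.05/0.01.

An alpha-lattice layout is analyzed as an RCBD (the `block` column is
ignored) on the grounds that inter-block effects in these trials are
typically negligible once replicates are modelled; the generator has a
`var_block` knob for studying what happens when they are not.

### Variance components and heritability

From a per-condition ANOVA (sources Y, Rep(Y), G, G×Y, Residual), the
method-of-moments solution of the expected mean squares for $r$ replicates
and $y$ years is

$$\hat\sigma^2_e = MS_{res},\qquad
  \hat\sigma^2_{GY} = \frac{MS_{GY} - MS_{res}}{r},\qquad
  \hat\sigma^2_G = \frac{MS_G - MS_{GY}}{r\,y}.$$

Moment estimators can go negative; negative components are truncated to zero
and flagged, with the raw values retained for diagnostics. Broad-sense
heritability on a genotype-mean basis is

$$h^2_b = \frac{\sigma^2_G}{\sigma^2_P},\qquad
  \sigma^2_P = \sigma^2_G + \frac{\sigma^2_{GY}}{y} + \frac{\sigma^2_e}{r\,y},$$

reported as `"np"` (non-predictive) whenever $\hat\sigma^2_G$ truncates to
zero — the honest statement that the trial provides no usable genetic signal
for that trait, common for grain yield itself in strongly G×E-driven panels.

Fisher's LSD for mean separation is $t_{1-\alpha/2,\,df_e}\sqrt{2\,MS_e/n}$.
Outliers are screened, never auto-removed: `screen_outliers()` fits a
preliminary RCBD per condition×year environment and flags plots with
externally studentized residuals beyond |3|; removal requires an explicit
`remove_records()` call, reserved for observations with a non-experimental
cause.

## The stress indices

Writing $Y_P, Y_S$ for a genotype's condition means and $X_P, X_S$ for the
panel means, `stress_indices()` computes

| Index | Formula | Direction |
|---|---|---|
| HSI | $(1-Y_S/Y_P)/(1-X_S/X_P)$ | low = tolerant |
| YSI | $Y_S/Y_P$ | high |
| STI | $Y_S Y_P/X_P^2$ | high |
| TOL | $Y_P-Y_S$ | low |
| MP | $(Y_P+Y_S)/2$ | high |
| GMP | $\sqrt{Y_P Y_S}$ | high |
| YI | $Y_S/X_S$ | high |
| HM | $2Y_PY_S/(Y_P+Y_S)$ | high |
| MRP | $Y_S/X_S + Y_P/X_P$ | high |
| PYR | $100\,(Y_P-Y_S)/Y_P$ | low |

GMP is implemented as the geometric mean $\sqrt{Y_P Y_S}$ — that is what
"geometric mean productivity" means, and it is what makes the AM–GM–HM chain
$HM \le GMP \le MP$ hold with equality iff $Y_P = Y_S$. Some reports print
the GMP formula as the raw product $Y_S \times Y_P$; that quantity is simply
$STI \cdot X_P^2$ and is exposed separately as `yield_product` for anyone
replicating such tables. The panel means are computed from the analyzed
panel itself, controls included, since that is how $X_P$ and $X_S$ are
defined; they can also be supplied explicitly through `yield_summary()` when
working from published per-genotype tables whose panel means come from a
larger panel.

Several identities are structural and are asserted wherever index tables are
computed: $PYR = 100(1-YSI)$, $HSI = (1-YSI)/(1-X_S/X_P)$,
$STI = GMP^2/X_P^2$, $MRP = YI + Y_P/X_P$. Because HSI is a *decreasing
affine* function of YSI across a panel (the panel loss factor is a shared
constant), $\mathrm{corr}(YSI, HSI) = -1$ and $\mathrm{corr}(HSI, PYR) = +1$
exactly, on any panel whatsoever — the −1.0/+1.0 entries seen in published
index-correlation tables are analytic facts, not empirical findings.

### Classification and selection

`classify_hsi()` groups genotypes as tolerant (HSI ≤ 0.8), semi-tolerant
(0.8 < HSI ≤ 1.3) or susceptible (HSI > 1.3), boundaries inclusive exactly
as written; 1.2 is a common alternative susceptible boundary and both are
reachable through `hsi_thresholds()`. `composite_rank()` converts HSI (low
good), MP and STI (high good) to within-index ranks — average ranks on ties,
since the choice is otherwise arbitrary — and orders genotypes by mean rank,
breaking residual ties by lower HSI and then genotype id so the ordering is
total and reproducible. `hsi_mp_selection()` operationalizes the common
HSI-versus-MP scatter: an OLS line of HSI on MP is fitted and genotypes with
above-mean MP *and* below-line HSI (negative residual) are selected — i.e.
better-than-expected tolerance at high productivity. The below-line rule is
one reasonable reading of how such scatters are used for selection; it is
documented as an interpretation, and the fitted line and residuals are
returned so users can apply their own rule.

## Correlations and PCA

Trait correlations are computed on genotype means within each condition —
one value per genotype per trait, the granularity at which screening reports
quote one r per trait pair per condition — with two-sided p-values from the
t transform on $n-2$ df and the `*`/`**` star convention (no multiple-testing
correction, matching reporting practice in this literature). Index
correlations are computed across the panel on the index table itself.

PCA (`trait_pca()`) standardizes complete cases to z-scores and
eigen-decomposes the correlation matrix. Eigenvector signs are fixed
deterministically — the largest-magnitude loading in each component is made
positive — because the sign is otherwise arbitrary and platform-dependent.
Both per-condition PCAs and a pooled mode (condition-specific genotype means
stacked as rows, so both environments enter one ordination) are provided,
since published biplots are drawn both ways; `genotype_mean_table(wide =
TRUE)` gives the third option of condition means concatenated as columns.

## The synthetic generator

`generate_trial()` draws balanced trials from

$$y_{ijkl} = \mu_j + g_i + (g\,sd)_{ij} + y_k + (sd\,y)_{jk} + (g\,y)_{ik}
 + (g\,sd\,y)_{ijk} + r_{l(jk)} + \varepsilon_{ijkl},$$

with $\mu_{stress} = \mu_{normal}(1-\text{penalty})$ and every random term
independent Gaussian. Gaussianity is a modelling choice, not a claim about
field data: the ANOVA and heritability machinery uses only second moments,
so the generator needs correct variances, not correct shapes. Each term
draws from its own seed sub-stream, so changing one variance never perturbs
the realized draws of another — essential for controlled recovery
experiments. A truth sidecar records the realized $g_i$ and $(g\,sd)_{ij}$
and the implied true expected condition means and true HSI per genotype; it
is consumed only by tests, never by the analysis path.

`reference_trial_config()` fixes the study conditions the package is
exercised under: 156 genotypes × 2 sowing dates × 2 years × 2 replicates,
$\mu_{normal} = 899$ g/m², a 25 % stress penalty, and variance components
chosen once from the published panel's summary statistics — genotype-mean
standard deviations near 130 (normal) and 100 (stress) g/m², residual
variance 2358 g²/m⁴ giving a residual CV near 6 % — via the balanced-design
identity $\mathrm{Var}(\bar y_{i\cdot}) = \sigma^2_G + \sigma^2_{G\times SD}
+ (\sigma^2_{GY}+\sigma^2_{GSDY})/y + \sigma^2_e/(ry)$. Companion traits
(days to flowering with a large condition effect; thousand-kernel weight;
grain protein with near-zero condition effect and dominant genotype
variance, the typical quality-trait pattern) exercise the multi-trait
paths. What the generator does **not** emulate: spatial field trend,
lattice block structure (unless `var_block` is set), non-Gaussian error,
genotype-specific multiplicative stress response, or missing data. Passing
tests therefore certify the *arithmetic and inferential machinery*, not the
field realism of any particular dataset.

## Numerical choices

* Report tables round half away from zero at the printed precision
  (`round_half_away()`), the convention of agronomic tables; base `round()`
  rounds ties to even and disagrees at exactly-half values.
* Mean squares below $10^{-10}$ of the largest mean square are treated as
  exact zeros when forming F ratios, so degenerate noise-free layouts give a
  clean `F = Inf` sentinel instead of floating-point noise.
* A correlation of exactly ±1 gets p = 0 directly rather than through the
  (infinite) t transform.
* SS/df conservation is asserted inside the ANOVA constructor on every call;
  an imbalance is refused with a pointer to the exclusion report rather than
  silently falling back to non-orthogonal sums of squares (no Type-III path
  in this version).
* Test and example problem sizes: property tests run oracles at 4–8
  genotypes where brute force is exact and cheap; distributional recovery
  tests run 120–200 simulated trials at the full 156-genotype scale, enough
  for Monte-Carlo standard errors a few percent of the target quantities.

## Worked example

```{r example}
scr <- heat_screen(config = reference_trial_config(seed = 42))
scr
head(scr$top)
scr$anova$GY$per_condition$normal$h2b
```

```{r plot, fig.width = 6, fig.height = 5}
plot(scr, which = "hsi_mp")
```

## Known limitations

Only balanced data are analyzed; unbalanced trials must be completed or
explicitly reduced first. Variance components come from moment equations,
not REML, so they inherit the truncation issue (flagged, and reported as
"np" heritability when genotypic variance vanishes). The per-condition model
treats the genotype effect within a condition as the screened quantity; a
genotype excellent under stress but absent under normal sowing cannot be
indexed. And the HSI classes depend on the panel composition through
$X_S/X_P$: adding or removing genotypes moves everyone's HSI, which is
inherent to the index, not to the implementation.
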