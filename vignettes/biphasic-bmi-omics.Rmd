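---
title: "Detecting biphasic BMI dependence in myocardial omics data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting biphasic BMI dependence in myocardial omics data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmiomics)
```

## The scientific problem

Clinical cohorts under acute metabolic stress show a u-shaped ("obesity
paradox") relationship between body mass index and mortality: overweight and
moderately obese patients fare better than lean or severely obese ones. If
this paradox has a molecular substrate, some myocardial transcripts and
metabolites should respond *biphasically* to BMI — falling and then rising
(u-shape) or rising and then falling (n-shape) with an interior extremum —
rather than monotonically. `bmiomics` implements a complete pipeline for
asking that question of a bulk transcriptome plus a targeted metabolite
panel measured on the same cohort: a per-feature two-segment breakpoint
statistic, data-driven BMI grouping from the breakpoint distribution,
moderated differential expression, correlation-adjusted competitive gene-set
tests, weighted correlation-network modules with eigengene analysis, PLS-DA
metabolite contrasts, and a two-block latent-variable transcript–metabolite
association network.

Everything is exercised on seeded synthetic data with planted ground truth,
so each stage's statistical behaviour is testable without any external
download.

## The two-segment ("two lines") biphasic statistic

For one feature with response $y$ (normalized log2 expression) and covariate
$x$ (BMI), the procedure fits two separate regression lines on either side
of a data-chosen breakpoint $c$:

$$y = a_1 + b_1 x \ (x < c), \qquad y = a_2 + b_2 x \ (x \ge c).$$

A feature is called **u-shaped** when $b_1 < 0 < b_2$ and both arms are
individually significant ($\max(p_1, p_2) < \alpha$, default
$\alpha = 0.05$), **n-shaped** for the opposite signs, and **none**
otherwise. Demanding *two* independently significant, opposite-signed
slopes is what distinguishes this from a quadratic-term test, which is
known to produce false positives for merely monotone-but-curved
relationships: a monotone trend cannot satisfy the sign rule no matter how
strong its curvature.

The breakpoint is located in three steps:

1. **Quadratic pilot.** OLS of $y$ on $(x, x^2)$; the extremum $-b/(2c)$ of
   the fitted parabola is the initial breakpoint, clipped so each arm keeps
   at least `min_arm` observations (default 5 — below that, arm p-values
   are unstable). If the curvature is numerically degenerate, the midpoint
   of the covariate range is used.
2. **Robin Hood adjustment.** The breakpoint moves one observation at a
   time toward the arm with the larger $|t|$, handing observations from the
   statistically rich arm to the poor one, as long as
   $\min(|t_1|, |t_2|)$ strictly increases; it stops at the first
   non-improvement. This is a greedy hill climb: it can stop at a local
   optimum of the $\min |t|$ landscape, which is part of the documented
   contract and is what the test suite verifies against an independent
   reimplementation.
3. **Reporting.** The breakpoint is reported as the midpoint between the
   two boundary observations. An exhaustive mode
   (`fit_two_lines(..., method = "exhaustive")`) searches every admissible
   split for the global optimum; it exists for oracle testing and for
   users who prefer the optimized statistic with its higher sensitivity —
   and correspondingly higher false-call rate.

Arms are fitted as two fully separate OLS lines (a discontinuity at the
breakpoint is allowed) with ordinary standard errors. Across features, the
scan reports a BH-adjusted q-value over the combined p-value
$\max(p_1, p_2)$, restricted to opposite-sign features; shape *calls*
however use the raw per-arm $\alpha$ rule, mirroring the method's published
use. Users who need FDR-gated calls should filter on `q_value`.

### Calibration and honest error rates

On null features the both-arms rule is conservative: the measured call rate
on 5,000 simulated null features is about 0.6% at $\alpha = 0.05$. But in a
genome-scale scan even a sub-percent false-call rate produces tens of false
calls, so when true biphasic features are rare the false discovery
*proportion* among calls is substantial (on the default synthetic study —
60 planted biphasic among 2,000 features — roughly a quarter of calls are
false at raw $\alpha$). This is a property of raw-significance calling, not
of the implementation; the q-value column is provided precisely so users
can trade sensitivity for FDR control.

## Data-driven BMI groups

Breakpoints of significant features are rounded to integer BMI and binned.
The modal region is the argmax bin plus all bins with at least 80% of the
maximal count contiguous with it; the middle BMI group spans the modal bins
± `halfwidth` (default 3 BMI units). Group assignment is inclusive on both
boundaries: low ($x < \ell$), mid ($\ell \le x \le u$), high ($x > u$). On
data whose breakpoints concentrate at BMI 28–29 this reproduces the
grouping low / 25–32 / high.

## Expression preparation

Counts are filtered by an explicit rule (CPM above `min_count` scaled by
the median library size in at least `min(group_sizes)` samples, and total
count at least `min_count + 5`), log2-CPM transformed with a half-count
offset, quantile normalized (every sample receives the mean of the sorted
sample vectors; ties get the mean of the tied reference values), and
batch-corrected by subtracting per-feature least-squares batch
coefficients, with an exact re-centering so per-feature grand means are
unchanged. Batch removal runs before groups exist (the groups are derived
*from* these data), so no group term is protected at this stage; the
synthetic generator assigns batches round-robin, keeping them balanced with
respect to BMI by construction. `remove_batch(preserve =)` is available
when a protected structure is known up front.

## Moderated differential expression

Per feature, OLS on the design `[group means, batch]`; residual variances
are shrunk by empirical Bayes: the marginal distribution of
$\log s_g^2$ is moment-matched through digamma/trigamma identities to
estimate a prior $(d_0, s_0^2)$, and the posterior variance is
$\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$ with moderated t on
$d_0 + d_g$ df. The contrasts are mid−low, high−mid and high−low, plus a
moderated F across the group means; all are BH-adjusted. The
implementation is cross-checked in the tests against the established
empirical-Bayes reference to machine precision, and `d0_override` exposes
the no-shrinkage (0) and full-shrinkage (`Inf`) limits.

Precision weights for the count-level mean–variance trend are deliberately
not implemented: they change efficiency, not the pipeline's structure, and
the moderated model runs directly on normalized log-CPM.

## Competitive gene-set tests

For each set, the mean pairwise correlation $\bar\rho$ of member residual
profiles gives a variance inflation factor
$\mathrm{VIF} = 1 + (m-1)\bar\rho$; the member-vs-rest difference in
moderated t statistics is tested by a two-sample t whose set-mean variance
is inflated by the VIF. Two conventions matter numerically and are exposed
as arguments:

- `df_stat`: when the gene statistics are t's with finite df, they are
  converted to equivalent normal z-scores and the test df is bounded by
  the residual df — without this the p-values are anti-conservative at
  small sample sizes (verified against a 20,000-draw simulation oracle).
- `vif_floor`: the default floor of 1 truncates negative correlation
  estimates and makes the null slightly conservative; setting
  `vif_floor = 0` yields p-values that are uniform under the null to
  Kolmogorov–Smirnov precision at 5,000 sets.
- `fixed_cor`: a known inter-gene correlation can be supplied instead of
  estimating it per set (then the classical $G-2$ df applies).

$\bar\rho$ is truncated below at $-1/(m-1)$ so the VIF is nonnegative.

## Correlation-network modules and eigengenes

On the features most variable across groups (overall-F p below `p_cut`),
the unsigned adjacency $a_{ij} = |\mathrm{cor}(x_i, x_j)|^\beta$ uses the
smallest power $\beta$ whose connectivity distribution reaches a signed
scale-free fit $R^2$ of `r2_target` (default 0.8, powers 1–20). The
topological overlap
$\mathrm{TOM}_{ij} = (\sum_u a_{iu}a_{uj} + a_{ij}) /
(\min(k_i, k_j) + 1 - a_{ij})$
credits shared neighbours; modules are found by average-linkage clustering
of $1-\mathrm{TOM}$ with a *static* tree cut (height 0.25, minimum size
10 by default). A static cut is deterministic and fully testable; it is an
acknowledged simplification of the dynamic tree cut used by the canonical
network package, and the cut height should be raised (e.g. to 0.6 on
block-structured data) when modules are weakly separated. Clusters below
the minimum size fold into `grey` (unassigned), whose only normative
meaning is "not in any module".

A module's eigengene is the unit-norm first principal component of its
standardized member submatrix, sign-oriented so the mean correlation with
members is nonnegative. Eigengenes are then tested against BMI three ways:
Pearson correlation (BH across modules), the two-segment biphasic fit, and
one-way ANOVA across the BMI groups. Module membership is tested for
over-representation in user-supplied gene sets by upper-tail
hypergeometric p-values.

## Metabolite panel analysis

Preprocessing follows targeted-metabolomics convention: metabolites
missing in more than 20% of samples are dropped; constant rows and rows
with relative standard deviation above 3.0 on the raw scale are dropped
(the RSD cutoff is a named convention — the filter is standard, the value
is exposed in the config); remaining missing cells are imputed with half
the metabolite's observed minimum; intensities are log2-transformed, and
Pareto scaling ($x \mapsto (x - \bar x)/\sqrt{s}$) is applied only for
PLS-DA. Half-minimum imputation is a left-censoring convention; on truly
MCAR missingness it biases imputed cells low and measurably attenuates
group contrasts (in simulation, 5% missingness costs roughly ten points of
power at a 1.2-log2 planted shift), which is why the power guarantees
quoted below are stated for complete data.

PLS-DA is NIPALS with a one-hot class matrix and per-component deflation;
VIP scores satisfy $\sum_j \mathrm{VIP}_j^2 = p$ exactly (checked to 1e-8
on every model, and against the reference multivariate implementation to
machine precision), and classification accuracy is estimated by stratified
k-fold cross-validation. Pairwise group contrasts report the equal-variance
two-sample t on log intensities, the fold change as a ratio of geometric
means with the *higher-BMI group in the numerator* (so positive log2 fold
change always means higher expression at higher BMI), and the VIP from a
two-group PLS-DA on the pair; a metabolite is *differential* when VIP > 1
and p < 0.05. VIP is computed per pairwise model rather than from a single
three-group model because the reported contrasts are pairwise.

One sign convention deserves a note: in the source data underlying this
design, the text and the contrast table disagree on the direction of the
α-ketoglutarate difference; this package follows the table's convention
(fold change with the higher-BMI group in the numerator, so a ratio below
1 means the metabolite is higher at lower BMI).

## Transcript–metabolite integration

A two-block PLS in canonical mode (each block deflated on its own scores)
links the standardized transcript and metabolite blocks; the similarity
between transcript $j$ and metabolite $k$ is
$s_{jk} = \sum_h \mathrm{cor}(x_j, t_h)\,\mathrm{cor}(y_k, u_h)$, clipped
to $[-1, 1]$. Edges with $|s| \ge$ `threshold` (default 0.7, the display
convention of canonical multi-omics network tools) form a bipartite relevance
network exportable as SIF and GraphML with weight, biotype and
fold-change attributes. The post-hoc threshold approximates the sparse
variant of such models; penalized weight selection is out of scope.
Note that $s$ is a product of two sample correlations, so even a
metabolite identical to a transcript scores slightly below 1 at finite
sample size (about 0.92 at n = 60); thresholds near 1 are only meaningful
with hundreds of samples.

## The synthetic study generator

`default_fixture()` generates the complete study the tests and the
acceptance script run on, emulating the cohort structure the pipeline
assumes:

- 53 samples, BMI from a truncated normal (mean 29, sd 4.5, range 18–45 —
  peaking near 28–29), two round-robin sequencing batches with additive
  per-feature log2 offsets (sd 0.3);
- 2,000 transcript features: 60 biphasic (breakpoints from
  Normal(28.5, 2) truncated to [22, 35], half u and half n, segment slopes
  drawn uniformly from 0.08–0.15 log2 per BMI unit, extra observation
  noise 0.1 log2), 100 monotone (slopes 0.05–0.12), the rest null;
  negative-binomial counts with gene-wise dispersion log-normal around
  0.05 (realistic bulk RNA-seq overdispersion), baselines uniform on 2–9
  log2 CPM, per-sample library sizes log-normal around 5 million with 20%
  CV;
- a 144-metabolite log-normal panel with eight acylcarnitine-like upshifts
  (0.7–1.2 log2) in the BMI > 32 stratum and one α-ketoglutarate-like
  metabolite elevated (0.541 log2) below BMI 25, plus 5% MCAR missingness.

The biphasic mean function is a continuous hinge (two linear segments
meeting at the breakpoint), so the planted extremum is well defined. Slope
magnitudes, baselines and library sizes are this package's one-time
choices of realistic values — no public dataset reports them for this
design, so they are conventions, not calibrations. What the generator does
*not* emulate: transcript-length effects (the pipeline starts from a
gene-level count matrix, so length-scaled TPM is replaced by CPM),
mean–variance trends beyond the NB dispersion model, missingness that
depends on abundance (MCAR only), cell-type composition differences
between biopsies, and sample outliers. Passing tests therefore demonstrate
the statistical machinery recovers structure it models, not that every
property of real myocardial data is captured.

## Numerical and testing choices

- Degenerate inputs (too few points, constant response) return
  `shape = "none"` with p = 1 rather than an error, so genome-wide scans
  never abort on an edge case.
- Splits with tied covariate values are skipped so the breakpoint always
  strictly separates the arms; the trigamma inverse is solved by Newton
  iteration to 1e-10 relative precision.
- Test problem sizes: the fixture scan uses the full 2,000 × 53 study;
  null calibration uses 5,000 features; the set-test oracle uses 20,000
  simulation draws; metabolite power uses 200 replicates. These sizes keep
  the whole suite to a few minutes on one core while leaving Monte-Carlo
  error well below the asserted margins.

## Known limitations

- With raw per-arm significance calling, FDP among biphasic calls is high
  when true effects are rare (see above); use `q_value` for FDR-gated
  calls.
- The greedy breakpoint climb can stall at a local optimum when the pilot
  parabola lands far from the true bend (asymmetric slopes skew the
  parabola's vertex toward the shallow arm); exhaustive mode trades this
  for a higher false-call rate.
- Half-minimum imputation attenuates contrasts under MCAR missingness.
- The static tree cut requires a sensible cut height for the correlation
  scale of the data; there is no automatic selection.
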