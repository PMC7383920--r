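---
title: "Methods: metabolome quantitative genetics in RIL populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metabolome quantitative genetics in RIL populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaboqtl)
```

`metaboqtl` implements a complete metabolite-QTL (mQTL) analysis for
biparental recombinant inbred line (RIL) populations: descriptive trait
genetics, composite interval scanning with permutation thresholds,
replicate consolidation, hotspot calling, mQTL–pQTL colocalization, and
metabolite-based prediction of agronomic traits. This vignette records
the models, the tunable parameters, and the design decisions a
maintainer would want to know about.

## The population and genotype model

A RIL population derives from a biparental cross followed by repeated
selfing; lines are (near-)homozygous mosaics of the two parental
genomes, coded +1 (P1) and −1 (P2) with no heterozygous class.
Between two loci at genetic distance $d$ cM, the per-meiosis
recombination fraction follows Haldane's no-interference map function,
$r = (1 - e^{-2d/100})/2$, and the probability that a RIL switches
parental state is the Haldane–Waddington equilibrium rate
$R = 2r/(1+2r)$, which accounts for recombination accumulating over
the selfing generations. The simulator draws each chromosome as a
two-state Markov chain over the marker grid with switch probability
$R$ between adjacent markers — equivalent, marginally, to
generation-by-generation selfing but far cheaper. Residual F6-level
heterozygosity, segregation distortion, genotyping error and epistasis
are deliberately not modelled.

## Synthetic study conditions

The `"paper"` preset fixes the study conditions: 145 lines, 21
chromosomes of 150 cM, markers every 5 cM, 200 metabolite features
measured in 3 biological replicates, 3 pleiotropic hotspot loci with 25
attached metabolites each, and 17 agronomic traits. The 5 cM marker
spacing was chosen so interval positions between markers carry real
uncertainty (a 1 cM marker grid would reduce interval mapping to
single-marker regression); 200 features rather than the study's 1260
keep a full multi-replicate scan of the genome in the tens of seconds
while preserving every qualitative property being tested (hundreds of
scans, hotspot enrichment, colocalization structure). Problem sizes in
the test-suite calibration experiments (seed counts, permutation
counts) are stated in the tests themselves.

Metabolite $j$ is generated on the log2 scale,
$$y_{ijk} = \mu_j + \textstyle\sum_q a_q x_{iq} + g_i + e_{ijk},$$
with planted-locus genotypes $x_{iq} \in \{+1,-1\}$ sampled from the
Markov bridge between flanking markers, a polygenic line effect $g_i$
filling the heritable variance not claimed by planted QTL, and
replicate noise $e_{ijk}$ scaled so broad-sense heritability hits its
target; abundances are exponentiated ($2^y$) so the pipeline's log2
transform is exercised. Targets: heritabilities are Beta-distributed
with mean 0.6 (clamped to [0.2, 0.95]); background QTL variances are
right-skewed over roughly 1–50%; hotspot attachments add 12–40% loci.
Each planted QTL's *realized* variance share is recorded from the
realized genotypes, so recovery is scored against what was actually
simulated, not the nominal target.

Agronomic traits load on designated metabolites' genetic values
(mediation share 0.45 by default, so a shared locus induces a
trait-side PVE of roughly 20–26% — a clearly detectable pQTL, which is
what the sharing mechanism promises), plus one private QTL and
polygenic background up to a heritability of 0.61. The designated
(metabolite, trait) pairs, with both effect sizes, form the expected
colocalization truth set. The three field "environments" of a real
study are treated as exchangeable biological replicates;
genotype-by-environment interaction is not modelled, so passing tests
say nothing about G×E robustness on real data.

## Descriptive trait statistics

* **CV** is $100 \cdot s/\bar x$ (sample SD, $n-1$) over per-line
  replicate means of *untransformed* abundances.
* **Broad-sense heritability** comes from one-way ANOVA with lines as
  groups: $\sigma^2_g = \max(0, (MS_B - MS_W)/r)$ and
  $H^2 = \sigma^2_g / (\sigma^2_g + MS_W)$, clamped to [0, 1].
  The per-observation ("plot") denominator is the default — replicate
  scatter *is* the environmental phenotypic variance here — with the
  line-mean basis ($MS_W/r$) behind `basis = "line-mean"`. Unbalanced
  replication uses the mean replicate count.
* **Correlations** (Pearson default, Spearman available — both are in
  legitimate use for metabolite heatmaps vs. metabolite–trait networks)
  are computed on pairwise-complete line means with t-approximation
  P-values; pairs with < 4 complete lines are skipped. The network
  keeps raw $P <$ 0.01 edges by default — no multiple-testing
  correction, matching common practice for these display networks; a
  BH option exists.

## The QTL engine

Scanning is Haley–Knott regression on the conditional expectation of
the locus genotype given the nearest flanking marker calls,
$E[x] = 2P(Q{=}P1 \mid \text{flanks}) - 1$, on a 1 cM grid covering
each chromosome end to end. A missing flank is marginalized at the 1/2
prior. The LOD is $\tfrac{n}{2}\log_{10}(RSS_0/RSS_1)$.
Haley–Knott rather than a full EM mixture likelihood is a deliberate
choice: for RIL with modest missingness the two agree to first order,
and least squares is deterministic and testable against closed forms.

Background control follows the inclusive-composite-interval-mapping
idea: cofactors are chosen once per trait by forward–backward stepwise
regression (entry at partial-F $p \le$ PIN = 0.001, removal at
2·PIN, ties broken by lowest p then map order, and a hard stop if more
than $n/2$ markers enter), and the phenotype is adjusted by all
cofactors except those within 10 cM of the scanned position. The
window width is configurable; 10 cM is wide enough that a QTL's own
proxy marker never absorbs the signal being scanned.

Peaks are called per contiguous supra-threshold segment (leftmost grid
point wins on plateaus). The support interval takes the outermost grid
positions within 1.5 LOD of the peak and widens them to the nearest
mapped marker at or beyond each end; this marker-extended interval is
what consolidation and colocalization overlap. PVE is recovered from
the peak likelihood ratio, $100(1 - 10^{-2\,\mathrm{LOD}/n})$, i.e.
against the cofactor-adjusted null; loci above 15% are flagged major.
The pipeline's default threshold is the conventional fixed LOD 2.5;
`permutation_threshold()` (trait shuffles with per-permutation cofactor
reselection, type-1 quantile of the genome-wide maximum) is provided
for principled use and is what the calibration tests exercise.

Replicates are scanned independently and consolidated — groups of
same-trait records with overlapping marker-extended intervals,
supported by ≥ 2 of 3 replicates, are represented by their highest-PVE
member. Grouping chains overlaps on the sorted intervals; a chain can
in principle join records that do not all pairwise overlap, which we
accept for its determinism and simplicity.

Hotspots: the genome is tiled into 10 cM bins anchored at 0
(half-open, last bin truncated and closed; a peak on a boundary goes
right). The permutation null scatters the $n$ observed QTL uniformly
over the $B$ bins — uniform over *bins*, not cM, which is exactly what
the resampling scheme it mirrors does — and the cutoff is the ceiling
of the 0.99 quantile of the per-permutation maximum bin count. The
chi-squared genome-distribution test takes expected counts
proportional to chromosome *genetic* length by default (marker count
as an option); whether a length- or marker-based expectation is the
right null is genuinely open, so both are exposed.

Colocalization is closed-interval intersection of marker-extended
support intervals on the genetic map (touching endpoints count);
physical Mb positions are carried as annotation only. Cross-referencing
marks a pair as a candidate causal link when the metabolite–trait
correlation passes the network threshold.

## Prediction

The metabolite kernel is $K = ZZ^{\top}/m$ on column-standardized,
replicate-averaged log2 abundances. BLUP fits
$y = \mu + u + e,\; u \sim N(0, \sigma^2_u K)$ by REML per training
fold — eigen-decomposition of $K$ plus 1-D optimization of the profile
REML in $\log\delta$, $\delta = \sigma^2_u/\sigma^2_e$ (we use Brent's
method via `optimize()`, which is as deterministic as the
grid-plus-Newton alternative and simpler) — and predicts held-out
lines by the conditional expectation
$\hat u_{\text{test}} = \delta K_{\text{te,tr}}(\delta K_{\text{tr}} +
I)^{-1}(y_{\text{tr}} - \hat\mu)$. BLUP at a fixed $\delta$ is
algebraically ridge regression on $Z$ with penalty $m/\delta$, which
the tests verify to 1e-6. LASSO uses `glmnet` with the penalty chosen
by inner 5-fold CV on training lines only (lambda-min default,
lambda-1se optional); reported features come from a final inner-CV fit
on all lines.

**Predictability** is the Pearson correlation between observations and
out-of-fold predictions, averaged over folds. We examined the
alternative — one correlation over the pooled prediction vector — and
found it biased to roughly −0.25 for signal-free traits at these fold
sizes (each prediction embeds its training-fold mean, which
anti-correlates with the held-out values), and still around −0.1 after
per-fold mean alignment. Since a predictability estimate should be 0
for a trait with no signal, the fold-averaged form is the default;
pooled is available via `pooling = "pooled"` and is used automatically
for leave-one-out, where within-fold correlations do not exist.
Constant predictions (e.g. an all-zero LASSO path) are flagged and
reported as 0. Post-selection feature P-values are a plain OLS refit
of the selected set, labelled nominal — the same data chose the
features, and no selective-inference correction is attempted.

## Numerical conventions and degenerate inputs

Genetic coordinates are 0-based cM per chromosome with closed
intervals. Genotype files accept A/B, 1/−1 and 0/2 dialects; markers
or lines with more than 10% missing calls are dropped with a warning.
Monomorphic scan regions get LOD 0 and a flag. Singular kernels are
ridge-jittered at 1e-8. Zero abundances under the half-min log policy
take half the trait's minimum positive value. Quantiles of permutation
distributions use type-1 (order statistic) so thresholds are values
actually attained. All randomness flows from one master seed through
fixed per-stage substreams, so any stage can be rerun in isolation.

## Known limitations

Equivalence to any particular interval-mapping implementation is not
claimed — only internal calibration (null false-positive rates at
nominal level) and parameter recovery on data of known architecture.
The synthetic preset's marker density (5 cM) is far sparser than a
SNP-array map; support intervals on real dense maps will be narrower
and consolidation correspondingly stricter. Replicate exchangeability
stands in for multi-environment structure. Prediction results on the
preset quantify the mediated traits only; traits whose genetics bypass
the metabolome are (correctly) near-unpredictable from it.
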