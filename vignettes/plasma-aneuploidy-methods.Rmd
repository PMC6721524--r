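---
title: "Methods: arm-level aneuploidy scoring and tumor-fraction estimation in plasma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: arm-level aneuploidy scoring and tumor-fraction estimation in plasma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmaZ)
```

This vignette is the package's own account of its models, conventions and
design choices: what is computed, under which assumptions, which defaults
matter, and what the synthetic-data studies do and do not demonstrate.

## 1. The aneuploidy score

Somatic copy-number alterations (SCNAs) in tumor cells shift the share of
plasma cfDNA fragments mapping to each chromosome arm in proportion to the
tumor fraction. For a sample with arm read fractions $x_a$ over the 39
autosomal arms (acrocentric short arms and sex chromosomes excluded) and a
panel of healthy controls with per-arm mean $\mu_a$ and standard deviation
$\sigma_a$ (denominator $n-1$), the package computes

$$z_a = \frac{x_a - \mu_a}{\sigma_a}, \qquad
  S = \sum_a z_a^2, \qquad
  Z = \frac{S - \mu_S}{\sigma_S}.$$

$S$ alone is non-negative, but observed genome-wide scores of healthy-like
samples can fall *below* a typical control. The package therefore treats
$S$ as a raw statistic and standardizes it against the control panel's own
distribution of $S$: each control's $S$ is computed **leave-one-out**
(its $z_a$ taken against the panel of the remaining $n-1$ controls, so no
control is compared against statistics that include itself), and $\mu_S,
\sigma_S$ are the mean and sd of those $n$ values. $Z$ is then centred
near 0 with unit scale on controls and may be negative. A sample is called
ctDNA-positive when $Z \ge 3$, with the boundary counting as positive.

Two conventions are isolated behind single functions and documented here
because the assay's original description leaves them open:

* normalization is the **total-count fraction** (`normalize_to_fractions`);
  any per-arm rescaling would belong there;
* no arms are excluded for germline copy-number variation; the catalog is
  user-replaceable (`make_arm_catalog`) if a different arm set is wanted.

Scores are invariant under scaling a sample's counts by any positive
constant, and the leave-one-out construction keeps control scores
calibrated (mean near 0, sd near 1), which the tests verify on freshly
simulated panels.

## 2. The tumor-fraction estimator

The estimator is a deliberately simple, fully deterministic replacement
for HMM-based callers, built to reproduce the *relationship* between the
aneuploidy score and tumor fraction on synthetic data rather than any
specific caller's output.

**Segmentation.** Within each arm, a one-pass greedy scan merges a bin
into the open segment while its value differs from the segment's running
mean by less than `min_gap` (default 0.1 in log2 units; use about three
times the bin noise sd). A post-pass absorbs segments shorter than
`min_seg_bins = 3` into the neighbour with the closer mean. Without this
runt merge, isolated noise bins survive as one-bin segments and the fit
stage can chase them: small tumor-fraction candidates offer a denser set
of predicted levels, so spurious segments systematically pull the
estimate down or toward half its value.

**Fit.** For each tumor fraction $t$ on a grid (step 0.01 over
$[0, 0.95]$), each segment takes the copy state $c \in \{0,\dots,6\}$
minimizing the squared deviation of its mean from the mixture prediction
$\log_2\!\big((2 + t(c-2))/2\big)$, and the objective is

$$\sum_{\text{seg}} n_{\text{seg}}\,r_{\text{seg}}^2(t)
  \;+\; \lambda \sum_{\text{seg}} n_{\text{seg}}\,|c_{\text{seg}} - 2|,$$

with the smallest $t$ winning ties. The **graded** penalty $|c-2|$ (rather
than a flat non-diploid indicator) is essential: a profile of single-copy
gains at $t$ fits the data exactly at $t/2$ with double gains, at $t/4$
with quadruple gains, and so on; these exact-fit alternatives carry the
same flat penalty but a larger graded one, so the graded penalty resolves
the family toward states near diploid and the largest consistent tumor
fraction. The converse ambiguity is fundamental: a profile consisting
*only* of even states ($c \in \{0,4\}$) at $t$ produces data identical to
an odd-state profile at $2t$, and no estimator can tell them apart. The
synthetic profile generator therefore favours single-copy events
(state weights 0.35/0.35/0.2/0.1 for $c = 1/3/4/0$), which is also the
realistic arm-level pattern; all-even profiles become vanishingly rare.

**Choice of $\lambda$.** Calling a truly altered segment diploid costs its
squared log2 shift, about $(t/2.77)^2$ for a single-copy gain at tumor
fraction $t$; the penalty must stay below that for every alteration worth
detecting. The default $\lambda = 3\times10^{-4}$ resolves single-copy
events down to $t \approx 0.05$ while still breaking the exact-fit
degeneracies above. A much larger penalty silently absorbs low-burden
samples into the neutral state.

With these defaults, noise-free recovery is exact on the grid, and at bin
noise sd 0.05 with 50 bins per arm the root-mean-square error over
replicate cohorts is well below 0.01.

**Few-arm attenuation.** Because $Z$ aggregates over all 39 arms, a tumor
altering only one or two arms produces a modest $Z$ even at a high tumor
fraction, while the segment-based estimator remains accurate. The package
reproduces this asymmetry: adding few-arm samples to a cohort lowers the
$Z$-versus-$\hat{t}$ linear fit, and removing them restores it
(`concordance_analysis`).

## 3. The synthetic-data generator

The generator produces every input the pipeline consumes, with ground
truth attached. What it emulates, and the defaults that matter:

* **Control panels** — `n_controls = 18` samples at `read_depth = 1e5`
  reads, Dirichlet-multinomial with concentration $\theta$. The Dirichlet
  fraction variance is $w(1-w)/(\theta+1)$; the default
  $\theta = 4\times10^4$ gives a per-arm fraction CV of roughly 3%,
  between pure multinomial noise and the heavier between-library
  variability of amplicon assays. No public value pins this down; it is a
  package choice, exposed in `sim_config`.
* **Arm weights** — proportional to approximate GRCh37 arm lengths
  (packaged table, user-overridable). Real amplicon densities differ per
  arm; only relative weight stability between samples matters for the
  score.
* **Tumor samples** — arm fractions from the diploid/tumor mixture
  $w_a\,((1-t)\cdot 2 + t\,c_a)/2$, renormalized; counts
  Dirichlet-multinomial.
* **Binned log2 ratios** — per-bin mean $\log_2(((1-t)2 + t\,c)/2)$ plus
  Gaussian noise (default sd 0.05, 25 bins/arm; the recovery studies use
  50), a stand-in for shallow whole-genome coverage tracks. GC and
  mappability artefacts are *not* modelled.
* **Longitudinal cohorts** — per patient: a baseline tumor fraction, a
  random SCNA profile (8–16 altered arms by default), responder status,
  and samples at baseline / during treatment / at progression with tumor
  fraction multipliers U(0.05, 0.3) for responders, U(0.8, 1.5) for
  non-responders and U(1.2, 3.0) at progression — so mean true tumor
  fraction orders progression > baseline ≥ treatment by construction.
* **Baseline tumor-fraction mixture** — 45% ctDNA-negative spike (near 0),
  a main lognormal component centred near the tumor fraction whose
  genome-wide score sits at the clinical cutoff, and a 15%-of-positives
  high-burden tail U(0.25, 0.7). This places cohort baseline positivity
  near one third — the regime reported for treated metastatic breast
  cancer — keeps a realistic spread of extreme scores, and, importantly,
  populates the score region around the candidate cutoffs so that the
  cutoff-scan analysis is informative. A distribution with all positives
  far above every cutoff makes the four candidate groupings nearly
  identical and cutoff selection arbitrary.
* **Survival** — exponential progression-free survival with hazard
  $h_0\,\mathrm{HR}^{\mathbf{1}[Z \ge 3]}$ (default HR 3, low-group PFS
  median 14 months), overall survival as progression time plus an
  independent exponential increment under the same group effect (so
  OS ≥ PFS entry-wise when both events occur), and uniform administrative
  censoring on [0, 120] months. The hazard group uses the *measured*
  baseline score against the simulated panel, exactly the quantity the
  downstream scan stratifies on. The low-group OS median (30 months) and
  the horizon favour adequate event counts over mimicking any specific
  follow-up pattern.
* **Co-biomarkers** — CTC counts (zero-inflated negative binomial, 45%
  structural zeros), CEA and CA15-3 (lognormal), coupled to the true
  tumor fraction through a Gaussian copula. Spearman targets are
  converted to latent Pearson correlations via
  $r = 2\sin(\pi\rho/6)$, the matrix is checked for positive
  semidefiniteness, and the first latent coordinate is rank-matched to
  the already-drawn tumor fractions. Discreteness of CTC counts
  attenuates its rank correlations slightly; targets are recovered within
  about ±0.05 at large n. Default targets (0.02, 0.26, 0.25, 0.01, 0.30,
  0.41) follow the correlation structure reported for this marker set.

All draws flow from one master seed; cohort objects and run manifests
record it. What the generator does **not** emulate: fragment-level
biology (size distributions, GC bias), amplicon dropout, germline CNVs,
subclonal or non-integer copy states, and inter-arm correlation of
alterations. Tests passing on this generator show the *statistical
machinery* behaves as designed; they cannot certify performance on real
sequencing data.

## 4. Clinical statistics conventions

* **Kaplan–Meier** — product-limit; events before censorings at tied
  times; the median is the smallest $t$ with $S(t) \le 0.5$ (computed
  directly, avoiding the interval-midpoint convention some software uses
  when the curve sits exactly at 0.5); "not reached" propagates as `NA`.
  Median follow-up uses the reverse Kaplan–Meier method (event and
  censoring flags swapped).
* **Log-rank** — two groups, hypergeometric variance, $\chi^2_1$ p-value.
  A group with zero events is computed but flagged.
* **Cutoff scan** — candidate cutoffs {2, 3, 4, 5} on the baseline
  genome-wide score; a cutoff leaving fewer than two patients in a group
  is skipped with a reason; the selected cutoff minimizes the OS log-rank
  p (ties to the smaller cutoff). Because selection minimizes over
  candidates, the selected p-value is optimistic; the scan table is
  always reported in full, and under a null hazard ratio the scan's
  type-I error exceeds the nominal level — this multiplicity is inherent
  to the procedure and disclosed rather than corrected.
* **Cox regression** — partial likelihood with Efron tie handling
  (Breslow available), Wald inference; monotone likelihood is detected
  and the affected intervals reported as unbounded.
* **Linear mixed model** — $Z_{ij} = \beta_{\mathrm{cat}(ij)} + u_i +
  \varepsilon_{ij}$ with patient random intercepts, independent
  variance-covariance structure, **maximum likelihood** (not REML)
  estimation via `nlme`, Wald tests for the overall category effect and
  the pairwise contrasts (progression vs treatment, baseline vs
  treatment), and model-based standard errors. Samples taken after a
  patient's first progression sample can be excluded with a documented
  flag, restricting the monitoring analysis to the disease course up to
  progression. A boundary estimate ($\hat\tau^2 \approx 0$) is flagged;
  fixing $\tau^2 = 0$ reproduces ordinary per-category means exactly.
  ML variance components are slightly biased low, so 2-SE coverage of
  the category means runs a little under the nominal 95% per coefficient.
* **Contingency tables** — Pearson chi-square without continuity
  correction when every expected count is ≥ 5, otherwise the exact test:
  direct hypergeometric enumeration for 2×2, Freeman–Halton enumeration
  for r×c (bounded at 12 cells). The two-sided p is the total probability
  of tables with the observed margins no more probable than the observed
  table (float ties within 1e-12 included) — the convention of mainstream
  clinical statistics software, which the tests cross-check against
  `stats::fisher.test` and against published association tables.
* **Spearman matrices** — pairwise-complete, average-rank ties, per-pair
  n, significance from the t approximation.

## 5. Problem sizes and numerical choices

The test suite and the acceptance script run desk-scale studies: 18-control
panels over 20 seeds for score calibration; a 72-sample cohort (60 samples
with 5–20 altered arms plus 12 few-arm samples) for the concordance and
few-arm analyses; 50 replicates at 50 bins/arm for estimator recovery;
50 simulated 30-patient cohorts for mixed-model recovery; and 25
100-patient cohorts for the end-to-end cutoff scan. These sizes give
stable statistics while keeping a full run in minutes. Stochastic checks
declare fixed seed sets; the cutoff-scan selection probability under the
default conditions is about 0.86 — selection among four highly correlated
log-rank statistics retains irreducible noise even at strong signal, so
the declared-seed study documents a property that a single arbitrary seed
could misrepresent in either direction.

Degenerate inputs are rejected with named errors rather than propagated:
zero-total samples, constant arms in a panel, constant covariates,
single-patient mixed models, inconsistent overlap counts, overlapping
bins. Ties are broken deterministically everywhere (smallest tumor
fraction; smaller cutoff; first minimum), so identical seeds give
byte-identical outputs, which the manifest checksums in
`run_end_to_end` make visible.

## 6. Known limitations

* The tumor-fraction estimator is a methodological stand-in: no ploidy or
  subclonality modelling, no GC/mappability correction, integer arm-level
  states only. Its numbers are not comparable to any specific published
  caller, only its correlation structure.
* The even-state ambiguity above means tumor fraction is not identifiable
  from ratio data alone for profiles without single-copy events; the
  estimator then prefers the near-diploid interpretation.
* The survival generator uses exponential hazards with a single
  multiplicative group effect; no competing risks, no time-dependent
  effects.
* The scan's selected cutoff and p-value are reported with their
  selection bias disclosed, not corrected; the package deliberately
  applies no multiple-testing adjustment anywhere, matching the analysis
  conventions it reproduces.
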