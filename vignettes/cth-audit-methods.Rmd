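---
title: "Auditing blood methylation clocks for cell-type confounding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing blood methylation clocks for cell-type confounding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Whole blood is a mixture of immune cell types, each with its own methylome.
Any quantity computed from a bulk blood beta-value matrix — a per-CpG
association, a linear "clock", a signature score — therefore confounds two
very different signal sources: methylation changes *within* cell types, and
shifts in the *proportions* of cell types. Inflammatory conditions shift
composition strongly (acutely, a higher neutrophil-to-lymphocyte ratio;
chronically, an expansion of memory lymphocyte subsets at the expense of
naive ones), so an instrument advertised as measuring "inflammaging" may in
fact be a roundabout estimator of cell composition.

`cthaudit` packages the analysis chain needed to make that distinction
explicit, and a simulator with known ground truth on which every link of the
chain can be validated:

1. reference-based deconvolution of 12 immune cell-type fractions;
2. rectified linear clocks and extrinsic age acceleration (EAA);
3. a signed-signature inflammation score on z-scored methylomes;
4. EWAS with and without fraction adjustment;
5. per-cohort association models pooled by inverse-variance meta-analysis;
6. multivariate-vs-univariate coefficient sign concordance.

# The mixture model and deconvolution

The observed beta value of CpG $j$ in sample $i$ is modelled as a convex
mixture over $K$ cell types,

$$x_{ji} = \sum_{k=1}^{K} B_{jk}\, w_{ik} + \varepsilon_{ji},
\qquad w_{ik}\ge 0,\ \sum_k w_{ik} \le 1,$$

where $B$ is the reference panel of cell-type methylomes over marker CpGs
and $w_i$ the sample's cell-type proportions. Two estimators are provided.

**Constrained least squares (CLS)** solves the quadratic program per sample
($w \ge 0$ with the sum constrained to 1 or at most 1). Internally the sum
constraint is appended to the least-squares system as a heavily weighted
row ($M = 10^3$), with a non-negative slack variable for the inequality
form, and the resulting non-negative least-squares problem is solved by the
Lawson–Hanson active-set method. For a consistent (noise-free) system the
penalty row is satisfied exactly at the optimum; otherwise the violation is
$O(M^{-2})$, far below the reporting precision of fractions. A second
active-set implementation with a generous iteration budget backs up the
library routine, whose fixed iteration cap can trip on the augmented
system. Correctness is pinned by oracle tests (grid search over the
feasible simplex, exact recovery of convex combinations), not by solver
identity.

**Robust partial correlations (RPC)**, the default, fits a Huber
M-estimator regression (IRLS, tuning constant 1.345 — the classical 95%
Gaussian-efficiency value — MAD scale, up to 500 iterations) of the sample
profile on the reference, truncates negative coefficients to zero and
renormalizes to proportions. Robust weighting down-weights CpGs that
deviate from the mixture model (outliers, disease effects confined to one
cell type), which plain least squares spreads across all coefficients. On
clean mixtures the two estimators agree to $10^{-4}$; under 5% corrupted
markers RPC's error is reliably smaller — both properties are test-pinned.
A sample whose robust coefficients are all non-positive is flagged as a
failure (all-`NA` row) rather than forced onto the simplex.

# Clocks, rectification and EAA

A clock is a linear predictor $\hat a_i = c_0 + \sum_j c_j \tilde\beta_{ji}$
over its CpGs. Rectified inflammation clocks keep all $c_j > 0$ and instead
flip CpGs whose methylation moves *against* the age direction under
inflammation: flagged CpGs enter as $\tilde\beta = 1 - \beta$. Rectification
is an involution (applying it twice is the identity), which the tests
exploit.

Extrinsic age acceleration is the residual of an OLS fit of clock age on
chronological age. Two properties follow by construction and are asserted
to $10^{-10}$: residuals sum to zero and are uncorrelated with age. EAA is
fitted **per cohort**: pooling cohorts would let additive batch offsets
masquerade as age acceleration, exactly the cohort-of-origin confounding
the audit is designed to expose.

# The inflammation score

Given a signature of CpGs with effect signs $s_j \in \{-1,+1\}$ (e.g. the
direction of association with serum C-reactive protein), each cohort's
beta matrix is z-scored per CpG (mean 0, sample standard deviation 1 with
the $n-1$ denominator; zero-variance CpGs are dropped and reported), and a
sample's score is the **Pearson** correlation between its z-vector and the
sign vector over the shared CpGs. Pearson rather than a rank correlation is
the natural reading of correlating a z-scored profile with a $\pm 1$
vector, and is pinned in tests; the score is invariant to any per-CpG
affine rescaling of the raw betas, since z-scoring absorbs it. Signs only
(not effect magnitudes) weight the score.

# EWAS and fraction adjustment

Per CpG, OLS of beta on the phenotype plus covariates; two-sided p from the
t distribution with residual degrees of freedom; Bonferroni threshold
$\alpha/m$ over the $m$ CpGs tested (no FDR option — the family-wise rule
is the one the audit's claims are phrased in). When adjusting for
composition, the fraction matrix enters as covariates with one cell type
dropped — by default the most abundant (neutrophils in blood) — because the
fractions sum to one and a full set would be collinear. The choice of
dropped type is configurable and does not affect the other terms'
condition-effect inference.

# Association models and meta-analysis

Associations between a score (EAA or inflammation score) and cell-type
fractions are fitted **one cell type at a time** (`score ~ fraction +
covariates`): forest plots report one effect per cell type, and a joint
model of all 12 fractions would be rank-deficient on the simplex. EAA
models adjust for sex; inflammation-score models adjust for age and sex.

Per-cohort effects are pooled by classical inverse-variance meta-analysis:
fixed-effect weights $1/\mathrm{se}^2$; DerSimonian–Laird
$\tau^2 = \max\!\big(0, (Q - df)/(\sum w - \sum w^2 / \sum w)\big)$ with
random-effect weights $1/(\mathrm{se}^2+\tau^2)$; Cochran $Q$, $df = k-1$,
$I^2 = \max(0, (Q-df)/Q)\cdot 100$. Confidence intervals and p-values use
normal quantiles (no Knapp–Hartung adjustment), the classical
inverse-variance default. The formulas are implemented directly and are
verified in the test suite both against a literal transcription of the
formulas (to $10^{-12}$ over randomized inputs) and against
`metafor::rma`'s FE and DL estimators.

# Concordance analysis

A penalized multivariate predictor (elastic net, objective
$\frac{1}{2n}\,\mathrm{loss} + \lambda(\alpha\|\beta\|_1 +
\frac{1-\alpha}{2}\|\beta\|_2^2)$) selects CpGs whose coefficient signs are
compared with their univariate regression coefficients: a 2×2 sign table
(zero multivariate coefficients excluded first, zero univariate
coefficients carrying no sign excluded from the table), a one-tailed Fisher
exact p (upper hypergeometric tail of the concordant cell), and the Pearson
correlation between the coefficient vectors. The elastic net is solved by
`glmnet` along a decreasing path ending at the requested $\lambda$; the
unpenalized limit $\lambda = 0$ is computed exactly by OLS / unpenalized
logistic regression rather than asking a path solver for its boundary.
Analytic anchors are test-pinned: $\lambda = 0$ equals OLS to $10^{-8}$,
and the one-dimensional lasso reproduces the soft-threshold closed form
($S(2.0, 0.5) = 1.5$ for a standardized predictor).

# The synthetic-data generator

`simulate_cohort()` draws, per sample: age $\sim U(20, 80)$ years (an adult
whole-blood cohort range), sex $\sim$ Bernoulli(0.5), a balanced
deterministic case/control split, and fractions $w_i \sim
\mathrm{Dirichlet}(\alpha_i)$. The baseline $\alpha$ is blood-like —
weights Neu 55, Mono 8, CD4Tnv 7, CD4Tmem 6, NK 5, CD8Tnv 4, CD8Tmem 4,
Eos 3, Bnv 3, Bmem 2, Treg 2, Baso 1, scaled to a total concentration
$c_0 = 30$. With $c_0 = 30$ the neutrophil fraction has standard deviation
$\sqrt{0.55 \cdot 0.45 / 31} \approx 0.09$, matching the sample-to-sample
spread seen in real adult whole-blood cohorts; larger $c_0$ would make
cohorts unrealistically homogeneous.

Two regimes tilt the concentrations:

* **acute** — the neutrophil $\alpha$ is multiplied by 1.6 in cases,
  raising the mean neutrophil fraction from ~0.55 to ~0.66 and depressing
  every other fraction through renormalization — the acute
  neutrophilia/lymphopenia pattern of conditions like rheumatoid
  arthritis;
* **inflammaging** — memory subsets and NK scale by
  $e^{+\gamma\,\mathrm{age}}$ and naive subsets by
  $e^{-\gamma\,\mathrm{age}}$ with $\gamma = 0.02$/year. The literature
  does not quantify this tilt; $\gamma$ was chosen once so that the
  memory/naive shift is detectable at cohort sizes of a few hundred, and
  the generator's monotonicity in $\gamma$ is itself a test.

The observed matrix is the mixture $B w$ plus an additive per-CpG,
per-cohort batch offset $\sim N(0, 0.01^2)$ (the simplest confounder
reproducing cohort-of-origin effects), plus measurement noise
$\sim N(0, 0.02^2)$, clipped to $[0.001, 0.999]$ — the clip bounds avoid
degenerate logit transforms downstream. Optional planted DMCs add
`slope × age` or `slope × case` to the target cell type's reference value
(or all types for `"global"`) *before* mixing, so a DMC's bulk effect is
attenuated by that cell type's fraction, as in real data. Reference panels
are generated with, per cell type, marker CpGs near 0.1 in their own type
and near 0.85 elsewhere (half with reversed polarity), plus background
CpGs identical across cell types — carrying no composition signal, they
serve as true nulls. All draws flow from one seed in a fixed order, so
cohorts are bit-reproducible.

What the simulator does **not** emulate: probe-chemistry artifacts
(type I/II bias), SNP-affected probes, sex-chromosome effects, clonal
hematopoiesis, and real marker panels' imperfect specificity. Passing
tests therefore demonstrate the *statistical mechanics* of composition
confounding and its repair, not preprocessing robustness on array data.

# Validation sizes and the confounding demonstration

The pipeline-level checks use sizes a desk machine handles in minutes:
deconvolution recovery on 100 mixtures over 600 markers (noise-free CLS
recovery to $10^{-6}$; per-cell-type RMSE under 0.02 at noise 0.02); the
clock/score dissociation on 5 cohorts of 300 samples per regime; the
fraction-adjustment type-I check on one cohort of 400 samples with 2000
null CpGs.

The confounding-*inflation* demonstration (unadjusted EWAS flagging the
majority of marker CpGs) is sized at one cohort of 2000 samples — the
scale of the largest cohort the simulator emulates. The reason is a power
calculation, not convenience: for a non-neutrophil type with mean fraction
$p_k$, the acute shift moves its fraction by about $0.25\,p_k$, while the
between-sample composition noise contributes $\sqrt{p_k(1-p_k)/31}$ to
each of its markers' residuals. At $n = 400$ only markers of abundant
types clear a Bonferroni bar over ~2600 CpGs (about 28% of markers flag);
at $n = 2000$, markers of the nine most abundant types have power and
about two thirds flag — the "majority of DMCs are composition" picture.
The type-I clause is still evaluated at $n = 400$, where adjustment for
the true fractions returns the null CpGs' rejection rate at $p<0.05$ to
the nominal band.

# Degenerate inputs and numerical conventions

* Missing clock/signature CpGs: `strict` alignment errors; `impute_mean`
  fills 0.5 (the maximally uninformative beta) and reports coverage,
  warning below 80%.
* p-values are floored at $10^{-300}$ so $-\log_{10} p$ displays stay
  finite.
* Composition ratios floor the denominator at $10^{-6}$.
* Zero-variance rows (z-scoring) and zero-variance sample z-vectors
  (scoring) are dropped/`NA` with a report, never silently imputed.
* Sex is coded 0/1 (`F`→0, `M`→1 on read); ids are case-sensitive and
  never normalized.

# Limitations

The audit is immune-centric: it treats composition as the confounder and
within-cell-type methylation as the signal, and cannot speak to systemic
processes (senescence burden, metabolic change) invisible to both. The RPC
contract here is pinned by oracle properties, not bit-compatibility with
any particular published implementation. Real reference panels are built
from sorted-cell data with their own error structure; panel construction
is out of scope.
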