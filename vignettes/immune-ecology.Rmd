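---
title: "Methods: the ecology of immune state in wild house mice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the ecology of immune state in wild house mice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

ecoimmune implements, as one tested toolchain, the chain of analyses used
to characterise the immune state of wild house mouse (*Mus musculus
domesticus*) populations and to ask what drives it: condition and age
indices, a PCA-based immunological distance with its population
structure, SNP-based population genetics, matrix-correlation tests, and
latent-variable structural equation models (SEM). This vignette is the
package's own account of each method, its assumptions, the tunable
parameters, and the design decisions taken where the method left room.

## Condition and age indices

**Scaled mass index (SMI).** Body condition is body mass standardized to
the population's mean body length $L_0$ through the allometric exponent
$b$ of the mass–length power law,

$$\mathrm{SMI}_i = m_i \left(\frac{L_0}{\ell_i}\right)^{b}, \qquad
  b = \operatorname{sign}(r)\,\frac{s_{\ln m}}{s_{\ln \ell}},$$

with $b$ the standardized major axis (SMA) slope of $\ln m$ on
$\ln \ell$ — the symmetric regression appropriate when both axes carry
error. `compute_smi()` fits $b$ and $L_0$ per group; the default
grouping is sex, the natural reading of "the population under study"
when all downstream models split by sex (per-site grouping is available
via `group =`). Mice missing mass or length receive a missing SMI but do
not abort the group fit. One property of SMA worth keeping in mind: its
slope is a ratio of standard deviations and does not shrink toward zero
when the correlation is weak, so a noisy allometry yields a large
exponent of uncertain sign. This matters for the count scaling below.

**BMI** is mass in kg over squared length in m² (`compute_bmi()`); it
serves as a cross-check on SMI, not as the primary condition measure.

**Splenic cell-count scaling.** Each of the seven cell counts (CD4⁺,
CD8⁺, CD19⁺, NKp46⁺, Ly6G⁺, CD11c⁺, F4/80⁺) is standardized to $L_0$
with the same formula, replacing mass by the count and fitting a
separate SMA exponent per cell type (`scale_cell_counts()`). Zero counts
cannot enter the log–log fit; they are excluded from the exponent
estimation but still scaled with the fitted exponent, so those mice stay
in downstream analyses.

**Power-of-ten rescaling.** `pow10_rescale()` divides a variable by
$10^k$ with integer $k$ chosen so the median of its non-zero values
falls in $[1, 10)$; the rule is idempotent and an all-zero vector is
returned unchanged. It is the convention used before SEM fitting so that
most values sit within 1–10.

**Eye-lens ageing.** Age is estimated from dried eye-lens mass through a
monotone calibration, by default log-linear,
$\text{lens (mg)} = \alpha + \beta \ln(\text{age in days})$, inverted to
give age in weeks. The shipped coefficients
($\alpha = -2.0$, $\beta = 1.8$, support from 14 days) are **provisional
placeholders** spanning a plausible house-mouse lens-growth range; any
species-specific calibration can be supplied via `lens_calibration()`.
Lens masses below the calibration support are flagged as extrapolation
rather than rejected.

## Immunological distance

Ten immune measures (the seven scaled cell counts, serum IgG and IgE,
faecal IgA) enter a **standardized PCA** (`immune_pca()`): correlation-
matrix PCA, because counts and concentrations live on incommensurate
scales. Mice missing any measure are excluded (complete-case analysis)
and the exclusion count is always reported — in the study design one
site lacks faecal IgA entirely, so this number is not decorative. Scores
carry a deterministic sign convention (largest-magnitude loading
positive per component).

The **immunological distance** between two mice is the Euclidean
distance over their first three PC scores (`immune_distance()`). When an
externally computed per-mouse score table is supplied (the layout of the
deposited supplementary scores), the pipeline bypasses its own PCA and
uses those scores directly — that is the reproduction path for published
distances.

`site_distance_summary()` decomposes all $N(N-1)/2$ pairs into
within-site and among-site sets and reports means ± SE per site and
overall. The SE is $s/\sqrt{n_\text{pairs}}$ over pairwise distances,
which ignores the non-independence of pairs sharing a mouse; this
matches the conventional "mean ± 1 SE" presentation and is documented
here as a caveat, not a defensible standard error. Sites with a single
pair report a missing SE. `within_distance_vs_n()` checks that
immunologically diverse sites are not simply the well-sampled ones.
`classical_mds()` (Torgerson double-centering, eigenvectors scaled by
root eigenvalues, negative eigenvalues truncated with a warning) embeds
the among-site matrix for plotting.

## Population genetics

Genotypes are biallelic alt-allele dosages (0/1/2/missing), loci × mice,
with per-individual site labels; letter-pair encodings are auto-detected
and triallelic loci rejected by name.

**Heterozygosities.** Observed $H_o$ and unbiased expected
$H_e = 2\hat p \hat q \cdot 2n/(2n-1)$ per locus, overall or per site
(`locus_stats()`). Per-site analysis is the default posture for
equilibrium testing because pooling strongly differentiated sites
manufactures heterozygote deficits (the Wahlund effect).

**Hardy–Weinberg exact test.** `hwe_exact_mc()` estimates the
conditional exact p-value by a Metropolis chain over heterozygote counts
(the biallelic reduction of genotype-table switch moves), default one
million iterations, with a batch-means Monte-Carlo standard error. The
plain exact p-value of a discrete test is conservative — it has an atom
at 1 — so the function also returns the mid-p and a randomized p-value;
the randomized variant is exactly uniform under equilibrium and is what
the calibration tests check, while the plain exact p is the inferential
default.

**F_ST and F_IS.** `pairwise_fst()` implements the Weir–Cockerham (1984)
variance components $a$ (among sites), $b$ (among individuals within
sites), $c$ (within individuals) and combines loci by ratio of sums,
$\hat\theta = \sum_l a_l / \sum_l (a_l + b_l + c_l)$. Loci monomorphic
across a pair contribute zero components; negative estimates are
reported as computed (truncation, where needed for distance matrices, is
a reporting step). The cohort-level summary is the **unweighted** mean
over all 66 site pairs. `fis()` gives per-site
$1 - \sum_l H_{o,l} / \sum_l H_{e,l}$ and its unweighted site average.

**Individual distance and trees.** Genetic distance between mice is the
allele-difference count: the L1 distance between dosage vectors over
loci typed in both, rescaled to the full panel size so differential
missingness does not shrink distances. ("Nucleotide differences" for
diploid SNPs is ambiguous between dosage-L1 and identity-by-state
mismatch; dosage-L1 is the default and the tree-shape checks are
topological.) Neighbour-joining uses ape; bipartition support comes from
resampling loci with replacement (seeded), rebuilding the tree, and
counting bipartition recovery over replicates.

## Matrix comparisons

`among_site_distance()` averages mouse-level distances over all pairs
spanning two sites. `mantel()` correlates the unique off-diagonal pairs
of two site-level matrices and assesses significance by label
permutation with the add-one convention
$p = (1 + \#\{r^* \ge r\})/(n_\text{perm} + 1)$, so $p > 0$ always. The
default tail is one-sided on positive association — the convention
consistent with reporting large p-values for small positive correlations
— with a two-sided option; for small matrices an exhaustive enumeration
over all relabelings replaces sampling. Because geographic distance is
right-skewed, the comparison is run both on raw distances and on
$\log(d + 1)$, applied element-wise to the geographic matrix only.
`upgma()` builds the average-linkage tree of each matrix (node height =
half the merge distance, so ultrametric inputs are reproduced exactly);
tanglegram layout (crossing minimization) is deliberately out of scope —
the Newick trees are the product.

## The SEM engine

The core of the package is a covariance-based maximum-likelihood SEM
engine with one latent variable per model, written in the RAM
parameterization: with $A$ holding directed coefficients (paths and
loadings), $S_0$ the symmetric (residual and exogenous) covariances and
$F$ the observed-row selector,

$$\Sigma(\theta) = F (I - A)^{-1} S_0 (I - A)^{-\top} F^\top .$$

`fit_ml()` minimizes
$F_{ML} = \ln|\Sigma(\theta)| + \operatorname{tr}(S\Sigma^{-1}(\theta))
- \ln|S| - p$ over complete cases (listwise deletion, n reported), with
$\chi^2 = (n-1) F_{ML}$ at the optimum.

*Model structure.* `default_models()` encodes the three immune-state
models: exogenous Season (day length) and Age with free covariance;
paths Season/Age → Infection, Season/Age/Infection → Condition, and
Season/Age/Condition/Infection → the latent ImmuneState, measured by the
compartment's three (adaptive cellular, humoral) or four (innate
cellular) indicators with the first loading fixed to 1. Infection is
serological and therefore historical, so it may affect Condition but not
the reverse, and no path runs from ImmuneState back to Infection. This
reconstruction is validated structurally by its degrees of freedom: 20
free parameters over 7 observed variables (df = 8) for the 3-indicator
models and 22 over 8 (df = 14) for the innate model, matching the
published fit statistics' df. Arbitrary models can be written in the
`latent =~ i1 + i2`, `y ~ x1 + x2`, `a ~~ b` language of `sem_model()`;
models are checked for acyclicity and counting identification.

*Optimization.* A warm start is assembled from moment-based regressions
on the sample covariance, followed by seeded jittered restarts (default
10) of a bounded quasi-Newton search; the best admissible optimum is
kept and a gradient-norm check flags non-convergence rather than
returning silently. Internally the variables are sd-standardized before
fitting — the $\chi^2$ is exactly invariant to per-variable rescaling
when all variances are free, and the standardized scale keeps the
optimizer well-conditioned across counts (~10⁶) and minutes (~10²) — and
estimates and standard errors are mapped back to the analysis scale
afterwards. Standard errors come from the numeric Hessian of $F_{ML}$:
$\operatorname{cov}(\hat\theta) = \tfrac{2}{n-1} H^{-1}$. The
standardized solution rescales by model-implied standard deviations
(latents included) and is invariant to `pow10_rescale()` of the inputs.

*Fit indices* (`fit_indices()`):
RMSEA $= \sqrt{\max(\chi^2 - df,\,0)/(df\,(n-1))}$ with a 90% CI from
inverting the noncentral-$\chi^2$ CDF (upper-tail probabilities 0.95 and
0.05, lower bound truncated at 0; df = 0 degenerates to 0); CFI against
the independence baseline
$\chi^2_b = -(n-1)\ln|R|$ with $df_b = p(p-1)/2$; SRMR as the root mean
square of correlation-scale covariance residuals over the unique
moments. `acceptance_report()` applies the fit-acceptance rules:
RMSEA and SRMR below 0.05 are a good fit, an RMSEA above 0.05 is still
accepted when its lower 90% limit is 0.000, CFI above 0.95 is very good
and above 0.80 acceptable, and $\chi^2$ nonsignificance is reported but
flagged as unreliable at these sample sizes. Sexes are always fitted
separately in the pipeline.

## The synthetic cohort generator

No per-mouse raw data are deposited for this system, so every stage is
exercised against `gen_cohort()` / `gen_genotypes()`, whose **defaults
are the study conditions**: 12 sites with the deposited per-site
genotyping counts (total 433 — the per-site legend's numbers, whose sum
differs slightly from the round total quoted in prose); male:female odds
1.18; gamma ages matched to median 7.4 and upper quartile 12 weeks;
seven serological infections whose probabilities rise linearly with age
(baselines chosen so that overall seroprevalence is ≈95% and the
burden–age correlation ≈0.28); pinworm and mite presence at 79% and 67%;
day length uniform over 470–1000 minutes (southern-UK annual range);
SMI centred at 18 g (SD 2.5 g) on an exponent-2.7 mass–length allometry
over lengths ~N(82, 6²) mm; cell counts scaling with length as
length^1.7; and Balding–Nichols genotypes at 1,168 loci with
differentiation F = 0.48 (per-site allele frequencies drawn from
$\mathrm{Beta}(\bar p(1-F)/F,\ (1-\bar p)(1-F)/F)$, Hardy–Weinberg
within site). Balding–Nichols was chosen over explicit drift simulation
because it gives an analytic differentiation target, which is exactly
the surface the estimator checks recover.

The immune structure is a linear-Gaussian system: Condition is driven by
age, season and infection burden; three latent compartments (adaptive
cellular, innate cellular, humoral) are driven by condition, age, season
and infection, each with a per-site random intercept, the two cellular
latents sharing an extra common component; the ten measures load on
their compartment. The variance split was set against the published
component structure: with the default residual SDs (latent 0.35, shared
cellular 1.0, IgA loading 0.45) the implied correlation matrix has three
leading components — all seven cell counts, then IgG+IgE, then IgA —
explaining roughly 53/18/8% of variance, and a site-intercept SD of 0.7
yields an among/within immune-distance ratio near the published one.
Infection severities 1–4 are assigned uniformly to positives; only
presence/absence feeds the models. One RNG stream is derived per site
from the master seed, so adding a site never perturbs earlier sites'
draws, and identical configurations are byte-reproducible.

Because the system is linear in its exogenous drivers, the covariance of
the observed variables has a closed form (`generator_implied_cov()`),
used two ways: the generator is validated against its own algebra on
large samples, and the SEM engine's `implied_covariance()` must
reproduce the same matrix at the algebraically mapped true parameters to
machine precision — two independent routes to one matrix. The closed
form is exact when the cell-count body-size exponent is 0 (the
multiplicative length factor sits outside the linear system), so those
checks, and the SEM recovery study, run with `cell_allometry_b = 0` and
`site_sd = 0`; the fitted SEM has no site level, and a coverage check is
only meaningful when the generating model matches the fitted one.

What the generator does **not** emulate: real measurement distributions
(counts are truncated Gaussians, not flow-cytometry counts), linkage
disequilibrium or chromosome structure among loci, spatially structured
differentiation (site coordinates are independent of the genetics, so
matrix comparisons are calibrated under "no association"), per-site
ecological differences beyond random intercepts, temporal structure, or
sex-specific path coefficients. Passing tests therefore demonstrate that
the estimators recover known structure of this generating class — not
that the biological conclusions transfer to any particular real data
set.

## Numerical conventions and problem sizes

Distance matrices must be symmetric within 1e-9 (file round-trips use a
looser 1e-6 for printed precision) with zero diagonal and no negative
entries. Unicode minus and ± are normalized on read; missing values are
empty cells, never 0 or −1. The Markov-chain Hardy–Weinberg test
defaults to 10⁶ iterations; the pipeline's per-site screen uses 2×10⁴,
enough for ~10⁻² Monte-Carlo error on a screening p-value. The test
suite's simulation sizes are chosen to hold sampling error an order of
magnitude below each tolerance: 200 replicates at n = 5,000 for SEM
coverage and χ² calibration, 1,000 null draws at 99 permutations for
Mantel type-I error, 500 simulated loci for Hardy–Weinberg uniformity,
and 1,000-locus panels for F_ST calibration. The pipeline's
neighbour-joining bootstrap defaults to 0 in tests and 100 in the
analysis scripts; the function default remains 1,000.

## Known limitations

SEM standard errors use the numeric Hessian of the ML discrepancy
(expected-information variants are not implemented), full-information ML
for missing data is out of scope (listwise deletion only), ordinal
estimators are not provided (infection burden is treated as continuous),
and the SMA-based scalings inherit the estimator's noise-inflation
property discussed above — with weakly length-correlated counts the
fitted exponents are large and unstable, which is a property of the
method being reproduced, not of this implementation.
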