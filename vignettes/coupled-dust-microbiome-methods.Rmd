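---
title: "Methods: coupled geochemistry and microbiome analysis of dusty PM10"
author: "dustbiome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupled geochemistry and microbiome analysis of dusty PM10}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dustbiome)
```

`dustbiome` analyses urban respirable particulate matter (PM10) sampled
across a desert dust event on two coupled fronts: receptor-model
geochemistry (which sources contributed how much mass each day?) and
amplicon microbiome statistics (how did the airborne bacterial and
fungal communities respond?). This vignette is the package's own account
of the models it implements, the tunable parameters that matter, what
the synthetic-data generators do and do not emulate, and the numerical
choices that make results reproducible.

## Chemical mass balance with effective-variance weights

The receptor model expresses each measured element concentration
$C_i$ (ng/m^3^) as a linear combination of source contributions,

$$C_i = \sum_j F_{ij} S_j + e_i,$$

where $F_{ij}$ is the mass fraction of element $i$ per unit mass emitted
by source $j$ (dimensionless) and $S_j$ is the ambient contribution of
source $j$ (converted to µg/m^3^ for reporting). Both the measurements
and the profiles carry 1-sigma uncertainties, so `fitCMB()` solves the
weighted least-squares system under *effective variance* weights,

$$V_{e,i} = \sigma_{C_i}^2 + \sum_j S_j^2\, \sigma_{F_{ij}}^2,$$

which depend on the solution; the fit is iterated from an ordinary
weighted solve (measurement uncertainties only) until the maximum
relative change in $S$ falls below `tol = 1e-4` (50 iterations cap, an
error on non-convergence). Each weighted solve uses a QR factorization
of the weighted design rather than the normal equations: noise-free
synthetic panels produce weights spanning many orders of magnitude, and
only the QR route survives that in double precision. Contribution
uncertainties come from the diagonal of $(F^\top V_e^{-1} F)^{-1}$.

Diagnostics follow receptor-modelling convention: `rSquared` is the
weighted explained variance, `chiSquared` the weighted residual sum of
squares per degree of freedom ($n_\text{elements} - n_\text{sources}$).
Negative fitted contributions are legal output (reported with a
warning); `dropNegative = TRUE` iteratively removes the most negative
source and refits, the standard practical remedy. Rank deficiency of
the profile matrix is detected by its condition number and reported
with the most collinear source pair named.

Unit policy: element concentrations are ng/m^3^ and PM masses µg/m^3^
everywhere, including on disk; the only conversion (×1000) happens
inside `fitCMB()` and is paired with its inverse on output, so a silent
1000× error cannot arise.

Supporting diagnostics mirror standard dust-event practice:
`ratioDiagnostics()` computes La/Ce (≈0.5 marks upper-crustal
character), La/V (depressed by V-rich oil-combustion aerosol) and the
PM10/PM2.5 mass ratio (depressed during long-range dust transport);
`classifyDustDays()` labels days low/medium/peak with default
thresholds (10, 30) µg/m^3^ of apportioned dust;
`reconstructMineralMass()` compares apportioned mineral mass against
the oxide-weighted reconstruction 1.89 Al + 2.14 Si + 1.4 Ca + 1.43 Fe
+ 1.67 Ti (conventional crustal oxide multipliers);
`unapportionedFraction()` reports the PM10 share left unexplained,
conventionally read as secondary aerosol, and does not clip negative
(over-apportioned) values.

## UCC-normalized La–V–Ni ternary mixing

Ambient La, V and Ni arise almost entirely from two end-members —
crustal dust and V/Ni-rich oil combustion — so a three-component
diagram separates them cleanly once the upper continental crust (UCC)
is placed at the centroid. `centroidFactors()` computes multipliers
$f_e = \text{ref}[\text{anchor}]/\text{ref}[e]$; with the packaged UCC
reference (La 31, V 97, Ni 47 µg/g, Rudnick & Gao 2003 compilation,
overridable) and V anchored at 1 this gives 2.06 for Ni and 3.13 for
La. Samples are scaled and closed to the 2-simplex
(`ternaryCoordinates()`), and `mixingLineProjection()` projects them
onto the segment joining two end-member compositions in the standard
equilateral-triangle embedding — a design choice; any affine embedding
gives the same fractions, and the perpendicular deviation is reported
in embedding units where the triangle has unit side. Because closure
is a projective map, two-source mixtures are exactly collinear, and the
mixing fraction tracks the crustal mass share; whether concentrations
are pre-normalized per sample before closure is immaterial, closure
makes the two conventions identical.

## Alpha and beta diversity

`chao1()` implements the classic estimator $S_{obs} + F_1^2/(2F_2)$
with the bias-corrected branch $S_{obs} + F_1(F_1-1)/2$ when no
doubletons exist; `shannon()` uses natural logarithms (nats). No
rarefaction is applied by default — diversity is computed on the counts
as given. `brayCurtis()` is the classical
$\sum_i |x_i - y_i| / \sum_i (x_i + y_i)$ on counts (or proportions via
`proportions = TRUE`); a pair of all-zero samples is undefined and
flagged rather than silently zeroed. `pcoa()` is the Gower-centered
eigen-decomposition with coordinates scaled by the square root of the
positive eigenvalues; negative eigenvalues (non-Euclidean input) are
reported but excluded from the variance-explained denominator.

`correlationScreen()` regresses each OTU's relative abundance on each
covariate by Pearson correlation with a two-sided t-test. With nine
samples the test has 7 degrees of freedom — a real limitation of
campaign-scale data that the package documents rather than hides; the
screen is exploratory, p-values are uncorrected by default
(Benjamini–Hochberg via `adjust = "BH"`), and the per-OTU `strongest`
flag marks the covariate with the largest |r| among the OTU's
significant correlations. Whether such a screen should use Pearson,
Spearman or OLS slope tests is a genuinely open choice; Pearson on
relative abundances is the package default because it matches the
"linear regression" framing common in this literature, and the
alternatives reduce to it after rank- or scale-transforming inputs the
caller controls.

## Pagel's lambda

Under Brownian motion on a rooted tree, tip traits are multivariate
normal with covariance $C_{ij}$ = shared root-to-tip path length. The
lambda transform multiplies off-diagonal entries by $\lambda$:
$\lambda = 0$ is a star-like (signal-free) covariance, $\lambda = 1$
full Brownian signal. `fitLambda()` profiles the rate and root state by
GLS and maximizes over $\lambda$ with a 21-point grid pre-scan followed
by Brent refinement (tolerance 1e-6) — the pre-scan guards against
local optima in the 1-D profile likelihood. Bounds are $[0, 1]$ for
ultrametric trees; for non-ultrametric trees the upper bound is the
largest $\lambda$ keeping the transformed covariance positive definite,
found by bisection on the smallest eigenvalue.

For ultrametric trees the transform $\lambda C + (1-\lambda) h I$
shares the eigenbasis of $C$ (constant diagonal $h$), so after one
eigendecomposition every likelihood evaluation is $O(n)$; this is what
makes a 500-replicate calibration study with hundreds of permutations
each run in minutes. Non-ultrametric trees fall back to a Cholesky
factorization per evaluation.

Significance of $\lambda > 0$ uses a Monte-Carlo null: trait values are
permuted across tips `nSims` times (999 by default), each permutation
refit, and $p = (1 + \#\{\Delta\ell_{perm} \ge
\Delta\ell_{obs}\})/(nSims+1)$ with $\Delta\ell = \ell(\hat\lambda) -
\ell(0)$. Permutation was chosen over simulation from the fitted null
for distribution-freeness; a likelihood-ratio $\chi^2_1$ test is
available via `method = "lr"` (anti-conservative at the boundary, hence
not the default). The permutation stream is seeded and bit-reproducible.
On a star phylogeny the likelihood is constant in $\lambda$; the fit
reports non-identifiability instead of an arbitrary optimum. Traits for
OTU data come from `abundanceTrait()`: per-day relative abundance,
log-transformed with a pseudo-count defaulting to half the smallest
nonzero proportion.

## Generalized dissimilarity modelling

GDM regresses pairwise community dissimilarity $d_{ij} \in [0,1)$ on
site predictors through monotone I-spline transforms $f_k$ and the link
$\mu = 1 - \exp(-\eta)$, $\eta_{ij} = \beta_0 + \sum_k |f_k(x_{ki}) -
f_k(x_{kj})|$. Three I-splines per predictor with knots at the
0/50/100th percentiles follow common GDM practice; the basis is built
from quadratic B-splines via the cumulative-sum identity
($I_i = \sum_{j>i} B_j$), so each basis function rises from 0 at the
predictor minimum to 1 at its maximum. Quantile knots make the fit
invariant to strictly increasing predictor rescaling.

The fit minimizes the binomial-type deviance by iteratively reweighted
least squares with a non-negative least-squares solve per step
(tolerance 1e-8 on the deviance, 100 iterations cap); non-negativity
of all coefficients including the intercept is enforced *inside* the
optimization, never by post-hoc clipping, which keeps every fitted
transform monotone and every prediction in $[0,1)$. Observed
dissimilarities of exactly 1 are shrunk to $1 - 10^{-6}$ before the
link inversion used at initialization. Rank-deficient designs (e.g.
duplicated predictors) fall back to a ridge-stabilized solve.
Deviance explained is $100(1 - D_{res}/D_{null})$ against an
intercept-only null.

`predictorImportance()` permutes one predictor's site values across
sites, rebuilds that predictor's pair terms, refits, and reports the
mean drop in percent deviance explained (floored at 0; default 100
permutations). The two model families of interest are pGDM (predictors
= apportioned source contributions) and cGDM (predictors = element
concentrations); both are just choices of the covariate table, and the
package never guesses a default predictor subset — with nine sites and
36 pair rows a many-element cGDM is badly overparameterized, so
predictor lists are always the caller's explicit decision.

## Synthetic data: what it emulates, and what it does not

Every input class has a generator with known ground truth attached as a
`truth` attribute, deterministic given (arguments, seed):

- `genSourceProfiles()`: a seven-source urban library over 36 major and
  trace elements (crustal dust with La/Ce = 0.5; K/Mn/Rb-marked soil;
  Ca/Sr concrete; Fe/Cu/Zn/Zr/Sb/Ba road dust; S/Zn/Pb/Br vehicles;
  Na/Cl/Mg sea salt; V/Ni/S oil combustion). The distinct tracer
  signatures hold the normalized profile-matrix condition number near
  15 (draws are rejected above 100) so that source contributions are
  statistically identifiable — the defining property of a usable
  receptor-model library, and a precondition for Monte-Carlo bias
  checks at a few hundred replicates to be informative rather than
  noise-dominated.
- `genElementPanel()`: $C = 1000\, S\, F$ with mean-preserving
  multiplicative lognormal noise at the stated CV. Reported
  uncertainties equal CV × the *ideal* mixture rather than the noisy
  realization: uncertainties correlated with the realized noise would
  bias any weighted fit downward, an artifact of the simulation rather
  than a property of the estimator under study.
- `genOtuTable()`: log-normal baseline abundances, a linked subset
  whose expected proportions scale linearly with the standardized
  covariate, multinomial counts at fixed depth.
- `genTreeTraits()`: Yule trees (pure birth), traits multivariate
  normal with the λ-transformed Brownian covariance.
- `genTurnoverCommunities()`: species with Laplace (exponential) niches
  $e^{-|g - o|/\tau}$ and optima spaced densely along an extended
  gradient. With $\tau = 1/(2\,\text{rate})$ the expected Bray–Curtis
  dissimilarity between sites is exactly $1 - e^{-\text{rate}\,
  |\Delta g|}$ in the dense-optima limit (the integral
  $\int \min(e^{-|g_1-o|/\tau}, e^{-|g_2-o|/\tau})\,do =
  2\tau e^{-\Delta/2\tau}$ against site totals $2\tau$), giving a
  closed-form oracle for the GDM round trip.

The `houston9` scenario bundles these into a nine-day campaign shape —
a dust-pulse trajectory (low–peak–low) over seven sources, 848
bacterial and 1345 fungal OTUs with dust-linked members, an 18%
secondary-mass share — for demonstrations and qualitative end-to-end
checks.

What the generators deliberately do **not** emulate: sequencing-level
artifacts (chimeras, read errors, primer bias), taxonomic realism
beyond lineage-string formatting, compositional constraints between
elements and OTUs, temporal autocorrelation, or meteorology. Passing
the package's recovery suites therefore demonstrates that the
*estimators* are correct and calibrated under their stated models — it
does not certify conclusions drawn from any particular field campaign,
where none of the generating assumptions hold exactly. In the same
spirit, dataset-dependent campaign results (OTU totals, Chao1/Shannon
levels, observed Bray–Curtis means, per-day λ values, pGDM/cGDM
deviances) are not reproduction targets: they require the raw
sequence archives and full elemental tables, which are not packaged.

## Problem sizes and numerical choices

The test and acceptance suites run, at desk scale chosen once for
statistical informativeness: CMB zero-noise recovery to 1e-6 µg/m^3^
and a 200-replicate bias/coverage study at 10% noise (with the
36-element library, the Monte-Carlo standard error of each source's
mean is ≈1% of truth, so a 5% bias bound is a real test); λ recovery
with 100 replicates of 200-tip trees at λ ∈ {0, 1} and a 500-replicate
type-I calibration with 199 permutations each on 48-tip trees; GDM
recovery on noise-free exponential data, a 100-replicate permuted null
on 20 sites, and a 100-replicate importance-ranking study on 12 sites
with 20 permutations per predictor. One replicate-level check deserves
note: the sample covariance of 2000 replicate trait draws on a 10-tip
tree is compared to its target at the *theoretically expected* Wishart
sampling error $\sqrt{(\mathrm{tr}\Sigma^2 +
(\mathrm{tr}\Sigma)^2)/n}/\|\Sigma\|_F$ (≈6% here), since a fixed 5%
band would sit below the noise floor of the estimate itself.

Tie-breaks and degenerate inputs are handled explicitly throughout:
all-zero samples make Chao1/Shannon/Bray–Curtis undefined (flagged, not
zeroed); constant traits and constant dissimilarities are errors;
constant predictors are dropped from GDM with a warning; star
phylogenies report non-identifiability; zero ternary denominators flag
the sample.

## Known limitations

- The CMB assumes profiles are known up to stated uncertainty;
  systematically wrong profiles bias contributions in ways no
  diagnostic here detects.
- The correlation screen at n = 9 has low power and no multiplicity
  control by default; it mirrors exploratory practice, not confirmatory
  inference.
- GDM importance by permutation dilutes across collinear predictors;
  near-duplicate predictors share importance and can each look weak.
- The λ permutation test exchanges tips, which is exact under the
  signal-free null but only approximate power-wise for small trees.
- Readers are minimal by design: CSV/TSV/Newick only, no BIOM-HDF5 or
  FASTQ.
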