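# dustbiome

Coupled source apportionment and aerosol microbiome analysis for desert
dust events.

When a Saharan dust plume reaches an urban receptor site, two questions
arise together: *how much of the measured PM10 mass came from which
source*, and *what happened to the airborne bacterial and fungal
communities while it did*. `dustbiome` is an R package for analysts who
hold both kinds of data from the same campaign — per-sample element
concentration panels with uncertainties, aerosol source profiles, OTU
count tables with taxonomy, and phylogenetic trees — and want the two
sides analysed with one coherent, tested toolchain.

## What it computes

**Geochemistry.** The effective-variance chemical mass balance (CMB)
receptor model: measured concentrations C (ng/m³) are decomposed as
C = F·S over source profiles F, by weighted least squares with
effective-variance weights V_e = σ_C² + Σ_j S_j² σ_F², iterated to a
fixed point; per-sample contribution uncertainties, fit diagnostics,
dust-day classification (low/medium/peak), mineral-mass reconstruction
from crustal oxides (RMMM), unapportioned (secondary) mass, and La/Ce,
La/V, PM10/PM2.5 dust diagnostics. Plus the upper-continental-crust
normalized La–V–Ni ternary mixing construction: multipliers that place
the UCC at the ternary centroid (1 for V, 2.06 for Ni, 3.13 for La
with the packaged reference) and projections onto a two-end-member
mixing line.

**Microbiome.** Chao1 and Shannon alpha diversity; Bray–Curtis beta
diversity with principal coordinates analysis (Gower centering);
taxon aggregation with top-N / other / unclassified pooling; a per-OTU
covariate correlation screen (Pearson, two-sided t, p < 0.05
uncorrected by default); Pagel's λ phylogenetic signal by maximum
likelihood with a seeded 999-permutation Monte-Carlo test; and
generalized dissimilarity modelling (GDM) — monotone I-spline
transforms, link μ = 1 − exp(−η), non-negative IRLS fit, percent
deviance explained, and permutation predictor importance — for both
pGDM (source-contribution predictors) and cGDM (element predictors).

**Synthetic data.** Seeded generators with ground truth for every input
class: a well-conditioned seven-source, 36-element profile library;
linear source mixtures with multiplicative noise; OTU tables with
covariate-linked members; Yule trees with traits at known λ; and
communities with exactly exponential distance-decay turnover. The
`houston9` scenario bundles them into a nine-day dust-pulse campaign
shape for demos and end-to-end checks.

## Worked example

```r
library(dustbiome)

## nine-day campaign summary (packaged): dust diagnostics
t1 <- houstonCampaign()
pan <- readElementPanel(dustbiomeExtdata("elements_houston_synthetic.csv"))
attr(ratioDiagnostics(pan), "means")
#>     la_ce      la_v  pm_ratio
#> 0.5499960 0.2377778 4.0739487
summarizeContributions(setNames(t1$saharan_dust, t1$sample_id),
                       setNames(t1$pm10, t1$sample_id),
                       samples = c("S1", "S6", "S7", "S8", "S9"))[c("mean", "sd")]
#> $mean
#> [1] 11.6883
#> $sd
#> [1] 8.779342
classifyDustDays(setNames(t1$saharan_dust, t1$sample_id))
#>     S1     S2     S3     S4     S5     S6     S7     S8     S9
#>    low medium   peak   peak   peak medium    low medium    low
#> Levels: low < medium < peak

## synthetic end-to-end: known mixture -> CMB recovery
pr  <- genSourceProfiles(seed = 1)
S   <- matrix(c(10, 6, 8, 4, 9, 3, 1), 1,
              dimnames = list("day1", sourceNames(pr)))
fit <- fitCMB(genElementPanel(pr, S, noiseCV = 0, seed = 1), pr)
max(abs(sourceContributions(fit) - S))
#> [1] 1.776357e-15

## UCC ternary normalization factors
round(centroidFactors()$factors, 2)
#>   La    V   Ni
#> 3.13 1.00 2.06

## turnover round trip: exponential decay -> GDM
comm <- genTurnoverCommunities(nSites = 15, rate = 2, noise = 0.05, seed = 4)
g    <- attr(comm, "truth")$gradient
spt  <- buildSitePairTable(brayCurtis(comm),
                           matrix(g, 15, 1, dimnames = list(names(g), "grad")))
fitGdm(spt)
#> GdmModel: 1 predictors, deviance explained 100.0%
#>   partial curve heights: grad=1.996
#>   intercept 0.0014; converged in 4 IRLS iterations
```

The first block reads the packaged nine-sample campaign table: the
campaign-mean La/Ce of 0.55 is upper-crustal (dust-dominated), the
depressed La/V of 0.24 marks admixed industrial oil-combustion aerosol,
and on the five regular (non-peak) days apportioned Saharan dust
averaged ~12% of PM10 mass with population SD ~9%. The CMB block shows
exact recovery of a known seven-source mixture from a noise-free
panel; the GDM block recovers a distance-decay rate of 2 (partial curve
height ≈ the true η range) from simulated communities.

A thin command-line front end over the same functions ships in
`inst/scripts/pm10micro.R` with subcommands `apportion`, `ternary`,
`diversity`, `correlate`, `phylosig`, `gdm`, `simulate`.

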