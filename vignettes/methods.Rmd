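---
title: "Models and methods in dendroQG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in dendroQG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`dendroQG` analyses annual tree-ring series from common-garden provenance
trials to ask a quantitative-genetic question: how much of the variation in
growth, wood anatomy, and drought resilience among trees is genetic, how is
it structured among and within seed-source populations, and does it track
the climate of origin? This vignette documents the models, the tunable
parameters, the numerical choices, and the limits of what the synthetic
test bed can show.

## Soil moisture index

Monthly plant-available soil water $W_m$ follows a single-bucket recursion

$$W_m = \mathrm{clamp}\!\left(W_{m-1} + P_m - \mathrm{AET}_m,\; 0,\; w_{\max}\right),
\qquad \mathrm{SMI}_m = 100\, W_m / w_{\max},$$

with gains from monthly precipitation $P_m$ and losses from actual
evapotranspiration $\mathrm{AET}_m = \mathrm{PET}_m \, g(W_{m-1})$. The
drawdown function is quadratic below a critical store $w_{crit}$,
$g(W) = 2(W/w_{crit}) - (W/w_{crit})^2$, and 1 above it. Defaults are
$w_{\max} = 300$ mm and $w_{crit} = 400$ mm; because $w_{crit} > w_{\max}$
the store never leaves the quadratic (supply-limited) regime, and this is
kept as the default deliberately. PET uses a closed-form simplification of
Penman–Monteith for when radiation and wind data are unavailable:
$\mathrm{PET} = \alpha \cdot \mathrm{VPD} \cdot \Delta/(\Delta+\gamma)$
mm/day, zero at or below freezing, with $\Delta$ the saturation-vapour
slope at air temperature, $\gamma = 0.066$ kPa/°C, and $\alpha = 5$
mm day⁻¹ kPa⁻¹ chosen so mid-summer monthly PET is near 100 mm under
humid-continental conditions. Precipitation in months with mean temperature
below 0 °C is banked as snowpack and released at the first thaw month; the
rule is toggleable (`snow = FALSE`) since snow routing is a modelling
choice, not data. The initial store defaults to a full bucket
(`w_init = w_max`) and is recorded; tests show the recursion conserves mass
to machine precision and keeps SMI in [0, 100].

Drought events are years whose June–August SMI ratio (annual summer mean
over a baseline summer mean) falls below a quantile of the ratio
distribution (default 0.15); consecutive flagged years merge into one event
dated at the final year, so a two-year dry spell like 2001–2002 is indexed
at 2002. Quantile-based flagging makes detection invariant to affine
rescaling of the baseline.

## Ring traits and standardization

Ring widths convert to basal area increments assuming circular stems
measured pith-outward; the conversion telescopes to total basal area and is
exactly invertible. Lumen diameters are $LD = TD - CWT$; conduit wall
reinforcement uses the double-wall convention $CWR = (2\,CWT/LD)^2$, with a
`wall = "single"` option since both conventions circulate in the
literature.

Standardization is two-step. Step 1 removes non-climatic structure by an
additive model of the trait on cambial age, cumulative basal area, and
optionally a Hegyi competition index
$CI_i = \sum_j (s_j/s_i)/d_{ij}$ over neighbours within 3.6 m (three
1.2 m planting spacings), each covariate entering as a penalized regression
spline with smoothness chosen by generalized cross-validation (mgcv).
Residuals are response-scale. The original analysis used mixed additive
models with random smooths; fixed-effect smooths suffice for the
residual-extraction role and are a deliberate simplification. Step 2
removes serial persistence per tree with an AR(p) fit, $p$ chosen by AIC
over 0…3 (the cap is a design choice; ring series this short rarely support
more), keeping innovations recentred and rescaled to the input variance.
Years before a configurable cut (default 1989) are dropped from
chronologies to exclude the juvenile phase. Chronology quality is
summarized by the mean inter-series correlation $\bar r$ and
$EPS = N\bar r / (1 + (N-1)\bar r)$.

## Drought-resilience indices

For an event year $e$ with pre/post windows of `pre_n` and `post_n` years
(defaults 2 and 2, excluding the event year): $Rs = Dr/PreDr$,
$Rc = PostDr/Dr$, $Rl = PostDr/PreDr$, $Rr = Rl - Rs$. The identities
$Rl = Rs \cdot Rc$ and $Rr = Rl - Rs$ hold exactly and are asserted on
every simulated record, as is invariance to rescaling the BAI series.
Events closer together than `pre_n + post_n` years have overlapping
windows; a warning is emitted but windows are not trimmed, matching common
practice when events such as 1997/2002/2005 are closer than the window
span. Indices are computed per tree and then averaged to families or
provenances, never on group-mean chronologies.

## Mixed models, heritability, Q_ST

Two REML model shapes cover the analyses. For single-record traits
(e.g. $Rl_{2002}$): fixed block and tree-size effects; random provenance,
family-within-provenance, and family-by-block (plot) effects; independent
residuals. For repeated annual traits: fixed year and block effects; random
provenance, family, provenance-by-year, family-by-year and plot effects;
within-tree residuals correlated across years. Fitting uses glmmTMB with
REML; variances are parameterized on the log-sd scale (bounded at zero by
construction), and the covariance of the variance estimates comes from the
observed information at the optimum, delta-transformed to the variance
scale.

The heterogeneous AR structure deserves a note. The target residual
covariance for a tree's year vector is
$\mathrm{Cov}(e_s, e_t) = \sigma_s \sigma_t \rho^{|s-t|}$. No available
engine fits this form with crossed year-interaction random terms, so it is
represented as an `ar1()` within-tree term (homogeneous variance,
correlation $\rho$) plus year-specific diagonal variances through the
dispersion model; `"AR1"` drops the year-specific part. For
homoscedastic-in-year data the representation is exact; under strong
year-to-year variance trends the correlated component is an averaged
approximation, and the reported per-year variances absorb the difference.
Parameter-recovery tests at trial scale (below) fit the `"AR1"` structure.

Ratios follow the half-sib logic that the family variance estimates a
fraction $r$ of the additive variance, where $r$ is the average relatedness
of trees within open-pollinated families ($0.25$ for idealized half-sibs):

$$h^2_{ind} = \frac{1}{r}\,\frac{\hat\sigma^2_{fam}}{\hat\sigma^2_p},
\qquad
Q_{ST} = \frac{\hat\sigma^2_{pop}}
{\hat\sigma^2_{pop} + 2\hat\sigma^2_{fam}/r},$$

with $\hat\sigma^2_p$ the sum of the family, family-by-year, plot, and
residual components (year-specific components averaged across years; the
population components are excluded by convention). The placement of $r$ in
$Q_{ST}$ — divide, not multiply — is the only form consistent with
half-sib theory and with published variance-component tables for such
trials, and is asserted against reference values to three decimals in the
test suite. Standard errors use the delta method; 95% intervals are
$\pm 1.96\,SE$ and hence symmetric — they can cross zero or one for weak
components, which is reported as-is rather than truncated.

Because paternity in open-pollinated families is unknown, $r$ may exceed
0.25 (full-sib contamination); the package accepts a realized genomic
estimate instead: the VanRaden method-1 relationship matrix
$G = WW^\top / (2\sum_k p_k(1-p_k))$ with mean-imputed missing genotypes,
averaged over within-family pairs. One subtlety the synthetic tests expose:
$G$ is centred on the whole-trial allele frequencies, so when provenances
are differentiated ($F_{ST}>0$) same-provenance pairs gain roughly $2F$ of
baseline relatedness and within-family means drift above the pedigree 0.25.
The bracket checks on relatedness therefore use panmictic simulations;
runs on differentiated panels report the realized value, as a real analysis
would. Neutral differentiation uses the Weir–Cockerham variance
decomposition per SNP, combined by ratio of sums; a Nei-style $G_{ST}$ is
emitted as a cross-check only, since it carries a $+1/(2n)$ finite-sample
bias.

Significance of random terms uses the REML likelihood-ratio statistic
against the boundary mixture $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$; type-I
simulations at 20 groups × 5 replicates put the realized rejection rate
near the nominal 5%.

## Clinal analysis with hinge splines

Provenance means are regressed on origin-climate normals (MAT, MAP, ADD,
Summer_SMI) with hinge-basis adaptive regression splines: a forward pass
greedily adds mirror-image hinge pairs $\max(0, x-k)/\max(0, k-x)$ at
observed predictor values (interaction degree ≤ 2, term cap 21), and a
backward pass deletes terms by generalized cross-validation
$GCV = (RSS/n)/(1 - C(M)/n)^2$ with effective parameters
$C(M) = M + d\,(M-1)/2$ and penalty $d = 3$ (the canonical choice when
interactions are allowed; 2 for additive fits). Both caps are exposed as
arguments. Predictors are standardized internally so greedy knot selection
is identical under affine rescaling; knots are mapped back to original
units for reporting. Since the full forward model is in the pruning
sequence, the selected GCV never exceeds the forward GCV — asserted as an
invariant. Response surfaces are evaluated on a rectangular grid with
out-of-range cells flagged as extrapolation; the bounding box, not the
convex hull, defines "observed", a coarser but transparent rule.

## The synthetic test bed

The generator mirrors the study design the package targets: 43 provenances
carrying one to five open-pollinated families each (197 total), each family
as a five-tree row-plot in all six randomized blocks (5910 tree slots,
1.2 m × 2.4 m spacing), ring years 1979–2007 with droughts imposed in 1997,
2001–2002 and 2005, and 6386 SNPs differentiated at a Balding–Nichols
$F_{ST}$ of 0.043. Weather is a seasonal sinusoid with AR(1) noise for
temperature, a two-state Markov occurrence chain with gamma amounts for
precipitation (stationary moments chosen to give roughly 4 °C mean annual
temperature and 1000 mm precipitation, a humid-continental regime), RH as
bounded noise and VPD derived from temperature and RH so it is never
negative. Drought years multiply June–September precipitation by
`severity` (default 0.35) and add 2 °C.

Log ring width is an age trend (negative exponential), a year effect
proportional to standardized site summer SMI, random population, family,
plot, population-by-year and family-by-year effects at the requested
variances, and an AR($\rho$) tree-year residual — the same structure the
repeated-measures model estimates, on the log scale so variance ratios are
scale-free. The drought-year dip is common to all provenances; the clinal
signal sits in the post-drought recovery deficit, which grows with origin
summer moisture at slope `beta`. This choice is deliberate: with two-year
pre/post windows around the 2002 event, the 2001 drought year sits inside
the pre-window for every tree, so a provenance-dependent dip alone would
bias $Rl$ in the wrong direction; making recovery clinal — which is also
where the biological signal was found — yields the intended negative
cline of resilience against origin Summer_SMI by construction. Half-sib
genotypes use explicit parent alleles (one maternal allele plus one from
the provenance pollen pool), so genomic and pedigree relatedness can
disagree realistically. Every dataset is reproducible from
`(params, seed)` and ships its ground truth.

What the generator does **not** emulate: spatial autocorrelation within
blocks, measurement error structure of X-ray densitometry, linkage
disequilibrium, selection at individual loci, mortality, and station
interpolation of climate. Passing tests therefore demonstrate correctness
of the estimators under the stated model, not robustness to every
real-data pathology.

## Problem sizes and numerical choices in the test suite

The suite favours structurally faithful but thinned designs so it runs
comfortably on one CPU: variance-component recovery uses 43 provenances ×
2 families × 6 blocks × 2-tree plots × 11 years with AR(0.5) residuals over
20 seeds (medians within 15% of truth); $Q_{ST}$ recovery uses the full
197-family design with single-tree plots; the $F_{ST}$ consistency check
uses 43 demes × 30 unrelated trees × 5000 SNPs; the cline check uses 43
provenances × 24 trees. Reader round-trips note one format quirk: the
Tucson stop marker 999 makes a true 9.99 mm ring unrepresentable, and the
writer nudges it one unit. Degenerate inputs (constant traits, all-zero
responses, monomorphic panels, single-tree groups) return flagged or zero
results rather than errors wherever a downstream stage can proceed.

Known limitations: the exact heterogeneous-AR likelihood is approximated
as described; the competition index is a standard Hegyi form rather than
the original study-specific index, whose definition is not publicly
available; the cross-dating check is a first-difference surrogate for
segment-based dating programs; and dataset-specific published quantities
(e.g. variance explained on restricted phenotype data) are out of reach by
construction — the package reproduces procedures, and exact ratio
arithmetic where the inputs are public.
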