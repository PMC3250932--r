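---
title: "Relationship-aware cross-validation for genomic prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relationship-aware cross-validation for genomic prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinfold)
```

## The problem

Genomic selection estimates the effects of dense SNP markers from a
training population and predicts *direct genomic values* (DGV) for
selection candidates as the sum of their marker effects. Reported
accuracies of such predictions depend strongly on how the validation
animals relate to the training animals: when close relatives of the
candidates sit in training, the markers capture family relationships as
much as marker-QTL linkage disequilibrium (LD), and cross-validation
with random folds overstates the accuracy that a breeder would see for
candidates from less-connected herds.

`kinfold` implements the full analysis for a pedigreed, SNP-genotyped
sire population:

1. quality control of an allele-dosage matrix (call rate, minor allele
   frequency, Hardy-Weinberg equilibrium) and deterministic mean
   imputation;
2. deregression of estimated breeding values (EBV) into weighted
   pseudo-phenotypes (DEBV) with parent-average information removed;
3. the pedigree numerator relationship matrix **A**, the dissimilarity
   transform, and K-means clustering of its rows into folds that
   *minimise* training-validation relatedness, alongside random folds
   and an old-to-young birth-year split;
4. a weighted BayesC Gibbs sampler for marker effects and DGV
   prediction;
5. validation statistics: pooled accuracy with contemporary-group
   (5-year birth interval) adjustment, bias slopes, and blending of
   adjusted parent averages with DGV into genomic-enhanced breeding
   values;
6. a weighted bivariate animal model (EM-REML) for the genetic
   correlation between a trait and its cross-validated DGV;
7. a seeded population simulator producing the pedigree structure,
   LD-bearing genotypes and EBV records that the machinery assumes, so
   everything runs and is tested without external data.

## Models and key formulas

**Deregression.** EBV = 2 x EPD and reliability
$r^2 = 1-(1-\mathrm{BIF})^2$. For each animal the two-variable
mixed-model system in the parent-average (PA) and individual variables
has coefficient matrix
$$C = \begin{pmatrix} Z'Z_{PA} + 4\lambda & -2\lambda \\
-2\lambda & Z'Z_i + 2\lambda \end{pmatrix},
\qquad \lambda = \frac{1-h^2}{h^2},$$
and the effective information contents $Z'Z_{PA}, Z'Z_i$ are chosen so
the model-implied reliabilities match the published ones:
$\lambda (C^{-1})_{11} = 0.5 - r^2_{PA}$ and
$\lambda (C^{-1})_{22} = 1 - r^2_i$ (the PA predicts at most half the
genetic variance because of Mendelian sampling). Reconstructing the
right-hand sides as $(y_{PA}, y_i)' = C\,(g_{PA}, EBV_i)'$ gives the
deregressed record $DEBV = y_i / Z'Z_i$ with reliability
$r^{*2} = Z'Z_i/(Z'Z_i+\lambda)$ and analysis weight
$$w = \frac{1-h^2}{\big(c + (1-r^{*2})/r^{*2}\big)\,h^2},$$
where $c$ is the fraction of genetic variance not captured by markers
(default 0.5, a common choice for 50K panels; it scales all weights
smoothly, and the package exposes it). The closed forms
$\alpha = 1/(0.5-r^2_{PA})$, $\delta = (0.5-r^2_{PA})/(1-r^2_i)$ solve
this system exactly; the implementation verifies them against the
reliability conditions with a Newton polish to $10^{-10}$.

Records with $r^2_i \le r^2_{PA}$ carry no usable own information and
are excluded. Two further behaviours deserve note. First, when
$r^2_i > 4 r^2_{PA}$ the solved $Z'Z_{PA}$ is negative: the parents'
published reliability is then incoherent with their having absorbed the
individual's own records. The deregressed record is still well defined
(only $Z'Z_i$ enters it) and such records are kept, but in that regime
the DEBV can appear *more* reliable than the EBV — an artifact of the
method worth knowing about. Second, because deregression divides by
$Z'Z_i$, records whose reliability barely exceeds their parent average
produce explosive pseudo-phenotypes with near-zero weight; since the
validation statistics are unweighted, `deregress_table()` excludes
records with $r^{*2} <$ `min_r2_star` (default 0.10), a practitioner's
minimum-information rule.

**Adjusted parent average.** The PA with the individual's contribution
removed is re-shrunken from the parent-side information only:
$PA_{adj} = y_{PA}/(Z'Z_{PA} + 2\lambda)$ (the PA variable has variance
$0.5\sigma^2_g$, hence prior precision $2\lambda$). This construction
has the correct limit: an individual with (almost) no own information
and an EBV at its expected value returns $PA_{adj} \to g_{PA}$. Its
reliability as a predictor of the individual is
$0.5\,Z'Z_{PA}/(Z'Z_{PA}+2\lambda) < 0.5$. When $Z'Z_{PA} \le 0$ the
quantity is undefined and flagged. The construction of an "adjusted PA"
from the deregression machinery is not uniquely determined; this
re-shrinkage reading was chosen because it is the only one with the
correct no-own-information limit, and it remains only approximately
independent of the Mendelian-sampling effect.

**BayesC.** The training model is
$y_i = \mu + \sum_j z_{ij} u_j + e_i$ with
$\mathrm{Var}(e_i) = \sigma^2_e / w_i$ and the mixture prior
$u_j \sim N(0, \sigma^2_u)$ with probability $1-\pi$, $u_j = 0$ with
probability $\pi$ (default $\pi = 0.995$, the standard choice for ~50K
panels; $\pi$ should scale with panel size so that $(1-\pi)m$ matches a
plausible number of effects — the test fixtures with ~900 markers use
0.97). A single-site Gibbs sampler updates $\mu$, each $u_j$ in fixed
map order (marginal inclusion odds from the weighted residual
cross-product), then $\sigma^2_u$ and $\sigma^2_e$ from scaled
inverse-chi-square full conditionals (df 4 and 10; scales set so the
prior means equal $\hat\sigma^2_g/((1-\pi)\sum_j \mathrm{var}(z_j))$
and $\hat\sigma^2_e$ from a preliminary full-data run). Default chain:
41 000 iterations, 1 000 burn-in; the test suite uses reduced chains
(1 000-2 000 iterations), which the determinism and oracle tests cover.
Fixed update order plus R's RNG make chains bitwise reproducible from a
seed. $DGV_i = \sum_j z_{ij}\hat u_j$ over posterior-mean effects.

**Folds.** The dissimilarity
$d_{ij} = 1 - a_{ij}/\sqrt{a_{ii} a_{jj}}$ removes inbreeding from the
relationship scale; each animal's row of **D** is its feature vector
for Hartigan-Wong K-means (default K = 5, 25 restarts; K-medoids was
rejected in favour of the classical algorithm on rows, which is what
the standard toolchain does with a distance matrix). A `K = n` request
short-circuits to singleton clusters because the Hartigan-Wong
implementation requires `K < n`. Random folds split a permutation into
near-equal groups; the age split picks the largest threshold year whose
younger side holds at least `valid_fraction` (default 0.20) of records,
ties to training.

**Validation.** With $\sigma^2_g = h^2 \sigma^2_p$ (phenotypic variance
= genetic + residual from the preliminary full-data run), the pooled
accuracy is
$$\hat\rho = \frac{\hat\sigma_{DEBV,DGV}}{\sqrt{\sigma^2_g\,
\hat\sigma^2_{DGV}}},$$
with covariances and variances centred within 5-year birth-interval
contemporary groups (anchored at the minimum birth year; groups of one
are dropped) and pooled by degrees of freedom, which absorbs genetic
trend. The estimator assumes the response is unbiased for the genetic
value ($E[DEBV\,|\,g] = g$); it can exceed 1 in small groups whose DGV
variance is far below $\sigma^2_g$, and its per-group sampling error is
roughly $\sqrt{\mathrm{Var}(DEBV)/(n_g\,\sigma^2_g)}$ — about 0.2 for a
40-animal group — which is why per-group accuracies are best averaged
over several traits. Bias is the plain OLS slope of DEBV on DGV
(expected 1); blending coefficients come from least squares of DEBV on
$PA_{adj}$ and DGV with partition-group x birth-interval classes as
fixed effects (the asymmetry — no contemporary groups in the bias
regression, contemporary groups in blending — follows the standard
reporting of these quantities).

**Bivariate animal model.** DEBV and DGV are treated as two traits:
trait 1 with an overall mean and residual variance $\sigma^2_{e1}/w_i$
(the deregression weights, normalised to mean 1), trait 2 with
partition-group fixed effects and iid residuals; additive effects have
covariance $G_0 \otimes A$ and the residual covariance is fixed at 0.
EM-REML on the mixed-model equations updates the five components; the
restricted log-likelihood is computed every iteration and is
non-decreasing (a property the tests assert). Non-PD $G_0$ proposals
are bent to an eigenvalue floor of $10^{-6}\times$trace. Standard
errors come from the average-information matrix at convergence with
delta-method SEs for $r_g = \sigma_{\alpha_{12}}/
\sqrt{\sigma^2_{\alpha_1}\sigma^2_{\alpha_2}}$ and the component
heritabilities. Because each animal's DGV is a linear combination of
other animals' DEBVs, the joint covariance can approach singularity;
the fitter warns on a near-singular **V** rather than attempting a
remedy. Convergence is declared at a relative parameter change of
$10^{-4}$ (default), which moves $r_g$ by well under its SE relative to
tighter tolerances; dense algebra targets n up to a few thousand.

## What the simulator emulates — and what it does not

`simulate_population()` builds: four open herds with patrilineal
half-sib sire families (5 sires per herd per generation; family sizes
8-14 growing over four generations, so birth years skew recent), 10%
dam migration between herds, and one line closed for nine generations
(36 animals per generation, 8 sires with balanced dam use) reaching a
mean inbreeding coefficient of about 0.12 in its final generations
versus about 0.04-0.05 in the open herds. Founder haplotypes are
mosaics of a small ancestral pool (10 haplotypes per chromosome,
segment switch rate 1.5 per Morgan), which gives adjacent-marker
$r^2 \approx 0.15$ decaying with map distance; meiosis uses Poisson
crossovers (Haldane, 1 Morgan per chromosome). The closed line's
founders draw from a separate ancestral pool: it represents an imported
herd of distinct origin, so marker-QTL phase does not carry over from
the open herds — the feature that makes prediction into that cluster
genuinely hard. QTL are drawn from a reserved off-panel pool of loci
(default 100 of 1 000), so the returned marker panel never contains the
causal loci and prediction must work through LD, as with a real array.
The genotyped set is the males of the two most recent generations
(about 300 in the `tiny` fixture).

EBV records are generated so that the deregression machinery sees a
correct measurement model: parents receive BLUP-calibrated EBVs
($E[g\,|\,EBV] = EBV$; sires progeny-tested at reliability ~0.85, dams
~0.5, candidates ~0.6), and each genotyped animal's EBV is the
model-implied blend of an unbiased own-data average
($DEBV = g + \varepsilon$,
$\mathrm{Var}(\varepsilon) = \sigma^2_g (1-r^{*2})/r^{*2}$) with its
parent average, using the same two-variable system that deregression
solves. Deregressing the generated records therefore returns exactly
the unbiased pseudo-phenotypes the validation statistics assume — this
is a property the test suite checks to $10^{-8}$.

The simulator does **not** emulate: selection (matings are random
within structure, so there is no genetic trend for the contemporary
groups to remove — their machinery is exercised but not stressed);
genotyping error and pedigree errors; multi-breed admixture; the
actual 16-trait genetic-correlation structure of a national evaluation;
or EBVs from a true joint BLUP evaluation (parent-offspring EBV
consistency is exact only through the blending construction above).
One consequence of the two-generation genotyped window: an old-to-young
split keeps every young bull's sire in training, so its relatedness —
and hence its accuracy — matches random folds instead of sitting
between random folds and relationship-aware folds, as it does in deep
multi-cohort data where many young candidates lack genotyped parents.
Passing tests on synthetic data therefore demonstrate correctness of
the algorithms and the direction of the relatedness effects, not the
absolute accuracy levels of any real population.

## Numerical and design choices

* Tabular method for **A** over the full ancestor pedigree, then
  subsetting — relationships through pruned or non-genotyped ancestors
  are never lost; founders appearing once as parents are pruned to a
  fixed point before the heavy recursion.
* Unknown parents are unrelated, non-inbred founders; one known parent
  contributes $r^2_{PA} = r^2_{known}/4$, $g_{PA} = EBV_{known}/2$.
* Dosages are used raw (0/1/2 of the B allele, real-valued after mean
  imputation); the intercept absorbs allele-frequency means.
* Mean imputation stands in for haplotype-based imputation: at the
  sub-percent missingness typical after call-rate filtering the choice
  is immaterial downstream.
* Hardy-Weinberg: Pearson chi-square on the three genotype classes with
  plug-in allele frequencies, 1 df; a locus with no heterozygotes has
  statistic exactly $n$, a useful mental anchor for the default
  threshold of 300.
* Monte-Carlo error of posterior means is estimated by batch means when
  requested (used by the ridge-equivalence tests).
* All randomness flows through explicit seeds; chains, folds, and
  simulations are bitwise reproducible.

## Problem sizes used by the tests

The suite runs with reduced sizes chosen to exercise every code path
with meaningful statistics: BayesC oracle checks at n = 40-50, m =
20-30 with 12 000-30 000 iterations; the calibration study at n = 500,
m = 1 000 over ten seeds with 1 500-iteration chains; gene-dropping
validation of **A** at 30 animals x 100 000 replicates; bivariate REML
recovery at n = 500 over ten replicates; and the fold-scheme comparison
on ten simulated populations (~300 genotyped bulls, ~900 panel markers,
three traits each, 1 000-iteration chains). The `paper_like` fixture
scale (3 500 bulls x 45 000 markers) is available from
`make_fixture("paper_like")` for larger experiments.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config()
pop <- simulate_population(cfg, seed = 1)
rec <- simulate_trait_records(pop, cfg, seed = 1)

report <- run_pipeline(pop$ped, pop$geno, rec$records, h2 = cfg$h2,
                       scheme = "kmeans",
                       bayesc = bayesc_config(pi = 0.97,
                                              chain_length = 2000,
                                              burn_in = 200),
                       bivar = TRUE, seed = 1)
report
report$diagnostics$summary
```

The report carries the pooled and per-group accuracies, the bias slope,
the blending coefficients, the partition with its relatedness
diagnostics (per-group mean inbreeding, within- and between-group
maximum relationships), and the bivariate fit with $r_g$ and the
component heritabilities.

## Known limitations

* The deregression artifacts described above for incoherent published
  reliabilities ($r^2_i > 4 r^2_{PA}$).
* The pooled accuracy estimator is a ratio estimator; in small groups
  with little DGV variance it is noisy and can leave $[-1, 1]$.
* EM-REML is first-order; very flat likelihoods (e.g. a DGV trait with
  almost no residual variance) converge slowly, and the average
  information matrix can be ill-conditioned there.
* The bivariate model inherits the near-singularity of the joint
  DEBV/DGV covariance when DGVs are linear combinations of the other
  folds' DEBVs; a condition-number warning is the only mitigation.
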