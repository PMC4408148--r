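---
title: "Methods and design notes for crabflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for crabflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

crabflow implements the statistical chain used in landscape-genetics
studies of crop-to-wild gene flow in apples: admixture inference on
microsatellite genotypes, threshold classification of hybrids,
within-species diversity and spatial genetic structure, and landscape
regressions. This vignette records the models, the tunable parameters
that matter, and the design decisions that were genuinely open, so that
a maintainer can tell deliberate choices from accidents.

## The admixture model and its sampler

Each individual *i* carries, at every locus, two gene copies whose
latent source clusters Z are drawn from the individual's ancestry vector
q_i (a point on the K-simplex); given its source cluster k, a copy's
allele is drawn from that cluster's frequency vector p_{k,l}. The model
assumes Hardy–Weinberg equilibrium within clusters and linkage
equilibrium among loci. `gibbs_admixture()` samples the posterior by
sweeping over (i) the latent sources, with
P(Z = k) proportional to q_ik · p_{k,l,a}; (ii) the cluster frequencies,
p_{k,l} ~ Dirichlet(lambda + assigned-copy counts); and (iii) the
ancestries, q_i ~ Dirichlet(alpha + per-cluster copy counts). Missing
copies are skipped. Reported Q and P are posterior means over retained
sweeps; the observed-data log-likelihood log P(X | P, Q) is recorded at
each retained sweep.

Choices a user should know about:

- **Sweeps.** Defaults (2000 sweeps, 500 burn-in) are desk scale so that
  calibration suites run in seconds; the field protocol this emulates
  used 500,000 iterations after 50,000 burn-in and 10 replicate runs.
  For publication-grade runs raise `n_sweeps`/`burn_in` and the number
  of aligned replicates; the interface is identical.
- **The ancestry hyperparameter alpha.** This is the one genuinely
  consequential prior. A symmetric Dirichlet(alpha) on q contributes
  K·alpha pseudo-copies against roughly 2L observed copies per
  individual, so with K = 6 and 26 loci, alpha = 1 shifts a truly pure
  individual's posterior-mean membership several points toward uniform
  — enough to drag some pure trees below the 0.9 classification
  threshold. Very small fixed alphas have the mirror-image failure:
  backcrosses get pushed above the threshold, because a sparse prior
  suppresses the minority component and the source-assignment step
  reinforces it. The reference clustering program resolves this by
  inferring alpha in the chain; that update is implemented
  (`update_alpha = TRUE`: uniform prior on (0, 10), log-normal
  random-walk proposal with the Jacobian term) but *degenerates on
  idealized simulations*: when most simulated individuals are exactly
  pure, the posterior for alpha collapses toward zero and backcross
  signal is erased — real data, with its pervasive low-level admixture,
  does not do this. The package default is therefore a fixed
  alpha = 0.7, calibrated once on synthetic truth at the reference
  scenario (it holds both hybrid sensitivity and specificity above 0.9);
  both the value and the update switch are exposed.
- **Frequencies prior.** Independent Dirichlet(lambda = 1) per cluster
  and locus; the correlated-frequencies prior is deliberately not
  implemented (the emulated analysis did not state its prior, and the
  independent prior is the conservative choice for well-separated
  pools).

Model evidence is `mean(trace) − var(trace)/2` with the sample variance
(denominator n − 1); the ΔK criterion only needs this estimator to be
consistent across K. `evanno_delta_k()` computes
|L(K+1) − 2L(K) + L(K−1)| / sd(L(K)) across replicates, flags endpoints
as undefined, and flags (rather than divides by) zero standard
deviations. Replicate runs are aligned by the cluster-label permutation
minimizing the Frobenius distance to the first run — exact search over
all K! permutations up to K = 8, greedy column matching (ties to the
lowest column index) above — and averaged element-wise with row
renormalization.

## Hybrid classification and introgression rates

The cumulative wild membership w_i sums q over the wild clusters; the
thresholds are strict: pure wild above 0.9, misidentified crop below
0.1, hybrid in between. The two boundary values land in the hybrid
class — a measure-zero convention fixed so classifications are
deterministic. "Introgression rate" is ambiguous between two readings
and both are computed and labelled: the *hybrid fraction* (hybrids over
non-misidentified individuals, with the fraction over the total group
also reported, since headline percentages are often quoted against the
whole dataset) and the *mean crop ancestry* (mean 1 − w over
non-misidentified individuals). The mean crop ancestry is the default
response for the landscape GLMs because it is continuous and
individual-level; the hybrid fraction is the natural site-summary
statistic. Population assignment within the wild species uses the
strict 0.55 rule on the largest wild-cluster membership, and
between-population admixed genotypes are counted in the 0.55–0.9
membership band.

## Diversity statistics

H_E uses Nei's unbiased correction (2n/(2n−1))(1 − Σp²). Multilocus
heterozygosities and richness are unweighted means over loci; the
F-statistics are ratios of summed Weir–Cockerham variance components
over loci and alleles (the estimator's own prescription). Loci
monomorphic over the analysis set are excluded. With a single unit,
F_ST is NA with a flag and F_IS is still estimated. The global
heterozygote-deficit test is a one-sided permutation test of the
multilocus F_IS under random reassembly of gene copies into diploids
within unit and locus — the emulated study did not state its procedure,
and this choice matches the quoted direction (deficit) while preserving
allele counts exactly. Permutation p-values are always
(1 + exceedances)/(n_perm + 1), so never zero.

Rarefied allelic richness A_R(g) and private allelic richness A_P(g)
use the exact combinatorial (ADZE-style) formulas; loci whose units
have fewer than g typed copies are excluded and flagged, never imputed.
Defaults g = 2 (richness) and g = 100 (private richness) follow the
emulated analysis; on small synthetic designs the pipeline lowers
g_private accordingly. Both statistics are verified against exhaustive
subsample enumeration in the test suite.

## Kinship, isolation by distance, and Sp

The Loiselle/Nason kinship estimator is computed with reference allele
frequencies taken from the analysis set itself (each population
analysed separately, matching the per-population spatial analyses it
emulates), with the per-locus small-sample correction
Σ p(1−p)/(n_l − 1) and ratio-of-sums combination over loci typed in
both individuals. Distances are great-circle (R = 6371.0088 km). The
isolation-by-distance slope regresses F_ij on ln d_ij over pairs with
d > 0; significance permutes individual *positions* (9999 by default)
and is two-sided, since the emulated description says only that spatial
structure was tested. The first-distance-class edge defining F_(1) is
not stated in the source material; the default is 1 km and it is a
parameter. Sp = −b_Ld/(1 − F_N) uses the 10 km-restricted slope by
default, falling back (with a flag) to the overall slope when no pairs
fall within the cap.

## Landscape GLMs

Models 1 and 2 regress the introgression response on cultivated-apple
density crossed with orchard number (model 1) or orchard area
(model 2), quasi-Poisson with log link. The emulated analysis is
ambiguous about its response (a proportion fitted with a count family,
with residual df implying individual-level records); the default here
is the individual-level crop-ancestry response with site-level
covariates, and a site-level mean response is one flag away
(`granularity = "site"`). Term tests are sequential (type-I) in the
printed row order — density, main covariate, interaction — each F
computed against the Pearson dispersion of the full model. Model 3
(visitor-taxon richness ~ management class + insect order) requires an
explicit granularity choice — `"cells"` (6 orders × 2 classes) or
`"observation"` — because the two imply very different residual df and
neither should be a silent default. Point estimates are identical to
Poisson maximum likelihood; the dispersion affects inference only, and
is floored at machine epsilon (flagged) for degenerate zero-variance
data.

## The synthetic world

The generator is a stated world, not a tuning dial; its defaults are
the reference scenario used throughout the tests.

- **F-model frequencies.** Per locus an ancestral vector is drawn from
  a flat Dirichlet; each pool then draws
  Dirichlet(p_anc (1−F)/F) — five wild clusters at F = 0.15 and one
  crop pool at F = 0.30, 26 loci, 5–15 alleles per locus with
  even-stepped integer codes emulating repeat sizes. A coalescent
  simulation would add nothing here: the downstream inference consumes
  allele frequencies, not genealogies.
- **Genotypes.** 50 diploids per pool in Hardy–Weinberg; hybrids (~10%
  of the wild sample, F1 and BC1 per cluster) follow diploid genetics:
  the ancestry vector is decomposed into two parental gamete
  distributions (greedy split of the doubled ancestry mass, largest
  contributions first), so an F1 is heterozygous crop/wild at every
  fixed difference and a BC1 carries one pure wild gamete — drawing
  every gene copy i.i.d. from the ancestry vector would violate this
  and make "F1" genotypes occasionally homozygous crop. Missingness
  (default 2%, strictly below the 20% retention threshold) masks both
  alleles of a call jointly, matching microsatellite dropout. Each wild
  cluster's individuals are spread round-robin over 4 sampling sites so
  that site-level analyses and landscape regressions have enough
  distinct covariate rows.
- **Dispersal pedigree.** Founders uniform on a rectangle (km, mapped
  to lat/lon around 47°N 2°E; planar vs great-circle error is
  negligible at these extents); constant population size; mothers
  uniform, fathers by a Gaussian pollen kernel (no selfing), offspring
  displaced by a Gaussian seed kernel with *reflecting* boundaries
  (absorbing edges would thin the margins). No mutation, selection,
  linkage, or overlapping generations. Smaller kernels give larger Sp
  in expectation; the monotonicity suite samples pollen/seed sigmas of
  0.4/0.2, 1.2/0.6 and 3.6/1.8 km — spanning realistic insect-pollination
  and bird/gravity seed-dispersal scales — over 25 generations.
- **Landscape link.** Orchard count and area are drawn log-normally
  with correlation 0.9 on the log scale (mirroring their strong
  collinearity in regional statistics, the reason models 1 and 2 are
  separate). The expected per-site introgression probability is
  exp(beta0 + beta_d·density + beta_n·orchards + beta_dn·density·orchards),
  rescaled so the most exposed site sits at `max_rate` (the rescale is a
  constant factor, so it is absorbed by the intercept and preserves the
  log-linear form). Individual hybrid status is then Bernoulli, and
  hybrid individuals get F1/BC1-like crop-ancestry values while pure
  trees get small positive estimation noise. That baseline noise is
  deliberate realism — ancestry estimates of pure trees are never
  exactly zero — and it makes the site-level mean response *not*
  exactly log-linear in the covariates: the Bernoulli chain therefore
  supports sign recovery of the interaction (its dominant, planted
  feature), while the coefficient-sign recovery suite plants effects
  under the correctly specified Poisson response, which is the property
  the GLM machinery actually claims.
- **Visitors.** Six insect orders with taxon pools summing to 86; the
  intensive management class draws from pools shrunk by
  exp(−management_effect) with a one-taxon floor; the observation split
  defaults to 59:247 out of 306.

What a green test establishes — and does not. The synthetic pure
individuals are *exactly* pure, clusters are exchangeable draws from a
shared ancestral pool, and loci are independent; real data have
low-level background admixture, mutation-model artefacts, null alleles
and genotyping error, none of which are modelled. Passing the recovery
suite therefore establishes the correctness of the estimators and the
internal consistency of the chain, not field-accuracy of any particular
threshold.

## Numerical conventions and degenerate inputs

Seeds: every stochastic entry point takes a seed and is byte-
reproducible; the pipeline fans a master seed into fixed per-stage
offsets so stages can be rerun in isolation. Permutation p-values are
bounded below by 1/(n_perm + 1). Drift parameters F ∈ {0, 1} are
rejected (degenerate Dirichlet concentration). K = 1 admixture
degenerates to posterior-mean sample frequencies with unit memberships.
Monomorphic-only data make kinship undefined (error) and the
heterozygote-deficit test NA with a flag. Alignment tie-breaks go to
the lowest column index. GLM rank deficiency errors name the aliased
term; IRLS uses a relative deviance tolerance of 1e-8 with at most 100
iterations.

## Known limitations

Advanced-generation backcrosses are not identifiable from ~26
microsatellites and are not claimed (the thresholds capture early
generations only). The spatially explicit clustering prior (CAR/TESS)
and DIC are out of scope; spatial signal is assessed through the
kinship module. No MCMC convergence diagnostics beyond the exported
log-likelihood trace. Kriged map rendering is replaced by a plain
inverse-distance-weighted grid export.
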