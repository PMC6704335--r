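---
title: "Imputed metagenomics of stratified gut microbiome cohorts: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imputed metagenomics of stratified gut microbiome cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imputome)
```

This vignette documents the models behind each stage of the pipeline,
the parameters that matter, the numerical conventions, and the design
decisions taken where the design was genuinely open. It states no
empirical result beyond what the package's tests and drivers themselves
compute.

## The scientific setting

The pipeline analyzes 16S rRNA amplicon cohorts in which samples belong
to one of three constitution groups (Vata, Pitta, Kapha) and one of two
gender strata, and every comparison is run within a gender stratum.
Marker-gene data observe taxa, not genes; the imputation step borrows a
reference gene-content matrix (taxon × gene family copy numbers) to
predict the community's functional repertoire, after correcting read
counts for 16S operon copy number. Everything downstream — attribution,
traits, signature discovery, networks — operates on those predicted
profiles, so all conclusions inherit the usual caveat of imputed
metagenomics: they describe functional *potential* inferred from
taxonomy, not measured gene abundance.

## Metagenome imputation

For counts $x_{so}$, copy numbers $c_o$ and gene content $g_{ok}$:

$$F_{sk} = \sum_o \frac{x_{so}}{c_o}\, g_{ok}.$$

The operation is linear in abundances and scale-equivariant per sample
(tested properties). OTUs missing a copy-number annotation default to 1
with a warning — the convention used for unannotated reference tips,
preferred over dropping samples. Pathway collapse sums gene families
into each pathway they map to, *without* splitting multi-mapped
families; mass is therefore conserved exactly when the map is a
partition and can only grow under multi-mapping. Set analysis of
detected functions uses "nonzero in at least one sample of the group"
as the default presence rule; the rule is configurable because
published analyses rarely state their inclusion threshold, which makes
absolute presence counts irreproducible in general.

## Taxon attribution

Attribution works on the same normalized abundances. For taxon $t$ (at
phylum or class rank), level-1 category $c$ and sample $s$,

$$A_{tcs} = \sum_{o \in t}\ \sum_{k \in c} \frac{x_{so}}{c_o}\,g_{ok},$$

and two percentages are averaged unweighted over samples: the share of
the category total (AAF) and the share of the grand total over all
five categories (AAT). Averaging proportions first and then taking the
mean — rather than pooling masses — is what makes each AAF column sum
to 100 and each taxon's summed AAT equal its printed per-taxon total;
published attribution tables are internally consistent only under this
definition, which fixed the choice. The grand total runs over all five
level-1 categories, including "Unclassified", which is retained as a
first-class category because reference catalogues carry one.

## Organism traits

Trait shares are abundance-weighted means of per-taxon memberships in
$[0,1]$; binary annotations are the synthetic default but continuous
memberships are accepted, since trait-inference services emit
coverage-thresholded continua. Shares are ratios, hence invariant to
per-sample rescaling. Mutually exclusive families (oxygen tolerance;
gram stain) partition the annotated fraction of the community. The
phylum breakdown of a trait is reported both ways a figure might
normalize it (within trait, via shares; within sample, via the trait
profile) because that normalization is usually unstated in
publications.

## Signature discovery

### Rank tests plus LDA effect size

Features are rescaled per sample to relative abundance × 10⁶, screened
by tie-corrected Kruskal–Wallis tests at α = 0.05, and checked for
pairwise directional consistency with two-sided midrank Wilcoxon tests:
the *strict* mode requires the top-mean class to beat every other class
significantly, the *less-strict* mode requires at least one such win.
Effect sizes follow the published discriminant-analysis recipe: over 30
bootstrap rounds of 2/3-per-class subsampling, a linear discriminant is
fitted and each feature scored by half the sum of its absolute
class-mean difference and the absolute difference of class-mean
discriminant scores projected through its unit-normalized coefficient;
multi-class inputs take the maximum over class pairs, and the reported
score is $\log_{10}(1 + \text{mean round score})$ with the conventional
threshold 2.0.

One ordering choice deviates from a literal reading of the published
workflow: effect sizes are computed once on the Kruskal–Wallis-passing
set, and the pairwise-consistency mode filter is applied afterwards.
Every emitted record still passes all three gates at the same
thresholds, but the joint discriminant fit no longer depends on the
mode — which guarantees that strict output is a subset of less-strict
output on any input and seed, a property a mode-dependent fit cannot
offer. A related, intentional property of the pinned formula is that a
feature's score is *not* a function of that feature alone: through the
discriminant coefficient it inherits part of the dominant axis of
separation (proportional to its sample correlation with that axis).
This is why the screen must run first; effect sizes of unscreened noise
features co-fitted with a strong signal are not meaningful.

### ANOVA route

Per-feature one-way fixed-effects ANOVA with η² = SS_between/SS_total,
Tukey–Kramer studentized-range pairwise p-values (valid for unequal
group sizes), and Benjamini–Hochberg correction across the features of
one level, retaining q ≤ 0.05. The published description of the filter
("q-value filter > 0.05") is read as *retain* q ≤ 0.05 — the standard
usage; the printed phrasing is inverted. P-values that underflow to
zero are floored at 1e-300.

### Importance ranking

The low-count filter keeps features with a count ≥ 2 in ≥ 20% of
samples; the low-variance filter then drops `floor(0.10 · m)` of the
survivors with the smallest inter-quartile range (the floor makes the
rule a deterministic integer; ties resolve by input order). Cumulative
sum scaling divides each sample by the sum of its counts up to the
median of its nonzero counts, × 1000, preserving zeros and within-sample
rank order. The ensemble classifier itself is an off-the-shelf
random forest (500 trees) behind a seam; only the filters, the scaling
and the ranking contract (stable sort on mean decrease in out-of-bag
accuracy, lexicographic ties) are bespoke.

## Co-occurrence networks

Within each (group, gender) stratum, Pearson correlations are tested
against a permutation null: each iteration shuffles every feature
column independently once and recomputes the full correlation matrix,
so one shuffle serves all pairs — $O(B(mn + m^2))$ rather than
per-pair shuffling, and exchangeability is preserved. Two-sided
p-values use add-one smoothing, $(\!\#\{|r_b| \ge |r_{obs}|\} + 1)/(B+1)$,
so p is never exactly zero; zero-variance features get p = 1 and
self-pairs are never tested. Edges are kept at p < 0.01 with both
correlation signs retained.

Edge and degree bookkeeping uses *ordered-pair* (doubled) counts: every
published edge, degree and density figure for these networks is even or
satisfies density = E/(N(N−1)) exactly under that convention, which
the package reproduces digit for digit (the acceptance script
recomputes the published densities from the published counts; one
printed female density is inconsistent with its own node/edge counts by
a factor of 10 and is treated as a typo). Diameter is taken on the
largest connected component, since disconnected graphs otherwise have
infinite diameter while published tables print finite ones.
Centralization is the Freeman formula $\sum_i (d_{max} -
d_i)/((n-1)(n-2))$ computed directly from degrees — 1 for a star, 0 for
regular graphs — rather than a library's differently normalized
variant; the three-node path (centralization 1) pins the convention.

## The synthetic cohort generator

The generator emulates the study design: 63 females (29 Vata, 11 Pitta,
23 Kapha) and 50 males (13, 18, 19), 113 samples in all. Counts follow
a Dirichlet-multinomial: per-sample Dirichlet draws around phylum-
structured mean compositions (Firmicutes 0.55, Bacteroidetes 0.33, four
minor phyla) with concentration `dispersion`, then a multinomial at
`sequencing_depth`. Gene content is sparse Poisson with phylum-specific
rate profiles, so the dominance of the two major phyla over most
functions emerges naturally; copy numbers are uniform on 1–7; traits
are assigned per taxon from per-phylum probabilities (e.g. anaerobes
dominate Firmicutes and Bacteroidetes, gram staining follows phylum).

Planted effects are realized through dedicated low-abundance *marker
OTUs* (two per planted function, each ~0.1% of the community) whose
gene content concentrates on the planted function (30 copies) while the
function's background gene content is attenuated tenfold; the marker
abundance is multiplied by the fold-change in the target stratum. This
keeps the realized function-level fold close to the nominal one while
leaving the rest of the community almost untouched. When whole
pathways are planted, the drivers and tests balance the planted
function load across groups so the compositional depression of
unplanted features is symmetric and does not masquerade as signal.

Defaults — depth 10⁴, dispersion 300, 150 background OTUs, 200 gene
families, 30/10 pathway ids — were chosen once for a realistically
overdispersed cohort with enough power for recovery experiments; no
published dispersion or depth figures exist for the emulated study, so
these are the package's own study conditions. Every block of the
generator (composition, counts, copy numbers, taxonomy, gene content,
hierarchy, traits) draws under its own seed derived from the single
config seed; this keeps the whole bundle reproducible from one integer
while making stages that do not depend on the planted effects (notably
the hierarchy) identical between a null and a planted configuration —
which is what lets an experiment select pathways from a null draw and
then plant them under the same seed.

What the generator does *not* emulate: real phylogenetic correlation of
gene content, uneven sequencing depth, zero-inflation beyond what the
Dirichlet-multinomial produces, batch effects, or compositional
covariance between specific taxa. Passing recovery tests therefore
demonstrates the pipeline's correctness and calibration under a clean
overdispersed compositional model, not performance on real data.

## Validation strategy and problem sizes

Correctness is anchored three ways. First, hand-checkable oracles: a
triple-loop matrix product for imputation; brute-force BFS shortest
paths, triangle counts and degree formulas for network metrics;
textbook four-point values for the Kruskal–Wallis statistic (H = 2.4)
and η² (0.8); closed-form single-feature LDA scores. Second,
published-table identities: the density identity against the six
reported stratum networks, and the attribution accounting identity
(per-taxon totals equal summed per-category attributions; the two
dominant phyla in the female reference table stand at 65.94 and 32.25,
a 2:1 ratio). Third, simulation calibration at deliberately modest
sizes chosen to keep the full suite fast: permutation-test edge rates
on 30 independent features × 40 samples with B = 1000 over 20
replicates (compared to the 0.01 nominal within three binomial standard
errors); rank-test type-I error on 1000 null features; null cohorts at
the full 113-sample design for the false-signature budget of the
less-strict route (≈ α·m); and pathway recovery at fold 8 with two
planted pathways per group over three seeded cohorts, scored for
sensitivity and false discovery against the planted truth with
spillover pathways (those sharing a multi-mapped planted family)
excluded from both counts. Study-scale parameters (B = 10000 network
permutations) remain the defaults of the pipeline configuration; the
drivers and tests state smaller B explicitly where they use one.

## Known limitations

* Gene-content imputation is only as good as the reference matrix; the
  package deliberately implements no nearest-taxon search or ancestral
  state reconstruction — reference content is an input.
* The LDA effect size couples co-selected features (see above); scores
  should be read as a ranking device above a threshold, not as
  per-feature effect estimates.
* Permutation p-values are exchangeable-null tests of the marginal
  correlation; they are not compositionality-aware (no log-ratio
  transform), matching the published method rather than improving it.
* Absolute "detected function" counts depend on an unstated presence
  threshold and are not comparable across pipelines.
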