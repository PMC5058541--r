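---
title: "Methods: diploid male production and genetic diversity under sl-CSD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diploid male production and genetic diversity under sl-CSD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slcsd)
```

## The biological model

Hymenoptera are haplodiploid: males normally develop from unfertilized,
haploid eggs and females from fertilized, diploid eggs. Under single-locus
complementary sex determination (sl-CSD), sex in a fertilized egg is decided
by heterozygosity at one gene, *csd*: heterozygotes become females and
homozygotes become diploid males. In the parasitoid wasp *Venturia
canescens*, which motivates this package, diploid males are viable but
sterile, and females that mate with them produce only sons. Because the
chance that two mates share a *csd* allele rises as allelic diversity falls,
the diploid male proportion among genotyped males,

$$\mathrm{DMP} = \frac{n_\text{diploid}}{n_\text{diploid} + n_\text{haploid}},$$

acts as a read-out of genetic erosion in small, isolated or captive
populations ("diploid male vortex" dynamics).

The package implements the complete genetic workflow around this quantity:
detecting diploid males from microsatellite heterozygosity, quantifying how
often that detection fails, computing mixed-ploidy diversity statistics, and
relating DMP to habitat type and diversity with a nested binomial GLM. A
forward population simulator supplies synthetic surveys with known truth for
every stage.

## Ploidy calling and its error model

A male heterozygous at one or more loci of the marker panel must be diploid;
a male homozygous everywhere is called haploid. Calls require at least
`min_typed` amplified loci (default 8 of the 10-locus panel; the threshold
is a parameter because both "at least eight loci" and "at most one failed
locus" conventions appear in survey practice).

The false-haploid probability of a diploid male is, per locus,
$P(\text{hom}) = F + (1 - F)\sum_i p_i^2$, where $F$ is the male's
inbreeding coefficient (the kinship of his parents) and $\sum_i p_i^2$ the
homozygosity-by-state; independent loci multiply. `sibling_kinship_haplodiploid()`
derives $F = 1/4$ for a brother--sister pair by recursive pedigree
enumeration (haploid individuals transmit their single maternal genome), and
is cross-checked in the tests against a forward gene-drop simulation.
`all_homozygous_probability()` accepts either raw allele-frequency tables
($\sum p_i^2$) or published expected heterozygosities ($1 - H_e$): published
tables usually print only $H_e$, and the two pathways differ slightly when
frequencies are unevenly distributed, so both are first-class. On the
packaged 10-locus panel with $F = 1/4$ the probability is
$\approx 1.7 \times 10^{-3}$ — small enough that heterozygosity-based
calling is reliable.

DMP interval estimates default to the exact Clopper--Pearson method (it
reproduces the published interval for the pooled survey, where the Wilson
score interval differs in the last digit); Wilson is available as an option.

## Mixed-ploidy diversity statistics

Haploid males contribute one gene copy and diploids two, so gene-copy
counting underlies every statistic. Expected heterozygosity uses Nei's
unbiased correction $\frac{n}{n-1}(1 - \sum \hat p_i^2)$ on gene copies;
observed heterozygosity is defined over diploids only, since a haploid's
heterozygosity is undefined.

The Hardy--Weinberg test is the exact conditional (Levene) probability test:
given the allele counts, the probability of each genotype table is
$$P(a) = \frac{N!\,\prod_i m_i!\;2^H}{(2N)!\,\prod_{i \le j} a_{ij}!},$$
and the p-value is the mass of tables no more probable than the observed
one. Tables are enumerated completely while the enumeration stays below a
work budget (`max_enum` completed tables, with total explored nodes capped
at 20 times that); beyond it the null is sampled by Monte-Carlo pairing of
the observed gene copies with the unbiased estimator $(k+1)/(n_{mc}+1)$,
which is also floored away from zero so that Fisher's combination across
populations is always finite. Linkage disequilibrium uses a G statistic on
the genotype-by-genotype table with a permutation null.

Null alleles follow the standard genotyping model: a non-amplifying allele
of frequency $r$ turns visible/null heterozygotes into apparent homozygotes
and null/null genotypes into blanks. `null_allele_em()` fits $(p, r)$ by
expectation-maximization; because EM approaches the boundary $r = 0$ only
hyperbolically, the implementation compares the converged likelihood with
the likelihood at $r = 0$ (when no blanks force $r > 0$) and snaps to the
boundary when it is not worse. The tests check the estimator against a
brute-force likelihood grid and in a parameter-recovery experiment
($r = 0.2$, $n = 500$).

Allelic richness is rarefied to a standard number of gene copies $g$
(per-locus minimum across populations, matching how richness is made
comparable across unequal samples):
$\sum_i \left[1 - \binom{N - N_i}{g} \big/ \binom{N}{g}\right]$, evaluated
with log-gamma binomials. Private alleles are those observed in exactly one
population.

Because most diploid-only software and several statistics need two alleles
per individual, `merge_haploid_pairs()` pools pairs of haploid males into
"false diploids" without changing allele frequencies. Pairing is
deterministic (lexicographic id) — allele counts are invariant to the
pairing order, and determinism makes runs reproducible; a seeded shuffled
mode exists for sensitivity checks. An odd male is dropped and logged.
`population_summary(mode = "males_merged_pairs")` chains calling, exclusion,
merging and all statistics into the survey-table layout.

## The DMP--diversity model

`dmp_glm()` fits, on counts $(n_\text{diploid}, n_\text{haploid})$ per
population, the binomial logit model with habitat-type intercepts and
habitat-nested slopes of allelic richness and private-allele number. Survey
designs routinely make parts of this design unidentifiable — a habitat whose
covariate is constant (captive populations with zero private alleles), or a
habitat with as many parameters as populations — so aliased columns are
detected through the pivoted QR factorization of the IRLS fit and reported
explicitly, never silently absorbed.

Terms are tested with type-II likelihood-ratio statistics that respect
marginality: the reference model for a term contains every term not
containing it, and the statistic is the deviance drop the term adds over
that reference. We chose this form (rather than dropping a term from the
full model while keeping interactions that contain it) because with
habitat-nested slopes the containing interactions absorb the habitat
intercepts, leaving a drop-from-full test of the habitat main effect with
essentially no content; the marginality form is also what the standard
analysis-of-deviance routine used in this literature computes, and the test
suite cross-checks against `car::Anova(type = 2)`. Degrees of freedom count
estimable columns only; a fully aliased term is reported with df = 0 and a
note. Quasi-complete separation is flagged when a coefficient exceeds 10 on
the logit scale.

Habitat-level comparisons use the tie-corrected Kruskal--Wallis test,
pooled-SD Cohen's d (with the conventional negligible/small/medium/large
labels), Welch's t, the Yates-corrected two-proportion test and
Benjamini--Hochberg FDR control — all delegated to base R's implementations
behind stable, validated interfaces.

## The forward simulator

`simulate_population()` advances discrete, non-overlapping generations.
Females are monoandrous; with probability $\alpha$ a female mates a brother
(same mother) when one is alive, otherwise a uniformly random adult male.
Clutch sizes are Poisson (mean 8); each egg is fertilized with probability
$\varphi$; fertilized eggs receive a paternal *csd* allele and become
females (heterozygous) or sterile diploid males (homozygous), unfertilized
eggs become haploid males. Females mated to diploid males produce only
haploid sons, as observed in *V. canescens*; an `excluded` mode removes
diploid males from mating entirely. Adults are truncated uniformly at
random to a carrying capacity, and a binomial fraction of adults can be
replaced each generation by migrants drawn from the founder allele pool (a
deliberately simple stand-in for dispersal from a large, stable source).
The *csd* locus is never genotyped — no marker for it exists in this
species — and exists only as simulator truth.

Under panmixia with $k$ equally frequent *csd* alleles, a mother is
heterozygous by construction, the sperm allele matches one of her two with
probability $2/k$, and the offspring is then homozygous with probability
$1/2$: the fraction of diploid males among fertilized eggs is $1/k$. This
closed form is the main calibration law and is verified by simulation for
$k \in \{2, 5, 10\}$.

Marker genotypes (10 loci, 2--12 founder alleles per locus) are inherited
Mendelianly. Founder frequencies default to a geometric series with ratio
0.7, chosen once so that panel heterozygosities span roughly 0.45--0.88 as
in real microsatellite panels; a Dirichlet option draws frequencies instead.
Genotyping noise is applied at survey time (`sample_trap_survey()`): missing
scores at a per-genotype rate, and null alleles carried in the founder pool
that score visible/null genotypes as apparent homozygotes.

Four presets encode the study histories: `mainland` (200 foundresses,
capacity 1000, 2% migration), `island` (30 foundresses, capacity 200,
closed), `captive_large` (120 foundresses, closed mass rearing, 20
generations) and `captive_small` (11 foundresses, 18 generations). Founder
numbers and generation counts for the captive presets follow the documented
rearing histories; capacities, the migration rate and $\alpha = 0.05$
(sib-mating exists but no quantitative rate is documented, so a small
nonzero value was fixed once) are the package's own choices. All presets
share a species-level pool of $k = 20$ *csd* alleles, so habitat contrasts
emerge from demography, not from assumed input differences.

What the simulator does **not** emulate: spatially explicit dispersal,
trapping attraction bias, thelytokous (asexual) lineages, overlapping
generations, allele-size mutation, and genotyping artefacts beyond missing
data and null alleles. Passing pipeline tests on simulated surveys therefore
demonstrates internal consistency of the estimators under the stated model,
not robustness to every feature of field data.

## Numerical and design choices

* Monte-Carlo p-values use $(k+1)/(n+1)$ and are never exactly zero;
  combined tests consequently cannot produce infinite chi-squares, which is
  deliberate.
* Probability comparisons in the exact HW test carry a $10^{-7}$ log-scale
  slack so that ties of equal-probability tables are counted as "no more
  probable".
* The EM boundary snap compares log-likelihoods with a $10^{-7}$ slack.
* Rarefaction binomials are evaluated via `lchoose`, exact to well below
  $10^{-9}$ relative error at survey sizes.
* All randomness flows from explicit seeds through an RNG-state-preserving
  wrapper; package functions never disturb the caller's RNG stream, and the
  full pipeline is byte-reproducible from its configuration.
* Default problem sizes in the shipped tests and the acceptance script
  (e.g., Monte-Carlo sizes of a few thousand, 12 replicate surveys of 150
  males for the habitat contrast, 100 replicates for slope recovery) were
  chosen so each experiment has comfortable statistical power for the
  property it checks while remaining quick on a single CPU; each can be
  scaled up through function arguments.

## Known limitations

* The exact HW enumeration is feasible only for small allele counts; beyond
  the work budget the Monte-Carlo branch takes over (with its own sampling
  error, controlled by `n_mc`).
* The misassignment probability treats loci as independent; linked markers
  would make it optimistic.
* The nested GLM's aliasing pattern depends on the survey design; with very
  few populations per habitat, slope terms are routinely dropped, and the
  reported type-II table must be read together with the aliasing notes.
* Null-allele estimation attributes all blanks at a locus to null
  homozygosity; systematic amplification failure inflates the estimate.
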