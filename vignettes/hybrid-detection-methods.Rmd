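---
title: "Detecting and classifying wild x domestic admixture: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and classifying wild x domestic admixture: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Anthropogenic hybridization between wild populations and their domestic
relatives — wolves and dogs being the canonical case — is a conservation
concern, but management decisions require more than a binary "hybrid or not":
a first-generation hybrid, a third-generation backcross with marginal dog
ancestry, and a pure wolf call for very different actions. `hybridgate`
implements a standardized workflow that turns multilocus codominant
genotypes (typically 39 or 12 microsatellites) into three operational
management categories, with the classification thresholds derived from
simulations rather than convention, and with quantified type I (pure called
admixed) and type II (admixed called pure) error rates.

The workflow has five stages:

1. **Reference selection** (`filter_reference_candidates`,
   `qc_filter_genotypes`): candidate wild and domestic reference individuals
   are retained only with complete genotypes and a membership coefficient
   above 0.99 to their own cluster, a deliberately conservative rule that
   keeps older admixed animals out of the reference pools.
2. **Hybrid simulation** (`build_class_ladder`): from parental allele
   frequencies, Mendelian gamete sampling generates pure parentals (PW, PD),
   F1, F2 and eight backcross generations toward the wild population
   (BC1W–BC8W). BC8W retains an expected `0.5^9 < 0.2%` domestic ancestry,
   bracketing anything detectable from a few dozen loci.
3. **Bayesian assignment** (`admixture_fit`, `assign_one_by_one`): a K = 2
   admixture model with independent allele frequencies, run one query at a
   time against the full reference panel.
4. **Threshold derivation** (`performance_grid`,
   `select_recent_threshold`, `select_pure_threshold`): an empirical
   performance analysis over candidate q-thresholds.
5. **Classification and reporting** (`classify_individuals`, `error_rates`,
   `integrate_evidence`): three-way classification plus corroborating
   evidence from uniparental markers and the K-locus.

A parallel genotype-frequency-class model (`genoclass_fit`) provides an
independent method check over five classes (PW, PD, F1, F2, BC1W).

## The admixture model

For individual $i$, locus $l$ and allele copy $a$, the model assumes a
latent cluster of origin $Z_{ila} \in \{1, 2\}$ with
$\Pr(Z_{ila} = k) = q_{ik}$, and $x_{ila} \mid Z_{ila} = k \sim p_{k,l,\cdot}$
with independent allele frequencies per cluster. Priors are
$p_{k,l,\cdot} \sim \mathrm{Dirichlet}(\lambda)$ with $\lambda = 1$,
$q_i \sim \mathrm{Dirichlet}(\alpha, \alpha)$ with a single shared $\alpha$
learned by random-walk Metropolis (proposal SD 0.025) under a flat prior on
$(0, 10]$ — the standard defaults for this model family. Missing loci
contribute nothing to the likelihood (no imputation); loci that happen to be
monomorphic are retained, since they only add a constant. The Gibbs sampler
(compiled code, one latent-origin update per allele copy per sweep, conjugate
Dirichlet updates for $p$ and $q$) reports the posterior mean membership to
the wild cluster $q_{iw}$ and an equal-tailed 90% credibility interval from
thinned draws (thin 10). The interval is widened minimally when required to
bracket the mean, which matters only for posteriors piled against 0 or 1.

Runs are **unsupervised**: reference individuals carry no prior population
flags. Cluster labels are anchored afterwards (`align_clusters`) by flipping
any retained sample in which the wild references' mean membership to cluster
1 falls below 0.5. On realistic reference panels the chain never visits the
mirrored labelling, so this coincides with a single whole-run flip; on tiny
toy problems the posterior is genuinely bimodal and per-sample flipping is
the correct relabelling. The alternative — supervised runs with population
priors — was considered and rejected because the unsupervised run reproduces
the published reporting and makes no extra assumptions.

### One-by-one assignment

Each query is assigned in its own MCMC run containing all references plus
that single query. This guarantees that the number and composition of other
query genotypes cannot distort allele-frequency estimation or the query's
posterior, and makes runs embarrassingly parallel. Per-query seeds derive
deterministically from the configuration seed and the query's identifier, so
results are independent of query order.

### Chain lengths

Full-length runs in this tradition use 5×10^4 burn-in + 5×10^5 sweeps. The
package default (`mcmc_config()`) is a desk-scale chain of 5×10^3 burn-in +
2×10^4 sweeps, chosen as the package's standard problem size after checking
that (i) independent desk-scale runs agree to |Δq| < 0.02 per individual and
(ii) posterior means on small enumerable problems match exact collapsed
enumeration to < 0.01 (see below). The full-length settings remain one
argument away.

## The genotype-frequency class model

Early hybrid classes differ not only in expected ancestry but in how
ancestry is arranged within loci: an F1 is heterozygous wild/domestic at
every locus, an F2 is (1/4, 1/2, 1/4) for (2, 1, 0) wild copies, a first
backcross (1/2, 1/2, 0). `genoclass_fit` implements the five-class mixture
model over these genotype-frequency vectors with latent per-individual class,
per-locus origin state, and the two parental frequency sets. Priors follow
the two standard choices: "Jeffreys-like" (Dirichlet concentration
1/(number of alleles) per locus; 1/5 for class mixing proportions) or
"uniform" (1 for both); on separated data the two are indistinguishable, and
the package tests assert this. The chain default is 2×10^3 burn-in + 10^4
sweeps (full-length: 10^4/10^5).

Two modelling notes. First, the five-class set deliberately omits deeper
backcrosses: BC2W and older are *expected* to be absorbed into BC1W or PW —
the model's genotype-frequency classes cannot express them — and the test
suite asserts this absorption rather than treating it as an error. Second,
the class labels are symmetric under swapping the two parental pools except
for BC1W; orientation is fixed by initialising reference-labelled
individuals at their parental classes. This is an initialisation, not a
prior: the likelihood is untouched, matching the convention of running the
model "without any individual prior information".

## Deriving the q-thresholds

Candidate thresholds run from 0.500 to 0.995 in steps of 0.005, plus a
terminal 0.999. For each nested split of the simulated ladder into a "pure"
side (starting at {PW} and growing one backcross generation at a time, never
including BC1W, F2 or F1) and an "admixed" side, two quantities are computed
at each threshold $t$, calling an individual admixed when $q_{iw} < t$:

* **efficiency** — the proportion of truly admixed individuals correctly
  identified (sensitivity);
* **accuracy** — the proportion of individuals called admixed that truly are
  (positive predictive value), vacuously 1 when nothing is called admixed;
* **performance** — their product.

The published definition of "accuracy" is worded once PPV-like and once
recall-like; the package defaults to the PPV reading (the product then
penalizes both missed hybrids and false alarms) and exposes a symmetric
`two_sided` variant that averages both sides' rates, for sensitivity
analysis. Splits whose best performance reaches 0.90 are retained, and the
**recent-admixture threshold** is the highest threshold attaining any
retained split's maximum performance — the conservative choice, maximizing
recognition of recent hybrids; ties inside a plateau resolve to the
plateau's top. (A plausible alternative rule — preferring the split with the
smallest admixed side — would select a much lower threshold and was
rejected: it contradicts the conservative intent and the published
selection.) A second, **pure threshold** is the minimum individual $q_{iw}$
observed among reference and simulated wild parentals, floored to three
decimals so that the defining individual still classifies as pure.

Classification is then: $q_{iw} \ge t_{pure}$ → pure (operational pure,
no action); $t_{recent} \le q_{iw} < t_{pure}$ → older admixed
(introgressed, low priority); $q_{iw} < t_{recent}$ → recent admixed
(operational hybrid, high priority). Boundary values belong to the upper
class, exactly as published (0.955 and 0.995 for the 39-locus panel).

## The synthetic reference generator

The empirical wolf/dog reference genotypes behind the published analysis are
not redistributable, so the package generates synthetic reference
populations with controlled differentiation: per locus, an ancestral
frequency vector from a symmetric Dirichlet(1), then each population's
frequencies from $\mathrm{Dirichlet}(\pi_{anc} (1-F)/F)$ — the multiallelic
Balding–Nichols construction, which makes $F$ the expected fixation index
without needing a mutation-drift simulation. Defaults: 39 loci, 8 alleles
per locus, $F = 0.30$ (published wolf–dog microsatellite differentiation is
of this order), 100 wild + 95 domestic references sampled under
Hardy–Weinberg. `realized_fst` (a Weir–Cockerham θ estimator, implemented
here because no installed dependency provides it for codominant tables)
verifies that realized differentiation lands in [0.2, 0.4].

What the generator does **not** emulate: allele-frequency spectra of real
microsatellites (real panels share most alleles between wolves and dogs;
Balding–Nichols draws with sparse concentrations produce more nearly
diagnostic loci), within-pool substructure (village dogs plus breed dogs),
linkage, and mutation. Consequences: cluster separation and backcross
recovery on the synthetic fixture are, if anything, slightly *sharper* than
on real data, so passing tests demonstrate correct mechanics and qualitative
behaviour — they do not certify per-locus error tolerance on a real panel.
One published quantity is genuinely sensitive to this: the robustness of
individual q values under heavy simulated genotyping error. On the synthetic
fixture, converting ~30% of an F1's or BC1W's heterozygous loci into false
homozygotes shifts its posterior mean q by ~0.05–0.1 on average — an
unavoidable consequence of near-diagnostic loci (a binomial back-of-envelope
gives the same order) — whereas the published full-scale analysis reports
<2% discrepancy. The
package reports the honestly computed value; the corresponding acceptance
check fails on the synthetic conditions and is documented as such rather
than weakened.

## Error simulation

`inject_ado` models allelic dropout at the scoring level: independently per
heterozygous locus call, with probability `rate` one allele (chosen
uniformly) overwrites the other, creating a false homozygote; homozygous and
missing calls are untouched and no allele is invented. `inject_missing`
blanks locus calls (both copies) independently at the nominal rate. The
published error protocol applies "both parameters" at the same nominal
level, read here as: dropout first, then missingness, so a dropped call can
still go missing. Whether the dropout rate applies per allele copy or per
heterozygous call is not specified in the source material; per-heterozygous
call is the declared convention here.

## Numerical and degenerate-input choices

* Allele codes are opaque positive integers; no repeat-length arithmetic.
* Missing data are per locus (both copies), the microsatellite scoring
  reality; the Structure-dialect sentinel is −9 in both columns.
* Allele-frequency estimation is plain counting with support harmonized to
  the union across groups (zero frequency where unobserved); smoothing lives
  in the MCMC priors, not the estimator.
* Gamete sampling for simulated crosses: parental gametes come from
  frequency pools; gametes of simulated hybrids come from sampled
  individuals (pick a parent, transmit one allele per locus), preserving the
  within-individual ancestry correlation that drives the q-value spread of
  backcrosses. Backcross wild-side gametes come from the wild frequency pool
  (equivalent in distribution to sampling simulated PW individuals).
* The samplers use an internal xoshiro256++ generator seeded from the
  configuration, so fits are reproducible from (data, seed) alone and
  results do not perturb or depend on R's global RNG stream.
* `run_stability` quantifies between-run Monte Carlo variation (mean ± SD of
  |Δq| across individuals and run pairs); at desk scale it stays below 0.02,
  at full scale it is an order of magnitude smaller.
* Group-level 90% intervals pool the posterior draws of the group's
  individuals (the source material reports group CIs without a formula; this
  is the declared convention).
* Welch's t-test is used wherever mean CI widths are compared between
  groups, since the variance-equality assumption is not defensible there.

## Problem sizes used by the tests

The packaged checks run the full workflow at a standard desk scale chosen as
the package's own test conditions: the 39-locus/8-allele/F = 0.30 reference
fixture above, 50 simulated F1 plus 14–20 individuals per remaining ladder
class assigned one-by-one with 5×10^3 + 2×10^4 chains, and a 60-individual
robustness subset rerun under 30% dropout + 30% missingness. Exact-oracle
comparisons (collapsed enumeration for the admixture model, closed-form
class likelihoods for the genotype-class model) run on 2-locus and 30-locus
toys where enumeration is feasible.

## Known limitations

* K is fixed at 2 and frequencies are independent; no correlated-frequencies
  model, no LOCPRIOR, no multi-run averaging (unnecessary at the observed
  run stability).
* The genotype-class model supports exactly five classes; deeper backcrosses
  are identifiable only through the admixture-threshold route.
* Evidence flags (mtDNA, Y haplotype, K-locus, phenotype) annotate but never
  reclassify; conflicting evidence is surfaced, not adjudicated.
* The synthetic generator's realism caveats above apply to every
  fixture-level result.
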