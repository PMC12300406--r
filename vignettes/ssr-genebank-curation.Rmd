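---
title: "Curating germplasm collections with SSR fingerprints: methods and design"
author: "ssrcurate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating germplasm collections with SSR fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrcurate)
```

# The problem

Clonally propagated fruit-tree collections (peach is the motivating case)
accumulate curation errors over decades: the same cultivar maintained
under several names (synonymy), different genotypes filed under one name
(homonymy), mislabelled trees, and undocumented duplicates within and
between collections. A panel of a dozen multi-allelic SSR markers is the
standard, affordable instrument for auditing such collections: it
fingerprints every accession, quantifies marker informativeness, verifies
declared pedigrees, and resolves broad population structure.

`ssrcurate` implements that audit end to end on a single container class,
`SSRGenotypes` (a `SummarizedExperiment` of loci × accessions with two
integer allele-size assays), and ships a seeded synthetic-collection
generator so that every stage can be validated against known truth.

# Diversity statistics

For each locus with allele frequencies $p_i$ estimated over the $2N$
allele copies of the $N$ typed accessions:

* effective allele number $N_e = 1/\sum p_i^2$, Shannon index
  $I = -\sum p_i \ln p_i$;
* Nei gene diversity $H_e = 1 - \sum p_i^2$ and observed heterozygosity
  $H_o$; fixation index $F = (H_e - H_o)/H_e$ ($F = 0$ reported for
  monomorphic loci). We use the uncorrected Nei form because it
  reproduces the $F$–$H_o$–$H_e$ relation of published report tables
  within rounding;
* Botstein $PIC = 1 - \sum p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2$;
* probability of identity (HWE form)
  $PI = \sum p_i^4 + \sum_{i<j} (2 p_i p_j)^2$ and discrimination power
  $PD = 1 - PI$; the multilocus identity probability is the product of
  per-locus $PI$ over the loci actually compared. The sibling-adjusted
  $PI$ variant is deliberately not used;
* parentage non-exclusion probabilities in the Jamieson–Taylor power-sum
  forms (the Cervus NE-1P/NE-2P quantities), validated in the test suite
  against exhaustive enumeration over all genotype configurations;
* rare alleles are those with frequency below 0.05 (a frequency, not a
  percentage), and private alleles are carried by exactly one *distinct
  multilocus genotype* — so a clone group counts as a single carrier and
  does not disqualify its own private alleles.

Hardy–Weinberg deviation is assessed by a Monte Carlo exact test: the
chi-square distance between observed and HWE-expected genotype counts is
compared with its null distribution obtained by re-pairing the observed
allele copies at random. Monomorphic loci return $p = 1$ by convention.

Report tables round half-up to two decimals, matching the convention of
published summary tables.

# Fingerprint matching and curation classification

Two accessions *match* when their genotypes are identical at every locus
typed in both and at least `min_overlap` loci were compared (default 8 of
12: a handful of loci can never declare identity). Because missing data
makes the relation non-transitive, groups of indistinguishable accessions
are the connected components of the match relation; non-clique components
are flagged rather than split, since a curation report deals in whole
groups.

Same-name entries with matching profiles are replicates, and only the
first in file order is retained; same-name entries with different
profiles are homonyms and receive deterministic alphabetic suffixes
(`_a`, `_b`, ...) in file order.

Each match group is classified by documented-cause precedence:
known sport mutation > known synonymy > shared declared parent >
mislabel. The collection error rate is

$$ 100 \cdot \frac{\#\{\text{accessions in mislabel groups}\} +
  \#\{\text{homonym entries}\}}{\#\{\text{accessions analyzed}\}}, $$

with the denominator taken before replicate consolidation. The published
figure this mirrors is not exactly derivable from any printed count
combination, so the package documents this formula and reports what it
computes.

# Band-sharing similarity and UPGMA

The Lynch band-sharing index is applied to co-dominant SSR data through
its natural dominant encoding: each distinct allele at a locus is one
band, so a homozygote contributes one band and a heterozygote two. For
profiles $x, y$ restricted to mutually typed loci,
$S = 2|B_x \cap B_y| / (|B_x| + |B_y|)$. Untyped loci are deleted
pairwise rather than listwise, preserving large panels with scattered
missing data. Whether the historical NTSYS SimGend routine normalizes
per locus before averaging is not documented; this package uses global
band-count normalization and says so here.

Clustering is UPGMA on $d = 1 - S$ with merge heights $d/2$, leaves at
height 0, and ties broken toward the lexicographically smallest pair of
cluster labels, which makes the dendrogram deterministic and invariant to
input order. The tree exports to standard Newick (branch length = parent
height − child height; labels with spaces are quoted) and the test suite
round-trips it through an independent parser and checks the
agglomeration against `stats::hclust(..., "average")`.

# Mendelian pedigree verification

Per-locus rules, each validated against brute-force enumeration in the
tests:

* one candidate parent: compatible iff child and parent share an allele;
* two parents: compatible iff the child pair can take one allele from
  each parent (all four assignments tried);
* selfing: the child must be producible by two independent draws from
  the parent's pair;
* clones delegate to the fingerprint match (missing-tolerant identity).

A record *matches* when zero non-excusable incompatible loci remain over
at least `min_loci` (default 8) compared loci — full matching, with an
optional mismatch-tolerance parameter defaulting to 0. With
`allow_null = TRUE`, configurations explainable by a shared
non-amplifying allele (e.g. child and parent homozygous for different
alleles) are flagged *excusable* instead of failed; enabling it can only
relax verdicts, never harden them. Open-pollinated offspring are checked
against the declared seed parent only, with a secondary scan reporting
which of them are also compatible with pure self-pollination. Match
percentages are always recomputed from the counts at one decimal.

# Admixture model and choice of K

`runGibbs()` fits the STRUCTURE-style admixture model: individual $i$
owns membership proportions $q_i$ over $K$ clusters, cluster $k$ owns
allele frequencies $p_{kl\cdot}$ per locus. A Gibbs sweep samples the
cluster of origin of every observed allele copy given $(Q, P)$, then
$P \sim \mathrm{Dir}(\lambda + \text{counts})$ and
$Q_i \sim \mathrm{Dir}(\alpha + \text{origin counts})$. Missing copies
are skipped (ignorable missingness). Design choices:

* **independent allele frequencies** per cluster rather than the
  correlated F-model: substantially simpler and sufficient for
  recovering strong subpopulation structure at desk scale; the
  correlated prior is listed as future work;
* **fixed $\alpha = 1$** rather than a Metropolis update, keeping runs
  fast and fully determined by the seed;
* **desk-scale defaults** `burnin = 2000`, `mcmc = 8000`. These are the
  package's working defaults for simulated panels of ~150 accessions ×
  12 loci, where the chain equilibrates within a few hundred sweeps;
  production panels should raise both (the software family this mirrors
  is customarily run at 100,000/500,000).

Model choice follows the Evanno procedure: per K, replicate runs yield
$\ln \hat P(X|K) = \bar L - s_L^2/2$ from the post-burn-in likelihood
trace; then $\Delta K = |L''(K)|/s(K)$ with mean-based differences and
sample (n−1) standard deviation across replicates. $\Delta K$ is
undefined at the boundary K values and wherever the replicate sd is zero
(flagged); the selected K is the interior argmax, ties toward smaller K.
$\Delta K$ is invariant to shifting or positively scaling all lnP values,
which the tests assert. Replicate label switching is undone by aligning
Q-matrix columns to the first run (exhaustive permutation search for
K ≤ 8, greedy assignment beyond), and the consensus Q is the row-wise
renormalized mean.

# The synthetic generator

`simulateCollection()` is first-class, tested code, not a fixture. It
emulates the statistical structure of a real two-collection peach panel:

* 12 loci with 8–19 alleles on an even (dinucleotide) size ladder —
  ladder spacing is cosmetic only;
* three subpopulations whose frequencies are drawn from a Dirichlet
  centred on the base frequencies with concentration $(1-d)/d$
  (an F-model with divergence $d$; default 0.15, with 0.30 used as the
  "strongly diverged" setting in the recovery experiments);
* excess homozygosity produced mechanistically by generations of partial
  selfing (default rate $s = 0.42$, giving equilibrium
  $F = s/(2-s) \approx 0.27$, the panel-level inbreeding the peach
  literature reports for autogamous collections). The breeding
  population is kept larger than the sample (≥150 per subpopulation) so
  that lineage coalescence does not flood the sample with accidental
  duplicate genotypes;
* curation errors: sport/clone pairs (documented via `known_sport_of`),
  synonym pairs (documented via a shared tag), mislabelled duplicates
  (undocumented), at desk-scale defaults of 4/3/8 per 150 accessions;
* null alleles as allele-specific dropouts (heterozygote carriers become
  apparent homozygotes, null homozygotes become missing) — exactly the
  mechanism the parentage null-excusal rule is designed for;
* 5% missing cells, matching the per-locus typing rates of published
  panels.

What it does **not** emulate: mutation (sports differ at zero loci here,
real sports may differ at a few), linkage between loci, genotyping error,
allele-size homoplasy, and collection-specific sampling structure.
Passing tests therefore demonstrate algorithmic correctness under the
stated model, not robustness to every artefact of real capillary data.

`simulatePedigreeOffspring()` draws Mendelian offspring (cross, self,
open pollination with a random pollen donor, clone) whose declared-check
closure properties are asserted in the tests.

# Numerical and edge-case policy

* Allele pairs are canonicalized ascending on entry; half-typed cells are
  rejected, never padded.
* Fractional allele sizes are rounded on read with a warning (capillary
  outputs are binned upstream).
* Accepted missing tokens on read: `"- -"`, `"-"`, empty, `NA`, `0`;
  written as `"- -"`.
* Monomorphic loci: $F = 0$, HWE $p = 1$, $PI = 1$, non-exclusion 1.
* Zero mutually typed loci between two profiles: no identity claim
  (warned), similarity undefined (imputed as 0 with a warning only
  inside UPGMA, which needs a complete matrix).
* The tag-offset correction subtracts a non-negative constant from every
  present allele (30 bp for tagged-primer protocols); whether a given
  register is already corrected is not always documented, so the default
  offset is 0 and the operation errors rather than produce non-positive
  sizes.
* All stochastic components (simulator, HWE permutations, Gibbs) take
  explicit seeds; replicate seeds inside `structureScan()` are derived
  deterministically from the top-level seed.

# Problem sizes used in validation

The shipped validation runs at desk scale, chosen so the full suite is a
coffee-break job on one core: synthetic collections of 60–200 accessions
(500 for the inbreeding-recovery check), K scans 1–6 with 3 replicates at
`burnin = 1000–2000`, `mcmc = 4000–8000`, 100–200 Monte Carlo replicates
for the HWE type-I experiment, and exhaustive enumeration oracles
restricted to ≤4 alleles per locus, where enumeration is exact and
instant. The K-recovery experiment repeats the entire scan under several
seeds and requires K = 3 in the large majority.

# Worked example

```{r example, eval = FALSE}
sim <- simulateCollection(n_accessions = 150, seed = 42)
x <- sim$genotypes

diversityStats(x)                      # per-locus marker panel
groups <- buildMatchGroups(x)          # indistinguishable accessions
report <- classifyGroups(groups, accessionMeta(x), n_total = ncol(x))
report$error_rate

scan <- structureScan(x, k_range = 1:6, reps = 3, seed = 42)
selectK(evannoTable(scan$lnP))         # expected: 3
```

# Known limitations

* The admixture sampler omits the correlated-frequencies prior and alpha
  inference, so its lnP values are not numerically comparable with the
  reference software's — only the model-choice behaviour is mirrored.
* Identity testing is exact-match only; near-matches (one-locus
  differences, as sports can show) are a reporting concern, not an
  identity claim.
* No linkage disequilibrium, null-allele frequency estimation, or
  likelihood-based paternity (LOD) — exclusion only.
* The Lynch-index dominant encoding of co-dominant data slightly
  compresses similarity between heterozygote-rich profiles; it is kept
  for continuity with the historical band-sharing methodology.
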