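---
title: "Methods: selection and driver analysis of mutations in lysine PTM sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: selection and driver analysis of mutations in lysine PTM sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind `ptmsel`, the parameters that
matter, what the synthetic-data generator does and does not emulate,
and the numerical and design choices made where more than one
reasonable option existed.

# Scope and data model

The package analyses somatic missense SNVs relative to lysine
acetylation and ubiquitination sites. All coordinates are 1-based
protein residue positions and all intervals are closed; this convention
holds in every file format and every function. The central container is
the S4 class `PTMDataset`: an `AAStringSet` proteome, per-residue
disorder and conservation tracks, a PTM site table, a mutation table,
and optional domain, predictor-call, network, survival and gene-set
tables. Only protein-level data are handled; genomic-to-protein
conversion, isoform selection and nucleotide mutation signatures are
out of scope.

A PTM site is a lysine at position $p$; its region is
$[\max(1, p-7), \min(L, p+7)]$ and overlapping regions are merged into
maximal disjoint intervals (implemented with `IRanges::reduce` and
cross-checked in the test suite against brute-force per-residue
marking). A mutation is classified by the minimal absolute offset to
any same-protein central lysine: 0 direct, 1–2 proximal, 3–7 distal,
otherwise unrelated. When two sites tie at the nearest distance their
PTM types are unioned; the category depends only on the distance, so
the tie-break affects annotation, not inference. Sites supplied as
15-mers are matched exactly (every occurrence yields a site; one
mismatch discards the record); a `_`-padded 15-mer matches only at the
corresponding protein terminus, the convention we adopt for sites close
to a protein end.

# Selection statistics

Four proteome-wide contrasts share one resampling engine. Restricted to
proteins that carry the tested modification, the observed statistic is
compared with a null that redistributes each protein's mutations
uniformly over that protein's residues, *preserving per-protein
totals*. Resampling within proteins rather than pooling across the
proteome avoids confounding by per-gene mutation burden; a pooled
variant would mistake burden differences between modified and
unmodified genes for positional selection. Because a uniformly placed
mutation falls in a region with a fixed per-protein probability, each
shuffle is realised as one binomial draw per protein — distributionally
identical to placing every mutation and orders of magnitude faster.

Empirical p values always use the add-one rule
$p = (1+b)/(1+B)$, so $p \ge 1/(B+1)$ and never equals zero. The
default $B$ is 100{,}000 shuffles per test. One-sided "greater than
expected" alternatives are used throughout, matching the directional
questions (enrichment, concentration, higher conservation).

The fold change of the region test is the ratio of per-residue rates
inside versus outside merged regions. The domain test reports observed
count over null mean instead, because its natural complement (sequence
outside domains) can be empty; with domains covering everything the
fold change is exactly 1. The conservation contrast uses ratios of
means (not medians) within each disorder stratum, with the null
shuffling the PTM/non-PTM labels of mutated residues inside the
stratum; strata with fewer than two mutations in either group are
reported as not applicable, and a cohort with only one label is a hard
error. The predictor-ensemble association scores each SNV 0–5 by
counting deleterious calls and tests the consensus-by-PTM 2×2 table
with a one-sided Fisher exact test (hypergeometric tail); the reported
odds ratio is $ad/bc$, with 0.5 added to every cell only when a zero
cell occurs, and that substitution is flagged.

# The per-gene driver test

For a gene with at least one site and one mutation, per-residue counts
$y_i$ are regressed on the disorder indicator with a log-link Poisson
model fitted over **all** residues of the gene; the expected active
count is $E = \sum_{i \in \text{regions}} \hat\mu_i$ and the observed
count $O$ is compared through the exact upper tail
$P(X \ge O \mid E)$ (`ppois`, no normal approximation — the test suite
pins it to a term-by-term summation oracle at $10^{-10}$). A constant
disorder track or a non-convergent fit falls back to the uniform rate
total/length, which makes $E$ = total × regional coverage in closed
form; the fallback is flagged in the output. Fitting the null over all
residues (rather than excluding regions) keeps that closed form exact
but means part of a true regional excess is absorbed into $E$: with
regional coverage $q$ and a planted rate fold $f$, $O/E$ converges to
$f/(1+(f-1)q)$, not $f$. The practical consequences are that the test
is conservative (null cohorts produce almost no false positives at BH
FDR < 0.05) and that modest per-gene mutation counts carry less power
than the planted fold suggests; the acceptance cohorts therefore give
planted drivers on the order of 50–150 mutations each, comfortably
above the ≥30 floor at which recovery is assessed. The significance
test uses the combined direct+proximal+distal region count; per-category
counts are reported for inspection but not separately tested, avoiding
a three-way multiplicity correction the data rarely support. A second
mode counts only central-lysine substitutions, so signal planted purely
in flanks vanishes — a deliberate sensitivity probe. The site-density
covariate is computed and available but excluded from the default null:
with sites defining both the covariate and the tested quantity it would
absorb signal.

The known-gene permutation test bins the universe into 100
equal-occupancy quantile bins by mutation count (ties broken by gene id
for determinism) and draws, per permutation, a gene set matching the
known genes' bin profile. Within a bin the draw is uniform without
replacement, so the per-bin overlap with the detected set is
hypergeometric; the implementation sums independent `rhyper` draws per
bin, which is exactly the same distribution as sampling gene identities
and scales to $10^7$ permutations (the default is $10^5$; both are
supported). With a single bin the statistic collapses to the classical
hypergeometric, which the tests verify.

# Pathway enrichment

Gene sets are restricted to their PTM-bearing members (unmodified
proteins carry no regions and are discarded), then filtered to 3–1000
members and at least two separately mutated proteins — the latter so a
single heavily mutated driver cannot carry a set. The background
per-residue rate is total regional mutations over total regional length
across the union of all pathway-annotated PTM-bearing proteins (the
pathway-annotated union, not the whole proteome, so genes never
mentioned in any set do not dilute the background). Each set's
$\lambda$ is that rate times the set's summed region length — a
length-based expectation; a per-protein-rate alternative was considered
and rejected as it would let one long unmutated member mask short
mutated ones. Both size filters and the mutated-protein filter are
independent predicates of a set, so their order cannot change the
retained rows. The enrichment-map export connects significant sets
whose overlap coefficient $|A\cap B|/\min(|A|,|B|)$ reaches 0.5, the
conventional default for this visualisation; thematic grouping of the
exported nodes is a manual step by design.

# Survival-correlated network modules

Within each cancer type with at least 10 patients, every mutated
network gene with at least `minSeedCarriers` carriers seeds a greedy
search. Carriers are patients with at least one direct, proximal or
distal mutation in a module gene; unrelated mutations never define
carriers. Growth adds the neighbour minimising the two-group log-rank p
value, requires strict improvement, stops at 20 nodes, and breaks ties
by smallest p then lexicographic gene id, making the search fully
deterministic; a neighbour whose carriers add nothing cannot change the
statistic and is never added. Seeding from mutated genes only is a
choice: an unmutated seed defines an empty carrier group and no
statistic. The log-rank statistic is the standard 1-df chi-square with
tied events evaluated against the shared risk set; it is implemented
in-package as a vectorised core over a presorted cohort scaffold
because the greedy loop evaluates it thousands of times, and the test
suite pins it to both a from-definition oracle and
`survival::survdiff` at $10^{-8}$.

Family-wise control deliberately avoids per-module BH on raw log-rank
p values: the greedy search optimises over seeds and unions, so raw p
values are strongly selection-biased. Instead, each of 100 permutations
shuffles the gene labels over the network nodes (topology, carrier
sets and survival data untouched), reruns the *entire* search, and
records the best module p; a module is significant when its p beats
the permutation minima with empirical p < 0.05 (add-one rule, computed
within its cancer type). This min-p null absorbs the search's
selection effect: it asks whether the observed gene-to-topology
assignment concentrates survival signal better than a random
assignment of the same carrier sets ever does. The per-module sign of
observed minus expected carrier events is reported (positive = reduced
carrier survival) but never enforced.

# The synthetic-data generator

The generator is first-class, tested code; its defaults define the
study conditions under which every claim in the test suite is made.

| parameter | default | rationale |
|---|---|---|
| `lysineFreq` | 0.06 | lysine abundance in vertebrate proteomes |
| `ptmSiteRate` | 0.25 | sites per lysine among PTM-bearing proteins |
| `sharedSiteRate` | 0.11 | shared acetyl+ubiquityl fraction in public site compendia |
| exclusive acetyl : ubiquityl | 1 : 4 | composition of public lysine-PTM compendia |
| `burdenMean`, `burdenDispersion` | 20, 2 | negative binomial; over-dispersion typical of exome cohorts |
| `hypermutatorFraction`, `hypermutatorMultiplier` | 0.03, 20 | a small extreme-burden tail so any outlier filter is exercised |
| `disorderSegmentRate` | 0.3 | disordered fraction; segments geometric, mean 20 residues |
| `conservationShift` | +0.15 | Beta-distributed scores (concentration 5, mean 0.45) shifted upward inside PTM regions |
| `driverPtmEnrichment` | 3 | per-residue region rate fold in driver genes |
| `networkEdgeProb` | 0.05 | sparse background interactome |
| `moduleHazardRatio` | 3 | exponential event hazard multiplier for module-mutation carriers |
| `censoringRate` | 0.3 | right-censoring uniform before the event time |
| `baselineHazard` | 1/1000 per day | median survival near two years |

Protein lengths are gamma (shape 4) around the configured mean,
minimum 30. Mutations pick a protein proportionally to its placement
weight (length, with driver-gene region residues up-weighted by the
planted fold), then a residue uniformly within the chosen compartment,
so the within-driver in/out rate ratio equals the planted fold by
construction — which is exactly how the recovery tests estimate it. The
alternate amino acid is uniform over the 19 non-reference residues;
codon structure and trinucleotide signatures are intentionally not
modelled. Per-sample burdens are negative binomial with the
hypermutator tail multiplied in. The network is Erdős–Rényi restricted
to edges touching at least one PTM-bearing protein, plus a random
spanning tree over the planted module, which is therefore always
connected. The planted module is drawn from the planted driver genes
whenever the driver set is large enough: survival-relevant modules are
made of recurrently mutated proteins, and without that concentration a
module's carriers would be statistically indistinguishable from the
carrier sets scattered over the rest of the network, leaving nothing
for the permutation filter to detect. Survival times are exponential;
carriers of planted-module region mutations have their hazard
multiplied by the configured ratio. Patient identity equals tumour
sample identity. Conservation scores and survival times are generated
at $10^{-4}$ resolution so that writing and re-reading a bundle is
lossless.

Stage seeding: the proteome, truth, cohort, network+survival and
gene-set stages derive their RNG seeds from the configuration seed plus
fixed small offsets, so each stage is independently deterministic and
the whole bundle is byte-stable. One interface note: the
network-and-survival generator takes the cohort as an explicit fourth
argument, because carrier-dependent hazards cannot be assigned without
the mutation table.

What passing tests on this generator do **not** show about real data:
real cohorts have nucleotide-context mutation processes, correlated
site positions (clusters beyond the Bernoulli-per-lysine model),
non-exponential survival with clinical covariates, and interactomes
with hub structure and study bias. The generator's purpose is to make
the statistical machinery falsifiable — calibration under its own
null, recovery of planted effects — not to imitate any particular
cohort.

# Numerical choices and degenerate inputs

* Empirical p values: add-one rule everywhere; never 0.
* Poisson and hypergeometric tails: exact cumulative distributions
  (`ppois`, `fisher.test`), pinned to independent summation /
  enumeration oracles in the tests.
* Benjamini–Hochberg via `p.adjust`, pinned to a from-definition
  oracle.
* Region test with an empty complement (a protein that is all region),
  a lysine contrast with no unmodified lysine, a missing domain table,
  or a stratum with fewer than two mutations in a group: reported as
  not-applicable results with a reason, not errors.
* Silent (K→K) records are rejected at load; mutations whose reference
  amino acid contradicts the sequence are dropped and counted, and the
  run continues.
* The hypermutated-sample rule is pluggable because the threshold is a
  cohort-level judgement with no canonical definition: the default
  flags samples with log10 burden above the median by more than 3 MADs,
  and `"none"` disables filtering; whatever rule ran is recorded in the
  run manifest.
* Greedy search and permutation filter are deterministic given the
  analysis seed; all ties break by (p, lexicographic id).

# Problem sizes used by the test suite

The suite checks calibration and recovery at sizes chosen to make each
claim statistically meaningful while keeping the default run desk-scale:
400 replicate null cohorts at 1000 shuffles for bootstrap calibration
(nominal 5% level, acceptance band 2–8%); fold-recovery at ≥10⁵
mutations (±0.1); 500-gene cohorts with 5 planted drivers for the
driver scan; 200 null gene sets plus one planted set over 20 replicate
cohorts for pathways; and 20 replicate cohorts of a planted 8-gene
module (hazard ratio 3, 200 patients, 100 network permutations,
seeding restricted to genes with ≥2 carriers) for the survival search.
Production analyses would raise `nShuffles` to 10⁵ and gene
permutations to 10⁷, both plain configuration changes.

# Known limitations

* Protein-level only; no genomic coordinates, no isoform logic.
* The per-gene null absorbs part of a true regional excess into $E$
  (see above), so per-gene fold estimates read from $O/E$ are
  attenuated by design; the bootstrap fold changes are the calibrated
  effect-size estimates.
* The pathway expectation is length-based; a set of short, densely
  modified proteins is compared against the global regional rate, not
  a protein-matched one.
* The module search's permutation null preserves carrier sets exactly;
  it controls for topology reassignment, not for misspecification of
  the survival model itself.
* Phosphorylation sites, PTM enzyme annotations and multivariate
  survival models are out of scope.
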