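---
title: "Methods: causal network reconstruction from a segregating cross"
author: "crossBN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: causal network reconstruction from a segregating cross}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossBN)
```

# The problem

In a segregating population — here a haploid yeast cross with ~120
progeny strains genotyped at ~2,000 biallelic markers — gene-expression
levels and metabolite concentrations are heritable quantitative traits.
Correlation among traits cannot, by itself, say which trait drives
which: directed graphs that encode the same conditional independences
(Markov-equivalent structures) fit observational data equally well.
The genetic perturbations segregating in the cross break that symmetry.
DNA variation is fixed at meiosis and cannot be caused by a transcript
or a metabolite, so a locus that affects two traits acts as a causal
anchor: orderings in which the trait "causes" the genotype are
inadmissible, and the remaining orderings differ in likelihood.

crossBN implements the full path from genotypes and traits to a directed
consensus network: LOD-score QTL scanning with permutation thresholds,
the three-model anchored causality test, structure priors assembled from
genetics, TF-binding sites, protein complexes and metabolic reaction
graphs, stochastic score-based Bayesian-network search with ensemble
averaging and loop removal, and subnetwork extraction with gene-set
statistics. A synthetic-cross generator provides ground-truth networks
so that every stage is testable.

# QTL scanning

For trait $y$ and biallelic genotype $g \in \{0,1\}$, the LOD score is
the $\log_{10}$ likelihood ratio of a two-mean versus one-mean Gaussian
model at the MLE, computed from residual sums of squares:
$\mathrm{LOD} = \tfrac{n}{2}\log_{10}(\mathrm{RSS}_0/\mathrm{RSS}_1)$.
A genome scan records the peak marker per (trait, chromosome).
Genome-wide significance comes from permuting segregant labels and
pooling per-trait maxima; the default thresholds mirror the study
design: LOD 3.9 for genome-wide significance at FDR 0.05 and LOD 2.8 as
the suggestive cutoff at which causality tests and priors operate. An
empirical-FDR mode (mean permuted exceedances over observed exceedances,
scanned over thresholds) is provided as well.

A peak is *cis* when it falls within 50 kb (closed interval) of the
measured gene's position on the same chromosome, else *trans*;
metabolites have no genomic position and are never cis. Trans hot spots
are detected in fixed 20-kb bins with a binomial tail test
(success probability = bin width / genome width per linked trait) and a
Bonferroni flag across bins. The original study reports hotspot
positions at ~10-kb resolution but states neither its bin width nor its
test; the binomial-bin procedure is this package's own stand-in, and
both constants are arguments.

# The anchored causality test

For traits $T_1, T_2$ sharing locus $L$, three models are scored:

* **causal** $L \to T_1 \to T_2$: $T_1$ normal about genotype-class
  means; $T_2$ a linear regression on $T_1$;
* **reactive** $L \to T_2 \to T_1$: the mirror image;
* **independent** $L \to T_1$, $L \to T_2$: each trait normal about its
  own class means, with a pooled slope of $T_2$ on the class-centred
  $T_1$ absorbing residual correlation from other shared loci or
  environment.

Each model's penalized statistic is
$S_i = -2\ln\hat L_i + p_i \ln n$ (BIC), with $p_1 = p_2 = 6$ and
$p_3 = 7$ parameters counted directly from the mean/variance
structures. The smallest $S_i$ wins; an exact tie (within $10^{-9}$)
falls back to "independent" with a flag — conservative for downstream
prior construction. Because the anchor genotype is observed, the
genotype probability $P(L)$ is common to all three models and cancels
from score differences; it is dropped.

Two numerical points deserve note. First, all MLEs are closed-form:
class means, OLS slopes, and $1/n$-normalised residual variances. For
the independent model the class-mean/pooled-slope estimator satisfies
every first-order condition of the joint likelihood (the cross terms
vanish because residuals sum to zero within each genotype class), so
the two-stage closed form *is* the exact joint MLE; the test suite
confirms agreement with direct numeric maximisation to $10^{-6}$.
Second, residual variances are floored at the smallest positive double
so that noiseless (deterministic) relationships produce finite,
overwhelmingly dominant scores instead of infinities.

Bootstrap reliabilities resample segregants with replacement and report
the fraction of resamples each model wins; resamples that lose one
allele class entirely are redrawn (at most 100 attempts) and the
fractions renormalised.

A property worth understanding: when the anchor is destroyed by
permuting $g$, the two directional models still beat the independent
model on parsimony (the independent model spends a seventh parameter
that buys no fit), but the causal-versus-reactive choice collapses to a
coin flip. The anchor's value is directional asymmetry, and the test
suite asserts exactly that.

# Structure priors

Priors are per-edge weights in $(0,1]$ entering the network score as
additive log-weights; weight 0 forbids an edge outright. Sources:

1. **Genetic asymmetry.** Where a cis-linked gene and a trans-linked
   gene share a suggestive locus (peaks within one 20-kb bin width of
   each other on the same chromosome), the trans gene may not parent
   the cis gene. The pairwise-distance reading of "within one bin"
   avoids quantization artifacts at bin boundaries.
2. **Causality reliabilities.** For tested pairs,
   $w(A\to B) = \sum_l r_l(\text{causal}) / \sum_l(\text{all three})$,
   the reactive analogue for $w(B\to A)$; when independence dominates,
   both are further shrunk by one minus the independence share.
3. **eQTL-signature complexity.** Remaining coincident pairs get
   $w(A \to B) = n(B)/(n(A)+n(B))$ with $n(\cdot)$ the count of
   suggestive linkages — simpler signatures are likelier causes.
4. **TF-binding sites.** A permutation-calibrated correlation cutoff
   (the $1-p_\mathrm{cut}$ quantile of per-permutation maximum $|r|$)
   counts each TF's correlated targets; TF weights are proportional to
   that count (scale-free prior), and TFs with no correlated target
   contribute nothing. TFs absent from the trait set are represented by
   the responding gene ranked highest by within-set causal support,
   tie-broken by LOD at the set's shared locus.
5. **Protein complexes.** k-clique percolation (default $k=3$, the
   smallest non-trivial clique size) infers complexes from PPI edges;
   a TFBS carried by at least half a complex's members extends to all
   members; complexes not integrated through TF priors get uniform
   within-complex weights $w_u$ (default 0.5).
6. **Metabolic reactions.** KGML files yield a bipartite
   enzyme-metabolite graph; all-pairs shortest distances are computed
   by repeated boolean matrix multiplication; the prior that an enzyme
   gene affects a metabolite decays as $w_{\max} \cdot 2^{-(d-1)}$ —
   the simplest form that anchors direct catalysis at $w_{\max}$ and
   halves per reaction step.

Sources merge by taking the per-pair maximum, with genetic exclusions
dominating any positive weight. Unlisted pairs carry a background
weight of 0.05, which doubles as a mild sparsity prior
($\ln 0.05 \approx -3$ per edge on the log scale). The exact functional
forms of (2), (3), (4) and (6) are rendered from prose constraints
("the shorter the distance, the stronger the prior", weights
"proportional to the number of correlated traits"), so each constant is
exposed as an argument.

# Network search, consensus, and loop removal

The local score of node $v$ with parent set $P$ is the Gaussian
log-likelihood of a linear model of $v$ on $P$ (genotype parents enter
as 0/1 indicators), minus the BIC penalty
$\tfrac12 (|P|+2)\ln n$, plus $\sum_{u \in P} \ln w(u \to v)$. Scores
are computed from a precomputed centred cross-product matrix, so each
evaluation solves at most a 3×3 system; results are cached per
(child, parent-set) bitmask. The parent limit defaults to 3.

Search starts from the empty graph and proposes uniformly random
single-edge changes (add / delete / reverse), accepting additions and
deletions only when they strictly improve the total score and keep the
graph acyclic. Reversals are also accepted when score-neutral: scores
tie exactly across Markov-equivalent orientations, and a strict rule
would freeze the chain in whichever orientation the proposal order
reached first — unable, for example, ever to exit a fully connected
three-node graph into the strictly better v-structure. Neutral
reversals let the chain walk within an equivalence class while strictly
improving exits, and structure priors that favour one orientation,
remain decisive. An optional simulated-annealing temperature (default
off) is available for rough landscapes.

An ensemble of independently seeded searches (1,000 by default; tests
and the acceptance script use 20–100 to keep runtimes in minutes on one
CPU) is averaged into a consensus containing the directed edges that
appear in strictly more than 30% of runs — the cutoff reported to give
the best precision/recall trade-off in the original simulation work.
The consensus may contain loops; while any remain, the shortest loop
length $L$ is found and, among the edges lying on a loop of length $L$,
the one with minimum frequency (ties broken lexicographically) is
removed. The removed edge is therefore always the most weakly supported
edge of the loop it sits on, and edges on no loop are never touched.
This edge-pool formulation makes the procedure deterministic even when
several shortest loops tie, which lets the test suite demand exact
agreement with an exhaustive cycle-enumeration oracle.

# The synthetic cross

`simulateGenotypes` draws each chromosome as a Markov chain: the first
allele is Bernoulli(0.5) and adjacent markers recombine with the
Haldane fraction $r = (1 - e^{-2d/100})/2$ from their cM distance, with
genetic positions defaulting to 1 cM per 2 kb when only bp are given.
`simulateTraits` evaluates a linear structural-equation model in
topological order: each trait is the sum of $\beta$-weighted parent
traits, $a$-weighted genotypes, and Gaussian noise. Named scenarios fix
the conditions used throughout the tests: `chain` ($L \to T_1 \to T_2$,
$a = \beta = \sigma = 1$, $n = 120$), `independent`, `hotspot` (one
locus driving 24 of 40 traits placed in trans), and `small_net` — a
fixed 30-node, 27-edge DAG of 24 genes and 6 metabolites with ten
cis-anchored driver genes on a 4-chromosome, 10-kb-spaced map. Unit
effects with unit noise give per-edge $R^2$ around 0.5 and trans-linkage
LODs a little above the suggestive threshold — deliberately
middle-of-the-road signal, strong enough to be recoverable and weak
enough that thresholds matter. Scenario *structure* is fixed; the seed
drives only genotypes and noise.

What the generator does not emulate: genotyping error and missingness,
epistasis, non-Gaussian trait distributions, batch structure,
measurement error correlated across traits, and diploid genetics.
Passing recovery tests therefore demonstrates correctness of the
machinery under the stated model, not robustness to everything real
data do.

# Evaluation conventions

Recovery of the `small_net` scenario is scored on the undirected
skeleton (precision and recall of unordered edges), with direction
accuracy reported separately among skeleton-true consensus edges. This
separation is deliberate: without genetic priors many edges are
recoverable only up to Markov equivalence, so folding orientation into
precision would conflate two different failure modes. The paired
prior/no-prior comparison runs both conditions on identical data and
ensemble seeds, with the no-prior arm using the same uniform background
weight so that only the informative prior content differs.

Problem sizes used by the shipped checks: 200 trios per generating
model for causality recovery; 50 random datasets for the score oracles;
500 null traits × 200 permutations for threshold calibration; a 100-run
ensemble (60,000 proposals each) for the main recovery; 20 scenario
seeds × 2 conditions × 20-run ensembles for the paired comparison;
1,000 random cyclic graphs for loop-removal soundness with exhaustive
oracles on ≤ 8 nodes.

# Limitations

* Local conditionals are linear-Gaussian; strongly non-linear or
  discretised regulation is out of scope (a multinomial local score is
  a natural extension).
* The search is a stochastic hill climber with neutral reversals, not a
  posterior sampler; consensus frequencies are ensemble statistics, not
  posterior edge probabilities.
* Single-marker scanning without interval mapping; with dense marker
  maps, interval interpolation adds little.
* Hotspot binning and several prior functional forms are documented
  stand-ins where the source methods are stated only in prose.
* Cataloged gene-set databases are not bundled; enrichment helpers
  accept user-supplied sets.
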