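---
title: "Models and methods behind lignodecay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lignodecay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lignodecay)
```

`lignodecay` implements the comparative-genomic inference stack used to
study how lignocellulose-decay lifestyles evolved in Agaricomycetes
fungi: a birth–death model of gene-family copy-number evolution on a
time-calibrated species tree, an enzyme-repertoire diversity index with
exact small-sample tests, phylogenetic PCA with PERMANOVA, a tuned
weighted k-nearest-neighbour (wknn) classifier that labels ancestral
repertoires with lifestyles, and a rule-based classifier plus marginal
ancestral reconstruction for the catalytic residues of ligninolytic
class-II peroxidases (PODs). This vignette explains the models, their
assumptions, the tunable parameters, and the design decisions taken
where the methodology was genuinely open.

## Gene-family evolution: the birth–death count process

Copy numbers of a gene family evolve along the dated tree as a linear
birth–death process with a single global rate $\lambda$ (events per
gene per million years), identical for gains and losses. Writing
$\alpha = \lambda t/(1+\lambda t)$, the probability that $s$ parent
copies leave $c$ descendants after $t$ My is

$$P(c \mid s, t) \;=\; \sum_{j=0}^{\min(s,c)} \binom{s}{j}
\binom{s+c-j-1}{s-1} \alpha^{s+c-2j} (1-2\alpha)^j ,$$

the $s$-fold convolution of the single-gene kernel
$P(1\to 0)=\alpha$, $P(1\to c)=(1-\alpha)^2\alpha^{c-1}$. The package
builds per-branch transition matrices by that convolution and verifies
them against the closed form and against event-level (Gillespie)
simulation in the test suite.

Likelihoods use Felsenstein pruning over the truncated state space
$\{0,\dots,n_{\max}\}$; $n_{\max}$ defaults to twice the family's
largest observed count with a floor of 10, which keeps the truncation
loss of row-stochasticity below $10^{-6}$ in the regimes exercised.
The root prior conditions on presence of the family at the root
(uniform over $1..n_{\max}$); it is exposed in `bdp_model()` because
the choice is a convention, not data-driven. $\hat\lambda$ maximises
the summed family log-likelihoods by bounded scalar search on
$[10^{-6}, 10]$.

Ancestral repertoires are the joint most-probable assignment
(max-product dynamic programming with backtracking); ties break toward
the smaller count so results are reproducible. Per-branch "Viterbi"
p-values sum every child state whose transition probability is as small
or smaller than the reconstructed transition's — an exact
as-or-less-likely tail over the truncated states, reported without
renormalisation.

Two open choices deserve a note:

* **Family-wide p-values.** The rate-heterogeneity test is Monte
  Carlo: null families are simulated under $\hat\lambda$ and the
  observed family's log-likelihood is ranked among the null
  log-likelihoods with the add-one estimator
  $p=(1+\#\{\ell_{sim}\le\ell_{obs}\})/(n_{sim}+1)$. `bdp_fit()`
  conditions the null on the family's reconstructed root count (a
  point root prior with a state cap shared across families), which
  makes log-likelihoods comparable across families of very different
  sizes and mirrors the conditioning used by the established
  gene-family evolution tools. The unconditional variant remains
  available through `familywide_pvalue()` with any root prior.
* **Scope.** Per-family or per-branch rate classes and count error
  models are deliberately out of scope; the model is the single
  global-rate process.

## Enzyme-repertoire diversity and small-sample tests

The diversity of a repertoire with family counts $n_i$
($N=\sum_i n_i$) is the Brillouin-type index

$$D = \frac{1}{N}\left(\log_2 N! - \sum_i \log_2 n_i!\right)
\quad\text{bits per gene},$$

extended to the non-integer *average* counts that arise when a group
of genomes is summarised, via $\log x! = \log\Gamma(x+1)$. $D$ is
zero exactly when one family carries all genes, order-invariant, and
unchanged by empty families. Group comparisons use the exact one-tailed
binomial and Fisher tests (delegated to `stats`); how a copy-number
comparison maps onto binomial trials and successes is left to the
analyst — the package ships the primitive only, because that mapping is
a modelling decision about the data at hand.

Phylogenetic ANOVA simulates the trait under Brownian motion (rate
and mean from their GLS/ML estimates on the tree) to build the null
distribution of the classical one-way F statistic. Under a star
phylogeny this reduces to an ordinary simulation ANOVA, which is the
oracle used in the tests; its size at $\alpha=0.05$ is verified to lie
in $[0.03, 0.07]$ over 500 null replicates.

## Phylogenetic ordination

`ppca()` follows the generalised-least-squares construction: with
Brownian covariance $C$ from the dated tree, phylogenetic mean
$a = (1'C^{-1}1)^{-1}1'C^{-1}X$ and evolutionary covariance
$R = (X-1a)'C^{-1}(X-1a)/(n-1)$, the loadings are the eigenvectors of
$R$ and scores are $S=(X-1a)V$. Covariance mode is the default —
matching the default of the reference implementation the field uses —
with correlation mode switchable. Counts enter untransformed by
default; whether to log- or rank-transform repertoires first is left
as an explicit user decision since it changes the variance shares the
ordination reports. A $10^{-8}$ ridge is added to $C$ only if it is
numerically singular, with a warning.

Ancestral nodes are projected into the morphospace with
maximum-likelihood Brownian ancestral estimates of each score column
(the root estimate is the GLS mean). PERMANOVA partitions squared
Euclidean distances among the retained components;
$p=(1+\#\{F_\pi\ge F\})/(n_\pi+1)$ under complete label permutation
with a mandatory seed, and pairwise comparisons are
Benjamini–Hochberg-adjusted over all group pairs in deterministic
order. Identical points yield an explicit degenerate flag rather than
a spurious F.

## Lifestyle classification by weighted kNN

The classifier standardises features (z-scores fitted on training data
only — refitted inside every leave-one-out fold), ranks training
points by Minkowski distance with exponent $d$, normalises the $k$
nearest distances by the $(k{+}1)$-th, and converts them to votes with
one of six kernels (rectangular, triangular, epanechnikov, gaussian,
rank, and Samworth-optimal rank weights). Ties at the $(k{+}1)$-th
neighbour are included with $u=1$; class-weight ties resolve
alphabetically. Tuning evaluates $k = 1..25$ for every kernel and
$d \in \{1, 2\}$ — 300 models — by leave-one-out accuracy, with ties
broken toward smaller $k$, the kernel order above, then smaller $d$.
$k$ is capped at 25 to avoid biasing predictions toward the most
abundant class, and Manhattan distance ($d=1$) is typically selected
on count data. The trained model applied to reconstructed ancestral
repertoires yields one lifestyle per internal node plus the full
class-weight vector for auditability.

## POD catalytic-residue toolkit

Class-II peroxidase types are determined by a small set of catalytic
residues read from named alignment columns (all 1-based, following
biologist convention): the distal His/Arg pair involved in activation
by H$_2$O$_2$, the three residues of the Mn$^{2+}$-oxidation site, the
lignin-oxidising surface Trp, a surface Tyr position, and the length
of the C-terminal tail. The decision order is: His/His distal pair →
NPOD; any other non-His/Arg pair → unclassified; then the Mn triad is
looked up (Glu/Glu/Asp canonical, Glu/Ser/Asp, Asp/Gly/Asp,
Asp/Glu/Asp); a surface Trp with a complete acidic triad gives VP,
with a two-acidic triad the atypical VP-a, and with no triad LiP;
without the Trp the canonical triad splits into long and short MnP by
tail length, the alternative triads give the MnP-ESD/DGD/DED
subfamilies, and no triad gives the generic peroxidase GP. Three
artifact decisions are config-exposed and reported in output:

* `tail_threshold = 16` residues past the tail anchor separates MnP-l
  from MnP-s (the literature states only that the subfamilies differ
  in tail length; 16 sits between the short and long tails of the
  reference enzymes).
* VP-a requires the catalytic Trp plus a triad retaining exactly two
  acidic residues; a Trp over the all-acidic Asp/Glu/Asp triad is
  treated as a full VP.
* A surface Tyr without the His/His pair sets an annotation flag
  rather than defining a type.

Ancestral residues come from marginal reconstruction: Felsenstein
pruning per column followed by the standard outside pass, under the
WAG model (exchangeabilities and frequencies taken from the installed
phylogenetics stack) with the stationary root prior, a single rate for
all sites, and gaps treated as missing data. These simplifications —
no gamma rate heterogeneity, no empirical-frequency re-estimation —
are documented divergences from the full ML machinery; they matter
little at the handful of strongly conserved catalytic columns the
classifier consumes. Ancestors are typed from the modal residue per
column; when any decisive column's modal posterior falls below 0.7 the
runner-up type (recomputed with the second-best residue at the least
certain column) is reported alongside, mirroring the two-colour
ambiguity convention of published POD phylogenies. Because tail length
is not reconstructable from catalytic columns, ancestors default to
the short-tail (ancestral) condition via `tail_policy`. Type origins
on the dated species tree are every node whose parent bears a
different type, so convergent appearances are all reported and the
first appearance of a type is its oldest origin.

## The synthetic-data generators

Every pipeline input can be generated with fixed seeds:

* `simulate_tree()` draws a pure-birth tree and rescales it to the
  target root age (default 52 tips, 192 My — the dimensions and crown
  age of the clade this package models).
* `simulate_lifestyles()` evolves the six decay lifestyles by a
  symmetric Mk process from a uniform root. The default rate
  (`q = 0.001`/My to each other state) yields a handful of lifestyle
  transitions across the tree, reflecting the phylogenetic
  conservatism of decay modes; it was chosen once on that reasoning.
* `simulate_counts()` runs an exact event-level birth–death
  simulation per branch, with per-gene gain rate
  $\lambda\, g_{f,\ell}$ in lifestyle $\ell$. Signal therefore enters
  through the process rates, not tip-level noise, so ancestral counts
  and lifestyles remain jointly coherent ground truth for validating
  ancestral-lifestyle prediction. Defaults: $\lambda = 0.002$ per gene
  per My (the order of magnitude typical of fungal gene-family
  turnover on 100-My timescales), 62 focal + 24 background families,
  root counts $1+\mathrm{Poisson}(4)$, seven signal families with
  gain multiplier 4 in their associated lifestyle (the strong-signal
  condition), and an optional overall 10x rate multiplier to plant
  fast-evolving families.
* `simulate_pod_alignment()` evolves neutral columns under WAG and
  overwrites the catalytic columns of each tip with its planted
  type's residue template, gapping the tail region to short (8) or
  long (20) tails.

What the generators deliberately do not emulate: annotation error in
copy numbers, correlated evolution among families beyond the shared
lifestyle signal, lineage-specific rate variation, indel processes in
alignments, and alignment uncertainty. Passing the validation suite
therefore demonstrates correctness of the inference machinery under
its own model class, not robustness to the messiness of real genome
annotations.

## Numerical choices and problem sizes

Transition kernels are computed in signed log-space (the
$(1-2\alpha)^j$ factor changes sign when $\lambda t > 1$); pruning
rescales partial likelihoods per family at every edge, keeping 52-tip
trees far from underflow. Viterbi ties break toward smaller counts;
wknn class ties alphabetically; eigenvector signs are fixed by making
the largest-magnitude loading positive. The validation suite sizes
its simulations to run on a single CPU in minutes: $10^5$ draws for
the kernel check, 300 families for rate recovery (recovering
$\lambda$ within a few percent), 62 families with seven 10x-rate
plants for detection recall, 500 replicates for the size of the
permutation tests, and 200 null families for p-value calibration.
These sizes are the package's validation conditions and are stated in
the test files themselves.

## Known limitations

The birth–death engine assumes equal birth and death rates and one
global rate; families under directional selection are flagged by the
family-wide test rather than modelled. The wknn classifier inherits
the label imbalance of its training tips. POD typing reads a
user-supplied site map; on real alignments the catalytic columns must
be identified from structure-anchored reference sequences before the
toolkit applies. Printed results from any particular genomic study
(total enzyme counts, specific accuracies or variance percentages)
depend on that study's annotation pipeline and data and are not
reproduced by the synthetic conditions here.
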