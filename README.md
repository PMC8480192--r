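# lignodecay

Comparative-genomic inference of lignocellulose-decay lifestyle
evolution in Agaricomycetes fungi.

Wood- and litter-decomposing fungi differ in the repertoires of plant
cell-wall degrading enzymes (PCWDEs) their genomes encode, and those
repertoires carry the signature of their lifestyle — white rot, brown
rot, decayed wood, grass litter, forest litter or mycorrhiza.
`lignodecay` implements the full inference stack needed to go from a
dated species tree plus gene-family copy numbers to a reconstruction
of how decay lifestyles and ligninolytic enzymes evolved:

* **Gene-family evolution** — a linear birth–death model of copy
  numbers with a single global rate λ (events · gene⁻¹ · My⁻¹):
  transition kernel
  `P(c|s,t) = Σ_j C(s,j) C(s+c−j−1, s−1) α^{s+c−2j} (1−2α)^j` with
  `α = λt/(1+λt)`, pruning likelihoods, maximum-likelihood λ,
  joint most-probable ancestral counts, Monte-Carlo family-wide
  p-values for fast-evolving families, and per-branch Viterbi
  p-values for significant expansions/contractions.
* **Repertoire diversity** — the Brillouin-type index
  `D = (1/N)(log₂N! − Σᵢ log₂nᵢ!)` (log-gamma extension for average
  counts), exact binomial/Fisher tests and phylogenetic ANOVA.
* **Phylogenetic ordination** — pPCA in the Brownian-motion metric of
  the tree, projection of ancestral nodes into the morphospace, and
  PERMANOVA with FDR-corrected pairwise lifestyle comparisons.
* **Ancestral lifestyle classification** — a weighted k-nearest-
  neighbour classifier (6 kernels × k = 1..25 × Minkowski d ∈ {1,2};
  300 models tuned by leave-one-out accuracy) applied to the
  reconstructed repertoires of the fast-evolving families.
* **Class-II peroxidase (POD) toolkit** — rule-based typing of PODs
  (LiP, VP, VP-a, MnP-s/l, MnP-ESD/DGD/DED, NPOD, GP) from catalytic
  residues, marginal ancestral reconstruction of those residues under
  WAG, typing of ancestors, and dating of type origins on the species
  tree.
* **Synthetic data** — seeded generators for every input (dated Yule
  trees, Mk lifestyle evolution, lifestyle-linked birth–death counts
  with ancestral truth, planted POD alignments), so the whole pipeline
  runs and is validated without any external data.

## Worked example

```r
library(lignodecay)

# synthetic study: 52 species, 192-My tree, 62 focal + 24 background
# families, lifestyle-linked gain rates
pre <- decay_preset(seed = 1)
b   <- simulate_bundle(pre)

# global birth-death rate of the repertoire
fit <- estimate_lambda(b$tree, b$tip_counts)
fit$lambda
#> [1] 0.002123649

# tune the lifestyle classifier on the seven signal families
sig  <- pre$signal_families
tune <- wknn_tune(b$tip_counts[, sig], b$lifestyles[b$tree$tip.label])
tune$best
#>    k  kernel d  accuracy
#> 53 5 optimal 1 0.8076923

# label the 51 ancestors from their reconstructed repertoires
anc <- sapply(sig, function(f) {
  m <- bdp_model(fit$lambda, max(2 * max(b$tip_counts[, f]), 10))
  ancestral_counts(b$tree, b$tip_counts[, f], m)[b$tree$node.label]
})
pred <- predict_ancestral_lifestyles(tune$model, anc)
mean(pred$label == b$lifestyles[b$tree$node.label])
#> [1] 0.9607843
```

The fitted λ recovers the generating rate (0.002/gene/My) to within a
few percent; the tuned classifier reaches 81% leave-one-out accuracy
on the tips and recovers 96% of the true (simulated) ancestral
lifestyles. `run_pipeline()` chains the same stages from a YAML
config and writes TSV outputs plus a JSON manifest.

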