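# txatlas

Multiscale transcriptome atlases at desk scale: recursive clustering of
expression cohorts into a hierarchy of transcriptional classes,
entropy-based heterogeneity statistics over that hierarchy, hierarchical
similarity scores, and a hierarchical multilabel classifier with
probability consistency enforcement and recalibration.

## The problem

Bulk tumor transcriptomes form structure at several scales at once: major
lineages, histotypes within them, and molecular subtypes within those. A
single flat clustering either merges subtypes or shatters lineages.
txatlas addresses this for computational biologists who want to (i) build
a class *hierarchy* directly from expression data, (ii) quantify how
disordered each class still is, and (iii) classify new samples into the
hierarchy with calibrated, parent-consistent probabilities — all of it
reproducible and testable on synthetic cohorts, with no external data.

## Methods at the core

* **Recursive clustering.** At each node, remove a fraction of
  low-variance genes, embed with UMAP (12 dimensions), cluster with DBSCAN,
  and pick the grid combination (cutoff × neighbours × eps) maximising the
  mean silhouette *s̄* in embedded space. Split only if *s̄* ≥ 0 with ≥ 2
  clusters; stop below 25 members; prune children below 10.
* **Transcriptional entropy.** Per gene *g* and class *c*, a
  fixed-bandwidth Gaussian KDE on z-scored expression evaluated on a
  100,000-point grid gives *S(g,c) = −Σᵢ Pᵢ ln Pᵢ*; entropies are divided
  by the reference-class median and residualised against median expression.
  Classes are summarised by median and MAD over genes.
* **PaWS.** For a node *n* with leaf set *Lₙ* in a hierarchy with leaves
  *L*: `PaWS(n) = (|Lₙ|/|L|) · (log|root| / log|n|)` — inter-tumoral
  heterogeneity as captured by the hierarchy itself.
* **Hierarchical similarity.** With SimGIC weights *w(n) = −log p(n)*,
  `H(v₁,v₂) = Σ w·min(v₁,v₂) / Σ w·max(v₁,v₂)` between membership vectors;
  the one-sided η replaces the denominator by Σ w·v₁ and ignores
  false-positive branches.
* **Classifier.** 1-D conv + dense networks (or a fast logistic backbone)
  with sigmoid outputs over all non-root nodes, binary cross-entropy,
  Adadelta, ensemble mean of three; then parent–child consistency
  enforcement (child ≤ parent) and piecewise-linear recalibration mapping
  each node's precision+recall-optimal cutoff to 0.5.

See `vignettes/multiscale-atlas.Rmd` for assumptions, parameters and
design decisions.

## Worked example

```r
library(txatlas)

# a synthetic two-level cohort: 4 lineages x 2 subtypes, 40 samples/leaf
co   <- generateCohort(TreeSpec(depth = 2, branching = c(4L, 2L),
                                samplesPerLeaf = 40, seed = 21))
norm <- normalizeCounts(co$counts)

# train + calibrate the hierarchical classifier (fast logistic backbone)
ens <- trainEnsemble(norm, co$labels, co$tree, backbone = "logistic", seed = 33)
map <- calibrateEnsemble(ens, norm, co$labels, co$tree, seed = 33)
rep <- predictSamples(ens, norm, co$tree, map)

Y <- multiHotLabels(co$tree, co$labels)
levelMicroF1(co$tree, Y, rep@calibrated[rownames(Y), colnames(Y)] >= 0.5, 1)
#> [1] 1

# a 60/40 mixture of two lineage centroids is flagged as multi-class
a <- colMeans(exprValues(co$counts)[nodeMembers(co$tree, "T001"), ])
b <- colMeans(exprValues(co$counts)[nodeMembers(co$tree, "T002"), ])
mix <- GeneMatrix(matrix(round(mixSamples(a, b, 0.6)), 1,
                         dimnames = list("mix", names(a))))
predictSamples(ens, normalizeCounts(mix), co$tree, map)@calibrated[1, c("T001", "T002")]
#>      T001      T002
#> 0.7146505 0.3508904

# robustness to shallower sequencing: binomial count thinning
depthRobustness(ens, co$counts[seq(1, 320, by = 16), ], co$tree, map,
                fractions = c(1, 0.5, 0.1, 0.01), seed = 7)
#>   fraction    mean_H         sd_H
#> 1     1.00 1.0000000 0.0000000000
#> 2     0.50 0.9932538 0.0006462547
#> 3     0.10 0.9801509 0.0018023635
#> 4     0.01 0.9340733 0.0052487036
```

The micro-F1 of 1 says every first-level lineage call on the training
cohort is correct; the mixture sample carries calibrated probability well
above the 2% secondary-class threshold for *both* constituent lineages;
and the mean hierarchical similarity *H* to the full-depth prediction
degrades monotonically — but gracefully — as counts are thinned to 1%.

Hierarchy discovery works the same way from the other end:

```r
tree <- recursiveCluster(norm, SearchGrid(), minSplit = 25, minKeep = 10,
                         seed = 9)
adjustedMutualInformation(levelAssignment(co$tree, 1)[names(co$labels)],
                          levelAssignment(tree, 1)[names(co$labels)])
```

A thin command-line wrapper over the same functions ships in
`inst/cli/txatlas.R` (subcommands `simulate`, `preprocess`, `cluster`,
`entropy`, `paws`, `train`, `predict`, `evaluate`, `depth-robustness`,
`pipeline`).

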