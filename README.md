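# asrbench

Simulation benchmarking of how multiple sequence alignment (MSA) quality
shapes the accuracy of ancestral sequence reconstruction (ASR) for
proteins.

ASR pipelines infer the sequences of extinct ancestors from extant
sequences placed on a phylogeny — but only after those sequences have been
aligned, and alignment errors flow straight into the reconstructed
ancestors. `asrbench` builds fully controlled test beds in which the truth
is known: it simulates ultrametric birth–death trees with species
sampling, evolves proteins with substitutions and indels while recording
the true alignment of every node (tips *and* ancestors), reconstructs
ancestors by marginal maximum likelihood, and scores both the
reconstructions and the alignments. It is written for molecular
evolutionists and methods developers who want to stress-test ASR under
explicit, reproducible conditions.

## What it computes

**Simulation.** Trees come from a birth–death kernel conditioned on the
number of sampled tips (birth 6, death 3, sampling fraction ρ ∈ (0, 1]),
rescaled so the root-to-tip height (expected substitutions/site) is exact.
Sequences evolve under WAG + Γ (α = 1.8, 4 categories) from a 408-residue
root, with insertions at the L+1 inter-residue slots and deletions at the
L residues, both at configurable rates relative to a substitution rate
of 1, and truncated-Zipf lengths (exponent 1.7, max 20).

**Reconstruction.** Marginal posteriors at every internal node by the
pruning algorithm with discrete-gamma mixing; gap states by a two-state
presence/absence model on the same tree. A column is reported when its
non-gap posterior is ≥ 0.50, emitting the posterior argmax.

**Scoring.** Each reconstructed ancestor is pairwise-aligned to the truth
(deterministic affine Needleman–Wunsch, BLOSUM62, 11/1) and decomposed as

    accuracy = 1 − insertion error − deletion error − substitution error,

all as proportions of pairwise-alignment columns. Estimated MSAs are
scored against the true alignment with the sum-of-pairs (developer),
modeler, total-column and Cline shift (ε = 0.2) scores.

**Comparison harness.** A 72-scenario grid (3 taxon counts × 3 sampling
fractions × 4 heights × 2 indel rates), pluggable aligner adapters
(true-alignment baseline, built-in progressive aligner, external command
templates with optional guide trees), pairwise Mann–Whitney–Wilcoxon tests
with joint Benjamini–Hochberg correction and strict-threshold win counts,
accuracy-by-depth profiles, indel bias summaries, and quality–accuracy
correlations.

## Worked example

```r
library(asrbench)

tree <- simulateTree(TreeSimParams(nTaxa = 16, height = 1.2,
                                   samplingFraction = 0.99), seed = 11)
history <- evolveSequences(tree, wagModel(), IndelParams(0.05), seed = 12)
history
#> EvolutionHistory: 16 tips, 15 internal nodes, 690 alignment columns
#>   events: 2318, simulation attempts: 1

rec <- reconstructAncestors(tipAlignment(history), tree, wagModel(),
                            flipRate = 0.1)
truth  <- as.character(ancestorSequences(history))
recon  <- as.character(ancestralSequences(rec))
depths <- nodeDepths(tree)
scores <- do.call(rbind, lapply(names(truth), function(v)
  reconstructionAccuracy(recon[[v]], truth[[v]],
                         depth = depths[[v]], node = v)))
head(round(scores[, -1], 3), 4)
#>   distanceToRoot insertionError deletionError substitutionError accuracy
#> 1          0.000          0.026         0.098             0.382    0.494
#> 2          0.382          0.000         0.064             0.329    0.606
#> 3          0.640          0.000         0.024             0.230    0.746
#> 4          0.705          0.000         0.003             0.190    0.807
mean(scores$accuracy)
#> [1] 0.8752356
```

Reading the output: even when reconstructing from the *true* alignment,
the root (`distanceToRoot = 0`) is recovered with accuracy 0.49 — half of
its pairwise-alignment columns carry a correct residue — while ancestors
near the tips approach 0.95+; averaged over all 15 ancestors the accuracy
is 0.875. Scoring an estimated MSA against the recorded truth works the
same way:

```r
est <- progressiveAlign(tipSequences(history))
round(msaScores(est, tipAlignment(history)), 3)
#>      sp modeler    tc clineShift testColumns refColumns
#> 1 0.656   0.625 0.054      0.672         488        690
```

Scenario-scale runs go through `scenarioGrid()` / `runScenario()` /
`runBenchmark()`, and the comparison statistics through
`compareAligners()`, `depthProfile()`, `indelBias()` and
`qualityVsAccuracy()`.

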