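---
title: "How alignment quality shapes ancestral sequence reconstruction: the asrbench methods"
author: "asrbench authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How alignment quality shapes ancestral sequence reconstruction: the asrbench methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asrbench)
```

## The question the package answers

Ancestral sequence reconstruction (ASR) infers the protein sequences of
extinct ancestors from the sequences of extant species placed on a
phylogeny. In practice the extant sequences must first be arranged into a
multiple sequence alignment (MSA), and every error in that alignment
propagates into the reconstruction. `asrbench` provides a controlled,
fully simulated test bed for quantifying that propagation: it simulates
trees and indel-rich protein evolution where the *true* ancestors and the
*true* alignment are known, reconstructs ancestors from either the true
alignment (the baseline) or any estimated MSA, and scores both the
reconstructions and the alignments themselves.

Everything is seeded and deterministic, so a scenario is reproducible from
its parameter set and one integer.

## Tree simulation

Trees are rooted, binary and ultrametric, simulated under a birth–death
process with species sampling, conditioned on the number of sampled tips
$n$. Ultrametric trees keep all tips equidistant from the root, which makes
node depth the single variable controlling reconstruction difficulty along
the tree and avoids confounding by unequal tip branch lengths.

We use the conditioned kernel-density construction: with birth rate
$\lambda$, death rate $\mu$ and sampling fraction $\rho$, the probability
that a lineage alive at age $t$ (time before present, root age scaled to 1)
leaves at least one sampled descendant is

$$P(0,t) = \frac{\rho\,(\lambda-\mu)}{\rho\lambda + \left[\lambda(1-\rho)-\mu\right]e^{-(\lambda-\mu)t}},$$

and the $n-2$ non-root node ages are i.i.d. draws from the kernel density
$g(t) \propto \lambda\,P(0,t)^2\,e^{-(\lambda-\mu)t}/\rho$ on $(0,1)$,
sorted and attached by uniform random joins of the extant lineages. The
kernel CDF has a closed form, which the simulator inverts analytically;
the test suite checks the sampled ages against a numerically integrated
CDF by a Kolmogorov–Smirnov test over 2,000 trees. This construction
guarantees exactly $n$ tips (a forward simulation with rejection would
discard almost every replicate at $\rho = 0.01$), and the tree is scaled
so the root-to-tip distance equals the requested height exactly, because
height — expected substitutions per site from root to tip — is a
controlled variable of the study design.

Low sampling fractions push divergences toward the root and produce
"star-like" trees; high fractions produce trees with late divergences.
Defaults follow the study grid: $\lambda = 6$, $\mu = 3$, $n \in \{16, 32,
64\}$, $\rho \in \{0.01, 0.25, 0.99\}$, heights $\{0.8, 1.0, 1.2, 2.0\}$.
Internal nodes are labelled `N1..N(n-1)` in preorder (root `N1`), so true
and reconstructed ancestors correspond by label.

## Sequence simulation

Substitutions follow the WAG empirical amino-acid model with
discrete-gamma rate variation (shape $\alpha = 1.8$, 4 equal-probability
categories, each represented by its bin's conditional mean; category rates
average exactly 1). The generator is normalized so one unit of branch
length is one expected substitution per average-rate site at stationarity.
The root sequence (408 residues by default) is drawn from the stationary
frequencies with i.i.d. category assignments.

Indels are a Gillespie process run along each branch: insertions at rate
`insertionRate` per inter-residue slot (there are $L+1$ slots, both ends
included), deletions at rate `deletionRate` per residue; both rates are
expressed relative to an average substitution rate of 1. Lengths are
truncated-Zipf, $P(L=k) \propto k^{-1.7}$, capped at 20 residues.
Deletions start at a uniformly chosen residue and are truncated at the
sequence end when they overrun; inserted residues receive fresh stationary
amino acids and fresh gamma categories, consistent with the i.i.d.-site
model. These end-handling conventions are symmetric and standard, and are
this package's documented choices.

The simulation is factored exactly into (1) the indel skeleton — indel
rates depend only on current sequence length, never on residues — and
(2) per-site substitution jump chains over each surviving site's lifetime
on the branch. This is equivalent to a naive whole-sequence Gillespie
simulation but runs in time proportional to the number of events, which is
what lets the test suite validate a 100,000-site branch against a
matrix-exponential oracle. Because every residue carries a permanent
homology identity, the simulator emits the exact alignment of *all* nodes
(tips and ancestors) plus a complete event log; removing gaps from any
alignment row reproduces that node's sequence verbatim.

A lineage that loses every residue makes the replicate undefined; such
replicates are rejected and re-simulated from the continuing RNG stream,
with the attempt count recorded on the returned object.

## Marginal reconstruction

Reconstruction takes the tree, branch lengths and model as given (the
benchmark always reconstructs on the true tree with the true parameters,
isolating the MSA as the experimental variable). For each alignment column
and each internal node, the marginal posterior over the 20 amino acids is
computed by Felsenstein pruning per gamma category with an outside
(up–down) recursion — equivalent to re-rooting at every node under this
reversible model — and categories are mixed by the per-column category
posterior. Gaps and ambiguity codes (`X`, `B`, `Z`, `J`) are missing data
in the amino-acid likelihood. Per-column scaling keeps 64-taxon problems
away from underflow while preserving cross-category comparability; the
total log-likelihood agrees with an independent implementation
(`phangorn::pml`) to six decimals and is invariant to rerooting.

Gap states are reconstructed by a separate two-state (present/absent)
symmetric reversible model pruned over the same tree. Its flip rate is
expressed in expected presence switches per unit branch length and
defaults to the scenario's insertion + deletion rate total (0.1 for the
default 0.05 + 0.05); the benchmark's reconstruction engine exposes it as
an explicit parameter rather than hard-wiring an undocumented internal
value. A column is called present when its posterior non-gap probability
is at least 0.50 — the cutoff is inclusive, and the boundary case is
pinned by a unit test. Present columns emit the posterior argmax, with
exact ties broken alphabetically for determinism.

## Accuracy decomposition

A reconstructed ancestor is compared to its true counterpart through a
deterministic global pairwise alignment (affine Needleman–Wunsch/Gotoh,
BLOSUM62, gap open 11, extension 1, "high-road" traceback). Writing $L$
for the pairwise alignment length:

- insertion error = columns with a residue in the reconstruction but a gap
  in the truth, divided by $L$;
- deletion error = columns with a gap in the reconstruction but a residue
  in the truth, divided by $L$;
- substitution error = mismatched residue pairs divided by $L$;
- accuracy = $1 -$ (insertion + deletion + substitution error), the
  proportion of columns carrying a correctly aligned, identical residue.

The four proportions always sum to one (they are computed from integer
column counts to keep the identity exact in floating point). The choice of
an internal deterministic aligner — rather than an external alignment
program — makes the metric reproducible bit-for-bit; absolute accuracy
values can shift in the third decimal relative to scores computed with a
different pairwise aligner, which is why the package's own acceptance
checks are bounds and directions rather than third-decimal matches.

## MSA quality scores

Estimated alignments are scored against the simulator's true tip
alignment: sum-of-pairs/developer score (fraction of reference residue
pairs recovered), modeler score (fraction of test pairs that are correct;
an empty test pair set scores 0, so pathological underalignment is not
rewarded), total-column score (fraction of reference columns reproduced
exactly, as sets of (sequence, residue-index) entries restricted to
non-gap cells), and the Cline shift score with $\epsilon = 0.2$,
symmetrized over both directions, which credits near-miss placements and
lives in $[-\epsilon, 1]$. TC can exceed SP when the reference contains
single-residue columns (they count toward TC but contribute no pairs), so
the "TC $\le$ SP" relation is only guaranteed — and only asserted — for
gap-free references.

## The benchmark pipeline

`scenarioGrid()` enumerates the Cartesian design (default: 3 taxon counts
× 3 sampling fractions × 4 heights × 2 indel rates = 72 scenarios over 36
tree configurations). Seeds are derived per scenario and per replicate by
a documented polynomial hash of the master seed and a readable key
(`deriveSeed`), so any cell can be reproduced in isolation. Aligners are
plugged in as adapters: the true-alignment baseline, a built-in
progressive aligner (UPGMA guide tree on k-mer distances, profile–profile
affine merges; a dependency-free stand-in so the whole pipeline is testable
without external tools, not a competitor to production aligners), or
external commands via `{in}`/`{out}`/`{tree}` templates. Guide-tree
variants are suffixed `*` in reports. Adapter output must contain exactly
the input sequences after degapping; failures become missing rows that are
preserved but excluded from every downstream statistic.

Aligner comparisons use a two-sided Mann–Whitney–Wilcoxon test on
node-level accuracies per scenario. For small samples the p-value is
computed exactly by enumerating group assignments (tie-aware; base R's
`wilcox.test` exact path refuses ties), otherwise the tie-corrected normal
approximation is used. All scenario × pair p-values are adjusted jointly
by Benjamini–Hochberg — the joint family is the conservative choice and is
stated here because the alternative (per-scenario families) is also
defensible. A "win" requires adjusted $p$ strictly below $\alpha = 0.01$
*and* the higher median; an adjusted $p$ exactly at the threshold does not
count. Degenerate all-tied comparisons record $p = 1$ rather than failing.

Depth profiles report binned mean accuracy (equal-width bins over distance
to root, with counts and standard errors); the binned means are the tested
artifact, and any LOESS curve drawn over them is presentation smoothing
only, since smoothing parameters are not part of the study design.
Quality–accuracy relations are reported as Pearson $r$, $r^2$ and Spearman
$\rho$ per aligner and pooled, over scenario means; zero-variance inputs
are flagged as undefined rather than propagated as NaN.

## What the generator does and does not emulate

The simulator reproduces the features the study design manipulates:
tree shape under incomplete sampling, divergence depth, among-site rate
variation, and realistic indel length laws. It deliberately omits
lineage-specific rate variation, domain or secondary-structure
organization, selection, compositional drift and alignment-unfriendly
low-complexity regions. Passing tests therefore demonstrate correctness of
the machinery and the direction of alignment-quality effects under the
i.i.d.-site model; they do not certify absolute accuracy values for real
protein families, where alignment errors are typically more structured.

## Numerical and design choices

- Transition probabilities come from the symmetrized eigendecomposition of
  the normalized generator; $t = 0$ short-circuits to an exact identity
  matrix so that zero-length branches force identity and truly impossible
  columns raise a zero-likelihood error instead of returning rounding
  noise.
- Pruning partials are rescaled per column at every internal node, with
  per-category log-scale accumulators, so 64-taxon × height-2 problems stay
  in range.
- The pairwise and profile aligners share one C++ affine DP with a fixed
  tie preference (match, then gap in the second profile, then gap in the
  first), making every alignment deterministic.
- Argmax ties in reconstruction are broken alphabetically; the presence
  cutoff is inclusive.
- WAG exchangeabilities and frequencies are read from the model tables
  shipped with phangorn, the standard R source for empirical amino-acid
  models; structural invariants (symmetry, frequency sum, generator
  normalization, detailed balance) are asserted in the test suite.
- Problem sizes in the tests and the acceptance script are desk-scale by
  design: 16-taxon trees, 10 replicates and root length 408 for the
  headline quantity; shorter root lengths (150–200) for direction checks
  where the effect size dwarfs Monte Carlo noise. The full 10 × 10
  replication of the 72-scenario grid is a loop away (`runBenchmark`), not
  a different code path.

## Known limitations

- The presence/absence model is a two-state stand-in for the undocumented
  indel reconstruction internals of the original ASR software; its flip
  rate is explicit and configurable, but it ignores indel length structure.
- The built-in progressive aligner is intentionally simple; conclusions
  about specific production aligners require the external adapters and the
  corresponding binaries.
- Accuracy values depend (weakly) on the pairwise aligner's scoring
  parameters; comparisons within a run are unaffected because every
  reconstruction is scored identically.
- Reported correlations are over scenario means; node-level correlation
  structure within replicates is not modelled.
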