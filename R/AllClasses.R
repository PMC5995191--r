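setOldClass("phylo")

#' Birth-death tree simulation parameters
#'
#' Parameters of the conditioned birth-death tree simulator: number of sampled
#' taxa, tree height in expected substitutions per site from root to tip,
#' species sampling fraction, and per-lineage birth and death rates.
#'
#' @slot nTaxa integer, number of sampled tips (>= 2).
#' @slot height numeric, root-to-tip path length in expected
#'   substitutions/site (> 0).
#' @slot samplingFraction numeric in (0, 1], probability that a lineage is
#'   sampled; low values yield star-like trees with divergences concentrated
#'   near the root.
#' @slot birthRate,deathRate numeric per-lineage rates on the unit time scale
#'   of the kernel; `birthRate > deathRate >= 0` is required.
#' @export
setClass("TreeSimParams",
         representation(nTaxa = "integer", height = "numeric",
                        samplingFraction = "numeric", birthRate = "numeric",
                        deathRate = "numeric"))

setValidity("TreeSimParams", function(object) {
  msg <- character(0)
  if (object@nTaxa < 2L) msg <- c(msg, "nTaxa must be >= 2")
  if (!(object@height > 0)) msg <- c(msg, "height must be > 0")
  if (!(object@samplingFraction > 0 && object@samplingFraction <= 1))
    msg <- c(msg, "samplingFraction must be in (0, 1]")
  if (object@deathRate < 0) msg <- c(msg, "deathRate must be >= 0")
  if (!(object@birthRate > object@deathRate))
    msg <- c(msg, "birthRate must exceed deathRate")
  if (length(msg)) msg else TRUE
})

#' @describeIn TreeSimParams-class Constructor with validation; defaults match
#'   the benchmark's birth/death rates (6 and 3).
#' @param nTaxa,height,samplingFraction,birthRate,deathRate see slots.
#' @export
TreeSimParams <- function(nTaxa, height, samplingFraction,
                          birthRate = 6, deathRate = 3) {
  obj <- new("TreeSimParams", nTaxa = .checkCount(nTaxa, "nTaxa", 2L),
             height = height, samplingFraction = samplingFraction,
             birthRate = birthRate, deathRate = deathRate)
  obj
}

setMethod("show", "TreeSimParams", function(object) {
  cat(sprintf(
    "TreeSimParams: %d taxa, height %.3g, sampling %.3g, birth %.3g, death %.3g\n",
    object@nTaxa, object@height, object@samplingFraction, object@birthRate,
    object@deathRate))
})

#' Amino-acid substitution model with discrete-gamma rate variation
#'
#' A reversible 20-state substitution model defined by symmetric
#' exchangeabilities and stationary frequencies, with among-site rate
#' variation discretized into `nCategories` equal-probability gamma
#' categories. The generator `Q` is normalized so one unit of branch length
#' equals one expected substitution per average-rate site at stationarity.
#'
#' @slot exchangeabilities symmetric non-negative 20x20 matrix (zero diagonal).
#' @slot frequencies stationary amino-acid frequencies, summing to 1.
#' @slot alpha gamma shape parameter of the rate distribution.
#' @slot nCategories number of discrete gamma categories.
#' @slot Q normalized rate matrix (rows sum to 0).
#' @slot categoryRates the discrete category rates, mean 1.
#' @slot eig eigen-decomposition cache used for transition probabilities.
#' @export
setClass("RateModel",
         representation(exchangeabilities = "matrix", frequencies = "numeric",
                        alpha = "numeric", nCategories = "integer",
                        Q = "matrix", categoryRates = "numeric",
                        eig = "list"))

setValidity("RateModel", function(object) {
  msg <- character(0)
  S <- object@exchangeabilities
  pi <- object@frequencies
  if (!all(dim(S) == c(20L, 20L))) msg <- c(msg, "exchangeabilities must be 20x20")
  if (any(S < 0)) msg <- c(msg, "exchangeabilities must be non-negative")
  if (max(abs(S - t(S))) > 1e-10) msg <- c(msg, "exchangeabilities must be symmetric")
  if (abs(sum(pi) - 1) > 1e-12) msg <- c(msg, "frequencies must sum to 1")
  if (!(object@alpha > 0)) msg <- c(msg, "alpha must be > 0")
  if (object@nCategories < 1L) msg <- c(msg, "nCategories must be >= 1")
  if (max(abs(rowSums(object@Q))) > 1e-8) msg <- c(msg, "Q rows must sum to 0")
  if (abs(-sum(pi * diag(object@Q)) - 1) > 1e-10)
    msg <- c(msg, "Q must be normalized to 1 expected substitution/site")
  if (abs(mean(object@categoryRates) - 1) > 1e-10)
    msg <- c(msg, "category rates must have mean 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "RateModel", function(object) {
  cat(sprintf("RateModel: 20-state reversible, gamma(alpha = %.3g) x %d categories\n",
              object@alpha, object@nCategories))
  cat("  category rates:", paste(sprintf("%.4f", object@categoryRates),
                                 collapse = " "), "\n")
})

#' Indel process parameters
#'
#' Insertion and deletion rates are expressed relative to an average
#' substitution rate of 1 (i.e. events per site per unit branch length).
#' Indel lengths follow a truncated Zipf (power-law) distribution,
#' `P(L = k) proportional to k^(-zipfExponent)` for `k` in
#' `1..maxLength`.
#'
#' @slot insertionRate insertion rate per inter-residue slot.
#' @slot deletionRate deletion rate per residue.
#' @slot zipfExponent power-law exponent (> 1).
#' @slot maxLength maximum indel length in residues.
#' @export
setClass("IndelParams",
         representation(insertionRate = "numeric", deletionRate = "numeric",
                        zipfExponent = "numeric", maxLength = "integer"))

setValidity("IndelParams", function(object) {
  msg <- character(0)
  if (object@insertionRate < 0) msg <- c(msg, "insertionRate must be >= 0")
  if (object@deletionRate < 0) msg <- c(msg, "deletionRate must be >= 0")
  if (!(object@zipfExponent > 1)) msg <- c(msg, "zipfExponent must be > 1")
  if (object@maxLength < 1L) msg <- c(msg, "maxLength must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @describeIn IndelParams-class Constructor; defaults follow the benchmark's
#'   indel length law (exponent 1.7, maximum 20 residues).
#' @param insertionRate,deletionRate,zipfExponent,maxLength see slots.
#' @export
IndelParams <- function(insertionRate, deletionRate = insertionRate,
                        zipfExponent = 1.7, maxLength = 20L) {
  new("IndelParams", insertionRate = insertionRate,
      deletionRate = deletionRate, zipfExponent = zipfExponent,
      maxLength = .checkCount(maxLength, "maxLength"))
}

setMethod("show", "IndelParams", function(object) {
  cat(sprintf("IndelParams: ins %.3g, del %.3g, Zipf exponent %.3g, max length %d\n",
              object@insertionRate, object@deletionRate, object@zipfExponent,
              object@maxLength))
})

#' Simulated evolutionary history
#'
#' The complete record of one sequence-evolution simulation: the tree, the
#' ungapped sequence at every node (tips and ancestors), the true all-node
#' alignment over homology columns, the gamma category of every column, and
#' the event log. Row order of the alignment is tips first, then internal
#' nodes in preorder (`N1` = root).
#'
#' @slot tree the `phylo` the sequences were evolved on.
#' @slot alignment character matrix, one row per node over homology columns,
#'   gap character `"-"`.
#' @slot siteCategories integer vector, gamma category of each column.
#' @slot eventLog data.frame of indel and substitution events per branch.
#' @slot attempts number of simulation attempts (re-runs after a lineage lost
#'   all sites).
#' @slot rootLength the configured root sequence length.
#' @export
setClass("EvolutionHistory",
         representation(tree = "phylo", alignment = "matrix",
                        siteCategories = "integer", eventLog = "data.frame",
                        attempts = "integer", rootLength = "integer"))

setValidity("EvolutionHistory", function(object) {
  msg <- character(0)
  m <- object@alignment
  if (!is.character(m) || is.null(rownames(m)))
    msg <- c(msg, "alignment must be a character matrix with row names")
  if (ncol(m) > 0 && any(colSums(m != "-") < 1L))
    msg <- c(msg, "every alignment column must contain at least one residue")
  if (length(object@siteCategories) != ncol(m))
    msg <- c(msg, "siteCategories length must equal alignment width")
  root <- "N1"
  if (root %in% rownames(m)) {
    if (sum(m[root, ] != "-") != object@rootLength)
      msg <- c(msg, "root sequence length must equal rootLength")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "EvolutionHistory", function(object) {
  nt <- length(object@tree$tip.label)
  cat(sprintf(
    "EvolutionHistory: %d tips, %d internal nodes, %d alignment columns\n",
    nt, object@tree$Nnode, ncol(object@alignment)))
  cat(sprintf("  events: %d, simulation attempts: %d\n",
              nrow(object@eventLog), object@attempts))
})

#' Marginal posterior probabilities at internal nodes
#'
#' Holds the column-wise marginal posteriors produced by the reconstruction
#' engine: a 20-state amino-acid posterior per internal node and column
#' (`aminoAcid`, an array `[state, column, node]`) and/or a presence
#' (non-gap) probability per internal node and column (`presence`, a matrix
#' `[node, column]`).
#'
#' @slot aminoAcid numeric array `[20, columns, nodes]` (may be empty).
#' @slot presence numeric matrix `[nodes, columns]` (may be empty).
#' @slot logLikelihood total log-likelihood of the alignment under the model
#'   used for the amino-acid part.
#' @export
setClass("MarginalPosterior",
         representation(aminoAcid = "array", presence = "matrix",
                        logLikelihood = "numeric"))

setValidity("MarginalPosterior", function(object) {
  msg <- character(0)
  if (length(object@aminoAcid)) {
    s <- apply(object@aminoAcid, c(2L, 3L), sum)
    if (max(abs(s - 1)) > 1e-9)
      msg <- c(msg, "amino-acid posteriors must sum to 1 per node/column")
    if (min(object@aminoAcid) < -1e-12 || max(object@aminoAcid) > 1 + 1e-12)
      msg <- c(msg, "posterior probabilities must lie in [0, 1]")
  }
  if (length(object@presence) &&
      (min(object@presence) < -1e-12 || max(object@presence) > 1 + 1e-12))
    msg <- c(msg, "presence probabilities must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MarginalPosterior", function(object) {
  if (length(object@aminoAcid))
    cat(sprintf("MarginalPosterior: %d nodes x %d columns (amino acid), logL %.4f\n",
                dim(object@aminoAcid)[3L], dim(object@aminoAcid)[2L],
                object@logLikelihood))
  if (length(object@presence))
    cat(sprintf("  presence part: %d nodes x %d columns\n",
                nrow(object@presence), ncol(object@presence)))
})

#' Ancestral reconstruction result
#'
#' Per internal node: the reconstructed ungapped sequence, the per-column
#' presence call and chosen state, plus provenance (cutoff and model used).
#' A column is called present when its posterior non-gap probability is
#' greater than or equal to the cutoff (inclusive), and the emitted state is
#' the posterior argmax with alphabetical tie-breaking.
#'
#' @slot sequences `AAStringSet` of reconstructed (ungapped) ancestors.
#' @slot states character matrix `[node, column]` of argmax states.
#' @slot presenceCalls logical matrix `[node, column]`.
#' @slot posterior the underlying [MarginalPosterior-class] object.
#' @slot cutoff presence probability cutoff in (0, 1).
#' @slot modelDescription character provenance string.
#' @export
setClass("AncestralReconstruction",
         representation(sequences = "AAStringSet", states = "matrix",
                        presenceCalls = "matrix",
                        posterior = "MarginalPosterior", cutoff = "numeric",
                        modelDescription = "character"))

setValidity("AncestralReconstruction", function(object) {
  msg <- character(0)
  if (!(object@cutoff > 0 && object@cutoff < 1))
    msg <- c(msg, "cutoff must lie in (0, 1)")
  for (nm in names(object@sequences)) {
    want <- paste(object@states[nm, object@presenceCalls[nm, ]],
                  collapse = "")
    if (!identical(as.character(object@sequences[[nm]]), want)) {
      msg <- c(msg, "sequences must equal states at present columns")
      break
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "AncestralReconstruction", function(object) {
  cat(sprintf(
    "AncestralReconstruction: %d ancestors, cutoff %.2f, model %s\n",
    length(object@sequences), object@cutoff, object@modelDescription))
})

#' Aligner adapter
#'
#' Describes how the benchmark obtains an MSA for a replicate: the recorded
#' true alignment (`"true_alignment"` baseline), the package's built-in
#' progressive aligner (`"builtin"`), or an external command
#' (`"external"`) templated with `{in}`, `{out}` and optionally `{tree}`
#' placeholders. Adapters whose tool receives the true tree as a guide tree
#' are flagged with `guideTree = TRUE` and reported with a `"*"` suffix,
#' following the benchmark's notation.
#'
#' @slot id adapter identifier used in benchmark tables.
#' @slot mode one of `"true_alignment"`, `"builtin"`, `"external"`.
#' @slot command external command template (empty unless external).
#' @slot guideTree logical; whether the true tree is passed as a guide tree.
#' @export
setClass("AlignerAdapter",
         representation(id = "character", mode = "character",
                        command = "character", guideTree = "logical"))

setValidity("AlignerAdapter", function(object) {
  msg <- character(0)
  if (!object@mode %in% c("true_alignment", "builtin", "external"))
    msg <- c(msg, "mode must be true_alignment, builtin or external")
  if (object@mode == "external" && !nzchar(object@command))
    msg <- c(msg, "external adapters need a command template")
  if (object@mode == "external" && !grepl("{in}", object@command, fixed = TRUE))
    msg <- c(msg, "command template must contain {in}")
  if (object@guideTree && object@mode == "external" &&
      !grepl("{tree}", object@command, fixed = TRUE))
    msg <- c(msg, "guide-tree adapters must use a {tree} placeholder")
  if (length(msg)) msg else TRUE
})

setMethod("show", "AlignerAdapter", function(object) {
  cat(sprintf("AlignerAdapter '%s' (%s)%s\n", object@id, object@mode,
              if (object@guideTree) " [guide tree *]" else ""))
  if (nzchar(object@command)) cat("  command:", object@command, "\n")
})
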