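#' Draw indel lengths from a truncated Zipf distribution
#'
#' Lengths follow `P(L = k) proportional to k^(-a)` for `k` in
#' `1..maxLength` (power-law with exponent `a`, hard upper truncation).
#'
#' @param params an [IndelParams-class] object.
#' @param n number of draws.
#' @return Integer vector of lengths in `[1, maxLength]`.
#' @examples
#' set.seed(1)
#' table(drawIndelLength(IndelParams(0.05), 1000))
#' @export
drawIndelLength <- function(params, n = 1L) {
  stopifnot(is(params, "IndelParams"))
  validObject(params)
  k <- seq_len(params@maxLength)
  sample.int(params@maxLength, n, replace = TRUE,
             prob = k^(-params@zipfExponent))
}

.extinctCondition <- function(branch) {
  structure(class = c("asrbenchExtinct", "error", "condition"),
            list(message = paste0("sequence lost all sites on branch to ",
                                  branch),
                 call = NULL))
}

# Evolve one branch. The process is simulated exactly in two phases:
# (1) the indel skeleton by Gillespie -- indel rates depend only on the
#     current length (insertions at the L+1 inter-site slots, deletions at
#     the L sites), never on residues, so it can be drawn first;
# (2) substitution jump chains per surviving site over that site's lifetime
#     on the branch, at the site's gamma-category rate.
# Sites deleted mid-branch appear at no node, so their substitutions need
# not be simulated. Deletions overrunning the end are truncated.
# Event vectors are local and preallocated (doubling on overflow) so event
# recording stays in-place.
.evolveBranch <- function(ids, res, t, child, reg, model, indels) {
  insRate <- indels@insertionRate
  delRate <- indels@deletionRate
  cap <- max(64L, ceiling(2 * length(ids) * t *
                          (1 + insRate + delRate)) + 16L)
  evType <- character(cap); evPos <- integer(cap)
  evLen <- integer(cap); evTime <- numeric(cap)
  nEv <- 0L
  idsNow <- ids
  birth <- numeric(length(ids))
  resStart <- res
  tm <- 0
  repeat {
    L <- length(idsNow)
    if (L == 0L) stop(.extinctCondition(child))
    totIns <- insRate * (L + 1)
    tot <- totIns + delRate * L
    if (tot <= 0) break
    tm <- tm + rexp(1L, tot)
    if (tm > t) break
    if (runif(1L) < totIns / tot) {
      len <- drawIndelLength(indels)
      pos <- sample.int(L + 1L, 1L) - 1L  # insert after residue `pos`
      newIds <- reg$nextId + seq_len(len) - 1L
      reg$nextId <- reg$nextId + len
      reg$cat[newIds] <- sample.int(model@nCategories, len, replace = TRUE)
      anchorAt <- if (pos == 0L) match(idsNow[1L], reg$order) - 1L
                  else match(idsNow[pos], reg$order)
      reg$order <- append(reg$order, newIds, after = anchorAt)
      idsNow <- append(idsNow, newIds, after = pos)
      birth <- append(birth, rep(tm, len), after = pos)
      resStart <- append(resStart,
                         sample.int(20L, len, replace = TRUE,
                                    prob = model@frequencies),
                         after = pos)
      nEv <- nEv + 1L
      if (nEv > length(evType)) {
        evType <- c(evType, character(nEv)); evPos <- c(evPos, integer(nEv))
        evLen <- c(evLen, integer(nEv)); evTime <- c(evTime, numeric(nEv))
      }
      evType[nEv] <- "insertion"; evPos[nEv] <- pos
      evLen[nEv] <- len; evTime[nEv] <- tm
    } else {
      len <- drawIndelLength(indels)
      start <- sample.int(L, 1L)
      idx <- start:min(L, start + len - 1L)
      idsNow <- idsNow[-idx]
      birth <- birth[-idx]
      resStart <- resStart[-idx]
      nEv <- nEv + 1L
      if (nEv > length(evType)) {
        evType <- c(evType, character(nEv)); evPos <- c(evPos, integer(nEv))
        evLen <- c(evLen, integer(nEv)); evTime <- c(evTime, numeric(nEv))
      }
      evType[nEv] <- "deletion"; evPos[nEv] <- start
      evLen[nEv] <- length(idx); evTime[nEv] <- tm
    }
  }
  # substitutions per surviving site
  leave <- reg$leave
  jump <- reg$jump
  catRates <- model@categoryRates
  cat <- reg$cat
  resNow <- resStart
  for (i in seq_along(idsNow)) {
    r <- catRates[cat[idsNow[i]]]
    tau <- t - birth[i]
    x <- resNow[i]
    tm2 <- rexp(1L, r * leave[x])
    while (tm2 <= tau) {
      x <- sample.int(20L, 1L, prob = jump[x, ])
      nEv <- nEv + 1L
      if (nEv > length(evType)) {
        evType <- c(evType, character(nEv)); evPos <- c(evPos, integer(nEv))
        evLen <- c(evLen, integer(nEv)); evTime <- c(evTime, numeric(nEv))
      }
      evType[nEv] <- "substitution"; evPos[nEv] <- i
      evLen[nEv] <- 1L; evTime[nEv] <- birth[i] + tm2
      tm2 <- tm2 + rexp(1L, r * leave[x])
    }
    resNow[i] <- x
  }
  list(ids = idsNow, res = resNow,
       events = data.frame(type = evType[seq_len(nEv)],
                           position = evPos[seq_len(nEv)],
                           length = evLen[seq_len(nEv)],
                           time = evTime[seq_len(nEv)],
                           stringsAsFactors = FALSE))
}

#' Evolve protein sequences along a phylogeny
#'
#' Simulates substitutions and indels down `tree` under `model` (WAG-style
#' reversible substitution with discrete-gamma site rates) and `indels`
#' (insertions at the L+1 inter-residue slots, deletions starting at a
#' uniform residue and truncated at the sequence end, Zipfian lengths). The
#' root sequence is drawn i.i.d. from the stationary frequencies with i.i.d.
#' gamma categories; inserted sites likewise receive fresh stationary
#' residues and categories. Homology is tracked per residue, so the returned
#' [EvolutionHistory-class] contains the exact alignment of every node
#' (tips and ancestors) and the complete event log.
#'
#' If a lineage loses all sites the replicate is rejected and re-simulated
#' with the continuing RNG stream; the attempt count is recorded.
#'
#' @param tree a rooted `phylo` with branch lengths; internal nodes without
#'   labels are labelled `N1..Nk` in preorder.
#' @param model a [RateModel-class] object.
#' @param indels an [IndelParams-class] object.
#' @param rootLength length of the root sequence (default 408 residues).
#' @param seed optional integer seed.
#' @param maxAttempts maximum number of re-simulations after extinction.
#' @return An [EvolutionHistory-class] object.
#' @examples
#' tr <- simulateTree(TreeSimParams(4, 0.5, 0.99), seed = 1)
#' h <- evolveSequences(tr, wagModel(), IndelParams(0.05), rootLength = 60,
#'                      seed = 1)
#' h
#' @export
evolveSequences <- function(tree, model, indels, rootLength = 408L,
                            seed = NULL, maxAttempts = 100L) {
  stopifnot(inherits(tree, "phylo"), is(model, "RateModel"),
            is(indels, "IndelParams"))
  rootLength <- .checkCount(rootLength, "rootLength")
  validObject(model); validObject(indels)
  .maybeSeed(seed)
  tree <- ape::reorder.phylo(tree, "cladewise")
  if (is.null(tree$node.label) || !length(tree$node.label) ||
      !all(nzchar(tree$node.label))) {
    ord <- unique(tree$edge[, 1L])
    lab <- character(tree$Nnode)
    lab[ord - length(tree$tip.label)] <- paste0("N", seq_along(ord))
    tree$node.label <- lab
  }
  for (attempt in seq_len(maxAttempts)) {
    h <- tryCatch(.evolveOnce(tree, model, indels, rootLength),
                  asrbenchExtinct = function(e) NULL)
    if (!is.null(h)) {
      h@attempts <- attempt
      validObject(h)
      return(h)
    }
  }
  stop("all ", maxAttempts, " simulation attempts lost a lineage; ",
       "indel parameters are too aggressive for this tree", call. = FALSE)
}

.evolveOnce <- function(tree, model, indels, rootLength) {
  nTip <- length(tree$tip.label)
  labels <- c(tree$tip.label, tree$node.label)
  reg <- new.env(parent = emptyenv())
  reg$nextId <- rootLength + 1L
  reg$order <- seq_len(rootLength)
  reg$cat <- sample.int(model@nCategories, rootLength, replace = TRUE)
  reg$leave <- -diag(model@Q)
  jump <- model@Q / reg$leave
  diag(jump) <- 0
  reg$jump <- jump

  states <- vector("list", length(labels))
  names(states) <- labels
  rootLab <- labels[nTip + 1L]
  states[[rootLab]] <- list(
    ids = seq_len(rootLength),
    res = sample.int(20L, rootLength, replace = TRUE,
                     prob = model@frequencies))

  branchEvents <- vector("list", nrow(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    parent <- labels[tree$edge[e, 1L]]
    child <- labels[tree$edge[e, 2L]]
    st <- .evolveBranch(states[[parent]]$ids, states[[parent]]$res,
                        tree$edge.length[e], child, reg, model, indels)
    if (nrow(st$events))
      branchEvents[[e]] <- cbind(branch = child, st$events)
    states[[child]] <- list(ids = st$ids, res = st$res)
  }

  present <- unique(unlist(lapply(states, `[[`, "ids"), use.names = FALSE))
  columns <- reg$order[reg$order %in% present]
  aln <- matrix("-", nrow = length(labels), ncol = length(columns),
                dimnames = list(labels, NULL))
  for (lab in labels) {
    st <- states[[lab]]
    aln[lab, match(st$ids, columns)] <- AA_CODES[st$res]
  }
  log <- do.call(rbind, branchEvents[!vapply(branchEvents, is.null,
                                             logical(1))])
  if (is.null(log))
    log <- data.frame(branch = character(0), type = character(0),
                      position = integer(0), length = integer(0),
                      time = numeric(0), stringsAsFactors = FALSE)
  new("EvolutionHistory", tree = tree, alignment = aln,
      siteCategories = as.integer(reg$cat[columns]), eventLog = log,
      attempts = 1L, rootLength = rootLength)
}

#' @rdname EvolutionHistory-class
#' @export
setMethod("tipSequences", "EvolutionHistory", function(x) {
  rows <- x@tree$tip.label
  Biostrings::AAStringSet(.degap(setNames(
    apply(x@alignment[rows, , drop = FALSE], 1L, paste, collapse = ""),
    rows)))
})

#' @rdname EvolutionHistory-class
#' @export
setMethod("ancestorSequences", "EvolutionHistory", function(x) {
  rows <- x@tree$node.label
  Biostrings::AAStringSet(.degap(setNames(
    apply(x@alignment[rows, , drop = FALSE], 1L, paste, collapse = ""),
    rows)))
})

#' @rdname EvolutionHistory-class
#' @export
setMethod("nodeSequences", "EvolutionHistory", function(x) {
  Biostrings::AAStringSet(.degap(setNames(
    apply(x@alignment, 1L, paste, collapse = ""), rownames(x@alignment))))
})

#' @rdname EvolutionHistory-class
#' @export
setMethod("trueAlignment", "EvolutionHistory", function(x) {
  .matrixToAA(x@alignment)
})

#' @rdname EvolutionHistory-class
#' @export
setMethod("eventLog", "EvolutionHistory", function(x) x@eventLog)

#' @rdname EvolutionHistory-class
#' @export
setMethod("siteCategories", "EvolutionHistory", function(x) x@siteCategories)

#' True alignment restricted to the tips
#'
#' Returns the simulator's true alignment with ancestor rows dropped and
#' columns that become all-gap removed -- the reference against which
#' estimated tip MSAs are scored.
#'
#' @param history an [EvolutionHistory-class] object.
#' @return `AAStringSet` of gapped tip rows.
#' @export
tipAlignment <- function(history) {
  stopifnot(is(history, "EvolutionHistory"))
  m <- history@alignment[history@tree$tip.label, , drop = FALSE]
  m <- m[, colSums(m != "-") > 0L, drop = FALSE]
  .matrixToAA(m)
}

#' Write an evolution history to FASTA files
#'
#' Writes `tips.fasta` (ungapped tip sequences), `ancestors.fasta` (ungapped
#' true ancestral sequences), `true_alignment.fasta` (the gapped all-node
#' alignment) and `events.tsv` (the event log) into `dir`.
#'
#' @param history an [EvolutionHistory-class] object.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
exportHistory <- function(history, dir) {
  stopifnot(is(history, "EvolutionHistory"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(tipSequences(history),
                              file.path(dir, "tips.fasta"))
  Biostrings::writeXStringSet(ancestorSequences(history),
                              file.path(dir, "ancestors.fasta"))
  Biostrings::writeXStringSet(trueAlignment(history),
                              file.path(dir, "true_alignment.fasta"))
  utils::write.table(history@eventLog, file.path(dir, "events.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
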