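# Marginal maximum-likelihood ancestral reconstruction.
#
# Likelihoods are computed by Felsenstein pruning per discrete-gamma
# category; marginal posteriors at every internal node come from the
# standard up-down (inside-outside) recursion, so a single pass yields all
# nodes without explicit re-rooting. Categories are mixed by the per-column
# category posterior. Per-column scaling keeps 64-taxon alignments away from
# underflow while preserving cross-category comparability.

.ensureNodeLabels <- function(tree) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  if (is.null(tree$node.label) || !length(tree$node.label) ||
      !all(nzchar(tree$node.label))) {
    ord <- unique(tree$edge[, 1L])
    lab <- character(tree$Nnode)
    lab[ord - length(tree$tip.label)] <- paste0("N", seq_along(ord))
    tree$node.label <- lab
  }
  tree
}

.colMax <- function(m) {
  mx <- m[1L, ]
  for (i in seq_len(nrow(m))[-1L]) mx <- pmax(mx, m[i, ])
  mx
}

# Generic pruning + marginal engine over an arbitrary finite state space.
# tipPartials: list (by tip node number) of nStates x ncol matrices.
# Pfun(t, k): transition matrix for branch length t, category k.
.pruneEngine <- function(tree, tipPartials, nStates, prior, Pfun, nCat,
                         catPrior) {
  nTip <- length(tree$tip.label)
  ncols <- ncol(tipPartials[[1L]])
  edge <- tree$edge
  childrenOf <- vector("list", nTip + tree$Nnode)
  for (e in seq_len(nrow(edge)))
    childrenOf[[edge[e, 1L]]] <- c(childrenOf[[edge[e, 1L]]], edge[e, 2L])
  blen <- numeric(nTip + tree$Nnode)
  blen[edge[, 2L]] <- tree$edge.length
  P <- vector("list", nTip + tree$Nnode)
  for (v in edge[, 2L])
    P[[v]] <- lapply(seq_len(nCat), function(k) Pfun(blen[v], k))

  preInternal <- unique(edge[, 1L])  # preorder, root first
  Lint <- vector("list", nTip + tree$Nnode)
  Msg <- vector("list", nTip + tree$Nnode)
  S <- matrix(0, nCat, ncols)
  for (v in rev(preInternal)) {
    Lint[[v]] <- vector("list", nCat)
    for (k in seq_len(nCat)) {
      acc <- matrix(1, nStates, ncols)
      for (ch in childrenOf[[v]]) {
        Lch <- if (ch <= nTip) tipPartials[[ch]] else Lint[[ch]][[k]]
        m <- P[[ch]][[k]] %*% Lch
        if (is.null(Msg[[ch]])) Msg[[ch]] <- vector("list", nCat)
        Msg[[ch]][[k]] <- m
        acc <- acc * m
      }
      mx <- .colMax(acc)
      if (any(mx <= 0))
        stop("zero total likelihood in alignment column ",
             which(mx <= 0)[1L], call. = FALSE)
      acc <- acc * rep(1 / mx, each = nStates)
      S[k, ] <- S[k, ] + log(mx)
      Lint[[v]][[k]] <- acc
    }
  }
  root <- preInternal[1L]

  # category posterior weights and total log-likelihood
  logw <- matrix(0, nCat, ncols)
  for (k in seq_len(nCat))
    logw[k, ] <- log(catPrior[k]) +
      log(colSums(prior * Lint[[root]][[k]])) + S[k, ]
  mxw <- apply(logw, 2L, max)
  w <- exp(logw - rep(mxw, each = nCat))
  colLik <- colSums(w)
  w <- w * rep(1 / colLik, each = nCat)
  logLik <- sum(mxw + log(colLik))

  # outside pass: F[[v]][[k]] is the likelihood flow arriving at v from the
  # rest of the tree (root prior included)
  Fl <- vector("list", nTip + tree$Nnode)
  Fl[[root]] <- lapply(seq_len(nCat),
                       function(k) matrix(prior, nStates, ncols))
  for (v in preInternal) {
    kids <- childrenOf[[v]]
    for (ch in kids) {
      if (ch <= nTip) next
      Fl[[ch]] <- vector("list", nCat)
      for (k in seq_len(nCat)) {
        contrib <- Fl[[v]][[k]]
        for (sib in kids)
          if (sib != ch) contrib <- contrib * Msg[[sib]][[k]]
        f <- crossprod(P[[ch]][[k]], contrib)
        mx <- .colMax(f)
        Fl[[ch]][[k]] <- f * rep(1 / mx, each = nStates)
      }
    }
  }

  post <- array(0, dim = c(nStates, ncols, length(preInternal)))
  for (vi in seq_along(preInternal)) {
    v <- preInternal[vi]
    for (k in seq_len(nCat)) {
      a <- Fl[[v]][[k]] * Lint[[v]][[k]]
      a <- a * rep(1 / colSums(a), each = nStates)
      post[, , vi] <- post[, , vi] + a * rep(w[k, ], each = nStates)
    }
  }
  list(post = post, nodes = preInternal, logLik = logLik)
}

.checkAlignmentTree <- function(alnm, tree) {
  missing <- setdiff(tree$tip.label, rownames(alnm))
  if (length(missing))
    stop("alignment is missing tips: ", paste(missing, collapse = ", "),
         call. = FALSE)
}

#' Column-wise marginal amino-acid posteriors
#'
#' Computes, for every internal node and alignment column, the marginal
#' posterior distribution over the 20 amino acids by the pruning algorithm
#' with discrete-gamma mixing. Gaps and ambiguity codes (`-`, `X`, `B`, `Z`,
#' `J`, `?`, `.`, `*`) are treated as missing data (partial likelihood of
#' ones); the root prior is the model's stationary distribution, and
#' non-root marginals come from the standard outside recursion, equivalent
#' to re-rooting at each node under this reversible model.
#'
#' @param alignment alignment of the tree's tips (`AAStringSet`, named
#'   character vector, or character matrix).
#' @param tree rooted `phylo` with branch lengths; tip labels must appear in
#'   the alignment.
#' @param model a [RateModel-class] object.
#' @return A [MarginalPosterior-class] with the amino-acid part filled.
#' @export
columnMarginals <- function(alignment, tree, model) {
  stopifnot(is(model, "RateModel"))
  alnm <- .alnMatrix(alignment)
  tree <- .ensureNodeLabels(tree)
  .checkAlignmentTree(alnm, tree)
  nTip <- length(tree$tip.label)
  ncols <- ncol(alnm)
  tipPartials <- vector("list", nTip)
  for (i in seq_len(nTip)) {
    chars <- alnm[tree$tip.label[i], ]
    L <- matrix(0, 20L, ncols)
    idx <- match(chars, AA_CODES)
    miss <- chars %in% AA_MISSING
    bad <- is.na(idx) & !miss
    if (any(bad))
      stop("unknown residue '", chars[bad][1L], "' in sequence ",
           tree$tip.label[i], call. = FALSE)
    L[cbind(idx[!miss], which(!miss))] <- 1
    L[, miss] <- 1
    tipPartials[[i]] <- L
  }
  K <- model@nCategories
  res <- .pruneEngine(
    tree, tipPartials, nStates = 20L, prior = model@frequencies,
    Pfun = function(t, k) transitionMatrix(model, t, model@categoryRates[k]),
    nCat = K, catPrior = rep(1 / K, K))
  labels <- c(tree$tip.label, tree$node.label)
  dimnames(res$post) <- list(AA_CODES, NULL, labels[res$nodes])
  new("MarginalPosterior", aminoAcid = res$post,
      presence = matrix(numeric(0), 0L, 0L), logLikelihood = res$logLik)
}

#' Column-wise marginal presence (non-gap) posteriors
#'
#' Recodes each alignment column as binary (residue = present, `-` =
#' absent) and prunes a two-state symmetric reversible model over the same
#' tree and branch lengths, returning each internal node's posterior
#' probability of being non-gapped. The flip rate is expressed in expected
#' presence/absence switches per unit branch length; by default it equals
#' the benchmark's insertion + deletion rate total.
#'
#' @inheritParams columnMarginals
#' @param flipRate expected state flips per unit branch length (default 0.1,
#'   i.e. insertion 0.05 + deletion 0.05).
#' @return A [MarginalPosterior-class] with the presence part filled.
#' @export
presenceMarginals <- function(alignment, tree, flipRate = 0.1) {
  .checkPositive(flipRate, "flipRate")
  alnm <- .alnMatrix(alignment)
  tree <- .ensureNodeLabels(tree)
  .checkAlignmentTree(alnm, tree)
  nTip <- length(tree$tip.label)
  ncols <- ncol(alnm)
  tipPartials <- vector("list", nTip)
  for (i in seq_len(nTip)) {
    presentRow <- alnm[tree$tip.label[i], ] != "-"
    L <- matrix(0, 2L, ncols)
    L[1L, !presentRow] <- 1
    L[2L, presentRow] <- 1
    tipPartials[[i]] <- L
  }
  Pfun <- function(t, k) {
    stay <- 0.5 + 0.5 * exp(-2 * flipRate * t)
    matrix(c(stay, 1 - stay, 1 - stay, stay), 2L, 2L)
  }
  res <- .pruneEngine(tree, tipPartials, nStates = 2L, prior = c(0.5, 0.5),
                      Pfun = Pfun, nCat = 1L, catPrior = 1)
  labels <- c(tree$tip.label, tree$node.label)
  pres <- t(res$post[2L, , , drop = TRUE])
  if (ncols == 1L) pres <- matrix(res$post[2L, 1L, ], ncol = 1L)
  rownames(pres) <- labels[res$nodes]
  new("MarginalPosterior", aminoAcid = array(numeric(0), c(0L, 0L, 0L)),
      presence = pres, logLikelihood = res$logLik)
}

#' Reconstruct ancestral sequences by marginal maximum likelihood
#'
#' Runs [columnMarginals()] and [presenceMarginals()] on the same tree and
#' alignment and assembles, for each internal node, the reconstructed
#' ancestral sequence: a column is called present when its posterior
#' non-gap probability is `>= cutoff` (the cutoff is inclusive), and
#' present columns emit the amino acid with maximal marginal posterior,
#' breaking exact ties alphabetically. The tree, branch lengths and model
#' are taken as given; no parameters are re-estimated.
#'
#' @inheritParams columnMarginals
#' @param flipRate presence-model flip rate, see [presenceMarginals()].
#' @param cutoff presence probability cutoff in (0, 1); default 0.50.
#' @return An [AncestralReconstruction-class] object.
#' @examples
#' tr <- simulateTree(TreeSimParams(8, 0.5, 0.99), seed = 3)
#' h <- evolveSequences(tr, wagModel(), IndelParams(0.05), rootLength = 50,
#'                      seed = 3)
#' rec <- reconstructAncestors(trueAlignment(h), tr, wagModel())
#' ancestralSequences(rec)
#' @export
reconstructAncestors <- function(alignment, tree, model, flipRate = 0.1,
                                 cutoff = 0.5) {
  if (!(cutoff > 0 && cutoff < 1))
    stop("'cutoff' must lie in (0, 1)", call. = FALSE)
  aa <- columnMarginals(alignment, tree, model)
  pres <- presenceMarginals(alignment, tree, flipRate)
  post <- new("MarginalPosterior", aminoAcid = aa@aminoAcid,
              presence = pres@presence, logLikelihood = aa@logLikelihood)
  nodes <- dimnames(aa@aminoAcid)[[3L]]
  ncols <- dim(aa@aminoAcid)[2L]
  states <- matrix("", length(nodes), ncols, dimnames = list(nodes, NULL))
  calls <- pres@presence >= cutoff
  seqs <- character(length(nodes))
  for (vi in seq_along(nodes)) {
    p <- aa@aminoAcid[, , vi, drop = FALSE]
    dim(p) <- dim(aa@aminoAcid)[1:2]
    mx <- .colMax(p)
    # argmax with alphabetical tie-break: scan states in alphabetical order
    pick <- integer(ncols)
    for (s in order(AA_CODES)) {
      hit <- pick == 0L & p[s, ] == mx
      pick[hit] <- s
    }
    states[vi, ] <- AA_CODES[pick]
    seqs[vi] <- paste(states[vi, calls[nodes[vi], ]], collapse = "")
  }
  new("AncestralReconstruction",
      sequences = Biostrings::AAStringSet(setNames(seqs, nodes)),
      states = states, presenceCalls = calls[nodes, , drop = FALSE],
      posterior = post, cutoff = cutoff,
      modelDescription = sprintf(
        "marginal ML, gamma(alpha=%.3g) x %d, presence flip rate from config",
        model@alpha, model@nCategories))
}

#' @rdname AncestralReconstruction-class
#' @export
setMethod("ancestralSequences", "AncestralReconstruction",
          function(x) x@sequences)

#' @rdname AncestralReconstruction-class
#' @export
setMethod("presenceCalls", "AncestralReconstruction",
          function(x) x@presenceCalls)

#' @rdname MarginalPosterior-class
#' @export
setMethod("aminoAcidPosterior", "MarginalPosterior", function(x) x@aminoAcid)

#' @rdname MarginalPosterior-class
#' @export
setMethod("presencePosterior", "MarginalPosterior", function(x) x@presence)

#' @rdname MarginalPosterior-class
#' @export
setMethod("totalLogLikelihood", "MarginalPosterior",
          function(x) x@logLikelihood)
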