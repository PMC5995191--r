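# Independent oracles used by the tests. Each re-derives its quantity by a
# route deliberately different from the package implementation: exhaustive
# enumeration, numeric quadrature, or plain double loops.

AA20 <- asrbench:::AA_CODES

# ---- exhaustive marginal posterior over all internal-state assignments ----
# Enumerates every assignment of states to internal nodes, per gamma
# category, accumulating the joint likelihood; marginals are ratios of sums.
# Feasible for <= 3 internal nodes and a handful of columns.
bruteMarginalsAA <- function(alnv, tree, model) {
  K <- model@nCategories
  pi <- model@frequencies
  chars <- do.call(rbind, strsplit(alnv, "", fixed = TRUE))
  rownames(chars) <- names(alnv)
  ncols <- ncol(chars)
  tipset <- function(ch) {
    if (ch %in% asrbench:::AA_MISSING) seq_len(20L) else match(ch, AA20)
  }
  labs <- c(tree$tip.label, tree$node.label)
  edges <- tree$edge
  out <- array(0, c(20L, ncols, tree$Nnode),
               dimnames = list(AA20, NULL, tree$node.label))
  for (cc in seq_len(ncols)) {
    tot <- 0
    acc <- matrix(0, 20L, tree$Nnode)
    for (k in seq_len(K)) {
      P <- lapply(seq_len(nrow(edges)), function(e)
        transitionMatrix(model, tree$edge.length[e], model@categoryRates[k]))
      grid <- expand.grid(rep(list(seq_len(20L)), tree$Nnode))
      for (g in seq_len(nrow(grid))) {
        istates <- as.integer(grid[g, ])
        names(istates) <- tree$node.label
        lik <- pi[istates[1L]] / K
        for (e in seq_len(nrow(edges))) {
          ps <- istates[labs[edges[e, 1L]]]
          cl <- labs[edges[e, 2L]]
          lik <- lik * if (cl %in% tree$tip.label)
            sum(P[[e]][ps, tipset(chars[cl, cc])])
          else P[[e]][ps, istates[cl]]
        }
        tot <- tot + lik
        for (v in seq_len(tree$Nnode))
          acc[istates[v], v] <- acc[istates[v], v] + lik
      }
    }
    out[, cc, ] <- acc / tot
  }
  out
}

# two-state analogue for the presence model (state 1 = absent, 2 = present)
bruteMarginalsPresence <- function(alnv, tree, flipRate) {
  chars <- do.call(rbind, strsplit(alnv, "", fixed = TRUE))
  rownames(chars) <- names(alnv)
  ncols <- ncol(chars)
  labs <- c(tree$tip.label, tree$node.label)
  edges <- tree$edge
  P <- lapply(seq_len(nrow(edges)), function(e) {
    stay <- 0.5 + 0.5 * exp(-2 * flipRate * tree$edge.length[e])
    matrix(c(stay, 1 - stay, 1 - stay, stay), 2L, 2L)
  })
  out <- matrix(0, tree$Nnode, ncols, dimnames = list(tree$node.label, NULL))
  for (cc in seq_len(ncols)) {
    tot <- 0
    acc <- matrix(0, 2L, tree$Nnode)
    grid <- expand.grid(rep(list(1:2), tree$Nnode))
    for (g in seq_len(nrow(grid))) {
      istates <- as.integer(grid[g, ])
      names(istates) <- tree$node.label
      lik <- 0.5
      for (e in seq_len(nrow(edges))) {
        ps <- istates[labs[edges[e, 1L]]]
        cl <- labs[edges[e, 2L]]
        lik <- lik * if (cl %in% tree$tip.label)
          P[[e]][ps, if (chars[cl, cc] == "-") 1L else 2L]
        else P[[e]][ps, istates[cl]]
      }
      tot <- tot + lik
      for (v in seq_len(tree$Nnode))
        acc[istates[v], v] <- acc[istates[v], v] + lik
    }
    out[, cc] <- acc[2L, ] / tot
  }
  out
}

# ---- exhaustive global alignment score by move enumeration ----
# Recursively walks every monotone move sequence, carrying the running
# affine score (a gap run of length g costs open + g * ext); returns the
# maximum. Exponential, so only for short strings.
bruteAlignScore <- function(s1, s2, open = 11, ext = 1, sub = NULL) {
  if (is.null(sub)) sub <- asrbench:::.blosum62()
  i1 <- match(strsplit(s1, "", fixed = TRUE)[[1L]], AA20)
  i2 <- match(strsplit(s2, "", fixed = TRUE)[[1L]], AA20)
  n1 <- length(i1); n2 <- length(i2)
  best <- -Inf
  rec <- function(i, j, last, score) {
    if (i > n1 && j > n2) {
      if (score > best) best <<- score
      return(invisible(NULL))
    }
    if (i <= n1 && j <= n2)
      rec(i + 1L, j + 1L, 0L, score + sub[i1[i], i2[j]])
    if (i <= n1)
      rec(i + 1L, j, 1L, score - ext - if (last == 1L) 0 else open)
    if (j <= n2)
      rec(i, j + 1L, 2L, score - ext - if (last == 2L) 0 else open)
  }
  rec(1L, 1L, 0L, 0)
  best
}

# ---- numeric CDF of the conditioned birth-death kernel ----
# Integrates the kernel density lambda * P(0,t)^2 exp(-(lambda-mu)t) / rho
# on a fine grid (trapezoid rule) and normalizes; returns a vectorized CDF.
bdKernelCdfNumeric <- function(lambda, mu, rho, n = 4001L) {
  a <- lambda - mu
  dens <- function(t) {
    P0 <- rho * a / (rho * lambda + (lambda * (1 - rho) - mu) * exp(-a * t))
    lambda * P0^2 * exp(-a * t) / rho
  }
  grid <- seq(0, 1, length.out = n)
  d <- dens(grid)
  cdf <- cumsum(c(0, (d[-1L] + d[-n]) / 2 * diff(grid)))
  cdf <- cdf / cdf[n]
  approxfun(grid, cdf, yleft = 0, yright = 1)
}

# ---- discrete-gamma bin means by adaptive quadrature ----
gammaBinMeansQuadrature <- function(alpha, k) {
  qs <- c(0, qgamma(seq_len(k - 1L) / k, alpha, alpha), Inf)
  vapply(seq_len(k), function(i) {
    k * integrate(function(x) x * dgamma(x, alpha, alpha),
                  qs[i], qs[i + 1L], rel.tol = 1e-10)$value
  }, numeric(1))
}

# ---- exact two-sided Mann-Whitney p by assignment enumeration ----
# Walks every way of labelling m of the pooled values as group 1 and counts
# assignments whose U statistic (pair counting with 1/2 for ties) is at
# least as extreme as observed.
mwwEnumP <- function(x, y) {
  v <- c(x, y)
  m <- length(x)
  ustat <- function(a, b) {
    u <- 0
    for (xi in a) for (yi in b)
      u <- u + (xi > yi) + 0.5 * (xi == yi)
    u
  }
  obs <- ustat(x, y)
  center <- m * length(y) / 2
  sets <- combn(length(v), m, simplify = FALSE)
  hits <- vapply(sets, function(s) {
    abs(ustat(v[s], v[-s]) - center) >= abs(obs - center) - 1e-9
  }, logical(1))
  mean(hits)
}

# ---- plain double-loop SP/modeler/TC oracle ----
# Walks every ordered pair of rows and pair of residues, asking directly in
# which columns they sit.
bruteMsaScores <- function(test, ref) {
  tm <- asrbench:::.alnMatrix(test)
  rm_ <- asrbench:::.alnMatrix(ref)
  rows <- sort(rownames(rm_))
  colAt <- function(m, row, ridx) {
    # column of the ridx-th residue of `row`
    which(cumsum(m[row, ] != "-") == ridx & m[row, ] != "-")[1L]
  }
  nres <- vapply(rows, function(r) sum(rm_[r, ] != "-"), integer(1))
  aligned <- function(m, r1, i, r2, j) {
    colAt(m, r1, i) == colAt(m, r2, j)
  }
  refPairs <- 0L; testPairs <- 0L; common <- 0L
  for (a in seq_along(rows)[-length(rows)]) {
    for (b in (a + 1L):length(rows)) {
      for (i in seq_len(nres[a])) {
        for (j in seq_len(nres[b])) {
          inRef <- aligned(rm_, rows[a], i, rows[b], j)
          inTest <- aligned(tm, rows[a], i, rows[b], j)
          refPairs <- refPairs + inRef
          testPairs <- testPairs + inTest
          common <- common + (inRef && inTest)
        }
      }
    }
  }
  # TC by direct column-set comparison
  nrep <- 0L; nref <- 0L
  for (j in seq_len(ncol(rm_))) {
    occ <- which(rm_[, j] != "-")
    if (!length(occ)) next
    nref <- nref + 1L
    cols <- vapply(occ, function(r) {
      colAt(tm, rownames(rm_)[r], sum(rm_[r, seq_len(j)] != "-"))
    }, integer(1))
    if (length(unique(cols)) == 1L &&
        sum(tm[, cols[1L]] != "-") == length(occ))
      nrep <- nrep + 1L
  }
  c(sp = if (refPairs == 0L) as.numeric(testPairs == 0L) else
      common / refPairs,
    modeler = if (testPairs == 0L) 0 else common / testPairs,
    tc = if (nref == 0L) 1 else nrep / nref)
}

# ---- small simulation fixtures shared across tests ----
smallHistory <- function(nTaxa = 8, height = 0.8, rho = 0.99, indel = 0.05,
                         rootLength = 120, seed = 1) {
  tr <- simulateTree(TreeSimParams(nTaxa, height, rho), seed = seed)
  list(tree = tr,
       history = evolveSequences(tr, wagModel(), IndelParams(indel),
                                 rootLength = rootLength, seed = seed + 1))
}

randomAASeq <- function(n) paste(sample(AA20, n, replace = TRUE),
                                 collapse = "")

# mean baseline (true-alignment) reconstruction accuracy over a seeded batch
baselineBatch <- function(nTaxa, height, rho, indel, nReps, rootLength,
                          seedBase) {
  m <- wagModel()
  vapply(seq_len(nReps), function(i) {
    tr <- simulateTree(TreeSimParams(nTaxa, height, rho),
                       seed = seedBase + 2L * i)
    h <- evolveSequences(tr, m, IndelParams(indel),
                         rootLength = rootLength,
                         seed = seedBase + 2L * i + 1L)
    rec <- reconstructAncestors(tipAlignment(h), tr, m,
                                flipRate = 2 * indel)
    recs <- as.character(ancestralSequences(rec))
    truth <- as.character(ancestorSequences(h))
    mean(vapply(names(truth), function(v)
      reconstructionAccuracy(recs[[v]], truth[[v]])$accuracy, numeric(1)))
  }, numeric(1))
}

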