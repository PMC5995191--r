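test_that("zero-length branches force identity and conflicting tips raise a zero-likelihood error", {
  m <- wagModel(1.8, 2)
  star <- ape::read.tree(text = "(A:0,B:0,C:0);")
  mp <- columnMarginals(c(A = "A", B = "A", C = "A"), star, m)
  expect_equal(unname(aminoAcidPosterior(mp)["A", 1L, 1L]), 1)
  expect_error(columnMarginals(c(A = "A", B = "R", C = "A"), star, m),
               "zero total likelihood")
  expect_error(columnMarginals(c(A = "A", B = "A"), star, m),
               "missing tips")
})

test_that("saturated branches return the stationary frequencies at every node", {
  m <- wagModel(1.8, 4)
  tr <- ape::read.tree(text = "((A:500,B:500)N2:500,(C:500,D:500)N3:500)N1;")
  mp <- columnMarginals(c(A = "A", B = "W", C = "C", D = "Y"), tr, m)
  post <- aminoAcidPosterior(mp)
  for (v in 1:3)
    expect_equal(unname(post[, 1L, v]),
                 unname(stationaryFrequencies(m)), tolerance = 1e-6)
})

test_that("4-taxon marginals with gamma mixing match exhaustive enumeration", {
  m <- wagModel(1.8, 2)
  tr <- ape::read.tree(
    text = "((A:0.3,B:0.7)N2:0.2,(C:0.5,D:0.1)N3:0.4)N1;")
  aln <- c(A = "ARL", B = "ADL", C = "RXI", D = "-VV")
  mine <- aminoAcidPosterior(columnMarginals(aln, tr, m))
  oracle <- bruteMarginalsAA(aln, tr, m)
  expect_lt(max(abs(mine - oracle)), 1e-10)
})

test_that("presence marginals match enumeration and respect symmetry", {
  tr3 <- ape::read.tree(text = "((A:0.3,B:0.6)N2:0.2,C:0.9)N1;")
  aln3 <- c(A = "A-", B = "AC", C = "-D")
  mine <- presencePosterior(presenceMarginals(aln3, tr3, flipRate = 0.1))
  oracle <- bruteMarginalsPresence(aln3, tr3, 0.1)
  expect_lt(max(abs(mine - oracle)), 1e-12)
  # symmetric cherry, one gapped tip of two: root presence is exactly 1/2
  cherry <- ape::read.tree(text = "(A:1,B:1)N1;")
  p <- presencePosterior(presenceMarginals(c(A = "A", B = "-"), cherry,
                                           flipRate = 0.1))
  expect_identical(unname(p["N1", 1L]), 0.5)
  # gap-free column on a short-branch cherry: presence prob well above 1/2
  p2 <- presencePosterior(presenceMarginals(c(A = "A", B = "C"), cherry,
                                            flipRate = 0.1))
  expect_gt(p2["N1", 1L], 0.5)
})

test_that("the presence cutoff is inclusive, ties break alphabetically, and higher cutoffs never lengthen ancestors", {
  m <- wagModel(1.8, 2)
  cherry <- ape::read.tree(text = "(A:1,B:1)N1;")
  # root presence of an A/- column is exactly 0.5: >= keeps it
  rec <- reconstructAncestors(c(A = "AC", B = "-C"), cherry, m,
                              cutoff = 0.5)
  expect_true(all(presenceCalls(rec)["N1", ]))
  expect_equal(nchar(as.character(ancestralSequences(rec))[["N1"]]), 2L)
  recAbove <- reconstructAncestors(c(A = "AC", B = "-C"), cherry, m,
                                   cutoff = 0.5 + 1e-9)
  expect_false(presenceCalls(recAbove)["N1", 1L])
  # exact posterior tie under a fully symmetric model: A beats C
  uniform <- rateModel(matrix(1, 20, 20) - diag(20), rep(1 / 20, 20),
                       alpha = 1, nCategories = 1)
  tie <- reconstructAncestors(c(A = "A", B = "C"), cherry, uniform)
  expect_identical(as.character(ancestralSequences(tie))[["N1"]], "A")
  # monotonicity in the cutoff on simulated data
  fix <- smallHistory(nTaxa = 8, rootLength = 100, seed = 51)
  lens <- vapply(c(0.3, 0.5, 0.7), function(ct) {
    r <- reconstructAncestors(trueAlignment(fix$history)[fix$tree$tip.label],
                              fix$tree, m, cutoff = ct)
    sum(nchar(as.character(ancestralSequences(r))))
  }, numeric(1))
  expect_true(all(diff(lens) <= 0))
  expect_error(reconstructAncestors(c(A = "A", B = "C"), cherry, m,
                                    cutoff = 1), "cutoff")
})

test_that("the total likelihood is invariant to rerooting and matches phangorn", {
  fix <- smallHistory(nTaxa = 6, rootLength = 60, seed = 61)
  aln <- trueAlignment(fix$history)[fix$tree$tip.label]
  m <- wagModel(1.8, 4)
  ll <- totalLogLikelihood(columnMarginals(aln, fix$tree, m))
  pd <- phangorn::phyDat(asrbench:::.alnMatrix(aln), type = "AA")
  fit <- phangorn::pml(fix$tree, pd, model = "WAG", k = 4, shape = 1.8)
  expect_equal(ll, fit$logLik, tolerance = 1e-6)
  rerooted <- ape::root(ape::unroot(fix$tree), outgroup = "t3",
                        resolve.root = TRUE)
  ll2 <- totalLogLikelihood(columnMarginals(aln, rerooted, m))
  expect_equal(ll, ll2, tolerance = 1e-8)
})

test_that("no-indel truth reconstructs full-length ancestors and true alignments beat column-shuffled corruptions", {
  m <- wagModel()
  tr <- simulateTree(TreeSimParams(6, 0.8, 0.99), seed = 71)
  h <- evolveSequences(tr, m, IndelParams(0), rootLength = 408, seed = 71)
  rec <- reconstructAncestors(trueAlignment(h)[tr$tip.label], tr, m)
  expect_true(all(nchar(as.character(ancestralSequences(rec))) == 408L))
  expect_true(all(presenceCalls(rec)))

  set.seed(72)
  deltas <- replicate(20, {
    tr <- simulateTree(TreeSimParams(6, 0.8, 0.99))
    h <- evolveSequences(tr, m, IndelParams(0.05), rootLength = 60)
    aln <- asrbench:::.alnMatrix(trueAlignment(h))[tr$tip.label, ]
    shuffled <- aln[, sample(ncol(aln))]
    truth <- as.character(ancestorSequences(h))
    accOf <- function(a) {
      r <- reconstructAncestors(a, tr, m)
      s <- as.character(ancestralSequences(r))
      mean(vapply(names(truth), function(v)
        reconstructionAccuracy(s[[v]], truth[[v]])$accuracy, numeric(1)))
    }
    accOf(aln) - accOf(shuffled)
  })
  expect_gt(mean(deltas), 0)
})

test_that("posterior arrays are normalized and bounded for simulated data", {
  fix <- smallHistory(nTaxa = 8, rootLength = 80, seed = 81)
  mp <- columnMarginals(trueAlignment(fix$history)[fix$tree$tip.label],
                        fix$tree, wagModel())
  post <- aminoAcidPosterior(mp)
  expect_lt(max(abs(apply(post, c(2, 3), sum) - 1)), 1e-9)
  expect_gte(min(post), 0)
  expect_lte(max(post), 1 + 1e-12)
  pres <- presencePosterior(
    presenceMarginals(trueAlignment(fix$history)[fix$tree$tip.label],
                      fix$tree))
  expect_true(all(pres >= 0 & pres <= 1))
})
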