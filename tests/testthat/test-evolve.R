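test_that("indel lengths follow the truncated Zipf law", {
  one <- IndelParams(0.05, maxLength = 1L)
  expect_true(all(drawIndelLength(one, 1000) == 1L))
  p <- IndelParams(0.05, zipfExponent = 1.7, maxLength = 20L)
  set.seed(5)
  big <- drawIndelLength(p, 1e5)
  expect_lte(max(big), 20L)
  expect_identical(max(big), 20L)
  draws <- drawIndelLength(p, 1e6)
  pk1 <- 1 / sum((1:20)^(-1.7))  # direct summation of the normalizer
  se <- sqrt(pk1 * (1 - pk1) / 1e6)
  expect_lt(abs(mean(draws == 1L) - pk1), 3 * se)
})

test_that("without indels the alignment is gap-free with exactly the root length", {
  tr <- simulateTree(TreeSimParams(8, 0.8, 0.99), seed = 2)
  h <- evolveSequences(tr, wagModel(), IndelParams(0), rootLength = 408,
                       seed = 2)
  m <- asrbench:::.alnMatrix(trueAlignment(h))
  expect_equal(ncol(m), 408L)
  expect_false(any(m == "-"))
  expect_true(all(nchar(as.character(nodeSequences(h))) == 408L))
  expect_equal(nrow(eventLog(h)[eventLog(h)$type != "substitution", ]), 0L)
})

test_that("single-branch divergence matches the matrix-exponential oracle", {
  m <- wagModel()
  tr <- ape::read.tree(text = "(A:2,B:0);")
  h <- evolveSequences(tr, m, IndelParams(0), rootLength = 1e5, seed = 11)
  aln <- as.character(trueAlignment(h))
  a <- strsplit(aln[["A"]], "", fixed = TRUE)[[1L]]
  r <- strsplit(aln[["N1"]], "", fixed = TRUE)[[1L]]
  expect_identical(aln[["B"]], aln[["N1"]])  # zero-length branch
  obs <- mean(a != r)
  Q <- m@Q
  pi <- stationaryFrequencies(m)
  expected <- mean(vapply(categoryRates(m), function(rr) {
    P <- as.matrix(Matrix::expm(Q * 2 * rr))
    1 - sum(pi * diag(P))
  }, numeric(1)))
  se <- sqrt(expected * (1 - expected) / 1e5)
  expect_lt(abs(obs - expected), 3 * se)
})

test_that("a long branch drives the composition to stationarity", {
  m <- wagModel()
  tr <- ape::read.tree(text = "(A:50,B:0);")
  h <- evolveSequences(tr, m, IndelParams(0), rootLength = 2000, seed = 4)
  child <- strsplit(as.character(tipSequences(h))[["A"]], "",
                    fixed = TRUE)[[1L]]
  counts <- table(factor(child, levels = asrbench:::AA_CODES))
  cs <- suppressWarnings(
    chisq.test(counts, p = stationaryFrequencies(m)))
  expect_gt(cs$p.value, 0.01)
})

test_that("homology conservation: each residue occupies exactly one column and insertions only widen the alignment", {
  fix <- smallHistory(nTaxa = 8, indel = 0.05, rootLength = 150, seed = 21)
  h <- fix$history
  m <- asrbench:::.alnMatrix(trueAlignment(h))
  seqs <- as.character(nodeSequences(h))
  for (nm in rownames(m)) {
    expect_identical(paste(m[nm, m[nm, ] != "-"], collapse = ""),
                     seqs[[nm]])
  }
  expect_true(all(colSums(m != "-") >= 1L))
  ev <- eventLog(h)
  if (any(ev$type == "insertion")) expect_gte(ncol(m), 150L)
  expect_length(siteCategories(h), ncol(m))
  expect_true(all(siteCategories(h) %in% 1:4))
  # seeded determinism of the full history
  h2 <- evolveSequences(fix$tree, wagModel(), IndelParams(0.05),
                        rootLength = 150, seed = 22)
  expect_identical(asrbench:::.alnMatrix(trueAlignment(h2)), m)
  expect_identical(eventLog(h2), ev)
})

test_that("equal insertion and deletion rates keep the mean tip length near the root length", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  set.seed(31)
  lens <- numeric(200)
  sawFrontInsertion <- FALSE
  for (i in seq_len(200)) {
    h <- evolveSequences(tr, wagModel(), IndelParams(0.05),
                         rootLength = 408)
    lens[i] <- mean(nchar(as.character(tipSequences(h))))
    ev <- eventLog(h)
    if (any(ev$type == "insertion" & ev$position == 0L))
      sawFrontInsertion <- TRUE
  }
  expect_lt(abs(mean(lens) - 408) / 408, 0.05)
  # insertions use the L+1 inter-residue slots, including the front one
  expect_true(sawFrontInsertion)
})

test_that("lineages that lose every site are retried and eventually error", {
  tr <- ape::read.tree(text = "(A:5,B:5);")
  harsh <- IndelParams(insertionRate = 0, deletionRate = 50)
  expect_error(
    evolveSequences(tr, wagModel(), harsh, rootLength = 2, seed = 1,
                    maxAttempts = 5),
    "attempts")
  ok <- evolveSequences(tr, wagModel(), IndelParams(0.05), rootLength = 50,
                        seed = 2)
  expect_gte(ok@attempts, 1L)
})

test_that("FASTA export round-trips losslessly", {
  fix <- smallHistory(nTaxa = 6, rootLength = 80, seed = 41)
  d <- tempfile("hist")
  exportHistory(fix$history, d)
  tips <- Biostrings::readAAStringSet(file.path(d, "tips.fasta"))
  expect_equal(length(tips), 6L)
  expect_identical(as.character(tips),
                   as.character(tipSequences(fix$history)))
  aln <- Biostrings::readAAStringSet(file.path(d, "true_alignment.fasta"))
  expect_identical(as.character(aln),
                   as.character(trueAlignment(fix$history)))
  anc <- Biostrings::readAAStringSet(file.path(d, "ancestors.fasta"))
  expect_identical(as.character(anc),
                   as.character(ancestorSequences(fix$history)))
})
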