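test_that("the scenario grid enumerates the full design deterministically", {
  g <- scenarioGrid()
  expect_equal(nrow(g), 72L)
  expect_equal(nrow(treeConfigurations(g)), 36L)
  expect_false(anyDuplicated(g$scenario) > 0)
  expect_true(all(g$seed >= 1 & g$seed < 2^31))
  g2 <- scenarioGrid()
  expect_identical(g, g2)
  single <- scenarioGrid(nTaxa = 16, samplingFraction = 0.99, height = 0.8,
                         indelRate = 0.05)
  expect_equal(nrow(single), 1L)
  expect_error(scenarioGrid(nTaxa = numeric(0)), "nTaxa")
  # documented seed splitting: reproducible, 31-bit, key-sensitive
  expect_identical(deriveSeed(1, "a", 2), deriveSeed(1, "a", 2))
  expect_false(deriveSeed(1, "a", 2) == deriveSeed(1, "a", 3))
})

test_that("runScenario yields one row per internal node and is fully reproducible", {
  sc <- scenarioGrid(nTaxa = 16, samplingFraction = 0.99, height = 0.8,
                     indelRate = 0.05, rootLength = 120,
                     nTreeReps = 1, nSeqReps = 1, masterSeed = 5)
  tab <- runScenario(sc[1, ])
  expect_equal(nrow(tab), 15L)  # taxa - 1 internal nodes
  expect_false(anyDuplicated(tab[, c("scenario", "treeRep", "seqRep",
                                     "aligner", "node")]) > 0)
  expect_true(all(tab$accuracy >= 0 & tab$accuracy <= 1))
  expect_true(all(tab$sp == 1))  # baseline scored against itself
  tab2 <- runScenario(sc[1, ])
  expect_identical(tab, tab2)
})

test_that("exact Mann-Whitney p-values match assignment enumeration and the win rule is strict", {
  p <- asrbench:::.mwwPValue(rep(0.9, 4), rep(0.1, 4))
  expect_equal(p, mwwEnumP(rep(0.9, 4), rep(0.1, 4)))
  expect_equal(p, 2 / 70)
  # untied small samples agree with wilcox.test's exact distribution
  x <- c(1.1, 2.3, 3.1, 4.9); y <- c(0.6, 2.8, 5.4)
  expect_equal(asrbench:::.mwwPValue(x, y),
               wilcox.test(x, y, exact = TRUE)$p.value)
  expect_equal(asrbench:::.mwwPValue(x, y), mwwEnumP(x, y))
  # tied samples still agree with the enumeration oracle
  xt <- c(1, 1, 2, 3); yt <- c(1, 2, 2, 4)
  expect_equal(asrbench:::.mwwPValue(xt, yt), mwwEnumP(xt, yt))
  # all-tied degenerate comparison records p = 1, not an exception
  expect_equal(asrbench:::.mwwPValue(rep(0.5, 4), rep(0.5, 6)), 1)
  # adjusted p exactly at the threshold is NOT a win
  expect_false(asrbench:::.isWin(0.01, 0.01))
  expect_true(asrbench:::.isWin(0.00999, 0.01))
})

test_that("identical accuracy vectors produce no wins; separated ones do", {
  mkRows <- function(scenario, aligner, acc) {
    data.frame(scenario = scenario, treeRep = 1L, seqRep = 1L,
               aligner = aligner, node = paste0("N", seq_along(acc)),
               distanceToRoot = 0.5, insertionError = 0, deletionError = 0,
               substitutionError = 1 - acc, accuracy = acc,
               alignmentLength = 100L, lengthRatio = 1, msaLength = 100L,
               sp = 1, modeler = 1, tc = 1, clineShift = 1,
               missing = FALSE, stringsAsFactors = FALSE)
  }
  same <- rbind(mkRows("s1", "a", seq(0.5, 0.9, 0.1)),
                mkRows("s1", "b", seq(0.5, 0.9, 0.1)))
  cmp <- compareAligners(same, alpha = 0.05)
  expect_true(all(cmp$wins == 0L))
  expect_equal(cmp$tests$p, 1)
  sep <- do.call(rbind, lapply(paste0("s", 1:3), function(s)
    rbind(mkRows(s, "good", rep(c(0.9, 0.92, 0.95), 3)),
          mkRows(s, "bad", rep(c(0.1, 0.15, 0.2), 3)))))
  cmp2 <- compareAligners(sep, alpha = 0.05)
  expect_equal(unname(cmp2$wins["good", "bad"]), 3L)
  expect_equal(unname(cmp2$wins["bad", "good"]), 0L)
  expect_equal(sum(diag(cmp2$wins)), 0L)
})

test_that("depth profiles and indel bias summaries match hand-grouped oracles", {
  set.seed(131)
  fixture <- data.frame(
    scenario = "s", treeRep = 1L, seqRep = 1L,
    aligner = rep(c("a", "b"), each = 10L),
    node = paste0("N", 1:20),
    distanceToRoot = rep(seq(0.05, 0.95, 0.1), 2),
    insertionError = runif(20, 0, 0.2),
    deletionError = runif(20, 0, 0.2),
    substitutionError = 0, accuracy = 1 - seq(0.05, 0.95, 0.1),
    alignmentLength = 100L, lengthRatio = runif(20, 0.8, 1.2),
    msaLength = 100L, sp = 1, modeler = 1, tc = 1, clineShift = 1,
    missing = FALSE, stringsAsFactors = FALSE)
  prof <- depthProfile(fixture, nBins = 5L)
  # independent group-by: bins of width 0.18 starting at 0.05
  for (r in seq_len(nrow(prof))) {
    lo <- 0.05 + (prof$bin[r] - 1L) * 0.18
    sel <- fixture$aligner == prof$aligner[r] &
      fixture$distanceToRoot >= lo - 1e-9 &
      fixture$distanceToRoot <= lo + 0.18 + 1e-9
    expect_equal(prof$mean[r], mean(fixture$accuracy[sel]))
    expect_equal(prof$n[r], sum(sel))
  }
  # accuracy = 1 - depth is recovered by the binned means at bin centres
  expect_equal(prof$mean, 1 - prof$binMid, tolerance = 0.1)
  bias <- indelBias(fixture)
  for (al in c("a", "b")) {
    sel <- fixture$aligner == al
    expect_equal(bias$meanInsertionError[bias$aligner == al],
                 mean(fixture$insertionError[sel]))
    expect_equal(bias$medianLengthRatio[bias$aligner == al],
                 median(fixture$lengthRatio[sel]))
  }
  # all nodes at a single depth collapse to one occupied bin
  one <- fixture; one$distanceToRoot <- 0.4
  prof1 <- depthProfile(one, nBins = 5L)
  expect_equal(sort(unique(prof1$bin)), 1L)
  expect_equal(prof1$mean[prof1$aligner == "a"],
               mean(one$accuracy[one$aligner == "a"]))
  # perfect reconstructions: ratio 1, zero indel errors
  perf <- fixture; perf$insertionError <- 0; perf$deletionError <- 0
  perf$lengthRatio <- 1
  biasP <- indelBias(perf)
  expect_true(all(biasP$meanLengthRatio == 1))
  expect_true(all(biasP$meanInsertionError == 0))
})

test_that("quality-accuracy correlations: exact cases, textbook formula, zero-variance flag", {
  mk <- function(scenario, aligner, acc, sp) {
    data.frame(scenario = scenario, treeRep = 1L, seqRep = 1L,
               aligner = aligner, node = "N1", distanceToRoot = 0.5,
               insertionError = 0, deletionError = 0,
               substitutionError = 1 - acc, accuracy = acc,
               alignmentLength = 100L, lengthRatio = 1, msaLength = 100L,
               sp = sp, modeler = sp, tc = 1 - sp, clineShift = 0.5,
               missing = FALSE, stringsAsFactors = FALSE)
  }
  acc <- c(0.31, 0.45, 0.52, 0.63, 0.66, 0.71, 0.78, 0.84, 0.9, 0.97)
  tab <- do.call(rbind, lapply(seq_along(acc), function(i)
    mk(paste0("s", i), "a", acc[i], sp = acc[i])))
  qa <- qualityVsAccuracy(tab)
  spRow <- qa[qa$aligner == "a" & qa$metric == "sp", ]
  expect_equal(spRow$pearson, 1)
  expect_equal(spRow$spearman, 1)
  tcRow <- qa[qa$aligner == "a" & qa$metric == "tc", ]
  expect_equal(tcRow$spearman, -1)  # anti-monotone metric
  # textbook formula on a 10-point fixture with noise
  set.seed(141)
  spNoisy <- acc + rnorm(10, 0, 0.05)
  tab2 <- do.call(rbind, lapply(seq_along(acc), function(i)
    mk(paste0("s", i), "a", acc[i], sp = spNoisy[i])))
  qa2 <- qualityVsAccuracy(tab2)
  r <- sum((acc - mean(acc)) * (spNoisy - mean(spNoisy))) /
    sqrt(sum((acc - mean(acc))^2) * sum((spNoisy - mean(spNoisy))^2))
  row2 <- qa2[qa2$aligner == "a" & qa2$metric == "sp", ]
  expect_equal(row2$pearson, r, tolerance = 1e-12)
  expect_equal(row2$r2, r^2, tolerance = 1e-12)
  # constant quality metric: flagged undefined, not NaN
  csRow <- qa[qa$aligner == "a" & qa$metric == "clineShift", ]
  expect_false(csRow$defined)
  expect_true(is.na(csRow$pearson))
  expect_error(qualityVsAccuracy(tab[1:2, ]), "at least 3")
})

test_that("failed adapters leave missing rows that downstream statistics preserve but exclude", {
  sc <- scenarioGrid(nTaxa = 8, samplingFraction = 0.99, height = 0.8,
                     indelRate = 0.05, rootLength = 60,
                     nTreeReps = 1, nSeqReps = 1, masterSeed = 7)
  broken <- externalAligner("broken", "false # {in} {out}")
  tab <- suppressWarnings(
    runScenario(sc[1, ], adapters = list(trueAlignmentAdapter(), broken)))
  expect_equal(nrow(tab), 14L)  # 7 nodes x 2 aligners
  expect_true(all(tab$missing[tab$aligner == "broken"]))
  expect_true(all(is.na(tab$accuracy[tab$missing])))
  prof <- depthProfile(tab)
  expect_false("broken" %in% prof$aligner)
  bias <- indelBias(tab)
  expect_false("broken" %in% bias$aligner)
})
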