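# Scenario grid, replicate orchestration, and the study's comparison
# statistics.

#' Scenario grid
#'
#' Builds the Cartesian product of the candidate parameter values in a
#' deterministic order, one row per simulation scenario. With the default
#' candidate sets (3 taxon counts x 3 sampling fractions x 4 tree heights x
#' 2 indel rates) this yields 72 scenarios over 36 tree configurations.
#' Each scenario receives a deterministic id and a sub-seed derived from the
#' master seed by [deriveSeed()].
#'
#' @param nTaxa,samplingFraction,height,indelRate candidate values (each
#'   non-empty).
#' @param birthRate,deathRate,rootLength,alpha,nCategories,zipfExponent,maxIndelLength
#'   fixed simulation settings shared by all scenarios.
#' @param nTreeReps,nSeqReps replicate counts: trees per scenario and
#'   sequence data sets per tree.
#' @param masterSeed integer master seed for the whole grid.
#' @return `data.frame` with one row per scenario, including `scenario` (id)
#'   and `seed` columns.
#' @examples
#' nrow(scenarioGrid())  # 72
#' @export
scenarioGrid <- function(nTaxa = c(16, 32, 64),
                         samplingFraction = c(0.01, 0.25, 0.99),
                         height = c(0.8, 1.0, 1.2, 2.0),
                         indelRate = c(0.01, 0.05),
                         birthRate = 6, deathRate = 3, rootLength = 408,
                         alpha = 1.8, nCategories = 4, zipfExponent = 1.7,
                         maxIndelLength = 20, nTreeReps = 10, nSeqReps = 10,
                         masterSeed = 1) {
  for (nm in c("nTaxa", "samplingFraction", "height", "indelRate"))
    if (!length(get(nm)))
      stop("no candidate values supplied for '", nm, "'", call. = FALSE)
  g <- expand.grid(height = height, samplingFraction = samplingFraction,
                   nTaxa = nTaxa, indelRate = indelRate,
                   KEEP.OUT.ATTRS = FALSE)
  g$scenario <- sprintf("n%d_f%s_h%s_r%s", g$nTaxa,
                        format(g$samplingFraction, trim = TRUE),
                        format(g$height, trim = TRUE),
                        format(g$indelRate, trim = TRUE))
  g$birthRate <- birthRate; g$deathRate <- deathRate
  g$rootLength <- rootLength; g$alpha <- alpha
  g$nCategories <- nCategories; g$zipfExponent <- zipfExponent
  g$maxIndelLength <- maxIndelLength
  g$nTreeReps <- nTreeReps; g$nSeqReps <- nSeqReps
  g$seed <- vapply(g$scenario, function(id) deriveSeed(masterSeed, id),
                   integer(1))
  g[, c("scenario", "nTaxa", "samplingFraction", "height", "indelRate",
        "birthRate", "deathRate", "rootLength", "alpha", "nCategories",
        "zipfExponent", "maxIndelLength", "nTreeReps", "nSeqReps", "seed")]
}

#' @describeIn scenarioGrid The distinct tree configurations of a grid
#'   (taxon count x sampling fraction x height).
#' @param grid a scenario grid.
#' @export
treeConfigurations <- function(grid) {
  unique(grid[, c("nTaxa", "samplingFraction", "height")])
}

# missing-cell row template: one row per internal node with NA metrics
.missingRows <- function(scenario, treeRep, seqRep, alignerId, nodes,
                         depths) {
  data.frame(scenario = scenario, treeRep = treeRep, seqRep = seqRep,
             aligner = alignerId, node = nodes,
             distanceToRoot = depths[nodes], insertionError = NA_real_,
             deletionError = NA_real_, substitutionError = NA_real_,
             accuracy = NA_real_, alignmentLength = NA_integer_,
             lengthRatio = NA_real_, msaLength = NA_integer_,
             sp = NA_real_, modeler = NA_real_, tc = NA_real_,
             clineShift = NA_real_, missing = TRUE,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Run one benchmark scenario
#'
#' For every tree replicate x sequence replicate x aligner: simulate the
#' tree and sequences, obtain the MSA through the adapter (or take the true
#' alignment for the baseline), reconstruct all ancestors on the TRUE tree
#' with the TRUE model parameters, and score every internal node against its
#' true ancestral sequence, together with the MSA quality scores of the
#' estimated alignment against the true tip alignment. Failures of an
#' external adapter are recorded as missing rows, never silently dropped.
#' Identical scenario + seed always reproduces the identical table.
#'
#' @param scenario one row of [scenarioGrid()] (or an equivalent list).
#' @param adapters list of [AlignerAdapter-class] objects.
#' @param nTreeReps,nSeqReps optional overrides of the scenario's replicate
#'   counts.
#' @return A long-format `data.frame` (the benchmark table) keyed by
#'   `(scenario, treeRep, seqRep, aligner, node)`.
#' @export
runScenario <- function(scenario, adapters = list(trueAlignmentAdapter()),
                        nTreeReps = NULL, nSeqReps = NULL) {
  sc <- as.list(scenario)
  if (is.null(nTreeReps)) nTreeReps <- sc$nTreeReps
  if (is.null(nSeqReps)) nSeqReps <- sc$nSeqReps
  params <- TreeSimParams(sc$nTaxa, sc$height, sc$samplingFraction,
                          sc$birthRate, sc$deathRate)
  model <- wagModel(sc$alpha, sc$nCategories)
  indels <- IndelParams(sc$indelRate, sc$indelRate, sc$zipfExponent,
                        sc$maxIndelLength)
  flipRate <- 2 * sc$indelRate
  ids <- vapply(adapters, function(a)
    paste0(a@id, if (a@guideTree) "*" else ""), character(1))
  if (anyDuplicated(ids))
    stop("adapter ids must be unique", call. = FALSE)
  rows <- vector("list", nTreeReps * nSeqReps * length(adapters))
  ri <- 0L
  for (i in seq_len(nTreeReps)) {
    tree <- simulateTree(params, seed = deriveSeed(sc$seed, "tree", i))
    depths <- nodeDepths(tree)
    nodes <- tree$node.label
    for (j in seq_len(nSeqReps)) {
      history <- evolveSequences(tree, model, indels,
                                 rootLength = sc$rootLength,
                                 seed = deriveSeed(sc$seed, "seq", i, j))
      tips <- as.character(tipSequences(history))
      refAln <- tipAlignment(history)
      truth <- as.character(ancestorSequences(history))
      for (a in seq_along(adapters)) {
        ri <- ri + 1L
        msa <- tryCatch(
          runAligner(adapters[[a]], tips, history = history, tree = tree),
          error = function(e) {
            warning("adapter '", ids[a], "' failed on ", sc$scenario,
                    " tree ", i, " seq ", j, ": ", conditionMessage(e),
                    call. = FALSE)
            NULL
          })
        if (is.null(msa)) {
          rows[[ri]] <- .missingRows(sc$scenario, i, j, ids[a], nodes,
                                     depths)
          next
        }
        q <- if (adapters[[a]]@mode == "true_alignment")
          data.frame(sp = 1, modeler = 1, tc = 1, clineShift = 1)
        else msaScores(msa, refAln)
        rec <- reconstructAncestors(msa, tree, model, flipRate = flipRate)
        recSeqs <- as.character(ancestralSequences(rec))
        acc <- do.call(rbind, lapply(nodes, function(v)
          reconstructionAccuracy(recSeqs[[v]], truth[[v]],
                                 depth = unname(depths[v]), node = v)))
        rows[[ri]] <- data.frame(
          scenario = sc$scenario, treeRep = i, seqRep = j, aligner = ids[a],
          acc[, c("node", "distanceToRoot", "insertionError",
                  "deletionError", "substitutionError", "accuracy",
                  "alignmentLength")],
          lengthRatio = nchar(recSeqs[nodes]) / nchar(truth[nodes]),
          msaLength = unique(Biostrings::width(msa)),
          sp = q$sp, modeler = q$modeler, tc = q$tc,
          clineShift = q$clineShift, missing = FALSE,
          stringsAsFactors = FALSE, row.names = NULL)
      }
    }
  }
  do.call(rbind, rows)
}

#' @describeIn runScenario Run every scenario of a grid and bind the tables.
#' @param grid a [scenarioGrid()] data.frame.
#' @export
runBenchmark <- function(grid, adapters = list(trueAlignmentAdapter()),
                         nTreeReps = NULL, nSeqReps = NULL) {
  do.call(rbind, lapply(seq_len(nrow(grid)), function(r)
    runScenario(grid[r, ], adapters, nTreeReps, nSeqReps)))
}

# Two-sided Mann-Whitney-Wilcoxon p-value. Exact (tie-aware, by complete
# enumeration of group assignments) when the sample is small enough;
# otherwise the usual normal approximation with tie correction.
.mwwPValue <- function(x, y, enumLimit = 100000) {
  m <- length(x); n <- length(y)
  if (m == 0L || n == 0L) return(NA_real_)
  v <- c(x, y)
  if (all(v == v[1L])) return(1)
  if (choose(m + n, m) <= enumLimit) {
    rk <- rank(v)
    obs <- sum(rk[seq_len(m)]) - m * (m + 1) / 2
    center <- m * n / 2
    combos <- combn(m + n, m)
    W <- colSums(matrix(rk[combos], nrow = m)) - m * (m + 1) / 2
    mean(abs(W - center) >= abs(obs - center) - 1e-9)
  } else {
    suppressWarnings(
      wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
  }
}

# strict-inequality significance rule: adjusted p exactly equal to alpha is
# NOT a win
.isWin <- function(padj, alpha) is.finite(padj) & padj < alpha

#' Pairwise aligner comparison (win matrix)
#'
#' Within every scenario, compares each pair of aligners' node-level
#' accuracy distributions with a two-sided Mann-Whitney-Wilcoxon test,
#' adjusts all p-values jointly by Benjamini-Hochberg, and counts a win for
#' the aligner with the higher median accuracy whenever the adjusted p-value
#' is strictly below `alpha`. Degenerate all-tied comparisons record p = 1.
#'
#' @param table a benchmark table from [runScenario()].
#' @param alpha FDR-adjusted significance threshold (default 0.01).
#' @return List with `wins` (aligner x aligner integer matrix, entry
#'   `[i, j]` = number of scenarios where i beat j), `tests` (per
#'   scenario/pair data.frame with p-values, adjusted p-values and medians)
#'   and `nScenarios`.
#' @export
compareAligners <- function(table, alpha = 0.01) {
  tab <- table[!table$missing & !is.na(table$accuracy), , drop = FALSE]
  aligners <- sort(unique(tab$aligner))
  if (length(aligners) < 2L)
    stop("need at least two aligners to compare", call. = FALSE)
  tests <- list(); ti <- 0L
  for (sc in unique(tab$scenario)) {
    sub <- tab[tab$scenario == sc, ]
    present <- intersect(aligners, unique(sub$aligner))
    if (length(present) < 2L) next
    for (pair in combn(present, 2L, simplify = FALSE)) {
      x <- sub$accuracy[sub$aligner == pair[1L]]
      y <- sub$accuracy[sub$aligner == pair[2L]]
      ti <- ti + 1L
      tests[[ti]] <- data.frame(
        scenario = sc, aligner1 = pair[1L], aligner2 = pair[2L],
        median1 = median(x), median2 = median(y),
        p = .mwwPValue(x, y), stringsAsFactors = FALSE)
    }
  }
  tests <- do.call(rbind, tests)
  tests$padj <- p.adjust(tests$p, method = "BH")
  wins <- matrix(0L, length(aligners), length(aligners),
                 dimnames = list(aligners, aligners))
  sig <- .isWin(tests$padj, alpha)
  for (r in which(sig)) {
    if (tests$median1[r] > tests$median2[r])
      wins[tests$aligner1[r], tests$aligner2[r]] <-
        wins[tests$aligner1[r], tests$aligner2[r]] + 1L
    else if (tests$median2[r] > tests$median1[r])
      wins[tests$aligner2[r], tests$aligner1[r]] <-
        wins[tests$aligner2[r], tests$aligner1[r]] + 1L
  }
  list(wins = wins, tests = tests,
       nScenarios = length(unique(tab$scenario)))
}

#' Accuracy profile by distance to root
#'
#' Bins internal nodes into equal-width bins of distance to root and
#' reports, per aligner and bin, the mean accuracy, observation count and
#' standard error. Missing cells are excluded (and stay excluded from the
#' means).
#'
#' @param table a benchmark table.
#' @param nBins number of equal-width depth bins.
#' @return `data.frame` with columns `aligner`, `bin`, `binMid`, `mean`,
#'   `n`, `se`.
#' @export
depthProfile <- function(table, nBins = 10L) {
  tab <- table[!table$missing & !is.na(table$accuracy), , drop = FALSE]
  if (!nrow(tab)) stop("benchmark table is empty", call. = FALSE)
  rng <- range(tab$distanceToRoot)
  if (diff(rng) == 0) {
    breaks <- c(rng[1L] - 0.5, rng[1L] + 0.5)
  } else {
    breaks <- seq(rng[1L], rng[2L], length.out = nBins + 1L)
  }
  bin <- cut(tab$distanceToRoot, breaks, include.lowest = TRUE,
             labels = FALSE)
  mids <- (head(breaks, -1L) + breaks[-1L]) / 2
  agg <- aggregate(tab$accuracy, by = list(aligner = tab$aligner, bin = bin),
                   FUN = function(v) c(mean = mean(v), n = length(v),
                                       se = sd(v) / sqrt(length(v))))
  data.frame(aligner = agg$aligner, bin = agg$bin, binMid = mids[agg$bin],
             mean = agg$x[, "mean"], n = as.integer(agg$x[, "n"]),
             se = agg$x[, "se"], stringsAsFactors = FALSE)
}

#' Insertion/deletion bias summary
#'
#' Per aligner: mean and median insertion error, deletion error and
#' reconstructed/true length ratio. Length ratios above one flag
#' reconstructions longer than the true ancestor (an insertion bias).
#'
#' @param table a benchmark table.
#' @return `data.frame`, one row per aligner.
#' @export
indelBias <- function(table) {
  tab <- table[!table$missing & !is.na(table$accuracy), , drop = FALSE]
  if (!nrow(tab)) stop("benchmark table is empty", call. = FALSE)
  f <- function(v) c(mean = mean(v), median = median(v))
  agg <- aggregate(tab[, c("insertionError", "deletionError",
                           "lengthRatio")],
                   by = list(aligner = tab$aligner), FUN = f)
  data.frame(aligner = agg$aligner,
             meanInsertionError = agg$insertionError[, "mean"],
             medianInsertionError = agg$insertionError[, "median"],
             meanDeletionError = agg$deletionError[, "mean"],
             medianDeletionError = agg$deletionError[, "median"],
             meanLengthRatio = agg$lengthRatio[, "mean"],
             medianLengthRatio = agg$lengthRatio[, "median"],
             stringsAsFactors = FALSE)
}

.corSafe <- function(x, y, method) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L || sd(x) == 0 || sd(y) == 0)
    return(c(value = NA_real_, defined = 0))
  c(value = cor(x, y, method = method), defined = 1)
}

#' Correlation of MSA quality scores with reconstruction accuracy
#'
#' Aggregates the benchmark table to scenario means (per aligner) and
#' reports, for each aligner and quality metric, the Pearson correlation,
#' its square, and the Spearman rank correlation with mean reconstruction
#' accuracy, plus pooled correlations across all aligners. Comparisons with
#' zero variance are flagged as undefined (`defined = FALSE`) rather than
#' propagating NaN.
#'
#' @param table a benchmark table covering >= 3 scenario/aligner means.
#' @return `data.frame` with columns `aligner` (`"(pooled)"` for the pooled
#'   rows), `metric`, `pearson`, `r2`, `spearman`, `n`, `defined`.
#' @export
qualityVsAccuracy <- function(table) {
  tab <- table[!table$missing & !is.na(table$accuracy), , drop = FALSE]
  metrics <- c("sp", "modeler", "tc", "clineShift")
  agg <- aggregate(tab[, c("accuracy", metrics)],
                   by = list(scenario = tab$scenario, aligner = tab$aligner),
                   FUN = mean)
  if (nrow(agg) < 3L)
    stop("need at least 3 paired scenario/aligner observations",
         call. = FALSE)
  out <- list(); oi <- 0L
  groups <- c(as.list(unique(agg$aligner)), list(NULL))
  for (g in groups) {
    sub <- if (is.null(g)) agg else agg[agg$aligner == g, ]
    for (met in metrics) {
      pe <- .corSafe(sub$accuracy, sub[[met]], "pearson")
      sp <- .corSafe(sub$accuracy, sub[[met]], "spearman")
      oi <- oi + 1L
      out[[oi]] <- data.frame(
        aligner = if (is.null(g)) "(pooled)" else g, metric = met,
        pearson = unname(pe["value"]), r2 = unname(pe["value"])^2,
        spearman = unname(sp["value"]), n = nrow(sub),
        defined = pe["defined"] == 1, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
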