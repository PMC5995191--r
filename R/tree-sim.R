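# Conditioned birth-death tree simulation.
#
# Node ages (time before present, on a unit root age) are drawn i.i.d. from
# the birth-death kernel density conditioned on n sampled tips with sampling
# fraction rho, sorted, and attached by random coalescent-style joins; the
# tree is then scaled so the root-to-tip distance equals the requested
# height. With P(0,t) the probability that a lineage alive at age t leaves
# at least one sampled descendant,
#   P(0,t) = rho a / (c + d e^{-a t}),  a = lambda - mu,
#   c = rho lambda, d = lambda (1 - rho) - mu,
# the kernel density is g(t) = lambda p1(t) / v1 on [0, 1], where
# p1(t) = P(0,t)^2 e^{-a t} / rho and v1 normalizes. The CDF has the closed
# form G(t) = num(t)/num(1) with num(t) = 1/(c + d e^{-a t}) - 1/a, which is
# inverted analytically for sampling.

.bdKernelCDF <- function(t, lambda, mu, rho) {
  a <- lambda - mu
  cc <- rho * lambda
  d <- lambda * (1 - rho) - mu
  if (abs(d) < 1e-12) {
    (1 - exp(-a * t)) / (1 - exp(-a))
  } else {
    num <- function(s) 1 / (cc + d * exp(-a * s)) - 1 / a
    num(t) / num(1)
  }
}

.bdKernelQuantile <- function(y, lambda, mu, rho) {
  a <- lambda - mu
  cc <- rho * lambda
  d <- lambda * (1 - rho) - mu
  if (abs(d) < 1e-12) {
    -log(1 - y * (1 - exp(-a))) / a
  } else {
    n1 <- 1 / (cc + d * exp(-a)) - 1 / a
    w <- 1 / (y * n1 + 1 / a)
    -log((w - cc) / d) / a
  }
}

#' Simulate an ultrametric birth-death tree
#'
#' Simulates a rooted binary ultrametric tree with exactly `nTaxa` tips under
#' a birth-death process with species sampling, conditioned on the number of
#' sampled tips (kernel-density/order-statistics construction). Interior node
#' ages are i.i.d. draws from the conditioned birth-death kernel; the root age
#' is fixed, and the tree is scaled so every root-to-tip path equals
#' `height` (expected substitutions per site). Tips are labelled
#' `t1..tn`; internal nodes are labelled `N1..N(n-1)` in preorder with
#' `N1` the root, so simulated and reconstructed ancestors correspond by
#' label.
#'
#' @param params a [TreeSimParams-class] object.
#' @param seed optional integer seed for reproducibility.
#' @return An `ape` `phylo` object.
#' @examples
#' tr <- simulateTree(TreeSimParams(16, height = 0.8,
#'                                  samplingFraction = 0.99), seed = 1)
#' max(nodeDepths(tr))
#' @export
simulateTree <- function(params, seed = NULL) {
  stopifnot(is(params, "TreeSimParams"))
  validObject(params)
  .maybeSeed(seed)
  n <- params@nTaxa
  h <- params@height
  fmt <- function(x) sprintf("%.15g", x)
  if (n == 2L) {
    txt <- sprintf("(t1:%s,t2:%s);", fmt(h), fmt(h))
  } else {
    ages <- sort(.bdKernelQuantile(runif(n - 2L), params@birthRate,
                                   params@deathRate,
                                   params@samplingFraction)) * h
    labels <- paste0("t", seq_len(n))
    sub <- as.list(labels)
    subAge <- numeric(n)
    for (age in c(ages, h)) {
      k <- length(sub)
      ij <- sample.int(k, 2L)
      i <- ij[1L]; j <- ij[2L]
      merged <- sprintf("(%s:%s,%s:%s)", sub[[i]], fmt(age - subAge[i]),
                        sub[[j]], fmt(age - subAge[j]))
      sub[[i]] <- merged
      subAge[i] <- age
      sub <- sub[-j]
      subAge <- subAge[-j]
    }
    txt <- paste0(sub[[1L]], ";")
  }
  tr <- ape::read.tree(text = txt)
  tr <- ape::reorder.phylo(tr, "cladewise")
  ord <- unique(tr$edge[, 1L])
  lab <- character(tr$Nnode)
  lab[ord - length(tr$tip.label)] <- paste0("N", seq_along(ord))
  tr$node.label <- lab
  tr
}

#' Distance of every node from the root
#'
#' @param tree a `phylo` object with branch lengths.
#' @return Named numeric vector over tips and internal nodes; the root is 0
#'   and a child's depth is its parent's depth plus the connecting branch
#'   length.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1)N2:0.5,C:1.5)N1;")
#' nodeDepths(tr)
#' @export
nodeDepths <- function(tree) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  d <- ape::node.depth.edgelength(tree)
  nlab <- tree$node.label
  if (is.null(nlab) || !length(nlab))
    nlab <- paste0("node", seq_len(tree$Nnode) + length(tree$tip.label))
  setNames(d, c(tree$tip.label, nlab))
}

#' Read and write Newick trees
#'
#' Thin, validating wrappers around \pkg{ape}'s Newick I/O. `readNewickTree`
#' accepts a file path or a literal Newick string and reports unbalanced
#' parentheses with their character offset; `writeNewickTree` serializes
#' branch lengths with 15 significant digits so simulator output round-trips
#' with sub-1e-12 error.
#'
#' @param x a file path or Newick string.
#' @return `readNewickTree`: a `phylo`; `writeNewickTree`: the Newick string,
#'   invisibly if written to a file.
#' @examples
#' tr <- readNewickTree("((A:1,B:1):0.5,C:1.5);")
#' writeNewickTree(tr)
#' @export
readNewickTree <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  txt <- if (file.exists(x) && !grepl("(", x, fixed = TRUE))
    paste(readLines(x, warn = FALSE), collapse = "") else x
  depth <- 0L
  chars <- strsplit(txt, "", fixed = TRUE)[[1L]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("malformed Newick: unmatched ')' at character ", i,
             call. = FALSE)
    }
  }
  if (depth != 0L)
    stop("malformed Newick: ", depth, " unclosed '(' by character ",
         length(chars), call. = FALSE)
  tr <- tryCatch(ape::read.tree(text = txt), error = function(e) NULL)
  if (is.null(tr))
    stop("malformed Newick: could not be parsed", call. = FALSE)
  tr
}

#' @rdname readNewickTree
#' @param tree a `phylo` object.
#' @param file optional output path; when `NULL` the string is returned.
#' @export
writeNewickTree <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree, digits = 15)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}
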