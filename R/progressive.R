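# Built-in progressive aligner: UPGMA guide tree on k-mer distances, then
# profile-profile merges with the same affine DP core as the pairwise
# aligner. Deterministic by construction; intended as a dependency-free
# aligner so the whole pipeline can run without external tools, not as a
# competitor to production MSA programs.

.kmerDistance <- function(seqs, k = 3L) {
  n <- length(seqs)
  k <- max(1L, min(k, min(nchar(seqs))))
  counts <- lapply(seqs, function(s) {
    L <- nchar(s)
    km <- substring(s, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L)
    table(km)
  })
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ci <- counts[[i]]; cj <- counts[[j]]
      shared <- sum(pmin(ci[intersect(names(ci), names(cj))],
                         cj[intersect(names(ci), names(cj))]))
      denom <- min(nchar(seqs[i]), nchar(seqs[j])) - k + 1L
      D[i, j] <- D[j, i] <- 1 - shared / denom
    }
  }
  D
}

.profileFreq <- function(m) {
  # columns x 20 residue frequency matrix; gaps contribute zero weight
  f <- matrix(0, ncol(m), 20L)
  for (s in seq_along(AA_CODES))
    f[, s] <- colSums(m == AA_CODES[s])
  f / nrow(m)
}

.mergeProfiles <- function(m1, m2, gapOpen, gapExtend, sub) {
  f1 <- .profileFreq(m1)
  f2 <- .profileFreq(m2)
  S <- f1 %*% sub %*% t(f2)
  mv <- .affine_dp(S, gapOpen, gapExtend)$moves
  out <- matrix("-", nrow(m1) + nrow(m2), length(mv),
                dimnames = list(c(rownames(m1), rownames(m2)), NULL))
  i <- 0L; j <- 0L
  r1 <- seq_len(nrow(m1)); r2 <- nrow(m1) + seq_len(nrow(m2))
  for (kk in seq_along(mv)) {
    if (mv[kk] != 3L) { i <- i + 1L; out[r1, kk] <- m1[, i] }
    if (mv[kk] != 2L) { j <- j + 1L; out[r2, kk] <- m2[, j] }
  }
  out
}

#' Progressive multiple alignment (built-in)
#'
#' Aligns protein sequences with a deterministic progressive strategy:
#' UPGMA guide tree on k-mer distances, then profile-profile merges under an
#' affine gap model (BLOSUM62 expected-score profiles). For two sequences
#' the result equals [pairwiseAlign()]. Output rows keep the input order and
#' reproduce the input sequences exactly after removing gaps.
#'
#' @param seqs named `AAStringSet` or character vector of ungapped
#'   sequences (>= 1).
#' @inheritParams pairwiseAlign
#' @param k k-mer size for the guide-tree distance (default 3).
#' @return `AAStringSet` of gapped rows.
#' @examples
#' progressiveAlign(c(a = "HEAGAWGHEE", b = "PAWHEAE", c = "HEAGAWGHE"))
#' @export
progressiveAlign <- function(seqs, gapOpen = 11, gapExtend = 1, k = 3L,
                             substitutionMatrix = NULL) {
  if (methods::is(seqs, "XStringSet")) seqs <- as.character(seqs)
  stopifnot(is.character(seqs), length(seqs) >= 1L, !is.null(names(seqs)))
  if (any(!nzchar(seqs)))
    stop("progressiveAlign requires non-empty sequences", call. = FALSE)
  if (is.null(substitutionMatrix)) substitutionMatrix <- .blosum62()
  for (nm in names(seqs)) .aaIndex(seqs[[nm]], nm)
  if (length(seqs) == 1L) return(Biostrings::AAStringSet(seqs))
  mats <- lapply(names(seqs), function(nm) {
    matrix(strsplit(seqs[[nm]], "", fixed = TRUE)[[1L]], nrow = 1L,
           dimnames = list(nm, NULL))
  })
  if (length(seqs) == 2L) {
    merged <- .mergeProfiles(mats[[1L]], mats[[2L]], gapOpen, gapExtend,
                             substitutionMatrix)
  } else {
    hc <- hclust(as.dist(.kmerDistance(seqs, k)), method = "average")
    nodes <- vector("list", nrow(hc$merge))
    for (r in seq_len(nrow(hc$merge))) {
      get <- function(x) if (x < 0L) mats[[-x]] else nodes[[x]]
      nodes[[r]] <- .mergeProfiles(get(hc$merge[r, 1L]),
                                   get(hc$merge[r, 2L]),
                                   gapOpen, gapExtend, substitutionMatrix)
    }
    merged <- nodes[[nrow(hc$merge)]]
  }
  merged <- merged[names(seqs), , drop = FALSE]
  .matrixToAA(merged)
}
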