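# Deterministic pairwise alignment and the insertion/deletion/substitution
# accuracy decomposition.

.pkgCache <- new.env(parent = emptyenv())

.blosum62 <- function() {
  if (is.null(.pkgCache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkgCache$blosum62 <- e$BLOSUM62[AA_CODES, AA_CODES]
  }
  .pkgCache$blosum62
}

.aaIndex <- function(seq, what) {
  if (!nzchar(seq)) return(integer(0))
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  idx <- match(chars, AA_CODES)
  if (anyNA(idx))
    stop("non-amino-acid character '", chars[is.na(idx)][1L], "' in ", what,
         call. = FALSE)
  idx
}

#' Deterministic global pairwise alignment
#'
#' Global affine-gap (Gotoh) alignment of two protein sequences with a fully
#' deterministic "high road" traceback: on score ties a match is preferred,
#' then a gap in the second sequence, then a gap in the first. A gap run of
#' length g costs `gapOpen + g * gapExtend`. An empty sequence aligns as
#' all-gaps against the other.
#'
#' @param seq1,seq2 amino-acid strings (possibly empty).
#' @param gapOpen,gapExtend non-negative gap penalties; defaults are the
#'   standard protein settings (11, 1).
#' @param substitutionMatrix a 20x20 scoring matrix with rows/columns named
#'   by one-letter codes, or the default BLOSUM62.
#' @return Character vector of the two gapped rows, with the alignment score
#'   in attribute `"score"`.
#' @examples
#' pairwiseAlign("ACDE", "ACE")
#' @export
pairwiseAlign <- function(seq1, seq2, gapOpen = 11, gapExtend = 1,
                          substitutionMatrix = NULL) {
  stopifnot(gapOpen >= 0, gapExtend >= 0)
  if (is.null(substitutionMatrix)) substitutionMatrix <- .blosum62()
  i1 <- .aaIndex(seq1, "seq1")
  i2 <- .aaIndex(seq2, "seq2")
  n1 <- length(i1); n2 <- length(i2)
  if (n1 == 0L && n2 == 0L)
    return(structure(c("", ""), score = 0))
  if (n1 == 0L)
    return(structure(c(strrep("-", n2), seq2),
                     score = -gapOpen - gapExtend * n2))
  if (n2 == 0L)
    return(structure(c(seq1, strrep("-", n1)),
                     score = -gapOpen - gapExtend * n1))
  S <- substitutionMatrix[i1, i2, drop = FALSE]
  res <- .affine_dp(S, gapOpen, gapExtend)
  mv <- res$moves
  c1 <- strsplit(seq1, "", fixed = TRUE)[[1L]]
  c2 <- strsplit(seq2, "", fixed = TRUE)[[1L]]
  r1 <- character(length(mv)); r2 <- character(length(mv))
  p1 <- 0L; p2 <- 0L
  for (k in seq_along(mv)) {
    if (mv[k] == 1L) {
      p1 <- p1 + 1L; p2 <- p2 + 1L
      r1[k] <- c1[p1]; r2[k] <- c2[p2]
    } else if (mv[k] == 2L) {
      p1 <- p1 + 1L
      r1[k] <- c1[p1]; r2[k] <- "-"
    } else {
      p2 <- p2 + 1L
      r1[k] <- "-"; r2[k] <- c2[p2]
    }
  }
  structure(c(paste(r1, collapse = ""), paste(r2, collapse = "")),
            score = res$score)
}

#' Reconstruction accuracy decomposition
#'
#' Pairwise-aligns a reconstructed ancestral sequence to the true one and
#' decomposes the disagreement into three column proportions: insertion
#' error (residue in the reconstruction, gap in the truth), deletion error
#' (gap in the reconstruction, residue in the truth) and substitution error
#' (mismatched residue pair), each divided by the pairwise alignment length.
#' `accuracy = 1 - (insertion + deletion + substitution)` is the proportion
#' of alignment columns carrying a correctly aligned, identical residue.
#'
#' @param recon reconstructed (ungapped) amino-acid string.
#' @param truth true ancestral (ungapped) amino-acid string.
#' @param depth optional distance of the node from the root.
#' @param node optional node label.
#' @inheritParams pairwiseAlign
#' @return One-row `data.frame` with columns `node`, `distanceToRoot`,
#'   `insertionError`, `deletionError`, `substitutionError`, `accuracy`,
#'   `alignmentLength`.
#' @examples
#' reconstructionAccuracy("ACFE", "ACDE")
#' @export
reconstructionAccuracy <- function(recon, truth, depth = NA_real_,
                                   node = NA_character_, gapOpen = 11,
                                   gapExtend = 1,
                                   substitutionMatrix = NULL) {
  aln <- pairwiseAlign(recon, truth, gapOpen, gapExtend, substitutionMatrix)
  a <- strsplit(aln[1L], "", fixed = TRUE)[[1L]]
  b <- strsplit(aln[2L], "", fixed = TRUE)[[1L]]
  len <- length(a)
  if (len == 0L) {
    nIns <- nDel <- nSub <- 0L
    acc <- 1
  } else {
    nIns <- sum(a != "-" & b == "-")
    nDel <- sum(a == "-" & b != "-")
    nSub <- sum(a != "-" & b != "-" & a != b)
    acc <- (len - nIns - nDel - nSub) / len
  }
  data.frame(node = node, distanceToRoot = depth,
             insertionError = if (len) nIns / len else 0,
             deletionError = if (len) nDel / len else 0,
             substitutionError = if (len) nSub / len else 0,
             accuracy = acc, alignmentLength = len, stringsAsFactors = FALSE)
}
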