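# Reference-based MSA quality scores: sum-of-pairs (developer), modeler,
# total-column, and Cline shift.

# residue index per cell (NA at gaps)
.residueIndex <- function(m) {
  ri <- matrix(NA_integer_, nrow(m), ncol(m), dimnames = dimnames(m))
  for (r in seq_len(nrow(m))) {
    ng <- m[r, ] != "-"
    ri[r, ng] <- seq_len(sum(ng))
  }
  ri
}

.checkSameSequences <- function(testM, refM) {
  if (!setequal(rownames(testM), rownames(refM)))
    stop("test and reference alignments contain different sequences",
         call. = FALSE)
  for (nm in rownames(refM)) {
    a <- paste(testM[nm, testM[nm, ] != "-"], collapse = "")
    b <- paste(refM[nm, refM[nm, ] != "-"], collapse = "")
    if (!identical(a, b))
      stop("degapped sequence '", nm, "' differs between alignments",
           call. = FALSE)
  }
}

#' Aligned residue pairs of an MSA
#'
#' Enumerates the set of homology statements an alignment makes: one entry
#' per pair of residues placed in the same column, encoded as
#' `"seqA|i|seqB|j"` with sequence names in sorted order. Row and column
#' order of the alignment do not affect the result.
#'
#' @param msa an alignment (`AAStringSet`, named character vector or
#'   character matrix).
#' @return Character vector of residue-pair keys.
#' @export
homologyPairs <- function(msa) {
  m <- .alnMatrix(msa)
  m <- m[order(rownames(m)), , drop = FALSE]
  ri <- .residueIndex(m)
  rows <- rownames(m)
  out <- character(0)
  if (length(rows) < 2L) return(out)
  for (a in seq_len(length(rows) - 1L)) {
    for (b in (a + 1L):length(rows)) {
      both <- !is.na(ri[a, ]) & !is.na(ri[b, ])
      if (!any(both)) next
      out <- c(out, paste(rows[a], ri[a, both], rows[b], ri[b, both],
                          sep = "|"))
    }
  }
  out
}

#' Sum-of-pairs, modeler and total-column scores
#'
#' Scores a test alignment against a reference over the same sequences.
#' The sum-of-pairs (developer) score is the fraction of reference residue
#' pairs recovered by the test; the modeler score is the fraction of test
#' residue pairs present in the reference (0 when the test asserts no pairs
#' at all); the total-column score is the fraction of reference columns
#' whose residue set is reproduced exactly as a test column.
#'
#' @param test,ref alignments with identical sequence content (after
#'   removing gaps).
#' @return Named numeric vector `c(sp, modeler, tc)`.
#' @export
spModelerTc <- function(test, ref) {
  testM <- .alnMatrix(test)
  refM <- .alnMatrix(ref)
  .checkSameSequences(testM, refM)
  pt <- homologyPairs(testM)
  pr <- homologyPairs(refM)
  inter <- length(intersect(pt, pr))
  sp <- if (length(pr) == 0L) as.numeric(length(pt) == 0L) else
    inter / length(pr)
  modeler <- if (length(pt) == 0L) 0 else inter / length(pt)

  # total-column: each reference column, as a set of (sequence, residue
  # index) entries, must appear verbatim as one test column
  ri_t <- .residueIndex(testM)
  ri_r <- .residueIndex(refM)
  # colOf[row, residueIndex] = test column holding that residue
  colOf <- matrix(NA_integer_, nrow(testM),
                  max(c(1L, ri_t[!is.na(ri_t)])))
  rownames(colOf) <- rownames(testM)
  for (r in seq_len(nrow(testM))) {
    ng <- which(!is.na(ri_t[r, ]))
    colOf[r, ri_t[r, ng]] <- ng
  }
  testColCount <- colSums(testM != "-")
  nref <- 0L; nrep <- 0L
  for (j in seq_len(ncol(refM))) {
    rows <- which(!is.na(ri_r[, j]))
    if (!length(rows)) next
    nref <- nref + 1L
    rowIdx <- match(rownames(refM)[rows], rownames(colOf))
    tc <- colOf[cbind(rowIdx, ri_r[rows, j])]
    if (length(unique(tc)) == 1L && testColCount[tc[1L]] == length(rows))
      nrep <- nrep + 1L
  }
  tc <- if (nref == 0L) 1 else nrep / nref
  c(sp = sp, modeler = modeler, tc = tc)
}

# partner residue maps for one sequence pair in one alignment:
# partner[[1]][i] = residue index of the second sequence aligned to residue
# i of the first (NA when i sits against a gap), and vice versa.
.partnerMap <- function(rowA, rowB, riA, riB) {
  both <- !is.na(riA) & !is.na(riB)
  pa <- rep(NA_integer_, max(0L, suppressWarnings(max(riA, na.rm = TRUE))))
  pb <- rep(NA_integer_, max(0L, suppressWarnings(max(riB, na.rm = TRUE))))
  if (any(both)) {
    pa[riA[both]] <- riB[both]
    pb[riB[both]] <- riA[both]
  }
  list(pa, pb)
}

#' Cline shift score
#'
#' Alignment agreement score that credits near-miss placements: an aligned
#' residue pair of one alignment scores `(1 + epsilon) / (1 + shift) -
#' epsilon`, where the shift is how many residues its partner has moved
#' relative to the other alignment (0 when the other alignment does not
#' align that residue at all). The score is symmetrized by summing over the
#' pairs of both alignments and dividing by the total pair count, giving a
#' value in `[-epsilon, 1]` with 1 for identical alignments.
#'
#' @inheritParams spModelerTc
#' @param epsilon shift penalty parameter (default 0.2).
#' @return Single numeric score.
#' @export
clineShift <- function(test, ref, epsilon = 0.2) {
  testM <- .alnMatrix(test)
  refM <- .alnMatrix(ref)
  .checkSameSequences(testM, refM)
  testM <- testM[order(rownames(testM)), , drop = FALSE]
  refM <- refM[rownames(testM), , drop = FALSE]
  ri_t <- .residueIndex(testM)
  ri_r <- .residueIndex(refM)
  rows <- rownames(testM)
  total <- 0
  npairs <- 0L
  directed <- function(riX_a, riX_b, riY_a, riY_b) {
    # sum contributions of pairs in alignment X against partners in Y
    both <- !is.na(riX_a) & !is.na(riX_b)
    if (!any(both)) return(c(0, 0L))
    i <- riX_a[both]; j <- riX_b[both]
    mapY <- .partnerMap(NULL, NULL, riY_a, riY_b)[[1L]]
    j2 <- rep(NA_integer_, length(i))
    ok <- i <= length(mapY)
    j2[ok] <- mapY[i[ok]]
    contrib <- ifelse(is.na(j2), 0, (1 + epsilon) / (1 + abs(j - j2)) -
                        epsilon)
    c(sum(contrib), length(i))
  }
  if (length(rows) >= 2L) {
    for (a in seq_len(length(rows) - 1L)) {
      for (b in (a + 1L):length(rows)) {
        dTR <- directed(ri_t[a, ], ri_t[b, ], ri_r[a, ], ri_r[b, ])
        dRT <- directed(ri_r[a, ], ri_r[b, ], ri_t[a, ], ri_t[b, ])
        total <- total + dTR[1L] + dRT[1L]
        npairs <- npairs + dTR[2L] + dRT[2L]
      }
    }
  }
  if (npairs == 0L) return(1)
  total / npairs
}

#' All reference-based MSA quality scores at once
#'
#' @inheritParams clineShift
#' @return One-row `data.frame` with columns `sp`, `modeler`, `tc`,
#'   `clineShift`, `testColumns`, `refColumns`.
#' @examples
#' ref <- c(A = "AC-D", B = "ACED")
#' test <- c(A = "ACD-", B = "ACED")
#' msaScores(test, ref)
#' @export
msaScores <- function(test, ref, epsilon = 0.2) {
  s <- spModelerTc(test, ref)
  cs <- clineShift(test, ref, epsilon)
  data.frame(sp = unname(s["sp"]), modeler = unname(s["modeler"]),
             tc = unname(s["tc"]), clineShift = cs,
             testColumns = ncol(.alnMatrix(test)),
             refColumns = ncol(.alnMatrix(ref)))
}
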