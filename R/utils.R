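# Internal helpers shared across modules.

# Canonical amino-acid order used throughout (PAML/WAG convention).
AA_CODES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Characters treated as missing data in the amino-acid likelihood.
AA_MISSING <- c("-", "X", "B", "Z", "J", "?", ".", "*")

.checkPositive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop("'", name, "' must be a single positive number", call. = FALSE)
  invisible(x)
}

.checkCount <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != as.integer(x))
    stop("'", name, "' must be a single integer >= ", min, call. = FALSE)
  invisible(as.integer(x))
}

#' Stable seed derivation
#'
#' Derives a reproducible 31-bit sub-seed from a master seed and a character
#' key, via a polynomial rolling hash. Used by the benchmark pipeline so that
#' every scenario/replicate gets an independent, documented seed stream.
#'
#' @param masterSeed single integer master seed.
#' @param ... character or numeric components identifying the stream
#'   (e.g. scenario id, `"tree"`, replicate number).
#' @return A single integer in `[1, 2^31 - 2]`.
#' @examples
#' deriveSeed(1, "t16_s0.99_h1.2_i0.05", "tree", 3)
#' @export
deriveSeed <- function(masterSeed, ...) {
  key <- paste(c(as.character(masterSeed), vapply(list(...), as.character,
                                                  character(1))),
               collapse = "/")
  h <- 7
  m <- 2147483647  # 2^31 - 1 (prime)
  for (cp in utf8ToInt(key)) {
    h <- (h * 31 + cp) %% m
  }
  as.integer(h %% (m - 2L) + 1L)
}

# Set the RNG deterministically when a seed is supplied; otherwise leave the
# current stream untouched.
.maybeSeed <- function(seed) {
  if (!is.null(seed)) {
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

# Coerce an alignment (AAStringSet, AAMultipleAlignment, character vector or
# matrix) to a character matrix of single residues, rows named by sequence.
.alnMatrix <- function(x) {
  if (is.matrix(x) && is.character(x)) {
    if (is.null(rownames(x)))
      stop("alignment matrix must have row names", call. = FALSE)
    return(x)
  }
  if (methods::is(x, "AAMultipleAlignment"))
    x <- as(x, "AAStringSet")
  if (methods::is(x, "XStringSet"))
    x <- as.character(x)
  if (!is.character(x) || is.null(names(x)))
    stop("alignment must be a named character vector, AAStringSet or matrix",
         call. = FALSE)
  w <- unique(nchar(x))
  if (length(w) != 1L)
    stop("alignment rows differ in width", call. = FALSE)
  m <- do.call(rbind, strsplit(x, "", fixed = TRUE))
  rownames(m) <- names(x)
  m
}

# Character matrix -> AAStringSet (rows pasted).
.matrixToAA <- function(m) {
  Biostrings::AAStringSet(setNames(apply(m, 1L, paste, collapse = ""),
                                   rownames(m)))
}

.degap <- function(x) gsub("-", "", x, fixed = TRUE)
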