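#' Aligner adapters
#'
#' Constructors for the three adapter kinds used by the benchmark:
#' `trueAlignmentAdapter()` returns the simulator's recorded true alignment
#' (the baseline), `builtinAlignerAdapter()` runs [progressiveAlign()], and
#' `externalAligner()` shells out to an installed MSA tool via a command
#' template with `{in}`, `{out}` and optional `{tree}` placeholders, e.g.
#' `"mafft --retree 2 {in} > {out}"`. Adapters receiving the true tree as a
#' guide tree set `guideTree = TRUE` and are reported with a `"*"` suffix.
#'
#' @param id identifier used in benchmark tables.
#' @param command external command template.
#' @param guideTree whether the true tree is supplied as a guide tree.
#' @return An [AlignerAdapter-class] object.
#' @examples
#' trueAlignmentAdapter()
#' externalAligner("mafft", "mafft --quiet --retree 2 {in} > {out}")
#' @export
trueAlignmentAdapter <- function(id = "baseline") {
  new("AlignerAdapter", id = id, mode = "true_alignment", command = "",
      guideTree = FALSE)
}

#' @rdname trueAlignmentAdapter
#' @export
builtinAlignerAdapter <- function(id = "builtin") {
  new("AlignerAdapter", id = id, mode = "builtin", command = "",
      guideTree = FALSE)
}

#' @rdname trueAlignmentAdapter
#' @export
externalAligner <- function(id, command, guideTree = FALSE) {
  new("AlignerAdapter", id = id, mode = "external", command = command,
      guideTree = guideTree)
}

#' Obtain an MSA through an adapter
#'
#' Runs an [AlignerAdapter-class] on a replicate and validates its output:
#' the returned alignment must contain exactly the input sequences (matched
#' by name, compared after removing gaps), otherwise an adapter error is
#' raised. Rows are returned in the input order.
#'
#' @param adapter an [AlignerAdapter-class].
#' @param sequences ungapped tip sequences (`AAStringSet` or named character
#'   vector).
#' @param history the replicate's [EvolutionHistory-class] (required for the
#'   true-alignment baseline).
#' @param tree the true tree (required when `guideTree` is set).
#' @param workDir scratch directory for external tools.
#' @return `AAStringSet` of gapped rows in input order.
#' @export
runAligner <- function(adapter, sequences, history = NULL, tree = NULL,
                       workDir = tempfile("aligner")) {
  stopifnot(is(adapter, "AlignerAdapter"))
  validObject(adapter)
  if (methods::is(sequences, "XStringSet")) sequences <- as.character(sequences)
  out <- switch(
    adapter@mode,
    true_alignment = {
      if (is.null(history))
        stop("the true-alignment adapter needs the simulation history",
             call. = FALSE)
      as.character(tipAlignment(history))
    },
    builtin = as.character(progressiveAlign(sequences)),
    external = {
      dir.create(workDir, showWarnings = FALSE, recursive = TRUE)
      inFile <- file.path(workDir, "input.fasta")
      outFile <- file.path(workDir, "output.fasta")
      Biostrings::writeXStringSet(Biostrings::AAStringSet(sequences), inFile)
      cmd <- adapter@command
      cmd <- gsub("{in}", shQuote(inFile), cmd, fixed = TRUE)
      cmd <- gsub("{out}", shQuote(outFile), cmd, fixed = TRUE)
      if (grepl("{tree}", cmd, fixed = TRUE)) {
        if (is.null(tree))
          stop("adapter '", adapter@id, "' needs a guide tree", call. = FALSE)
        treeFile <- file.path(workDir, "guide.nwk")
        writeNewickTree(tree, treeFile)
        cmd <- gsub("{tree}", shQuote(treeFile), cmd, fixed = TRUE)
      }
      status <- system(cmd, ignore.stdout = FALSE)
      if (status != 0L || !file.exists(outFile))
        stop("external aligner '", adapter@id, "' failed (exit ", status,
             ")", call. = FALSE)
      as.character(Biostrings::readAAStringSet(outFile))
    })
  if (!setequal(names(out), names(sequences)))
    stop("adapter '", adapter@id, "' returned a different sequence set",
         call. = FALSE)
  out <- out[names(sequences)]
  if (!identical(unname(.degap(out)), unname(sequences)))
    stop("adapter '", adapter@id,
         "' altered sequence content (degapped identity check failed)",
         call. = FALSE)
  Biostrings::AAStringSet(out)
}
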