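## End-to-end orchestration: FASTA -> model -> trajectories -> images ->
## histograms -> distance matrices -> UPGMA trees -> optional RF scores.

## Rethrow any stage error prefixed with the stage name.
.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage %s: %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full comparison pipeline
#'
#' Reads a multi-FASTA file, cleans the sequences, builds (or loads) the
#' weighting model, draws each sequence as a weighted trajectory, rasterizes
#' it, counts the 3x3 local patterns, and computes one distance matrix and
#' one UPGMA tree per requested measure.  If a reference Newick tree is
#' supplied, Robinson-Foulds distances against it are computed as well.
#' All intermediates are written under \code{outDir} together with a
#' manifest of the configuration; the run is deterministic given inputs and
#' configuration.
#'
#' @param fastaPath multi-FASTA input with >= 2 sequences.
#' @param outDir output directory (created if missing).
#' @param scheme assignment scheme label (default \code{"ATGC"}).
#' @param weighting apply self-information weighting factors (default TRUE).
#' @param pixelSize pixel side in trajectory units (default 1).
#' @param blockSize block side in pixels (default 10).
#' @param measures distance measures to compute (default all five).
#' @param weightTable optional path to a precomputed weight table TSV
#'   ([writeWeightTable()] layout); when given, the model is not rebuilt
#'   from the input corpus.
#' @param referenceTree optional path to a reference Newick tree for
#'   Robinson-Foulds evaluation.
#' @param writeImages also export each binary image as PBM (default FALSE;
#'   images can be large).
#' @return invisibly, a list with elements \code{sequences}, \code{model}
#'   (or NULL when a weight table was supplied), \code{weights},
#'   \code{histograms}, \code{matrices}, \code{trees}, and \code{rf}
#'   (named numeric or NULL).
#' @export
runPipeline <- function(fastaPath, outDir,
                        scheme = "ATGC",
                        weighting = TRUE,
                        pixelSize = 1,
                        blockSize = 10L,
                        measures = c("HI", "MD", "BD", "JS", "TAU"),
                        weightTable = NULL,
                        referenceTree = NULL,
                        writeImages = FALSE) {
  measures <- match.arg(measures, several.ok = TRUE)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  seqs <- .stage("read", {
    raw <- readFastaDNA(fastaPath)
    if (length(raw) < 2L)
      stop("need at least 2 sequences")
    cleanSequences(raw)$sequences
  })

  model <- NULL
  weightsLookup <- NULL
  if (weighting) {
    if (!is.null(weightTable)) {
      weightsLookup <- .stage("weights", readWeightTable(weightTable))
    } else {
      model <- .stage("weights", buildTrinucleotideModel(seqs))
      weightsLookup <- modelWeights(model)
      writeWeightTable(model, file.path(outDir, "weights.tsv"))
      writeTrinucleotideCounts(model, file.path(outDir, "triplet_counts.tsv"))
    }
  }

  sch <- assignmentVectors(scheme)
  hists <- .stage("histograms", {
    out <- vector("list", length(seqs))
    names(out) <- names(seqs)
    for (id in names(seqs)) {
      w <- if (weighting)
        suppressMessages(sequenceWeights(seqs[id], weightsLookup))
      else NULL
      traj <- buildTrajectory(seqs[id], scheme = sch, weights = w, id = id)
      img <- rasterize(traj, pixelSize = pixelSize, blockSize = blockSize)
      if (writeImages)
        writePBM(img, file.path(outDir, paste0(id, ".pbm")))
      h <- normalizeHistogram(countPatterns(img))
      writeHistogram(h, file.path(outDir, paste0(id, ".hist.tsv")))
      out[[id]] <- h
    }
    out
  })

  matrices <- list()
  trees <- list()
  for (ms in measures) {
    dm <- .stage(paste0("distance:", ms), distanceMatrix(hists, ms))
    writePhylipMatrix(dm, file.path(outDir, paste0("dist_", ms, ".phy")))
    tr <- .stage(paste0("tree:", ms), upgma(dm))
    writeNewick(tr, file.path(outDir, paste0("tree_", ms, ".nwk")))
    matrices[[ms]] <- dm
    trees[[ms]] <- tr
  }

  rf <- NULL
  if (!is.null(referenceTree)) {
    ref <- .stage("rf", readNewick(referenceTree))
    rf <- vapply(measures, function(ms)
      .stage("rf", robinsonFoulds(trees[[ms]], ref)), numeric(1L))
    utils::write.table(
      data.frame(measure = measures, rf = rf),
      file.path(outDir, "rf.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }

  manifest <- c(
    sprintf("lphist_version: %s",
            as.character(utils::packageVersion("lphist"))),
    sprintf("input: %s", fastaPath),
    sprintf("n_sequences: %d", length(seqs)),
    sprintf("scheme: %s", scheme),
    sprintf("weighting: %s", weighting),
    sprintf("weight_table: %s",
            if (is.null(weightTable)) "corpus" else weightTable),
    sprintf("pixel_size: %g", pixelSize),
    sprintf("block_size: %d", as.integer(blockSize)),
    "window_size: 3",
    sprintf("measures: %s", paste(measures, collapse = ",")),
    sprintf("reference_tree: %s",
            if (is.null(referenceTree)) "none" else referenceTree))
  writeLines(manifest, file.path(outDir, "manifest.txt"))

  invisible(list(sequences = seqs, model = model, weights = weightsLookup,
                 histograms = hists, matrices = matrices, trees = trees,
                 rf = rf))
}
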