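## FASTA input, cleaning of ambiguity codes, and synthetic-sequence
## generation.  Sequences travel through the package as named DNAStringSet
## objects (names are the sequence ids).

#' Read a multi-FASTA file of DNA sequences
#'
#' Reads a (possibly empty) multi-record FASTA file into a named
#' \code{DNAStringSet}.  Record ids are the first whitespace-delimited token
#' of each header and must be unique; residues are upper-cased.  Ambiguity
#' codes are accepted here and removed by [cleanSequences()].
#'
#' @param path path to a FASTA file.
#' @return a named \code{DNAStringSet}, one element per record, in file
#'   order; empty set for an empty file.
#' @export
readFastaDNA <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank))
    return(Biostrings::DNAStringSet())
  if (!startsWith(trimws(lines[nonblank[1L]]), ">"))
    stop(sprintf(
      "malformed FASTA in '%s': line %d precedes any '>' header",
      path, nonblank[1L]))
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (any(!nzchar(ids)))
    stop("malformed FASTA: empty record id")
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  out <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  names(out) <- ids
  out
}

#' Write sequences to FASTA
#'
#' @param seqs a named \code{DNAStringSet} (or named character vector).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeFastaDNA <- function(seqs, path) {
  if (is.character(seqs))
    seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Remove non-ACGT characters from a raw sequence
#'
#' Ambiguity codes (N, R, Y, ...) and gap characters are removed rather than
#' randomly resolved, because the graphical representation defines vectors
#' only for A, C, G and T.  The number of removed characters is returned for
#' logging.
#'
#' @param raw a character scalar.
#' @return list with elements \code{residues} (cleaned upper-case string)
#'   and \code{removed} (integer count of dropped characters).
#' @examples
#' cleanSequence("ACNNGT")  # residues "ACGT", removed 2
#' @export
cleanSequence <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  up <- toupper(raw)
  kept <- gsub("[^ACGT]", "", up)
  list(residues = kept, removed = nchar(up) - nchar(kept))
}

#' Clean every sequence of a set
#'
#' Applies [cleanSequence()] to each element and messages the total number
#' of removed characters when positive.
#'
#' @param seqs named \code{DNAStringSet} or named character vector.
#' @return list with \code{sequences} (cleaned \code{DNAStringSet}) and
#'   \code{removed} (named integer vector of per-sequence removal counts).
#' @export
cleanSequences <- function(seqs) {
  chars <- toupper(as.character(seqs))
  kept <- gsub("[^ACGT]", "", chars)
  removed <- nchar(chars) - nchar(kept)
  names(removed) <- names(seqs)
  if (sum(removed) > 0L)
    message(sprintf("removed %d non-ACGT character(s) across %d sequence(s)",
                    sum(removed), sum(removed > 0L)))
  out <- Biostrings::DNAStringSet(kept)
  names(out) <- names(seqs)
  list(sequences = out, removed = removed)
}

## Run `expr` under a temporary RNG state seeded with `seed`.
withSeed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

.checkTransitionTable <- function(model) {
  if (!is.matrix(model) || !identical(dim(model), c(16L, 4L)))
    stop("transition table must be a 16 x 4 matrix (rows = doublet context)")
  if (is.null(colnames(model)) || !setequal(colnames(model), BASES))
    stop("transition table columns must be A, C, G, T")
  doublets <- as.vector(t(outer(BASES, BASES, paste0)))
  if (is.null(rownames(model)) || !setequal(rownames(model), doublets))
    stop("transition table rows must be named by the 16 doublets")
  if (any(abs(rowSums(model) - 1) > 1e-8))
    stop("transition table rows must sum to 1")
  invisible(model)
}

#' Generate a random DNA sequence
#'
#' Draws a synthetic DNA sequence, either i.i.d. uniform over A, C, G, T or
#' from a second-order Markov chain given a 16 x 4 row-stochastic transition
#' table \eqn{P(z|xy)} (rows named by doublet, columns A, C, G, T; the first
#' two bases are uniform).  Deterministic for a given seed.
#'
#' @param length sequence length, >= 1.
#' @param model \code{"iid"} (default) or a 16 x 4 transition matrix.
#' @param seed integer seed.
#' @param id sequence id for the returned set.
#' @return a named \code{DNAStringSet} of one sequence.
#' @export
generateRandomSequence <- function(length, model = "iid", seed, id = "synthetic_1") {
  stopifnot(length >= 1L)
  s <- withSeed(seed, .drawSequence(length, model))
  out <- Biostrings::DNAStringSet(s)
  names(out) <- id
  out
}

.drawSequence <- function(length, model) {
  if (identical(model, "iid"))
    return(paste(sample(BASES, length, replace = TRUE), collapse = ""))
  .checkTransitionTable(model)
  x <- character(length)
  x[1L] <- sample(BASES, 1L)
  if (length >= 2L) x[2L] <- sample(BASES, 1L)
  if (length >= 3L) {
    for (k in 3:length) {
      ctx <- paste0(x[k - 2L], x[k - 1L])
      x[k] <- sample(BASES, 1L, prob = model[ctx, BASES])
    }
  }
  paste(x, collapse = "")
}

#' Generate a synthetic corpus of random DNA sequences
#'
#' @param n number of sequences.
#' @param length common sequence length (or vector of length \code{n}).
#' @param model as in [generateRandomSequence()].
#' @param seed integer seed governing the whole corpus.
#' @param prefix id prefix; ids are \code{prefix_01}, \code{prefix_02}, ...
#' @return a named \code{DNAStringSet} of \code{n} sequences.
#' @export
generateRandomGenomes <- function(n, length, model = "iid", seed,
                                  prefix = "seq") {
  stopifnot(n >= 1L)
  len <- rep_len(length, n)
  seqs <- withSeed(seed, vapply(len, .drawSequence, character(1L),
                                model = model))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- sprintf("%s_%02d", prefix, seq_len(n))
  out
}
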