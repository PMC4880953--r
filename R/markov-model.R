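## Trinucleotide counting, conditional probabilities of the second-order
## Markov chain, and self-information weighting factors.

#' Count trinucleotides over a set of sequences
#'
#' Slides a window of length three one nucleotide per move over every
#' sequence and pools the counts: a sequence of length L contributes
#' max(L - 2, 0) windows.  Windows containing a non-ACGT character are not
#' counted (inputs are normally cleaned first).
#'
#' @param seqs named \code{DNAStringSet} or character vector.
#' @return named integer vector of length 64 (triplets AAA, AAC, ..., TTT).
#' @export
countTrinucleotides <- function(seqs) {
  if (is.character(seqs))
    seqs <- Biostrings::DNAStringSet(seqs)
  if (!length(seqs)) {
    counts <- integer(64L)
    names(counts) <- TRIPLETS
    return(counts)
  }
  tf <- Biostrings::trinucleotideFrequency(seqs, step = 1L)
  counts <- as.integer(colSums(tf))
  names(counts) <- colnames(tf)
  counts[TRIPLETS]
}

#' Conditional probabilities P(z | xy) from trinucleotide counts
#'
#' For each triplet xyz returns \eqn{N_{xyz} / \sum_s N_{xys}}; \code{NA}
#' where the doublet context xy never occurs (undefined, not an error).
#'
#' @param counts complete named 64-entry count vector (zeros allowed).
#' @return named numeric vector of length 64.
#' @export
conditionalProbabilities <- function(counts) {
  stopifnot(length(counts) == 64L, !is.null(names(counts)))
  counts <- counts[TRIPLETS]
  ctx <- substr(TRIPLETS, 1L, 2L)
  den <- stats::ave(as.numeric(counts), ctx, FUN = sum)
  p <- ifelse(den > 0, counts / den, NA_real_)
  names(p) <- TRIPLETS
  p
}

#' @rdname conditionalProbabilities
#' @param x,y,z single bases; returns the scalar P(z | xy).
#' @export
conditionalProbability <- function(counts, x, y, z) {
  p <- conditionalProbabilities(counts)
  unname(p[paste0(x, y, z)])
}

#' Self-information in bits
#'
#' \eqn{I(E) = -\log_2 P(E)}: the information content of observing an event
#' of probability p.  Rare triplets receive large weights.
#'
#' @param p probability (vectorized), each in (0, 1].
#' @return weights in bits, >= 0.
#' @examples
#' signif(selfInformation(c(0.20, 0.66, 0.41, 0.31, 0.44)), 2)
#' @export
selfInformation <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("self-information requires probabilities in (0, 1]")
  -log2(p)
}

#' Build a second-order Markov model from a corpus
#'
#' Pools trinucleotide counts over all input sequences, derives the
#' conditional probabilities P(z | xy) and the self-information weights
#' \eqn{-\log_2 P(z|xy)}.  Weights are \code{NA} for undefined contexts and
#' for zero-probability triplets; [sequenceWeights()] falls back to 1 there.
#'
#' @param seqs named \code{DNAStringSet} or character vector.
#' @return a [TrinucleotideModel-class] object.
#' @export
buildTrinucleotideModel <- function(seqs) {
  counts <- countTrinucleotides(seqs)
  p <- conditionalProbabilities(counts)
  w <- ifelse(!is.na(p) & p > 0, -log2(p), NA_real_)
  names(w) <- TRIPLETS
  new("TrinucleotideModel", counts = counts, probabilities = p, weights = w)
}

#' Per-position weighting factors for one sequence
#'
#' Positions 1 and 2 get weight 1 (no preceding doublet); position k >= 3
#' gets the self-information of \eqn{P(s_k | s_{k-2} s_{k-1})} under the
#' model.  Contexts unseen in the model corpus (or with zero probability)
#' fall back to weight 1, with a message reporting how many positions were
#' affected.
#'
#' @param seq a single sequence: character scalar, \code{DNAString}, or a
#'   \code{DNAStringSet} of length one.
#' @param model a [TrinucleotideModel-class], or a named 64-entry numeric
#'   weight vector (e.g. from [readWeightTable()]).
#' @return numeric vector of weights, length = sequence length.
#' @export
sequenceWeights <- function(seq, model) {
  s <- .asSequenceString(seq)
  L <- nchar(s)
  w <- rep(1, L)
  if (L < 3L)
    return(w)
  wt <- if (is(model, "TrinucleotideModel")) modelWeights(model) else model
  stopifnot(length(wt) == 64L, !is.null(names(wt)))
  trips <- substring(s, seq_len(L - 2L), 3:L)
  wk <- unname(wt[trips])
  nFallback <- sum(is.na(wk))
  if (nFallback > 0L) {
    message(sprintf(
      "%d position(s) with unseen/zero-probability context: weight 1 used",
      nFallback))
    wk[is.na(wk)] <- 1
  }
  w[3:L] <- wk
  w
}

.asSequenceString <- function(seq) {
  if (is.character(seq)) {
    stopifnot(length(seq) == 1L)
    return(toupper(seq))
  }
  s <- as.character(seq)
  if (length(s) != 1L)
    stop("expected a single sequence")
  toupper(unname(s))
}

#' Resampling robustness of the weighting factors
#'
#' Repeatedly draws \code{subsetSize} sequences without replacement from the
#' corpus, rebuilds the model on each subset, and records the 64 weighting
#' factors, returning their per-triplet mean and standard deviation.  Used
#' to check that corpus-level weights are stable snapshots of the analyzed
#' genomes.
#'
#' @param seqs named \code{DNAStringSet}.
#' @param subsetSize number of sequences per trial (<= \code{length(seqs)}).
#' @param trials number of resampling trials, >= 1.
#' @param seed integer seed; results are deterministic given the seed.
#' @return data.frame with columns \code{triplet}, \code{mean}, \code{sd}.
#' @export
bootstrapWeights <- function(seqs, subsetSize, trials, seed) {
  n <- length(seqs)
  if (subsetSize > n)
    stop(sprintf("subsetSize (%d) exceeds number of sequences (%d)",
                 subsetSize, n))
  stopifnot(trials >= 1L)
  mat <- withSeed(seed, {
    m <- matrix(NA_real_, nrow = trials, ncol = 64L,
                dimnames = list(NULL, TRIPLETS))
    for (t in seq_len(trials)) {
      idx <- sample.int(n, subsetSize)
      m[t, ] <- modelWeights(buildTrinucleotideModel(seqs[idx]))
    }
    m
  })
  sds <- apply(mat, 2L, function(v) {
    v <- v[!is.na(v)]
    if (length(v) <= 1L) 0 else stats::sd(v)
  })
  data.frame(
    triplet = TRIPLETS,
    mean = colMeans(mat, na.rm = TRUE),
    sd = sds,
    row.names = NULL
  )
}

## ---- weight-table / count export ------------------------------------------

#' Export the weighting factors as a 4 x (4 x 4) TSV table
#'
#' Lays the 64 weights out as 16 rows (first base x third base) by 4 columns
#' (second base), the conventional compact display for a trinucleotide
#' table.  Undefined weights are written as NA.
#'
#' @param model a [TrinucleotideModel-class] or named 64-entry weight vector.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeWeightTable <- function(model, path) {
  w <- if (is(model, "TrinucleotideModel")) modelWeights(model) else model
  stopifnot(length(w) == 64L, !is.null(names(w)))
  df <- data.frame(
    first = rep(BASES, each = 4L),
    third = rep(BASES, times = 4L),
    stringsAsFactors = FALSE
  )
  for (second in BASES)
    df[[second]] <- w[paste0(df$first, second, df$third)]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a weight table written by [writeWeightTable()]
#'
#' @param path TSV path.
#' @return named numeric vector of 64 weights.
#' @export
readWeightTable <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("first", "third", BASES)
  if (!all(need %in% names(df)) || nrow(df) != 16L)
    stop("not a weight table: expected 16 rows with columns ",
         paste(need, collapse = ", "))
  w <- rep(NA_real_, 64L)
  names(w) <- TRIPLETS
  for (second in BASES)
    w[paste0(df$first, second, df$third)] <- df[[second]]
  w
}

#' Export trinucleotide counts as TSV
#'
#' @param model a [TrinucleotideModel-class] or named 64-entry count vector.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeTrinucleotideCounts <- function(model, path) {
  cts <- if (is(model, "TrinucleotideModel")) modelCounts(model) else model
  utils::write.table(
    data.frame(triplet = names(cts), count = as.integer(cts)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
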