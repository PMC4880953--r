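## UPGMA tree construction, Newick I/O, and the Robinson-Foulds
## symmetric-difference distance.  Trees are "phylo" objects (ape).

#' UPGMA tree from a distance matrix
#'
#' Standard unweighted pair-group agglomeration: repeatedly merge the
#' closest pair of clusters at height d/2; the distance from a merged
#' cluster to any other is the size-weighted arithmetic mean of its parts'
#' distances.  Ties are broken by the lexicographically smallest pair of
#' cluster representatives (a cluster is represented by its alphabetically
#' first leaf), so the output is deterministic and invariant to input label
#' order.  The result is a rooted ultrametric tree.
#'
#' @param dm a [DistanceMatrix-class], \code{dist}, or symmetric numeric
#'   matrix with dimnames; entries must be finite and non-negative.
#' @return a rooted \code{phylo} tree with branch lengths.
#' @export
upgma <- function(dm) {
  m <- if (is(dm, "DistanceMatrix")) as.matrix(dm) else as.matrix(dm)
  if (is.null(rownames(m)))
    stop("distance matrix must carry labels")
  if (nrow(m) < 2L)
    stop("need at least 2 taxa")
  if (any(!is.finite(m)))
    stop("distance matrix contains non-finite entries")
  if (max(abs(m - t(m))) > 1e-12)
    stop("distance matrix must be symmetric")
  labs <- rownames(m)
  ## active clusters: representative label, size, height, newick fragment
  cl <- lapply(labs, function(l)
    list(rep = l, size = 1L, height = 0, nwk = l))
  names(cl) <- labs
  d <- m
  while (length(cl) > 1L) {
    keys <- names(cl)
    n <- length(keys)
    best <- NULL
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        dij <- d[keys[i], keys[j]]
        pair <- sort(c(cl[[i]]$rep, cl[[j]]$rep))
        if (is.null(best) || dij < best$d ||
            (dij == best$d &&
             (pair[1L] < best$pair[1L] ||
              (pair[1L] == best$pair[1L] && pair[2L] < best$pair[2L])))) {
          best <- list(i = i, j = j, d = dij, pair = pair)
        }
      }
    }
    a <- cl[[best$i]]
    b <- cl[[best$j]]
    h <- best$d / 2
    merged <- list(
      rep = min(a$rep, b$rep),
      size = a$size + b$size,
      height = h,
      nwk = sprintf("(%s:%.10g,%s:%.10g)",
                    a$nwk, h - a$height, b$nwk, h - b$height))
    ka <- keys[best$i]
    kb <- keys[best$j]
    others <- setdiff(keys, c(ka, kb))
    newKey <- merged$rep
    if (length(others)) {
      dn <- (a$size * d[ka, others] + b$size * d[kb, others]) / merged$size
      d2 <- d[others, others, drop = FALSE]
      d <- rbind(cbind(d2, dn), c(dn, 0))
      rownames(d)[length(others) + 1L] <- newKey
      colnames(d)[length(others) + 1L] <- newKey
    } else {
      d <- matrix(0, 1L, 1L, dimnames = list(newKey, newKey))
    }
    cl[[ka]] <- NULL
    cl[[kb]] <- NULL
    cl[[newKey]] <- merged
  }
  ape::read.tree(text = paste0(cl[[1L]]$nwk, ";"))
}

#' Newick I/O
#'
#' Thin wrappers around the standard Newick reader/writer with a light
#' well-formedness check that reports the character position of unbalanced
#' parentheses.
#'
#' @param path Newick file path.
#' @return \code{readNewick}: a \code{phylo}; \code{writeNewick}: the path,
#'   invisibly.
#' @export
readNewick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  .checkNewick(txt)
  tr <- ape::read.tree(text = txt)
  if (is.null(tr))
    stop("malformed Newick in ", path)
  tr
}

.checkNewick <- function(txt) {
  chars <- strsplit(txt, "")[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("Newick parse error: unmatched ')' at character %d", i))
    }
  }
  if (depth != 0L)
    stop(sprintf(
      "Newick parse error: %d unclosed '(' at end of input (length %d)",
      depth, length(chars)))
  if (!grepl(";\\s*$", txt))
    stop("Newick parse error: missing terminal ';'")
  invisible(TRUE)
}

#' @rdname readNewick
#' @param tree a \code{phylo}.
#' @export
writeNewick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

## Non-trivial bipartitions of a tree as canonical strings.  Each internal
## edge splits the leaves in two; the side not containing the reference
## leaf (the alphabetically first label) is sorted and serialized.  Rooted
## trees are handled as unrooted: the two root clades induce the same
## split and are deduplicated.
.bipartitions <- function(tree) {
  tips <- tree$tip.label
  n <- length(tips)
  ref <- min(tips)
  nnode <- tree$Nnode
  root <- n + 1L
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  cladeTips <- function(node) {
    if (node <= n)
      return(tips[node])
    unlist(lapply(kids[[as.character(node)]], cladeTips), use.names = FALSE)
  }
  keys <- character(0L)
  internal <- setdiff(root:(n + nnode), root)
  for (node in internal) {
    s <- cladeTips(node)
    if (ref %in% s)
      s <- setdiff(tips, s)
    if (length(s) >= 2L && length(s) <= n - 2L)
      keys <- c(keys, paste(sort(s), collapse = "\x1f"))
  }
  unique(keys)
}

#' Robinson-Foulds distance between two trees
#'
#' Both trees are treated as unrooted; the distance is the size of the
#' symmetric difference of their non-trivial bipartition sets
#' (\eqn{|B_1 \setminus B_2| + |B_2 \setminus B_1|}), i.e. each split
#' present in only one tree counts once per direction.  Multifurcating
#' trees are accepted; only the bipartitions actually present are compared.
#' Branch lengths are ignored.
#'
#' @param t1,t2 \code{phylo} trees on the same leaf set (>= 4 leaves).
#' @return non-negative integer.
#' @export
robinsonFoulds <- function(t1, t2) {
  l1 <- sort(t1$tip.label)
  l2 <- sort(t2$tip.label)
  if (!identical(l1, l2)) {
    only1 <- setdiff(l1, l2)
    only2 <- setdiff(l2, l1)
    stop("leaf sets differ",
         if (length(only1)) paste0("; only in tree 1: ",
                                   paste(only1, collapse = ", ")) else "",
         if (length(only2)) paste0("; only in tree 2: ",
                                   paste(only2, collapse = ", ")) else "")
  }
  if (length(l1) < 4L)
    stop("Robinson-Foulds needs at least 4 leaves")
  b1 <- .bipartitions(t1)
  b2 <- .bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}
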