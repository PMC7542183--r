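# Distance matrices to trees and standard files: square PHYLIP writer
# and reader, neighbor joining (Saitou-Nei, via ape), Newick output, and
# quartet-split extraction.

#' Write and read square PHYLIP distance matrices
#'
#' Square dialect: first line the taxon count, then one row per taxon
#' with the name padded to 10 characters and values to 6 decimal
#' places.  The writer is the single formatting authority; the reader
#' round-trips its output up to that precision.
#'
#' @param m symmetric numeric matrix with dimnames (labels at most 10
#'   characters after sanitization).
#' @param path optional file path; when `NULL` the text is returned.
#' @return `write_phylip()`: the text (invisibly when written to file);
#'   `read_phylip()`: a numeric matrix with dimnames.
#' @examples
#' m <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
#' cat(write_phylip(m))
#' @export
write_phylip <- function(m, path = NULL) {
  labs <- rownames(m)
  if (is.null(labs)) stop("matrix needs dimnames")
  labs <- gsub("[^A-Za-z0-9_.-]", "_", labs)
  if (any(nchar(labs) > 10L))
    stop("taxon label longer than 10 characters: ",
         labs[which.max(nchar(labs))])
  rows <- vapply(seq_len(nrow(m)), function(i)
    paste0(formatC(labs[i], width = -10L),
           paste(sprintf("%.6f", m[i, ]), collapse = " ")),
    character(1))
  text <- paste0(c(as.character(nrow(m)), rows), "\n", collapse = "")
  if (is.null(path)) return(text)
  cat(text, file = path)
  invisible(text)
}

#' @rdname write_phylip
#' @param text PHYLIP text (used when `path` is `NULL`).
#' @export
read_phylip <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(path)) readLines(path)
           else strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  k <- as.integer(trimws(lines[1]))
  if (length(lines) != k + 1L) stop("malformed PHYLIP matrix")
  labs <- character(k)
  m <- matrix(0, k, k)
  for (i in seq_len(k)) {
    labs[i] <- trimws(substr(lines[i + 1L], 1L, 10L))
    vals <- as.numeric(strsplit(trimws(substr(lines[i + 1L], 11L, 1e6)),
                                "[[:space:]]+")[[1]])
    if (length(vals) != k) stop("row ", i, " has ", length(vals), " values")
    m[i, ] <- vals
  }
  dimnames(m) <- list(labs, labs)
  m
}

#' Neighbor joining
#'
#' Saitou-Nei agglomeration on a distance matrix, returning an unrooted
#' tree.  On an additive matrix the unique generating tree is recovered
#' exactly (four-point condition).  Negative branch lengths, which can
#' arise on non-additive input, are clamped to zero with a warning;
#' topology is unaffected.
#'
#' @param m symmetric numeric distance matrix with dimnames, at least 3
#'   taxa.
#' @return An unrooted `phylo` tree (ape).
#' @export
neighbor_joining <- function(m) {
  if (nrow(m) < 3L) stop("neighbor joining needs at least 3 taxa")
  if (is.null(rownames(m))) stop("matrix needs dimnames")
  tr <- ape::nj(stats::as.dist(m))
  if (any(tr$edge.length < 0)) {
    warning("negative NJ branch lengths clamped to zero")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Write a tree in Newick format
#'
#' Deterministic output: children are rotated into alphabetical leaf
#' order before writing, so equal trees always serialize identically.
#'
#' @param t a `phylo` tree.
#' @param path optional file path.
#' @return The Newick string (invisibly when written to file).
#' @export
write_newick <- function(t, path = NULL) {
  t <- ape::rotateConstr(t, sort(t$tip.label))
  txt <- ape::write.tree(t)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' @rdname write_newick
#' @param text a Newick string.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  if (!is.null(path)) ape::read.tree(path) else ape::read.tree(text = text)
}

#' Which quartet split does a tree induce?
#'
#' Restricts the tree to four leaves and reports which pairing is
#' separated by an internal edge: `"AC|BD"`-style strings built from the
#' supplied labels, or `"unresolved"` for a star quartet.
#'
#' @param t a `phylo` tree.
#' @param quartet character vector of four leaf labels.
#' @return A string `"<x><y>|<z><w>"` with the first pair containing the
#'   first quartet label, or `"unresolved"`.
#' @examples
#' tr <- read_newick(text = "((A:1,C:1):1,B:1,D:1);")
#' topology_split(tr, c("A", "B", "C", "D"))
#' @export
topology_split <- function(t, quartet) {
  if (length(quartet) != 4L || !all(quartet %in% t$tip.label))
    stop("quartet must name four leaves of the tree")
  sub <- ape::keep.tip(t, quartet)
  # topological pairwise distances: a cherry pair in a resolved quartet
  # is 2 edges apart, cross pairs 3; in a star all pairs are 2
  sub$edge.length <- rep(1, nrow(sub$edge))
  dm <- stats::cophenetic(sub)[quartet, quartet]
  a <- quartet[1]
  partner <- quartet[-1][which(dm[a, quartet[-1]] == min(dm[a, quartet[-1]]))]
  if (length(partner) != 1L) return("unresolved")
  rest <- setdiff(quartet, c(a, partner))
  paste0(a, partner, "|", rest[1], rest[2])
}
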