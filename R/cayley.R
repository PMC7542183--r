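# Independent distance oracle: explicit weighted Cayley graph plus
# shortest-path search (igraph).  Everything here is deliberately
# separate from the rewriting engine, so agreement between the two is a
# genuine cross-check, not a tautology.

#' Enumerate the group generated by a generator set
#'
#' Breadth-first closure under right multiplication by the generators,
#' starting from the identity.  Fails loudly if the closure exceeds
#' `bound` elements.
#'
#' @param gens a [generator_set()].
#' @param bound maximum number of elements to enumerate.
#' @return A list with components `elements` (list of permutations, the
#'   identity first, in BFS order), `keys` (their one-line keys) and
#'   `words` (for each element, a word over the labels evaluating to it,
#'   found by BFS — shortest in letter count, no weight-optimality
#'   claim).
#' @export
enumerate_group <- function(gens, bound = 50000L) {
  n <- gens$n
  id <- perm_identity(n)
  elements <- list(id)
  words <- list(character(0))
  index <- new.env(parent = emptyenv())
  assign(perm_key(id), 1L, envir = index)
  head <- 1L
  while (head <= length(elements)) {
    cur <- elements[[head]]
    curw <- words[[head]]
    for (lab in gens$labels) {
      nxt <- compose(cur, gens$perms[[lab]])
      k <- perm_key(nxt)
      if (!exists(k, envir = index, inherits = FALSE)) {
        if (length(elements) >= bound)
          stop("group enumeration exceeded bound ", bound)
        elements[[length(elements) + 1L]] <- nxt
        words[[length(words) + 1L]] <- c(curw, lab)
        assign(k, length(elements), envir = index)
      }
    }
    head <- head + 1L
  }
  list(elements = elements,
       keys = vapply(elements, perm_key, character(1)),
       words = words, index = index)
}

#' Build the weighted Cayley graph
#'
#' Vertices are the group elements (enumerated by [enumerate_group()]);
#' an edge joins `g` and `g s` for each generator `s`, weighted by
#' `s`'s weight.  Both built-in models consist of involutions, so the
#' graph is undirected.
#'
#' @param gens a [generator_set()].
#' @param bound enumeration bound passed to [enumerate_group()].
#' @return A list with the enumeration (`elements`, `keys`, `index`),
#'   the `igraph` object (`graph`), and `edge_labels`.
#' @export
cayley_graph <- function(gens, bound = 50000L) {
  enum <- enumerate_group(gens, bound)
  keys <- enum$keys
  nverts <- length(keys)
  k <- length(gens$labels)
  lookup <- enum$index
  # each generator contributes one neighbor per vertex; keep each
  # undirected edge once (vi < target)
  from <- integer(nverts * k); to <- integer(nverts * k)
  wts <- numeric(nverts * k); elabs <- character(nverts * k)
  nedges <- 0L
  for (gi in seq_len(k)) {
    lab <- gens$labels[[gi]]
    pimg <- unclass(gens$perms[[lab]])
    w <- as.numeric(gens$weights[[lab]])
    for (vi in seq_len(nverts)) {
      timg <- pimg[unclass(enum$elements[[vi]])]
      ti <- get(paste(timg, collapse = ","), envir = lookup,
                inherits = FALSE)
      if (vi < ti) {
        nedges <- nedges + 1L
        from[nedges] <- vi; to[nedges] <- ti
        wts[nedges] <- w; elabs[nedges] <- lab
      }
    }
  }
  length(from) <- nedges; length(to) <- nedges
  length(wts) <- nedges; length(elabs) <- nedges
  g <- igraph::make_graph(rbind(from, to), n = nverts, directed = FALSE)
  igraph::E(g)$weight <- wts
  igraph::E(g)$label <- elabs
  list(elements = enum$elements, keys = keys, index = enum$index,
       words = enum$words, graph = g)
}

cayley_vertex <- function(cg, p) {
  k <- perm_key(p)
  if (!exists(k, envir = cg$index, inherits = FALSE))
    stop("permutation not in the generated group")
  get(k, envir = cg$index, inherits = FALSE)
}

#' Geodesic distance on the weighted Cayley graph
#'
#' Exact shortest-path (Dijkstra) distance from the identity to `g`,
#' with a witness path whose edge labels spell a word evaluating to `g`
#' of weight equal to the distance.  This is the brute-force oracle for
#' [weighted_length()].
#'
#' @param g a [permutation()] in the generated group.
#' @param gens a [generator_set()].
#' @param cg optional pre-built [cayley_graph()] (rebuilt otherwise).
#' @return The distance (numeric) with attribute `witness`, the word.
#' @examples
#' gens <- linear_inversion_model(3)
#' geodesic_distance(make_inversion(1, 3, 3), gens)   # 2 under length weights
#' @export
geodesic_distance <- function(g, gens, cg = NULL) {
  if (is.null(cg)) cg <- cayley_graph(gens)
  vid <- cayley_vertex(cg, g)
  sp <- igraph::shortest_paths(cg$graph, from = 1, to = vid,
                               weights = igraph::E(cg$graph)$weight,
                               output = "epath")
  epath <- sp$epath[[1]]
  d <- sum(igraph::E(cg$graph)$weight[epath])
  word <- igraph::E(cg$graph)$label[epath]
  # the epath's labels visit edges in path order; each edge is one
  # generator multiplication, so the labels spell a word for g
  structure(d, witness = as.character(word))
}

#' All geodesic distances from the identity
#'
#' Single-source Dijkstra over the whole group: the exhaustive oracle
#' table used to cross-check the rewriting engine element by element.
#'
#' @param gens a [generator_set()].
#' @param cg optional pre-built [cayley_graph()].
#' @return A named numeric vector: one distance per group element,
#'   keyed by one-line image string (identity included, distance 0).
#' @export
all_distances <- function(gens, cg = NULL) {
  if (is.null(cg)) cg <- cayley_graph(gens)
  d <- igraph::distances(cg$graph, v = 1,
                         weights = igraph::E(cg$graph)$weight)[1, ]
  names(d) <- cg$keys
  d
}
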