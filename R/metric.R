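# Minimal weighted lengths via normal forms, genome-to-genome distances,
# the dihedral quotient for circular genomes, and distance matrices.

#' Some word spelling a group element
#'
#' Breadth-first factorization of `g` over the generators: any valid
#' word, shortest in letter count but with no weight-optimality claim
#' (optimality comes from normalization afterwards).  Signals an error
#' if `g` is not reached within the enumeration bound, i.e. lies outside
#' the generated group.
#'
#' @param g a [permutation()].
#' @param gens a [generator_set()].
#' @param enum optional pre-built [enumerate_group()] result.
#' @return A word (character vector of labels); `character(0)` for the
#'   identity.
#' @export
initial_word <- function(g, gens, enum = NULL) {
  if (is.null(enum)) enum <- enumerate_group(gens)
  k <- perm_key(g)
  if (!exists(k, envir = enum$index, inherits = FALSE))
    stop("permutation is not in the group generated by the generator set")
  enum$words[[get(k, envir = enum$index, inherits = FALSE)]]
}

#' Minimal weighted length of a group element
#'
#' The least total weight over all spellings of `g` as a product of
#' generators, computed as the weight of `g`'s unique normal form under
#' a confluent rewriting system: any initial word for `g` is normalized,
#' and confluence plus the weight-first reduction order guarantee the
#' normal form is the minimum-weight spelling.
#'
#' @param g a [permutation()].
#' @param sys a confluent `rewriting_system` for `gens`.
#' @param gens a [generator_set()]; defaults to the system's own.
#' @param enum optional pre-built enumeration (speeds up batch calls).
#' @return A [rational()] with attribute `witness`: the normal-form
#'   word, which evaluates to `g` and whose weight equals the value.
#' @examples
#' gens <- linear_inversion_model(3)
#' sys <- knuth_bendix(linear_inversion_presentation(gens))
#' weighted_length(make_inversion(1, 3, 3), sys)
#' @export
weighted_length <- function(g, sys, gens = sys$gens, enum = NULL) {
  if (!isTRUE(sys$confluent))
    stop("weighted_length needs a certified-confluent rewriting system")
  w0 <- initial_word(g, gens, enum)
  nf <- normalize(w0, sys)
  structure(word_weight(nf, sys$order), witness = nf)
}

#' Weighted distance between two genomes
#'
#' The minimal weighted length of the group element separating the two
#' arrangements (the product of `g2` with the inverse of `g1` under the
#' package composition convention).  Symmetric because every generator
#' in the built-in models is its own inverse with equal weight.
#'
#' @param g1,g2 genome arrangements ([permutation()]s of equal size).
#' @param sys a confluent `rewriting_system`.
#' @param gens a [generator_set()]; defaults to the system's own.
#' @param enum optional pre-built enumeration.
#' @return A [rational()] with attribute `witness`.
#' @export
genome_distance <- function(g1, g2, sys, gens = sys$gens, enum = NULL) {
  if (perm_n(g1) != perm_n(g2)) stop("genomes have different sizes")
  weighted_length(compose(g2, inverse(g1)), sys, gens, enum)
}

#' The dihedral group acting on circular positions
#'
#' All `2n` rotations and reflections of the position circle `1..n`,
#' as permutations.
#'
#' @param n number of positions.
#' @return A list of `2n` permutations.
#' @export
dihedral_elements <- function(n) {
  rot <- function(k) permutation(((seq_len(n) - 1L + k) %% n) + 1L)
  refl <- permutation(n + 1L - seq_len(n))
  rots <- lapply(0:(n - 1L), rot)
  c(rots, lapply(rots, function(r) compose(refl, r)))
}

#' Weighted distance between circular genomes
#'
#' Quotients out the rotational and reflection symmetry of a circular
#' genome: the distance is the minimum of [weighted_length()] over the
#' dihedral orbit of the separating element (relabelings of the position
#' circle applied to one side).  Zero exactly when the genomes differ
#' only by rotation/reflection, and invariant when both genomes are
#' relabeled simultaneously.  The orbit convention is isolated here so
#' an alternative quotient convention can be swapped in.
#'
#' @inheritParams genome_distance
#' @return A [rational()] with attribute `witness` (witness of the
#'   minimizing orbit representative).
#' @export
circular_distance <- function(g1, g2, sys, gens = sys$gens, enum = NULL) {
  if (perm_n(g1) != perm_n(g2)) stop("genomes have different sizes")
  topo <- attr(sys, "topology")
  if (identical(topo, "linear"))
    stop("circular_distance called with a linear model")
  if (is.null(enum)) enum <- enumerate_group(gens)
  best <- NULL
  for (s in dihedral_elements(perm_n(g1))) {
    # relabel one genome by the symmetry s, then measure
    z <- compose(compose(s, g2), inverse(g1))
    d <- weighted_length(z, sys, gens, enum)
    if (is.null(best) || rat_cmp(d, best) < 0L) best <- d
  }
  best
}

#' Pairwise weighted distance matrix
#'
#' Distances between all pairs of labeled genomes, by the rewriting
#' engine (when `sys` is supplied) or by the Cayley-graph oracle (when
#' `sys` is `NULL`) — the oracle route serves models too small to
#' justify completion and independent cross-checks.
#'
#' @param genomes named list of [permutation()]s (all the same size,
#'   distinct labels).
#' @param gens a [generator_set()].
#' @param sys a confluent `rewriting_system`, or `NULL` to use the
#'   oracle.
#' @param circular quotient by the dihedral symmetry (circular genomes).
#' @return A symmetric numeric matrix with zero diagonal, dimnames the
#'   genome labels.
#' @examples
#' gens <- linear_inversion_model(4)
#' gs <- list(a = perm_identity(4), b = make_inversion(1, 4, 4))
#' distance_matrix(gs, gens)          # via the Dijkstra oracle
#' @export
distance_matrix <- function(genomes, gens, sys = NULL, circular = FALSE) {
  labs <- names(genomes)
  if (is.null(labs) || anyDuplicated(labs) > 0L || any(labs == ""))
    stop("genomes must be a named list with distinct labels")
  sizes <- vapply(genomes, perm_n, integer(1))
  if (length(unique(sizes)) != 1L) stop("genomes have mixed sizes")
  k <- length(genomes)
  m <- matrix(0, k, k, dimnames = list(labs, labs))
  if (k == 1L) return(m)
  if (is.null(sys)) {
    cg <- cayley_graph(gens)
    dvec <- all_distances(gens, cg)  # one single-source Dijkstra
    dih <- if (circular) dihedral_elements(sizes[[1]]) else
      list(perm_identity(sizes[[1]]))
    for (a in seq_len(k - 1L)) {
      for (b in seq.int(a + 1L, k)) {
        d <- min(vapply(dih, function(s) {
          z <- compose(compose(s, genomes[[b]]), inverse(genomes[[a]]))
          k2 <- perm_key(z)
          if (is.na(dvec[k2]))
            stop("permutation not in the generated group")
          dvec[[k2]]
        }, numeric(1)))
        m[a, b] <- m[b, a] <- d
      }
    }
  } else {
    enum <- enumerate_group(gens)
    for (a in seq_len(k - 1L)) {
      for (b in seq.int(a + 1L, k)) {
        d <- if (circular)
          circular_distance(genomes[[a]], genomes[[b]], sys, gens, enum)
        else
          genome_distance(genomes[[a]], genomes[[b]], sys, gens, enum)
        m[a, b] <- m[b, a] <- as.numeric(d)
      }
    }
  }
  m
}
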