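# Weighted inversion models: generator sets with exact positive weights
# and a precedence, plus their group presentations.  Every relation of
# every presentation is verified by evaluating both sides as concrete
# permutations before it is handed to the completion engine.

#' Weighted generator sets
#'
#' A set of labeled generator permutations with positive exact weights
#' and a fixed precedence (the total order used for tie-breaks in the
#' weighted lexicographic reduction order).  The set must be closed under
#' inverses; for both built-in inversion models every generator is an
#' involution, which satisfies this automatically.
#'
#' @param perms named list of [permutation()]s (names are the labels).
#' @param weights named list/vector of positive weights ([rational()],
#'   integer, or strings like `"3/2"`), one per label.
#' @param precedence character vector of all labels in ascending
#'   precedence order (later = greater).  Defaults to ascending weight
#'   with ties broken by label order as given in `perms`.
#' @return An object of class `generator_set` with fields `labels`,
#'   `perms`, `weights`, `precedence`, `n`.
#' @export
generator_set <- function(perms, weights, precedence = NULL) {
  labels <- names(perms)
  if (is.null(labels) || anyDuplicated(labels) > 0L || any(labels == ""))
    stop("perms must be a named list with distinct labels")
  sizes <- vapply(perms, perm_n, integer(1))
  if (length(unique(sizes)) != 1L) stop("generators have mixed sizes")
  w <- lapply(labels, function(l) as_rational(weights[[l]]))
  names(w) <- labels
  for (l in labels) {
    if (rat_cmp(w[[l]], rational(0)) <= 0L)
      stop("weight of ", l, " must be positive")
  }
  # inverse closure
  keys <- vapply(perms, perm_key, character(1))
  for (l in labels) {
    ik <- perm_key(inverse(perms[[l]]))
    if (!ik %in% keys)
      stop("generator set not closed under inverses (", l, ")")
  }
  if (is.null(precedence)) {
    wnum <- vapply(w, as.numeric, numeric(1))
    precedence <- labels[order(wnum, seq_along(labels))]
  }
  if (!setequal(precedence, labels) || length(precedence) != length(labels))
    stop("precedence must be a permutation of the labels")
  structure(list(labels = labels, perms = perms, weights = w,
                 precedence = precedence, n = sizes[[1]]),
            class = "generator_set")
}

#' @export
print.generator_set <- function(x, ...) {
  cat("generator_set: ", length(x$labels), " generators on 1..", x$n, "\n",
      sep = "")
  wtxt <- vapply(x$weights, format, character(1))
  cat("  weights: ", paste0(x$labels, "=", wtxt, collapse = " "), "\n")
  cat("  precedence (ascending): ", paste(x$precedence, collapse = " < "),
      "\n")
  invisible(x)
}

#' Group presentations
#'
#' Generators plus relations `u = v` between words over the generator
#' labels.  Every relation is verified by evaluation in the concrete
#' permutation group on construction.
#'
#' @param gens a [generator_set()].
#' @param relations list of two-element lists of label vectors
#'   (`character(0)` is the empty word).
#' @return An object of class `presentation`.
#' @export
presentation <- function(gens, relations) {
  stopifnot(inherits(gens, "generator_set"))
  for (rel in relations) {
    lu <- evaluate_word(rel[[1]], gens)
    lv <- evaluate_word(rel[[2]], gens)
    if (!(lu == lv))
      stop("relation fails evaluation: ",
           paste(rel[[1]], collapse = " "), " = ",
           paste(rel[[2]], collapse = " "))
  }
  structure(list(gens = gens, relations = relations), class = "presentation")
}

#' @export
print.presentation <- function(x, ...) {
  cat("presentation: ", length(x$gens$labels), " generators, ",
      length(x$relations), " relations\n", sep = "")
  invisible(x)
}

inversion_label <- function(i, j) sprintf("t[%d,%d]", i, j)

#' The linear all-inversions model
#'
#' All inversion operators `t[i,j]`, `1 <= i < j <= n`, on a linear
#' genome with `n` regions: `n(n-1)/2` generators.  The `"length"`
#' weight scheme assigns weight `j - i` (longer inversions cost more);
#' `"unit"` assigns weight 1 to every inversion (the uniform model used
#' by GRIMM-style distances); a named list gives custom positive weights.
#'
#' @param n number of regions (`n >= 2`).
#' @param weight_scheme `"length"`, `"unit"`, or a named list of
#'   positive weights keyed by label `t[i,j]`.
#' @param precedence optional precedence override (see [generator_set()]).
#' @return A [generator_set()].
#' @examples
#' linear_inversion_model(4)
#' @export
linear_inversion_model <- function(n, weight_scheme = "length",
                                   precedence = NULL) {
  n <- as.integer(n)
  if (n < 2L) stop("need n >= 2")
  perms <- list()
  weights <- list()
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      lab <- inversion_label(i, j)
      perms[[lab]] <- make_inversion(i, j, n)
      weights[[lab]] <- if (identical(weight_scheme, "length"))
        rational(j - i)
      else if (identical(weight_scheme, "unit"))
        rational(1)
      else as_rational(weight_scheme[[lab]])
    }
  }
  generator_set(perms, weights, precedence)
}

#' Order of the product of two permutations
#'
#' The smallest `m >= 1` with `(g h)^m = e`; always finite in a finite
#' group.  Supplies the exponents of the pairwise relators
#' `(g h)^m = e` in the linear model's presentation.
#'
#' @param g,h permutations of equal size.
#' @return A positive integer.
#' @examples
#' s1 <- permutation(c(2, 1, 3, 4)); s2 <- permutation(c(1, 3, 2, 4))
#' order_of_product(s1, s2)   # braid pair: 3
#' @export
order_of_product <- function(g, h) perm_elt_order(compose(g, h))

#' Presentation of the linear all-inversions model
#'
#' Emits three relator families, each verified by evaluation:
#' involutions `g g = e`; for every unordered pair of distinct
#' generators the power relator `(g h)^m = e` with `m` the order of the
#' product (ordered-pair duplicates are conjugate relators and are
#' omitted); and for every inversion with `j - i >= 2` a factorization
#' relation `t[i,j] = w` where `w` is the bubble word reversing the
#' block `i..j` with adjacent inversions.
#'
#' The involution and power families alone form an abstract
#' Coxeter-type presentation, which for these generating sets defines
#' an infinite group (already for three regions the three inversions
#' give the (3,3,3) triangle group); the factorization family pins the
#' group to the symmetric group, since the adjacent inversions present
#' it and every remaining generator is expressed in terms of them.
#' Completion therefore terminates, and because the reduced confluent
#' system depends only on the group and the reduction order, the rule
#' counts do not depend on this choice of faithful presentation.
#'
#' @param gens a [generator_set()] from [linear_inversion_model()].
#' @return A [presentation()].
#' @export
linear_inversion_presentation <- function(gens) {
  stopifnot(inherits(gens, "generator_set"))
  rels <- list()
  labs <- gens$labels
  for (l in labs)
    rels[[length(rels) + 1L]] <- list(c(l, l), character(0))
  k <- length(labs)
  if (k > 1L) {
    for (a in seq_len(k - 1L)) {
      for (b in seq.int(a + 1L, k)) {
        g <- gens$perms[[labs[a]]]
        h <- gens$perms[[labs[b]]]
        m <- order_of_product(g, h)
        if (m > 1L)
          rels[[length(rels) + 1L]] <-
            list(rep(c(labs[a], labs[b]), m), character(0))
      }
    }
  }
  # factorization of each long inversion over adjacent inversions
  for (l in labs) {
    ij <- parse_inversion_label(l)
    if (ij[2] - ij[1] >= 2L)
      rels[[length(rels) + 1L]] <-
        list(l, adjacent_factorization(ij[1], ij[2]))
  }
  presentation(gens, rels)
}

parse_inversion_label <- function(label) {
  m <- regmatches(label, regexec("^t\\[(\\d+),(\\d+)\\]$", label))[[1]]
  if (length(m) != 3L) stop("not an inversion label: ", label)
  c(as.integer(m[2]), as.integer(m[3]))
}

# bubble word reversing block i..j using adjacent inversions t[k,k+1]:
# repeatedly carry the leading region to the end of the shrinking block
adjacent_factorization <- function(i, j) {
  out <- character(0)
  for (top in seq.int(j - 1L, i)) {
    for (kk in seq.int(i, top))
      out <- c(out, inversion_label(kk, kk + 1L))
  }
  out
}

#' The circular adjacent-inversion model
#'
#' Generators `s[1]..s[n]` on a circular genome with `n` regions:
#' `s[i] = (i, i+1)` for `i < n` and `s[n] = (1, n)`, all with unit
#' weight.
#'
#' @param n number of regions (`n >= 3`).
#' @param precedence optional precedence override.
#' @return A [generator_set()].
#' @export
circular_adjacent_model <- function(n, precedence = NULL) {
  n <- as.integer(n)
  if (n < 3L) stop("need n >= 3")
  perms <- list()
  for (i in seq_len(n - 1L))
    perms[[sprintf("s[%d]", i)]] <- make_inversion(i, i + 1L, n)
  perms[[sprintf("s[%d]", n)]] <- {
    img <- seq_len(n); img[c(1L, n)] <- c(n, 1L); permutation(img)
  }
  weights <- rep(list(rational(1)), n)
  names(weights) <- names(perms)
  generator_set(perms, weights, precedence)
}

#' Presentation of the circular adjacent-inversion model
#'
#' Emits the four relation families of the circular model: involutions
#' `s[i]^2 = e`; commutations `s[i] s[j] = s[j] s[i]` for circularly
#' non-adjacent indices (`(i - j) mod n` not in `{1, n-1}`); braid
#' relations `s[i] s[i+1] s[i] = s[i+1] s[i] s[i+1]` for `i < n`; and
#' the wrap-around relation
#' `s[n] = s[n-1] s[n-2] ... s[2] s[1] s[2] ... s[n-2] s[n-1]`.
#' Every relation is verified by evaluation; a failure indicates an
#' index-convention error and raises.
#'
#' @param gens a [generator_set()] from [circular_adjacent_model()].
#' @return A [presentation()].
#' @export
circular_adjacent_presentation <- function(gens) {
  stopifnot(inherits(gens, "generator_set"))
  n <- length(gens$labels)
  s <- function(i) sprintf("s[%d]", i)
  rels <- list()
  for (i in seq_len(n))
    rels[[length(rels) + 1L]] <- list(c(s(i), s(i)), character(0))
  if (n > 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        d <- (i - j) %% n
        if (d != 1L && d != (n - 1L))
          rels[[length(rels) + 1L]] <- list(c(s(i), s(j)), c(s(j), s(i)))
      }
    }
  }
  # braid relations s_i s_{i+1} s_i = s_{i+1} s_i s_{i+1}, i = 1..n-1
  # (for i = n-1 the partner is s_n = (1,n), which shares position n
  # with s_{n-1}, so the braid identity still holds)
  for (i in seq_len(n - 1L))
    rels[[length(rels) + 1L]] <-
      list(c(s(i), s(i + 1L), s(i)), c(s(i + 1L), s(i), s(i + 1L)))
  # wrap-around: s_n = s_{n-1} ... s_2 s_1 s_2 ... s_{n-1}
  if (n >= 3L) {
    down <- vapply(seq.int(n - 1L, 1L), s, character(1))
    up <- vapply(seq.int(2L, n - 1L), s, character(1))
    rels[[length(rels) + 1L]] <- list(c(down, up), s(n))
  }
  presentation(gens, rels)
}

#' Build a model from arbitrary invertible generators
#'
#' Generic entry point for user-supplied rearrangement models: any
#' inverse-closed set of labeled permutations with positive weights.
#' Relators are generated in two families: involution/`(g h)^m` power
#' relators from the orders of pairwise products, and Cayley-graph
#' relations `w_x s = w_{xs}` from a breadth-first enumeration of the
#' generated group (`w_x` a BFS word for element `x`).  The second
#' family makes the presentation faithful to the concrete permutation
#' group — power relators alone can present a larger (even infinite)
#' group — at the cost of enumerating the group, so this entry point is
#' intended for small models.
#'
#' @inheritParams generator_set
#' @param bound group-enumeration bound (faithfulness requires the full
#'   group to fit).
#' @return A list with components `gens` (a [generator_set()]) and
#'   `presentation` (a [presentation()]).
#' @examples
#' cox <- list("s1" = permutation(c(2,1,3,4)),
#'             "s2" = permutation(c(1,3,2,4)),
#'             "s3" = permutation(c(1,2,4,3)))
#' m <- generic_model(cox, list(s1 = 1, s2 = 1, s3 = 1))
#' length(m$gens$labels)
#' @export
generic_model <- function(perms, weights, precedence = NULL, bound = 50000L) {
  gens <- generator_set(perms, weights, precedence)
  rels <- list()
  labs <- gens$labels
  for (l in labs) {
    m <- perm_elt_order(gens$perms[[l]])
    if (m > 1L)
      rels[[length(rels) + 1L]] <- list(rep(l, m), character(0))
  }
  k <- length(labs)
  if (k > 1L) {
    for (a in seq_len(k - 1L)) {
      for (b in seq.int(a + 1L, k)) {
        m <- order_of_product(gens$perms[[labs[a]]], gens$perms[[labs[b]]])
        if (m > 1L)
          rels[[length(rels) + 1L]] <-
            list(rep(c(labs[a], labs[b]), m), character(0))
      }
    }
  }
  # Cayley-graph relations from BFS words: pin the presented group to
  # the concrete one
  enum <- enumerate_group(gens, bound)
  for (vi in seq_along(enum$elements)) {
    wx <- enum$words[[vi]]
    for (l in labs) {
      nxt <- compose(enum$elements[[vi]], gens$perms[[l]])
      wn <- enum$words[[get(perm_key(nxt), envir = enum$index,
                            inherits = FALSE)]]
      lhs <- c(wx, l)
      if (!identical(lhs, wn))
        rels[[length(rels) + 1L]] <- list(lhs, wn)
    }
  }
  list(gens = gens, presentation = presentation(gens, rels))
}
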