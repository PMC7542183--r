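# Permutations of {1..n} in one-line image form, and the unsigned
# inversion operators t[i,j] that act on genome arrangements.
#
# Composition convention (fixed package-wide): products read left to
# right, i.e. in a product a*b the factor a acts first on a position,
# so (a*b)[x] = b[a[x]].  A genome arrangement pi maps positions to
# regions; an operator g transforms it to the arrangement x -> pi[g[x]].
# With this convention a sequence of inversions applied to a genome one
# after another multiplies up on the *left* of the arrangement, and the
# element separating arrangements pi1, pi2 is the product pi2 * pi1^-1.

#' Permutations in one-line notation
#'
#' A permutation of positions `{1..n}` stored as its image vector:
#' `x[i]` is the image of position `i`.
#'
#' @param images an integer vector that is a bijection of `1..length(images)`.
#' @return An object of class `permutation`.
#' @examples
#' permutation(c(2, 1, 3))       # the transposition (1,2) in S_3
#' perm_identity(5)
#' @export
permutation <- function(images) {
  images <- as.integer(images)
  n <- length(images)
  if (n < 1L) stop("permutation needs at least one position")
  if (anyNA(images) || !setequal(images, seq_len(n)) ||
      anyDuplicated(images) > 0L)
    stop("images must be a bijection of 1..", n)
  structure(images, class = "permutation")
}

#' @rdname permutation
#' @param n number of positions.
#' @export
perm_identity <- function(n) permutation(seq_len(n))

#' @export
print.permutation <- function(x, ...) {
  cyc <- format_cycles(x)
  cat("permutation of 1..", length(unclass(x)), ": ", cyc,
      "  [", paste(unclass(x), collapse = ","), "]\n", sep = "")
  invisible(x)
}

#' @export
`==.permutation` <- function(e1, e2) {
  identical(as.integer(unclass(e1)), as.integer(unclass(e2)))
}

# trusted internal constructor: skips the bijection check (used on
# outputs that are bijections by construction, e.g. products)
new_perm <- function(images) structure(images, class = "permutation")

perm_n <- function(p) length(unclass(p))

perm_key <- function(p) paste(unclass(p), collapse = ",")

is_identity <- function(p) all(unclass(p) == seq_along(unclass(p)))

#' Compose two permutations (left-to-right)
#'
#' Returns the product `a b` under the package's left-to-right
#' convention: `a` acts first, so `compose(a, b)[x] = b[a[x]]`.
#'
#' @param a,b permutations of the same size.
#' @return A `permutation`.
#' @examples
#' s1 <- permutation(c(2, 1, 3))
#' s2 <- permutation(c(1, 3, 2))
#' compose(s1, s2)   # the 3-cycle sending 1 -> 3
#' @export
compose <- function(a, b) {
  ia <- unclass(a); ib <- unclass(b)
  if (length(ia) != length(ib)) stop("size mismatch: ", length(ia),
                                     " vs ", length(ib))
  new_perm(ib[ia])
}

#' Invert a permutation
#'
#' @param a a permutation.
#' @return The inverse permutation.
#' @export
inverse <- function(a) {
  ia <- unclass(a)
  inv <- integer(length(ia))
  inv[ia] <- seq_along(ia)
  new_perm(inv)
}

#' The inversion operator t[i,j]
#'
#' The unsigned inversion reversing the regions in positions `i..j` of a
#' linear arrangement.  As a permutation of positions it is the product
#' of disjoint transpositions `(i,j)(i+1,j-1)...` working inwards, e.g.
#' `t[1,4] = (1,4)(2,3)` and `t[1,6] = (1,6)(2,5)(3,4)`.  Always an
#' involution, fixing every position outside `[i,j]`.
#'
#' @param i,j positions with `1 <= i < j <= n`.
#' @param n number of positions.
#' @return A `permutation`.
#' @examples
#' make_inversion(1, 4, 7)
#' @export
make_inversion <- function(i, j, n) {
  i <- as.integer(i); j <- as.integer(j); n <- as.integer(n)
  if (i >= j) stop("need i < j, got i=", i, " j=", j)
  if (i < 1L || j > n) stop("inversion out of range: (", i, ",", j,
                            ") with n=", n)
  images <- seq_len(n)
  images[i:j] <- j:i
  permutation(images)
}

#' Apply an inversion (or any operator) to a genome arrangement
#'
#' A genome arrangement is a permutation read as the map positions ->
#' regions.  Applying operator `t` yields the arrangement whose position
#' `x` holds the region previously at position `t[x]`; for `t = t[i,j]`
#' this reverses the block of regions in positions `i..j`.
#'
#' @param t operator permutation (typically from [make_inversion()]).
#' @param g genome arrangement, a `permutation`.
#' @return The rearranged genome as a `permutation`.
#' @examples
#' g <- permutation(c(3, 1, 4, 2, 5))
#' apply_inversion(make_inversion(2, 4, 5), g)   # regions 2..4 reversed
#' @export
apply_inversion <- function(t, g) {
  it <- unclass(t); ig <- unclass(g)
  if (length(it) != length(ig)) stop("size mismatch")
  new_perm(ig[it])
}

#' Parse and format cycle notation
#'
#' Cycle notation as in `"(1,4)(3,7,6)"`: comma-separated entries,
#' disjoint cycles, fixed points omitted, whitespace ignored.  `"()"` or
#' an empty string is the identity.  `format_cycles()` writes each cycle
#' starting at its smallest element, cycles ordered by that element, so
#' the two functions round-trip.
#'
#' @param text cycle-notation string.
#' @param n number of positions (fixed points above the largest moved
#'   element are allowed, e.g. `"(3,4,6)"` with `n = 7`).
#' @return `parse_cycles()`: a `permutation`; `format_cycles()`: a string.
#' @examples
#' parse_cycles("(1,4)(3,7,6)", 7)
#' format_cycles(make_inversion(1, 6, 7))
#' @export
parse_cycles <- function(text, n) {
  text <- gsub("[[:space:]]", "", text)
  images <- seq_len(as.integer(n))
  if (text == "" || text == "()") return(permutation(images))
  if (!grepl("^(\\([0-9]+(,[0-9]+)*\\))+$", text))
    stop("malformed cycle notation: ", text)
  seen <- integer(0)
  chunks <- regmatches(text, gregexpr("\\(([0-9,]*)\\)", text))[[1]]
  for (ch in chunks) {
    entries <- as.integer(strsplit(gsub("[()]", "", ch), ",")[[1]])
    if (any(entries < 1L | entries > n))
      stop("cycle entry out of range 1..", n, ": ", ch)
    if (anyDuplicated(c(seen, entries)) > 0L)
      stop("repeated element across cycles in ", text)
    seen <- c(seen, entries)
    if (length(entries) > 1L)
      images[entries] <- entries[c(seq_along(entries)[-1], 1L)]
  }
  permutation(images)
}

#' @rdname parse_cycles
#' @param p a `permutation`.
#' @export
format_cycles <- function(p) {
  ip <- unclass(p)
  n <- length(ip)
  done <- logical(n)
  out <- character(0)
  for (start in seq_len(n)) {
    if (done[start] || ip[start] == start) { done[start] <- TRUE; next }
    cyc <- start
    x <- ip[start]
    done[start] <- TRUE
    while (x != start) {
      cyc <- c(cyc, x)
      done[x] <- TRUE
      x <- ip[x]
    }
    out <- c(out, paste0("(", paste(cyc, collapse = ","), ")"))
  }
  if (length(out) == 0L) "()" else paste(out, collapse = "")
}

#' Read a permutation from text
#'
#' Accepts either cycle notation (`"(1,4)(3,7,6)"`) or one-line notation
#' as comma-separated images (`"4,2,7,1,5,3,6"`).
#'
#' @inheritParams parse_cycles
#' @return A `permutation`.
#' @export
parse_perm <- function(text, n) {
  text <- trimws(text)
  if (grepl("^\\(", text) || text == "") parse_cycles(text, n)
  else {
    images <- as.integer(strsplit(text, ",")[[1]])
    if (length(images) != n)
      stop("one-line notation has ", length(images), " entries, expected ", n)
    permutation(images)
  }
}

# order of a permutation's product with repeated composition
perm_elt_order <- function(p) {
  acc <- p
  m <- 1L
  while (!is_identity(acc)) {
    acc <- compose(acc, p)
    m <- m + 1L
  }
  m
}
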