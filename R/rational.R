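# Minimal exact-rational helpers.  Generator weights and word weights are
# kept as integer numerator/denominator pairs so that reduction-order
# comparisons are exact; everything is reduced with gcd on construction.

gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  a
}

lcm2 <- function(a, b) {
  if (a == 0 || b == 0) return(0)
  abs(a / gcd2(a, b) * b)
}

#' Exact rational numbers
#'
#' A small exact-rational scalar type used for generator weights and word
#' weights, so that comparisons in the weighted lexicographic order never
#' go through floating point.
#'
#' @param num integer numerator (may be a vector, recycled with `den`).
#' @param den positive integer denominator.
#' @return An object of class `rational` with fields `num` and `den`
#'   (always in lowest terms, `den > 0`).
#' @examples
#' rational(3, 6)            # 1/2
#' rational(1, 3) + rational(1, 6)
#' as.numeric(rational(7, 2))
#' @export
rational <- function(num, den = 1L) {
  stopifnot(length(num) == 1L, length(den) == 1L, den != 0)
  num <- as.numeric(num); den <- as.numeric(den)
  if (num != round(num) || den != round(den))
    stop("rational() needs integer numerator and denominator")
  if (den < 0) { num <- -num; den <- -den }
  g <- gcd2(num, den)
  if (g > 0) { num <- num / g; den <- den / g }
  structure(list(num = num, den = den), class = "rational")
}

#' @export
print.rational <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.rational <- function(x, ...) {
  if (x$den == 1) sprintf("%d", as.integer(x$num))
  else sprintf("%d/%d", as.integer(x$num), as.integer(x$den))
}

#' @export
as.double.rational <- function(x, ...) x$num / x$den

#' @export
as.numeric.rational <- function(x, ...) x$num / x$den

#' @export
`+.rational` <- function(e1, e2) {
  e1 <- as_rational(e1); e2 <- as_rational(e2)
  rational(e1$num * e2$den + e2$num * e1$den, e1$den * e2$den)
}

#' @export
`==.rational` <- function(e1, e2) rat_cmp(as_rational(e1), as_rational(e2)) == 0L

#' @export
`<.rational` <- function(e1, e2) rat_cmp(as_rational(e1), as_rational(e2)) < 0L

#' @export
`>.rational` <- function(e1, e2) rat_cmp(as_rational(e1), as_rational(e2)) > 0L

#' Parse a rational from text
#'
#' Accepts `"p/q"` or a bare integer string, the format used in weight
#' tables and rewriting-system files.
#'
#' @param text a character scalar such as `"3"` or `"5/2"`.
#' @return A [rational()].
#' @export
parse_rational <- function(text) {
  text <- trimws(text)
  if (grepl("/", text, fixed = TRUE)) {
    parts <- strsplit(text, "/", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop("malformed rational: ", text)
    rational(as.numeric(parts[1]), as.numeric(parts[2]))
  } else {
    rational(as.numeric(text))
  }
}

as_rational <- function(x) {
  if (inherits(x, "rational")) return(x)
  if (is.character(x)) return(parse_rational(x))
  if (is.numeric(x) && length(x) == 1L && x == round(x)) return(rational(x))
  stop("cannot interpret as rational: ", deparse(x))
}

rat_cmp <- function(a, b) {
  d <- a$num * b$den - b$num * a$den
  if (d > 0) 1L else if (d < 0) -1L else 0L
}

rat_sum <- function(lst) {
  acc <- rational(0)
  for (x in lst) acc <- acc + x
  acc
}

# Scale a list of rationals to exact integers by the lcm of denominators.
rat_scale_integer <- function(lst) {
  dens <- vapply(lst, function(x) x$den, numeric(1))
  L <- Reduce(lcm2, dens, accumulate = FALSE)
  vapply(lst, function(x) x$num * (L / x$den), numeric(1))
}
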