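# Words over a generator set, the weighted lexicographic reduction
# order, and the rewriting-system machinery: orientation, normalization,
# critical pairs, Knuth-Bendix completion, confluence certification.
# Words at the R surface are character vectors of generator labels
# (character(0) is the empty word); internally they are integer id
# vectors handed to the C++ engine.

word_to_ids <- function(w, labels) {
  if (length(w) == 0L) return(integer(0))
  ids <- match(w, labels)
  if (anyNA(ids)) stop("unknown generator label: ",
                       paste(w[is.na(ids)], collapse = ", "))
  ids
}

ids_to_word <- function(ids, labels) {
  if (length(ids) == 0L) character(0) else labels[ids]
}

format_word <- function(w) {
  if (length(w) == 0L) "-" else paste(w, collapse = " ")
}

#' Evaluate a word in the permutation group
#'
#' Maps a word (sequence of generator labels) to the group element it
#' spells, multiplying left to right under the package composition
#' convention.  The empty word evaluates to the identity.
#'
#' @param w character vector of generator labels (possibly empty).
#' @param gens a [generator_set()].
#' @return A [permutation()].
#' @examples
#' gens <- linear_inversion_model(4)
#' evaluate_word(c("t[1,4]", "t[1,4]"), gens)   # involution: identity
#' @export
evaluate_word <- function(w, gens) {
  acc <- perm_identity(gens$n)
  for (lab in w) {
    p <- gens$perms[[lab]]
    if (is.null(p)) stop("unknown generator label: ", lab)
    acc <- compose(acc, p)
  }
  acc
}

#' Reduction orders on words
#'
#' The weighted lexicographic order: `u > v` if the total weight of `u`
#' exceeds that of `v`, or the weights are equal and the first letter at
#' which they differ is greater under the generator precedence.  With
#' strictly positive weights this is a reduction order: total,
#' translation-invariant and well-founded, so it certifies termination
#' of any rule set oriented by it.
#'
#' @param gens a [generator_set()] (its weights and precedence define
#'   the order).
#' @return An object of class `reduction_order` carrying integer-scaled
#'   exact weights and precedence ranks.
#' @export
reduction_order <- function(gens) {
  stopifnot(inherits(gens, "generator_set"))
  scaled <- rat_scale_integer(gens$weights)  # common-denominator integers
  rank <- match(gens$labels, gens$precedence)
  structure(list(labels = gens$labels, weights = gens$weights,
                 scaled = scaled, rank = rank,
                 precedence = gens$precedence),
            class = "reduction_order")
}

#' @export
print.reduction_order <- function(x, ...) {
  cat("weighted lexicographic reduction order on", length(x$labels),
      "generators\n")
  invisible(x)
}

#' Total weight of a word
#'
#' Sum of the letter weights (exact rational); the empty word has
#' weight 0.
#'
#' @param w character vector of generator labels.
#' @param order a [reduction_order()] (or a [generator_set()]).
#' @return A [rational()].
#' @export
word_weight <- function(w, order) {
  weights <- order$weights  # same field on generator_set and reduction_order
  rat_sum(lapply(w, function(l) {
    wt <- weights[[l]]
    if (is.null(wt)) stop("unknown generator label: ", l)
    wt
  }))
}

#' Compare two words under a reduction order
#'
#' @param u,v character vectors of generator labels.
#' @param order a [reduction_order()].
#' @return `"less"`, `"equal"` or `"greater"` (for `u` relative to `v`).
#' @export
compare_words <- function(u, v, order) {
  c1 <- cpp_compare(word_to_ids(u, order$labels),
                    word_to_ids(v, order$labels),
                    order$scaled, order$rank)
  c("less", "equal", "greater")[c1 + 2L]
}

new_rule <- function(lhs, rhs) structure(list(lhs = lhs, rhs = rhs),
                                         class = "rewrite_rule")

#' @export
print.rewrite_rule <- function(x, ...) {
  cat(format_word(x$lhs), "->", format_word(x$rhs), "\n")
  invisible(x)
}

#' Orient a relation into a rewrite rule
#'
#' Directs a verified relation `u = v` so that the greater side under
#' the reduction order becomes the left-hand side.  Refuses relations
#' whose sides evaluate to different permutations (a corrupt relation),
#' and returns `NULL` for the trivial case `u = v` as words.
#'
#' @param u,v words (character vectors of labels) with equal evaluation.
#' @param order a [reduction_order()].
#' @param gens a [generator_set()] used to verify the relation.
#' @return A rule object (fields `lhs`, `rhs`) or `NULL` if trivial.
#' @export
orient <- function(u, v, order, gens) {
  if (!(evaluate_word(u, gens) == evaluate_word(v, gens)))
    stop("cannot orient: sides evaluate to different permutations")
  cmp <- compare_words(u, v, order)
  if (cmp == "equal") return(NULL)
  if (cmp == "greater") new_rule(u, v) else new_rule(v, u)
}

new_rewriting_system <- function(rules, order, gens, confluent = FALSE,
                                 reduced = FALSE, stats = list()) {
  structure(list(rules = rules, order = order, gens = gens,
                 confluent = confluent, reduced = reduced, stats = stats),
            class = "rewriting_system")
}

#' @export
print.rewriting_system <- function(x, ...) {
  cat("rewriting_system: ", length(x$rules), " rules over ",
      length(x$gens$labels), " generators",
      if (isTRUE(x$confluent)) " [confluent]" else "",
      if (isTRUE(x$reduced)) " [reduced]" else "", "\n", sep = "")
  invisible(x)
}

sys_rule_ids <- function(sys) {
  labels <- sys$order$labels
  list(lhs = lapply(sys$rules, function(r) word_to_ids(r$lhs, labels)),
       rhs = lapply(sys$rules, function(r) word_to_ids(r$rhs, labels)))
}

#' Normalize a word
#'
#' Rewrites `w` with the system's rules until no left-hand side occurs
#' as a factor.  Termination is guaranteed because every rule strictly
#' decreases the reduction order; for a confluent system the result is
#' the unique normal form of the word's group element, independent of
#' rewriting strategy.
#'
#' @param w character vector of generator labels.
#' @param sys a `rewriting_system` (from [knuth_bendix()] or
#'   [read_rws()]).
#' @return The irreducible word (character vector).
#' @export
normalize <- function(w, sys) {
  labels <- sys$order$labels
  ids <- sys_rule_ids(sys)
  out <- cpp_normalize(word_to_ids(w, labels), ids$lhs, ids$rhs,
                       length(labels))
  ids_to_word(out, labels)
}

#' Critical pairs of two rules
#'
#' Enumerates all superpositions where a non-empty suffix of `r1`'s
#' left-hand side equals a prefix of `r2`'s, or where one left-hand
#' side occurs inside the other, and returns the two one-step reducts of
#' each superposition.  Self-overlaps (`r1` equal to `r2`) are included.
#'
#' @param r1,r2 rules (fields `lhs`, `rhs`, as produced by [orient()]).
#' @param same_rule set `TRUE` when `r1` and `r2` are the same rule, to
#'   drop the trivial identical superposition.
#' @return A list of two-element lists of words.
#' @export
critical_pairs <- function(r1, r2, same_rule = identical(r1, r2)) {
  alphabet <- unique(c(r1$lhs, r1$rhs, r2$lhs, r2$rhs))
  if (length(alphabet) == 0L) return(list())
  raw <- c(cpp_critical_pairs(word_to_ids(r1$lhs, alphabet),
                              word_to_ids(r1$rhs, alphabet),
                              word_to_ids(r2$lhs, alphabet),
                              word_to_ids(r2$rhs, alphabet), same_rule),
           if (!same_rule)
             cpp_critical_pairs(word_to_ids(r2$lhs, alphabet),
                                word_to_ids(r2$rhs, alphabet),
                                word_to_ids(r1$lhs, alphabet),
                                word_to_ids(r1$rhs, alphabet), FALSE))
  lapply(raw, function(pr) list(ids_to_word(pr[[1]], alphabet),
                                ids_to_word(pr[[2]], alphabet)))
}

#' Does a critical pair resolve?
#'
#' A pair resolves when both sides normalize to the same word; by the
#' critical-pair theorem a terminating system is confluent exactly when
#' every critical pair of every rule pair resolves.
#'
#' @param pair two-element list of words.
#' @param sys a `rewriting_system`.
#' @return Logical scalar.
#' @export
resolves <- function(pair, sys) {
  identical(normalize(pair[[1]], sys), normalize(pair[[2]], sys))
}

#' Knuth-Bendix completion
#'
#' Completes a verified group presentation into a reduced confluent
#' rewriting system under the weighted lexicographic order: unresolved
#' critical pairs are oriented into new rules (smallest larger-side
#' first), the rule set is interreduced after every insertion, and the
#' loop runs until no unresolved pair remains.  For a finite group this
#' terminates, and the resulting reduced system is uniquely determined
#' by the congruence and the order (not by strategy), so rule counts are
#' reproducible.
#'
#' @param p a [presentation()].
#' @param order a [reduction_order()]; defaults to the order induced by
#'   the presentation's generator set.
#' @param max_rules abort threshold on the number of active rules.
#' @param max_iter abort threshold on queue iterations.
#' @return A `rewriting_system` with `confluent = TRUE`.  If a limit is
#'   hit, an error of class `kb_incomplete` is signalled whose
#'   `partial` field carries the partial (non-confluent) system.
#' @examples
#' gens <- linear_inversion_model(3)
#' sys <- knuth_bendix(linear_inversion_presentation(gens))
#' length(sys$rules)
#' @export
knuth_bendix <- function(p, order = NULL, max_rules = 100000L,
                         max_iter = 5e7) {
  stopifnot(inherits(p, "presentation"))
  gens <- p$gens
  if (is.null(order)) order <- reduction_order(gens)
  labels <- order$labels
  eq_lhs <- lapply(p$relations, function(r) word_to_ids(r[[1]], labels))
  eq_rhs <- lapply(p$relations, function(r) word_to_ids(r[[2]], labels))
  res <- cpp_knuth_bendix(eq_lhs, eq_rhs, length(labels),
                          order$scaled, order$rank,
                          as.integer(max_rules), max_iter)
  rules <- mapply(function(l, r) new_rule(ids_to_word(l, labels),
                                          ids_to_word(r, labels)),
                  res$lhs, res$rhs, SIMPLIFY = FALSE)
  sys <- new_rewriting_system(rules, order, gens,
                              confluent = isTRUE(res$complete),
                              reduced = isTRUE(res$complete),
                              stats = list(iterations = res$iterations,
                                           pairs_generated = res$pairs_generated))
  if (!isTRUE(res$complete)) {
    cond <- structure(class = c("kb_incomplete", "error", "condition"),
                      list(message = paste0(
                             "Knuth-Bendix hit a limit before confluence (",
                             length(rules), " rules); partial system attached"),
                           call = sys.call(-1), partial = sys))
    stop(cond)
  }
  # soundness: every rule's two sides evaluate to the same permutation
  for (r in sys$rules) {
    if (!(evaluate_word(r$lhs, gens) == evaluate_word(r$rhs, gens)))
      stop("internal error: unsound rule ", format_word(r$lhs),
           " -> ", format_word(r$rhs))
  }
  sys
}

#' Certify confluence by exhaustive critical-pair check
#'
#' Checks every critical pair of every ordered rule pair for
#' resolution.  Independent of the completion run: this re-examines the
#' finished rule set from scratch.
#'
#' @param sys a `rewriting_system`.
#' @return Logical scalar with attributes `pairs_checked` (count) and,
#'   when non-confluent, `counterexample` (an unresolved pair).
#' @export
is_confluent <- function(sys) {
  ids <- sys_rule_ids(sys)
  res <- cpp_check_confluence(ids$lhs, ids$rhs, length(sys$order$labels))
  out <- isTRUE(res$confluent)
  attr(out, "pairs_checked") <- res$pairs_checked
  if (!out && !is.null(res$counterexample)) {
    labels <- sys$order$labels
    attr(out, "counterexample") <-
      lapply(res$counterexample, ids_to_word, labels = labels)
  }
  out
}

#' Interreduce a rule set
#'
#' Brings a set of oriented rules to reduced form: every left-hand side
#' irreducible with respect to the other rules, every right-hand side
#' fully normalized, duplicates collapsed.  The generated congruence is
#' unchanged (rules whose lhs becomes reducible are re-oriented from
#' their normalized sides, or dropped when trivial).
#'
#' @param rules list of rules (fields `lhs`, `rhs`).
#' @param order a [reduction_order()].
#' @return A list of rules.
#' @export
interreduce <- function(rules, order) {
  labels <- order$labels
  repeat {
    changed <- FALSE
    i <- 1L
    while (i <= length(rules)) {
      others <- rules[-i]
      olhs <- lapply(others, function(r) word_to_ids(r$lhs, labels))
      orhs <- lapply(others, function(r) word_to_ids(r$rhs, labels))
      nf <- function(w) ids_to_word(
        cpp_normalize(word_to_ids(w, labels), olhs, orhs, length(labels)),
        labels)
      l2 <- nf(rules[[i]]$lhs)
      r2 <- nf(rules[[i]]$rhs)
      if (!identical(l2, rules[[i]]$lhs) || !identical(r2, rules[[i]]$rhs)) {
        changed <- TRUE
        rules <- others
        cmp <- compare_words(l2, r2, order)
        if (cmp != "equal") {
          rules[[length(rules) + 1L]] <-
            if (cmp == "greater") new_rule(l2, r2) else new_rule(r2, l2)
        }
        i <- 1L
      } else {
        i <- i + 1L
      }
    }
    if (!changed) break
  }
  # collapse duplicates
  keys <- vapply(rules, function(r)
    paste(format_word(r$lhs), "->", format_word(r$rhs)), character(1))
  rules[!duplicated(keys)]
}

#' Read and write rewriting-system files
#'
#' Plain-text, bit-exact round-trip format: header lines `n=`, `topology=`,
#' `weights=label:p/q ...`, `precedence=label>label>...`, then one rule
#' per line `lhs -> rhs` with space-separated labels and the empty word
#' written `-`.  `read_rws()` rebuilds the generator set from the header
#' (labels `t[i,j]` / `s[i]` are reconstructed as inversion operators),
#' verifies every rule's two sides evaluate equally, and rejects files
#' with rules violating `lhs > rhs`.
#'
#' @param sys a `rewriting_system`.
#' @param path file path.
#' @return `write_rws()`: `path`, invisibly.  `read_rws()`: a
#'   `rewriting_system`.
#' @export
write_rws <- function(sys, path) {
  gens <- sys$gens
  topology <- attr(sys, "topology")
  if (is.null(topology)) topology <- "custom"
  wtxt <- paste0(gens$labels, ":",
                 vapply(gens$weights, function(w)
                   paste0(w$num, "/", w$den), character(1)),
                 collapse = " ")
  hdr <- c(paste0("n=", gens$n),
           paste0("topology=", topology),
           paste0("weights=", wtxt),
           paste0("precedence=", paste(gens$precedence, collapse = ">")),
           paste0("confluent=", if (isTRUE(sys$confluent)) "yes" else "no"))
  body <- vapply(sys$rules, function(r)
    paste(format_word(r$lhs), "->", format_word(r$rhs)), character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_rws
#' @export
read_rws <- function(path) {
  lines <- readLines(path)
  hdr <- lines[grepl("^[a-z]+=", lines)]
  body <- lines[grepl("->", lines, fixed = TRUE)]
  getv <- function(key) {
    m <- hdr[startsWith(hdr, paste0(key, "="))]
    if (length(m) != 1L) stop("missing or duplicate header: ", key)
    sub(paste0("^", key, "="), "", m)
  }
  n <- as.integer(getv("n"))
  wparts <- strsplit(strsplit(getv("weights"), " ", fixed = TRUE)[[1]], ":",
                     fixed = TRUE)
  labels <- vapply(wparts, `[`, character(1), 1L)
  weights <- lapply(wparts, function(p) parse_rational(p[2]))
  names(weights) <- labels
  perms <- lapply(labels, label_to_perm, n = n)
  names(perms) <- labels
  precedence <- strsplit(getv("precedence"), ">", fixed = TRUE)[[1]]
  gens <- generator_set(perms, weights, precedence)
  order <- reduction_order(gens)
  parse_side <- function(txt) {
    txt <- trimws(txt)
    if (txt == "-" || txt == "") character(0)
    else strsplit(txt, " +")[[1]]
  }
  rules <- lapply(body, function(ln) {
    sides <- strsplit(ln, "->", fixed = TRUE)[[1]]
    if (length(sides) != 2L) stop("malformed rule line: ", ln)
    r <- new_rule(parse_side(sides[1]), parse_side(sides[2]))
    if (compare_words(r$lhs, r$rhs, order) != "greater")
      stop("rule violates lhs > rhs: ", ln)
    if (!(evaluate_word(r$lhs, gens) == evaluate_word(r$rhs, gens)))
      stop("rule fails evaluation: ", ln)
    r
  })
  sys <- new_rewriting_system(rules, order, gens,
                              confluent = identical(getv("confluent"), "yes"),
                              reduced = identical(getv("confluent"), "yes"))
  attr(sys, "topology") <- getv("topology")
  sys
}

# reconstruct a generator permutation from its conventional label
label_to_perm <- function(label, n) {
  m <- regmatches(label, regexec("^t\\[(\\d+),(\\d+)\\]$", label))[[1]]
  if (length(m) == 3L)
    return(make_inversion(as.integer(m[2]), as.integer(m[3]), n))
  m <- regmatches(label, regexec("^s\\[(\\d+)\\]$", label))[[1]]
  if (length(m) == 2L) {
    i <- as.integer(m[2])
    if (i < n) return(make_inversion(i, i + 1L, n))
    img <- seq_len(n); img[c(1L, n)] <- c(n, 1L)
    return(permutation(img))
  }
  stop("cannot reconstruct generator from label: ", label)
}
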