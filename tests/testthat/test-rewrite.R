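test_that("evaluate_word maps words to group elements", {
  cox <- coxeter_model(4)
  w <- c("s2", "s3", "s2", "s1", "s3", "s1", "s2", "s3")
  expect_true(evaluate_word(w, cox$gens) == perm_identity(4))
  expect_true(evaluate_word(character(0), cox$gens) == perm_identity(4))
  g7 <- linear_inversion_model(7)
  expect_true(evaluate_word("t[1,4]", g7) == make_inversion(1, 4, 7))
  expect_error(evaluate_word("nope", g7), "unknown")
})

test_that("word weights are exact and additive", {
  gens <- linear_inversion_model(7)
  ord <- reduction_order(gens)
  expect_equal(as.numeric(word_weight(character(0), ord)), 0)
  expect_equal(as.numeric(word_weight(c("t[1,4]", "t[2,3]"), ord)), 4)
  set.seed(21)
  for (rep in 1:50) {
    u <- random_word(gens$labels)
    v <- random_word(gens$labels)
    expect_equal(as.numeric(word_weight(c(u, v), ord)),
                 as.numeric(word_weight(u, ord)) +
                   as.numeric(word_weight(v, ord)))
  }
})

test_that("the weighted lexicographic order is a reduction order", {
  gens <- linear_inversion_model(4)
  ord <- reduction_order(gens)
  expect_equal(compare_words("t[1,3]", "t[1,2]", ord), "greater")
  expect_equal(compare_words(c("t[1,2]", "t[1,2]"), c("t[1,2]", "t[1,2]"),
                             ord), "equal")
  set.seed(22)
  for (rep in 1:300) {
    u <- random_word(gens$labels, 6)
    v <- random_word(gens$labels, 6)
    cuv <- compare_words(u, v, ord)
    cvu <- compare_words(v, u, ord)
    # totality + antisymmetry
    if (identical(u, v)) {
      expect_equal(cuv, "equal")
    } else {
      expect_true(cuv %in% c("less", "greater"))
      expect_equal(cvu, setdiff(c("less", "greater"), cuv))
      # translation invariance
      a <- random_word(gens$labels, 3)
      b <- random_word(gens$labels, 3)
      expect_equal(compare_words(c(a, u, b), c(a, v, b), ord), cuv)
    }
  }
  # equal-weight distinct words are decided at the first difference,
  # never "equal": exhaustive over short words on two unit-weight letters
  g2 <- generator_set(list(a = permutation(c(2, 1, 3)),
                           b = permutation(c(1, 3, 2))),
                      list(a = 1, b = 1))
  o2 <- reduction_order(g2)
  words2 <- unlist(lapply(1:3, function(len) {
    apply(expand.grid(rep(list(c("a", "b")), len)), 1,
          function(r) paste(r, collapse = " "))
  }))
  for (wu in words2) for (wv in words2) {
    u <- strsplit(wu, " ")[[1]]; v <- strsplit(wv, " ")[[1]]
    if (length(u) == length(v) && !identical(u, v))
      expect_true(compare_words(u, v, o2) != "equal")
  }
})

test_that("orient directs relations by the order and rejects corrupt ones", {
  gens <- linear_inversion_model(4)
  ord <- reduction_order(gens)
  r <- orient(c("t[1,2]", "t[1,2]"), character(0), ord, gens)
  expect_equal(r$lhs, c("t[1,2]", "t[1,2]"))
  expect_length(r$rhs, 0)
  # smaller side first: orientation flips
  r2 <- orient(character(0), c("t[1,2]", "t[1,2]"), ord, gens)
  expect_equal(r2$lhs, c("t[1,2]", "t[1,2]"))
  expect_null(orient("t[1,2]", "t[1,2]", ord, gens))
  expect_error(orient("t[1,2]", "t[2,3]", ord, gens), "different")
})

test_that("critical pairs enumerate overlaps and containments", {
  # lhs [a,b] over lhs [b,c]: one pair from the superposition [a,b,c]
  r1 <- list(lhs = c("a", "b"), rhs = c("x"))
  r2 <- list(lhs = c("b", "c"), rhs = c("y"))
  cps <- critical_pairs(r1, r2, same_rule = FALSE)
  expect_true(any(vapply(cps, function(p)
    identical(p[[1]], c("x", "c")) && identical(p[[2]], c("a", "y")),
    logical(1))))
  # disjoint alphabets: nothing
  r3 <- list(lhs = c("p", "q"), rhs = character(0))
  expect_length(critical_pairs(r1, r3, same_rule = FALSE), 0)
  # self-overlap of [a,a] at the middle: pair from [a,a,a]
  r4 <- list(lhs = c("a", "a"), rhs = character(0))
  cps4 <- critical_pairs(r4, r4, same_rule = TRUE)
  expect_length(cps4, 1)
  expect_equal(cps4[[1]][[1]], "a")
  expect_equal(cps4[[1]][[2]], "a")
})

test_that("resolves detects joinable and non-joinable pairs", {
  lin <- cached_model("linear", 4)
  expect_true(resolves(list(c("t[1,2]"), c("t[1,2]")), lin$sys))
  # a deliberately non-confluent system: only the involution rules
  gens <- lin$gens
  ord <- reduction_order(gens)
  rules <- lapply(gens$labels, function(l)
    orient(c(l, l), character(0), ord, gens))
  partial <- kbinv:::new_rewriting_system(rules, ord, gens)
  # braid words normalize differently without the braid rules
  pair <- list(c("t[2,3]", "t[1,2]", "t[2,3]"),
               c("t[1,2]", "t[2,3]", "t[1,2]"))
  expect_false(resolves(pair, partial))
  expect_true(resolves(pair, lin$sys))
})

test_that("knuth_bendix completes small models to known rule counts", {
  expect_length(cached_model("linear", 3)$sys$rules, 9)
  # a single involution: exactly one rule aa -> empty
  m1 <- generic_model(list(a = permutation(c(2, 1))), list(a = 1))
  s1 <- knuth_bendix(m1$presentation)
  expect_length(s1$rules, 1)
  expect_equal(s1$rules[[1]]$lhs, c("a", "a"))
  expect_length(s1$rules[[1]]$rhs, 0)
  # limit breach signals an incomplete-completion error with the partial
  gens <- linear_inversion_model(4)
  expect_error(knuth_bendix(linear_inversion_presentation(gens),
                            max_rules = 5L),
               class = "kb_incomplete")
})

test_that("normalization reaches the unique normal form", {
  cox <- coxeter_model(4)
  sys <- knuth_bendix(cox$presentation)
  w <- c("s2", "s3", "s2", "s1", "s3", "s1", "s2", "s3")
  expect_length(normalize(w, sys), 0)
  # an irreducible word is unchanged
  expect_equal(normalize("s1", sys), "s1")
  expect_equal(normalize(c("s1", "s1"), sys), character(0))
  # canonical completeness: distinct normal forms number exactly |G|
  for (n in 3:5) {
    lin <- cached_model("linear", n)
    enum <- cached_enum(lin$gens, paste("linear", n))
    nfs <- vapply(enum$words, function(w)
      paste(normalize(w, lin$sys), collapse = " "), character(1))
    expect_equal(length(unique(nfs)), factorial(n))
  }
})

test_that("normalization is strategy-independent on a confluent system", {
  lin <- cached_model("linear", 4)
  set.seed(23)
  for (rep in 1:1000) {
    w <- random_word(lin$gens$labels, 8)
    expect_identical(random_normalize(w, lin$sys), normalize(w, lin$sys))
  }
})

test_that("every completed rule is sound under evaluation", {
  for (key in list(c("linear", "3"), c("linear", "4"), c("circular", "5"))) {
    m <- cached_model(key[1], as.integer(key[2]))
    for (r in m$sys$rules) {
      expect_true(evaluate_word(r$lhs, m$gens) ==
                  evaluate_word(r$rhs, m$gens))
      expect_equal(compare_words(r$lhs, r$rhs, m$sys$order), "greater")
    }
  }
})

test_that("is_confluent certifies completed systems and rejects broken ones", {
  lin <- cached_model("linear", 4)
  ok <- is_confluent(lin$sys)
  expect_true(ok)
  expect_gt(attr(ok, "pairs_checked"), 0)
  # drop one non-involution rule: local confluence must fail
  long <- which(vapply(lin$sys$rules, function(r) length(r$lhs) > 2,
                       logical(1)))
  broken <- lin$sys
  broken$rules <- broken$rules[-long[1]]
  expect_false(is_confluent(broken))
  # empty rule set is vacuously confluent
  empty <- kbinv:::new_rewriting_system(list(), lin$sys$order, lin$gens)
  expect_true(is_confluent(empty))
})

test_that("interreduce removes subsumed rules and normalizes right sides", {
  g2 <- generator_set(list(a = permutation(c(2, 1, 3)),
                           b = permutation(c(1, 3, 2))),
                      list(a = 1, b = 1))
  ord <- reduction_order(g2)
  rules <- list(list(lhs = c("a", "a"), rhs = character(0)),
                list(lhs = c("a", "a", "b"), rhs = c("b")))
  out <- interreduce(rules, ord)
  expect_length(out, 1)
  expect_equal(out[[1]]$lhs, c("a", "a"))
  # already-reduced set unchanged; duplicates collapsed
  lin <- cached_model("linear", 3)
  expect_equal(interreduce(lin$sys$rules, lin$sys$order), lin$sys$rules)
  expect_length(interreduce(c(rules[1], rules[1]), ord), 1)
})

test_that("rewriting-system files round-trip bit-exactly", {
  lin <- cached_model("linear", 4)
  path <- withr::local_tempfile(fileext = ".rws")
  write_rws(lin$sys, path)
  back <- read_rws(path)
  expect_length(back$rules, length(lin$sys$rules))
  expect_identical(lapply(back$rules, `[[`, "lhs"),
                   lapply(lin$sys$rules, `[[`, "lhs"))
  path2 <- withr::local_tempfile(fileext = ".rws")
  write_rws(back, path2)
  expect_identical(readLines(path), readLines(path2))
  # reject rules violating lhs > rhs
  lines <- readLines(path)
  swapped <- sub("^(.*) -> (.*)$", "\\2 -> \\1",
                 lines[grepl("->", lines)][1])
  writeLines(c(lines[!grepl("->", lines)], swapped), path2)
  expect_error(read_rws(path2), "lhs > rhs")
})
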