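test_that("linear model has n(n-1)/2 generators with the right weights", {
  g7 <- linear_inversion_model(7)
  expect_length(g7$labels, 21)
  expect_equal(as.numeric(g7$weights[["t[1,4]"]]), 3)
  g3 <- linear_inversion_model(3)
  expect_equal(vapply(g3$weights[c("t[1,2]", "t[2,3]", "t[1,3]")],
                      as.numeric, numeric(1)),
               c("t[1,2]" = 1, "t[2,3]" = 1, "t[1,3]" = 2))
  gu <- linear_inversion_model(7, "unit")
  expect_true(all(vapply(gu$weights, as.numeric, numeric(1)) == 1))
  expect_error(linear_inversion_model(4, list()))
  expect_error(generator_set(list(a = permutation(c(2, 1))),
                             list(a = 0)), "positive")
})

test_that("order_of_product matches brute force", {
  s <- coxeter_perms(4)
  expect_equal(order_of_product(s$s1, s$s1), 1)   # involution squared
  expect_equal(order_of_product(s$s1, s$s3), 2)   # commuting pair
  expect_equal(order_of_product(s$s1, s$s2), 3)   # braid pair
  t14 <- make_inversion(1, 4, 4)
  expect_equal(order_of_product(t14, t14), 1)
})

test_that("every linear-presentation relation verifies by evaluation", {
  for (n in 3:5) {
    gens <- linear_inversion_model(n)
    pres <- linear_inversion_presentation(gens)
    for (rel in pres$relations) {
      expect_true(evaluate_word(rel[[1]], gens) ==
                  evaluate_word(rel[[2]], gens))
    }
    # power relator for the braid pair is present at n=3
    if (n == 3) {
      has_braid <- any(vapply(pres$relations, function(r)
        identical(r[[1]], rep(c("t[1,2]", "t[2,3]"), 3)), logical(1)))
      expect_true(has_braid)
    }
  }
})

test_that("circular model is n unit-weight adjacent inversions plus (1,n)", {
  g8 <- circular_adjacent_model(8)
  expect_length(g8$labels, 8)
  expect_true(all(vapply(g8$weights, as.numeric, numeric(1)) == 1))
  moved <- which(unclass(g8$perms[["s[8]"]]) != 1:8)
  expect_equal(moved, c(1, 8))
  g3 <- circular_adjacent_model(3)
  expect_setequal(vapply(g3$perms, format_cycles, character(1)),
                  c("(1,2)", "(2,3)", "(1,3)"))
})

test_that("circular presentation relations verify, incl. the wrap relation", {
  for (n in c(5, 8)) {
    gens <- circular_adjacent_model(n)
    pres <- circular_adjacent_presentation(gens)
    for (rel in pres$relations) {
      expect_true(evaluate_word(rel[[1]], gens) ==
                  evaluate_word(rel[[2]], gens))
    }
    # the wrap relation s_n = s_{n-1}...s_1...s_{n-1} is present
    wrap <- Filter(function(r) identical(r[[2]], sprintf("s[%d]", n)),
                   pres$relations)
    expect_length(wrap, 1)
    expect_length(wrap[[1]][[1]], 2L * n - 3L)
    # commutations only between circularly non-adjacent generators
    comms <- Filter(function(r) length(r[[1]]) == 2 && length(r[[2]]) == 2,
                    pres$relations)
    for (rel in comms) {
      i <- as.integer(sub("s\\[(\\d+)\\]", "\\1", rel[[1]][1]))
      j <- as.integer(sub("s\\[(\\d+)\\]", "\\1", rel[[1]][2]))
      expect_false(((i - j) %% n) %in% c(1, n - 1))
    }
  }
})

test_that("each model generates the full symmetric group for n <= 5", {
  for (n in 3:5) {
    expect_length(enumerate_group(linear_inversion_model(n))$elements,
                  factorial(n))
    expect_length(enumerate_group(circular_adjacent_model(n))$elements,
                  factorial(n))
  }
})

test_that("generic_model presents the generated group faithfully", {
  # a single involution generates a 2-element group
  m1 <- generic_model(list(a = permutation(c(2, 1, 3))), list(a = 1))
  expect_length(enumerate_group(m1$gens)$elements, 2)
  # adjacent transpositions of S_5 close to 120 elements
  m5 <- coxeter_model(5)
  expect_length(enumerate_group(m5$gens)$elements, 120)
  # all relations evaluate
  m4 <- coxeter_model(4)
  for (rel in m4$presentation$relations) {
    expect_true(evaluate_word(rel[[1]], m4$gens) ==
                evaluate_word(rel[[2]], m4$gens))
  }
  expect_error(generic_model(list(a = parse_cycles("(1,2,3)", 3)),
                             list(a = 1)), "inverse")
})
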