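test_that("initial_word factorizes arbitrary elements", {
  gens <- linear_inversion_model(5)
  enum <- cached_enum(gens, "linear 5")
  expect_length(initial_word(perm_identity(5), gens, enum), 0)
  for (lab in gens$labels) {
    expect_equal(initial_word(gens$perms[[lab]], gens, enum), lab)
  }
  set.seed(41)
  for (rep in 1:50) {
    p <- permutation(sample.int(5))
    w <- initial_word(p, gens, enum)
    expect_true(evaluate_word(w, gens) == p)
  }
  # an element outside the generated group is rejected
  m1 <- generic_model(list(a = permutation(c(2, 1, 3))), list(a = 1))
  expect_error(initial_word(parse_cycles("(1,3)", 3), m1$gens), "not in")
})

test_that("weighted_length equals the geodesic oracle with a sound witness", {
  lin <- cached_model("linear", 3)
  d0 <- weighted_length(perm_identity(3), lin$sys)
  expect_equal(as.numeric(d0), 0)
  expect_length(attr(d0, "witness"), 0)
  expect_equal(as.numeric(weighted_length(make_inversion(1, 2, 3),
                                          lin$sys)), 1)
  expect_equal(as.numeric(weighted_length(make_inversion(1, 3, 3),
                                          lin$sys)), 2)
  # witness soundness across the whole group at n=4
  lin4 <- cached_model("linear", 4)
  enum4 <- cached_enum(lin4$gens, "linear 4")
  for (p in enum4$elements) {
    d <- weighted_length(p, lin4$sys, enum = enum4)
    w <- attr(d, "witness")
    expect_true(evaluate_word(w, lin4$gens) == p)
    expect_equal(as.numeric(word_weight(w, lin4$sys$order)), as.numeric(d))
  }
})

test_that("genome distance is a metric realized by the separating element", {
  lin <- cached_model("linear", 5)
  enum <- cached_enum(lin$gens, "linear 5")
  set.seed(42)
  tab <- all_distances(lin$gens)
  for (rep in 1:100) {
    g1 <- permutation(sample.int(5))
    g2 <- permutation(sample.int(5))
    d12 <- genome_distance(g1, g2, lin$sys, enum = enum)
    d21 <- genome_distance(g2, g1, lin$sys, enum = enum)
    expect_equal(as.numeric(d12), as.numeric(d21))
    # equals the oracle distance of the separating element
    z <- compose(g2, inverse(g1))
    expect_equal(as.numeric(d12), tab[[kbinv:::perm_key(z)]])
  }
  g <- permutation(sample.int(5))
  expect_equal(as.numeric(genome_distance(g, g, lin$sys, enum = enum)), 0)
  expect_error(genome_distance(perm_identity(4), perm_identity(5),
                               lin$sys), "different sizes")
})

test_that("circular distance quotients dihedral symmetry", {
  circ <- cached_model("circular", 5)
  enum <- cached_enum(circ$gens, "circular 5")
  dih <- dihedral_elements(5)
  expect_length(dih, 10)
  set.seed(43)
  for (rep in 1:25) {
    g1 <- permutation(sample.int(5))
    g2 <- permutation(sample.int(5))
    d <- circular_distance(g1, g2, circ$sys, enum = enum)
    # zero iff related by a rotation/reflection
    rot <- dih[[sample.int(10, 1)]]
    expect_equal(as.numeric(circular_distance(g1, compose(rot, g1),
                                              circ$sys, enum = enum)), 0)
    # invariant under relabeling both genomes simultaneously
    s <- dih[[sample.int(10, 1)]]
    d2 <- circular_distance(compose(s, g1), compose(s, g2), circ$sys,
                            enum = enum)
    expect_equal(as.numeric(d), as.numeric(d2))
    # symmetric
    expect_equal(as.numeric(circular_distance(g2, g1, circ$sys,
                                              enum = enum)),
                 as.numeric(d))
  }
  lin <- cached_model("linear", 4)
  expect_error(circular_distance(perm_identity(4), perm_identity(4),
                                 lin$sys), "linear")
})

test_that("circular distance agrees with the brute-force orbit oracle", {
  circ <- cached_model("circular", 5)
  enum <- cached_enum(circ$gens, "circular 5")
  tab <- all_distances(circ$gens)
  dih <- dihedral_elements(5)
  set.seed(44)
  for (rep in 1:25) {
    g1 <- permutation(sample.int(5))
    g2 <- permutation(sample.int(5))
    d <- circular_distance(g1, g2, circ$sys, enum = enum)
    oracle <- min(vapply(dih, function(s) {
      z <- compose(compose(s, g2), inverse(g1))
      tab[[kbinv:::perm_key(z)]]
    }, numeric(1)))
    expect_equal(as.numeric(d), oracle)
  }
})

test_that("distance matrices are symmetric, zero-diagonal and oracle-exact", {
  lin <- cached_model("linear", 4)
  set.seed(45)
  genomes <- random_genomes(4, 5, seed = 450)
  m <- distance_matrix(genomes, lin$gens, sys = lin$sys)
  expect_equal(m, t(m))
  expect_true(all(diag(m) == 0))
  expect_true(all(m >= 0))
  # triangle inequality
  for (a in 1:5) for (b in 1:5) for (cc in 1:5) {
    expect_lte(m[a, b], m[a, cc] + m[cc, b] + 1e-12)
  }
  # engine matrix equals oracle matrix
  m2 <- distance_matrix(genomes, lin$gens, sys = NULL)
  expect_equal(m, m2)
  # single genome: 1x1 zero
  m1 <- distance_matrix(genomes[1], lin$gens, sys = lin$sys)
  expect_equal(dim(m1), c(1L, 1L))
  expect_equal(m1[1, 1], 0)
  expect_error(distance_matrix(stats::setNames(genomes, rep("X", 5)),
                               lin$gens), "distinct")
})
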