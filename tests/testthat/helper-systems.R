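# Shared fixtures: completed rewriting systems are expensive enough to
# build once per test run, so they are cached here, keyed by model.

.sys_cache <- new.env(parent = emptyenv())

cached_model <- function(topology, n, weights = "length") {
  key <- paste(topology, n, weights)
  got <- get0(key, envir = .sys_cache)
  if (!is.null(got)) return(got)
  model <- build_model(n, topology, weights)
  sys <- knuth_bendix(model$presentation)
  attr(sys, "topology") <- topology
  out <- list(gens = model$gens, sys = sys,
              presentation = model$presentation)
  assign(key, out, envir = .sys_cache)
  out
}

cached_enum <- function(gens, key) {
  k2 <- paste("enum", key)
  got <- get0(k2, envir = .sys_cache)
  if (!is.null(got)) return(got)
  enum <- enumerate_group(gens)
  assign(k2, enum, envir = .sys_cache)
  enum
}

# Coxeter generators (adjacent transpositions) of S_n with unit weights
coxeter_perms <- function(n) {
  out <- list()
  for (i in seq_len(n - 1L)) {
    img <- seq_len(n)
    img[c(i, i + 1L)] <- c(i + 1L, i)
    out[[paste0("s", i)]] <- permutation(img)
  }
  out
}

coxeter_model <- function(n) {
  perms <- coxeter_perms(n)
  w <- as.list(rep(1, length(perms)))
  names(w) <- names(perms)
  generic_model(perms, w)
}

# randomized-strategy normalization in plain R: apply a randomly chosen
# applicable rule at a randomly chosen position until irreducible
random_normalize <- function(w, sys) {
  repeat {
    hits <- list()
    for (ri in seq_along(sys$rules)) {
      l <- sys$rules[[ri]]$lhs
      if (length(l) > length(w)) next
      for (pos in seq_len(length(w) - length(l) + 1L)) {
        if (identical(w[pos:(pos + length(l) - 1L)], l))
          hits[[length(hits) + 1L]] <- c(ri, pos)
      }
    }
    if (length(hits) == 0L) return(w)
    pick <- hits[[sample.int(length(hits), 1L)]]
    r <- sys$rules[[pick[1]]]
    pos <- pick[2]
    w <- c(if (pos > 1L) w[seq_len(pos - 1L)],
           r$rhs,
           if (pos + length(r$lhs) <= length(w))
             w[seq.int(pos + length(r$lhs), length(w))])
    if (is.null(w)) w <- character(0)
  }
}

random_word <- function(labels, maxlen = 10L) {
  len <- sample.int(maxlen, 1L)
  labels[sample.int(length(labels), len, replace = TRUE)]
}
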