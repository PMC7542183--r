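# Genome list files and seeded fixture generation.

#' Read and write genome list files
#'
#' One labeled permutation per line: `LABEL<TAB>notation`, where the
#' notation is either cycle notation (`"(1,4)(3,7,6)"`) or one-line
#' notation (`"4,2,7,1,5,3,6"`).  Blank lines and `#` comments are
#' ignored on read.
#'
#' @param path file path.
#' @param n number of positions.
#' @return `read_genomes()`: a named list of [permutation()]s.
#' @export
read_genomes <- function(path, n) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop("malformed genome line (need LABEL<TAB>permutation): ", ln)
    lab <- trimws(parts[1])
    if (!is.null(out[[lab]])) stop("duplicate genome label: ", lab)
    out[[lab]] <- parse_perm(parts[2], n)
  }
  out
}

#' @rdname read_genomes
#' @param genomes named list of [permutation()]s.
#' @export
write_genomes <- function(genomes, path) {
  lines <- vapply(names(genomes), function(lab)
    paste0(lab, "\t", format_cycles(genomes[[lab]])), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Generate random genome fixtures
#'
#' `count` distinct random permutations of `1..n`, uniform via seeded
#' Fisher-Yates shuffle (R's `sample`), labeled `G1..Gcount` (or
#' `A, B, C, ...` for up to 26).  Reproducible: the seed fully
#' determines the output.
#'
#' @param n number of positions.
#' @param count how many genomes.
#' @param seed integer seed (required: fixtures must be reproducible).
#' @return A named list of [permutation()]s.
#' @export
random_genomes <- function(n, count, seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  set.seed(as.integer(seed))
  labs <- if (count <= 26L) LETTERS[seq_len(count)]
          else paste0("G", seq_len(count))
  out <- list()
  seen <- character(0)
  for (lab in labs) {
    repeat {
      p <- permutation(sample.int(n))
      if (!perm_key(p) %in% seen) break
    }
    seen <- c(seen, perm_key(p))
    out[[lab]] <- p
  }
  out
}
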