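# Synthetic benchmark fixtures -----------------------------------------------
#
# Deterministic generators emulating the shape of a realistic evaluation:
# a uniform-composition synthetic genome and sets of planted queries
# (1000-3000 bp substrings, optionally reverse-complemented and point
# mutated) with a truth table, so recovery can be measured exactly
# without any external data.

# run code under a seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed) || is.na(seed)) stop("a seed is required", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic genome
#'
#' A uniform-composition ACGT sequence, deterministic for a given seed.
#' No GC skew, repeats or Ns: the simplest background against which
#' planted-query recovery is provable.
#'
#' @param length Genome length in bases (>= 1).
#' @param seed Mandatory integer seed; the caller's RNG state is left
#'   untouched.
#' @param name Sequence name for the resulting record.
#' @return A [dna_record].
#' @examples
#' make_genome(50, seed = 1)
#' @export
make_genome <- function(length, seed, name = "synth") {
  length <- as.numeric(length)
  if (is.na(length) || length < 1) {
    stop("genome length must be >= 1", call. = FALSE)
  }
  res <- with_seed(seed, {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
          collapse = "")
  })
  dna_record(name, res)
}

#' Plant query sequences in a genome
#'
#' Samples `n` substrings uniformly (lengths uniform over
#' `length_range`), reverse-complements each with probability
#' `strand_mix`, applies point mutations at `mutation_rate` per base,
#' and returns both the queries and a truth table recording where each
#' was planted.
#'
#' @param genome A [dna_record] (longer than the maximum planted
#'   length).
#' @param n Number of queries (>= 0).
#' @param length_range Two-element range of planted lengths in bases.
#' @param mutation_rate Per-base substitution probability in `[0, 1)`.
#' @param strand_mix Probability a query is planted on the minus strand.
#' @param seed Mandatory integer seed.
#' @param prefix Query name prefix.
#' @return A list with `queries` (list of [dna_record]) and `truth`, a
#'   data.frame with columns `query`, `target`, `target_start` (0-based),
#'   `strand`, `length`, `mutations`.
#' @export
plant_queries <- function(genome, n, length_range = c(1000L, 3000L),
                          mutation_rate = 0, strand_mix = 0.5, seed,
                          prefix = "q") {
  stopifnot(inherits(genome, "dna_record"))
  n <- as.integer(n)
  if (is.na(n) || n < 0L) stop("n must be >= 0", call. = FALSE)
  length_range <- as.integer(length_range)
  if (length(length_range) != 2L || any(is.na(length_range)) ||
      length_range[1L] < 1L || length_range[1L] > length_range[2L]) {
    stop("length_range must be an increasing pair of positive lengths",
         call. = FALSE)
  }
  if (genome$length <= length_range[2L]) {
    stop("genome must be longer than the maximum planted length",
         call. = FALSE)
  }
  if (mutation_rate < 0 || mutation_rate >= 1) {
    stop("mutation_rate must be in [0, 1)", call. = FALSE)
  }
  truth <- data.frame(query = character(n), target = character(n),
                      target_start = numeric(n), strand = character(n),
                      length = integer(n), mutations = integer(n),
                      stringsAsFactors = FALSE)
  if (n == 0L) {
    return(list(queries = structure(list(), names = character()),
                truth = truth))
  }
  bases <- c("A", "C", "G", "T")
  queries <- with_seed(seed, {
    lens <- sample(length_range[1L]:length_range[2L], n, replace = TRUE)
    starts <- vapply(lens, function(l) {
      sample.int(genome$length - l + 1L, 1L) - 1L  # 0-based
    }, 0L)
    strands <- ifelse(stats::runif(n) < strand_mix, "-", "+")
    lapply(seq_len(n), function(i) {
      res <- substr(genome$residues, starts[i] + 1L, starts[i] + lens[i])
      if (strands[i] == "-") res <- reverse_complement(res)
      nmut <- 0L
      if (mutation_rate > 0) {
        pos <- which(stats::runif(lens[i]) < mutation_rate)
        nmut <- length(pos)
        if (nmut) {
          chars <- strsplit(res, "")[[1L]]
          for (pp in pos) {
            chars[pp] <- sample(setdiff(bases, toupper(chars[pp])), 1L)
          }
          res <- paste(chars, collapse = "")
        }
      }
      nm <- sprintf("%s%04d", prefix, i)
      truth[i, ] <<- list(nm, genome$name, starts[i], strands[i],
                          lens[i], nmut)
      dna_record(nm, res)
    })
  })
  names(queries) <- truth$query
  list(queries = queries, truth = truth)
}

#' Fraction of planted queries recovered by an alignment run
#'
#' A planted query counts as recovered when some PSL record for it has
#' the planted strand and target, a `tStart` within `tile_size` bases of
#' the planted position, and `matches` of at least 95 percent of the
#' planted length.
#'
#' @param truth Truth table from [plant_queries()].
#' @param records PSL data.frame from the same run.
#' @param tile_size Positional slack in bases.
#' @return A fraction in `[0, 1]` (`NaN` for an empty truth table).
#' @export
recovery_rate <- function(truth, records, tile_size = 11L) {
  stopifnot(is.data.frame(truth), is.data.frame(records))
  if (!nrow(truth)) return(NaN)
  hit <- vapply(seq_len(nrow(truth)), function(i) {
    tr <- truth[i, ]
    sub <- records[records$qName == tr$query &
                   records$tName == tr$target &
                   records$strand == tr$strand, , drop = FALSE]
    any(abs(sub$tStart - tr$target_start) <= tile_size &
        sub$matches >= 0.95 * tr$length)
  }, TRUE)
  mean(hit)
}

#' Benchmark-shaped fixture suite
#'
#' Eight query sets of sizes `{50, 50, 100, 200, 300, 400, 500, 600}`
#' (the seven canonical sizes with the smallest duplicated to make
#' eight), each of 1000-3000 bp queries planted in one shared synthetic
#' genome.
#'
#' @param genome_length Length of the shared genome (default 2 Mb).
#' @param sizes Query-set sizes.
#' @param length_range Planted length range in bases.
#' @param mutation_rate Per-base substitution probability.
#' @param seed Mandatory integer seed; each set derives its own subseed.
#' @return A list with `genome` (a [dna_record]) and `sets`, a list of
#'   `plant_queries()` results.
#' @export
benchmark_suite <- function(genome_length = 2e6,
                            sizes = c(50L, 50L, 100L, 200L, 300L, 400L,
                                      500L, 600L),
                            length_range = c(1000L, 3000L),
                            mutation_rate = 0, seed) {
  genome <- make_genome(genome_length, seed = seed, name = "synth1")
  sets <- lapply(seq_along(sizes), function(i) {
    plant_queries(genome, sizes[i], length_range = length_range,
                  mutation_rate = mutation_rate, seed = seed + 1000L + i,
                  prefix = sprintf("s%d_q", i))
  })
  list(genome = genome, sets = sets)
}
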