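# shared generators and oracles for the test suite

# a random record with run-structured soft-masking and N-runs
rand_record <- function(name, len) {
  if (len == 0L) return(dna_record(name, ""))
  chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  for (i in seq_len(sample(0:3, 1L))) {       # lowercase runs
    w <- sample.int(min(len, 50L), 1L)
    s <- sample.int(len - w + 1L, 1L)
    chars[s:(s + w - 1L)] <- tolower(chars[s:(s + w - 1L)])
  }
  for (i in seq_len(sample(0:3, 1L))) {       # N runs (mixed case)
    w <- sample.int(min(len, 20L), 1L)
    s <- sample.int(len - w + 1L, 1L)
    chars[s:(s + w - 1L)] <- ifelse(stats::runif(w) < 0.5, "N", "n")
  }
  dna_record(name, paste(chars, collapse = ""))
}

rand_records <- function(n, max_len = 200L, min_len = 0L) {
  lens <- sample(min_len:max_len, n, replace = TRUE)
  recs <- lapply(seq_len(n), function(i) rand_record(sprintf("r%04d", i),
                                                     lens[i]))
  names(recs) <- vapply(recs, `[[`, "", "name")
  recs
}

# comma-terminated PSL list field -> numeric vector
parse_psl_list <- function(s) {
  if (!nzchar(s)) return(numeric(0))
  as.numeric(strsplit(sub(",$", "", s), ",", fixed = TRUE)[[1]])
}

# exhaustive best ungapped local alignment between a short query and a
# target, scanning every diagonal of both strands (+1 match / -1
# mismatch; N never matches).  Ties: higher score first; at equal score
# the earliest end, then the latest start (i.e. the shortest segment).
# Strands are scanned '+' first, so an exact cross-strand tie keeps '+'.
# Coordinates are 0-based half-open in oriented-query space.
brute_best_ungapped <- function(query, target) {
  tr <- charToRaw(toupper(target))
  rawn <- charToRaw("N")
  best <- list(score = -Inf)
  for (strand in c("+", "-")) {
    qres <- if (strand == "-") reverse_complement(query) else query
    qr <- charToRaw(toupper(qres))
    Q <- length(qr); Tn <- length(tr)
    for (d in seq(-(Q - 1L), Tn - 1L)) {
      lo <- max(0L, -d); hi <- min(Q, Tn - d)
      if (hi <= lo) next
      qi <- (lo + 1L):hi
      m <- qr[qi] == tr[qi + d] & qr[qi] != rawn & tr[qi + d] != rawn
      v <- ifelse(m, 1L, -1L)
      # prefix-sum scan: segment (i, j] scores S_j - S_i, so for each
      # end j the best start is the latest argmin of the prefix sums
      # left of j; the overall best updates only on strict improvement
      # so the earliest end wins at equal score
      pre_min <- 0L; pre_idx <- 0L; s <- 0L
      for (j in seq_along(v)) {
        s <- s + v[j]
        cand <- s - pre_min
        if (cand > best$score) {
          best <- list(score = cand, strand = strand, d = d,
                       qs = lo + pre_idx, qe = lo + j)
        }
        if (s <= pre_min) { pre_min <- s; pre_idx <- j }
      }
    }
  }
  if (!is.finite(best$score)) return(NULL)
  list(score = best$score, strand = best$strand,
       q_start = best$qs, q_end = best$qe,
       t_start = best$qs + best$d, t_end = best$qe + best$d)
}

# free port helper: pick a base port per call site to avoid collisions
test_port <- local({
  counter <- 0L
  function(base = 46000L) {
    counter <<- counter + 37L
    base + (Sys.getpid() + counter) %% 2000L
  }
})
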