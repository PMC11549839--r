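test_that("tile codes follow the 2bit base code table", {
  expect_equal(tile_encode("TT", 2), 0)
  expect_equal(tile_encode("TC", 2), 1)
  expect_equal(tile_encode("CT", 2), 4)
  expect_equal(tile_encode("acgt", 4), tile_encode("ACGT", 4))
  expect_true(is.na(tile_encode("AN", 2)))
  expect_error(tile_encode("ACG", 2), "does not match")

  # consistency with the packed-byte layout: ACGT's code is 0x9c
  expect_equal(tile_encode("ACGT", 4), 0x9c)
})

test_that("index construction steps tiles, skips Ns, drops overused codes", {
  p <- align_params(tile_size = 4L, step_size = 4L, min_seeds = 1L)
  idx <- build_tile_index(list(dna_record("t", "ACGTACGT")), p)
  pos <- tile_positions(idx, tile_encode("ACGT", 4))
  expect_equal(pos$target_offset, c(0, 4))
  expect_equal(pos$target, c("t", "t"))

  idx <- build_tile_index(list(dna_record("t", "ACGNACGT")), p)
  expect_equal(tile_positions(idx, tile_encode("ACGT", 4))$target_offset, 4)

  p2 <- align_params(tile_size = 4L, step_size = 4L,
                     overused_threshold = 1L)
  idx <- build_tile_index(list(dna_record("t", strrep("A", 100))), p2)
  expect_equal(nrow(tile_positions(idx, tile_encode("AAAA", 4))), 0L)
  expect_equal(idx$dropped_tiles, tile_encode("AAAA", 4))

  expect_error(build_tile_index(list()), "no target")
})

test_that("stored offsets are step-multiples and tiles never span an N", {
  set.seed(21)
  p <- align_params(tile_size = 5L, step_size = 3L)
  recs <- rand_records(5, max_len = 300L, min_len = 30L)
  idx <- build_tile_index(recs, p)
  expect_true(all(idx$tiles$target_offset %% p$step_size == 0))
  for (i in seq_len(nrow(idx$tiles))) {
    r <- recs[[idx$tiles$target_id[i]]]
    kmer <- substr(r$residues, idx$tiles$target_offset[i] + 1L,
                   idx$tiles$target_offset[i] + p$tile_size)
    expect_false(grepl("n", kmer, ignore.case = TRUE))
    expect_equal(tile_encode(kmer, p$tile_size), idx$tiles$code[i])
  }
})

test_that("seed finding scans both strands at step 1", {
  p <- align_params(tile_size = 4L, step_size = 4L, min_seeds = 1L)
  idx <- build_tile_index(list(dna_record("t", "TTTTACGTCCCC")), p)

  hits <- find_seed_hits(idx, dna_record("q", "ACGT"))
  plus <- hits[hits$strand == "+", ]
  expect_true(any(plus$query_offset == 0 & plus$target_offset == 4))

  # query below tile size, and all-N queries, yield nothing
  expect_equal(nrow(find_seed_hits(idx, dna_record("q", "ACG"))), 0L)
  expect_equal(nrow(find_seed_hits(idx, dna_record("q", "NNNNNNNN"))), 0L)

  # a minus-strand query seeds via its reverse complement
  hits <- find_seed_hits(idx, dna_record("q", reverse_complement("ACGT")))
  expect_true(any(hits$strand == "-" & hits$target_offset == 4))
})

test_that("a planted 3x-tile exact substring yields >= 2 seeds, one diagonal", {
  set.seed(17)
  for (rep in 1:20) {
    g <- make_genome(2000, seed = 100 + rep)
    idx <- build_tile_index(list(g))
    len <- 3L * idx$params$tile_size
    s <- sample.int(g$length - len, 1L)
    q <- dna_record("q", substr(g$residues, s, s + len - 1L))
    hits <- find_seed_hits(idx, q)
    planted_diag <- (s - 1L) - 0L
    on_diag <- hits[hits$strand == "+" & hits$diagonal == planted_diag, ]
    expect_gte(nrow(on_diag), 2L)
  }
})

test_that("diagonal clustering bands hits and enforces min_seeds", {
  p <- align_params(tile_size = 4L, max_gap = 100L, min_seeds = 2L)
  h <- function(qoff, toff, strand = "+", target = "t") {
    data.frame(strand = strand, query_offset = qoff, target = target,
               target_offset = toff, diagonal = toff - qoff,
               stringsAsFactors = FALSE)
  }
  cl <- cluster_hits(rbind(h(0, 50), h(8, 58)), p)
  expect_length(cl, 1L)
  expect_equal(nrow(cl[[1]]$hits), 2L)

  expect_length(cluster_hits(h(0, 50), p), 0L)

  p1 <- align_params(tile_size = 4L, max_gap = 100L, min_seeds = 1L)
  two <- rbind(h(0, 50), h(0, 50 + 101))
  expect_length(cluster_hits(two, p1), 2L)
  near <- rbind(h(0, 50), h(0, 50 + 100))
  expect_length(cluster_hits(near, p1), 1L)

  # strands and targets never share a cluster
  mixed <- rbind(h(0, 50), h(0, 50, strand = "-"),
                 h(0, 50, target = "u"), h(8, 58))
  cl <- cluster_hits(mixed, p1)
  expect_length(cl, 3L)
})
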