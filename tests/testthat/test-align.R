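make_target_with_plant <- function(glen, plant, at, seed, name = "t") {
  g <- make_genome(glen, seed = seed, name = name)
  res <- paste0(substr(g$residues, 1, at), plant,
                substr(g$residues, at + nchar(plant) + 1, glen))
  dna_record(name, res)
}

test_that("a planted exact 100-mer extends to one full-length plus block", {
  plant <- make_genome(100, seed = 900, name = "p")$residues
  target <- make_target_with_plant(8000, plant, at = 5000, seed = 901)
  arc <- encode_twobit(list(target))
  idx <- build_tile_index(list(target))
  q <- dna_record("q", plant)

  recs <- align(list(q), idx, arc)
  top <- recs[1, ]
  expect_equal(top$matches, 100)
  expect_equal(top$misMatches, 0)
  expect_equal(top$blockCount, 1)
  expect_equal(top$tStart, 5000)
  expect_equal(top$strand, "+")

  # the same plant queried as its reverse complement: '-' strand,
  # identical target span
  rcq <- dna_record("q", reverse_complement(plant))
  rrecs <- align(list(rcq), idx, arc)
  rtop <- rrecs[1, ]
  expect_equal(rtop$strand, "-")
  expect_equal(rtop$tStart, top$tStart)
  expect_equal(rtop$tEnd, top$tEnd)
  expect_equal(rtop$matches, 100)
})

test_that("records below min_score or min_identity are suppressed", {
  target <- make_genome(5000, seed = 77, name = "t")
  arc <- encode_twobit(list(target))
  p <- align_params(min_score = 30L)
  idx <- build_tile_index(list(target), p)
  # a 22-base exact plant seeds (2 step-aligned tiles) but scores 22 < 30
  q <- dna_record("q", substr(target$residues, 2201, 2222))
  hits <- find_seed_hits(idx, q)
  cl <- cluster_hits(hits, p)
  if (length(cl)) {
    expect_null(extend_cluster(cl[[1]], q, arc, p))
  }
  expect_equal(nrow(align(list(q), idx, arc)), 0L)

  # lowering min_score recovers it
  p2 <- align_params(min_score = 20L)
  expect_gte(nrow(align(list(q), idx, arc, p2)), 1L)
})

test_that("align handles degenerate inputs and checks provenance", {
  target <- make_genome(3000, seed = 3, name = "t")
  arc <- encode_twobit(list(target))
  idx <- build_tile_index(list(target))
  expect_equal(nrow(align(list(), idx, arc)), 0L)
  expect_equal(nrow(align(list(dna_record("q", "ACGTAC")), idx, arc)), 0L)

  other <- encode_twobit(list(make_genome(3000, seed = 4, name = "u")))
  expect_error(align(list(dna_record("q", "ACGTACGTACGTACGT")), idx, other),
               "same targets")
})

test_that("multiple planted queries reproduce the planting table", {
  g <- make_genome(60000, seed = 12)
  arc <- encode_twobit(list(g))
  idx <- build_tile_index(list(g))
  pq <- plant_queries(g, 25, length_range = c(100L, 400L), seed = 13)
  recs <- align(pq$queries, idx, arc)
  expect_equal(recovery_rate(pq$truth, recs), 1.0)
  # every planted query aligns full length with zero mismatches
  m <- recs[match(pq$truth$query, recs$qName), ]
  expect_equal(m$matches, as.numeric(pq$truth$length))
  expect_equal(m$misMatches, rep(0, 25))
  expect_equal(m$strand, pq$truth$strand)
  expect_equal(m$tStart, pq$truth$target_start)
  expect_true(all(psl_valid(recs)))
})

test_that("minus-strand records re-map to the same target residues", {
  g <- make_genome(20000, seed = 31)
  arc <- encode_twobit(list(g))
  idx <- build_tile_index(list(g))
  pq <- plant_queries(g, 10, length_range = c(60L, 200L), strand_mix = 1,
                      seed = 32)
  recs <- align(pq$queries, idx, arc)
  expect_true(all(recs$strand == "-"))
  for (i in seq_len(nrow(recs))) {
    r <- recs[i, ]
    q <- pq$queries[[r$qName]]
    # aligning the reverse-complemented query on '+' hits the same span
    rcq <- dna_record(paste0(q$name, "_rc"),
                      reverse_complement(q$residues))
    rrec <- align(list(rcq), idx, arc)[1, ]
    expect_equal(rrec$strand, "+")
    expect_equal(rrec$tStart, r$tStart)
    expect_equal(rrec$tEnd, r$tEnd)
    # and the block's target residues equal the oriented query block
    sizes <- parse_psl_list(r$blockSizes)
    qs <- parse_psl_list(r$qStarts)
    ts <- parse_psl_list(r$tStarts)
    oriented <- reverse_complement(q$residues)
    for (b in seq_along(sizes)) {
      expect_equal(fetch_subsequence(arc, r$tName, ts[b], ts[b] + sizes[b]),
                   substr(oriented, qs[b] + 1, qs[b] + sizes[b]))
    }
  }
})

test_that("identical inputs give byte-identical PSL across runs", {
  g <- make_genome(30000, seed = 41)
  arc <- encode_twobit(list(g))
  idx <- build_tile_index(list(g))
  pq <- plant_queries(g, 15, length_range = c(100L, 300L),
                      mutation_rate = 0.02, seed = 42)
  one <- write_psl(align(pq$queries, idx, arc))
  two <- write_psl(align(pq$queries, build_tile_index(list(g)), arc))
  expect_identical(one, two)
})

test_that("percent identity is the match fraction of aligned non-N bases", {
  r <- psl_empty()[0, ]
  mk <- function(m, mm) {
    data.frame(matches = m, misMatches = mm, repMatches = 0, nCount = 0)
  }
  expect_equal(percent_identity(mk(100, 0)), 100.0)
  expect_equal(percent_identity(mk(90, 10)), 90.0)
  expect_equal(percent_identity(mk(97, 3)), 97.0)
  expect_true(is.na(percent_identity(mk(0, 0))))
})
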