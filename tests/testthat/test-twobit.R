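test_that("packed bases follow the standard code table (ACGT -> 0x9c)", {
  bytes <- encode_twobit(list(dna_record("s", "ACGT")))
  # A=2,C=1,G=3,T=0 packed most-significant-first: 10 01 11 00
  expect_equal(bytes[length(bytes)], as.raw(0x9c))
})

test_that("N runs and lowercase runs become n_blocks and mask_blocks", {
  a <- twobit_parse(encode_twobit(list(dna_record("s", "ACGTN"))))
  expect_equal(unname(a$sequences$s$n_blocks), cbind(4, 1))
  expect_equal(nrow(a$sequences$s$mask_blocks), 0L)

  a <- twobit_parse(encode_twobit(list(dna_record("s", "acgt"))))
  expect_equal(unname(a$sequences$s$mask_blocks), cbind(0, 4))
  expect_equal(nrow(a$sequences$s$n_blocks), 0L)

  # lowercase n sits in both block lists
  a <- twobit_parse(encode_twobit(list(dna_record("s", "AnnA"))))
  expect_equal(unname(a$sequences$s$n_blocks), cbind(1, 2))
  expect_equal(unname(a$sequences$s$mask_blocks), cbind(1, 2))
})

test_that("encode/decode round-trips names, case, and Ns exactly", {
  set.seed(101)
  recs <- rand_records(50, max_len = 500L)
  expect_identical(decode_twobit(encode_twobit(recs)), recs)

  expect_length(decode_twobit(encode_twobit(list())), 0L)
})

test_that("archives in either byte order decode identically", {
  set.seed(5)
  recs <- rand_records(8, max_len = 120L)
  little <- encode_twobit(recs, endian = "little")
  big <- encode_twobit(recs, endian = "big")
  expect_false(identical(little, big))
  expect_identical(decode_twobit(little), recs)
  expect_identical(decode_twobit(big), recs)
})

test_that("malformed archives are rejected with informative errors", {
  expect_error(twobit_parse(charToRaw("not a twobit archive")),
               "bad signature")
  good <- encode_twobit(list(dna_record("s", "ACGTACGT")))
  expect_error(twobit_parse(good[1:20]), "truncated")
  expect_error(twobit_parse(good[seq_len(length(good) - 1L)]), "truncated")
  expect_error(encode_twobit(list(dna_record("s", "ACGT"),
                                  dna_record("s", "TTTT"))), "duplicate")
})

test_that("fetch_subsequence decodes only the requested window", {
  arc <- encode_twobit(list(dna_record("g", "ACGTACGT")))
  expect_equal(fetch_subsequence(arc, "g", 2, 6), "GTAC")
  expect_equal(fetch_subsequence(arc, "g", 3, 3), "")
  expect_error(fetch_subsequence(arc, "g", 2, 9), "out of range")
  expect_error(fetch_subsequence(arc, "nope", 0, 1), "no sequence named")

  # intervals overlapping an N-block or mask block restore them
  arc <- encode_twobit(list(dna_record("g", "ACGNNNacgTGCA")))
  expect_equal(fetch_subsequence(arc, "g", 2, 8), "GNNNac")

  # oracle equivalence against whole-sequence decode, random intervals
  set.seed(33)
  recs <- rand_records(5, max_len = 400L, min_len = 50L)
  arc <- twobit_parse(encode_twobit(recs))
  for (rec in recs) {
    full <- rec$residues
    for (i in 1:40) {
      s <- sample.int(rec$length, 1L) - 1L
      e <- s + sample.int(rec$length - s + 1L, 1L) - 1L
      expect_identical(fetch_subsequence(arc, rec$name, s, e),
                       substr(full, s + 1L, e))
    }
  }
})

test_that("fa2twobit/twobit2fa compose the codecs (with regions)", {
  fa <- ">g\nACGTACGT\n"
  expect_equal(twobit2fa(fa2twobit(fa)), fa)
  expect_match(twobit2fa(fa2twobit(fa), name = "g", start = 2, end = 6),
               "GTAC", fixed = TRUE)
  empty <- fa2twobit("")
  expect_length(twobit_names(empty), 0L)

  set.seed(9)
  recs <- rand_records(10, max_len = 200L)
  fa <- write_fasta(recs)
  expect_equal(twobit2fa(fa2twobit(fa)), fa)
})

test_that("emitted archives interoperate with an independent 2bit reader", {
  skip_if_not_installed("rtracklayer")
  set.seed(55)
  recs <- rand_records(6, max_len = 300L, min_len = 10L)
  path <- withr::local_tempfile(fileext = ".2bit")
  writeBin(encode_twobit(recs), path)
  ext <- rtracklayer::import.2bit(path)
  expect_equal(names(ext), unname(vapply(recs, `[[`, "", "name")))
  # the external reader drops soft-mask case; compare uppercased residues
  expect_equal(unname(as.character(ext)),
               unname(vapply(recs, function(r) toupper(r$residues), "")))

  # and our decoder reads archives written by the external writer
  path2 <- withr::local_tempfile(fileext = ".2bit")
  seqs <- Biostrings::DNAStringSet(
    vapply(recs, function(r) toupper(r$residues), ""))
  rtracklayer::export.2bit(seqs, path2)
  ours <- decode_twobit(path2)
  expect_equal(unname(vapply(ours, `[[`, "", "residues")),
               unname(vapply(recs, function(r) toupper(r$residues), "")))
})
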