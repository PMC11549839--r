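server_fixture <- function(glen = 60000L, n = 6L, seed = 401L) {
  g <- make_genome(glen, seed = seed)
  arc <- encode_twobit(list(g))
  pq <- plant_queries(g, n, length_range = c(200L, 500L), seed = seed + 1L)
  list(genome = g, archive = arc, queries = pq$queries, truth = pq$truth,
       index = build_tile_index(list(g)))
}

test_that("start/wait/status/query/stop lifecycle works end to end", {
  fx <- server_fixture()
  h <- start_server(server_config(port = test_port()), fx$archive)
  withr::defer(try(stop_server(h), silent = TRUE))
  expect_true(h$owned)
  expect_equal(wait_server(h, timeout = 30), "ready")

  st <- status_server(h)
  expect_true(st$ready)
  expect_equal(st$sequence_count, 1L)
  expect_equal(st$total_bases, fx$genome$length)
  expect_equal(st$tile_size, 11L)
  expect_equal(st$request_count, 0)

  res <- query_server(h, fx$queries, as = "psl")
  expect_equal(recovery_rate(fx$truth, res), 1.0)

  # request_count counts completed queries
  expect_equal(status_server(h)$request_count, length(fx$queries))

  stop_server(h)
  expect_error(status_server(h), "connection error")
  # double stop is an idempotent success
  expect_true(stop_server(h))
  expect_true(stop_server(h))
})

test_that("socket results are byte-identical to in-process alignment", {
  fx <- server_fixture()
  h <- start_server(server_config(port = test_port()), fx$archive)
  withr::defer(try(stop_server(h), silent = TRUE))
  expect_equal(wait_server(h, timeout = 30), "ready")

  # watch the session temp dir: querying must create no files on either side
  before <- list.files(tempdir(), recursive = TRUE)
  via_socket <- query_server(h, fx$queries, as = "psl_text")
  after <- list.files(tempdir(), recursive = TRUE)
  expect_identical(after, before)

  in_process <- write_psl(align(fx$queries, fx$index, fx$archive))
  expect_identical(via_socket, in_process)

  # and the QueryResult view matches the in-process records
  qres <- query_server(h, fx$queries)
  expect_equal(vapply(qres, `[[`, "", "query_id"),
               unique(read_psl(text = in_process)$qName))
  stop_server(h)
})

test_that("port retry binds the next free port within the retry budget", {
  fx <- server_fixture(glen = 20000L, n = 2L, seed = 421L)
  p <- test_port()
  h1 <- start_server(server_config(port = p), fx$archive)
  withr::defer(try(stop_server(h1), silent = TRUE))
  expect_equal(h1$port, p)

  h2 <- start_server(server_config(port = p, max_retries = 5L), fx$archive)
  withr::defer(try(stop_server(h2), silent = TRUE))
  expect_gt(h2$port, p)
  expect_lte(h2$port - p, 5L)

  expect_error(start_server(server_config(port = p, can_retry = FALSE),
                            fx$archive),
               sprintf("tried port\\(s\\) %d$", p))
  stop_server(h2); stop_server(h1)
})

test_that("wait_server reports readiness of a delayed-start server", {
  fx <- server_fixture(glen = 20000L, n = 2L, seed = 431L)
  # nothing listening: times out without raising
  expect_equal(wait_server("127.0.0.1", port = test_port(), timeout = 1),
               "timeout")

  h <- start_server(server_config(port = test_port(), warmup_delay = 2),
                    fx$archive)
  withr::defer(try(stop_server(h), silent = TRUE))
  expect_equal(wait_server(h, timeout = 30), "ready")
  expect_true(status_server(h)$ready)
  stop_server(h)
})

test_that("queries against a not-yet-ready server fail explicitly", {
  fx <- server_fixture(glen = 20000L, n = 2L, seed = 441L)
  h <- start_server(server_config(port = test_port(), warmup_delay = 4),
                    fx$archive)
  withr::defer(try(stop_server(h), silent = TRUE))
  expect_error(query_server(h, fx$queries), "not ready")
  expect_equal(wait_server(h, timeout = 30), "ready")
  stop_server(h)
})

test_that("attach finds compatible servers and rejects mismatches", {
  fx <- server_fixture(glen = 20000L, n = 2L, seed = 451L)
  expect_null(attach_server("127.0.0.1", port = test_port()))

  p <- test_port()
  h <- start_server(server_config(port = p), fx$archive,
                    align_params(tile_size = 12L))
  withr::defer(try(stop_server(h), silent = TRUE))
  expect_equal(wait_server(h, timeout = 30), "ready")

  att <- attach_server("127.0.0.1", port = p)
  expect_s3_class(att, "server_handle")
  expect_false(att$owned)
  # an attached handle can query
  expect_silent(query_server(att, fx$queries[1],
                             params = align_params(tile_size = 12L)))

  expect_error(attach_server("127.0.0.1", port = p,
                             expected_params = align_params(tile_size = 11L)),
               "tile_size \\(server 12, expected 11\\)")

  # unowned stop is refused unless the server allows it
  expect_error(stop_server(att), "refused")
  stop_server(h)
})

test_that("protocol guards: oversized queries and parameter mismatches", {
  fx <- server_fixture(glen = 20000L, n = 2L, seed = 461L)
  h <- start_server(server_config(port = test_port(),
                                  max_query_bases = 100L), fx$archive)
  withr::defer(try(stop_server(h), silent = TRUE))
  expect_equal(wait_server(h, timeout = 30), "ready")
  big <- dna_record("big", strrep("ACGT", 50L))  # 200 bases > cap
  expect_error(query_server(h, list(big)), "cap")
  expect_error(query_server(h, fx$queries[1],
                            params = align_params(tile_size = 9L)),
               "mismatch")
  expect_length(query_server(h, list()), 0L)
  stop_server(h)
})

test_that("one server start amortises many queries without rebinding", {
  fx <- server_fixture(glen = 30000L, n = 4L, seed = 471L)
  h <- start_server(server_config(port = test_port()), fx$archive)
  withr::defer(try(stop_server(h), silent = TRUE))
  expect_equal(wait_server(h, timeout = 30), "ready")

  # two clients interleaving query batches each get their own results
  for (rep in 1:3) {
    r1 <- query_server(h, fx$queries[1:2], as = "psl")
    r2 <- query_server(h, fx$queries[3:4], as = "psl")
    expect_setequal(unique(r1$qName), names(fx$queries)[1:2])
    expect_setequal(unique(r2$qName), names(fx$queries)[3:4])
  }
  st <- status_server(h)
  expect_equal(st$request_count, 12)
  expect_equal(st$ready, TRUE)
  stop_server(h)
})
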