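# Genome-search server / client ----------------------------------------------
#
# A single-threaded TCP server holding the tile index and target context
# in memory, so one index build amortises any number of queries and no
# intermediate files are involved on either side.  The wire protocol is
# line-oriented text:
#
#   status                          -> "ok", "key: value" lines, "."
#   query <name> <len> [minScore] [minIdentity]
#     followed by one line of <len> residues
#                                   -> "ok <n>", n PSL lines, "."
#   quit [token]                    -> "bye" (or "err ..." if refused)
#
# The server process is forked from the caller (the listening socket is
# bound by the parent first, so the post-retry port is known
# immediately and the archive passes by memory, not by file).

#' Server configuration
#'
#' @param host Interface/host for the listener (and for clients).
#' @param port TCP port to bind (1024..65535).
#' @param can_retry On a busy port, try `port+1 .. port+max_retries`.
#' @param max_retries Number of successive ports to try (>= 0).
#' @param ready_timeout Default seconds [wait_server()] waits for
#'   readiness.
#' @param allow_remote_stop Honour `quit` from clients that do not hold
#'   the owner token.
#' @param max_query_bases Per-query length cap enforced by the server.
#' @param warmup_delay Seconds the server sleeps before building its
#'   index; useful for exercising readiness logic.
#' @return A `server_config` object.
#' @export
server_config <- function(host = "127.0.0.1", port = 17779L,
                          can_retry = TRUE, max_retries = 10L,
                          ready_timeout = 60, allow_remote_stop = FALSE,
                          max_query_bases = 1e6, warmup_delay = 0) {
  port <- as.integer(port)
  if (is.na(port) || port < 1024L || port > 65535L) {
    stop("port must be in 1024..65535", call. = FALSE)
  }
  max_retries <- as.integer(max_retries)
  if (is.na(max_retries) || max_retries < 0L) {
    stop("max_retries must be >= 0", call. = FALSE)
  }
  structure(list(host = host, port = port, can_retry = isTRUE(can_retry),
                 max_retries = max_retries,
                 ready_timeout = as.numeric(ready_timeout),
                 allow_remote_stop = isTRUE(allow_remote_stop),
                 max_query_bases = as.numeric(max_query_bases),
                 warmup_delay = as.numeric(warmup_delay)),
            class = "server_config")
}

resolve_address <- function(x, port = NULL) {
  if (inherits(x, "server_handle")) return(list(host = x$host, port = x$port))
  if (inherits(x, "server_config")) return(list(host = x$host, port = x$port))
  if (is.list(x) && !is.null(x$host) && !is.null(x$port)) {
    return(list(host = x$host, port = as.integer(x$port)))
  }
  if (is.character(x) && !is.null(port)) {
    return(list(host = x, port = as.integer(port)))
  }
  stop("expected a server handle, or host and port", call. = FALSE)
}

bind_with_retry <- function(config) {
  ports <- config$port
  if (config$can_retry) {
    ports <- config$port + 0:config$max_retries
  }
  tried <- integer(0)
  for (p in ports) {
    sock <- tryCatch(serverSocket(p), error = function(e) NULL)
    tried <- c(tried, p)
    if (!is.null(sock)) return(list(socket = sock, port = p))
  }
  stop(sprintf("could not bind a listening socket; tried port(s) %s",
               paste(tried, collapse = ", ")), call. = FALSE)
}

#' Start a genome-search server
#'
#' Binds a TCP listener (retrying successive ports if the requested one
#' is busy and `can_retry` is set), then forks a worker that builds the
#' tile index over the archive and serves queries.  The returned handle
#' reports the actually bound port; the server reports `ready: true`
#' only once its index is complete (poll with [wait_server()]).
#'
#' @param config A [server_config].
#' @param archive Target .2bit archive: raw bytes, a path, or a parsed
#'   `twobit_archive`.
#' @param params [align_params] for the served index.
#' @return A `server_handle` (fields `host`, `port`, `owned`, `pid`,
#'   `token`).
#' @export
start_server <- function(config = server_config(), archive,
                         params = align_params()) {
  stopifnot(inherits(config, "server_config"))
  params <- as_align_params(params)
  archive <- twobit_parse(archive)
  if (!length(archive$sequences)) {
    stop("refusing to serve an empty archive", call. = FALSE)
  }
  bound <- bind_with_retry(config)
  token <- paste0("tok", Sys.getpid(), basename(tempfile("")))
  job <- parallel::mcparallel({
    gf_serve(bound$socket, archive, params, config, token)
  }, detached = FALSE)
  close(bound$socket)  # the parent's copy only; the child keeps its own
  structure(list(host = config$host, port = bound$port, owned = TRUE,
                 pid = job$pid, token = token, job = job,
                 config = config),
            class = "server_handle")
}

#' @export
print.server_handle <- function(x, ...) {
  cat(sprintf("<server_handle> %s:%d (%s)\n", x$host, x$port,
              if (isTRUE(x$owned)) sprintf("owned, pid %d", x$pid)
              else "attached"))
  invisible(x)
}

# The blocking serve loop (runs in the forked worker; also the CLI's
# foreground path).
gf_serve <- function(socket, archive, params, config, token = "") {
  if (!nzchar(token)) token <- paste0("tok", Sys.getpid(),
                                      basename(tempfile("")))
  started <- Sys.time()
  if (config$warmup_delay > 0) Sys.sleep(config$warmup_delay)
  archive <- twobit_parse(archive)
  targets <- decode_twobit(archive)
  index <- build_tile_index(targets, params)
  ctx <- target_context(archive)
  request_count <- 0
  status_lines <- function() {
    c("ok",
      "version: blatr 0.1.0",
      sprintf("tile_size: %d", params$tile_size),
      sprintf("step_size: %d", params$step_size),
      sprintf("sequence_count: %d", length(index$target_names)),
      sprintf("total_bases: %.0f", sum(index$target_lengths)),
      sprintf("request_count: %.0f", request_count),
      sprintf("uptime: %.3f",
              as.numeric(difftime(Sys.time(), started, units = "secs"))),
      "ready: true",
      ".")
  }
  repeat {
    con <- tryCatch(socketAccept(socket, blocking = TRUE, open = "r+",
                                 timeout = 3600),
                    error = function(e) NULL)
    if (is.null(con)) next
    quitting <- FALSE
    # a client may vanish mid-exchange (e.g. a status poll that timed
    # out); treat any read/write failure as end of that conversation,
    # never as a reason to stop serving
    send <- function(lines) {
      tryCatch({ writeLines(lines, con); flush(con); TRUE },
               error = function(e) FALSE)
    }
    repeat {
      line <- tryCatch(readLines(con, n = 1L), error = function(e) character(0))
      if (!length(line)) break
      parts <- strsplit(trimws(line), "[[:space:]]+")[[1L]]
      cmd <- if (length(parts)) parts[1L] else ""
      ok <- if (cmd == "status") {
        send(status_lines())
      } else if (cmd == "quit") {
        client_tok <- if (length(parts) > 1L) parts[2L] else ""
        if (identical(client_tok, token) || config$allow_remote_stop) {
          quitting <- TRUE
          send("bye")
        } else {
          send(c("err stop refused: not the owner and remote stop is disabled",
                 "."))
        }
      } else if (cmd == "query") {
        if (length(parts) < 3L) {
          send(c("err malformed query command", "."))
        } else {
          qname <- parts[2L]
          qlen <- suppressWarnings(as.numeric(parts[3L]))
          seqline <- tryCatch(readLines(con, n = 1L),
                              error = function(e) character(0))
          if (!length(seqline) || is.na(qlen) || nchar(seqline) != qlen) {
            send(c("err query length mismatch", "."))
          } else if (qlen > config$max_query_bases) {
            send(c(sprintf("err query exceeds the %d-base cap",
                           as.integer(config$max_query_bases)), "."))
          } else {
            p2 <- params
            if (length(parts) >= 4L) p2$min_score <-
              as.integer(parts[4L])
            if (length(parts) >= 5L) p2$min_identity <-
              as.numeric(parts[5L])
            res <- tryCatch({
              q <- dna_record(qname, seqline)
              recs <- align(list(q), index, ctx, p2)
              request_count <- request_count + 1
              txt <- write_psl(recs)
              lines <- if (nzchar(txt)) {
                strsplit(txt, "\n", fixed = TRUE)[[1L]]
              } else character(0)
              c(sprintf("ok %d", length(lines)), lines, ".")
            }, error = function(e) {
              c(paste0("err ", conditionMessage(e)), ".")
            })
            send(res)
          }
        }
      } else {
        send(c(sprintf("err unknown command '%s'", cmd), "."))
      }
      if (!ok || quitting) break
    }
    tryCatch(close(con), error = function(e) NULL)
    if (quitting) break
  }
  close(socket)
  invisible(TRUE)
}

client_connect <- function(addr, timeout) {
  con <- suppressWarnings(tryCatch(
    socketConnection(addr$host, addr$port, blocking = TRUE, open = "r+",
                     timeout = timeout),
    error = function(e) NULL))
  if (is.null(con)) {
    stop(sprintf("connection error: no server listening at %s:%d",
                 addr$host, addr$port), call. = FALSE)
  }
  con
}

# read response lines until the "." terminator; character(0) on timeout
read_response <- function(con) {
  out <- character(0)
  repeat {
    line <- tryCatch(readLines(con, n = 1L), error = function(e) character(0))
    if (!length(line)) return(out)
    if (identical(line, ".")) return(out)
    out <- c(out, line)
    if (identical(out[1L], "bye")) return(out)
  }
}

#' Query a server's status
#'
#' Distinguishes three situations: no listener at the address (a
#' connection error is raised), a listener that is still building its
#' index (returns with `ready = FALSE` and `NA` counters), and a ready
#' server (live counters; `request_count` increments by one per
#' completed query).
#'
#' @param x A `server_handle`, or a host string with `port` given.
#' @param port Port when `x` is a host string.
#' @param timeout Seconds to wait for the status reply.
#' @return A `server_status` object.
#' @export
status_server <- function(x, port = NULL, timeout = 2) {
  addr <- resolve_address(x, port)
  con <- client_connect(addr, timeout)
  on.exit(close(con))
  writeLines("status", con); flush(con)
  lines <- read_response(con)
  if (!length(lines) || lines[1L] != "ok") {
    return(structure(list(version = NA_character_, tile_size = NA_integer_,
                          step_size = NA_integer_,
                          sequence_count = NA_integer_,
                          total_bases = NA_real_, request_count = NA_real_,
                          uptime = NA_real_, ready = FALSE),
                     class = "server_status"))
  }
  kv <- strsplit(lines[-1L], ": ", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  structure(list(version = vals[["version"]],
                 tile_size = as.integer(vals[["tile_size"]]),
                 step_size = as.integer(vals[["step_size"]]),
                 sequence_count = as.integer(vals[["sequence_count"]]),
                 total_bases = as.numeric(vals[["total_bases"]]),
                 request_count = as.numeric(vals[["request_count"]]),
                 uptime = as.numeric(vals[["uptime"]]),
                 ready = identical(vals[["ready"]], "true")),
            class = "server_status")
}

#' @export
print.server_status <- function(x, ...) {
  cat(sprintf(
    "<server_status> %s: ready=%s, %s seq / %s bases, tile %s step %s, %s request(s), up %.1fs\n",
    if (is.na(x$version)) "?" else x$version, x$ready,
    x$sequence_count, format(x$total_bases, big.mark = ",", scientific = FALSE), x$tile_size,
    x$step_size, x$request_count,
    if (is.na(x$uptime)) 0 else x$uptime))
  invisible(x)
}

#' Wait until a server is ready (or a timeout elapses)
#'
#' Polls [status_server()] every 0.2 s.  Never raises: an unreachable
#' address simply keeps polling until the timeout.
#'
#' @inheritParams status_server
#' @param timeout Seconds to keep polling (> 0).
#' @return `"ready"` or `"timeout"`.
#' @export
wait_server <- function(x, port = NULL, timeout = 60) {
  stopifnot(timeout > 0)
  deadline <- Sys.time() + timeout
  repeat {
    st <- tryCatch(status_server(x, port, timeout = 1),
                   error = function(e) NULL)
    if (!is.null(st) && isTRUE(st$ready)) return("ready")
    if (Sys.time() >= deadline) return("timeout")
    Sys.sleep(0.2)
  }
}

#' Submit queries to a running server
#'
#' Streams each query over the socket and collects the PSL response; no
#' files are written on either side.  Results are identical, byte for
#' byte at the PSL level, to running [align()] in-process on the same
#' inputs.
#'
#' @inheritParams status_server
#' @param queries A list of [dna_record] objects.
#' @param params Optional [align_params]; `min_score`/`min_identity`
#'   are forwarded to the server (tile parameters must match the
#'   server's and are checked against its status).
#' @param as Result shape: `"query_results"` (default), `"psl"`
#'   (data.frame) or `"psl_text"`.
#' @param timeout Per-response read timeout in seconds.
#' @return Per `as`: a list of `query_result`, a PSL data.frame, or PSL
#'   text.
#' @export
query_server <- function(x, queries, port = NULL, params = NULL,
                         as = c("query_results", "psl", "psl_text"),
                         timeout = 300) {
  as <- match.arg(as)
  addr <- resolve_address(x, port)
  queries <- as_dna_records(queries)
  st <- status_server(x, port)
  if (!isTRUE(st$ready)) {
    stop(sprintf("server at %s:%d is not ready", addr$host, addr$port),
         call. = FALSE)
  }
  if (!is.null(params)) {
    params <- as_align_params(params)
    if (params$tile_size != st$tile_size ||
        params$step_size != st$step_size) {
      stop(sprintf(
        "parameter mismatch with server: tile_size %d vs %d, step_size %d vs %d",
        params$tile_size, st$tile_size, params$step_size, st$step_size),
        call. = FALSE)
    }
  }
  psl_lines <- character(0)
  if (length(queries)) {
    con <- client_connect(addr, timeout)
    on.exit(close(con))
    for (q in queries) {
      cmdline <- if (is.null(params)) {
        sprintf("query %s %d", q$name, q$length)
      } else {
        sprintf("query %s %d %d %s", q$name, q$length, params$min_score,
                format(params$min_identity, scientific = FALSE))
      }
      writeLines(c(cmdline, q$residues), con); flush(con)
      resp <- read_response(con)
      if (!length(resp)) {
        stop("protocol error: empty response from server", call. = FALSE)
      }
      if (!startsWith(resp[1L], "ok")) {
        stop(sprintf("server error for query '%s': %s", q$name,
                     sub("^err ", "", resp[1L])), call. = FALSE)
      }
      psl_lines <- c(psl_lines, resp[-1L])
    }
  }
  txt <- if (length(psl_lines)) {
    paste0(paste(psl_lines, collapse = "\n"), "\n")
  } else ""
  switch(as,
         psl_text = txt,
         psl = read_psl(text = txt),
         query_results = psl_to_query_results(read_psl(text = txt)))
}

#' Stop a server
#'
#' Owned handles carry the owner token and always succeed; unowned
#' (attached) handles are honoured only when the server was started
#' with `allow_remote_stop`.  Stopping an already-stopped server is an
#' idempotent success.
#'
#' @param handle A `server_handle`.
#' @return `TRUE`, invisibly.
#' @export
stop_server <- function(handle) {
  stopifnot(inherits(handle, "server_handle"))
  addr <- resolve_address(handle)
  con <- tryCatch(client_connect(addr, timeout = 5), error = function(e) NULL)
  if (is.null(con)) {
    reap_server(handle)
    return(invisible(TRUE))  # already stopped
  }
  writeLines(trimws(paste("quit", handle$token)), con); flush(con)
  resp <- read_response(con)
  close(con)
  if (length(resp) && startsWith(resp[1L], "err")) {
    stop(sub("^err ", "", resp[1L]), call. = FALSE)
  }
  reap_server(handle)
  invisible(TRUE)
}

reap_server <- function(handle, timeout = 5) {
  if (!isTRUE(handle$owned) || is.null(handle$job)) return(invisible())
  deadline <- Sys.time() + timeout
  repeat {
    res <- suppressWarnings(parallel::mccollect(handle$job, wait = FALSE))
    if (!is.null(res) || Sys.time() >= deadline) break
    Sys.sleep(0.05)
  }
  invisible()
}

#' Attach to an already-running server
#'
#' Probes the address: if a compatible server answers (tile and step
#' sizes matching `expected_params` when given), an unowned handle is
#' returned; if nothing is listening, `NULL` (so the caller may start
#' one); incompatible parameters raise a mismatch error naming the
#' fields.
#'
#' @inheritParams status_server
#' @param expected_params Optional [align_params] the server must match.
#' @return A `server_handle` with `owned = FALSE`, or `NULL`.
#' @export
attach_server <- function(x, port = NULL, expected_params = NULL) {
  addr <- resolve_address(x, port)
  st <- tryCatch(status_server(x, port), error = function(e) NULL)
  if (is.null(st)) return(NULL)
  if (!is.null(expected_params)) {
    expected_params <- as_align_params(expected_params)
    bad <- character(0)
    if (!is.na(st$tile_size) && st$tile_size != expected_params$tile_size) {
      bad <- c(bad, sprintf("tile_size (server %d, expected %d)",
                            st$tile_size, expected_params$tile_size))
    }
    if (!is.na(st$step_size) && st$step_size != expected_params$step_size) {
      bad <- c(bad, sprintf("step_size (server %d, expected %d)",
                            st$step_size, expected_params$step_size))
    }
    if (length(bad)) {
      stop("server parameter mismatch: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  structure(list(host = addr$host, port = addr$port, owned = FALSE,
                 pid = NA_integer_, token = "", job = NULL, config = NULL),
            class = "server_handle")
}
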