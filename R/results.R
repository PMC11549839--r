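# QueryResult / Hit / HSP ----------------------------------------------------
#
# Per-query -> per-target -> per-alignment hierarchy over PSL records, in
# the spirit of search-result object models common in sequence analysis:
# a query_result holds one hit per target, each hit holds >= 1 HSPs.
# Ordering is deterministic: results follow query first-appearance order,
# hits are sorted by descending best-HSP score (ties by target_id), HSPs
# within a hit by descending score.

hsp_score <- function(records) {
  records$matches - records$misMatches - records$nCount
}

new_hsp <- function(rec) {
  sizes <- psl_list_parse(rec$blockSizes)
  qs <- psl_list_parse(rec$qStarts)
  ts <- psl_list_parse(rec$tStarts)
  structure(
    list(score = hsp_score(rec),
         identity = percent_identity(rec),
         strand = rec$strand,
         q_span = c(start = rec$qStart, end = rec$qEnd),
         t_span = c(start = rec$tStart, end = rec$tEnd),
         blocks = cbind(q_start = qs, t_start = ts, size = sizes),
         record = rec),
    class = "blat_hsp")
}

#' Group PSL records into QueryResult objects
#'
#' Groups validated PSL records by query name, then by target name; every
#' record becomes one HSP.  Grouping conserves records: the total number
#' of HSPs across all results equals `nrow(records)`.
#'
#' @param records A PSL data.frame; records failing [validate_psl()] are
#'   rejected.
#' @return A list of `query_result` objects (classes `query_result`,
#'   `blat_hit`, `blat_hsp`), in query first-appearance order.
#' @export
psl_to_query_results <- function(records) {
  stopifnot(is.data.frame(records))
  problems <- validate_psl(records)
  bad <- which(lengths(problems) > 0L)
  if (length(bad)) {
    stop(sprintf("invalid PSL record %d: %s", bad[1L],
                 paste(problems[[bad[1L]]], collapse = "; ")), call. = FALSE)
  }
  if (!nrow(records)) return(list())
  qorder <- unique(records$qName)
  lapply(qorder, function(q) {
    sub <- records[records$qName == q, , drop = FALSE]
    hits <- lapply(unique(sub$tName), function(t) {
      hs <- sub[sub$tName == t, , drop = FALSE]
      hsps <- lapply(seq_len(nrow(hs)), function(i) new_hsp(hs[i, ]))
      hsps <- hsps[order(-vapply(hsps, `[[`, 0, "score"))]
      structure(list(target_id = t, hsps = hsps), class = "blat_hit")
    })
    best <- vapply(hits, function(h) h$hsps[[1L]]$score, 0)
    tids <- vapply(hits, `[[`, "", "target_id")
    hits <- hits[order(-best, tids)]
    structure(list(query_id = q, hits = hits), class = "query_result")
  })
}

#' Flatten QueryResult objects back to PSL records
#'
#' @param results A list of `query_result` objects.
#' @return A PSL data.frame (record order follows result/hit/HSP order).
#' @export
query_results_to_psl <- function(results) {
  rows <- unlist(lapply(results, function(qr) {
    lapply(qr$hits, function(h) lapply(h$hsps, `[[`, "record"))
  }), recursive = FALSE)
  rows <- unlist(rows, recursive = FALSE)
  if (!length(rows)) return(psl_empty())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.query_result <- function(x, ...) {
  n_hsp <- sum(vapply(x$hits, function(h) length(h$hsps), 0L))
  cat(sprintf("<query_result> %s: %d hit(s), %d HSP(s)\n",
              x$query_id, length(x$hits), n_hsp))
  for (h in x$hits) {
    top <- h$hsps[[1L]]
    cat(sprintf("  %s: %d HSP(s), best score %g (%.1f%% id, %s, t:%g-%g)\n",
                h$target_id, length(h$hsps), top$score, top$identity,
                top$strand, top$t_span[["start"]], top$t_span[["end"]]))
  }
  invisible(x)
}

#' @export
print.blat_hit <- function(x, ...) {
  cat(sprintf("<blat_hit> %s: %d HSP(s)\n", x$target_id, length(x$hsps)))
  invisible(x)
}

#' @export
print.blat_hsp <- function(x, ...) {
  cat(sprintf(
    "<blat_hsp> score %g, %.1f%% identity, strand %s, q:%g-%g, t:%g-%g, %d block(s)\n",
    x$score, x$identity, x$strand, x$q_span[["start"]], x$q_span[["end"]],
    x$t_span[["start"]], x$t_span[["end"]], nrow(x$blocks)))
  invisible(x)
}
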