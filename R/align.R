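# Seed extension and alignment ----------------------------------------------

# Prepared per-target residue context: uppercase raw bytes per target.
# Alignment compares bases case-insensitively (soft-masked lowercase
# aligns like its uppercase form); N never matches.
target_context <- function(archive) {
  if (inherits(archive, "target_context")) return(archive)
  recs <- decode_twobit(archive)
  structure(
    list(names = names(recs),
         lengths = vapply(recs, function(r) as.numeric(r$length), 0),
         raw = lapply(recs, function(r) charToRaw(toupper(r$residues)))),
    class = "target_context")
}

RAW_N <- charToRaw("N")

# x-drop extension of the score path v (+1 match / -1 mismatch-or-N) away
# from a committed core.  Returns how many positions to take: scanning
# stops once the score falls more than xdrop below the running maximum,
# and the block is trimmed back to the maximum.  At equal score the
# shorter extension wins (ties broken toward the core), so the final
# segment is the unique shortest maximal-scoring one.
xdrop_take <- function(v, xdrop) {
  if (!length(v)) return(0L)
  s <- cumsum(v)
  cm <- cummax(s)
  stop_at <- which(cm - s > xdrop)
  limit <- if (length(stop_at)) stop_at[1L] - 1L else length(s)
  if (!limit) return(0L)
  s <- s[seq_len(limit)]
  best <- max(s)
  if (best <= 0) return(0L)
  min(which(s == best))
}

# per-block base accounting against the oriented query / target bytes
block_counts <- function(qr, tr, qs, ts, size) {
  qb <- qr[(qs + 1):(qs + size)]
  tb <- tr[(ts + 1):(ts + size)]
  is_n <- qb == RAW_N | tb == RAW_N
  eq <- qb == tb & !is_n
  c(matches = sum(eq), ncount = sum(is_n),
    mismatches = size - sum(eq) - sum(is_n))
}

#' Extend a seed cluster into a PSL record
#'
#' Each diagonal of the cluster is extended ungapped in both directions
#' under an x-drop rule (+`match_score` per matching base,
#' `mismatch_cost` per mismatching or N base; extension stops when the
#' running score falls `match_score * tile_size` below its maximum, and
#' the block is trimmed back to the maximum).  Same-diagonal seed runs
#' are merged before extension; the per-diagonal blocks are then chained
#' in increasing query and target order, gaps are counted into the
#' insert fields, and a record is emitted only if the alignment score
#' reaches `min_score` and the percent identity reaches `min_identity`.
#'
#' @param cluster A `seed_cluster` from [cluster_hits()].
#' @param query The [dna_record] the cluster's seeds came from.
#' @param archive The target .2bit archive (bytes, path, parsed archive,
#'   or a prepared internal context).
#' @param params An [align_params] object.
#' @return A one-row PSL data.frame, or `NULL` when no extension meets
#'   the thresholds.
#' @export
extend_cluster <- function(cluster, query, archive, params = align_params()) {
  params <- as_align_params(params)
  ctx <- target_context(archive)
  ti <- match(cluster$target, ctx$names)
  if (is.na(ti)) {
    stop(sprintf("cluster target '%s' not present in archive",
                 cluster$target), call. = FALSE)
  }
  oriented <- if (cluster$strand == "-") reverse_complement(query$residues)
              else query$residues
  qr <- charToRaw(toupper(oriented))
  tr <- ctx$raw[[ti]]
  Q <- length(qr); Tn <- length(tr)
  k <- params$tile_size
  xdrop <- params$match_score * k

  # one ungapped block per distinct diagonal
  blocks <- lapply(split(seq_len(nrow(cluster$hits)),
                         cluster$hits$diagonal),
                   function(ii) {
    d <- round(cluster$hits$diagonal[ii[1L]])
    qoffs <- cluster$hits$query_offset[ii]
    q0 <- min(qoffs); q1 <- max(qoffs) + k       # seed-covered core [q0,q1)
    lo <- max(0, -d); hi <- min(Q, Tn - d)       # admissible query range
    vmatch <- function(qa, qb) {                 # score path over [qa,qb)
      if (qb <= qa) return(integer(0))
      qi <- (qa + 1):qb
      m <- qr[qi] == tr[qi + d] & qr[qi] != RAW_N & tr[qi + d] != RAW_N
      ifelse(m, params$match_score, params$mismatch_cost)
    }
    right <- xdrop_take(vmatch(q1, hi), xdrop)
    left <- xdrop_take(rev(vmatch(lo, q0)), xdrop)
    qs <- q0 - left; qe <- q1 + right
    cnt <- block_counts(qr, tr, qs, qs + d, qe - qs)
    list(d = d, qs = qs, qe = qe,
         score = params$match_score * cnt[["matches"]] +
                 params$mismatch_cost * (cnt[["mismatches"]] +
                                         cnt[["ncount"]]))
  })

  # chain blocks: increasing, non-overlapping in both query and target;
  # simple DP maximising total block score (unit cost per gap opened)
  ord <- order(vapply(blocks, `[[`, 0, "qs"),
               vapply(blocks, `[[`, 0, "d"))
  blocks <- blocks[ord]
  n <- length(blocks)
  best <- numeric(n); prev <- integer(n)
  for (i in seq_len(n)) {
    b <- blocks[[i]]
    best[i] <- b$score; prev[i] <- 0L
    for (j in seq_len(i - 1L)) {
      a <- blocks[[j]]
      if (a$qe <= b$qs && a$qe + a$d <= b$qs + b$d) {
        cand <- best[j] + b$score - 1L
        if (cand > best[i]) { best[i] <- cand; prev[i] <- j }
      }
    }
  }
  end <- which.max(best)
  chain <- integer(0)
  while (end) { chain <- c(end, chain); end <- prev[end] }
  blocks <- blocks[chain]

  qs <- vapply(blocks, `[[`, 0, "qs")
  qe <- vapply(blocks, `[[`, 0, "qe")
  d <- vapply(blocks, `[[`, 0, "d")
  sizes <- qe - qs
  ts <- qs + d
  counts <- rowSums(vapply(seq_along(blocks), function(i) {
    block_counts(qr, tr, qs[i], ts[i], sizes[i])
  }, c(matches = 0, ncount = 0, mismatches = 0)))
  score <- params$match_score * counts[["matches"]] +
           params$mismatch_cost * (counts[["mismatches"]] +
                                   counts[["ncount"]])
  denom <- counts[["matches"]] + counts[["mismatches"]]
  identity <- if (denom > 0) 100 * counts[["matches"]] / denom else 0
  if (score < params$min_score || identity < params$min_identity) {
    return(NULL)
  }

  qgaps <- if (length(qs) > 1L) utils::tail(qs, -1L) - utils::head(qe, -1L)
           else numeric(0)
  tgaps <- if (length(ts) > 1L) {
    utils::tail(ts, -1L) - utils::head(ts + sizes, -1L)
  } else numeric(0)
  qlo <- qs[1L]; qhi <- qe[length(qe)]
  df <- data.frame(
    matches = counts[["matches"]], misMatches = counts[["mismatches"]],
    repMatches = 0, nCount = counts[["ncount"]],
    qNumInsert = as.numeric(sum(qgaps > 0)),
    qBaseInsert = as.numeric(sum(qgaps)),
    tNumInsert = as.numeric(sum(tgaps > 0)),
    tBaseInsert = as.numeric(sum(tgaps)),
    strand = cluster$strand, qName = query$name, qSize = as.numeric(Q),
    qStart = as.numeric(if (cluster$strand == "-") Q - qhi else qlo),
    qEnd = as.numeric(if (cluster$strand == "-") Q - qlo else qhi),
    tName = cluster$target, tSize = ctx$lengths[[ti]],
    tStart = ts[1L], tEnd = ts[length(ts)] + sizes[length(sizes)],
    blockCount = as.numeric(length(sizes)),
    blockSizes = psl_list_field(sizes),
    qStarts = psl_list_field(qs), tStarts = psl_list_field(ts),
    stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

#' Align queries against an indexed target archive
#'
#' The full seed-and-extend pipeline: per query, find seed hits on both
#' strands ([find_seed_hits()]), cluster them by diagonal band
#' ([cluster_hits()]), extend each cluster ([extend_cluster()]), and
#' keep the records passing the score and identity thresholds.  Output
#' order is deterministic: query input order, then descending score,
#' then `(tName, tStart)`.
#'
#' @param queries A list of [dna_record] objects (or a FASTA path).
#' @param index A `tile_index` built over the same targets as `archive`.
#' @param archive The target .2bit archive (bytes, path, or parsed).
#' @param params An [align_params] object; defaults to the index's own
#'   parameters.  `tile_size`/`step_size` must match the index.
#' @return A PSL data.frame.
#' @export
align <- function(queries, index, archive, params = index$params) {
  stopifnot(inherits(index, "tile_index"))
  params <- as_align_params(params)
  if (params$tile_size != index$params$tile_size ||
      params$step_size != index$params$step_size) {
    stop("params tile_size/step_size disagree with the index", call. = FALSE)
  }
  if (is.character(queries) && length(queries) == 1L &&
      file.exists(queries)) {
    queries <- read_fasta(file = queries)
  }
  queries <- as_dna_records(queries)
  ctx <- target_context(archive)
  if (!identical(unname(ctx$names), unname(index$target_names)) ||
      !identical(unname(ctx$lengths), unname(index$target_lengths))) {
    stop("index and archive were not built from the same targets",
         call. = FALSE)
  }
  per_query <- lapply(queries, function(q) {
    if (q$length < index$params$tile_size) return(psl_empty())
    hits <- find_seed_hits(index, q)
    clusters <- cluster_hits(hits, params)
    recs <- lapply(clusters, extend_cluster, query = q, archive = ctx,
                   params = params)
    recs <- recs[!vapply(recs, is.null, TRUE)]
    if (!length(recs)) return(psl_empty())
    df <- do.call(rbind, recs)
    df[order(-hsp_score(df), df$tName, df$tStart), , drop = FALSE]
  })
  out <- do.call(rbind, c(list(psl_empty()), per_query))
  rownames(out) <- NULL
  out
}
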