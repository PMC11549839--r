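# Tile index -----------------------------------------------------------------

#' Encode a k-mer as a 2-bit tile code
#'
#' Uses the same base code table as the 2bit codec (T=0, C=1, A=2, G=3),
#' first base in the most significant position, case-insensitive.  A
#' k-mer containing `N` (or any base outside ACGT) is untileable and
#' yields `NA`.
#'
#' @param kmer Character scalar of length `tile_size`.
#' @param tile_size Expected k-mer length (1..18).
#' @return Numeric code in `[0, 4^tile_size)`, or `NA` if untileable.
#' @examples
#' tile_encode("TT", 2)  # 0
#' tile_encode("TC", 2)  # 1
#' @export
tile_encode <- function(kmer, tile_size = nchar(kmer)) {
  .tb_init()
  stopifnot(is.character(kmer), length(kmer) == 1L)
  if (nchar(kmer) != tile_size) {
    stop(sprintf("k-mer length %d does not match tile_size %d",
                 nchar(kmer), as.integer(tile_size)), call. = FALSE)
  }
  codes <- .tb$tile_code[utf8ToInt(kmer) + 1L]
  if (anyNA(codes)) return(NA_real_)
  sum(codes * 4^(rev(seq_along(codes)) - 1))
}

# All rolling tile codes of a sequence at query-side resolution (step 1).
# Returns a numeric vector of length L - k + 1 (empty when L < k); windows
# containing N are NA.  Position i (1-based) is the tile starting at
# 0-based offset i - 1.
rolling_tile_codes <- function(residues, k) {
  .tb_init()
  codes <- .tb$tile_code[utf8ToInt(residues) + 1L]
  L <- length(codes)
  if (L < k) return(numeric(0))
  n <- L - k + 1L
  acc <- numeric(n)
  for (j in seq_len(k)) acc <- acc * 4 + codes[j:(n + j - 1L)]
  acc
}

#' Build a tile index over target sequences
#'
#' Samples tiles from each target at offsets `0, step, 2*step, ...`,
#' skipping tiles that span an `N`.  Tile codes occurring at more than
#' `overused_threshold` positions are dropped from the lookup and
#' recorded in `dropped_tiles` (this is the classic defence against
#' low-complexity and repeat tiles flooding the seed stage).
#'
#' @param targets A list of [dna_record] objects (or anything
#'   [as_dna_records()] accepts), or a .2bit archive / path /
#'   `twobit_archive`, in which case it is decoded first.
#' @param params An [align_params] object (or a list of overrides).
#' @return A `tile_index` object.
#' @export
build_tile_index <- function(targets, params = align_params()) {
  params <- as_align_params(params)
  if (is.raw(targets) || inherits(targets, "twobit_archive") ||
      (is.character(targets) && length(targets) == 1L &&
       file.exists(targets))) {
    targets <- decode_twobit(targets)
  }
  targets <- as_dna_records(targets)
  if (!length(targets)) stop("no target sequences to index", call. = FALSE)
  check_unique_names(targets, "targets")
  k <- params$tile_size
  step <- params$step_size
  pieces <- lapply(seq_along(targets), function(ti) {
    r <- targets[[ti]]
    if (r$length < k) return(NULL)
    all_codes <- rolling_tile_codes(r$residues, k)
    offsets <- seq.int(0L, r$length - k, by = step)
    code <- all_codes[offsets + 1L]
    keep <- !is.na(code)
    if (!any(keep)) return(NULL)
    data.table::data.table(code = code[keep], target_id = ti,
                           target_offset = as.numeric(offsets[keep]))
  })
  dt <- data.table::rbindlist(pieces)
  dropped <- numeric(0)
  if (nrow(dt)) {
    counts <- dt[, .N, by = "code"]
    dropped <- counts$code[counts$N > params$overused_threshold]
    if (length(dropped)) dt <- dt[!dt$code %in% dropped, ]
    data.table::setkeyv(dt, "code")
  }
  structure(
    list(params = params,
         tiles = dt,
         target_names = vapply(targets, `[[`, "", "name"),
         target_lengths = vapply(targets, function(r) as.numeric(r$length), 0),
         dropped_tiles = sort(dropped)),
    class = "tile_index")
}

#' @export
print.tile_index <- function(x, ...) {
  cat(sprintf(
    "<tile_index> %d target(s), %s bp; tile %d step %d; %s tile position(s), %d overused code(s) dropped\n",
    length(x$target_names), format(sum(x$target_lengths), big.mark = ",", scientific = FALSE),
    x$params$tile_size, x$params$step_size,
    format(nrow(x$tiles), big.mark = ","), length(x$dropped_tiles)))
  invisible(x)
}

#' Look up the indexed positions of a tile code
#'
#' @param index A `tile_index`.
#' @param code Numeric tile code (e.g. from [tile_encode()]).
#' @return A data.frame with columns `target`, `target_offset` (0-based);
#'   empty for unindexed, untileable (`NA`) or dropped codes.
#' @export
tile_positions <- function(index, code) {
  stopifnot(inherits(index, "tile_index"))
  if (length(code) != 1L || is.na(code)) {
    hits <- index$tiles[0L, ]
  } else {
    lookup <- data.table::data.table(code = as.numeric(code))
    hits <- index$tiles[lookup, nomatch = NULL, on = "code"]
  }
  data.frame(target = index$target_names[hits$target_id],
             target_offset = hits$target_offset,
             stringsAsFactors = FALSE)
}

#' Find seed hits for a query against a tile index
#'
#' Scans every query offset (step 1) on both strands; the minus strand
#' scans the reverse complement of the query.  Each index lookup hit
#' yields one seed with its diagonal (`target_offset - query_offset`).
#' Query offsets for strand `-` are in reverse-complement query
#' coordinates.
#'
#' @param index A `tile_index`.
#' @param query A [dna_record].
#' @return A data.frame of seeds: `strand`, `query_offset`, `target`,
#'   `target_offset`, `diagonal` (all offsets 0-based).  Empty when the
#'   query is shorter than the tile size.
#' @export
find_seed_hits <- function(index, query) {
  stopifnot(inherits(index, "tile_index"), inherits(query, "dna_record"))
  dt <- seed_hits_dt(index, query$residues)
  data.frame(strand = dt$strand, query_offset = dt$query_offset,
             target = index$target_names[dt$target_id],
             target_offset = dt$target_offset, diagonal = dt$diagonal,
             stringsAsFactors = FALSE)
}

# internal: seeds as a data.table keeping integer target ids
seed_hits_dt <- function(index, residues) {
  k <- index$params$tile_size
  one_strand <- function(res, strand) {
    codes <- rolling_tile_codes(res, k)
    keep <- which(!is.na(codes))
    if (!length(keep)) {
      return(data.table::data.table(strand = character(0),
                                    query_offset = numeric(0),
                                    target_id = integer(0),
                                    target_offset = numeric(0)))
    }
    q <- data.table::data.table(code = codes[keep],
                                query_offset = as.numeric(keep - 1L))
    j <- index$tiles[q, nomatch = NULL, on = "code"]
    data.table::data.table(strand = rep(strand, nrow(j)),
                           query_offset = j$query_offset,
                           target_id = j$target_id,
                           target_offset = j$target_offset)
  }
  dt <- data.table::rbindlist(list(
    one_strand(residues, "+"),
    one_strand(reverse_complement(residues), "-")))
  dt$diagonal <- dt$target_offset - dt$query_offset
  dt
}

#' Cluster seed hits into diagonal bands
#'
#' Groups seeds by `(strand, target)`, then splits each group into
#' single-linkage diagonal bands: consecutive diagonals further apart
#' than `max_gap` start a new cluster.  Clusters with fewer than
#' `min_seeds` hits are discarded.
#'
#' @param hits Seed hits from [find_seed_hits()].
#' @param params An [align_params] object.
#' @return A list of `seed_cluster` objects, each with fields `strand`,
#'   `target`, `hits` (the member seeds), `q_span` and `t_span`.
#' @export
cluster_hits <- function(hits, params = align_params()) {
  params <- as_align_params(params)
  stopifnot(is.data.frame(hits))
  if (!nrow(hits)) return(list())
  k <- params$tile_size
  hits <- hits[order(hits$strand, hits$target, hits$diagonal,
                     hits$query_offset), , drop = FALSE]
  key <- paste(hits$strand, hits$target, sep = "\r")
  out <- list()
  for (grp in split(seq_len(nrow(hits)), key)) {
    d <- hits$diagonal[grp]
    band <- cumsum(c(1, diff(d) > params$max_gap))
    for (idx in split(grp, band)) {
      if (length(idx) < params$min_seeds) next
      sub <- hits[idx, , drop = FALSE]
      out[[length(out) + 1L]] <- structure(
        list(strand = sub$strand[1L], target = sub$target[1L],
             hits = sub,
             q_span = c(min(sub$query_offset), max(sub$query_offset) + k),
             t_span = c(min(sub$target_offset),
                        max(sub$target_offset) + k)),
        class = "seed_cluster")
    }
  }
  # deterministic order: strand, target, then leftmost target offset
  ord <- order(vapply(out, `[[`, "", "strand"),
               vapply(out, `[[`, "", "target"),
               vapply(out, function(cl) cl$t_span[1L], 0))
  out[ord]
}

#' @export
print.seed_cluster <- function(x, ...) {
  cat(sprintf("<seed_cluster> %s%s: %d seed(s), q:[%g,%g) t:[%g,%g)\n",
              x$target, x$strand, nrow(x$hits), x$q_span[1L], x$q_span[2L],
              x$t_span[1L], x$t_span[2L]))
  invisible(x)
}
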