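#' Alignment parameters
#'
#' Tunable parameters of the seed-and-extend search.  Defaults mirror
#' classic BLAT DNA behaviour: 11-base tiles sampled from the target at a
#' step equal to the tile size, +1/-1 ungapped extension, a minimum score
#' of 30 and a minimum identity of 90 percent.
#'
#' @param tile_size Tile (k-mer) length in bases, 1..18.
#' @param step_size Spacing of tiles on the target, >= 1 (defaults to
#'   `tile_size`; may exceed it).
#' @param overused_threshold Tiles occurring at more than this many target
#'   positions are dropped from the index.
#' @param min_seeds Minimum seed hits for a diagonal cluster to be
#'   extended.
#' @param max_gap Diagonal-band window, in bases, for clustering seed
#'   hits.
#' @param match_score,mismatch_cost Per-base scores for the ungapped
#'   extension (`match_score > 0`, `mismatch_cost < 0`).
#' @param min_score Minimum alignment score
#'   (`match_score*matches + mismatch_cost*(misMatches + nCount)`) for a
#'   record to be emitted.
#' @param min_identity Minimum percent identity (0..100) for a record to
#'   be emitted.
#' @return An `align_params` object (a validated list).
#' @examples
#' align_params(tile_size = 8, min_score = 20)
#' @export
align_params <- function(tile_size = 11L, step_size = tile_size,
                         overused_threshold = 1024L, min_seeds = 2L,
                         max_gap = 100L, match_score = 1L,
                         mismatch_cost = -1L, min_score = 30L,
                         min_identity = 90) {
  p <- list(tile_size = as.integer(tile_size),
            step_size = as.integer(step_size),
            overused_threshold = as.integer(overused_threshold),
            min_seeds = as.integer(min_seeds),
            max_gap = as.integer(max_gap),
            match_score = as.integer(match_score),
            mismatch_cost = as.integer(mismatch_cost),
            min_score = as.integer(min_score),
            min_identity = as.numeric(min_identity))
  if (is.na(p$tile_size) || p$tile_size < 1L || p$tile_size > 18L) {
    stop("tile_size must be in 1..18", call. = FALSE)
  }
  if (is.na(p$step_size) || p$step_size < 1L) {
    stop("step_size must be >= 1", call. = FALSE)
  }
  if (p$overused_threshold < 1L || p$min_seeds < 1L || p$max_gap < 1L) {
    stop("overused_threshold, min_seeds and max_gap must be positive",
         call. = FALSE)
  }
  if (p$match_score < 1L) stop("match_score must be positive", call. = FALSE)
  if (p$mismatch_cost >= 0L) stop("mismatch_cost must be negative",
                                  call. = FALSE)
  if (is.na(p$min_identity) || p$min_identity < 0 || p$min_identity > 100) {
    stop("min_identity must be in [0, 100]", call. = FALSE)
  }
  structure(p, class = "align_params")
}

#' @export
print.align_params <- function(x, ...) {
  cat(sprintf(
    paste0("<align_params> tile %d, step %d, overused > %d, min_seeds %d,\n",
           "  max_gap %d, scores %+d/%d, min_score %d, min_identity %.1f%%\n"),
    x$tile_size, x$step_size, x$overused_threshold, x$min_seeds, x$max_gap,
    x$match_score, x$mismatch_cost, x$min_score, x$min_identity))
  invisible(x)
}

as_align_params <- function(x) {
  if (inherits(x, "align_params")) return(x)
  if (is.null(x)) return(align_params())
  if (is.list(x)) return(do.call(align_params, x))
  stop("expected align_params, a list of parameter overrides, or NULL",
       call. = FALSE)
}
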