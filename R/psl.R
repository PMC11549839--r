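# PSL records ----------------------------------------------------------------
#
# A PSL collection is a data.frame with the 21 standard columns; the three
# list fields (blockSizes, qStarts, tStarts) are comma-terminated strings,
# as in PSL text.  Coordinates are 0-based half-open.  For '-' strand
# records qStarts are in reverse-complemented query coordinates while
# qStart/qEnd are in plus-strand query coordinates (the standard
# convention).

PSL_COLUMNS <- c("matches", "misMatches", "repMatches", "nCount",
                 "qNumInsert", "qBaseInsert", "tNumInsert", "tBaseInsert",
                 "strand", "qName", "qSize", "qStart", "qEnd",
                 "tName", "tSize", "tStart", "tEnd",
                 "blockCount", "blockSizes", "qStarts", "tStarts")

PSL_NUMERIC <- setdiff(PSL_COLUMNS,
                       c("strand", "qName", "tName",
                         "blockSizes", "qStarts", "tStarts"))

#' An empty PSL collection
#'
#' @return A zero-row data.frame with the 21 standard PSL columns.
#' @export
psl_empty <- function() {
  df <- as.data.frame(
    c(lapply(stats::setNames(PSL_NUMERIC, PSL_NUMERIC),
             function(.) numeric(0)),
      list(strand = character(0), qName = character(0),
           tName = character(0), blockSizes = character(0),
           qStarts = character(0), tStarts = character(0))),
    stringsAsFactors = FALSE)
  df[, PSL_COLUMNS]
}

# comma-terminated list field <-> numeric vector
psl_list_field <- function(x) paste0(paste(format(x, scientific = FALSE,
                                                  trim = TRUE),
                                           collapse = ","), ",")
psl_list_parse <- function(s) {
  if (!nzchar(s)) return(numeric(0))
  as.numeric(strsplit(sub(",$", "", s), ",", fixed = TRUE)[[1]])
}

PSL_HEADER <- c(
  "psLayout version 3",
  "",
  paste0("match\tmis- \trep. \tN's\tQ gap\tQ gap\tT gap\tT gap\tstrand\t",
         "Q        \tQ   \tQ    \tQ  \tT        \tT   \tT    \tT  \t",
         "block\tblockSizes \tqStarts\t tStarts"),
  paste0("     \tmatch\tmatch\t   \tcount\tbases\tcount\tbases\t      \t",
         "name     \tsize\tstart\tend\tname     \tsize\tstart\tend\tcount"),
  strrep("-", 159))

#' Write PSL records as text
#'
#' @param records A PSL data.frame (see [psl_empty()] for the columns).
#' @param file Optional output path; when `NULL` the text is returned.
#' @param header Emit the 5-line psLayout header first.
#' @return PSL text (invisibly when written to `file`).
#' @export
write_psl <- function(records, file = NULL, header = FALSE) {
  stopifnot(is.data.frame(records))
  missing <- setdiff(PSL_COLUMNS, names(records))
  if (length(missing)) {
    stop("PSL data.frame is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  lines <- character(0)
  if (nrow(records)) {
    cells <- vapply(PSL_COLUMNS, function(col) {
      v <- records[[col]]
      if (is.numeric(v)) format(v, scientific = FALSE, trim = TRUE)
      else as.character(v)
    }, character(nrow(records)))
    if (nrow(records) == 1L) cells <- matrix(cells, nrow = 1L)
    lines <- apply(cells, 1L, paste, collapse = "\t")
  }
  if (header) lines <- c(PSL_HEADER, lines)
  txt <- if (length(lines)) paste0(paste(lines, collapse = "\n"), "\n") else ""
  if (is.null(file)) return(txt)
  writeLines(txt, file, sep = "")
  invisible(txt)
}

#' Read PSL text into records
#'
#' Accepts headerless PSL or PSL with the standard 5-line psLayout header.
#' List fields are accepted with or without the trailing comma (and
#' written back with it).
#'
#' @param file Path to a PSL file, or a connection.
#' @param text PSL text given directly instead of `file`.
#' @return A PSL data.frame.
#' @export
read_psl <- function(file = NULL, text = NULL) {
  if (is.null(file) == is.null(text)) {
    stop("supply exactly one of 'file' or 'text'", call. = FALSE)
  }
  lines <- if (is.null(text)) readLines(file, warn = FALSE)
           else strsplit(text, "\n", fixed = TRUE)[[1]]
  offset <- 0L
  if (length(lines) && startsWith(lines[1L], "psLayout")) {
    if (length(lines) < 5L) {
      stop("PSL parse error: truncated psLayout header", call. = FALSE)
    }
    lines <- lines[-(1:5)]
    offset <- 5L
  }
  keep <- nzchar(lines)
  lineno <- which(keep) + offset
  lines <- lines[keep]
  if (!length(lines)) return(psl_empty())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 21L)) {
    i <- which(nf != 21L)[1L]
    stop(sprintf("PSL parse error at line %d: expected 21 columns, found %d",
                 lineno[i], nf[i]), call. = FALSE)
  }
  m <- do.call(rbind, fields)
  colnames(m) <- PSL_COLUMNS
  df <- as.data.frame(m, stringsAsFactors = FALSE)
  for (col in PSL_NUMERIC) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1L]
      stop(sprintf("PSL parse error at line %d: non-numeric '%s' in column %s",
                   lineno[i], df[[col]][i], col), call. = FALSE)
    }
    df[[col]] <- v
  }
  for (col in c("blockSizes", "qStarts", "tStarts")) {
    n <- vapply(df[[col]], function(s) length(psl_list_parse(s)), 0L,
                USE.NAMES = FALSE)
    # normalise to the trailing-comma dialect
    df[[col]] <- vapply(df[[col]],
                        function(s) psl_list_field(psl_list_parse(s)), "",
                        USE.NAMES = FALSE)
    if (any(n != df$blockCount)) {
      i <- which(n != df$blockCount)[1L]
      stop(sprintf(
        "PSL parse error at line %d: blockCount %g but %s lists %d block(s)",
        lineno[i], df$blockCount[i], col, n[i]), call. = FALSE)
    }
  }
  rownames(df) <- NULL
  df
}

#' Validate PSL records against the format's arithmetic invariants
#'
#' Checks, per record: the block-sum identity
#' `matches + misMatches + repMatches + nCount == sum(blockSizes)`;
#' span bounds `0 <= qStart < qEnd <= qSize` (and likewise for the
#' target); agreement of `blockCount` with the three list fields; strict
#' monotonicity / non-overlap of blocks in both query and target; and
#' consistency of the spans with the block lists under the strand
#' convention.
#'
#' @param records A PSL data.frame.
#' @return A list with one character vector of failure reasons per record
#'   (empty vector = pass).  Use [psl_valid()] for a logical summary.
#' @export
validate_psl <- function(records) {
  stopifnot(is.data.frame(records))
  lapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    reasons <- character(0)
    sizes <- psl_list_parse(r$blockSizes)
    qs <- psl_list_parse(r$qStarts)
    ts <- psl_list_parse(r$tStarts)
    if (!(r$strand %in% c("+", "-"))) {
      reasons <- c(reasons, sprintf("strand '%s' is not + or -", r$strand))
    }
    if (r$blockCount != length(sizes) || r$blockCount != length(qs) ||
        r$blockCount != length(ts)) {
      reasons <- c(reasons, sprintf(
        "blockCount %g disagrees with list lengths (%d,%d,%d)",
        r$blockCount, length(sizes), length(qs), length(ts)))
    }
    total <- r$matches + r$misMatches + r$repMatches + r$nCount
    if (total != sum(sizes)) {
      reasons <- c(reasons, sprintf(
        "matches+misMatches+repMatches+nCount = %g but sum(blockSizes) = %g",
        total, sum(sizes)))
    }
    if (!(r$qStart >= 0 && r$qStart < r$qEnd && r$qEnd <= r$qSize)) {
      reasons <- c(reasons, sprintf("query span [%g,%g) invalid for qSize %g",
                                    r$qStart, r$qEnd, r$qSize))
    }
    if (!(r$tStart >= 0 && r$tStart < r$tEnd && r$tEnd <= r$tSize)) {
      reasons <- c(reasons, sprintf("target span [%g,%g) invalid for tSize %g",
                                    r$tStart, r$tEnd, r$tSize))
    }
    if (length(sizes) && length(sizes) == length(qs) &&
        length(sizes) == length(ts)) {
      if (any(sizes < 1)) reasons <- c(reasons, "zero-size block")
      if (length(sizes) > 1L) {
        dq <- utils::head(qs + sizes, -1L) > utils::tail(qs, -1L)
        dt <- utils::head(ts + sizes, -1L) > utils::tail(ts, -1L)
        if (any(dq)) reasons <- c(reasons, "blocks overlap or regress in query")
        if (any(dt)) reasons <- c(reasons, "blocks overlap or regress in target")
      }
      if (ts[1L] != r$tStart ||
          ts[length(ts)] + sizes[length(sizes)] != r$tEnd) {
        reasons <- c(reasons, "tStart/tEnd disagree with block list")
      }
      qlo <- qs[1L]; qhi <- qs[length(qs)] + sizes[length(sizes)]
      span_ok <- if (identical(r$strand, "-")) {
        r$qStart == r$qSize - qhi && r$qEnd == r$qSize - qlo
      } else {
        r$qStart == qlo && r$qEnd == qhi
      }
      if (!span_ok) {
        reasons <- c(reasons,
                     "qStart/qEnd disagree with block list under strand convention")
      }
    }
    reasons
  })
}

#' @rdname validate_psl
#' @return `psl_valid()`: logical vector, one element per record.
#' @export
psl_valid <- function(records) {
  lengths(validate_psl(records)) == 0L
}

#' Percent identity of PSL records
#'
#' `100 * matches / (matches + misMatches)`, reported to 0.1.  `N` bases
#' (the `nCount` field) are excluded from both numerator and denominator.
#'
#' @param records A PSL data.frame.
#' @return Numeric vector of percentages; `NA` where no non-N bases are
#'   aligned.
#' @export
percent_identity <- function(records) {
  denom <- records$matches + records$misMatches
  out <- ifelse(denom > 0, round(100 * records$matches / denom, 1), NA_real_)
  as.numeric(out)
}
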