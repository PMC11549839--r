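#' Create a DNA sequence record
#'
#' A `dna_record` carries a named DNA sequence over the alphabet
#' `{A,C,G,T,N}` in either case.  Lowercase residues mark soft-masked
#' (repeat) regions, following the FASTA convention; the case is preserved
#' through every operation in the package, including the 2bit codec where
#' lowercase runs become mask blocks.
#'
#' @param name Sequence name: a non-empty token without whitespace.
#' @param residues Character scalar of residues over `ACGTNacgtn`.
#' @param desc Optional free-text description (the FASTA header text after
#'   the first whitespace).
#' @return An object of class `dna_record` with fields `name`, `desc`,
#'   `residues` and `length`.
#' @examples
#' rec <- dna_record("chr1", "ACGTacgtNN")
#' rec$length
#' @export
dna_record <- function(name, residues, desc = "") {
  if (!is.character(name) || length(name) != 1L || is.na(name) ||
      !nzchar(name) || grepl("[[:space:]]", name)) {
    stop("record name must be a non-empty token without whitespace",
         call. = FALSE)
  }
  if (!is.character(residues) || length(residues) != 1L || is.na(residues)) {
    stop("residues must be a single character string", call. = FALSE)
  }
  check_residues(residues, name)
  structure(
    list(name = name, desc = desc, residues = residues,
         length = nchar(residues)),
    class = "dna_record"
  )
}

#' @export
print.dna_record <- function(x, ...) {
  head <- if (x$length > 50L) paste0(substr(x$residues, 1L, 50L), "...")
          else x$residues
  cat(sprintf("<dna_record> %s (%d bp)%s\n  %s\n", x$name, x$length,
              if (nzchar(x$desc)) paste0(" ", x$desc) else "", head))
  invisible(x)
}

#' @export
format.dna_record <- function(x, ...) {
  sprintf("%s (%d bp)", x$name, x$length)
}

# Reject residues outside ACGTNacgtn, reporting the 1-based offset of the
# first offender.
check_residues <- function(residues, name = "<unnamed>") {
  bad <- regexpr("[^ACGTNacgtn]", residues)
  if (bad != -1L) {
    stop(sprintf(
      "record '%s': invalid residue '%s' at offset %d (allowed: ACGTN, either case)",
      name, substr(residues, bad, bad), as.integer(bad)), call. = FALSE)
  }
  invisible(TRUE)
}

check_unique_names <- function(records, what = "input") {
  nms <- vapply(records, `[[`, "", "name")
  dup <- nms[duplicated(nms)]
  if (length(dup)) {
    stop(sprintf("duplicate record name(s) in %s: %s", what,
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  invisible(nms)
}

#' Read DNA sequences from FASTA
#'
#' Parses multi-record FASTA with wrapped or unwrapped sequence lines.
#' The first whitespace-delimited token of each header is the record name;
#' the remainder is the description.  Case (soft-masking) and `N`s are
#' preserved exactly.  Residues outside `ACGTNacgtn` and duplicate names
#' are rejected with informative errors.
#'
#' @param file Path to a FASTA file, or a connection.
#' @param text FASTA text given directly instead of `file`.
#' @return A list of [dna_record] objects in file order, named by record
#'   name.  An empty input yields an empty list.
#' @examples
#' read_fasta(text = ">q1 demo\nACGT\nacgt\n")
#' @export
read_fasta <- function(file = NULL, text = NULL) {
  if (is.null(file) == is.null(text)) {
    stop("supply exactly one of 'file' or 'text'", call. = FALSE)
  }
  lines <- if (is.null(text)) readLines(file, warn = FALSE)
           else strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(structure(list(), names = character()))
  hdr <- startsWith(lines, ">")
  if (!hdr[1L]) {
    stop("FASTA parse error at line 1: expected '>' header", call. = FALSE)
  }
  grp <- cumsum(hdr)
  records <- lapply(split(seq_along(lines), grp), function(idx) {
    header <- sub("^>", "", lines[idx[1L]])
    name <- sub("[[:space:]].*$", "", header)
    desc <- if (grepl("[[:space:]]", header)) {
      sub("^[^[:space:]]+[[:space:]]+", "", header)
    } else ""
    seq <- paste(lines[idx[-1L]], collapse = "")
    seq <- gsub("[[:space:]]", "", seq)
    dna_record(name, seq, desc)
  })
  records <- unname(records)
  names(records) <- check_unique_names(records, "FASTA input")
  records
}

#' Write DNA sequences as FASTA
#'
#' The inverse of [read_fasta()]: round-tripping preserves names,
#' descriptions, order, case, and `N`s exactly (only line wrapping may
#' differ).
#'
#' @param records A list of [dna_record] objects.
#' @param file Optional path; when `NULL` the FASTA text is returned.
#' @param line_width Residues per sequence line (>= 1).
#' @return The FASTA text (invisibly when written to `file`).
#' @export
write_fasta <- function(records, file = NULL, line_width = 60L) {
  line_width <- as.integer(line_width)
  if (is.na(line_width) || line_width < 1L) {
    stop("line_width must be >= 1", call. = FALSE)
  }
  records <- as_dna_records(records)
  chunks <- vapply(records, function(r) {
    header <- paste0(">", r$name,
                     if (nzchar(r$desc)) paste0(" ", r$desc) else "")
    if (r$length == 0L) return(paste0(header, "\n"))
    starts <- seq.int(1L, r$length, by = line_width)
    body <- substring(r$residues, starts,
                      pmin(starts + line_width - 1L, r$length))
    paste0(header, "\n", paste(body, collapse = "\n"), "\n")
  }, character(1))
  out <- paste(chunks, collapse = "")
  if (is.null(file)) return(out)
  writeLines(out, file, sep = "")
  invisible(out)
}

# Accept a single record, a list of records, or a named character vector.
as_dna_records <- function(x) {
  if (inherits(x, "dna_record")) return(structure(list(x), names = x$name))
  if (is.character(x)) {
    if (is.null(names(x)) || any(!nzchar(names(x)))) {
      stop("character input to as_dna_records must be fully named",
           call. = FALSE)
    }
    x <- mapply(dna_record, names(x), x, SIMPLIFY = FALSE)
  }
  if (!is.list(x) || !all(vapply(x, inherits, TRUE, "dna_record"))) {
    stop("expected a dna_record or a list of dna_record objects",
         call. = FALSE)
  }
  structure(unname(x), names = vapply(x, `[[`, "", "name"))
}

#' Reverse complement of a DNA string
#'
#' Complements `A<->T`, `C<->G`, `N<->N` preserving case, then reverses.
#' An involution: `reverse_complement(reverse_complement(s)) == s`.
#'
#' @param residues Character scalar over `ACGTNacgtn`.
#' @return The reverse-complemented string.
#' @examples
#' reverse_complement("AAAC")  # "GTTT"
#' @export
reverse_complement <- function(residues) {
  stopifnot(is.character(residues), length(residues) == 1L)
  check_residues(residues)
  if (!nchar(residues)) return(residues)
  comp <- chartr("ACGTacgtNn", "TGCAtgcaNn", residues)
  intToUtf8(rev(utf8ToInt(comp)))
}
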