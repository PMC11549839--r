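# .2bit codec ----------------------------------------------------------------
#
# Standard UCSC .2bit layout: 16-byte header (signature 0x1A412743, version 0,
# sequenceCount, reserved), an index of (nameSize, name, offset) entries, then
# per-sequence records: dnaSize, nBlockCount, nBlockStarts[], nBlockSizes[],
# maskBlockCount, maskBlockStarts[], maskBlockSizes[], reserved, packedDna.
# Base codes are T=0, C=1, A=2, G=3, packed 4 bases/byte with the first base
# in the most significant bits.  Archives are written little-endian by
# default; the reader accepts either byte order (the signature reveals it).
# All coordinates are 0-based half-open.

TWOBIT_SIG <- 0x1A412743

# byte value -> 4 base codes, and base char -> 2-bit code lookup tables,
# built once at load time.
.tb <- new.env(parent = emptyenv())

.tb_init <- function() {
  if (!is.null(.tb$byte_codes)) return(invisible())
  b <- 0:255
  .tb$byte_codes <- rbind(b %/% 64L, (b %/% 16L) %% 4L,
                          (b %/% 4L) %% 4L, b %% 4L)
  code <- rep(NA_integer_, 256L)
  code[utf8ToInt("T") + 1L] <- 0L; code[utf8ToInt("t") + 1L] <- 0L
  code[utf8ToInt("C") + 1L] <- 1L; code[utf8ToInt("c") + 1L] <- 1L
  code[utf8ToInt("A") + 1L] <- 2L; code[utf8ToInt("a") + 1L] <- 2L
  code[utf8ToInt("G") + 1L] <- 3L; code[utf8ToInt("g") + 1L] <- 3L
  # N (either case) is stored as code 0 in the packed bits and restored
  # from the N-blocks on decode.
  code[utf8ToInt("N") + 1L] <- 0L; code[utf8ToInt("n") + 1L] <- 0L
  .tb$base_code <- code
  # tile codes: like base codes but N is untileable (NA)
  tcode <- code
  tcode[utf8ToInt("N") + 1L] <- NA_integer_
  tcode[utf8ToInt("n") + 1L] <- NA_integer_
  .tb$tile_code <- tcode
  .tb$code_char <- utf8ToInt("TCAG")  # code -> uppercase utf8 codepoint
  invisible()
}

# unsigned 32-bit <-> raw, done in doubles to dodge R's signed integers
u32_bytes <- function(x, endian = "little") {
  x <- as.numeric(x)
  b <- rbind(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
             (x %/% 16777216) %% 256)
  if (endian == "big") b <- b[4:1, , drop = FALSE]
  as.raw(as.vector(b))
}

u32_read <- function(raw, pos, n = 1L, endian = "little") {
  # pos is a 0-based byte offset; reads n consecutive u32 values
  if (n == 0) return(numeric(0))
  need <- pos + 4 * n
  if (need > length(raw)) {
    stop(sprintf("truncated 2bit archive: need %d bytes at offset %d, have %d",
                 4 * n, pos, length(raw) - pos), call. = FALSE)
  }
  b <- matrix(as.numeric(raw[(pos + 1):(pos + 4 * n)]), nrow = 4L)
  if (endian == "big") b <- b[4:1, , drop = FALSE]
  b[1, ] + 256 * b[2, ] + 65536 * b[3, ] + 16777216 * b[4, ]
}

# 0-based (start, size) runs of TRUE in a logical vector
runs_of <- function(flag) {
  if (!length(flag) || !any(flag)) {
    return(matrix(numeric(0), ncol = 2,
                  dimnames = list(NULL, c("start", "size"))))
  }
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  cbind(start = starts[r$values], size = r$lengths[r$values])
}

#' Encode DNA records as a .2bit archive
#'
#' Produces a standard .2bit byte stream: `N` positions (either case) are
#' recorded as N-blocks, lowercase runs as soft-mask blocks, and the
#' uppercase base identity is bit-packed 4 bases per byte with codes
#' T=0, C=1, A=2, G=3 (first base in the most significant bits).
#' `decode_twobit(encode_twobit(x))` reproduces `x` exactly.
#'
#' @param records A list of [dna_record] objects with unique names.
#' @param endian Byte order to write; readers accept either.
#' @return A raw vector holding the archive.
#' @examples
#' bytes <- encode_twobit(list(dna_record("s", "ACGT")))
#' bytes[length(bytes)]  # the packed byte 0x9c
#' @export
encode_twobit <- function(records, endian = c("little", "big")) {
  endian <- match.arg(endian)
  .tb_init()
  records <- as_dna_records(records)
  check_unique_names(records, "2bit input")
  nms <- names(records)
  if (any(!nzchar(nms))) stop("empty record name", call. = FALSE)

  bodies <- lapply(records, function(r) {
    ints <- utf8ToInt(r$residues)
    codes <- .tb$base_code[ints + 1L]
    n_blocks <- runs_of(ints == 78L | ints == 110L)      # N, n
    mask_blocks <- runs_of(ints >= 97L)                  # lowercase
    L <- length(codes)
    pad <- (-L) %% 4L
    if (pad) codes <- c(codes, integer(pad))
    m <- matrix(codes, nrow = 4L)
    packed <- as.raw(m[1, ] * 64L + m[2, ] * 16L + m[3, ] * 4L + m[4, ])
    c(list(u32_bytes(L, endian)),
      list(u32_bytes(nrow(n_blocks), endian)),
      list(u32_bytes(n_blocks[, "start"], endian)),
      list(u32_bytes(n_blocks[, "size"], endian)),
      list(u32_bytes(nrow(mask_blocks), endian)),
      list(u32_bytes(mask_blocks[, "start"], endian)),
      list(u32_bytes(mask_blocks[, "size"], endian)),
      list(u32_bytes(0, endian)),
      list(packed))
  })
  body_raw <- lapply(bodies, function(b) do.call(c, b))
  body_sizes <- vapply(body_raw, length, 0L)

  name_raw <- lapply(nms, charToRaw)
  index_size <- sum(vapply(name_raw, length, 0L) + 5L)
  offsets <- if (length(records)) {
    16L + index_size + c(0, cumsum(utils::head(body_sizes, -1L)))
  } else numeric(0)

  header <- c(u32_bytes(TWOBIT_SIG, endian), u32_bytes(0, endian),
              u32_bytes(length(records), endian), u32_bytes(0, endian))
  index <- do.call(c, c(list(raw(0)), mapply(function(nm, off) {
    c(as.raw(length(nm)), nm, u32_bytes(off, endian))
  }, name_raw, offsets, SIMPLIFY = FALSE)))
  unname(do.call(c, c(list(header, index), body_raw)))
}

#' Parse a .2bit archive into a random-access handle
#'
#' Reads the header and index (in either byte order) and the per-sequence
#' block tables, returning a `twobit_archive` object that supports
#' [fetch_subsequence()] without decoding whole sequences.
#'
#' @param archive Raw vector of .2bit bytes, a path to a .2bit file, or an
#'   already-parsed `twobit_archive` (returned unchanged).
#' @return A `twobit_archive` object.
#' @export
twobit_parse <- function(archive) {
  if (inherits(archive, "twobit_archive")) return(archive)
  if (is.character(archive)) {
    archive <- readBin(archive[1L], raw(), file.size(archive[1L]))
  }
  if (!is.raw(archive)) {
    stop("archive must be raw bytes, a file path, or a twobit_archive",
         call. = FALSE)
  }
  .tb_init()
  if (length(archive) < 16L) {
    stop("truncated 2bit archive: shorter than the 16-byte header",
         call. = FALSE)
  }
  endian <- if (u32_read(archive, 0, endian = "little") == TWOBIT_SIG) {
    "little"
  } else if (u32_read(archive, 0, endian = "big") == TWOBIT_SIG) {
    "big"
  } else {
    stop("not a 2bit archive: bad signature", call. = FALSE)
  }
  n_seq <- u32_read(archive, 8, endian = endian)
  pos <- 16
  entries <- vector("list", n_seq)
  for (i in seq_len(n_seq)) {
    if (pos + 1 > length(archive)) {
      stop(sprintf("truncated 2bit archive at byte offset %d", pos),
           call. = FALSE)
    }
    nlen <- as.integer(archive[pos + 1]); pos <- pos + 1
    if (pos + nlen > length(archive)) {
      stop(sprintf("truncated 2bit archive at byte offset %d", pos),
           call. = FALSE)
    }
    nm <- rawToChar(archive[(pos + 1):(pos + nlen)]); pos <- pos + nlen
    off <- u32_read(archive, pos, endian = endian); pos <- pos + 4
    entries[[i]] <- list(name = nm, offset = off)
  }
  seqs <- lapply(entries, function(e) {
    p <- e$offset
    dna_size <- u32_read(archive, p, endian = endian); p <- p + 4
    n_cnt <- u32_read(archive, p, endian = endian); p <- p + 4
    n_starts <- u32_read(archive, p, n_cnt, endian = endian); p <- p + 4 * n_cnt
    n_sizes <- u32_read(archive, p, n_cnt, endian = endian); p <- p + 4 * n_cnt
    m_cnt <- u32_read(archive, p, endian = endian); p <- p + 4
    m_starts <- u32_read(archive, p, m_cnt, endian = endian); p <- p + 4 * m_cnt
    m_sizes <- u32_read(archive, p, m_cnt, endian = endian); p <- p + 4 * m_cnt
    p <- p + 4  # reserved
    packed_len <- ceiling(dna_size / 4)
    if (p + packed_len > length(archive)) {
      stop(sprintf("truncated 2bit archive: packed DNA for '%s' ends past EOF",
                   e$name), call. = FALSE)
    }
    list(name = e$name, dna_size = dna_size, packed_offset = p,
         n_blocks = cbind(start = n_starts, size = n_sizes),
         mask_blocks = cbind(start = m_starts, size = m_sizes))
  })
  names(seqs) <- vapply(seqs, `[[`, "", "name")
  structure(list(raw = archive, endian = endian, sequences = seqs),
            class = "twobit_archive")
}

#' @export
print.twobit_archive <- function(x, ...) {
  cat(sprintf("<twobit_archive> %d sequence(s), %d bytes (%s-endian)\n",
              length(x$sequences), length(x$raw), x$endian))
  for (s in x$sequences) {
    cat(sprintf("  %s: %d bp, %d N-block(s), %d mask-block(s)\n", s$name,
                s$dna_size, nrow(s$n_blocks), nrow(s$mask_blocks)))
  }
  invisible(x)
}

#' Sequence names and lengths of a .2bit archive
#' @param archive Anything accepted by [twobit_parse()].
#' @return `twobit_names()`: character vector; `twobit_lengths()`: named
#'   numeric vector of sequence lengths in bases.
#' @export
twobit_names <- function(archive) names(twobit_parse(archive)$sequences)

#' @rdname twobit_names
#' @export
twobit_lengths <- function(archive) {
  vapply(twobit_parse(archive)$sequences, `[[`, 0, "dna_size")
}

#' Fetch a subsequence from a .2bit archive
#'
#' Decodes only the packed bytes covering the requested 0-based half-open
#' interval, then restores `N`s from the N-blocks and lowercase from the
#' mask blocks.
#'
#' @param archive Anything accepted by [twobit_parse()].
#' @param name Sequence name.
#' @param start,end 0-based half-open interval; defaults to the whole
#'   sequence.
#' @return Character scalar of residues.
#' @export
fetch_subsequence <- function(archive, name, start = 0, end = NULL) {
  a <- twobit_parse(archive)
  s <- a$sequences[[name]]
  if (is.null(s)) stop(sprintf("no sequence named '%s' in archive", name),
                       call. = FALSE)
  if (is.null(end)) end <- s$dna_size
  start <- as.numeric(start); end <- as.numeric(end)
  if (is.na(start) || is.na(end) || start < 0 || end > s$dna_size ||
      start > end) {
    stop(sprintf("interval [%s,%s) out of range for '%s' (%d bp)",
                 format(start), format(end), name, s$dna_size), call. = FALSE)
  }
  if (start == end) return("")
  byte0 <- start %/% 4          # first packed byte needed (0-based)
  byte1 <- (end - 1) %/% 4      # last packed byte needed
  bytes <- a$raw[(s$packed_offset + byte0 + 1):(s$packed_offset + byte1 + 1)]
  codes <- as.vector(.tb$byte_codes[, as.integer(bytes) + 1L])
  # trim the partial bases at both ends of the byte window
  codes <- codes[(start - byte0 * 4 + 1):(end - byte0 * 4)]
  chars <- .tb$code_char[codes + 1L]
  chars <- overlay_blocks(chars, s$n_blocks, start, end, set_n = TRUE)
  chars <- overlay_blocks(chars, s$mask_blocks, start, end, set_n = FALSE)
  intToUtf8(chars)
}

# overlay N-blocks (set codepoint to 'N') or mask blocks (+32 = lowercase)
# onto a window [start, end) of utf8 codepoints
overlay_blocks <- function(chars, blocks, start, end, set_n) {
  if (!nrow(blocks)) return(chars)
  bs <- pmax(blocks[, "start"], start)
  be <- pmin(blocks[, "start"] + blocks[, "size"], end)
  keep <- bs < be
  if (!any(keep)) return(chars)
  idx <- unlist(mapply(function(b0, b1) seq.int(b0 - start + 1, b1 - start),
                       bs[keep], be[keep], SIMPLIFY = FALSE))
  if (set_n) chars[idx] <- 78L else chars[idx] <- chars[idx] + 32L
  chars
}

#' Decode a .2bit archive into DNA records
#'
#' The inverse of [encode_twobit()]: restores residues with `N`s from
#' N-blocks and lowercase from mask blocks.  Archives written in either
#' byte order decode identically.
#'
#' @inheritParams fetch_subsequence
#' @return A list of [dna_record] objects in archive order.
#' @export
decode_twobit <- function(archive) {
  a <- twobit_parse(archive)
  recs <- lapply(a$sequences, function(s) {
    dna_record(s$name, fetch_subsequence(a, s$name))
  })
  structure(unname(recs), names = names(a$sequences))
}

#' Convert FASTA to .2bit and back
#'
#' `fa2twobit()` reads FASTA (file or text) and encodes a .2bit archive;
#' `twobit2fa()` decodes an archive (optionally a single named region)
#' back to FASTA.
#'
#' @param fasta FASTA path (or text when `text = TRUE` input is given via
#'   `read_fasta`) for `fa2twobit`.
#' @param out Optional output path; when `NULL` the bytes/text are
#'   returned.
#' @inheritParams fetch_subsequence
#' @param line_width FASTA line width for `twobit2fa`.
#' @return `fa2twobit()`: raw .2bit bytes (invisibly when written);
#'   `twobit2fa()`: FASTA text (invisibly when written).
#' @export
fa2twobit <- function(fasta, out = NULL) {
  records <- if (file.exists(fasta)) read_fasta(file = fasta)
             else read_fasta(text = fasta)
  bytes <- encode_twobit(records)
  if (is.null(out)) return(bytes)
  writeBin(bytes, out)
  invisible(bytes)
}

#' @rdname fa2twobit
#' @param twobit .2bit bytes, path, or parsed archive.
#' @export
twobit2fa <- function(twobit, out = NULL, name = NULL, start = NULL,
                      end = NULL, line_width = 60L) {
  a <- twobit_parse(twobit)
  if (is.null(name)) {
    if (!is.null(start) || !is.null(end)) {
      stop("region extraction requires 'name'", call. = FALSE)
    }
    records <- decode_twobit(a)
  } else {
    s <- if (is.null(start)) 0 else as.numeric(start)
    e <- if (is.null(end)) NULL else as.numeric(end)
    res <- fetch_subsequence(a, name, s, e)
    e_shown <- if (is.null(e)) a$sequences[[name]]$dna_size else e
    label <- if (is.null(start) && is.null(end)) name
             else sprintf("%s:%d-%d", name, s, e_shown)
    records <- list(dna_record(label, res))
  }
  txt <- write_fasta(records, line_width = line_width)
  if (is.null(out)) return(txt)
  writeLines(txt, out, sep = "")
  invisible(txt)
}
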