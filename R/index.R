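# Random-access machinery: byte-range indexes over text and XML MS data files,
# built by buffered streaming (never a whole-file load), plus JSON persistence
# so a file indexed once can be reopened without re-scanning.

# 1 MiB buffered-scan chunk; also the allowance in the bounded-I/O contract.
MS_CHUNK_SIZE <- 1048576L

# ---- instrumented low-level I/O --------------------------------------------
# Every byte the package reads from a data file flows through here, so tests
# can assert the bounded-memory contract (fetch of one spectrum reads at most
# span length + one buffer).
.ms_io <- new.env(parent = emptyenv())
.ms_io$bytes <- 0

ms_read_bytes_con <- function(con, n) {
  b <- readBin(con, "raw", n = n)
  .ms_io$bytes <- .ms_io$bytes + length(b)
  b
}

#' Instrumented I/O counters
#'
#' All file reads performed by the package are counted; useful to verify that
#' indexed access does not load whole files.
#'
#' @return `io_bytes_read()` returns the number of bytes read from data files
#'   since the last [io_reset()].
#' @export
io_bytes_read <- function() .ms_io$bytes

#' @rdname io_bytes_read
#' @export
io_reset <- function() { .ms_io$bytes <- 0; invisible(NULL) }

# ---- spans and indexes ------------------------------------------------------

#' Construct a record span
#'
#' One spectrum record's byte range in a source file: `start` is a 0-based
#' byte offset, `length` > 0, `position` the 0-based spectrum ordinal, and
#' `native_id` the format's own identifier when the format has one.
#'
#' @param start 0-based byte offset.
#' @param length span length in bytes, positive.
#' @param position 0-based spectrum ordinal.
#' @param native_id optional identifier text.
#' @return an object of class `ms_span`.
#' @export
record_span <- function(start, length, position, native_id = NULL) {
  if (length <= 0) ms_stop("domain_error", "span length must be positive")
  if (start < 0) ms_stop("domain_error", "span start must be >= 0")
  structure(list(start = as.numeric(start), length = as.numeric(length),
                 position = as.integer(position),
                 native_id = if (!is.null(native_id) && !is.na(native_id))
                   as.character(native_id)),
            class = "ms_span")
}

#' Construct a file index
#'
#' @param path source file path.
#' @param format one of the seven format ids (see [ms_formats()]).
#' @param records list of [record_span()]s in file order.
#' @param header_span optional span covering file-level header material (MGF
#'   global parameters, MS2 H-lines).
#' @param file_size,fingerprint captured from the file at index time; used for
#'   best-effort stale detection when a persisted index is reused.
#' @return an object of class `ms_file_index`.
#' @export
file_index <- function(path, format, records, header_span = NULL,
                       file_size = file.size(path),
                       fingerprint = ms_fingerprint(path)) {
  ids <- unlist(lapply(records, function(r) r$native_id))
  if (anyDuplicated(ids))
    ms_stop("integrity_error",
            sprintf("duplicate native ids in %s: %s", path,
                    paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  structure(list(version = "msreader-index/1", path = path, format = format,
                 file_size = as.numeric(file_size), fingerprint = fingerprint,
                 header_span = header_span, records = records),
            class = "ms_file_index")
}

#' Fingerprint a file for stale-index detection
#'
#' Size plus an MD5 over the first and last 8 KiB. Hashing the whole file
#' would defeat the point of indexing large files, so detection is
#' best-effort by design: any append, truncation or edit near either end is
#' caught.
#'
#' @param path file path.
#' @return fingerprint text.
#' @export
ms_fingerprint <- function(path) {
  sz <- file.size(path)
  if (is.na(sz)) ms_stop("io_error", sprintf("cannot stat '%s'", path))
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", n = min(8192, sz))
  tail <- raw(0)
  if (sz > 8192) {
    seek(con, max(0, sz - 8192))
    tail <- readBin(con, "raw", n = 8192)
  }
  tmp <- tempfile()
  writeBin(c(head, tail), tmp)
  on.exit(unlink(tmp), add = TRUE)
  sprintf("%.0f:%s", sz, unname(tools::md5sum(tmp)))
}

# ---- buffered line scanner --------------------------------------------------
# Streams the file once in fixed-size chunks and calls
# line_fun(abs_start, raw_len, text) per physical line, where abs_start is the
# 0-based offset of the line's first byte, raw_len includes the terminator,
# and text has \n and a trailing \r stripped.
scan_file_lines <- function(path, line_fun, chunk_size = MS_CHUNK_SIZE) {
  con <- tryCatch(file(path, "rb"),
                  error = function(e) ms_stop("io_error", conditionMessage(e)))
  on.exit(close(con))
  offset <- 0
  carry <- raw(0)
  repeat {
    chunk <- ms_read_bytes_con(con, chunk_size)
    eof <- length(chunk) < chunk_size
    buf <- c(carry, chunk)
    n <- length(buf)
    if (n == 0) break
    ends <- which(buf == as.raw(10L))
    if (eof && (length(ends) == 0 || ends[length(ends)] < n))
      ends <- c(ends, n)
    if (length(ends) > 0) {
      starts <- c(1, ends[-length(ends)] + 1)
      txt <- rawToChar(buf[seq_len(ends[length(ends)])])
      Encoding(txt) <- "latin1"
      parts <- strsplit(txt, "\n", fixed = TRUE)[[1]]
      if (length(parts) < length(ends)) parts <- c(parts, "")
      for (i in seq_along(ends)) {
        line_fun(offset + starts[i] - 1,
                 ends[i] - starts[i] + 1,
                 sub("\r$", "", parts[i]))
      }
      consumed <- ends[length(ends)]
    } else consumed <- 0
    carry <- if (consumed < n) buf[(consumed + 1):n] else raw(0)
    offset <- offset + consumed
    if (eof) break
  }
  invisible(NULL)
}

# ---- text-format indexing ---------------------------------------------------

#' Build a byte-range index of a text peak-list file
#'
#' One [record_span()] per spectrum record: MGF records run from `BEGIN IONS`
#' through `END IONS` inclusive; MS2 records from an S-line through the line
#' before the next S-line; DTA and PKL records are contiguous non-blank
#' blocks (consecutive blank lines collapse to one separator). MGF global
#' parameters and MS2 H-lines become the `header_span`. The file is read once
#' in 1 MiB buffered chunks.
#'
#' @param path file path.
#' @param format one of "dta", "pkl", "mgf", "ms2".
#' @param chunk_size buffered-read chunk size in bytes.
#' @return an `ms_file_index`.
#' @export
build_text_index <- function(path, format, chunk_size = MS_CHUNK_SIZE) {
  format <- match.arg(tolower(format), c("dta", "pkl", "mgf", "ms2"))
  st <- new.env(parent = emptyenv())
  st$records <- list()
  st$rec_start <- NULL      # current record start offset
  st$rec_end <- NULL        # exclusive end (content end of last line kept)
  st$rec_id <- NULL
  st$hdr_start <- NULL
  st$hdr_end <- NULL
  st$seen_record <- FALSE

  close_rec <- function() {
    if (!is.null(st$rec_start)) {
      st$records[[length(st$records) + 1]] <-
        record_span(st$rec_start, st$rec_end - st$rec_start,
                    length(st$records), st$rec_id)
      st$rec_start <- NULL; st$rec_end <- NULL; st$rec_id <- NULL
    }
  }

  if (format %in% c("dta", "pkl")) {
    line_fun <- function(abs_start, raw_len, text) {
      if (grepl("^[ \t]*$", text)) {
        close_rec()
      } else {
        if (is.null(st$rec_start)) st$rec_start <- abs_start
        st$rec_end <- abs_start + nchar(text, type = "bytes")
      }
    }
  } else if (format == "mgf") {
    line_fun <- function(abs_start, raw_len, text) {
      content_end <- abs_start + nchar(text, type = "bytes")
      if (startsWith(text, "BEGIN IONS")) {
        close_rec()
        st$seen_record <- TRUE
        st$rec_start <- abs_start
        st$rec_end <- content_end
      } else if (startsWith(text, "END IONS")) {
        if (!is.null(st$rec_start)) { st$rec_end <- content_end; close_rec() }
      } else if (!is.null(st$rec_start)) {
        st$rec_end <- content_end
      } else if (!st$seen_record && !grepl("^[ \t]*$", text)) {
        if (is.null(st$hdr_start)) st$hdr_start <- abs_start
        st$hdr_end <- content_end
      }
    }
  } else { # ms2
    line_fun <- function(abs_start, raw_len, text) {
      content_end <- abs_start + nchar(text, type = "bytes")
      if (grepl("^S[ \t]", text)) {
        close_rec()
        st$seen_record <- TRUE
        st$rec_start <- abs_start
        st$rec_end <- content_end
        tok <- strsplit(trimws(text), "[ \t]+")[[1]]
        st$rec_id <- if (length(tok) >= 2) tok[2] else NULL
      } else if (!grepl("^[ \t]*$", text)) {
        if (!is.null(st$rec_start)) {
          st$rec_end <- content_end
        } else if (!st$seen_record) {
          if (is.null(st$hdr_start)) st$hdr_start <- abs_start
          st$hdr_end <- content_end
        }
      }
    }
  }

  scan_file_lines(path, line_fun, chunk_size)
  close_rec()
  if (length(st$records) == 0 && isTRUE(file.size(path) > 0))
    ms_warn("empty_index", sprintf("no spectrum records found in '%s'", path))
  header_span <- if (!is.null(st$hdr_start))
    record_span(st$hdr_start, st$hdr_end - st$hdr_start, 0)
  file_index(path, format, st$records, header_span)
}

# ---- XML indexing -----------------------------------------------------------

# Pull one attribute value out of an opening-tag string.
extract_attr <- function(tagtxt, name) {
  m <- regmatches(tagtxt, regexec(
    sprintf("[\\s<]%s\\s*=\\s*(\"([^\"]*)\"|'([^']*)')", name), tagtxt,
    perl = TRUE))[[1]]
  if (length(m) == 0) return(NULL)
  if (nzchar(m[3]) || m[2] == "\"\"") m[3] else m[4]
}

#' Build a byte-range index of an XML MS data file
#'
#' Spans cover each `<scan>` (mzXML; nested scans are flattened in document
#' order, each with its own span covering its full element) or `<spectrum>`
#' (mzData, mzML) element, from its opening `<` to its closing tag's `>`.
#' Native ids are the mzXML scan `num`, or the mzData/mzML spectrum `id`.
#' Scanning is byte-pattern based (quote-aware tag matching) in fixed-size
#' buffered chunks, not a DOM parse, so memory stays bounded regardless of
#' file size.
#'
#' @param path file path.
#' @param format one of "mzxml", "mzdata", "mzml".
#' @param chunk_size buffered-read chunk size in bytes.
#' @return an `ms_file_index`.
#' @export
build_xml_index <- function(path, format, chunk_size = MS_CHUNK_SIZE) {
  format <- match.arg(tolower(format), c("mzxml", "mzdata", "mzml"))
  tag <- if (format == "mzxml") "scan" else "spectrum"
  id_attr <- if (format == "mzxml") "num" else "id"
  tag_raw <- charToRaw(tag)
  tlen <- length(tag_raw)
  LT <- as.raw(60L); GT <- as.raw(62L); SLASH <- as.raw(47L)
  Q1 <- as.raw(34L); Q2 <- as.raw(39L)
  delim <- as.raw(c(32L, 9L, 10L, 13L, 62L, 47L))  # space tab nl cr > /

  recs <- list()        # completed: list(start, end, id, position)
  stack <- list()       # open elements: list(start, id, position)
  npos <- 0L

  con <- tryCatch(file(path, "rb"),
                  error = function(e) ms_stop("io_error", conditionMessage(e)))
  on.exit(close(con))
  offset <- 0           # 0-based file offset of buf[1]
  carry <- raw(0)
  min_keep <- tlen + 2L

  repeat {
    chunk <- ms_read_bytes_con(con, chunk_size)
    eof <- length(chunk) < chunk_size
    buf <- c(carry, chunk)
    n <- length(buf)
    if (n == 0) break
    lts <- which(buf == LT)
    resume <- n + 1L      # buf position from which to carry over
    for (i in lts) {
      if (i < resume - 0L && i <= n) {
        # classify: open <tag..., close </tag...>
        is_close <- (i + 1L <= n) && buf[i + 1L] == SLASH
        nm_at <- if (is_close) i + 2L else i + 1L
        if (nm_at + tlen - 1L > n) {          # name may be cut at boundary
          if (!eof) { resume <- min(resume, i); break }
          next
        }
        if (!identical(buf[nm_at:(nm_at + tlen - 1L)], tag_raw)) next
        after <- nm_at + tlen
        if (after <= n && !(buf[after] %in% delim)) next  # e.g. <spectrumList
        # find quote-aware tag end '>'
        j <- i + 1L; inq <- as.raw(0L); found <- FALSE
        while (j <= n) {
          b <- buf[j]
          if (inq != as.raw(0L)) {
            if (b == inq) inq <- as.raw(0L)
          } else if (b == Q1 || b == Q2) {
            inq <- b
          } else if (b == GT) { found <- TRUE; break }
          j <- j + 1L
        }
        if (!found) {
          if (!eof) { resume <- min(resume, i); break }
          ms_stop("integrity_error",
                  sprintf("truncated tag at byte %.0f in '%s'",
                          offset + i - 1, path))
        }
        if (is_close) {
          if (length(stack) == 0)
            ms_stop("integrity_error",
                    sprintf("unmatched </%s> at byte %.0f in '%s'",
                            tag, offset + i - 1, path))
          open <- stack[[length(stack)]]
          stack[[length(stack)]] <- NULL
          recs[[open$position + 1L]] <-
            list(start = open$start, end = offset + j, id = open$id,
                 position = open$position)
        } else {
          tagtxt <- rawToChar(buf[i:j])
          Encoding(tagtxt) <- "latin1"
          id <- extract_attr(tagtxt, id_attr)
          self_closing <- buf[j - 1L] == SLASH
          start <- offset + i - 1
          if (self_closing) {
            recs[[npos + 1L]] <- list(start = start, end = offset + j,
                                      id = id, position = npos)
          } else {
            stack[[length(stack) + 1L]] <-
              list(start = start, id = id, position = npos)
          }
          npos <- npos + 1L
        }
      }
    }
    if (eof) {
      if (length(stack) > 0)
        ms_stop("integrity_error",
                sprintf("truncated <%s> element (opened at byte %.0f) in '%s'",
                        tag, stack[[1]]$start, path))
      break
    }
    keep_from <- min(resume, n - min_keep + 1L)
    keep_from <- max(keep_from, 1L)
    carry <- buf[keep_from:n]
    offset <- offset + keep_from - 1
  }

  records <- lapply(recs, function(r)
    record_span(r$start, r$end - r$start, r$position, r$id))
  file_index(path, format, records)
}

# ---- span reads and persistence --------------------------------------------

#' Read the bytes of one record span
#'
#' @param path source file path.
#' @param span an [record_span()].
#' @return raw vector of exactly `span$length` bytes starting at `span$start`.
#' @export
read_span <- function(path, span) {
  sz <- file.size(path)
  if (is.na(sz)) ms_stop("io_error", sprintf("cannot stat '%s'", path))
  if (span$start + span$length > sz)
    ms_stop("stale_index",
            sprintf("span [%.0f, +%.0f) extends past EOF (%.0f) of '%s'; re-index the file",
                    span$start, span$length, sz, path))
  con <- file(path, "rb")
  on.exit(close(con))
  seek(con, span$start)
  ms_read_bytes_con(con, span$length)
}

span_text <- function(path, span) {
  txt <- rawToChar(read_span(path, span))
  Encoding(txt) <- "latin1"
  txt
}

#' Persist a file index to JSON / restore it
#'
#' The persisted form is a versioned JSON object
#' (`"version": "msreader-index/1"`) holding path, format, file size,
#' fingerprint, optional header span and the record spans. `load_index()`
#' restores it field-for-field; a version mismatch is an error. Staleness
#' against the actual file is checked at *use* time (see [open_reader()]).
#'
#' @param ix an `ms_file_index`.
#' @return `save_index()`: JSON text. `load_index()`: an `ms_file_index`.
#' @export
save_index <- function(ix) {
  stopifnot(inherits(ix, "ms_file_index"))
  span_obj <- function(s) {
    o <- list(start = s$start, length = s$length, position = s$position)
    if (!is.null(s$native_id)) o$native_id <- s$native_id
    o
  }
  obj <- list(version = ix$version, path = ix$path, format = ix$format,
              file_size = ix$file_size, fingerprint = ix$fingerprint)
  if (!is.null(ix$header_span)) obj$header_span <- span_obj(ix$header_span)
  obj$records <- lapply(ix$records, span_obj)
  as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
}

#' @rdname save_index
#' @param json JSON text produced by `save_index()`.
#' @export
load_index <- function(json) {
  obj <- tryCatch(jsonlite::fromJSON(json, simplifyVector = FALSE),
                  error = function(e)
                    ms_stop("versioned_format",
                            paste("not a valid index JSON:", conditionMessage(e))))
  if (!identical(obj$version, "msreader-index/1"))
    ms_stop("versioned_format",
            sprintf("unsupported index version '%s' (expected msreader-index/1)",
                    obj$version %||% "<missing>"))
  span_from <- function(o)
    record_span(o$start, o$length, o$position, o$native_id)
  structure(list(version = obj$version, path = obj$path, format = obj$format,
                 file_size = as.numeric(obj$file_size),
                 fingerprint = obj$fingerprint,
                 header_span = if (!is.null(obj$header_span))
                   span_from(obj$header_span),
                 records = lapply(obj$records, span_from)),
            class = "ms_file_index")
}

# Validate a (possibly restored) index against the file on disk.
check_index_fresh <- function(ix) {
  fp <- ms_fingerprint(ix$path)
  if (!identical(fp, ix$fingerprint))
    ms_stop("stale_index",
            sprintf("file '%s' changed since it was indexed; re-index", ix$path))
  invisible(TRUE)
}

#' @export
print.ms_file_index <- function(x, ...) {
  cat(sprintf("<ms_file_index> %s [%s] %d records, %.0f bytes\n",
              x$path, x$format, length(x$records), x$file_size))
  invisible(x)
}
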