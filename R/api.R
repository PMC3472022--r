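# The common reader interface: one abstraction over all seven formats (and
# DTA/PKL directories), the three mzIdentML referencing schemes, and
# persisted-index reuse. A reader is immutable after opening, so it may be
# shared for concurrent reads.

#' The seven supported format identifiers
#'
#' @return character vector `c("dta","pkl","mgf","ms2","mzxml","mzdata","mzml")`.
#' @export
ms_formats <- function()
  c("dta", "pkl", "mgf", "ms2", "mzxml", "mzdata", "mzml")

#' Which mzIdentML referencing scheme a reader uses
#'
#' mzIdentML references external spectra three ways: by the format's own
#' spectrum id (mzData, mzXML, mzML), by 0-based position in the file (DTA,
#' PKL, MS2, MGF), and — for formats whose files hold a single spectrum (DTA,
#' PKL) — by filename within a directory.
#'
#' @param format a format id, or an `ms_reader`.
#' @param is_dir TRUE for a DTA/PKL directory reader.
#' @return one of `"id"`, `"position"`, `"filename"`.
#' @export
reference_scheme <- function(format, is_dir = FALSE) {
  if (inherits(format, "ms_reader")) {
    is_dir <- format$is_dir
    format <- format$format
  }
  if (is_dir) {
    if (!format %in% c("dta", "pkl"))
      ms_stop("unsupported_format",
              "directory readers exist only for DTA and PKL")
    return("filename")
  }
  if (format %in% c("mzxml", "mzdata", "mzml")) "id" else "position"
}

ext_format_map <- c(mgf = "mgf", ms2 = "ms2", dta = "dta", pkl = "pkl",
                    mzxml = "mzxml", mzdata = "mzdata", mzml = "mzml")

sniff_content <- function(path) {
  con <- file(path, "rb")
  head <- rawToChar(ms_read_bytes_con(con, 4096))
  close(con)
  Encoding(head) <- "latin1"
  if (grepl("<(mzXML|mzData|mzML|indexedmzML)[\\s>]", head, perl = TRUE))
    return(detect_dialect(path)$format)
  lines <- strsplit(head, "\r?\n")[[1]]
  lines <- lines[!grepl("^[ \t]*$", lines)]
  if (any(startsWith(lines, "BEGIN IONS")) ||
      any(grepl("^[A-Z_]+=", lines)))
    return("mgf")
  if (any(grepl("^[HS][ \t]", lines))) return("ms2")
  if (length(lines) > 0) {
    tok <- split_ws(lines[1])
    if (!anyNA(num_token(tok))) {
      if (length(tok) == 2) return("dta")
      if (length(tok) == 3) return("pkl")
    }
  }
  NULL
}

#' Guess the format of an MS data file
#'
#' Extension map first (`.mgf`, `.ms2`, `.dta`, `.pkl`, `.mzxml`, `.mzdata`,
#' `.mzml`), content probe second (XML root element, `BEGIN IONS`, S-lines,
#' the arity of a numeric first line). When extension and content disagree,
#' content wins with a warning.
#'
#' @param path file path.
#' @return a format id.
#' @export
sniff_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  by_ext <- unname(ext_format_map[ext])
  by_content <- sniff_content(path)
  if (!is.null(by_content) && !is.na(by_content)) {
    if (!is.na(by_ext) && length(by_ext) == 1 && !identical(by_ext, by_content))
      ms_warn("dialect",
              sprintf("extension says '%s' but content looks like '%s'; using content",
                      by_ext, by_content))
    return(by_content)
  }
  if (length(by_ext) == 1 && !is.na(by_ext)) return(by_ext)
  ms_stop("unsupported_format",
          sprintf("cannot determine format of '%s'", path))
}

#' Open a reader on an MS data file or a DTA/PKL directory
#'
#' The single entry point of the common interface. Builds (or restores) the
#' byte-range index, captures format-level header material (MGF global
#' parameters, MS2 H-lines, XML dialect), and returns an immutable reader.
#' Passing `saved_index` (JSON text or an `ms_file_index`) skips re-scanning:
#' the index's fingerprint is checked against the file and a mismatch is a
#' stale-index error — the caller may re-open without the index.
#'
#' @param path a file, or a directory of single-spectrum DTA/PKL files.
#' @param format format id; sniffed via [sniff_format()] when omitted.
#' @param saved_index previously exported index (see [export_index()]).
#' @param mode "lenient" (default: warn and skip bad peak lines) or "strict".
#' @return an object of class `ms_reader`.
#' @export
open_reader <- function(path, format = NULL, saved_index = NULL,
                        mode = c("lenient", "strict")) {
  mode <- match.arg(mode)
  if (dir.exists(path)) return(open_dir_reader(path, format, saved_index, mode))
  if (!file.exists(path))
    ms_stop("io_error", sprintf("no such file: '%s'", path))
  format <- tolower(format %||% sniff_format(path))
  if (!format %in% ms_formats())
    ms_stop("unsupported_format", sprintf("unknown format '%s'", format))

  is_xml <- format %in% c("mzxml", "mzdata", "mzml")
  dialect <- if (is_xml) detect_dialect(path)
  if (is_xml && dialect$format != format)
    ms_stop("unsupported_format",
            sprintf("'%s' declares dialect %s, not %s", path, dialect$format,
                    format))

  if (!is.null(saved_index)) {
    ix <- if (inherits(saved_index, "ms_file_index")) saved_index
          else load_index(saved_index)
    ix$path <- path
    check_index_fresh(ix)
    if (!identical(ix$format, format))
      ms_stop("stale_index",
              sprintf("saved index is for format '%s', file is '%s'",
                      ix$format, format))
  } else {
    ix <- if (is_xml) build_xml_index(path, format)
          else build_text_index(path, format)
  }

  globals <- ms_params()
  header <- ms_params()
  if (!is.null(ix$header_span)) {
    htxt <- span_text(path, ix$header_span)
    if (format == "mgf") globals <- parse_mgf_header(htxt)
    if (format == "ms2") {
      for (ln in record_lines(htxt)) {
        if (grepl("^H[ \t]", ln)) {
          tok <- split_ws(ln)
          header <- params_add(header, paste0("H:", tok[2]),
                               paste(tok[-(1:2)], collapse = " "))
        }
      }
    }
  }
  structure(list(path = path, format = format, mode = mode, is_dir = FALSE,
                 index = ix, globals = globals, header = header,
                 dialect = dialect),
            class = "ms_reader")
}

open_dir_reader <- function(path, format, saved_index, mode) {
  if (is.null(format)) {
    exts <- tolower(tools::file_ext(list.files(path)))
    format <- if (any(exts == "dta")) "dta"
              else if (any(exts == "pkl")) "pkl"
              else ms_stop("unsupported_format",
                           sprintf("no .dta or .pkl files in directory '%s'", path))
  }
  format <- tolower(format)
  if (!format %in% c("dta", "pkl"))
    ms_stop("unsupported_format",
            "directory readers are supported for DTA and PKL only")
  files <- sort(list.files(path, pattern = paste0("\\.", format, "$"),
                           ignore.case = TRUE))
  if (!is.null(saved_index)) {
    obj <- jsonlite::fromJSON(saved_index, simplifyVector = FALSE)
    if (!identical(obj$version, "msreader-dirindex/1"))
      ms_stop("versioned_format",
              sprintf("unsupported directory index version '%s'",
                      obj$version %||% "<missing>"))
    indexes <- lapply(obj$files, function(f) {
      ix <- load_index(jsonlite::toJSON(f$index, auto_unbox = TRUE, digits = NA))
      ix$path <- file.path(path, f$name)
      check_index_fresh(ix)
      ix
    })
    names(indexes) <- vapply(obj$files, `[[`, character(1), "name")
    if (!identical(sort(names(indexes)), files))
      ms_stop("stale_index",
              sprintf("directory '%s' contents changed since indexing", path))
  } else {
    indexes <- lapply(files, function(f)
      build_text_index(file.path(path, f), format))
    names(indexes) <- files
  }
  structure(list(path = path, format = format, mode = mode, is_dir = TRUE,
                 files = files, indexes = indexes,
                 globals = ms_params(), header = ms_params(), dialect = NULL),
            class = "ms_reader")
}

parse_record_text <- function(r, text, position, source) {
  strict <- r$mode == "strict"
  switch(r$format,
         dta = parse_dta_block(text, source, position, strict),
         pkl = parse_pkl_block(text, source, position, strict),
         mgf = parse_mgf_block(text, r$globals, source, position, strict),
         ms2 = parse_ms2_record(text, r$header, source, position, strict),
         mzxml = parse_mzxml_scan(text, r$dialect, position, source),
         mzdata = parse_mzdata_spectrum(text, r$dialect, position, source),
         mzml = parse_mzml_spectrum(text, r$dialect, position, source))
}

#' Number of spectra behind a reader
#'
#' @param r an `ms_reader`.
#' @return integer count.
#' @export
get_spectra_count <- function(r) {
  stopifnot(inherits(r, "ms_reader"))
  if (r$is_dir) length(r$files) else length(r$index$records)
}

#' Fetch one spectrum by 0-based position
#'
#' Reads exactly that record's byte span (plus nothing else) and parses it;
#' equals the position-th element of the iteration order.
#'
#' @param r an `ms_reader`.
#' @param position 0-based ordinal, `0 <= position < get_spectra_count(r)`.
#' @return an `ms_spectrum`.
#' @export
get_spectrum_by_index <- function(r, position) {
  stopifnot(inherits(r, "ms_reader"))
  n <- get_spectra_count(r)
  if (position < 0 || position >= n)
    ms_stop("reference_not_found",
            sprintf("position %d out of range (reader holds %d spectra)",
                    position, n),
            count = n)
  if (r$is_dir) {
    ix <- r$indexes[[position + 1]]
    if (length(ix$records) == 0)
      ms_stop("malformed_record",
              sprintf("file '%s' contains no spectrum", ix$path))
    s <- parse_record_text(r, span_text(ix$path, ix$records[[1]]), position,
                           ix$path)
    return(s)
  }
  span <- r$index$records[[position + 1]]
  parse_record_text(r, span_text(r$path, span), position, r$path)
}

#' Fetch one spectrum by its mzIdentML-style reference
#'
#' Interprets `id` under the reader's [reference_scheme()]: for mzData, mzXML
#' and mzML the format's native id (mzXML scan numbers compared as canonical
#' integer text); for DTA, PKL, MS2 and MGF files a decimal 0-based position;
#' for DTA/PKL directories a base filename, with or without extension.
#'
#' @param r an `ms_reader`.
#' @param id reference text, non-empty.
#' @return an `ms_spectrum`.
#' @export
get_spectrum_by_id <- function(r, id) {
  stopifnot(inherits(r, "ms_reader"))
  id <- as.character(id)
  if (!nzchar(id)) ms_stop("reference_not_found", "empty spectrum reference")
  scheme <- reference_scheme(r)
  if (scheme == "id") {
    ids <- get_spectra_ids(r)
    canon <- function(x) {
      if (r$format == "mzxml" && grepl("^[0-9]+$", x)) sub("^0+(?=.)", "", x,
                                                           perl = TRUE)
      else x
    }
    hit <- which(vapply(ids, canon, character(1)) == canon(id))
    if (length(hit) == 0)
      ms_stop("reference_not_found",
              sprintf("no spectrum with native id '%s' (scheme: id)", id))
    return(get_spectrum_by_index(r, hit[1] - 1))
  }
  if (scheme == "position") {
    if (!grepl("^[0-9]+$", id))
      ms_stop("reference_format",
              sprintf("'%s' is not a 0-based position (scheme: position)", id))
    return(get_spectrum_by_index(r, as.integer(id)))
  }
  # filename scheme
  base <- basename(id)
  hit <- which(r$files == base |
               tools::file_path_sans_ext(r$files) == base)
  if (length(hit) == 0)
    ms_stop("reference_not_found",
            sprintf("no file '%s' in directory (scheme: filename)", id))
  get_spectrum_by_index(r, hit[1] - 1)
}

#' List the spectrum references a reader answers to
#'
#' Native ids for id-scheme formats, stringified 0-based positions for
#' positional formats, filenames for directory readers.
#'
#' @param r an `ms_reader`.
#' @return character vector, one entry per spectrum, in position order.
#' @export
get_spectra_ids <- function(r) {
  stopifnot(inherits(r, "ms_reader"))
  scheme <- reference_scheme(r)
  if (scheme == "filename") return(r$files)
  if (scheme == "position") {
    n <- get_spectra_count(r)
    return(if (n == 0) character(0) else as.character(0:(n - 1)))
  }
  vapply(r$index$records,
         function(sp) sp$native_id %||% NA_character_, character(1))
}

#' Iterate spectra lazily
#'
#' Returns a closure producing one spectrum per call and `NULL` past the end;
#' only one record's bytes are materialized at a time.
#'
#' @param r an `ms_reader`.
#' @return a function: `it()` yields the next `ms_spectrum` or `NULL`.
#' @export
spectra_iterator <- function(r) {
  stopifnot(inherits(r, "ms_reader"))
  i <- 0L
  n <- get_spectra_count(r)
  function() {
    if (i >= n) return(NULL)
    i <<- i + 1L
    get_spectrum_by_index(r, i - 1L)
  }
}

#' Read all spectra into a list
#'
#' Convenience eager form of [spectra_iterator()].
#'
#' @param r an `ms_reader`.
#' @return list of `ms_spectrum`.
#' @export
read_spectra <- function(r) {
  n <- get_spectra_count(r)
  lapply(seq_len(n) - 1L, function(k) get_spectrum_by_index(r, k))
}

#' Export a reader's live index as JSON
#'
#' The exported text can be stored externally (a database, a sidecar file)
#' and passed back to [open_reader()] to skip re-indexing. Directory readers
#' export a per-file index map (`"msreader-dirindex/1"`).
#'
#' @param r an `ms_reader`.
#' @return JSON text.
#' @export
export_index <- function(r) {
  stopifnot(inherits(r, "ms_reader"))
  if (!r$is_dir) return(save_index(r$index))
  entries <- lapply(seq_along(r$files), function(k)
    list(name = r$files[k],
         index = jsonlite::fromJSON(save_index(r$indexes[[k]]),
                                    simplifyVector = FALSE)))
  as.character(jsonlite::toJSON(
    list(version = "msreader-dirindex/1", path = r$path, files = entries),
    auto_unbox = TRUE, digits = NA))
}

#' @export
print.ms_reader <- function(x, ...) {
  cat(sprintf("<ms_reader> %s [%s%s] %d spectra, scheme=%s, mode=%s\n",
              x$path, x$format, if (x$is_dir) " directory" else "",
              get_spectra_count(x), reference_scheme(x), x$mode))
  invisible(x)
}
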