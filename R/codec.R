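#' Describe a binary peak-array encoding
#'
#' Parameterizes the binary payloads of the XML formats: mzXML stores one
#' base64 block of interleaved (m/z, intensity) pairs in network byte order
#' (big-endian); mzData stores separate m/z and intensity arrays whose
#' `endian` attribute is honored; mzML stores separate little-endian arrays.
#' zlib compression is legal for mzXML >= 3.0 and mzML.
#'
#' @param precision 32 or 64 (bits per IEEE-754 float).
#' @param byte_order "big" or "little".
#' @param compression "none" or "zlib".
#' @param layout "single_array" or "interleaved_pairs".
#' @return an object of class `ms_encoding`.
#' @export
ms_encoding <- function(precision = 64, byte_order = c("big", "little"),
                        compression = c("none", "zlib"),
                        layout = c("single_array", "interleaved_pairs")) {
  if (!precision %in% c(32, 64))
    ms_stop("domain_error", "precision must be 32 or 64")
  structure(list(precision = as.integer(precision),
                 byte_order = match.arg(byte_order),
                 compression = match.arg(compression),
                 layout = match.arg(layout)),
            class = "ms_encoding")
}

#' Decode a base64 binary data array
#'
#' @param b64 base64 text (embedded whitespace tolerated).
#' @param enc an [ms_encoding()].
#' @param expected_count if given, the expected number of values
#'   (for `interleaved_pairs`, the number of peaks — the returned vector has
#'   `2 * expected_count` elements); a mismatch is an integrity error.
#' @return numeric vector of decoded values.
#' @export
decode_array <- function(b64, enc, expected_count = NULL) {
  stopifnot(inherits(enc, "ms_encoding"))
  b64 <- gsub("[[:space:]]+", "", b64)
  if (!nzchar(b64)) {
    bytes <- raw(0)
  } else {
    if (grepl("[^A-Za-z0-9+/=]", b64))
      ms_stop("codec_error", "invalid base64 character in binary data array")
    bytes <- tryCatch(jsonlite::base64_dec(b64),
                      error = function(e)
                        ms_stop("codec_error",
                                paste("invalid base64:", conditionMessage(e))))
  }
  if (enc$compression == "zlib" && length(bytes) > 0) {
    bytes <- tryCatch(memDecompress(bytes, type = "gzip"),
                      error = function(e)
                        ms_stop("codec_error",
                                paste("zlib decompression failed:",
                                      conditionMessage(e))))
  }
  size <- enc$precision / 8L
  if (length(bytes) %% size != 0)
    ms_stop("codec_error",
            sprintf("byte length %d is not a multiple of %d", length(bytes), size))
  vals <- readBin(bytes, "numeric", n = length(bytes) / size, size = size,
                  endian = enc$byte_order)
  if (enc$layout == "interleaved_pairs" && length(vals) %% 2 != 0)
    ms_stop("codec_error", "interleaved payload has odd value count")
  if (!is.null(expected_count)) {
    actual <- if (enc$layout == "interleaved_pairs") length(vals) / 2 else length(vals)
    if (actual != expected_count)
      ms_stop("integrity_error",
              sprintf("declared count %d but decoded %d values",
                      expected_count, actual),
              expected = expected_count, actual = actual)
  }
  vals
}

#' Encode values as a base64 binary data array
#'
#' Inverse of [decode_array()]: exact round-trip at 64-bit precision, within
#' 1e-6 relative at 32-bit.
#'
#' @param values finite numeric vector (for `interleaved_pairs` the values are
#'   already interleaved: mz1, int1, mz2, int2, ...).
#' @param enc an [ms_encoding()].
#' @return base64 text (empty string for an empty vector).
#' @export
encode_array <- function(values, enc) {
  stopifnot(inherits(enc, "ms_encoding"))
  if (length(values) == 0) return("")
  if (any(!is.finite(values)))
    ms_stop("codec_error", "cannot encode non-finite values")
  bytes <- writeBin(as.numeric(values), raw(), size = enc$precision / 8L,
                    endian = enc$byte_order)
  if (enc$compression == "zlib")
    bytes <- memCompress(bytes, type = "gzip")
  gsub("[\r\n]", "", jsonlite::base64_enc(bytes))
}

#' Parse an xs:duration (or bare-decimal) retention time into seconds
#'
#' Handles the subset used by mzXML `retentionTime` attributes, e.g.
#' `"PT60.5S"`, `"PT2M3S"`, `"P1DT1H"`. Real-world mzXML writers sometimes
#' emit a bare number of seconds; lenient mode (the default) accepts that.
#'
#' @param text the duration string.
#' @param lenient accept a bare decimal as seconds.
#' @return non-negative seconds (numeric).
#' @export
parse_duration <- function(text, lenient = TRUE) {
  text <- trimws(text)
  m <- regmatches(text, regexec(
    "^-?P(?:([0-9]+(?:\\.[0-9]+)?)D)?(?:T(?:([0-9]+(?:\\.[0-9]+)?)H)?(?:([0-9]+(?:\\.[0-9]+)?)M)?(?:([0-9]+(?:\\.[0-9]+)?)S)?)?$",
    text))[[1]]
  if (length(m) > 0 && nzchar(m[1]) && any(nzchar(m[-1]))) {
    num <- function(x) if (nzchar(x)) as.numeric(x) else 0
    return(num(m[2]) * 86400 + num(m[3]) * 3600 + num(m[4]) * 60 + num(m[5]))
  }
  if (lenient && grepl("^[0-9]+(\\.[0-9]+)?([eE][+-]?[0-9]+)?$", text))
    return(as.numeric(text))
  ms_stop("format_dialect",
          sprintf("unparseable duration '%s'", text), raw = text)
}

#' Parse an MGF-style charge string
#'
#' Accepts `"2+"`, `"+2"`, `"2"`, `"3-"` and comma- or "and"-separated lists
#' such as `"2+, 3+"` or `"2+ and 3+"`. Sign convention: `"2-"` is -2, a bare
#' `"2"` is +2.
#'
#' @param text the charge string.
#' @return integer vector of signed charges.
#' @export
parse_charge <- function(text) {
  tokens <- strsplit(trimws(text), "\\s*(,|\\band\\b)\\s*")[[1]]
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0)
    ms_stop("format_dialect", sprintf("empty charge string '%s'", text),
            raw = text)
  vapply(tokens, function(tk) {
    m <- regmatches(tk, regexec("^([+-]?)([0-9]+)([+-]?)$", tk))[[1]]
    if (length(m) == 0 || (nzchar(m[2]) && nzchar(m[4])))
      ms_stop("format_dialect",
              sprintf("unparseable charge token '%s'", tk), raw = text)
    z <- as.integer(m[3])
    if (identical(m[2], "-") || identical(m[4], "-")) z <- -z
    z
  }, integer(1), USE.NAMES = FALSE)
}

#' Convert a singly-protonated mass (M+H)+ to precursor m/z
#'
#' `mz = (mh_plus + (z - 1) * m_p) / z` with the proton mass
#' `m_p = 1.00727646688` Da. DTA headers and MS2 Z-lines store (M+H)+; the
#' common interface exposes m/z and keeps the raw (M+H)+ in extras.
#'
#' @param mh_plus (M+H)+ in Da, positive.
#' @param z charge state, integer >= 1.
#' @return m/z in Th.
#' @export
mh_to_mz <- function(mh_plus, z) {
  if (any(z < 1)) ms_stop("domain_error", "charge z must be >= 1")
  (mh_plus + (z - 1) * PROTON_MASS) / z
}

#' Convert a precursor m/z back to (M+H)+ for a given charge
#'
#' Exact inverse of [mh_to_mz()]; used by the fixture generator and the
#' DTA/MS2 writers.
#'
#' @param mz precursor m/z in Th.
#' @param z charge state, integer >= 1.
#' @return (M+H)+ in Da.
#' @export
mz_to_mh <- function(mz, z) {
  if (any(z < 1)) ms_stop("domain_error", "charge z must be >= 1")
  mz * z - (z - 1) * PROTON_MASS
}
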