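# Record-level parsers for the XML formats: mzXML (2.1-3.2), mzData (1.05)
# and a minimal mzML (1.1) subset. Each parses the bytes of ONE indexed
# element (as delimited by build_xml_index) into an ms_spectrum; xml2 does the
# element-scope parsing, the streaming byte scanner in index.R never builds a
# DOM of the whole file.
#
# Tag matching is namespace-agnostic (local names) because an element cut out
# of a document loses the root's default-namespace declaration.

xml_dialect <- function(format, version, namespace = "") {
  structure(list(format = format, version = version, namespace = namespace),
            class = "ms_xml_dialect")
}

#' Detect the XML dialect of an MS data file
#'
#' Reads at most the first 4 KiB and inspects the root element: `<mzXML>`
#' (version taken from its schema/namespace URI, e.g. `..._3.2`), `<mzData
#' version="1.05">`, or `<mzML>`/`<indexedmzML>` (attribute `version`).
#' mzXML versions outside 2.1-3.2 and mzData versions other than 1.05 parse
#' best-effort with a warning.
#'
#' @param path file path.
#' @return an `ms_xml_dialect` with fields `format`, `version`, `namespace`.
#' @export
detect_dialect <- function(path) {
  con <- tryCatch(file(path, "rb"),
                  error = function(e) ms_stop("io_error", conditionMessage(e)))
  head <- rawToChar(ms_read_bytes_con(con, 4096))
  close(con)
  Encoding(head) <- "latin1"
  root <- regmatches(head, regexec("<(mzXML|mzData|mzML|indexedmzML)[\\s>]",
                                   head, perl = TRUE))[[1]]
  if (length(root) == 0)
    ms_stop("unsupported_format",
            sprintf("no known XML root element (mzXML/mzData/mzML) in '%s'", path))
  root <- root[2]
  tag <- regmatches(head, regexec(sprintf("<%s[^>]*>", root), head))[[1]][1]
  ns <- extract_attr(tag, "xmlns") %||% ""
  if (root == "mzXML") {
    v <- regmatches(ns, regexec("mzXML_([0-9.]+)", ns))[[1]]
    version <- if (length(v) == 2) v[2] else extract_attr(tag, "version") %||% ""
    if (nzchar(version) &&
        (numeric_version(version) < "2.1" || numeric_version(version) > "3.2"))
      ms_warn("dialect", sprintf(
        "mzXML version %s outside supported 2.1-3.2; parsing best-effort", version))
    return(xml_dialect("mzxml", version, ns))
  }
  if (root == "mzData") {
    version <- extract_attr(tag, "version") %||% ""
    if (nzchar(version) && version != "1.05")
      ms_warn("dialect", sprintf(
        "mzData version %s is not 1.05; parsing best-effort", version))
    return(xml_dialect("mzdata", version, ns))
  }
  xml_dialect("mzml", extract_attr(tag, "version") %||% "1.1.0", ns)
}

# parse one element's bytes/text into an xml2 node
read_element <- function(x, what, source, position) {
  txt <- if (is.raw(x)) { t <- rawToChar(x); Encoding(t) <- "latin1"; t } else x
  tryCatch(xml2::read_xml(txt),
           error = function(e)
             ms_stop("malformed_record",
                     sprintf("unparseable %s element (%s, record %d): %s",
                             what, source, position, conditionMessage(e)),
                     source = source, position = position))
}

xfind1 <- function(node, name)
  xml2::xml_find_first(node, sprintf("./*[local-name()='%s']", name))

xfind <- function(node, name)
  xml2::xml_find_all(node, sprintf("./*[local-name()='%s']", name))

attr_or <- function(node, name, default = NULL) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) default else v
}

num_attr <- function(node, name) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) NULL else as.numeric(v)
}

# cvParam lookup: accession first, name (case-insensitive) as fallback
cv_value <- function(cv_nodes, accessions, names_) {
  acc <- xml2::xml_attr(cv_nodes, "accession")
  nm <- tolower(xml2::xml_attr(cv_nodes, "name"))
  hit <- which(acc %in% accessions)
  if (length(hit) == 0) hit <- which(nm %in% tolower(names_))
  if (length(hit) == 0) return(NULL)
  xml2::xml_attr(cv_nodes[[hit[1]]], "value")
}

cv_present <- function(cv_nodes, accessions, names_) {
  acc <- xml2::xml_attr(cv_nodes, "accession")
  nm <- tolower(xml2::xml_attr(cv_nodes, "name"))
  any(acc %in% accessions) || any(nm %in% tolower(names_))
}

cv_to_extras <- function(extras, cv_nodes, consumed_acc = character()) {
  for (cv in cv_nodes) {
    acc <- attr_or(cv, "accession", NA_character_)
    if (!is.na(acc) && acc %in% consumed_acc) next
    extras <- params_add(extras, attr_or(cv, "name", "cvParam"),
                         attr_or(cv, "value", NA_character_), acc)
  }
  extras
}

zip_peak_arrays <- function(mz, int, source, position) {
  if (length(mz) != length(int))
    ms_stop("integrity_error",
            sprintf("m/z array (%d) and intensity array (%d) differ in length (%s, record %d)",
                    length(mz), length(int), source, position))
  ms_peaks(mz, int)
}

#' Parse one mzXML `<scan>` element
#'
#' Maps `num` to the native id, `msLevel`, `retentionTime` (xs:duration via
#' [parse_duration()]), `polarity` (`+`/`-`); `<precursorMz>` text becomes the
#' precursor m/z with its `precursorIntensity`/`precursorCharge` attributes;
#' `<peaks>` is decoded as base64 big-endian ("network") interleaved
#' (m/z, intensity) pairs at the declared `precision`, with `compressionType`
#' zlib honored for mzXML >= 3.0. `peaksCount` is cross-checked against the
#' decoded pair count. Nested child `<scan>` elements inside the span are
#' ignored — they have their own spans. Unconsumed attributes are kept in
#' extras.
#'
#' @param element_bytes raw vector or text covering one `<scan>` element.
#' @param dialect an `ms_xml_dialect` from [detect_dialect()].
#' @param position 0-based spectrum ordinal.
#' @param source source path for messages and the spectrum record.
#' @return an `ms_spectrum`.
#' @export
parse_mzxml_scan <- function(element_bytes, dialect, position = 0,
                             source = "<mzxml>") {
  node <- read_element(element_bytes, "scan", source, position)
  for (child in xfind(node, "scan")) xml2::xml_remove(child)

  extras <- ms_params()
  atts <- xml2::xml_attrs(node)
  known <- c("num", "msLevel", "peaksCount", "retentionTime", "polarity")
  for (a in setdiff(names(atts), known))
    extras <- params_add(extras, a, atts[[a]])

  rt <- NULL
  rt_raw <- attr_or(node, "retentionTime")
  if (!is.null(rt_raw)) {
    rt <- parse_duration(rt_raw)
    extras <- params_add(extras, "retentionTime", rt_raw)
  }
  pol <- switch(attr_or(node, "polarity", ""),
                "+" = "positive", "-" = "negative", NULL)

  pre <- NULL
  pnode <- xfind1(node, "precursorMz")
  if (!inherits(pnode, "xml_missing")) {
    z <- num_attr(pnode, "precursorCharge")
    pre <- ms_precursor(mz = as.numeric(xml2::xml_text(pnode)),
                        intensity = num_attr(pnode, "precursorIntensity"),
                        charges = if (!is.null(z)) as.integer(z) else integer())
  }

  peaks <- ms_peaks()
  knode <- xfind1(node, "peaks")
  n_declared <- num_attr(node, "peaksCount")
  if (!inherits(knode, "xml_missing")) {
    comp <- attr_or(knode, "compressionType", "none")
    if (!comp %in% c("none", "zlib"))
      ms_stop("codec_error",
              sprintf("unknown compressionType '%s' (%s, record %d)",
                      comp, source, position))
    if (comp == "zlib" && nzchar(dialect$version) &&
        numeric_version(dialect$version) < "3.0")
      ms_stop("codec_error",
              sprintf("zlib compression is not legal in mzXML %s (%s, record %d)",
                      dialect$version, source, position))
    enc <- ms_encoding(precision = as.integer(attr_or(knode, "precision", "64")),
                       byte_order = "big", compression = comp,
                       layout = "interleaved_pairs")
    vals <- decode_array(xml2::xml_text(knode), enc,
                         expected_count = n_declared)
    if (length(vals) > 0) {
      idx <- seq(1, length(vals), by = 2)
      peaks <- ms_peaks(vals[idx], vals[idx + 1])
    }
    ct <- attr_or(knode, "contentType")
    if (!is.null(ct)) extras <- params_add(extras, "contentType", ct)
  } else if (!is.null(n_declared) && n_declared > 0) {
    ms_stop("integrity_error",
            sprintf("peaksCount=%d declared but no <peaks> element (%s, record %d)",
                    n_declared, source, position))
  }

  ms_lvl <- num_attr(node, "msLevel")
  s <- ms_spectrum(source, position, native_id = attr_or(node, "num"),
                   ms_level = ms_lvl, retention_seconds = rt, polarity = pol,
                   precursor = pre, peaks = peaks, extras = extras,
                   format = "mzxml")
  normalize_spectrum(s)
}

#' Parse one mzData `<spectrum>` element
#'
#' Maps the `id` attribute to the native id, `spectrumInstrument/@msLevel` to
#' the MS level, and the precursor `ionSelection` cvParams (mass-to-charge
#' PSI:1000040, charge state PSI:1000041, intensity PSI:1000042 — matched by
#' accession first, name as fallback) to the precursor. `mzArrayBinary` and
#' `intenArrayBinary` `<data>` payloads are decoded per their `precision` and
#' `endian` attributes as two separate arrays and zipped into peaks; the
#' declared `length` attributes are cross-checked.
#'
#' @inheritParams parse_mzxml_scan
#' @return an `ms_spectrum`.
#' @export
parse_mzdata_spectrum <- function(element_bytes, dialect, position = 0,
                                  source = "<mzdata>") {
  node <- read_element(element_bytes, "spectrum", source, position)
  extras <- ms_params()

  desc <- xfind1(node, "spectrumDesc")
  ms_lvl <- NULL; pre <- NULL
  if (!inherits(desc, "xml_missing")) {
    inst <- xml2::xml_find_first(
      desc, ".//*[local-name()='spectrumInstrument']")
    if (!inherits(inst, "xml_missing")) {
      ms_lvl <- num_attr(inst, "msLevel")
      for (a in c("mzRangeStart", "mzRangeStop")) {
        v <- attr_or(inst, a)
        if (!is.null(v)) extras <- params_add(extras, a, v)
      }
    }
    ion <- xml2::xml_find_first(desc, ".//*[local-name()='ionSelection']")
    if (!inherits(ion, "xml_missing")) {
      cvs <- xfind(ion, "cvParam")
      mzv <- cv_value(cvs, c("PSI:1000040", "MS:1000744"),
                      c("MassToChargeRatio", "mass to charge ratio", "m/z"))
      zv <- cv_value(cvs, c("PSI:1000041", "MS:1000041"),
                     c("ChargeState", "charge state"))
      iv <- cv_value(cvs, c("PSI:1000042", "MS:1000042"),
                     c("Intensity", "intensity"))
      if (!is.null(mzv))
        pre <- ms_precursor(mz = as.numeric(mzv),
                            intensity = if (!is.null(iv)) as.numeric(iv),
                            charges = if (!is.null(zv)) as.integer(zv)
                                      else integer())
      extras <- cv_to_extras(extras, cvs,
                             c("PSI:1000040", "PSI:1000041", "PSI:1000042",
                               "MS:1000744", "MS:1000041", "MS:1000042"))
    }
  }

  decode_mzdata_array <- function(name) {
    wrap <- xfind1(node, name)
    if (inherits(wrap, "xml_missing")) return(NULL)
    data <- xfind1(wrap, "data")
    if (inherits(data, "xml_missing")) return(NULL)
    declared <- num_attr(data, "length")
    enc <- ms_encoding(precision = as.integer(attr_or(data, "precision", "64")),
                       byte_order = attr_or(data, "endian", "big"),
                       compression = "none", layout = "single_array")
    decode_array(xml2::xml_text(data), enc, expected_count = declared)
  }
  mz <- decode_mzdata_array("mzArrayBinary")
  int <- decode_mzdata_array("intenArrayBinary")
  if (is.null(mz) != is.null(int))
    ms_stop("integrity_error",
            sprintf("only one of mzArrayBinary/intenArrayBinary present (%s, record %d)",
                    source, position))
  peaks <- if (is.null(mz)) ms_peaks()
           else zip_peak_arrays(mz, int, source, position)

  s <- ms_spectrum(source, position, native_id = attr_or(node, "id"),
                   ms_level = ms_lvl, precursor = pre, peaks = peaks,
                   extras = extras, format = "mzdata")
  normalize_spectrum(s)
}

#' Parse one mzML `<spectrum>` element
#'
#' Minimal mzML 1.1 subset: the `id` attribute is the native id (verbatim,
#' e.g. `"scan=1"`); cvParam MS:1000511 gives the MS level and
#' MS:1000129/MS:1000130 the polarity; `selectedIon` cvParams (MS:1000744
#' m/z, MS:1000041 charge, MS:1000042 intensity) give the precursor; the scan
#' start time (MS:1000016, minute or second units) gives the retention time.
#' Each `binaryDataArray` is classified by its cvParams — m/z MS:1000514 /
#' intensity MS:1000515, 64-bit MS:1000523 / 32-bit MS:1000521, zlib
#' MS:1000574 / none MS:1000576 — and decoded as a little-endian single
#' array; `defaultArrayLength` is cross-checked.
#'
#' @inheritParams parse_mzxml_scan
#' @return an `ms_spectrum`.
#' @export
parse_mzml_spectrum <- function(element_bytes, dialect, position = 0,
                                source = "<mzml>") {
  node <- read_element(element_bytes, "spectrum", source, position)
  extras <- ms_params()
  declared <- num_attr(node, "defaultArrayLength")

  cvs <- xfind(node, "cvParam")
  lvl <- cv_value(cvs, "MS:1000511", "ms level")
  pol <- if (cv_present(cvs, "MS:1000130", "positive scan")) "positive"
         else if (cv_present(cvs, "MS:1000129", "negative scan")) "negative"
  extras <- cv_to_extras(extras, cvs,
                         c("MS:1000511", "MS:1000130", "MS:1000129"))

  rt <- NULL
  scan <- xml2::xml_find_first(
    node, ".//*[local-name()='scanList']/*[local-name()='scan']")
  if (!inherits(scan, "xml_missing")) {
    scvs <- xfind(scan, "cvParam")
    stime <- cv_value(scvs, "MS:1000016", "scan start time")
    if (!is.null(stime)) {
      hit <- which(xml2::xml_attr(scvs, "accession") == "MS:1000016" |
                   tolower(xml2::xml_attr(scvs, "name")) == "scan start time")
      unit <- tolower(attr_or(scvs[[hit[1]]], "unitName", "second"))
      rt <- as.numeric(stime) * if (unit == "minute") 60 else 1
    }
  }

  pre <- NULL
  ion <- xml2::xml_find_first(node, ".//*[local-name()='selectedIon']")
  if (!inherits(ion, "xml_missing")) {
    icvs <- xfind(ion, "cvParam")
    mzv <- cv_value(icvs, "MS:1000744", "selected ion m/z")
    zv <- cv_value(icvs, "MS:1000041", "charge state")
    iv <- cv_value(icvs, "MS:1000042", "peak intensity")
    if (!is.null(mzv))
      pre <- ms_precursor(mz = as.numeric(mzv),
                          intensity = if (!is.null(iv)) as.numeric(iv),
                          charges = if (!is.null(zv)) as.integer(zv)
                                    else integer())
  }

  arrays <- xml2::xml_find_all(
    node, ".//*[local-name()='binaryDataArrayList']/*[local-name()='binaryDataArray']")
  mz <- NULL; int <- NULL
  for (arr in arrays) {
    acvs <- xfind(arr, "cvParam")
    is_mz <- cv_present(acvs, "MS:1000514", "m/z array")
    is_int <- cv_present(acvs, "MS:1000515", "intensity array")
    if (!is_mz && !is_int)
      ms_stop("format_dialect",
              sprintf("binaryDataArray without m/z-array or intensity-array cvParam (%s, record %d)",
                      source, position))
    precision <- if (cv_present(acvs, "MS:1000523", "64-bit float")) 64
                 else if (cv_present(acvs, "MS:1000521", "32-bit float")) 32
                 else ms_stop("format_dialect",
                              sprintf("binaryDataArray without precision cvParam (%s, record %d)",
                                      source, position))
    comp <- if (cv_present(acvs, "MS:1000574", "zlib compression")) "zlib"
            else "none"
    enc <- ms_encoding(precision = precision, byte_order = "little",
                       compression = comp, layout = "single_array")
    bin <- xfind1(arr, "binary")
    vals <- decode_array(if (inherits(bin, "xml_missing")) ""
                         else xml2::xml_text(bin), enc,
                         expected_count = declared)
    if (is_mz) mz <- vals else int <- vals
  }
  if (is.null(mz) != is.null(int))
    ms_stop("integrity_error",
            sprintf("only one of m/z/intensity arrays present (%s, record %d)",
                    source, position))
  peaks <- if (is.null(mz)) ms_peaks()
           else zip_peak_arrays(mz, int, source, position)
  if (!is.null(declared) && declared > 0 && nrow(peaks) != declared)
    ms_stop("integrity_error",
            sprintf("defaultArrayLength=%d but %d peaks decoded (%s, record %d)",
                    declared, nrow(peaks), source, position))

  s <- ms_spectrum(source, position, native_id = attr_or(node, "id"),
                   ms_level = if (!is.null(lvl)) as.integer(lvl),
                   retention_seconds = rt, polarity = pol, precursor = pre,
                   peaks = peaks, extras = extras, format = "mzml")
  normalize_spectrum(s)
}
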