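# Synthetic-data generator: deterministic random spectra and test-grade
# writers for all seven formats (plus DTA/PKL directory mode and corrupted
# variants). These writers emit minimal valid documents — enough structure to
# exercise every reader, declared counts and required attributes included —
# and define the "printed precision" of the text formats: m/z with 6
# decimals, intensity with 4. The generator rounds values to those precisions
# up front so the same spectra survive every format's round trip exactly
# (64-bit paths bit-exact, text paths decimal-exact).

#' Describe a synthetic fixture
#'
#' @param n_spectra number of spectra.
#' @param peaks_per_spectrum integer range `c(min, max)`.
#' @param mz_range peak m/z range `c(low, high)` in Th.
#' @param seed RNG seed; the same spec always yields byte-identical fixtures.
#' @param ms_level_pattern recycled over spectra (e.g. `c(1, 2)` alternates
#'   survey and fragment scans). Default: all MS2, the common case for the
#'   peak-list formats (DTA/PKL/MS2 can only express fragment spectra).
#' @param charge_set precursor charges to draw from.
#' @return an object of class `ms_fixture_spec`.
#' @export
fixture_spec <- function(n_spectra = 10, peaks_per_spectrum = c(5, 20),
                         mz_range = c(100, 2000), seed = 1,
                         ms_level_pattern = 2, charge_set = c(2, 3)) {
  if (length(mz_range) != 2 || mz_range[2] <= mz_range[1])
    ms_stop("domain_error", "mz_range must be c(low, high) with low < high")
  if (n_spectra < 0) ms_stop("domain_error", "n_spectra must be >= 0")
  structure(list(n_spectra = as.integer(n_spectra),
                 peaks_per_spectrum = as.integer(peaks_per_spectrum),
                 mz_range = as.numeric(mz_range), seed = as.integer(seed),
                 ms_level_pattern = as.integer(ms_level_pattern),
                 charge_set = as.integer(charge_set)),
            class = "ms_fixture_spec")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Generate deterministic synthetic spectra
#'
#' Peak m/z values are uniform over `mz_range` (sorted ascending), intensities
#' log-uniform in [1, 1e6]. MS>=2 spectra get a precursor: charge drawn from
#' `charge_set`, m/z uniform over `mz_range`, (M+H)+ derived exactly via
#' [mz_to_mh()] so the DTA round trip through [mh_to_mz()] is closed.
#' Retention times increase monotonically. All values are pre-rounded to the
#' text writers' printed precision (m/z 1e-6, intensity 1e-4).
#'
#' @param spec an [fixture_spec()].
#' @return list of `ms_spectrum`.
#' @export
generate_spectra <- function(spec) {
  stopifnot(inherits(spec, "ms_fixture_spec"))
  with_seed(spec$seed, {
    lapply(seq_len(spec$n_spectra), function(i) {
      lvl <- spec$ms_level_pattern[(i - 1) %% length(spec$ms_level_pattern) + 1]
      npk_range <- spec$peaks_per_spectrum[1]:spec$peaks_per_spectrum[2]
      npk <- npk_range[sample.int(length(npk_range), 1)]
      mz <- round(sort(runif(npk, spec$mz_range[1], spec$mz_range[2])), 6)
      int <- round(10^runif(npk, 0, 6), 4)
      pre <- NULL
      if (lvl >= 2) {
        z <- spec$charge_set[sample.int(length(spec$charge_set), 1)]
        pmz <- round(runif(1, spec$mz_range[1], spec$mz_range[2]), 6)
        pre <- ms_precursor(mz = pmz, mh_plus = mz_to_mh(pmz, z),
                            intensity = round(10^runif(1, 2, 6), 4),
                            charges = z)
      }
      normalize_spectrum(ms_spectrum(
        source = "synthetic", position = i - 1L, ms_level = lvl,
        retention_seconds = round(i * 1.5 + runif(1), 4),
        polarity = "positive", precursor = pre,
        peaks = ms_peaks(mz, int), format = NULL))
    })
  })
}

fmt_mz <- function(x) sprintf("%.6f", x)
fmt_int <- function(x) sprintf("%.4f", x)

need_precursor <- function(s, format) {
  p <- s$precursor
  if (is.null(p) || length(p$charges) < 1)
    ms_stop("domain_error",
            sprintf("%s cannot express a spectrum without precursor and charge",
                    format))
  p
}

write_dta_text <- function(spectra) {
  vapply(spectra, function(s) {
    p <- need_precursor(s, "DTA")
    mh <- p$mh_plus %||% mz_to_mh(p$mz, p$charges[1])
    paste(c(paste(fmt_mz(mh), p$charges[1]),
            paste(fmt_mz(s$peaks$mz), fmt_int(s$peaks$intensity))),
          collapse = "\n")
  }, character(1))
}

write_pkl_text <- function(spectra) {
  vapply(spectra, function(s) {
    p <- need_precursor(s, "PKL")
    paste(c(paste(fmt_mz(p$mz), fmt_int(p$intensity %||% 0), p$charges[1]),
            paste(fmt_mz(s$peaks$mz), fmt_int(s$peaks$intensity))),
          collapse = "\n")
  }, character(1))
}

write_mgf_text <- function(spectra, header = TRUE) {
  blocks <- vapply(seq_along(spectra), function(i) {
    s <- spectra[[i]]
    out <- c("BEGIN IONS", sprintf("TITLE=synthetic spectrum %d", i - 1))
    p <- s$precursor
    if (!is.null(p) && !is.null(p$mz)) {
      pm <- paste0("PEPMASS=", fmt_mz(p$mz))
      if (!is.null(p$intensity)) pm <- paste(pm, fmt_int(p$intensity))
      out <- c(out, pm)
    }
    if (!is.null(p) && length(p$charges) > 0)
      out <- c(out, paste0("CHARGE=", paste(vapply(p$charges,
        format_charge_token, character(1)), collapse = " and ")))
    if (!is.null(s$retention_seconds))
      out <- c(out, paste0("RTINSECONDS=", s$retention_seconds))
    if (nrow(s$peaks) > 0)
      out <- c(out, paste(fmt_mz(s$peaks$mz), fmt_int(s$peaks$intensity)))
    paste(c(out, "END IONS"), collapse = "\n")
  }, character(1))
  hdr <- if (header) "COM=msreadr synthetic fixture\n\n" else ""
  paste0(hdr, paste(blocks, collapse = "\n\n"), "\n")
}

write_ms2_text <- function(spectra) {
  blocks <- vapply(seq_along(spectra), function(i) {
    s <- spectra[[i]]
    p <- need_precursor(s, "MS2")
    scan <- i
    out <- sprintf("S\t%d\t%d\t%s", scan, scan, fmt_mz(p$mz))
    if (!is.null(s$retention_seconds))
      out <- c(out, sprintf("I\tRTime\t%s", s$retention_seconds))
    for (z in p$charges)
      out <- c(out, sprintf("Z\t%d\t%s", z, fmt_mz(mz_to_mh(p$mz, z))))
    if (nrow(s$peaks) > 0)
      out <- c(out, paste(fmt_mz(s$peaks$mz), fmt_int(s$peaks$intensity)))
    paste(out, collapse = "\n")
  }, character(1))
  paste0("H\tCreationDate\tsynthetic\nH\tExtractor\tmsreadr fixtures\n",
         paste(blocks, collapse = "\n"), "\n")
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

write_mzxml_text <- function(spectra, version = "3.2", precision = 64,
                             compression = "none", nested = FALSE) {
  if (compression == "zlib" && numeric_version(version) < "3.0")
    ms_stop("domain_error",
            sprintf("zlib is not legal in mzXML %s", version))
  enc <- ms_encoding(precision, "big", compression, "interleaved_pairs")
  comp_attr <- if (compression == "zlib") " compressionType=\"zlib\"" else ""
  scan_xml <- function(s, i, indent, close = TRUE) {
    p <- s$precursor
    vals <- as.vector(rbind(s$peaks$mz, s$peaks$intensity))
    pre_xml <- if (!is.null(p) && !is.null(p$mz))
      sprintf("%s  <precursorMz precursorIntensity=\"%s\" precursorCharge=\"%d\">%s</precursorMz>\n",
              indent, fmt_int(p$intensity %||% 0), p$charges[1], fmt_mz(p$mz))
    else ""
    paste0(sprintf(
      "%s<scan num=\"%d\" msLevel=\"%d\" peaksCount=\"%d\" polarity=\"%s\" retentionTime=\"PT%sS\">\n",
      indent, i, s$ms_level %||% 2L, nrow(s$peaks),
      if (identical(s$polarity, "negative")) "-" else "+",
      s$retention_seconds %||% 0),
      pre_xml,
      sprintf("%s  <peaks precision=\"%d\" byteOrder=\"network\" contentType=\"m/z-int\"%s>%s</peaks>\n",
              indent, precision, comp_attr, encode_array(vals, enc)),
      if (close) sprintf("%s</scan>\n", indent) else "")
  }
  body <- character()
  if (nested) {
    # pair up: odd spectra are parents, the following spectrum nests inside
    i <- 1
    while (i <= length(spectra)) {
      if (i + 1 <= length(spectra)) {
        body <- c(body, scan_xml(spectra[[i]], i, "  ", close = FALSE),
                  scan_xml(spectra[[i + 1]], i + 1, "    "), "  </scan>\n")
        i <- i + 2
      } else {
        body <- c(body, scan_xml(spectra[[i]], i, "  "))
        i <- i + 1
      }
    }
  } else {
    body <- vapply(seq_along(spectra),
                   function(i) scan_xml(spectra[[i]], i, "  "), character(1))
  }
  paste0(sprintf(
    "<?xml version=\"1.0\" encoding=\"ISO-8859-1\"?>\n<mzXML xmlns=\"http://sashimi.sourceforge.net/schema_revision/mzXML_%s\">\n <msRun scanCount=\"%d\">\n",
    version, length(spectra)),
    paste(body, collapse = ""),
    " </msRun>\n</mzXML>\n")
}

write_mzdata_text <- function(spectra, precision = 64, endian = "big",
                              id_start = 1) {
  enc <- ms_encoding(precision, endian, "none", "single_array")
  blocks <- vapply(seq_along(spectra), function(i) {
    s <- spectra[[i]]
    p <- s$precursor
    pre_xml <- if (!is.null(p) && !is.null(p$mz)) paste0(
      "      <precursorList count=\"1\">\n",
      "        <precursor msLevel=\"1\" spectrumRef=\"0\">\n",
      "          <ionSelection>\n",
      sprintf("            <cvParam cvLabel=\"psi\" accession=\"PSI:1000040\" name=\"MassToChargeRatio\" value=\"%s\"/>\n",
              fmt_mz(p$mz)),
      if (length(p$charges) > 0)
        sprintf("            <cvParam cvLabel=\"psi\" accession=\"PSI:1000041\" name=\"ChargeState\" value=\"%d\"/>\n",
                p$charges[1]) else "",
      if (!is.null(p$intensity))
        sprintf("            <cvParam cvLabel=\"psi\" accession=\"PSI:1000042\" name=\"Intensity\" value=\"%s\"/>\n",
                fmt_int(p$intensity)) else "",
      "          </ionSelection>\n",
      "          <activation/>\n",
      "        </precursor>\n",
      "      </precursorList>\n") else ""
    paste0(sprintf("    <spectrum id=\"%d\">\n", id_start + i - 1),
      "      <spectrumDesc>\n",
      "        <spectrumSettings>\n",
      sprintf("          <spectrumInstrument msLevel=\"%d\"/>\n",
              s$ms_level %||% 2L),
      "        </spectrumSettings>\n",
      pre_xml,
      "      </spectrumDesc>\n",
      sprintf("      <mzArrayBinary><data precision=\"%d\" endian=\"%s\" length=\"%d\">%s</data></mzArrayBinary>\n",
              precision, endian, nrow(s$peaks),
              encode_array(s$peaks$mz, enc)),
      sprintf("      <intenArrayBinary><data precision=\"%d\" endian=\"%s\" length=\"%d\">%s</data></intenArrayBinary>\n",
              precision, endian, nrow(s$peaks),
              encode_array(s$peaks$intensity, enc)),
      "    </spectrum>\n")
  }, character(1))
  paste0("<?xml version=\"1.0\" encoding=\"ISO-8859-1\"?>\n",
         "<mzData version=\"1.05\" accessionNumber=\"0\">\n",
         sprintf("  <spectrumList count=\"%d\">\n", length(spectra)),
         paste(blocks, collapse = ""),
         "  </spectrumList>\n</mzData>\n")
}

write_mzml_text <- function(spectra, precision = 64, compression = "none") {
  enc <- ms_encoding(precision, "little", compression, "single_array")
  prec_cv <- if (precision == 64)
    "<cvParam cvRef=\"MS\" accession=\"MS:1000523\" name=\"64-bit float\"/>"
  else
    "<cvParam cvRef=\"MS\" accession=\"MS:1000521\" name=\"32-bit float\"/>"
  comp_cv <- if (compression == "zlib")
    "<cvParam cvRef=\"MS\" accession=\"MS:1000574\" name=\"zlib compression\"/>"
  else
    "<cvParam cvRef=\"MS\" accession=\"MS:1000576\" name=\"no compression\"/>"
  bda <- function(b64, type_cv) paste0(
    "          <binaryDataArray encodedLength=\"", nchar(b64), "\">\n",
    "            ", prec_cv, "\n",
    "            ", comp_cv, "\n",
    "            ", type_cv, "\n",
    "            <binary>", b64, "</binary>\n",
    "          </binaryDataArray>\n")
  blocks <- vapply(seq_along(spectra), function(i) {
    s <- spectra[[i]]
    p <- s$precursor
    pre_xml <- if (!is.null(p) && !is.null(p$mz)) paste0(
      "        <precursorList count=\"1\">\n",
      "          <precursor>\n",
      "            <selectedIonList count=\"1\">\n",
      "              <selectedIon>\n",
      sprintf("                <cvParam cvRef=\"MS\" accession=\"MS:1000744\" name=\"selected ion m/z\" value=\"%s\"/>\n",
              fmt_mz(p$mz)),
      if (length(p$charges) > 0)
        sprintf("                <cvParam cvRef=\"MS\" accession=\"MS:1000041\" name=\"charge state\" value=\"%d\"/>\n",
                p$charges[1]) else "",
      if (!is.null(p$intensity))
        sprintf("                <cvParam cvRef=\"MS\" accession=\"MS:1000042\" name=\"peak intensity\" value=\"%s\"/>\n",
                fmt_int(p$intensity)) else "",
      "              </selectedIon>\n",
      "            </selectedIonList>\n",
      "          </precursor>\n",
      "        </precursorList>\n") else ""
    rt_xml <- if (!is.null(s$retention_seconds)) paste0(
      "        <scanList count=\"1\">\n          <scan>\n",
      sprintf("            <cvParam cvRef=\"MS\" accession=\"MS:1000016\" name=\"scan start time\" value=\"%s\" unitName=\"second\"/>\n",
              s$retention_seconds),
      "          </scan>\n        </scanList>\n") else ""
    pol_cv <- if (identical(s$polarity, "negative"))
      "        <cvParam cvRef=\"MS\" accession=\"MS:1000129\" name=\"negative scan\"/>\n"
    else
      "        <cvParam cvRef=\"MS\" accession=\"MS:1000130\" name=\"positive scan\"/>\n"
    paste0(sprintf(
      "      <spectrum index=\"%d\" id=\"scan=%d\" defaultArrayLength=\"%d\">\n",
      i - 1, i, nrow(s$peaks)),
      sprintf("        <cvParam cvRef=\"MS\" accession=\"MS:1000511\" name=\"ms level\" value=\"%d\"/>\n",
              s$ms_level %||% 2L),
      pol_cv, rt_xml, pre_xml,
      "        <binaryDataArrayList count=\"2\">\n",
      bda(encode_array(s$peaks$mz, enc),
          "<cvParam cvRef=\"MS\" accession=\"MS:1000514\" name=\"m/z array\"/>"),
      bda(encode_array(s$peaks$intensity, enc),
          "<cvParam cvRef=\"MS\" accession=\"MS:1000515\" name=\"intensity array\"/>"),
      "        </binaryDataArrayList>\n",
      "      </spectrum>\n")
  }, character(1))
  paste0("<?xml version=\"1.0\" encoding=\"utf-8\"?>\n",
         "<mzML xmlns=\"http://psi.hupo.org/ms/mzml\" version=\"1.1.0\">\n",
         "  <run id=\"synthetic\">\n",
         sprintf("    <spectrumList count=\"%d\" defaultDataProcessingRef=\"dp\">\n",
                 length(spectra)),
         paste(blocks, collapse = ""),
         "    </spectrumList>\n  </run>\n</mzML>\n")
}

write_text_file <- function(text, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(text), con)
  path
}

#' Write synthetic spectra to any of the seven formats
#'
#' @param spectra list of `ms_spectrum` (e.g. from [generate_spectra()]).
#' @param format target format id.
#' @param destination output file path, or directory path when
#'   `directory = TRUE`.
#' @param version mzXML version string ("2.1".."3.2"); mzData is always 1.05,
#'   mzML 1.1.0.
#' @param precision 32 or 64 (XML formats).
#' @param compression "none" or "zlib" (mzXML >= 3.0 and mzML only; a domain
#'   error otherwise).
#' @param endian "big" or "little" (mzData only; it is the only format with
#'   an explicit endian attribute).
#' @param directory write one file per spectrum (DTA/PKL only), named
#'   `spec_000.dta` etc.
#' @param nested nest each even-position scan inside the preceding one
#'   (mzXML only; exercises nested-scan flattening).
#' @param id_start first mzData spectrum id.
#' @return the path(s) written, invisibly.
#' @export
write_fixture <- function(spectra, format, destination, version = "3.2",
                          precision = 64, compression = "none",
                          endian = "big", directory = FALSE, nested = FALSE,
                          id_start = 1) {
  format <- match.arg(tolower(format), ms_formats())
  if (directory) {
    if (!format %in% c("dta", "pkl"))
      ms_stop("domain_error", "directory mode exists only for DTA and PKL")
    if (!dir.exists(destination)) dir.create(destination, recursive = TRUE)
    texts <- if (format == "dta") write_dta_text(spectra)
             else write_pkl_text(spectra)
    paths <- file.path(destination,
                       sprintf("spec_%03d.%s", seq_along(spectra) - 1, format))
    for (k in seq_along(paths))
      write_text_file(paste0(texts[k], "\n"), paths[k])
    return(invisible(paths))
  }
  if (compression == "zlib" && !format %in% c("mzxml", "mzml"))
    ms_stop("domain_error",
            sprintf("zlib is not supported by format '%s'", format))
  text <- switch(format,
    dta = paste0(paste(write_dta_text(spectra), collapse = "\n\n"), "\n"),
    pkl = paste0(paste(write_pkl_text(spectra), collapse = "\n\n"), "\n"),
    mgf = write_mgf_text(spectra),
    ms2 = write_ms2_text(spectra),
    mzxml = write_mzxml_text(spectra, version, precision, compression, nested),
    mzdata = write_mzdata_text(spectra, precision, endian, id_start),
    mzml = write_mzml_text(spectra, precision, compression))
  invisible(write_text_file(text, destination))
}

#' Corrupt a fixture to trigger a documented error class
#'
#' Mutations: `truncate_tail` drops the last quarter of the file (stale-index
#' / truncation errors), `garble_base64` injects an illegal character into
#' the first binary payload (codec error), `drop_end_ions` removes the first
#' `END IONS` line of an MGF (malformed record), `bad_count_attr` increments
#' the first declared count attribute (integrity error).
#'
#' @param path fixture file; mutated in place.
#' @param mutation one of the four mutation names.
#' @return `path`, invisibly.
#' @export
corrupt_fixture <- function(path,
                            mutation = c("truncate_tail", "garble_base64",
                                         "drop_end_ions", "bad_count_attr")) {
  mutation <- match.arg(mutation)
  raw <- readBin(path, "raw", file.size(path))
  txt <- rawToChar(raw)
  Encoding(txt) <- "latin1"
  out <- switch(mutation,
    truncate_tail = {
      writeBin(raw[seq_len(floor(length(raw) * 0.75))], path)
      return(invisible(path))
    },
    garble_base64 = {
      m <- regexpr(">[A-Za-z0-9+/=]{8,}<", txt)
      if (m == -1) ms_stop("domain_error", "no base64 payload found")
      substr(txt, m + 2, m + 4) <- "*?*"
      txt
    },
    drop_end_ions = sub("END IONS\r?\n?", "", txt),
    bad_count_attr = {
      m <- regexpr("(peaksCount|defaultArrayLength|length)=\"[0-9]+\"", txt)
      if (m == -1) ms_stop("domain_error", "no count attribute found")
      attrtxt <- regmatches(txt, m)
      n <- as.integer(sub(".*=\"([0-9]+)\"", "\\1", attrtxt))
      regmatches(txt, m) <- sub("\"[0-9]+\"", sprintf("\"%d\"", n + 1), attrtxt)
      txt
    })
  write_text_file(out, path)
  invisible(path)
}
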