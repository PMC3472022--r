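# Shared fixtures and independent oracle routes used across test files.

BUF <- 1048576  # the package's buffered-read chunk size

# Write the same spectra to every format; returns named list of paths.
all_format_files <- function(spectra, dir, ...) {
  paths <- list()
  for (f in ms_formats()) {
    p <- file.path(dir, paste0("fixture.", f))
    write_fixture(spectra, f, p, ...)
    paths[[f]] <- p
  }
  paths
}

std_spectra <- function(n = 5, seed = 7, ...)
  generate_spectra(fixture_spec(n_spectra = n, seed = seed, ...))

# ---- independent sequential-parse oracle for the text formats --------------
# Locates records by reading the whole file with readLines and simple
# splitting logic, i.e. a route that shares nothing with the byte-range
# indexer. Returns the list of record texts in file order.
oracle_split_records <- function(path, format) {
  ln <- readLines(path, warn = FALSE)
  if (format == "mgf") {
    starts <- grep("^BEGIN IONS", ln)
    ends <- grep("^END IONS", ln)
    mapply(function(a, b) paste(ln[a:b], collapse = "\n"),
           starts, ends, SIMPLIFY = FALSE)
  } else if (format == "ms2") {
    starts <- grep("^S[ \t]", ln)
    stops <- c(starts[-1] - 1, length(ln))
    mapply(function(a, b) paste(ln[a:b], collapse = "\n"),
           starts, stops, SIMPLIFY = FALSE)
  } else {
    blank <- grepl("^[ \t]*$", ln)
    grp <- cumsum(blank)[!blank]
    lapply(unname(split(ln[!blank], grp)), paste, collapse = "\n")
  }
}

# ---- independent full-document oracle for the XML formats ------------------
# Parses the whole document with xml2 (DOM route) and extracts ids and peak
# arrays directly, without the indexer or the record-level parsers. The
# base64/IEEE-754 codec is shared, but it is itself pinned against
# independently computed values in test-codec.R.
oracle_xml_spectra <- function(path, format) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  if (format == "mzxml") {
    nodes <- xml2::xml_find_all(doc, "//scan")
    lapply(nodes, function(nd) {
      pk <- xml2::xml_find_first(nd, "./peaks")
      comp <- xml2::xml_attr(pk, "compressionType")
      enc <- ms_encoding(as.integer(xml2::xml_attr(pk, "precision")), "big",
                         if (!is.na(comp) && comp == "zlib") "zlib" else "none",
                         "interleaved_pairs")
      v <- decode_array(xml2::xml_text(pk), enc)
      idx <- seq_len(length(v) / 2) * 2 - 1
      list(id = xml2::xml_attr(nd, "num"), mz = v[idx], intensity = v[idx + 1])
    })
  } else if (format == "mzdata") {
    nodes <- xml2::xml_find_all(doc, "//spectrumList/spectrum")
    lapply(nodes, function(nd) {
      dec <- function(which) {
        d <- xml2::xml_find_first(nd, sprintf("./%s/data", which))
        enc <- ms_encoding(as.integer(xml2::xml_attr(d, "precision")),
                           xml2::xml_attr(d, "endian"), "none", "single_array")
        decode_array(xml2::xml_text(d), enc)
      }
      list(id = xml2::xml_attr(nd, "id"),
           mz = dec("mzArrayBinary"), intensity = dec("intenArrayBinary"))
    })
  } else {
    nodes <- xml2::xml_find_all(doc, "//spectrumList/spectrum")
    lapply(nodes, function(nd) {
      arrays <- xml2::xml_find_all(nd, ".//binaryDataArray")
      out <- list(id = xml2::xml_attr(nd, "id"))
      for (a in arrays) {
        accs <- xml2::xml_attr(xml2::xml_find_all(a, "./cvParam"), "accession")
        enc <- ms_encoding(if ("MS:1000523" %in% accs) 64 else 32, "little",
                           if ("MS:1000574" %in% accs) "zlib" else "none",
                           "single_array")
        v <- decode_array(xml2::xml_text(xml2::xml_find_first(a, "./binary")), enc)
        if ("MS:1000514" %in% accs) out$mz <- v else out$intensity <- v
      }
      out
    })
  }
}

xml_dialect_for_tests <- function(format,
                                  version = switch(format, mzxml = "3.2",
                                                   mzdata = "1.05", "1.1.0"))
  msreadr:::xml_dialect(format, version)

expect_ms_error <- function(expr, class) {
  expect_error(expr, class = paste0("msreadr_", class))
}
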