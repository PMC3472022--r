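test_that("detect_dialect identifies the three XML dialects and rejects others", {
  d <- withr::local_tempdir()
  sp <- std_spectra(2, seed = 31)

  p <- file.path(d, "a.mzxml")
  write_fixture(sp, "mzxml", p, version = "3.2")
  dia <- detect_dialect(p)
  expect_equal(dia$format, "mzxml")
  expect_equal(dia$version, "3.2")

  p2 <- file.path(d, "a.mzdata")
  write_fixture(sp, "mzdata", p2)
  dia2 <- detect_dialect(p2)
  expect_equal(dia2$format, "mzdata")
  expect_equal(dia2$version, "1.05")

  p3 <- file.path(d, "a.mzml")
  write_fixture(sp, "mzml", p3)
  expect_equal(detect_dialect(p3)$format, "mzml")

  p4 <- file.path(d, "a.mgf")
  write_fixture(sp, "mgf", p4)
  expect_ms_error(detect_dialect(p4), "unsupported_format")
})

test_that("mzXML versions 2.1 and 3.2 both parse; out-of-range versions warn", {
  d <- withr::local_tempdir()
  sp <- std_spectra(3, seed = 37)
  for (v in c("2.1", "3.2")) {
    p <- file.path(d, paste0("v", v, ".mzxml"))
    write_fixture(sp, "mzxml", p, version = v)
    r <- open_reader(p)
    expect_equal(r$dialect$version, v)
    expect_equal(get_spectra_count(r), 3)
    expect_identical(get_spectrum_by_index(r, 0)$peaks$mz, sp[[1]]$peaks$mz)
  }
  p <- file.path(d, "v1.1.mzxml")
  write_fixture(sp, "mzxml", p, version = "1.1")
  expect_warning(detect_dialect(p), class = "msreadr_warning")
})

test_that("parse_mzxml_scan maps attributes and decodes interleaved peaks", {
  dia <- xml_dialect_for_tests("mzxml")
  payload <- encode_array(c(100, 10, 200, 20),
                          ms_encoding(64, "big", layout = "interleaved_pairs"))
  el <- sprintf(paste0(
    '<scan num="7" msLevel="2" peaksCount="2" polarity="+" retentionTime="PT1.5S">',
    '<precursorMz precursorIntensity="1250" precursorCharge="2">701.7</precursorMz>',
    '<peaks precision="64" byteOrder="network">%s</peaks></scan>'), payload)
  s <- parse_mzxml_scan(el, dia, position = 0)
  expect_equal(s$native_id, "7")
  expect_equal(s$ms_level, 2L)
  expect_equal(s$retention_seconds, 1.5)
  expect_equal(s$polarity, "positive")
  expect_equal(s$precursor$mz, 701.7)
  expect_equal(s$precursor$charges, 2L)
  expect_equal(s$peaks$mz, c(100, 200))
  expect_equal(s$peaks$intensity, c(10, 20))

  # declared count disagrees with payload
  el_bad <- sub('peaksCount="2"', 'peaksCount="3"', el, fixed = TRUE)
  expect_ms_error(parse_mzxml_scan(el_bad, dia, 0), "integrity_error")

  # msLevel optional
  el_nolvl <- sub(' msLevel="2"', "", el, fixed = TRUE)
  expect_null(parse_mzxml_scan(el_nolvl, dia, 0)$ms_level)

  # unknown compression is a codec error; zlib in mzXML < 3.0 is illegal
  el_comp <- sub("<peaks ", '<peaks compressionType="lzma" ', el, fixed = TRUE)
  expect_ms_error(parse_mzxml_scan(el_comp, dia, 0), "codec_error")
  dia21 <- xml_dialect_for_tests("mzxml", "2.1")
  el_z <- sub("<peaks ", '<peaks compressionType="zlib" ', el, fixed = TRUE)
  expect_ms_error(parse_mzxml_scan(el_z, dia21, 0), "codec_error")
})

test_that("parse_mzdata_spectrum handles both endiannesses identically", {
  dia <- xml_dialect_for_tests("mzdata")
  mk <- function(endian) {
    enc <- ms_encoding(64, endian)
    sprintf(paste0(
      '<spectrum id="10"><spectrumDesc><spectrumSettings>',
      '<spectrumInstrument msLevel="2"/></spectrumSettings>',
      '<precursorList count="1"><precursor msLevel="1" spectrumRef="0"><ionSelection>',
      '<cvParam accession="PSI:1000040" name="MassToChargeRatio" value="701.7"/>',
      '<cvParam accession="PSI:1000041" name="ChargeState" value="2"/>',
      '</ionSelection></precursor></precursorList></spectrumDesc>',
      '<mzArrayBinary><data precision="64" endian="%s" length="2">%s</data></mzArrayBinary>',
      '<intenArrayBinary><data precision="64" endian="%s" length="2">%s</data></intenArrayBinary>',
      '</spectrum>'),
      endian, encode_array(c(100, 200), enc),
      endian, encode_array(c(10, 20), enc))
  }
  sb <- parse_mzdata_spectrum(mk("big"), dia, 0)
  sl <- parse_mzdata_spectrum(mk("little"), dia, 0)
  expect_equal(sb$native_id, "10")
  expect_equal(sb$ms_level, 2L)
  expect_equal(sb$precursor$mz, 701.7)
  expect_equal(sb$precursor$charges, 2L)
  expect_identical(sb$peaks, sl$peaks)
  expect_equal(sb$peaks$mz, c(100, 200))

  # zero-length arrays are a valid empty spectrum
  s0 <- parse_mzdata_spectrum(
    '<spectrum id="1"><mzArrayBinary><data precision="64" endian="big" length="0"></data></mzArrayBinary><intenArrayBinary><data precision="64" endian="big" length="0"></data></intenArrayBinary></spectrum>',
    dia, 0)
  expect_equal(nrow(s0$peaks), 0)

  # m/z and intensity arrays of different length
  bad <- sub('length="2">([^<]*)</data></intenArrayBinary>',
             sprintf('length="1">%s</data></intenArrayBinary>',
                     encode_array(10, ms_encoding(64, "big"))),
             mk("big"))
  expect_ms_error(parse_mzdata_spectrum(bad, dia, 0), "integrity_error")
})

test_that("parse_mzml_spectrum: cv-classified arrays, zlib twins, count check", {
  dia <- xml_dialect_for_tests("mzml")
  d <- withr::local_tempdir()
  sp <- std_spectra(2, seed = 41)
  plain <- file.path(d, "p.mzml"); zl <- file.path(d, "z.mzml")
  write_fixture(sp, "mzml", plain)
  write_fixture(sp, "mzml", zl, compression = "zlib")
  a <- read_spectra(open_reader(plain))
  b <- read_spectra(open_reader(zl))
  for (k in 1:2) expect_identical(a[[k]]$peaks, b[[k]]$peaks)
  expect_equal(a[[1]]$native_id, "scan=1")  # verbatim id string
  expect_equal(a[[1]]$ms_level, 2L)
  expect_equal(a[[1]]$precursor$mz, sp[[1]]$precursor$mz)

  # defaultArrayLength disagreeing with the arrays
  el <- rawToChar(read_span(plain, open_reader(plain)$index$records[[1]]))
  el_bad <- sub('defaultArrayLength="[0-9]+"', 'defaultArrayLength="99"', el)
  expect_ms_error(parse_mzml_spectrum(el_bad, dia, 0), "integrity_error")

  # an array without its type cvParam is a dialect error
  el_untyped <- sub(' accession="MS:1000514" name="m/z array"',
                    ' accession="MS:9999999" name="mystery array"', el)
  expect_ms_error(parse_mzml_spectrum(el_untyped, dia, 0), "format_dialect")
})

test_that("record parsers agree with a full-document DOM parse (oracle equivalence)", {
  d <- withr::local_tempdir()
  sp <- std_spectra(6, seed = 43, ms_level_pattern = c(1, 2))
  for (f in c("mzxml", "mzdata", "mzml")) {
    p <- file.path(d, paste0("o.", f))
    write_fixture(sp, f, p, nested = (f == "mzxml"))
    indexed <- read_spectra(open_reader(p))
    dom <- oracle_xml_spectra(p, f)
    expect_length(indexed, length(dom))
    for (k in seq_along(dom)) {
      expect_equal(indexed[[k]]$native_id, dom[[k]]$id, info = f)
      expect_identical(indexed[[k]]$peaks$mz, dom[[k]]$mz, info = f)
      expect_identical(indexed[[k]]$peaks$intensity, dom[[k]]$intensity,
                       info = f)
    }
  }
})

test_that("peak values survive write -> index -> parse bit-exactly at 64-bit", {
  d <- withr::local_tempdir()
  # values deliberately NOT representable at text precision
  set.seed(47)
  sp <- lapply(0:2, function(i) {
    mz <- sort(runif(8, 100, 2000)) + pi * 1e-9
    normalize_spectrum(ms_spectrum(
      "bits", i, ms_level = 2,
      precursor = ms_precursor(mz = runif(1, 300, 900), charges = 2L),
      peaks = ms_peaks(mz, runif(8, 0, 1e6))))
  })
  for (f in c("mzxml", "mzdata", "mzml")) {
    p <- file.path(d, paste0("bits.", f))
    write_fixture(sp, f, p)
    back <- read_spectra(open_reader(p))
    for (k in 1:3) {
      expect_identical(back[[k]]$peaks$mz, sp[[k]]$peaks$mz, info = f)
      expect_identical(back[[k]]$peaks$intensity, sp[[k]]$peaks$intensity,
                       info = f)
    }
  }
})
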