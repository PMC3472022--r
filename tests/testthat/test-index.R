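test_that("text indexing finds blank-separated DTA blocks at known offsets", {
  p <- withr::local_tempfile(fileext = ".dta")
  # three blocks; extra blank lines collapse to one separator
  txt <- "1000.0 2\n100.1 5.0\n\n1200.0 1\n200.2 6.0\n\n\n1300.0 3\n300.3 7.0\n"
  writeBin(charToRaw(txt), p)
  ix <- build_text_index(p, "dta")
  expect_length(ix$records, 3)
  expect_equal(vapply(ix$records, `[[`, numeric(1), "position"), 0:2)
  starts <- vapply(ix$records, `[[`, numeric(1), "start")
  # fixture offsets: blocks start at 0, 20, 41 (one extra blank line before #3)
  expect_equal(starts, c(0, 20, 41))
  expect_identical(rawToChar(read_span(p, ix$records[[2]])),
                   "1200.0 1\n200.2 6.0")
})

test_that("empty and record-less files index to zero records", {
  p <- withr::local_tempfile()
  file.create(p)
  expect_length(build_text_index(p, "dta")$records, 0)
  writeBin(charToRaw("   \n\n  \n"), p)
  expect_warning(ix <- build_text_index(p, "mgf"), class = "msreadr_warning")
  expect_length(ix$records, 0)
})

test_that("MGF indexing captures the header span and the BEGIN..END blocks", {
  p <- withr::local_tempfile(fileext = ".mgf")
  txt <- paste0("COM=two block file\n\n",
                "BEGIN IONS\nTITLE=a\nPEPMASS=500\n100 1\nEND IONS\n\n",
                "BEGIN IONS\nTITLE=b\nPEPMASS=600\n200 2\nEND IONS\n")
  writeBin(charToRaw(txt), p)
  ix <- build_text_index(p, "mgf")
  expect_length(ix$records, 2)
  expect_identical(rawToChar(read_span(p, ix$header_span)),
                   "COM=two block file")
  expect_match(rawToChar(read_span(p, ix$records[[1]])), "^BEGIN IONS")
  expect_match(rawToChar(read_span(p, ix$records[[1]])), "END IONS$")
})

test_that("MS2 indexing records S-line spans with scan-number ids", {
  p <- withr::local_tempfile(fileext = ".ms2")
  txt <- "H\tCreationDate\tx\nS\t12\t12\t701.7\nZ\t2\t1402.39\n100.1 50.0\nS\t15\t15\t800.2\n300 4\n"
  writeBin(charToRaw(txt), p)
  ix <- build_text_index(p, "ms2")
  expect_length(ix$records, 2)
  expect_equal(vapply(ix$records, `[[`, character(1), "native_id"),
               c("12", "15"))
  expect_match(rawToChar(read_span(p, ix$header_span)), "^H\t")
})

test_that("XML indexing flattens nested mzXML scans in document order", {
  d <- withr::local_tempdir()
  sp <- std_spectra(4, seed = 3, ms_level_pattern = c(1, 2))
  p <- file.path(d, "nested.mzxml")
  write_fixture(sp, "mzxml", p, nested = TRUE)
  ix <- build_xml_index(p, "mzxml")
  expect_length(ix$records, 4)
  expect_equal(vapply(ix$records, `[[`, character(1), "native_id"),
               as.character(1:4))
  # parent span contains the nested child span
  expect_true(ix$records[[2]]$start > ix$records[[1]]$start)
  expect_true(ix$records[[2]]$start + ix$records[[2]]$length <
              ix$records[[1]]$start + ix$records[[1]]$length)
  # every span covers a full element
  for (r in ix$records) {
    el <- rawToChar(read_span(p, r))
    expect_match(el, "^<scan")
    expect_match(el, "</scan>$")
  }
})

test_that("mzData spectrum ids are captured; empty spectrumList gives 0 records", {
  d <- withr::local_tempdir()
  p <- file.path(d, "f.mzdata")
  write_fixture(std_spectra(2, seed = 9), "mzdata", p, id_start = 10)
  ix <- build_xml_index(p, "mzdata")
  expect_equal(vapply(ix$records, `[[`, character(1), "native_id"),
               c("10", "11"))
  p0 <- file.path(d, "empty.mzdata")
  write_fixture(list(), "mzdata", p0)
  expect_length(build_xml_index(p0, "mzdata")$records, 0)
})

test_that("spans are non-overlapping and gap-free in position except nested scans", {
  d <- withr::local_tempdir()
  sp <- std_spectra(4, seed = 5)
  for (f in ms_formats()) {
    p <- file.path(d, paste0("x.", f))
    write_fixture(sp, f, p)
    ix <- if (f %in% c("mzxml", "mzdata", "mzml")) build_xml_index(p, f)
          else build_text_index(p, f)
    starts <- vapply(ix$records, `[[`, numeric(1), "start")
    ends <- starts + vapply(ix$records, `[[`, numeric(1), "length")
    expect_true(all(diff(starts) > 0), info = f)
    expect_true(all(ends[-length(ends)] <= starts[-1]), info = f)
    expect_equal(vapply(ix$records, `[[`, numeric(1), "position"), 0:3,
                 info = f)
  }
})

test_that("indexes are insensitive to CRLF line endings and trailing newline", {
  d <- withr::local_tempdir()
  sp <- std_spectra(3, seed = 13)
  for (f in c("dta", "pkl", "mgf", "ms2")) {
    p_lf <- file.path(d, paste0("lf.", f))
    write_fixture(sp, f, p_lf)
    txt <- rawToChar(readBin(p_lf, "raw", file.size(p_lf)))
    p_crlf <- file.path(d, paste0("crlf.", f))
    writeBin(charToRaw(gsub("\n", "\r\n", sub("\n$", "", txt), fixed = TRUE)),
             p_crlf)
    a <- read_spectra(open_reader(p_lf, f))
    b <- read_spectra(open_reader(p_crlf, f))
    expect_length(b, 3)
    for (k in 1:3) {
      expect_identical(a[[k]]$peaks, b[[k]]$peaks, info = f)
      expect_equal(a[[k]]$precursor$mz, b[[k]]$precursor$mz, info = f)
    }
  }
})

test_that("read_span rejects spans past EOF as stale and zero-length spans by invariant", {
  p <- withr::local_tempfile()
  writeBin(charToRaw("BEGIN IONS\nEND IONS\n"), p)
  expect_ms_error(read_span(p, record_span(10, 100, 0)), "stale_index")
  expect_ms_error(record_span(0, 0, 0), "domain_error")
})

test_that("index persistence round-trips field-for-field and is versioned", {
  d <- withr::local_tempdir()
  p <- file.path(d, "f.mgf")
  write_fixture(std_spectra(3, seed = 2), "mgf", p)
  ix <- build_text_index(p, "mgf")
  back <- load_index(save_index(ix))
  expect_identical(back, ix)
  expect_ms_error(load_index('{"version":"other/9","records":[]}'),
                  "versioned_format")
  expect_ms_error(load_index("not json at all {"), "versioned_format")
})

test_that("a persisted index goes stale when the file is mutated", {
  d <- withr::local_tempdir()
  p <- file.path(d, "f.mgf")
  write_fixture(std_spectra(3, seed = 2), "mgf", p)
  json <- export_index(open_reader(p))
  # appending changes size and tail hash
  cat("BEGIN IONS\nEND IONS\n", file = p, append = TRUE)
  expect_ms_error(open_reader(p, saved_index = json), "stale_index")
  expect_silent(r <- open_reader(p))   # re-indexing still works
  expect_equal(get_spectra_count(r), 4)
})

test_that("fetching one spectrum reads at most span + one buffer of bytes", {
  d <- withr::local_tempdir()
  sp <- std_spectra(30, seed = 4, peaks_per_spectrum = c(40, 80))
  for (f in ms_formats()) {
    p <- file.path(d, paste0("big.", f))
    write_fixture(sp, f, p)
    r <- open_reader(p, f)
    span <- r$index$records[[18]]
    io_reset()
    s <- get_spectrum_by_index(r, 17)
    expect_lte(io_bytes_read(), span$length + BUF)
    expect_lt(io_bytes_read(), file.size(p) + 1)  # never a whole-file slurp via unindexed path
    expect_equal(s$position, 17L)
  }
})

test_that("re-opening with a saved index skips the scanning pass", {
  d <- withr::local_tempdir()
  p <- file.path(d, "big.mzml")
  write_fixture(std_spectra(40, seed = 6, peaks_per_spectrum = c(50, 90)),
                "mzml", p)
  json <- export_index(open_reader(p))
  io_reset()
  r <- open_reader(p, saved_index = json)
  # only the 16 KiB fingerprint sample plus the dialect probe may be read
  expect_lte(io_bytes_read(), 16384 + 4096)
  expect_equal(get_spectra_count(r), 40)
})
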