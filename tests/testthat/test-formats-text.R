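test_that("parse_dta_block: header, derived precursor m/z, peakless and error cases", {
  s <- parse_dta_block("1402.2 2\n100.1 50.0\n200.2 25.0")
  expect_equal(s$precursor$mh_plus, 1402.2)
  expect_equal(s$precursor$charges, 2L)
  expect_equal(s$precursor$mz, 701.60363823344)   # (1402.2 + m_p) / 2
  expect_equal(nrow(s$peaks), 2)
  expect_true("dta_mh_plus" %in% s$extras$name)   # raw MH+ survives in extras

  peakless <- parse_dta_block("500.0 1\n")
  expect_equal(nrow(peakless$peaks), 0)
  expect_equal(peakless$precursor$mz, 500)        # z = 1 identity

  expect_ms_error(parse_dta_block("abc 2\n", strict = TRUE),
                  "malformed_record")
  expect_ms_error(parse_dta_block("1402.2 2 9\n"), "malformed_record")
  # lenient mode skips a bad peak line with a warning; strict errors
  expect_warning(s2 <- parse_dta_block("1402.2 2\nbroken line\n100.1 5"),
                 class = "msreadr_warning")
  expect_equal(nrow(s2$peaks), 1)
  expect_ms_error(
    suppressWarnings(parse_dta_block("1402.2 2\nbroken line\n", strict = TRUE)),
    "malformed_record")
})

test_that("parse_pkl_block: three-token header transcribed directly", {
  s <- parse_pkl_block("701.7 1250.0 2\n100.1 50.0")
  expect_equal(s$precursor$mz, 701.7)
  expect_equal(s$precursor$intensity, 1250)
  expect_equal(s$precursor$charges, 2L)
  expect_equal(nrow(s$peaks), 1)
  expect_ms_error(parse_pkl_block("701.7 1250.0\n"), "malformed_record")
})

test_that("parse_mgf_block: params, charges, per-peak charge, comments", {
  blk <- paste("BEGIN IONS", "TITLE=t1", "PEPMASS=896.05 25674.3",
               "CHARGE=2+", "# a comment", "100.1 50.0 1+", "200.0 10",
               "END IONS", sep = "\n")
  s <- parse_mgf_block(blk)
  expect_equal(s$precursor$mz, 896.05)
  expect_equal(s$precursor$intensity, 25674.3)
  expect_equal(s$precursor$charges, 2L)
  expect_equal(nrow(s$peaks), 2)
  expect_equal(s$peaks$charge[s$peaks$mz == 100.1], 1L)
  expect_identical(s$extras$value[s$extras$name == "TITLE"], "t1")

  # global CHARGE default applies when the block has none
  g <- parse_mgf_header("COM=x\nCHARGE=2+ and 3+\n")
  s2 <- parse_mgf_block("BEGIN IONS\nPEPMASS=500\n100 1\nEND IONS", global = g)
  expect_equal(s2$precursor$charges, c(2L, 3L))

  # no PEPMASS: valid spectrum without precursor
  s3 <- parse_mgf_block("BEGIN IONS\n100 1\nEND IONS")
  expect_null(s3$precursor)

  # RTINSECONDS feeds retention_seconds and stays in extras
  s4 <- parse_mgf_block("BEGIN IONS\nPEPMASS=5\nRTINSECONDS=62.5\nEND IONS")
  expect_equal(s4$retention_seconds, 62.5)
  expect_true("RTINSECONDS" %in% s4$extras$name)

  expect_ms_error(parse_mgf_block("BEGIN IONS\nPEPMASS=500\n100 1\n"),
                  "malformed_record")  # missing END IONS
})

test_that("parse_ms2_record: S/Z/I/D lines, multi-Z charges, header params", {
  rec <- "S\t12\t12\t701.7\nZ\t2\t1402.39\n100.1 50.0"
  s <- parse_ms2_record(rec)
  expect_equal(s$precursor$mz, 701.7)
  expect_equal(s$precursor$charges, 2L)
  expect_equal(s$native_id, "12")
  expect_equal(s$ms_level, 2L)
  expect_equal(nrow(s$peaks), 1)

  s2 <- parse_ms2_record("S 3 3 500.0\nZ 2 999.0\nZ 3 1497.0\n100 1")
  expect_equal(s2$precursor$charges, c(2L, 3L))
  expect_null(s2$precursor$mh_plus)  # ambiguous: no single (M+H)+ chosen

  hdr <- ms_params("H:CreationDate", "x")
  s3 <- parse_ms2_record("S 1 1 400.0\nZ 1 400.0\n", header = hdr)
  expect_true("H:CreationDate" %in% s3$extras$name)

  expect_ms_error(parse_ms2_record("S 1 1 400.0\nZ 2.5 900\n"),
                  "malformed_record")
  expect_warning(parse_ms2_record("S 1 1 400.0\nD foo bar\nZ 2 799\n"),
                 class = "msreadr_warning")  # D before Z: dialect warning
})

test_that("write_mgf: synthesized titles, multi-charge serialization, counts", {
  d <- withr::local_tempdir()
  out <- file.path(d, "o.mgf")
  expect_equal(write_mgf(list(), out), 0)
  expect_equal(file.size(out), 0)

  s <- normalize_spectrum(ms_spectrum(
    "src", 4, precursor = ms_precursor(mz = 500.25, charges = c(2L, 3L)),
    peaks = ms_peaks(c(100.5, 200), c(1, 2))))
  write_mgf(list(s), out)
  txt <- readLines(out)
  expect_true("CHARGE=2+ and 3+" %in% txt)
  expect_true("TITLE=src:4" %in% txt)
  expect_true("PEPMASS=500.25" %in% txt)
})

test_that("parse(write_F(spectra)) recovers peaks, precursor m/z and charges for each text format", {
  d <- withr::local_tempdir()
  sp <- std_spectra(5, seed = 17)
  for (f in c("dta", "pkl", "mgf", "ms2")) {
    p <- file.path(d, paste0("rt.", f))
    write_fixture(sp, f, p)
    back <- read_spectra(open_reader(p, f))
    expect_length(back, 5)
    for (k in seq_along(sp)) {
      # printed at 6 (m/z) and 4 (intensity) decimals; values are pre-rounded,
      # so recovery is exact
      expect_identical(back[[k]]$peaks$mz, sp[[k]]$peaks$mz, info = f)
      expect_identical(back[[k]]$peaks$intensity, sp[[k]]$peaks$intensity,
                       info = f)
      expect_lt(abs(back[[k]]$precursor$mz - sp[[k]]$precursor$mz) /
                sp[[k]]$precursor$mz, 1e-6)
      expect_true(sp[[k]]$precursor$charges[1] %in% back[[k]]$precursor$charges,
                  info = f)
    }
  }
})

test_that("MGF export is universal: peak lists survive export from every format exactly", {
  d <- withr::local_tempdir()
  sp <- std_spectra(3, seed = 23)
  paths <- all_format_files(sp, d)
  for (f in names(paths)) {
    out <- file.path(d, paste0("via_", f, ".mgf"))
    n <- write_mgf(open_reader(paths[[f]]), out)
    expect_equal(n, 3, info = f)
    orig <- read_spectra(open_reader(paths[[f]]))
    back <- read_spectra(open_reader(out, "mgf"))
    for (k in seq_along(orig)) {
      expect_identical(back[[k]]$peaks$mz, orig[[k]]$peaks$mz, info = f)
      expect_identical(back[[k]]$peaks$intensity, orig[[k]]$peaks$intensity,
                       info = f)
    }
  }
})

test_that("inserting a block at the head shifts all positions by exactly one", {
  d <- withr::local_tempdir()
  sp <- std_spectra(4, seed = 29)
  p <- file.path(d, "s.mgf")
  write_fixture(sp[2:4], "mgf", p)
  before <- read_spectra(open_reader(p))
  write_fixture(sp, "mgf", file.path(d, "s2.mgf"))
  # equivalent head insertion: write all 4 and compare positions of the tail
  after <- read_spectra(open_reader(file.path(d, "s2.mgf")))
  for (k in 1:3) {
    expect_identical(after[[k + 1]]$peaks, before[[k]]$peaks)
    expect_equal(after[[k + 1]]$position, before[[k]]$position + 1L)
  }
})
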