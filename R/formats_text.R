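# Parsers and writers for the four text peak-list formats: DTA, PKL, MGF, MS2.
# Each parser consumes the text of ONE record (as delimited by the index
# module) and returns an ms_spectrum; each is usable standalone.
#
# Numeric parsing is locale-independent (decimal point only) and accepts
# scientific notation. `strict = FALSE` (lenient, the default at Reader level)
# skips unparseable peak lines with a warning; strict mode errors.

num_token <- function(x) {
  suppressWarnings(v <- as.numeric(x))
  v
}

split_ws <- function(line) {
  tok <- strsplit(trimws(line), "[ \t]+")[[1]]
  tok[nzchar(tok)]
}

record_lines <- function(text) {
  ln <- strsplit(text, "\n", fixed = TRUE)[[1]]
  sub("\r$", "", ln)
}

bad_record <- function(what, source, position)
  ms_stop("malformed_record",
          sprintf("%s (%s, record %d)", what, source, position),
          source = source, position = position)

peak_lines_to_table <- function(lines, source, position, strict,
                                allow_charge = FALSE) {
  mz <- numeric(); int <- numeric(); chg <- integer()
  for (ln in lines) {
    tok <- split_ws(ln)
    v <- num_token(tok[seq_len(min(length(tok), 2))])
    ok <- length(tok) %in% c(2L, if (allow_charge) 3L) && !anyNA(v)
    z <- NA_integer_
    if (ok && allow_charge && length(tok) == 3) {
      z <- tryCatch(parse_charge(tok[3])[1], error = function(e) NA_integer_)
      if (is.na(z)) ok <- FALSE
    }
    if (!ok) {
      if (strict)
        bad_record(sprintf("invalid peak line '%s'", ln), source, position)
      ms_warn("skipped_peak",
              sprintf("skipping invalid peak line '%s' (%s, record %d)",
                      ln, source, position))
      next
    }
    mz <- c(mz, v[1]); int <- c(int, v[2]); chg <- c(chg, z)
  }
  ms_peaks(mz, int, chg)
}

#' Parse one SEQUEST DTA record
#'
#' Grammar: first line holds the singly-protonated precursor mass (M+H)+ in Da
#' and the charge; every following line is an `m/z intensity` pair. The common
#' interface exposes the derived precursor m/z (via [mh_to_mz()]); the raw
#' (M+H)+ is kept both in the precursor and in extras. A multi-spectrum DTA
#' file is blank-line-concatenated blocks of this grammar.
#'
#' @param text the record text (one block).
#' @param source source path, for error messages and the spectrum record.
#' @param position 0-based ordinal of the record.
#' @param strict error (TRUE) or warn-and-skip (FALSE) on bad peak lines.
#' @return an `ms_spectrum`.
#' @export
parse_dta_block <- function(text, source = "<dta>", position = 0,
                            strict = FALSE) {
  ln <- record_lines(text)
  ln <- ln[!grepl("^[ \t]*$", ln)]
  if (length(ln) == 0) bad_record("empty DTA block", source, position)
  tok <- split_ws(ln[1])
  v <- num_token(tok)
  if (length(tok) != 2 || anyNA(v))
    bad_record(sprintf("DTA header line must be 'MH+ charge', got '%s'", ln[1]),
               source, position)
  mh <- v[1]; z <- as.integer(v[2])
  pre <- ms_precursor(mz = mh_to_mz(mh, z), mh_plus = mh, charges = z)
  s <- ms_spectrum(source, position, precursor = pre,
                   peaks = peak_lines_to_table(ln[-1], source, position, strict),
                   extras = ms_params("dta_mh_plus", tok[1]),
                   format = "dta")
  normalize_spectrum(s)
}

#' Parse one Micromass PKL record
#'
#' Grammar: first line is `precursor_mz precursor_intensity charge`; following
#' lines are `m/z intensity` pairs. Blank-line-separated blocks form a
#' multi-spectrum file.
#'
#' @inheritParams parse_dta_block
#' @return an `ms_spectrum`.
#' @export
parse_pkl_block <- function(text, source = "<pkl>", position = 0,
                            strict = FALSE) {
  ln <- record_lines(text)
  ln <- ln[!grepl("^[ \t]*$", ln)]
  if (length(ln) == 0) bad_record("empty PKL block", source, position)
  tok <- split_ws(ln[1])
  v <- num_token(tok)
  if (length(tok) != 3 || anyNA(v))
    bad_record(sprintf("PKL header line must be 'mz intensity charge', got '%s'",
                       ln[1]), source, position)
  pre <- ms_precursor(mz = v[1], intensity = v[2], charges = as.integer(v[3]))
  s <- ms_spectrum(source, position, precursor = pre,
                   peaks = peak_lines_to_table(ln[-1], source, position, strict),
                   format = "pkl")
  normalize_spectrum(s)
}

#' Parse the global parameter header of an MGF file
#'
#' `KEY=VALUE` lines before the first `BEGIN IONS` block (e.g. `COM`, `DB`, a
#' default `CHARGE`). Keys are uppercased.
#'
#' @param text header text (may be empty).
#' @return a parameter table from [ms_params()].
#' @export
parse_mgf_header <- function(text) {
  params <- ms_params()
  if (is.null(text) || !nzchar(text)) return(params)
  for (ln in record_lines(text)) {
    if (grepl("^[ \t]*$", ln) || grepl("^[#;!/]", ln)) next
    m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)=(.*)$", ln))[[1]]
    if (length(m) == 3)
      params <- params_add(params, toupper(m[2]), trimws(m[3]))
  }
  params
}

#' Parse one Mascot Generic Format (MGF) ions block
#'
#' The record spans `BEGIN IONS` .. `END IONS`. Local `KEY=VALUE` parameters:
#' `PEPMASS` (m/z, optional intensity) feeds the precursor, `CHARGE` is parsed
#' with [parse_charge()] and overrides any global default, `RTINSECONDS` sets
#' the retention time; `TITLE`, `SCANS` and everything unrecognized go to
#' extras. Peak lines are `m/z intensity [charge]`. Comment lines starting
#' with `#`, `;`, `!` or `/` are ignored.
#'
#' @inheritParams parse_dta_block
#' @param global global parameter table from [parse_mgf_header()]; its
#'   `CHARGE` entry is the default when the block has none.
#' @return an `ms_spectrum`.
#' @export
parse_mgf_block <- function(text, global = ms_params(), source = "<mgf>",
                            position = 0, strict = FALSE) {
  ln <- record_lines(text)
  nb <- which(!grepl("^[ \t]*$", ln))
  if (length(nb) == 0 || !startsWith(ln[nb[1]], "BEGIN IONS"))
    bad_record("MGF block does not start with BEGIN IONS", source, position)
  end <- which(startsWith(ln, "END IONS"))
  if (length(end) == 0)
    bad_record("missing END IONS", source, position)
  body <- ln[(nb[1] + 1):(end[1] - 1)]

  extras <- ms_params()
  pre_mz <- NULL; pre_int <- NULL; charges <- NULL
  rt <- NULL
  pk_lines <- character()
  for (l in body) {
    if (grepl("^[ \t]*$", l) || grepl("^[#;!/]", l)) next
    m <- regmatches(l, regexec("^([A-Za-z_][A-Za-z0-9_]*)=(.*)$", l))[[1]]
    if (length(m) == 3) {
      key <- toupper(m[2]); val <- trimws(m[3])
      if (key == "PEPMASS") {
        tok <- split_ws(val)
        pre_mz <- num_token(tok[1])
        if (length(tok) > 1) pre_int <- num_token(tok[2])
        if (is.na(pre_mz))
          bad_record(sprintf("unparseable PEPMASS '%s'", val), source, position)
      } else if (key == "CHARGE") {
        charges <- parse_charge(val)
      } else if (key == "RTINSECONDS") {
        rt <- num_token(val)
        extras <- params_add(extras, key, val)
      } else {
        extras <- params_add(extras, key, val)
      }
    } else {
      pk_lines <- c(pk_lines, l)
    }
  }
  if (is.null(charges)) {
    g <- global$value[global$name == "CHARGE"]
    if (length(g) == 1) charges <- parse_charge(g)
  }
  pre <- if (!is.null(pre_mz))
    ms_precursor(mz = pre_mz, intensity = pre_int,
                 charges = charges %||% integer())
  s <- ms_spectrum(source, position, retention_seconds = rt, precursor = pre,
                   peaks = peak_lines_to_table(pk_lines, source, position,
                                               strict, allow_charge = TRUE),
                   extras = extras, format = "mgf")
  normalize_spectrum(s)
}

#' Parse one MS2 record (S-line block)
#'
#' Grammar: `S <firstScan> <lastScan> <precursor m/z>`, then optional `I`
#' (info), `Z <charge> <(M+H)+>` and `D` lines, then `m/z intensity` peak
#' lines. One `charges` entry per Z-line (no "best" charge is chosen when
#' several are present). File-level `H` lines are passed in as `header` and
#' attached to every spectrum's extras. `native_id` is the firstScan number
#' as text; `ms_level` is 2.
#'
#' @inheritParams parse_dta_block
#' @param header parameter table of file-level H-lines.
#' @return an `ms_spectrum`.
#' @export
parse_ms2_record <- function(text, header = ms_params(), source = "<ms2>",
                             position = 0, strict = FALSE) {
  ln <- record_lines(text)
  ln <- ln[!grepl("^[ \t]*$", ln)]
  if (length(ln) == 0 || !grepl("^S[ \t]", ln[1]))
    bad_record("MS2 record does not start with an S-line", source, position)
  tok <- split_ws(ln[1])
  if (length(tok) < 4 || anyNA(num_token(tok[2:4])))
    bad_record(sprintf("invalid S-line '%s'", ln[1]), source, position)
  first_scan <- tok[2]; last_scan <- tok[3]; pre_mz <- num_token(tok[4])

  extras <- header
  extras <- params_add(extras, "ms2_first_scan", first_scan)
  extras <- params_add(extras, "ms2_last_scan", last_scan)
  charges <- integer(); zmasses <- numeric()
  seen_z <- FALSE
  pk_lines <- character()
  for (l in ln[-1]) {
    lead <- substr(l, 1, 1)
    if (lead == "Z" && grepl("^Z[ \t]", l)) {
      zt <- split_ws(l)
      zv <- num_token(zt[2])
      if (length(zt) < 3 || is.na(zv) || zv != as.integer(zv))
        bad_record(sprintf("invalid Z-line '%s'", l), source, position)
      charges <- c(charges, as.integer(zv))
      zmasses <- c(zmasses, num_token(zt[3]))
      extras <- params_add(extras, "ms2_z_mh", zt[3])
      seen_z <- TRUE
    } else if (lead == "I" && grepl("^I[ \t]", l)) {
      it <- split_ws(l)
      extras <- params_add(extras, paste0("I:", it[2]),
                           paste(it[-(1:2)], collapse = " "))
    } else if (lead == "D" && grepl("^D[ \t]", l)) {
      if (!seen_z)
        ms_warn("dialect", sprintf("D-line before any Z-line (%s, record %d)",
                                   source, position))
      dt <- split_ws(l)
      extras <- params_add(extras, paste0("D:", dt[2]),
                           paste(dt[-(1:2)], collapse = " "))
    } else if (lead == "H") {
      extras <- params_add(extras, "H", sub("^H[ \t]+", "", l))
    } else {
      pk_lines <- c(pk_lines, l)
    }
  }
  pre <- ms_precursor(mz = pre_mz,
                      mh_plus = if (length(zmasses) == 1) zmasses,
                      charges = charges)
  s <- ms_spectrum(source, position, native_id = first_scan, ms_level = 2,
                   precursor = pre,
                   peaks = peak_lines_to_table(pk_lines, source, position, strict),
                   extras = extras, format = "ms2")
  normalize_spectrum(s)
}

# Shortest decimal text that parses back to exactly the same double.
repr_num <- function(x) {
  vapply(x, function(v) {
    if (v == floor(v) && abs(v) < 1e15) return(sprintf("%.0f", v))
    for (d in 6:17) {
      s <- trimws(formatC(v, digits = d, format = "g"))
      if (as.numeric(s) == v) return(s)
    }
    sprintf("%.17g", v)
  }, character(1), USE.NAMES = FALSE)
}

format_charge_token <- function(z) sprintf("%d%s", abs(z), if (z < 0) "-" else "+")

#' Export spectra to Mascot Generic Format
#'
#' Writes one `BEGIN IONS` block per spectrum, from any source format: the
#' universal export path. `TITLE` is preserved from extras when present,
#' otherwise synthesized as `"source:position"`. `PEPMASS` is written when a
#' precursor m/z is known (intensity appended when known), `CHARGE` whenever
#' charges are known (multiple as `"2+ and 3+"`), `RTINSECONDS` when the
#' retention time is known. Peak values use shortest round-trip decimal
#' formatting, so peak lists survive export bit-exactly. Output always uses
#' `\n` line endings.
#'
#' @param spectra a list of `ms_spectrum` or an `ms_reader` (streamed one
#'   record at a time).
#' @param destination output file path.
#' @return number of spectra written, invisibly.
#' @export
write_mgf <- function(spectra, destination) {
  con <- tryCatch(file(destination, "wb"),
                  error = function(e) ms_stop("io_error", conditionMessage(e)))
  on.exit(close(con))
  emit <- function(s) {
    out <- "BEGIN IONS"
    title <- s$extras$value[s$extras$name == "TITLE"]
    if (length(title) != 1)
      title <- sprintf("%s:%d", s$source %||% "spectrum", s$position)
    out <- c(out, paste0("TITLE=", title))
    p <- s$precursor
    if (!is.null(p) && !is.null(p$mz)) {
      pm <- paste0("PEPMASS=", repr_num(p$mz))
      if (!is.null(p$intensity)) pm <- paste(pm, repr_num(p$intensity))
      out <- c(out, pm)
    }
    if (!is.null(p) && length(p$charges) > 0)
      out <- c(out, paste0("CHARGE=", paste(vapply(p$charges,
        format_charge_token, character(1)), collapse = " and ")))
    if (!is.null(s$retention_seconds))
      out <- c(out, paste0("RTINSECONDS=", repr_num(s$retention_seconds)))
    pk <- s$peaks
    if (nrow(pk) > 0) {
      pl <- paste(repr_num(pk$mz), repr_num(pk$intensity))
      has_z <- !is.na(pk$charge)
      pl[has_z] <- paste(pl[has_z],
                         vapply(pk$charge[has_z], format_charge_token,
                                character(1)))
      out <- c(out, pl)
    }
    out <- c(out, "END IONS", "")
    writeLines(out, con, sep = "\n")
  }
  n <- 0L
  if (inherits(spectra, "ms_reader")) {
    it <- spectra_iterator(spectra)
    while (!is.null(s <- it())) { emit(s); n <- n + 1L }
  } else {
    for (s in spectra) { emit(s); n <- n + 1L }
  }
  invisible(n)
}
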