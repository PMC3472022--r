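#' Construct a peak table
#'
#' Peaks are the universal minimum shared by all supported formats: ordered
#' (m/z, intensity) pairs, with an optional per-peak charge that only MGF can
#' express (third column of a peak line). Duplicate m/z values are legal and
#' are preserved; peaks are a table, never a map keyed by m/z.
#'
#' @param mz numeric vector of mass-to-charge ratios (Th), all > 0.
#' @param intensity numeric vector of abundances (arbitrary units), all >= 0.
#' @param charge optional integer vector of per-peak charges (NA when absent).
#' @return a `data.frame` with columns `mz`, `intensity`, `charge`.
#' @export
ms_peaks <- function(mz = numeric(), intensity = numeric(), charge = NULL) {
  if (length(mz) != length(intensity))
    ms_stop("domain_error", "mz and intensity must have equal length")
  if (is.null(charge)) charge <- rep(NA_integer_, length(mz))
  data.frame(mz = as.numeric(mz), intensity = as.numeric(intensity),
             charge = as.integer(charge))
}

#' Construct precursor information
#'
#' Houses whichever precursor description a format provides: DTA stores the
#' singly-protonated mass (M+H)+ and one charge, PKL stores m/z + intensity +
#' charge, MS2 S/Z lines may carry several charge hypotheses, the XML formats
#' store m/z (and usually charge and intensity) as params.
#'
#' @param mz precursor m/z (Th), optional.
#' @param mh_plus singly-protonated mass (M+H)+ in Da, optional.
#' @param intensity precursor intensity, optional.
#' @param charges integer vector of charge states (possibly empty; more than
#'   one entry is legal, e.g. MS2 multi-Z records).
#' @return an object of class `ms_precursor`.
#' @export
ms_precursor <- function(mz = NULL, mh_plus = NULL, intensity = NULL,
                         charges = integer()) {
  if (is.null(mz) && is.null(mh_plus))
    ms_stop("domain_error", "precursor needs at least one of mz, mh_plus")
  structure(list(mz = if (!is.null(mz)) as.numeric(mz),
                 mh_plus = if (!is.null(mh_plus)) as.numeric(mh_plus),
                 intensity = if (!is.null(intensity)) as.numeric(intensity),
                 charges = as.integer(charges)),
            class = "ms_precursor")
}

#' Construct an extras (format-specific parameter) table
#'
#' The common spectrum model is a deliberate "smallest common denominator";
#' everything a format says beyond it is preserved verbatim here as
#' name/value/accession triples (accession for controlled-vocabulary params).
#'
#' @param name,value,accession character vectors of equal length (value and
#'   accession may be NA).
#' @return a `data.frame` with columns `name`, `value`, `accession`.
#' @export
ms_params <- function(name = character(), value = NA_character_,
                      accession = NA_character_) {
  n <- length(name)
  if (n > 0 && any(!nzchar(name)))
    ms_stop("domain_error", "param names must be non-empty")
  data.frame(name = as.character(name),
             value = rep_len(as.character(value), n),
             accession = rep_len(as.character(accession), n))
}

params_add <- function(params, name, value = NA_character_,
                       accession = NA_character_) {
  rbind(params, ms_params(name, value, accession))
}

#' Construct a spectrum
#'
#' The format-neutral record every parser produces. `position` is the 0-based
#' ordinal of the spectrum within its source (0-based everywhere in this
#' package, matching mzIdentML "index=" style references); `native_id` is the
#' identifier the format itself assigns (mzData/mzML `id`, mzXML scan `num` as
#' text) and is absent for the pure peak-list formats.
#'
#' @param source source file path (plus format tag as attribute).
#' @param position 0-based ordinal within the source.
#' @param native_id optional native identifier text.
#' @param ms_level optional integer >= 1 (1 = survey scan, 2 = fragment, ...).
#' @param retention_seconds optional non-negative retention time, seconds.
#' @param polarity optional, "positive" or "negative".
#' @param precursor optional [ms_precursor()].
#' @param peaks a peak table from [ms_peaks()].
#' @param extras a parameter table from [ms_params()].
#' @param format format tag recorded alongside the source path.
#' @return an object of class `ms_spectrum`.
#' @seealso [normalize_spectrum()], [peaks_as_arrays()]
#' @export
ms_spectrum <- function(source, position, native_id = NULL, ms_level = NULL,
                        retention_seconds = NULL, polarity = NULL,
                        precursor = NULL, peaks = ms_peaks(),
                        extras = ms_params(), format = NULL) {
  if (position < 0) ms_stop("domain_error", "position must be >= 0")
  if (!is.null(polarity) && !polarity %in% c("positive", "negative"))
    ms_stop("domain_error", "polarity must be 'positive' or 'negative'")
  structure(list(source = source,
                 format = format,
                 position = as.integer(position),
                 native_id = if (!is.null(native_id)) as.character(native_id),
                 ms_level = if (!is.null(ms_level)) as.integer(ms_level),
                 retention_seconds = if (!is.null(retention_seconds))
                   as.numeric(retention_seconds),
                 polarity = polarity,
                 precursor = precursor,
                 peaks = peaks,
                 extras = extras),
            class = "ms_spectrum")
}

#' Normalize a spectrum's peak order
#'
#' Parsers emit peaks in file order; the model invariant is ascending m/z with
#' ties broken by descending intensity. When reordering actually happened the
#' fact is recorded in `extras` (`peaks_reordered = "true"`) so the original
#' file order remains detectable. Normalization is idempotent and preserves
#' the multiset of (mz, intensity, charge) triples.
#'
#' @param s an `ms_spectrum`.
#' @return the spectrum with the peak-order invariant established.
#' @export
normalize_spectrum <- function(s) {
  stopifnot(inherits(s, "ms_spectrum"))
  p <- s$peaks
  bad <- !is.finite(p$mz) | p$mz <= 0 | !is.finite(p$intensity) | p$intensity < 0
  if (any(bad))
    ms_stop("malformed_record",
            sprintf("invalid peak (mz <= 0 or intensity < 0) in %s at position %d",
                    s$source, s$position),
            source = s$source, position = s$position)
  if (nrow(p) > 1) {
    ord <- order(p$mz, -p$intensity)
    if (!identical(ord, seq_len(nrow(p)))) {
      s$peaks <- p[ord, , drop = FALSE]
      rownames(s$peaks) <- NULL
      if (!any(s$extras$name == "peaks_reordered"))
        s$extras <- params_add(s$extras, "peaks_reordered", "true")
    }
  }
  s
}

#' Project a spectrum onto aligned m/z and intensity vectors
#'
#' @param s a normalized `ms_spectrum`.
#' @return a list with numeric vectors `mz` (ascending) and `intensity`,
#'   positionally aligned.
#' @export
peaks_as_arrays <- function(s) {
  stopifnot(inherits(s, "ms_spectrum"))
  list(mz = s$peaks$mz, intensity = s$peaks$intensity)
}

#' @export
print.ms_spectrum <- function(x, ...) {
  cat(sprintf("<ms_spectrum> %s position=%d%s\n",
              x$source %||% "?", x$position,
              if (!is.null(x$native_id)) paste0(" id=", x$native_id) else ""))
  cat(sprintf("  ms_level=%s  peaks=%d%s\n",
              x$ms_level %||% "NA", nrow(x$peaks),
              if (!is.null(x$precursor) && !is.null(x$precursor$mz))
                sprintf("  precursor m/z=%.4f", x$precursor$mz) else ""))
  invisible(x)
}

#' @export
print.ms_precursor <- function(x, ...) {
  cat(sprintf("<ms_precursor> mz=%s mh_plus=%s charges=[%s]\n",
              x$mz %||% "NA", x$mh_plus %||% "NA",
              paste(x$charges, collapse = ",")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Equality of the format-neutral payload of two spectra: peaks (within tol),
# precursor m/z (relative tol) and charge sets. Used by cross-format tests.
spectra_payload_equal <- function(a, b, mz_tol = 0, rel_pre_tol = 1e-6) {
  if (nrow(a$peaks) != nrow(b$peaks)) return(FALSE)
  if (nrow(a$peaks) > 0) {
    if (any(abs(a$peaks$mz - b$peaks$mz) > mz_tol)) return(FALSE)
    if (any(abs(a$peaks$intensity - b$peaks$intensity) > mz_tol)) return(FALSE)
  }
  pa <- a$precursor; pb <- b$precursor
  if (is.null(pa) != is.null(pb)) return(FALSE)
  if (!is.null(pa)) {
    if (is.null(pa$mz) != is.null(pb$mz)) return(FALSE)
    if (!is.null(pa$mz) &&
        abs(pa$mz - pb$mz) > rel_pre_tol * max(abs(pa$mz), 1)) return(FALSE)
    if (!setequal(pa$charges, pb$charges)) return(FALSE)
  }
  TRUE
}
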