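# Error taxonomy
#
# Every error signalled by the package carries the class "msreadr_error" plus
# one specific subclass so callers (and the CLI exit-code mapping) can react
# to error categories rather than message strings:
#
#   msreadr_unsupported_format  unknown/undetectable file format
#   msreadr_malformed_record    a record violates its format grammar
#   msreadr_codec_error         base64 / IEEE-754 / zlib payload failure
#   msreadr_integrity_error     declared counts/lengths disagree with data
#   msreadr_stale_index         persisted index no longer matches the file
#   msreadr_reference_not_found id/position/filename resolves to nothing
#   msreadr_format_dialect      unparseable dialect token (duration, charge)
#   msreadr_domain_error        argument outside its mathematical domain
#   msreadr_versioned_format    persisted index schema version mismatch
#   msreadr_io_error            unreadable/unwritable path

ms_stop <- function(class, message, ..., call. = FALSE) {
  stop(errorCondition(message,
                      ...,
                      class = c(paste0("msreadr_", class), "msreadr_error")))
}

ms_warn <- function(class, message, ...) {
  warning(warningCondition(message,
                           ...,
                           class = c(paste0("msreadr_", class), "msreadr_warning")))
}

# shared physical constant: mass of a proton in Da
PROTON_MASS <- 1.00727646688
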