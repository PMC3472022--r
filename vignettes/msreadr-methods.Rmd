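---
title: "msreadr: design and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{msreadr: design and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msreadr)
```

## What the package models

Tandem mass-spectrometry data lives in seven widely used container formats:
four line-oriented peak lists (DTA, PKL, MGF, MS2) and three XML documents
(mzXML, mzData, mzML). They all carry the same essential observation — a list
of (m/z, intensity) peaks, usually with a precursor ion description — but
differ in everything else: how the precursor mass is expressed, how spectra
are identified, how peak values are encoded, and how much instrument metadata
surrounds them.

`msreadr` models the intersection as a *smallest common denominator* record
(`ms_spectrum`): source + 0-based position, optional native id, MS level,
retention time (always seconds), polarity, a precursor (`ms_precursor`), and
a peak table. Everything a format says beyond that is kept as verbatim
name/value/accession rows in `extras`, so no information is discarded even
though the common surface stays minimal. Peaks are a table, never a map keyed
by m/z: duplicate m/z values are legal in real data and must survive round
trips.

### Peak ordering

The formats do not promise any peak order, so the package normalizes:
ascending m/z, ties broken by descending intensity. `normalize_spectrum()` is
idempotent, preserves the multiset of (m/z, intensity, charge) triples, and
records `peaks_reordered = "true"` in extras when it actually changed the
order, so file order remains detectable. This is a package design choice —
an order-preserving list plus explicit normalization — made because a
deterministic order is what downstream comparison code needs; nothing in the
formats mandates it.

### Precursor arithmetic

DTA headers and MS2 Z-lines store the singly protonated mass (M+H)+ rather
than m/z. The package exposes computed m/z through the common interface and
keeps the raw (M+H)+ both in the precursor record and in extras:

$$ m/z = \frac{\mathrm{MH}^{+} + (z-1)\,m_p}{z}, \qquad m_p = 1.00727646688\ \mathrm{Da}. $$

Exposing m/z (rather than returning MH+ as-is) was an open choice; it was
made so that the precursor field means the same physical quantity for all
seven formats. The exact inverse `mz_to_mh()` is used by the fixture
generator so DTA round trips are closed. When an MS2 record carries several
Z-lines, *all* charges are reported and no "best" one is chosen — there is no
principled rule for picking one.

## Random access: byte-range indexes

The reason this package exists rather than seven `readLines()` loops is file
size: production MS files reach tens of gigabytes, and mzIdentML consumers
need one spectrum at a time, not a whole-file parse.

* `build_text_index()` streams the file once in fixed 1 MiB chunks and emits
  one byte span per record: `BEGIN IONS`…`END IONS` for MGF, S-line to the
  line before the next S-line for MS2, contiguous non-blank blocks for
  DTA/PKL (consecutive blank lines collapse to one separator). MGF global
  parameters and MS2 H-lines become a header span that is parsed once per
  reader and attached to every spectrum.
* `build_xml_index()` is a quote-aware byte-pattern scanner (not a DOM
  parse): it tracks `<scan>`/`<spectrum>` open/close tags, including
  self-closing forms, in the same 1 MiB chunks, and records each element's
  full byte range plus its `num`/`id` attribute. Memory stays bounded
  regardless of document size; only the record-level parse (a few KiB) uses
  a real XML parser (xml2).
* Fetching a spectrum reads exactly its span (`read_span()`); an instrumented
  I/O layer (`io_bytes_read()`) lets the test suite assert the contract:
  one fetch reads at most span length + one buffer.

Nested mzXML scans (MS2 scans written inside their MS1 survey scan) are
flattened in document order; each nested scan gets its own span and the
record parser ignores child `<scan>` elements inside a parent's span. This is
the one place spans may overlap — a parent's element necessarily contains its
children — and it is a deliberate deviation from a strict "non-overlapping
spans" rule, which cannot coexist with per-nested-scan spans. Document order
is used because it is deterministic and equals byte order.

Indexing deliberately ignores mzXML's own trailing `<index>` and
indexedmzML's index blocks: self-indexing is simpler and robust against
offsets that lie.

### Index persistence and staleness

`export_index()` serializes the index as versioned JSON
(`"msreader-index/1"`; a per-file map `"msreader-dirindex/1"` for
directories), and `open_reader(path, saved_index = json)` restores it without
re-scanning. Staleness is detected by a fingerprint: file size plus an MD5
over the first and last 8 KiB. Hashing the whole file would defeat the
purpose of indexing large files, so detection is best-effort *by design* —
it catches truncation, appends and edits near either end, which are the
realistic mutations. A fingerprint mismatch raises a stale-index error; the
caller re-opens without the index.

## Binary codecs

The XML formats encode peaks as base64-wrapped IEEE-754 arrays. The encoding
matrix is: mzXML — one interleaved (m/z, intensity) array in network byte
order (big-endian); mzData — separate m/z and intensity arrays honoring the
explicit `endian` attribute of each `<data>` element; mzML — separate
little-endian arrays classified by controlled-vocabulary params (matched by
accession first, name second, to tolerate real-world files). zlib compression
is accepted for mzXML ≥ 3.0 and mzML and rejected with a codec error
elsewhere, following the formats' own rules. Declared counts (`peaksCount`,
`length`, `defaultArrayLength`) are always cross-checked against decoded
lengths; a mismatch is an integrity error, because silently trusting either
side corrupts downstream statistics.

64-bit round trips are bit-exact (asserted property-style over thousands of
random arrays); 32-bit round trips are exact to 1e-6 relative, the precision
the narrower float supports. Retention times arrive as xs:duration
(`PT60.5S`) in mzXML; a lenient mode also accepts bare decimals as seconds
because real-world writers emit them. The raw string is always preserved in
extras.

## Error taxonomy, strict vs lenient

Every failure carries a condition class (`msreadr_malformed_record`,
`msreadr_codec_error`, `msreadr_integrity_error`, `msreadr_stale_index`,
`msreadr_reference_not_found`, …) so callers can dispatch on category; the
CLI maps these 1:1 to exit codes 2–6. Readers default to lenient mode —
an unparseable *peak line* is skipped with a warning, and a malformed record
poisons only its own position — while strict mode (and the `validate`
subcommand) turns everything into an error. Structural violations (missing
`END IONS`, count mismatches, undecodable payloads) are errors in both modes.

## The synthetic-data generator

No test data ships with the package; `generate_spectra()` +
`write_fixture()` produce it deterministically (same spec ⇒ byte-identical
files). The stated world:

* peak m/z uniform over 100–2000 Th (the range of a typical tryptic-peptide
  fragment spectrum), 5–20 peaks per spectrum by default;
* intensities log-uniform over [1, 1e6], mimicking the heavy-tailed dynamic
  range of ion counts;
* precursor charges drawn from {2, 3} (the dominant tryptic charge states),
  with (M+H)+ derived exactly from m/z and z so the DTA path is closed;
* all spectra MS level 2 by default, because the peak-list formats can only
  express fragment spectra; an alternating 1/2 pattern is available for the
  XML formats and the nested-scan case;
* monotone retention times, positive polarity.

Values are pre-rounded to the text writers' printed precision (m/z 6
decimals, intensity 4), so the *same* spectra survive every format's round
trip exactly — 64-bit XML bit-exactly, text formats decimal-exactly. That
choice makes cross-format equality a sharp `identical()` test instead of a
tolerance test.

What the generator does *not* emulate: isotope envelopes, noise baselines,
profile-mode data, chromatographic peak shapes, vendor metadata breadth, or
malformed real-world files beyond the four scripted corruptions
(`corrupt_fixture()`). A green suite therefore establishes format, indexing
and referencing correctness — not robustness against every file in the wild.

## Numerical and formatting choices

* Positions are 0-based everywhere (API, CLI, index JSON), matching
  mzIdentML `index=`-style references; this was an open convention and is
  documented prominently rather than guessed both ways.
* `write_mgf()` prints peaks with shortest-round-trip decimal formatting, so
  MGF export preserves peak lists exactly from any source, including 64-bit
  XML payloads. The fixture writers instead use fixed decimals (6/4), which
  *defines* the printed precision of the text formats.
* mzXML scan-number references are compared as canonical integer text
  (`"002"` finds scan 2); mzML ids are verbatim strings, no nativeID-format
  CV dispatch (that belongs to mzIdentML itself, out of scope).
* Directory readers sort files lexicographically so positional fallback is
  deterministic.
* Format sniffing: extension first, content probe second; on conflict the
  content wins with a warning, because files get renamed more often than
  rewritten.

## Known limitations

* mzML support is a minimal subset: spectra, precursors, binary arrays and
  common scan metadata — no chromatograms, instrument/software lists,
  referenceable param groups, or schema validation.
* mzData versions other than 1.05 and mzXML outside 2.1–3.2 parse
  best-effort with a warning; behavior on such files is not a contract.
* Fingerprints cannot detect an in-place edit strictly between the first and
  last 8 KiB that preserves file size.
* The XML writers in the fixtures module emit test-grade documents (minimal
  valid structure), not standards-grade exports; the only production writer
  is MGF.
* No numpress or other non-zlib compressions; no vendor raw formats.
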