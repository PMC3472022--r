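# msreadr

Unified, indexed, random-access reading of the seven most widely used
mass-spectrometry data formats in R.

## The problem

A proteomics identification result (mzIdentML, the HUPO-PSI standard) does not
contain spectra. It *references* them in external MS data files — and those
files come in a zoo of formats: the text peak lists **DTA**, **PKL**, **MGF**
and **MS2**, and the XML formats **mzXML** (2.1–3.2), **mzData** (1.05) and
**mzML** (1.1). Software consuming identifications therefore has to parse all
of them, resolve three different referencing conventions (native spectrum id,
0-based position in file, filename for single-spectrum DTA/PKL directories),
and do so on files that are routinely too large to load into memory.

`msreadr` solves this with one common interface over seven independent
parsers:

* every format is read through the same five operations —
  `open_reader()`, `get_spectra_count()`, `get_spectra_ids()`,
  `get_spectrum_by_index()`, `get_spectrum_by_id()` — plus a lazy
  `spectra_iterator()`;
* spectra are located through **byte-range indexes** built in one buffered
  streaming pass (1 MiB chunks), so fetching one spectrum from an arbitrarily
  large file reads only that record's bytes;
* indexes are **persistable as versioned JSON** (`export_index()`) and can be
  handed back to `open_reader()` to skip re-scanning, with fingerprint-based
  stale detection — the building block of a flat-file spectrum database;
* `get_spectrum_by_id()` interprets a reference exactly the way mzIdentML
  does for the underlying format: native id for mzData/mzXML/mzML, 0-based
  position for DTA/PKL/MS2/MGF, filename for DTA/PKL directories;
* any source can be exported to Mascot Generic Format with `write_mgf()`.

The common spectrum record is a deliberate *smallest common denominator* —
peaks (m/z, intensity, optional charge), precursor, MS level, retention time,
polarity, ids — while everything format-specific is preserved verbatim in a
per-spectrum `extras` table.

At its numeric core sit two codecs: base64-wrapped IEEE-754 arrays (32/64
bit, both byte orders, optional zlib) for the XML peak payloads, and the
proton-mass arithmetic between a singly protonated mass and m/z,

    mz = (MH+ + (z - 1) * 1.00727646688) / z ,

used to expose DTA's (M+H)+ headers through the same precursor field as every
other format.

## Worked example

```r
library(msreadr)

spectra <- generate_spectra(fixture_spec(n_spectra = 3, seed = 42))
write_fixture(spectra, "mzxml", "demo.mzXML")

r <- open_reader("demo.mzXML")
r
#> <ms_reader> demo.mzXML [mzxml] 3 spectra, scheme=id, mode=lenient

s <- get_spectrum_by_id(r, "2")   # mzXML references by scan number
s
#> <ms_spectrum> demo.mzXML position=1 id=2
#>   ms_level=2  peaks=9  precursor m/z=1682.5406
head(s$peaks, 3)
#>         mz  intensity charge
#> 1 256.6314   1216.944     NA
#> 2 323.2260    219.392     NA
#> 3 363.5493 271912.258     NA

write_mgf(r, "demo.mgf")          # export any format to MGF
cat(readLines("demo.mgf", n = 6), sep = "\n")
#> BEGIN IONS
#> TITLE=demo.mzXML:0
#> PEPMASS=1875.87727 1051.2725
#> CHARGE=3+
#> RTINSECONDS=1.9623
#> 643.665116 26274.2234

cat(substr(export_index(r), 1, 120))  # persistable byte-range index
#> {"version":"msreader-index/1","path":"demo.mzXML","format":"mzxml",
#>  "file_size":1506,"fingerprint":"1506:18b83a17...
```

The reader printout says the file resolves references by native id (`scheme=id`);
`get_spectrum_by_id(r, "2")` therefore returns the scan whose mzXML `num`
attribute is 2, which sits at 0-based position 1. The peak table is
normalized to ascending m/z. The exported MGF block shows the precursor of
the first spectrum — m/z 1875.87727 Th at charge 3+ — and the index JSON is
everything needed to reopen the file later without re-scanning it.

**Positions are 0-based everywhere** (API, CLI, persisted indexes), matching
mzIdentML `index=`-style references.

## Command line

```sh
inst/scripts/msreader info demo.mzXML            # format, count, scheme
inst/scripts/msreader list demo.mzXML            # one line per spectrum
inst/scripts/msreader get demo.mzXML --id 2 --json
inst/scripts/msreader convert demo.mzXML --out demo.mgf
inst/scripts/msreader index demo.mzXML --out idx.json
inst/scripts/msreader info demo.mzXML --use-index idx.json
inst/scripts/msreader validate demo.mgf          # strict parse; exit 0 iff clean
```

Exit codes: 0 ok, 1 generic/IO, 2 unsupported format, 3 malformed record,
4 integrity error, 5 stale index, 6 reference not found.

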