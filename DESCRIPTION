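Package: msreadr
Title: Unified Random-Access Reading of Mass-Spectrometry Peak-List and XML Data Formats
Version: 0.1.0
Authors@R: person("msreadr", "developers", role = c("aut", "cre"),
    email = "msreadr@example.org")
Description: Independent parsers for the seven most widely used mass-spectrometry
    data formats -- the text peak lists DTA, PKL, MGF and MS2, and the XML
    formats mzXML (2.1-3.2), mzData (1.05) and a minimal mzML (1.1) subset --
    behind one common spectrum-access interface. Spectra are located through
    byte-range indexes built by buffered streaming, so arbitrarily large files
    are read without loading them into memory; indexes can be persisted to JSON
    and restored. Spectrum references follow the three mzIdentML schemes
    (native id, 0-based position, filename for single-spectrum DTA/PKL
    directories). Any supported file can be exported to Mascot Generic Format.
    Includes a deterministic synthetic-fixture generator for all seven formats
    and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    xml2,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
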