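Package: strandpairs
Title: Registration Statistics of Paired Beta-Strands from DSSP Assignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts paired beta-strands from classic fixed-column DSSP
    secondary-structure files via their bridge-partner annotations, decomposes
    each strand pair into the common paired part and the two terminal
    extensions (PL, Et1, Et2, EL), and computes the pairing-ratio statistics
    R = PL/EL and Rt_i = PL/SL_i together with the terminal-alignment rule
    R >= 25% and Rt_i >= 40%. Provides dataset-level summaries (length
    difference cross-tables, variable summaries, ratio histograms and
    cumulative curves) and a seeded synthetic strand-pair generator that
    emits parseable DSSP fixtures with known ground-truth registration, so
    the whole pipeline is testable without structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
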