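Package: morfscan
Title: Per-Residue Prediction of Molecular Recognition Features from
    Local PSSM Conservation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies molecular recognition features (MoRFs) -- short
    disorder-to-order binding regions inside intrinsically disordered
    proteins -- from evolutionary conservation alone.  Position-specific
    scoring matrices (PSSMs) are masked (local-mean subtraction),
    filtered (sub-average scores zeroed) and smoothed (windowed row
    summation) to turn absolute conservation into relative local
    conservation, then encoded with a sliding window and classified
    per residue by a radial-basis-function support vector machine.
    Includes PSI-BLAST ASCII PSSM parsing, region-composition analysis
    of MoRF flanks, CASP-style evaluation (balanced accuracy, ROC/AUC),
    and a seeded synthetic-data generator with planted, locally
    conserved MoRFs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
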