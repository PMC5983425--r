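Package: ifmicost
Title: Early Decision-Analytic Assessment of Fluorescence-Guided
    Breast-Conserving Surgery
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Decision-tree model comparing intra-operative fluorescence
    molecular imaging (IFMI) against standard techniques of
    breast-conserving surgery (ST) with frozen section analysis.
    Computes expected numbers of surgeries and expected costs per
    strategy from first-surgery and second-surgery positive-margin
    proportions, an itemized per-surgery cost model (DRG lump sum, lost
    productivity, device amortization, fluorescent agent, staffing and
    operating-time deltas), and their IFMI-minus-ST differences.
    Includes probabilistic sensitivity analysis by Monte Carlo with
    moment-matched beta, gamma and triangular distributions, tornado
    and one-way scenario analyses, relative-risk sweeps with linear
    interpolation, break-even analysis for the staff time saving
    factor, alternative tree structures, and a patient-level
    microsimulation that serves as a brute-force oracle for the
    cohort expectations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
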