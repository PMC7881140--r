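Package: esap
Title: Selection Analysis for Evolve-and-Resequence Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of pooled allele-frequency time series from
    evolve-and-resequence experiments. Provides a forward Wright-Fisher
    simulator for diploid populations with recombination, selection and
    time-varying census size; maximum-likelihood estimation of effective
    population size from temporal allele-frequency data via a hidden
    Wright-Fisher Markov chain; a composite likelihood-ratio scan for
    selective sweeps over sliding genomic windows and time intervals; and
    a decision engine that classifies each detected sweep as a hard sweep,
    a soft sweep from standing variation, a de novo late sweep, or a
    Fisher-Muller recombination event, from the allele-frequency
    trajectories alone. Includes Popoolation2 sync-format input/output and
    diagnostic analyses (sample PCA, allele-frequency spectra,
    between-generation divergence).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
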