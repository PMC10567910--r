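Package: arousalkit
Title: Analysis of Multimodal Sleep-Wake Arousal Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing synchronized fiber-photometry and EEG/EMG
    recordings of sleep-wake states in rodents, together with patch-clamp and
    behavioural readouts of arousal. Implements isosbestic-reference photometry
    preprocessing (exponential photobleaching removal, motion correction by
    reference subtraction, robust median/MAD z-scoring), calcium-transient
    detection by topographic prominence and width, hypnogram bout and
    state-transition statistics, transition-triggered trace averaging, Welch
    and short-time-Fourier EEG spectral analysis, relative EMG amplitude,
    firing-rate and f-I curve analysis of current-clamp recordings, and
    locomotor and startle summaries. A synthetic-data generator with known
    ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    pracma,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
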