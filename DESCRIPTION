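Package: smcleave
Title: Sequential DNA Cleavage Kinetics and Single-Molecule FRET/Unzipping
    Analysis for Miniature CRISPR Nucleases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the sequential DNA target cleavage of miniature type V-F
    CRISPR nucleases (nick, bidirectional exonucleolytic trimming of the
    non-target strand, endonucleolytic target-strand cut and PAM-distal
    release) as a continuous-time Markov chain with magnesium-scaled rates,
    predicts denaturing-gel fragment lengths and band-fraction timecourses,
    and fits rate constants to band data.  Provides a full single-molecule
    FRET toolchain: seeded simulators for two-colour intensity traces emitted
    from hidden mechanistic state paths (with donor leakage, background and
    single-step photobleaching), background/leakage correction, FRET
    efficiency computation and smoothing, trajectory selection, population
    contour plots, Gaussian-emission hidden Markov model idealization
    (Baum-Welch/Viterbi with compiled inner loops), transition density
    plots, dwell-time survival analysis with censoring-aware exponential
    fits, state-fraction summaries and two-group comparisons.  A companion
    module implements optical-tweezers DNA unzipping mechanics: freely
    jointed chain and worm-like chain elasticity, extension to base pairs
    unzipped conversion, theoretical quasi-static unzipping curves from
    nearest-neighbour energetics, cross-correlation alignment and protein
    roadblock/tether-breakage detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    survival,
    utils
LinkingTo:
    Rcpp
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
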