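Package: alunuc
Title: Nucleotide Periodicity and Nucleosome Positioning Around Alu Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying how Alu short interspersed elements shape
    nucleosome organisation in primate genomes. Computes Welch-windowed
    Fourier power spectra and signal-to-noise periodicity profiles of mono-
    and dinucleotide steps over sampled genome fragments; classifies
    RepeatMasker Alu annotations into dimeric, FLAM and FRAM elements;
    builds smoothed nucleosome-centre signals from paired-end MNase tags
    and averages them around Alu elements with matched random backgrounds;
    profiles tiling-array hybridisation values by distance from element
    edges against a shuffled null; and measures 5'-tag expression rates in
    Alu bodies, flanks, transcription start sites and random controls. A
    seeded synthetic-data generator emits genomes with planted Alu-like
    elements, nucleosome tag pairs, probe grids and 5' tags so that every
    analysis stage can be verified in a closed loop.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    rlang,
    readr,
    ggplot2,
    generics,
    Biostrings,
    IRanges,
    S4Vectors,
    methods,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
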