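Package: khscan
Title: Exchangeability-Partitioned Ka/Ks Screen for Positive Selection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Pairwise screen for positively selected genes in closely related
    coding-sequence pairs using the Kh statistic: nonsynonymous substitutions
    are partitioned over the 75 elementary amino-acid exchange classes ranked
    by an evolutionary exchangeability index, and the cumulative
    Jukes-Cantor-corrected rate over the 10 most exchangeable classes (Kh =
    K10*) replaces Ka as the numerator of the classical Ka/Ks ratio.
    Includes kappa estimation from fourfold-degenerate sites, Fisher's exact
    significance tests, the gene filters and PSG calls of the screen, supergene
    concatenation with the twofold-approximation regression, and a
    mutation-selection codon-pair simulator for calibration and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
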