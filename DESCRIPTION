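Package: statpos
Title: Statistical Positioning of Nucleosomes by a Hard-Rod (Tonks) Gas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of statistical nucleosome positioning around
    promoter nucleosome-free regions. Provides the exact one-dimensional
    hard-rod (Tonks) gas density near a barrier as a finite sum of shifted
    Erlang densities, a grand-canonical lattice solver for hard rods in an
    arbitrary external energy landscape, construction of read-density and
    Gaussian-per-call nucleosome density maps, metagene alignment of density
    maps to the +1/-1 nucleosomes flanking nucleosome-free regions,
    multi-start least-squares fitting of the gas model with boundary-condition
    (direct versus statistical positioning) scenario comparison, and a
    synthetic-data generator that emulates gas configurations, MNase-seq-like
    reads, nucleosome calls and gene tables so the whole analysis is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
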