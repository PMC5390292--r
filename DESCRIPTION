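Package: ndwrap
Title: Shape-Dependent Nanoparticle Endocytosis: Contact Geometry,
    Adhesion Energetics and Uptake Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing how nanoparticle shape governs the two
    stages of endocytosis (membrane anchoring and internalization).
    Provides a Monte-Carlo model of membrane contact area for random
    irregular polygons with circular corner fillets; a weighted-histogram
    (WHAM) estimator that reconstructs one-dimensional potentials of mean
    force from umbrella-sampling windows and converts free-energy depths
    into unit adhesion strengths; a continuum membrane-wrapping energy
    model with wrapping/no-wrapping phase diagrams; quantification of
    anchored versus internalized particles from plate-reader fluorescence
    using the 4 degree / 37 degree Celsius temperature-split subtraction
    with photoluminescence-slope normalization; and seedable
    synthetic-data generators (biased umbrella-window samples from a known
    free-energy profile, structured plate assays) so every stage of the
    pipeline can be validated end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
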