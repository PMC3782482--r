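Package: flychain
Title: Automatic Scoring of Sound-Evoked Chaining Behavior in Drosophila
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores male-male courtship chaining in backlit Drosophila
    chamber videos. Segments fly silhouettes by background subtraction and
    Otsu thresholding, fits body ellipses by covariance eigen-decomposition,
    disambiguates head from tail with a Harris corner response, projects a
    fan-shaped chain region in front of each fly's head, and counts the
    per-frame chain index (flies participating in chasing chains, passive
    recipients included). Also provides the behavioral metrics built on the
    1-Hz chain-index series (block smoothing, phase-cumulative indices,
    per-fly chain probability, arcsine-square-root transforms and
    suppression/recovery/drop rates), a courtship-song stimulus synthesizer
    (pulse and sine songs with controllable inter-pulse interval, burst
    structure and sinusoidal IPI oscillation, written as PCM WAV), and a
    synthetic-scene renderer with ground-truth poses and a brute-force
    chain-index oracle for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
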