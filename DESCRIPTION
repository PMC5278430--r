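Package: echowing
Title: Ultrasonic Absorption of Moth Wings by the Reverberation-Chamber Method
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Measures random-incidence ultrasound absorption factors of moth
    wings with the small reverberation-chamber method, and models the
    consequences for detection of moths by echolocating bats. Implements
    reverberation-time estimation from steady-state decay recordings
    (third-octave Kaiser FIR filtering, Hilbert envelope, Lundeby-style
    noise-time estimation, Schroeder backward integration, linear regression),
    Sabine-type absorption factors with a band-averaged thermoviscous air
    correction, planform wing-area estimation from photographs (bilateral
    smoothing and two-class k-means++ binarisation), a sonar-equation
    detection-distance comparison solved in closed form with the Lambert W
    function, and the repeated-measures statistical battery (between-subjects
    ANOVA, Mauchly sphericity, Greenhouse-Geisser correction, Tukey-Kramer
    pairwise tests). A synthetic-data generator emulates chamber recordings,
    specimen photographs and absorption tables so the whole pipeline is
    testable without hardware or specimens.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    pracma,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    tiff,
    car,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
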