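Package: dsnurse
Title: Dempster-Shafer Multi-Sensor Fusion for Excretion-Care Event Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects urination and defecation events in an intelligent
    excretion-nursing device from temperature, humidity and ammonia sensor
    excursions. Per-sensor evidence is expressed as basic probability
    assignments over the four care events (urine, stool, both, none) and
    combined with Dempster's rule of combination, first across the three
    sensors within a read cycle and then across cycles; the fused mass
    function is decided by maximum mass. Includes the interval detection
    basis with a direct threshold baseline classifier, a datasheet-faithful
    synthetic sensor-event simulator, a deterministic flush/clean/dry
    actuator workflow simulator with alarm logic, and evaluation tools
    (accuracy, confusion matrices, McNemar's paired chi-square test).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
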