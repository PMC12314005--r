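Package: thermoherd
Title: Thermal-Stress Exposure and Behaviour Analysis for Grazing Cattle Sensor Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multimodal analysis pipeline for collar-based grazing-cattle studies:
    computes the Comprehensive Climate Index (CCI) from 10-minute weather records,
    aggregates 1 Hz GNSS fixes into 10-minute median positions with canopy/open
    classification and haversine travel distances, turns 5-second behaviour labels
    into hourly and daily day/night time budgets, ranks trial days by daily maximum
    CCI into paired-week exposure groups, and reports Pearson correlations with
    Fisher 95% confidence intervals (plus a Spearman cross-check) between thermal
    exposure, behaviour, shade use, weight gain and Bos indicus proportion.
    Includes a deterministic synthetic-trial generator with planted, parameterised
    CCI-dependent behavioural effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
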