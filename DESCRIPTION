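Package: ftirlipids
Title: Monitoring Microbial Lipogenesis by High-Throughput FTIR Spectroscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Chemometric pipeline for screening oleaginous microorganisms by
    Fourier transform infrared (FTIR) spectroscopy of biomass. Provides
    spectral preprocessing (Savitzky-Golay second derivatives and extended
    multiplicative signal correction), lipid band analytics (ester carbonyl
    peak height, olefinic peak position, replicate reproducibility), handling
    of GC-FID fatty acid reference data (internal-standard FAME
    quantification, SAT/MUFA/PUFA sums, unsaturation index), and partial
    least squares calibration of fatty acid parameters against spectra with
    day-segmented cross-validation. A synthetic-data generator emulates
    time-resolved microcultivation experiments with full ground truth so the
    pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
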