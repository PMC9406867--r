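Package: implantheat
Title: Heating-Risk Assessment for MRI Scans of Patients with Metallic
    Orthopaedic Implants
Version: 0.1.0
Authors@R:
    person("implantheat", "developers", email = "implantheat@example.org",
           role = c("aut", "cre"))
Description: Tools to assess the radiofrequency (RF) and gradient-coil (GC)
    heating risk of MRI examinations for patients carrying passive metallic
    orthopaedic implants (hip, knee, shoulder).  The RF channel factorises the
    TR-averaged specific absorption rate (SAR) into a sequence stress index
    and a configuration index obtained by flip-angle calibration of a transmit
    sensitivity map, computes whole-body and 10 g spatial averages, and checks
    them against IEC 60601-2-33 style limits.  The GC channel computes the
    eddy-current power deposited in the implant by switched gradient fields
    with a quasi-static solver and a Q-matrix quadratic form over the gradient
    waveform spectrum, then scales a unit-power Pennes bioheat solution to
    obtain temperature-rise metrics.  A three-tier risk classifier, synthetic
    phantom/implant/sequence fixtures, voxel-field I/O and a command-line
    interface complete the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
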