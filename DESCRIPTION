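Package: transferkin
Title: Depth-Sensor Kinematics and Reliability Analysis for Wheelchair Sitting-Pivot Transfers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing marker-less skeletal recordings of wheelchair
    sitting-pivot transfers captured with consumer depth sensors (Kinect V2,
    Kinect Azure, RealSense/Nuitrack). Reads per-sensor joint-center CSV time
    series, harmonizes each sensor's joint vocabulary onto a canonical
    five-joint trunk/arm representation, segments the lift phase of a transfer
    from the filtered pelvis trajectory, and computes four lift-phase features:
    pelvis displacement, shoulder plane of elevation, shoulder elevation and
    trunk flexion. Provides the reliability and agreement statistics used to
    compare sensors -- single-measure intraclass correlations ICC(2,1) and
    ICC(3,1) with F-based confidence intervals, Bland-Altman limits of
    agreement, percent agreement and confusion accuracy for binary transfer
    quality scores -- together with a synthetic transfer simulator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    knitr
Config/testthat/edition: 3
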