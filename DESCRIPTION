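Package: magcellflow
Title: Magnetophoretic Transport Simulation and Video Analysis of
    SPION-Magnetized Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward simulation of the remote magnetic guidance of cells
    magnetized with superparamagnetic iron oxide nanoparticles (SPIONs) in a
    microfluidic chamber: the field and gradient of an axially magnetized
    cylindrical permanent magnet, the force balance between magnetophoresis
    and Stokes drag, and advection-diffusion transport of the cell
    concentration plume, plus Lagrangian single-cell trajectories. A
    synthetic fluorescence-video generator renders the simulated plume into
    camera frames with ground-truth masks; a classical segmentation and
    descriptor pipeline extracts centroid, lateral drift, deflection angle,
    mask area and displacement rate with quality-control filtering; and an
    inverse calibration maps measured deflections back to SPIONs per cell
    with reliability gating and approximation-error reporting.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    pracma,
    stats,
    tiff,
    tools,
    utils,
    yaml,
    graphics,
    grDevices
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
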