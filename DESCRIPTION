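Package: nnpir
Title: Neural Network Potentials and Machine-Learned Infrared Spectra from
    Molecular Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for simulating molecular infrared spectra with
    machine-learned potential energy surfaces. Implements high-dimensional
    neural network potentials built on atom-centered symmetry functions with
    analytic forces, an element-decoupled extended Kalman filter for combined
    energy and force training, a neural-network model of environment-dependent
    atomic charges trained on molecular dipole moments and total charges,
    committee (ensemble) potentials with a disagreement-based uncertainty,
    adaptive sampling of reference data during molecular dynamics, atom-centered
    molecular fragmentation with hydrogen capping, a velocity-Verlet/Langevin
    molecular dynamics engine, and infrared spectra from the Fourier transform
    of the dipole-derivative autocorrelation function. Analytic surrogate
    reference potentials (Morse/harmonic bonded terms with point-charge dipoles)
    make the entire pipeline testable without electronic-structure codes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
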