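Package: cardioelast
Title: Personalized Lumped-Parameter Modeling of Left-Heart Hemodynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A zero-dimensional (lumped-parameter) model of the left heart and
    systemic circulation with Double-Hill time-varying elastance chambers, a
    Garcia net-pressure-gradient aortic valve, viscoelastic vessel segments and
    a three-element viscoelastic Windkessel. Provides stiff-capable simulation
    to a periodic steady state, subject-specific personalization of 20 model
    parameters by bounded nonlinear least squares against volumetric flow
    waveforms sampled at the mitral valve, aortic valve and ascending aorta,
    derived hemodynamic indices (stroke volume, cardiac output, systemic
    vascular resistance, total arterial compliance, effective orifice area,
    mitral E/A analysis, elastance time constants), a paired rest/stress
    synthetic-cohort generator for validation studies, and paired Wilcoxon
    signed-rank statistics with cohort summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    lhs,
    stats,
    utils,
    tools,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
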