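Package: cogrnn
Title: Biologically Constrained Recurrent Neural Networks for Cognitive Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Train continuous-time rate recurrent neural networks on
    parameterised cognitive tasks (perceptual discrimination, delayed
    discrimination, delayed match-to-category) under neurobiological
    connectivity constraints such as Dale's principle, forbidden connections
    and fixed synapses. Provides masked loss functions, explicit
    backpropagation through time, closed-loop curriculum learning (task
    shaping), a standalone simulator for lesion and perturbation studies, and
    psychometric and state-space analyses of trained networks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
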