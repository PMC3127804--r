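Package: sizedist
Title: Bayesian Observer Models for Size-Aided Distance Perception
Version: 0.1.0
Author: sizedist developers
Maintainer: sizedist developers <maintainers@sizedist.dev>
Description: Probabilistic observer models for monocular distance perception
    disambiguated by haptic size cues. Implements a linear-Gaussian sensation
    model in log coordinates, the explaining-away perceptual posterior over
    log-distance, MAP and posterior-sample-averaging decision rules, the
    closed-form per-trial response likelihood for a 12-member candidate model
    family, a synthetic interception-experiment simulator, Metropolis-Hastings
    posterior inference over model parameters, and DIC-based model comparison
    with parameter-recovery tooling.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    coda,
    jsonlite,
    yaml,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
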