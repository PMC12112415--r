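Package: plugingan
Title: Memory-Efficient Video Synthesis via Latent Trajectories over a Frozen Progressive GAN
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage generative adversarial training for video at modest
    memory cost. Stage one trains a progressively grown 2D frame generator and
    critic with the WGAN-GP objective on individual video frames. Stage two
    freezes that backbone and trains a small time-conditioned plugin network
    that traces unit-norm trajectories through the frame generator's latent
    space, adversarially against a 2D-convolutional video discriminator that
    sees stacked frame-critic features instead of raw pixel volumes. Includes
    seeded synthetic video generators (moving shapes, tunnel fly-through) with
    PNG frame-directory input/output, evaluation via Frechet distances between
    fitted Gaussians (FID on frames, FVD on clips) and the Inception Score
    over pluggable embedders, and a command-line pipeline. All networks,
    backpropagation, and optimisers are implemented on base R arrays.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    png,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
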