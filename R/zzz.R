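#' GeomDyn: geometric deep featurization for conformational dynamics
#'
#' Pretrains an equivariant graph neural network by coordinate denoising,
#' freezes it as a universal geometric featurizer, coarse-grains per-atom
#' features into residue-level structural tokens, and trains lightweight
#' token mixers for two dynamics tasks: slow collective-variable discovery
#' (VAMPnets) and metastable-state identification (State Predictive
#' Information Bottleneck), with Markov state models built from the learned
#' states.  Synthetic benchmark systems with analytically known kinetics
#' provide a complete offline test bed.
#'
#' @keywords internal
#' @import methods
#' @importFrom stats rnorm runif dist sd kmeans dnorm
#' @importFrom utils head tail packageVersion read.csv write.csv
"_PACKAGE"
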