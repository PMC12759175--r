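# Small seeded riverscapes used across test files.

randomScape <- function(seed, nReaches = 20, dams = 3, falls = 1,
                        planned = 0, ...) {
  cfg <- riverscapeConfig(nReaches = nReaches, nDamsExisting = dams,
                          nWaterfalls = falls, nDamsPlanned = planned,
                          seed = seed, ...)
  net <- placeBarriers(generateNetwork(cfg), cfg)
  list(network = net, config = cfg)
}

uniformSuit <- function(net, value = 1) {
  setNames(rep(value, nReaches(net)), reaches(net)$reach_id)
}

randomSuit <- function(net, seed) {
  set.seed(seed)
  setNames(runif(nReaches(net)), reaches(net)$reach_id)
}
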