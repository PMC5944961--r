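# shared fixtures built in code

toyDataset <- function(abundance = c(1, 1, 2, 3, 5), community = "DH",
                       layer = "herb") {
  layerDataset(paste0("sp", seq_along(abundance)), abundance,
               community = community, layer = layer)
}

# long-format CSV with two layers, returned as a path
writeToyTable <- function(path = tempfile(fileext = ".csv")) {
  writeLines(c("community,layer,species,abundance",
               "DH,herb,fern,5", "DH,herb,grass,2", "DH,herb,moss,1",
               "DH,shrub,ilex,4", "DH,shrub,rubus,4", "DH,shrub,rosa,1",
               "DH,shrub,vitex,1"),
             path)
  path
}

# noisy LC-shaped histogram with deterministic perturbation, for solver tests
noisyHistogram <- function(seed, octaves = 1:9,
                           params = c(S_m = 20, alpha = 0.8, R_m = 1)) {
  set.seed(seed)
  mu <- evaluateModel("LC", params, octaves)
  octaveHistogram(octaves, pmax(0, mu + rnorm(length(octaves), sd = 1)))
}

# dense brute-force SS minimum for a 3-parameter symmetric model
bruteForceSS <- function(name, h, SmGrid, alphaGrid, RmGrid) {
  R <- octaves(h)
  Sobs <- unname(octaveCounts(h))
  best <- Inf
  for (a in alphaGrid) for (rm in RmGrid) {
    shape <- evaluateModel(name, c(S_m = 1, alpha = a, R_m = rm), R)
    for (sm in SmGrid) {
      ss <- sum((Sobs - sm * shape) ^ 2)
      if (ss < best) best <- ss
    }
  }
  best
}
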