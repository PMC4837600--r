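# Shared fixtures: all synthetic, generated in code.

relErr <- function(est, truth) abs(est - truth) / abs(truth)

# Noiseless, background-free sample on a regular grid.
noiselessSample <- function(K, r, N0, dt = 1 / 6, tEnd = 24, wellId = "w") {
  generateCurve(
    syntheticCurveSpec(K = K, r = r, N0 = N0, tStart = 0, tEnd = tEnd,
                       dt = dt, noiseSd = 0, background = 0),
    wellId = wellId
  )
}

# A plate of wells with well-to-well parameter variation, as a real
# multi-strain plate would show; parameters drawn once per well from a
# seeded stream.
variedPlateSpecs <- function(nWells, masterSeed = 101, noiseSd = 0.005,
                             background = 0.09) {
  set.seed(masterSeed)
  Ks <- runif(nWells, 0.3, 1.2)
  rs <- runif(nWells, 0.4, 2.5)
  N0s <- Ks * runif(nWells, 5e-4, 0.02)
  specs <- lapply(seq_len(nWells), function(i)
    syntheticCurveSpec(K = Ks[i], r = rs[i], N0 = N0s[i],
                       noiseSd = noiseSd, background = background,
                       seed = masterSeed + i))
  names(specs) <- sprintf("W%d", seq_len(nWells))
  specs
}
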