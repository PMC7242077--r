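test_that("identical seeds reproduce identical tables, distinct seeds differ", {
  a <- simulateLabellingExperiment(seed = 9)
  b <- simulateLabellingExperiment(seed = 9)
  expect_identical(a, b)
  c <- simulateLabellingExperiment(seed = 10)
  expect_false(identical(a$intensities$intensity, c$intensities$intensity))
  qa <- simulateQuantTables(seed = 9); qb <- simulateQuantTables(seed = 9)
  expect_identical(qa, qb)
  pa <- simulateQPCRPlate(seed = 9); pb <- simulateQPCRPlate(seed = 9)
  expect_identical(pa, pb)
  expect_false(identical(pa$cq$Cq, simulateQPCRPlate(seed = 10)$cq$Cq))
})

test_that("unlabelled, artifact-free, noise-free samples are the natural-abundance binomial", {
  cfg <- simulationConfig(
    enrichment = list(proline = c(L15 = 0, L11 = 0, L7 = 0, L3 = 0)),
    nAtoms = c(proline = 1L),
    contents = list(proline = c(L15 = 1, L11 = 1, L7 = 1, L3 = 1)),
    artifactR = 0, noiseCV = 0)
  sim <- simulateLabellingExperiment(cfg, seed = 2)
  one <- sim$intensities[sim$intensities$sample_id == "L15_T4h_rep1", ]
  frac <- one$intensity / sum(one$intensity)
  expect_equal(frac, c(dbinom(0:1, 1, 0.003663), 0, 0, 0),
               tolerance = 1e-12)
})

test_that("saturating enrichment concentrates the signal at M+n", {
  cfg <- simulationConfig(
    enrichment = list(proline = c(L15 = 1, L11 = 1, L7 = 1, L3 = 1)),
    nAtoms = c(proline = 1L),
    contents = list(proline = c(L15 = 1, L11 = 1, L7 = 1, L3 = 1)),
    artifactR = 0, noiseCV = 0)
  sim <- simulateLabellingExperiment(cfg, seed = 2)
  one <- sim$intensities[sim$intensities$sample_id == "L7_T4h_rep2", ]
  frac <- one$intensity / sum(one$intensity)
  expect_equal(frac, c(0, 1, 0, 0, 0))
})

test_that("generated MIDs sum to the configured total intensity before noise", {
  cfg <- simulationConfig(noiseCV = 0, artifactR = 0)
  sim <- simulateLabellingExperiment(cfg, seed = 4)
  sums <- aggregate(intensity ~ sample_id + amino_acid + group,
                    sim$intensities, sum)
  smp <- sums[sums$group != "standard", ]
  for (i in seq_len(nrow(smp))) {
    expected <- cfg$totalIntensity *
      cfg$contents[[smp$amino_acid[i]]][[smp$group[i]]]
    expect_equal(smp$intensity[i], expected, tolerance = 1e-9)
  }
})

test_that("zero-noise qPCR plates carry the exact analytic Cq values", {
  cfg <- simulationConfig()
  cfg$qpcr$cqNoiseSD <- 0; cfg$qpcr$refSdLog2 <- 0
  plate <- simulateQPCRPlate(cfg, seed = 3)
  # reference gene at base expression 1: Cq equals the intercept exactly
  ub <- plate$cq[plate$cq$gene == "BnaC.UBQ11", ]
  expect_equal(ub$Cq, rep(cfg$qpcr$cqIntercept, nrow(ub)))
  # induced target at T1/treatment: Cq drops by log2FC / log2(E)
  tg <- plate$cq[plate$cq$gene == "BnaC.ProDH1b", ]
  base <- cfg$qpcr$targets$baseExpression[1]
  E <- cfg$qpcr$targets$efficiency[1]
  cq0 <- cfg$qpcr$cqIntercept - log(base) / log(E)
  expect_equal(unique(tg$Cq[tg$arm == "control"]), cq0)
  expect_equal(unique(tg$Cq[tg$arm == "treatment" & tg$timepoint == "T1"]),
               cq0 - 7 * log(2) / log(E))
})

test_that("the decoy gene ranks last by GeNorm M on generated plates", {
  plate <- simulateQPCRPlate(seed = 8)
  cqm <- averageTechnicalReplicates(plate$cq)
  cand <- c("BnaC.UBQ11", "BnaC.RibS3", "BnaDecoy")
  effs <- c(BnaC.UBQ11 = 2, BnaC.RibS3 = 2, BnaDecoy = 2)
  samples <- unique(cqm$sample_id)
  expr <- sapply(cand, function(g) {
    cqg <- cqm$Cq[match(paste(samples, g), paste(cqm$sample_id, cqm$gene))]
    effs[[g]]^(-cqg)
  })
  st <- geNormStability(expr)
  expect_equal(st$gene[nrow(st)], "BnaDecoy")
  rk <- geNormRank(expr)
  expect_equal(rk$gene[1L], "BnaDecoy")
})

test_that("invalid configurations fail with field-level messages", {
  expect_error(
    simulationConfig(enrichment = list(
      proline = c(L15 = 1.5, L11 = 0, L7 = 0, L3 = 0)),
      nAtoms = c(proline = 1L),
      contents = list(proline = c(L15 = 1, L11 = 1, L7 = 1, L3 = 1))),
    "enrichment\\$proline")
  expect_error(simulationConfig(artifactR = 1), "artifactR")
  expect_error(simulationConfig(nReplicates = 0), "nReplicates")
  cfg <- simulationConfig()
  cfg$qpcr$targets$efficiency[1] <- 0.9
  expect_error(validateSimulationConfig(cfg), "exceed 1")
  # nitrogen count above the tracked isotopologue range
  expect_error(
    simulationConfig(nAtoms = c(proline = 5L, glutamate = 1L,
                                glutamine = 2L)),
    "xMax")
})

test_that("quant tables are reproducible and distinct across three seeds", {
  tabs <- lapply(1:3, function(s) simulateQuantTables(seed = s))
  again <- lapply(1:3, function(s) simulateQuantTables(seed = s))
  expect_identical(tabs, again)
  expect_false(identical(tabs[[1]]$samples$area, tabs[[2]]$samples$area))
  expect_false(identical(tabs[[2]]$samples$area, tabs[[3]]$samples$area))
})
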