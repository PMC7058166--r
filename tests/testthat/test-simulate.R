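test_that("tree simulation is seeded and sized correctly", {
  t1 <- simulateSpeciesTree(2, seed = 5)
  expect_equal(length(leafLabels(t1)), 2L)
  a <- writeNewick(simulateSpeciesTree(12, seed = 9))
  b <- writeNewick(simulateSpeciesTree(12, seed = 9))
  expect_identical(a, b)
  expect_equal(nLineages(simulateSpeciesTree(132, seed = 1)), 263L)
  expect_error(simulateSpeciesTree(1), "at least 2")
})

test_that("zero rates give the root profile everywhere and no events", {
  st <- simulateSpeciesTree(10, seed = 13)
  cfg <- simulationConfig(dupRate = 0, lossRate = 0)
  gc <- simulateGeneContent(st, cfg, seed = 13)
  expect_true(all(t(copyCounts(gc$counts)) == ancestralProfile()))
  expect_equal(nrow(eventTable(gc$truth)), 0L)
})

test_that("a WGD branch doubles exactly its clade and records duplications", {
  st <- parseNewick("((A,B),C);")
  cfg <- simulationConfig(dupRate = 0, lossRate = 0,
                          wgdBranches = "A..B",
                          rootProfile = c(F = 1L))
  gc <- simulateGeneContent(st, cfg, seed = 1)
  expect_equal(copyCounts(gc$counts)[, "F"], c(A = 2L, B = 2L, C = 1L))
  tab <- eventTable(gc$truth)
  expect_equal(tab$lineage_id, "A..B")
  expect_equal(tab$n_dup, 1L)
})

test_that("loss totals follow the Poisson expectation", {
  ## 251 taxa -> 500 branches; rate 0.05 -> mean 25, sd 5
  st <- simulateSpeciesTree(251, seed = 17)
  cfg <- simulationConfig(dupRate = 0, lossRate = 0.05,
                          rootProfile = c(F = 3L))
  gc <- simulateGeneContent(st, cfg, seed = 17)
  tot <- sum(eventTable(gc$truth)$n_loss)
  expect_gt(tot, 25 - 3 * 5)
  expect_lt(tot, 25 + 3 * 5)
})

test_that("replaying the truth map reproduces the simulated matrix", {
  set.seed(19)
  for (r in 1:10) {
    st <- simulateSpeciesTree(sample(4:20, 1))
    st <- markParasiticClades(st, 0.25)
    cfg <- simulationConfig(dupRate = 0.1, lossRate = 0.2,
                            parasiticLossMultiplier = 3)
    gc <- simulateGeneContent(st, cfg)
    for (f in names(cfg$rootProfile)) {
      expect_equal(replayEvents(st, gc$truth, family = f),
                   copyCounts(gc$counts)[leafLabels(st), f],
                   ignore_attr = TRUE)
    }
  }
})

test_that("generators are bit-reproducible given config and seed", {
  cfg <- simulationConfig(parasiticLossMultiplier = 5)
  a <- simulateDataset(20, seed = 23, nWgdBranches = 2)
  b <- simulateDataset(20, seed = 23, nWgdBranches = 2)
  expect_identical(copyCounts(a$counts), copyCounts(b$counts))
  expect_identical(a$sequences$sequences, b$sequences$sequences)
  expect_identical(eventTable(a$truth), eventTable(b$truth))
  expect_identical(a$metrics, b$metrics)
})

test_that("parasitic clade marking hits the target fraction consistently", {
  set.seed(29)
  fr <- replicate(20, {
    st <- markParasiticClades(simulateSpeciesTree(64), 0.25)
    nd <- nodeData(st)
    ## propagation invariant holds by construction
    mean(nd$parasitic)
  })
  expect_true(all(fr >= 0.2 & fr <= 0.35))
})

test_that("zero-probability substitutions reproduce the reference", {
  cfg <- simulationConfig(seqLength = 60L, motifs = motifSpec(41, 55),
                          backgroundSubProb = 0,
                          motifSubProb = c(centriole = 0,
                                           no_centriole = 0))
  taxa <- data.frame(taxon = c("t1", "t2"), centrioles = c(TRUE, FALSE))
  sim <- simulateOrc1Sequences(taxa, cfg, seed = 31)
  expect_true(all(sim$sequences == sim$sequences[["Hsap"]]))
  tab <- pactTable(sim$sequences, "Hsap", sim$motifs, preAligned = TRUE)
  expect_true(all(tab$identity_ratio == 1))
})

test_that("a fully conserved motif over a half-conserved background doubles the ratio", {
  cfg <- simulationConfig(seqLength = 400L, motifs = motifSpec(301, 360),
                          backgroundSubProb = 0.5,
                          motifSubProb = c(centriole = 0,
                                           no_centriole = 0))
  taxa <- data.frame(taxon = sprintf("t%02d", 1:20), centrioles = TRUE)
  sim <- simulateOrc1Sequences(taxa, cfg, seed = 37)
  tab <- pactTable(sim$sequences, "Hsap", sim$motifs, preAligned = TRUE)
  ## background identity ~ Binomial(340, 0.5)/340: ratio ~ 2 within CI
  expect_equal(mean(tab$identity_ratio), 2, tolerance = 0.1)
})
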