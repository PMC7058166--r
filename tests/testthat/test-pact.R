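test_that("the codon-distance table is a valid symmetric 0-3 matrix", {
  fm <- fitchMatrix()
  expect_equal(dim(fm), c(20L, 20L))
  expect_true(all(diag(fm) == 0))
  expect_identical(fm, t(fm))
  expect_true(all(fm %in% 0:3))
  ## single-nucleotide neighbours vs distant pairs
  expect_equal(fm["D", "E"], 1L)   # GAU/GAC -> GAA/GAG
  expect_gt(fm["W", "P"], 1L)
})

test_that("identical sequences align gap-free with unit identity", {
  s <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"
  a <- globalAlign(s, s)
  expect_equal(a@ref, s)
  expect_equal(a@query, s)
  cols <- list(ref = strsplit(a@ref, "")[[1]],
               query = strsplit(a@query, "")[[1]])
  expect_equal(unname(conservationMeasures(cols)["identity"]), 1.0)
})

test_that("alignment scores equal the brute-force affine DP", {
  expect_equal(globalAlign("HEAGAWGHEE", "PAWHEAE")@score,
               nwOracleScore("HEAGAWGHEE", "PAWHEAE", blosum62))
  set.seed(91)
  for (i in 1:40) {
    a <- randProtein(sample(3:12, 1))
    b <- randProtein(sample(3:12, 1))
    expect_equal(globalAlign(a, b)@score, nwOracleScore(a, b, blosum62))
  }
})

test_that("forced gap structure and input validation", {
  a <- globalAlign("MKTAY", "K")
  expect_equal(sum(strsplit(a@query, "")[[1]] == "-"), 4L)
  expect_error(globalAlign("", "MK"), "empty")
  expect_error(globalAlign("MKB", "MK"), "illegal character")
})

test_that("motif/background split follows reference coordinates", {
  aln <- alignmentPair("MKTAYI", "MKTAYI")
  sp <- splitByMotifs(aln, motifSpec(1, 3))
  expect_equal(length(sp$motif$ref), 3L)
  expect_equal(length(sp$background$ref), 3L)

  sp2 <- splitByMotifs(aln, motifSpec(c(2, 5), c(3, 5)))
  expect_equal(length(sp2$motif$ref), 3L)

  ## reference-gap column inside a motif span goes to background
  aln3 <- alignmentPair("MK-TAY", "MKQTAY")
  sp3 <- splitByMotifs(aln3, motifSpec(1, 3))
  expect_equal(length(sp3$motif$ref), 3L)      # M, K, T
  expect_true("-" %in% sp3$background$ref)

  expect_error(splitByMotifs(aln, motifSpec(1, 10)), "beyond reference")
  expect_error(motifSpec(c(1, 3), c(4, 6)), "overlap")
})

test_that("conservation measures respect gaps, ties and the threshold", {
  cols <- list(ref = c("A", "D", "W"), query = c("A", "E", "P"))
  m <- conservationMeasures(cols, threshold = 1)
  expect_equal(unname(m["identity"]), 1 / 3, tolerance = 1e-12)
  expect_equal(unname(m["similarity"]), 2 / 3, tolerance = 1e-12)

  allsame <- list(ref = c("A", "C"), query = c("A", "C"))
  expect_equal(unname(conservationMeasures(allsame)), c(1, 1))

  gappy <- list(ref = c("A", "C"), query = c("-", "-"))
  expect_error(conservationMeasures(gappy), "ungapped")

  ## similarity >= identity always
  set.seed(92)
  for (i in 1:30) {
    k <- sample(3:30, 1)
    cols <- list(ref = sample(c(orcEvo:::.AA_LETTERS, "-"), k, TRUE),
                 query = sample(c(orcEvo:::.AA_LETTERS, "-"), k, TRUE))
    keep <- cols$ref != "-" & cols$query != "-"
    if (!any(keep)) next
    m <- conservationMeasures(cols)
    expect_gte(m[["similarity"]], m[["identity"]])
  }
})

test_that("pact ratios behave on constructed fixtures", {
  motifs <- motifSpec(1, 10)
  ref <- paste(rep("A", 20), collapse = "")
  expect_equal(pactRatio(ref, ref, motifs)$identity_ratio, 1.0)

  ## mutate only outside the motif: background identity 0.5 -> ratio 2
  q <- paste(c(rep("A", 10), rep(c("A", "W"), 5)), collapse = "")
  rec <- pactRatio(ref, q, motifs, aln = alignmentPair(ref, q))
  expect_equal(rec$identity_nonPACT, 0.5)
  expect_equal(rec$identity_ratio, 2.0)

  ## zero background identity is an error
  q0 <- paste(c(rep("A", 10), rep("W", 10)), collapse = "")
  expect_error(pactRatio(ref, q0, motifs, aln = alignmentPair(ref, q0)),
               "undefined")
})

test_that("centriole-group comparison reports medians and P-values", {
  motifs <- motifSpec(1, 5)
  set.seed(93)
  recs <- do.call(rbind, lapply(1:12, function(i) {
    data.frame(taxon = paste0("t", i),
               identity_PACT = 1, identity_nonPACT = 1,
               similarity_PACT = 1, similarity_nonPACT = 1,
               identity_ratio = 1 + 0.01 * i,
               similarity_ratio = 1 + 0.01 * i,
               centrioles = rep(c(TRUE, FALSE), 6)[i])
  }))
  out <- compareCentrioleGroups(recs)
  expect_s4_class(out$identity, "StatResult")
  expect_equal(out$medians$n, c(6L, 6L))
  recs$centrioles <- TRUE
  expect_error(compareCentrioleGroups(recs), "non-empty")
})

test_that("group comparison has power when the motif effect is real", {
  cfg <- simulationConfig(seqLength = 120L, motifs = motifSpec(81, 110),
                          backgroundSubProb = 0.5,
                          motifSubProb = c(centriole = 0.1,
                                           no_centriole = 0.5))
  hits <- sum(vapply(1:20, function(s) {
    set.seed(4000 + s)
    taxa <- data.frame(taxon = sprintf("t%02d", 1:40),
                       centrioles = rep(c(TRUE, FALSE), each = 20))
    sim <- simulateOrc1Sequences(taxa, cfg)
    tab <- pactTable(sim$sequences, "Hsap", sim$motifs,
                     meta = taxa, preAligned = TRUE)
    compareCentrioleGroups(tab)$identity@p.value < 0.01
  }, logical(1)))
  expect_gte(hits, 19)
})
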