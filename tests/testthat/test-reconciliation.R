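test_that("a clade-wide absence is explained by one stem loss", {
  tr <- parseNewick("(((Ehis,Enut),Einv),Out);")
  ev <- inferEvents(tr, c(Ehis = 0, Enut = 0, Einv = 0, Out = 1),
                    rootCount = 1, family = "ORC2")
  tab <- eventTable(ev)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$n_loss, 1L)
  ## the loss sits on the stem of the three-species clade
  nd <- nodeData(tr)
  tu <- orcEvo:::.tipsUnder(treePhylo(tr))
  stem <- nd$id[vapply(tu, function(x) length(x) == 3L, logical(1))]
  expect_equal(tab$lineage_id, stem)
  expect_equal(replayEvents(tr, ev),
               c(Ehis = 0L, Enut = 0L, Einv = 0L, Out = 1L))
})

test_that("species-specific-paralog constraints force terminal duplications", {
  tr <- parseNewick("((Cang,Amac),Out);")
  counts <- c(Cang = 2, Amac = 2, Out = 1)
  cs <- constraintSet(data.frame(family = "ORC4",
                                 taxon = c("Cang", "Amac"), min_dup = 1L))
  ev <- inferEvents(tr, counts, rootCount = 1, family = "ORC4",
                    constraints = cs)
  tab <- eventTable(ev)
  expect_setequal(tab$lineage_id, c("Cang", "Amac"))
  expect_equal(sum(tab$n_dup), 2L)

  ## without the constraint a single ancestral duplication is cheaper
  free <- eventTable(inferEvents(tr, counts, rootCount = 1,
                                 family = "ORC4"))
  expect_equal(sum(free$n_dup), 1L)
  expect_false(any(free$lineage_id %in% c("Cang", "Amac")))

  ## constraints can only add events
  expect_gte(sum(tab$n_dup + tab$n_loss), sum(free$n_dup + free$n_loss))
})

test_that("uniform counts need no events; infeasibilities error", {
  tr <- parseNewick("((A,B),C);")
  ev <- inferEvents(tr, c(A = 2, B = 2, C = 2), rootCount = 2,
                    family = "CDC6/ORC1")
  expect_equal(nrow(eventTable(ev)), 0L)
  expect_error(inferEvents(tr, c(A = 1, B = 0, C = 0), rootCount = 0,
                           family = "F"), "single-origin")
  cs <- constraintSet(data.frame(family = "F", taxon = "A", min_dup = 3L))
  expect_error(inferEvents(tr, c(A = 1, B = 1, C = 1), rootCount = 1,
                           family = "F", constraints = cs), "infeasible")
})

test_that("forbidden-clade constraints veto stem duplications", {
  tr <- parseNewick("((A,B),C);")
  counts <- c(A = 2, B = 2, C = 1)
  free <- eventTable(inferEvents(tr, counts, rootCount = 1, family = "F"))
  expect_equal(free$lineage_id, "A..B")
  cs <- constraintSet(forbiddenClades = data.frame(family = "F",
                                                   clade_id = "A..B"))
  forced <- eventTable(inferEvents(tr, counts, rootCount = 1, family = "F",
                                   constraints = cs))
  expect_false("A..B" %in% forced$lineage_id[forced$n_dup > 0])
  expect_equal(sum(forced$n_dup), 2L)
})

test_that("replay applies events along paths and guards negatives", {
  tr <- parseNewick("((A,B),C);")
  em <- new("EventMap",
            events = data.frame(lineage_id = "A..B", family = "F",
                                n_dup = 0L, n_loss = 2L),
            rootCounts = c(F = 1L))
  expect_error(replayEvents(tr, em), "exceeds available copies")
  em2 <- new("EventMap", events = orcEvo:::.emptyEvents(),
             rootCounts = c(F = 2L))
  expect_equal(replayEvents(tr, em2), c(A = 2L, B = 2L, C = 2L))
})

test_that("parsimony total matches exhaustive Dollo minimization (spot sample)", {
  set.seed(31)
  for (i in 1:60) {
    n <- sample(3:6, 1)
    st <- randSpeciesTree(n)
    counts <- setNames(sample(0:3, n, replace = TRUE), leafLabels(st))
    rootCount <- sample(1:2, 1)
    oracle <- reconOracleMin(st, counts, rootCount)
    if (!is.finite(oracle)) next
    ev <- inferEvents(st, counts, rootCount = rootCount, family = "F")
    expect_equal(sum(eventTable(ev)$n_dup + eventTable(ev)$n_loss),
                 oracle)
    expect_equal(replayEvents(st, ev), counts[leafLabels(st)],
                 ignore_attr = TRUE)
  }
})

test_that("multifurcations are handled natively", {
  tr <- parseNewick("((A,B,C),D);")
  ev <- inferEvents(tr, c(A = 0, B = 0, C = 0, D = 1), rootCount = 1,
                    family = "F")
  expect_equal(sum(eventTable(ev)$n_loss), 1L)
  expect_equal(replayEvents(tr, ev), c(A = 0L, B = 0L, C = 0L, D = 1L))
})

test_that("tallies aggregate per family, globally and per class", {
  st <- parseNewick("((P1,P2),F1);")
  st <- propagateLifestyle(st, c("P1", "P2"))
  em <- new("EventMap",
            events = data.frame(
              lineage_id = c("P1..P2", "F1"),
              family = c("ORC3", "ORC2"),
              n_dup = c(0L, 2L), n_loss = c(1L, 0L)),
            rootCounts = c(ORC3 = 1L, ORC2 = 1L))
  tl <- tallyEvents(em, countLineages(st))
  expect_equal(unname(tl$global), c(1, 2))
  expect_equal(tl$perFamily$losses[tl$perFamily$family == "ORC3"], 1)
  pc <- tl$perClass
  expect_equal(pc$losses[pc$class == "parasitic"], 1)
  expect_equal(pc$duplications[pc$class == "parasitic"], 0)
})

test_that("low-rate simulations are tallied back exactly", {
  ## rates low enough that parsimony is exact: tallies equal truth
  set.seed(41)
  cfg <- simulationConfig(dupRate = 0.01, lossRate = 0.01)
  hits <- 0
  for (r in 1:20) {
    st <- simulateSpeciesTree(10)
    gc <- simulateGeneContent(st, cfg)
    inf <- inferAllEvents(st, gc$counts)
    if (identical(unname(tallyEvents(inf)$global),
                  unname(tallyEvents(gc$truth)$global)))
      hits <- hits + 1
  }
  expect_gte(hits, 18)
})
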