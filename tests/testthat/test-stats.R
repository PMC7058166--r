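test_that("Fisher upper tail matches enumeration and closed forms", {
  ## certain event: upper tail from the support minimum
  expect_equal(fisherOneTailed(matrix(c(0, 5, 5, 5), 2, byrow = TRUE))@p.value,
               1.0)
  ## exhaustive enumeration: [[3,1],[1,3]] -> 17/70
  expect_equal(fisherOneTailed(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))@p.value,
               17 / 70, tolerance = 1e-12)
  expect_error(fisherOneTailed(matrix(0L, 2, 2)), "all-zero")

  set.seed(51)
  for (i in 1:50) {
    tab <- matrix(sample(0:30, 4, replace = TRUE), 2)
    if (sum(tab) == 0) next
    p <- fisherOneTailed(tab)@p.value
    expect_equal(p, fisherUpperOracle(tab), tolerance = 1e-10)
    expect_equal(p, stats::fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-9)
  }
})

test_that("Fisher pmf sums to one and the tail is monotone in a", {
  set.seed(52)
  for (i in 1:30) {
    tab <- matrix(sample(1:40, 4, replace = TRUE), 2)
    sup <- orcEvo:::.fisherSupportPmf(tab)
    expect_lt(abs(sum(sup$pmf) - 1), 1e-12)
    ## P(X >= support minimum) = 1 exactly
    tmin <- tab
    shift <- tab[1, 1] - min(sup$support)
    tmin[1, 1] <- tab[1, 1] - shift; tmin[1, 2] <- tab[1, 2] + shift
    tmin[2, 1] <- tab[2, 1] + shift; tmin[2, 2] <- tab[2, 2] - shift
    expect_equal(fisherOneTailed(tmin)@p.value, 1.0, tolerance = 1e-12)
    ## non-increasing in a with margins fixed
    ps <- vapply(sup$support, function(a) {
      d <- a - tab[1, 1]
      t2 <- tab + matrix(c(d, -d, -d, d), 2, byrow = TRUE)
      fisherOneTailed(t2)@p.value
    }, numeric(1))
    expect_true(all(diff(ps) <= 1e-12))
  }
})

test_that("Mann-Whitney exact path matches enumeration and wilcox.test", {
  r <- mannWhitney(c(1, 2, 3), c(4, 5, 6), alternative = "less")
  expect_equal(r@p.value, 1 / 20)
  expect_equal(unname(r@statistic), 0)
  expect_equal(r@method, "exact")

  expect_equal(mannWhitney(c(1, 2, 3), c(1, 2, 3))@p.value, 1.0)

  set.seed(61)
  for (i in 1:30) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    z <- sample(1:50, n1 + n2)           # no ties
    x <- z[1:n1]; y <- z[-(1:n1)]
    for (alt in c("two.sided", "less", "greater")) {
      mine <- mannWhitney(x, y, alternative = alt)@p.value
      ref <- stats::wilcox.test(x, y, alternative = alt,
                                exact = TRUE)$p.value
      expect_equal(mine, ref, tolerance = 1e-12)
      if (alt != "two.sided")
        expect_equal(mine, mwEnumOracle(x, y, alt), tolerance = 1e-12)
    }
  }
})

test_that("Mann-Whitney permutation mode handles ties via midranks", {
  x <- c(1, 1, 2); y <- c(2, 3, 3)
  p <- mannWhitney(x, y, alternative = "less", method = "exact")@p.value
  expect_equal(p, mwEnumOracle(x, y, "less"), tolerance = 1e-12)
  ## tied samples fall back to the corrected normal approximation in auto
  r <- mannWhitney(x, y, alternative = "less")
  expect_equal(r@method, "normal-approximation")
  expect_equal(r@p.value,
               suppressWarnings(stats::wilcox.test(x, y,
                 alternative = "less", correct = TRUE)$p.value),
               tolerance = 1e-10)
  expect_error(mannWhitney(numeric(0), 1:3), "non-empty")
})

test_that("Spearman rho is Pearson on midranks, +-1 on monotone data", {
  expect_equal(unname(spearmanRho(1:10, (1:10)^3)@statistic), 1)
  expect_equal(unname(spearmanRho(1:10, -(1:10))@statistic), -1)
  expect_equal(unname(spearmanRho(c(1, 2, 3, 4), c(2, 1, 4, 3))@statistic),
               0.6)
  set.seed(71)
  for (i in 1:30) {
    n <- sample(4:20, 1)
    x <- sample(1:8, n, replace = TRUE)   # ties present
    y <- sample(1:8, n, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(unname(spearmanRho(x, y)@statistic),
                 suppressWarnings(stats::cor(x, y, method = "spearman")),
                 tolerance = 1e-12)
    ## invariance under strictly monotone transforms
    expect_equal(unname(spearmanRho(exp(x), y)@statistic),
                 unname(spearmanRho(x, y)@statistic), tolerance = 1e-12)
  }
  expect_error(spearmanRho(rep(1, 5), 1:5), "constant")
})

## helpers to build synthetic event maps over a plain lineage set
.linset <- function(L, K) new("LineageSet",
  ids = sprintf("L%03d", 1:L),
  parasitic = c(rep(TRUE, K), rep(FALSE, L - K)),
  wgd = rep(FALSE, L))

.lossMap <- function(lineages, nIn, nOut) {
  ids <- c(sample(lineages@ids[lineages@parasitic], nIn, replace = TRUE),
           sample(lineages@ids[!lineages@parasitic], nOut, replace = TRUE))
  tab <- table(ids)
  new("EventMap",
      events = data.frame(lineage_id = names(tab), family = "F",
                          n_dup = 0L, n_loss = as.integer(tab)),
      rootCounts = c(F = 1L))
}

test_that("enrichment builds the printed-count table and detects extremes", {
  set.seed(81)
  lin <- .linset(263, 83)
  em <- .lossMap(lin, 41, 28)
  res <- enrichmentTest(em, lin, "loss", "parasitic")
  expect_equal(unname(res@extra$table),
               matrix(c(41, 28, 83, 180), 2, byrow = TRUE),
               ignore_attr = TRUE)
  expect_equal(res@p.value, 2.43e-05, tolerance = 0.05)

  ## all losses in a balanced class: clearly enriched
  lin2 <- .linset(40, 20)
  em2 <- .lossMap(lin2, 15, 0)
  expect_lt(enrichmentTest(em2, lin2, "loss", "parasitic")@p.value, 0.05)

  expect_error(enrichmentTest(em2, .linset(40, 0), "loss", "parasitic"),
               "empty lineage class")
})

test_that("proportionally placed events are not flagged as enriched", {
  set.seed(82)
  ps <- replicate(100, {
    L <- sample(80:300, 1)
    K <- round(L * runif(1, 0.2, 0.5))
    nIn <- sample(3:10, 1)
    ratio <- K / (L - K)
    nOut <- max(1L, round(nIn / ratio))
    lin <- .linset(L, K)
    enrichmentTest(.lossMap(lin, nIn, nOut), lin, "loss",
                   "parasitic")@p.value
  })
  expect_true(all(ps >= 0.3))
})

test_that("enrichment type-I error is controlled under uniform placement", {
  set.seed(83)
  lin <- .linset(263, 83)
  rej <- mean(replicate(2000, {
    k <- sum(sample(263, 69, replace = TRUE) <= 83)
    fisherOneTailed(matrix(c(k, 69 - k, 83, 180), 2,
                           byrow = TRUE))@p.value < 0.05
  }))
  expect_lte(rej, 0.07)
})

test_that("the placement construction is available behind a flag", {
  set.seed(84)
  lin <- .linset(263, 20)
  lin@wgd <- lin@parasitic; lin@parasitic <- rep(FALSE, 263)
  ids <- c(sample(lin@ids[lin@wgd], 11), sample(lin@ids[!lin@wgd], 28))
  em <- new("EventMap",
            events = data.frame(lineage_id = ids, family = "F",
                                n_dup = 1L, n_loss = 0L),
            rootCounts = c(F = 1L))
  m <- enrichmentTest(em, lin, "duplication", "wgd", "margins")
  p <- enrichmentTest(em, lin, "duplication", "wgd", "placement")
  expect_equal(unname(m@extra$table[1, ]), c(11, 28))
  expect_equal(p@p.value,
               sum(stats::dhyper(11:20, 20, 243, 39)), tolerance = 1e-10)
})
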