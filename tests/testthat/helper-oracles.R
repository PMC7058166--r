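## Independent brute-force oracles used across the suite.  Each is a
## deliberately naive reimplementation of the quantity it checks, kept
## free of the package's own code paths.

## Gotoh affine-gap global alignment score; gap of length L costs
## open + L * ext (the same convention as the package aligner)
nwOracleScore <- function(a, b, mat, open = 10, ext = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)   # gap in b (consumes a)
  Iy <- matrix(NEG, n + 1, m + 1)   # gap in a (consumes b)
  M[1, 1] <- 0
  for (i in seq_len(n)) Ix[i + 1, 1] <- -(open + i * ext)
  for (j in seq_len(m)) Iy[1, j + 1] <- -(open + j * ext)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- mat[av[i], bv[j]]
    M[i + 1, j + 1] <- s + max(M[i, j], Ix[i, j], Iy[i, j])
    Ix[i + 1, j + 1] <- max(M[i, j + 1] - (open + ext),
                            Ix[i, j + 1] - ext,
                            Iy[i, j + 1] - (open + ext))
    Iy[i + 1, j + 1] <- max(M[i + 1, j] - (open + ext),
                            Iy[i + 1, j] - ext,
                            Ix[i + 1, j] - (open + ext))
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

## exhaustive minimal event total over all ancestral copy-number
## assignments in {0..max+1}, Dollo-filtered (a zero node forces zero on
## all its children), root fixed at rootCount
reconOracleMin <- function(st, leafCounts, rootCount) {
  ph <- treePhylo(st)
  ntip <- length(ph$tip.label)
  nn <- ntip + ph$Nnode
  cnt <- as.integer(leafCounts[ph$tip.label])
  kids <- ph$edge[, 2]
  root <- setdiff(seq_len(nn), kids)
  internals <- setdiff((ntip + 1):nn, root)
  hi <- max(cnt, rootCount) + 1L
  state <- integer(nn)
  state[seq_len(ntip)] <- cnt
  state[root] <- rootCount
  if (length(internals) == 0L) {
    return(sum(abs(state[ph$edge[, 1]] - state[ph$edge[, 2]])))
  }
  grid <- as.matrix(expand.grid(rep(list(0:hi), length(internals))))
  ## one column of states per node, one row per candidate assignment
  S <- matrix(rep(state, each = nrow(grid)), nrow(grid), nn)
  S[, internals] <- grid
  par <- S[, ph$edge[, 1], drop = FALSE]
  chi <- S[, ph$edge[, 2], drop = FALSE]
  ok <- rowSums(par == 0L & chi > 0L) == 0L   # Dollo: no regain below zero
  if (!any(ok)) return(Inf)
  min(rowSums(abs(par - chi))[ok])
}

## exact Mann-Whitney tail by full enumeration of rank splits
mwEnumOracle <- function(x, y, alternative = "less") {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y), ties.method = "average")
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- combn(n1 + n2, n1)
  us <- apply(idx, 2, function(k) sum(r[k]) - n1 * (n1 + 1) / 2)
  mu <- n1 * n2 / 2
  switch(alternative,
    greater = mean(us >= u - 1e-9),
    less = mean(us <= u + 1e-9),
    two.sided = mean(abs(us - mu) >= abs(u - mu) - 1e-9))
}

## hypergeometric upper tail via stats::dhyper (independent of the
## package's log-factorial summation)
fisherUpperOracle <- function(tab) {
  a <- tab[1, 1]; r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  hi <- min(r1, c1)
  sum(stats::dhyper(a:hi, r1, r2, c1))
}

## random protein sequence
randProtein <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
               replace = TRUE), collapse = "")
}

## random rooted tree (topology only) as a SpeciesTree
randSpeciesTree <- function(n) {
  ph <- ape::rtree(n, rooted = TRUE)
  ph$edge.length <- NULL
  speciesTree(ph)
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})
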