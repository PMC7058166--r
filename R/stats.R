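## Exact statistics used by the enrichment and conservation analyses:
## one-tailed Fisher exact test (hypergeometric upper tail by log-factorial
## summation), Mann-Whitney U (exact U distribution by counting recurrence,
## full permutation enumeration, or tie/continuity-corrected normal
## approximation), and Spearman rank correlation (Pearson on midranks).

.lchooseSafe <- function(n, k) ifelse(k < 0 | k > n, -Inf, lchoose(n, k))

## log pmf of the (1,1) cell of a 2x2 table with fixed margins
.hyperLogPmf <- function(x, r1, r2, c1) {
  .lchooseSafe(r1, x) + .lchooseSafe(r2, c1 - x) - lchoose(r1 + r2, c1)
}

#' One-tailed Fisher exact test (upper tail)
#'
#' Computes \eqn{P(X \ge a)} for the top-left cell of a 2x2 table under
#' the hypergeometric distribution with all margins fixed, by exact
#' summation of log-factorial terms (no approximation).
#'
#' @param table 2x2 integer matrix \code{[[a, b], [c, d]]}.
#' @return a \linkS4class{StatResult}; the statistic is the observed
#'   cell \code{a}, \code{extra$table} keeps the input.
#' @examples
#' ## losses on parasitic lineages: 41/69 events, 83/263 lineages
#' fisherOneTailed(matrix(c(41, 28, 83, 180), 2, byrow = TRUE))
#' @export
fisherOneTailed <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2L)) stop("need a 2x2 table")
  if (any(table < 0) || any(table != round(table)))
    stop("cells must be non-negative integers")
  if (sum(table) == 0L) stop("all-zero table")
  a <- table[1, 1]; r1 <- sum(table[1, ]); r2 <- sum(table[2, ])
  c1 <- sum(table[, 1])
  lo <- max(0L, c1 - r2); hi <- min(r1, c1)
  support <- lo:hi
  logp <- .hyperLogPmf(support, r1, r2, c1)
  p <- sum(exp(logp[support >= a]))
  new("StatResult", test = "Fisher exact (upper tail)",
      statistic = c(a = a), p.value = min(1, p), tails = "one",
      method = "exact", extra = list(table = table))
}

## pmf of the hypergeometric support of a table; exposed for invariants
.fisherSupportPmf <- function(table) {
  a <- table[1, 1]; r1 <- sum(table[1, ]); r2 <- sum(table[2, ])
  c1 <- sum(table[, 1])
  lo <- max(0L, c1 - r2); hi <- min(r1, c1)
  support <- lo:hi
  list(support = support, pmf = exp(.hyperLogPmf(support, r1, r2, c1)))
}

## null distribution of U over 0..n1*n2: the number of n1-subsets of the
## pooled ranks with statistic u equals the number of partitions of u
## into at most n1 parts each at most n2 (Mann & Whitney's recurrence)
.uCounts <- function(n1, n2) {
  umax <- n1 * n2
  memo <- new.env(parent = emptyenv())
  p <- function(u, k, m) {
    if (u < 0) return(0)
    if (k == 0L) return(as.numeric(u == 0))
    if (m == 0L) return(as.numeric(u == 0))
    key <- paste(u, k, m)
    v <- memo[[key]]
    if (!is.null(v)) return(v)
    ## partitions of u into at most k parts, each at most m
    v <- p(u - m, k - 1L, m) + p(u, k, m - 1L)
    memo[[key]] <- v
    v
  }
  vapply(0:umax, function(u) p(u, n1, n2), numeric(1))
}

.uStatistic <- function(x, y) {
  r <- rank(c(x, y), ties.method = "average")
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Mann-Whitney U test
#'
#' The U statistic is reported for sample \code{x} (number of
#' \code{(x, y)} pairs with \code{x > y}, ties counted half).
#' \code{method = "auto"} uses the exact U distribution (counting
#' recurrence) when \code{length(x) + length(y) <= 20} and there are no
#' ties, and the normal approximation with tie and continuity
#' corrections otherwise; \code{method = "exact"} enumerates all
#' assignments of the pooled midranks regardless of ties (permutation
#' null).
#'
#' @param x,y numeric samples.
#' @param alternative \code{"two.sided"}, \code{"less"} (x shifted
#'   left), or \code{"greater"}.
#' @param method \code{"auto"}, \code{"exact"}, or \code{"normal"}.
#' @return a \linkS4class{StatResult}.
#' @examples
#' mannWhitney(c(1, 2, 3), c(4, 5, 6), alternative = "less")  # P = 1/20
#' @export
mannWhitney <- function(x, y, alternative = c("two.sided", "less", "greater"),
                        method = c("auto", "exact", "normal")) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y)
  u <- .uStatistic(x, y)
  ties <- anyDuplicated(c(x, y)) > 0L
  tails <- if (alternative == "two.sided") "two" else "one"

  if (method == "auto")
    method <- if (!ties && n1 + n2 <= 20L) "distribution" else "normal"
  if (method == "exact") {
    ## full enumeration over C(n1+n2, n1) splits of the pooled midranks
    r <- rank(c(x, y), ties.method = "average")
    idx <- utils::combn(n1 + n2, n1)
    us <- apply(idx, 2L, function(k) sum(r[k]) - n1 * (n1 + 1) / 2)
    mu <- n1 * n2 / 2
    p <- switch(alternative,
      greater = mean(us >= u - 1e-9),
      less = mean(us <= u + 1e-9),
      two.sided = mean(abs(us - mu) >= abs(u - mu) - 1e-9))
    return(new("StatResult", test = "Mann-Whitney U",
               statistic = c(U = u), p.value = min(1, p), tails = tails,
               method = "exact", extra = list(n = c(n1, n2))))
  }
  if (method == "distribution") {
    cnt <- .uCounts(n1, n2)
    tot <- sum(cnt)
    pLE <- function(q) sum(cnt[seq_len(min(floor(q), n1 * n2) + 1L)]) / tot
    pGE <- function(q) 1 - (if (q <= 0) 0 else pLE(q - 1))
    p <- switch(alternative,
      greater = pGE(u),
      less = pLE(u),
      two.sided = {
        mu <- n1 * n2 / 2
        pp <- if (u > mu) 2 * pGE(u) else 2 * pLE(u)
        min(1, pp)
      })
    return(new("StatResult", test = "Mann-Whitney U",
               statistic = c(U = u), p.value = min(1, p), tails = tails,
               method = "exact", extra = list(n = c(n1, n2))))
  }
  ## normal approximation with tie + continuity corrections
  n <- n1 + n2
  r <- rank(c(x, y), ties.method = "average")
  tieTab <- table(r)
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(tieTab^3 - tieTab) / (n * (n - 1)))
  if (sigma2 <= 0) {
    p <- 1  # all observations tied: no evidence either way
  } else {
    mu <- n1 * n2 / 2
    z <- u - mu
    cc <- switch(alternative, two.sided = sign(z) * 0.5, greater = 0.5,
                 less = -0.5)
    z <- (z - cc) / sqrt(sigma2)
    p <- switch(alternative,
      two.sided = 2 * stats::pnorm(-abs(z)),
      greater = stats::pnorm(z, lower.tail = FALSE),
      less = stats::pnorm(z))
  }
  new("StatResult", test = "Mann-Whitney U", statistic = c(U = u),
      p.value = min(1, p), tails = tails, method = "normal-approximation",
      extra = list(n = c(n1, n2)))
}

#' Spearman rank correlation
#'
#' \eqn{\rho} is the Pearson correlation of the midranks (ties receive
#' their average rank); the P-value uses the t approximation on
#' \eqn{n - 2} degrees of freedom, two-tailed.
#'
#' @param x,y equal-length numeric vectors, length >= 3.
#' @return a \linkS4class{StatResult} with statistic \code{rho}.
#' @export
spearmanRho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("rho undefined for a constant vector")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  rho <- sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
  p <- if (abs(rho) >= 1) 0 else {
    t <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(t), df = n - 2)
  }
  new("StatResult", test = "Spearman rank correlation",
      statistic = c(rho = rho), p.value = p, tails = "two",
      method = "normal-approximation", extra = list(n = n))
}

#' Branch-class enrichment of duplication/loss events
#'
#' Tests whether events of one type concentrate in a lineage class.
#' The default \code{"margins"} construction builds the 2x2 table
#' \code{[[events in class, events outside], [lineages in class,
#' lineages outside]]} and takes the one-tailed (upper) Fisher exact
#' tail; event multiplicities count (a branch losing two copies
#' contributes two).  The alternative \code{"placement"} construction
#' treats the \emph{event-bearing lineages} as draws without
#' replacement from the lineage set and takes the hypergeometric upper
#' tail of the in-class draw count (multiplicities collapse to
#' presence).
#'
#' @param events an \linkS4class{EventMap}.
#' @param lineages a \linkS4class{LineageSet} over the same tree.
#' @param eventType \code{"loss"} or \code{"duplication"}.
#' @param lineageClass \code{"parasitic"} or \code{"wgd"}.
#' @param construction \code{"margins"} (default) or \code{"placement"}.
#' @return a \linkS4class{StatResult}; \code{extra$table} holds the 2x2
#'   table used.
#' @export
enrichmentTest <- function(events, lineages,
                           eventType = c("loss", "duplication"),
                           lineageClass = c("parasitic", "wgd"),
                           construction = c("margins", "placement")) {
  eventType <- match.arg(eventType)
  lineageClass <- match.arg(lineageClass)
  construction <- match.arg(construction)
  mask <- if (lineageClass == "parasitic") lineages@parasitic else lineages@wgd
  if (!any(mask)) stop("empty lineage class: ", lineageClass)
  L <- length(lineages@ids); K <- sum(mask)
  ev <- events@events
  w <- if (eventType == "loss") ev$n_loss else ev$n_dup
  inClass <- ev$lineage_id %in% lineages@ids[mask]
  if (sum(w) == 0L) stop("no ", eventType, " events to test")
  tab <- if (construction == "margins") {
    nEv <- sum(w); k <- sum(w[inClass])
    matrix(c(k, nEv - k, K, L - K), 2, byrow = TRUE,
           dimnames = list(c("events", "lineages"),
                           c("in_class", "out_class")))
  } else {
    hot <- unique(ev$lineage_id[w > 0L])
    nEv <- length(hot)
    k <- sum(hot %in% lineages@ids[mask])
    matrix(c(k, K - k, nEv - k, (L - K) - (nEv - k)), 2, byrow = TRUE,
           dimnames = list(c("drawn", "not_drawn"),
                           c("in_class", "out_class")))
  }
  res <- fisherOneTailed(tab)
  res@test <- paste0(eventType, " enrichment in ", lineageClass,
                     " lineages (", construction, ")")
  res@extra$construction <- construction
  res
}
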