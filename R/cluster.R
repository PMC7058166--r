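## Hierarchical clustering of taxa by subunit-count vectors and the
## ordered long-format table feeding the configuration heatmap.

#' Pairwise distances between taxon copy-number vectors
#'
#' @param x a \linkS4class{CopyNumberMatrix}.
#' @param metric \code{"euclidean"} or \code{"manhattan"}.
#' @return a \code{stats::dist} object over taxa (rows sorted by label
#'   so downstream tie-breaking is input-order independent).
#' @export
countDistances <- function(x, metric = c("euclidean", "manhattan")) {
  metric <- match.arg(metric)
  m <- copyCounts(x)
  if (nrow(m) < 2L) stop("need at least 2 taxa")
  m <- m[order(rownames(m)), , drop = FALSE]
  stats::dist(m, method = metric)
}

#' Agglomerative clustering of taxa
#'
#' Standard agglomerative clustering (via \code{stats::hclust}) under
#' the chosen linkage.  Because \code{\link{countDistances}} sorts taxa
#' by label, merge-order ties resolve to the smallest taxon-label pair
#' and the result does not depend on the input row order.
#'
#' @param distances a \code{dist} from \code{\link{countDistances}}.
#' @param linkage \code{"complete"} (default), \code{"average"}, or
#'   \code{"single"}.
#' @return an \code{hclust} object (\eqn{n - 1} merges, leaf order in
#'   \code{$order}).
#' @export
hierarchicalCluster <- function(distances,
                                linkage = c("complete", "average", "single")) {
  linkage <- match.arg(linkage)
  stats::hclust(distances, method = linkage)
}

#' Heatmap-ready ordered table of counts, metrics and classes
#'
#' @param dendrogram an \code{hclust} from
#'   \code{\link{hierarchicalCluster}}.
#' @param x the \linkS4class{CopyNumberMatrix} that was clustered.
#' @param metrics \code{data.frame} from \code{\link{readTaxonMetrics}}
#'   (normalized columns are added if absent).
#' @param reference reference profile for the configuration class.
#' @return \code{data.frame}, rows in dendrogram leaf order: taxon,
#'   one column per family, \code{gs_norm}, \code{gc_norm},
#'   \code{configuration}.
#' @export
heatmapTable <- function(dendrogram, x, metrics,
                         reference = ancestralProfile()) {
  ord <- dendrogram$labels[dendrogram$order]
  m <- copyCounts(x)
  if (!setequal(ord, rownames(m)))
    stop("dendrogram taxa do not match the copy-number matrix")
  if (!all(rownames(m) %in% metrics$taxon))
    stop("metrics missing for taxa: ",
         paste(setdiff(rownames(m), metrics$taxon), collapse = ", "))
  if (!all(c("gs_norm", "gc_norm") %in% names(metrics)))
    metrics <- normalizeMetrics(metrics)
  cls <- configurationClasses(x, reference)
  hit <- match(ord, metrics$taxon)
  out <- data.frame(taxon = ord, m[ord, , drop = FALSE],
                    gs_norm = metrics$gs_norm[hit],
                    gc_norm = metrics$gc_norm[hit],
                    configuration = cls[ord],
                    row.names = NULL, check.names = FALSE)
  out
}

#' Optional heatmap rendering
#'
#' Thin wrapper over \pkg{pheatmap} (suggested dependency); the tested
#' artifact is the ordered table from \code{\link{heatmapTable}}.
#'
#' @param table output of \code{\link{heatmapTable}}.
#' @param file optional output path (PNG).
#' @return invisibly, the pheatmap object (or \code{NULL} if pheatmap
#'   is unavailable).
#' @export
plotConfigurationHeatmap <- function(table, file = NULL) {
  if (!requireNamespace("pheatmap", quietly = TRUE)) {
    warning("pheatmap not installed; skipping rendering")
    return(invisible(NULL))
  }
  famCols <- setdiff(names(table),
                     c("taxon", "gs_norm", "gc_norm", "configuration"))
  m <- as.matrix(table[, famCols])
  rownames(m) <- table$taxon
  ann <- data.frame(GS = table$gs_norm, GC = table$gc_norm,
                    class = table$configuration, row.names = table$taxon)
  p <- pheatmap::pheatmap(m, cluster_rows = FALSE, cluster_cols = FALSE,
                          annotation_row = ann, silent = TRUE,
                          filename = file)
  invisible(p)
}
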