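## Copy-number matrix handling, configuration classes and the
## genome-metric normalizations used by the clustering heatmap.

#' Default ancestral subunit profile
#'
#' The last eukaryotic common ancestor is reconstructed with two copies
#' of the pooled CDC6/ORC1 initiator family and one copy each of
#' ORC2-ORC5: six subunits in total.
#'
#' @return named integer vector of per-family ancestral copy numbers.
#' @export
ancestralProfile <- function() {
  c("CDC6/ORC1" = 2L, ORC2 = 1L, ORC3 = 1L, ORC4 = 1L, ORC5 = 1L)
}

#' Construct a CopyNumberMatrix
#'
#' @param counts numeric matrix (taxa x families) of non-negative
#'   integers, with row and column names.
#' @return a \linkS4class{CopyNumberMatrix}.
#' @export
copyNumberMatrix <- function(counts) {
  storage.mode(counts) <- "integer"
  new("CopyNumberMatrix", counts = counts)
}

#' Read a copy-number matrix from TSV
#'
#' First column taxon label, remaining columns per-family counts.
#'
#' @param path TSV path.
#' @return a \linkS4class{CopyNumberMatrix}.
#' @export
readCopyNumbers <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  copyNumberMatrix(m)
}

#' Write a copy-number matrix to TSV
#'
#' @param x a \linkS4class{CopyNumberMatrix}.
#' @param path output TSV path.
#' @export
writeCopyNumbers <- function(x, path) {
  df <- data.frame(taxon = taxa(x), copyCounts(x), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read the per-taxon genome metrics table
#'
#' Columns: \code{taxon}, \code{genome_size_bp}, \code{gene_count},
#' \code{lifestyle} (\code{parasite}/\code{nonparasite}),
#' \code{centrioles} (0/1/NA).
#'
#' @param path TSV path.
#' @return a \code{data.frame}.
#' @export
readTaxonMetrics <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("taxon", "genome_size_bp", "gene_count", "lifestyle", "centrioles")
  if (!all(need %in% names(df)))
    stop("metrics table must have columns: ", paste(need, collapse = ", "))
  df$centrioles <- as.logical(as.integer(df$centrioles))
  df
}

#' Classify a taxon's subunit configuration
#'
#' Relative to a reference profile (default the six-subunit ancestral
#' configuration), a taxon is \code{ancestral} when it matches the
#' reference exactly, \code{expanded} when no family is below reference
#' and at least one is above, \code{reduced} when no family is above and
#' at least one is below, and \code{mixed} when it carries extra
#' paralogs of some family while having lost copies of another.
#'
#' @param row named per-family counts for one taxon.
#' @param reference named per-family reference counts over the same
#'   family set (default \code{\link{ancestralProfile}}).
#' @return one of \code{"ancestral"}, \code{"expanded"},
#'   \code{"reduced"}, \code{"mixed"}.
#' @examples
#' classifyConfiguration(c("CDC6/ORC1" = 6, ORC2 = 1, ORC3 = 0,
#'                         ORC4 = 1, ORC5 = 1))  # "mixed"
#' @export
classifyConfiguration <- function(row, reference = ancestralProfile()) {
  if (is.null(names(row)) || !setequal(names(row), names(reference)))
    stop("family sets of row and reference differ")
  r <- row[names(reference)]
  if (all(r == reference)) return("ancestral")
  if (all(r >= reference)) return("expanded")
  if (all(r <= reference)) return("reduced")
  "mixed"
}

#' Per-taxon configuration classes for a whole matrix
#'
#' @param x a \linkS4class{CopyNumberMatrix}.
#' @param reference reference profile, as in
#'   \code{\link{classifyConfiguration}}.
#' @return named character vector of classes, one per taxon.
#' @export
configurationClasses <- function(x, reference = ancestralProfile()) {
  m <- copyCounts(x)
  setNames(apply(m, 1L, classifyConfiguration, reference = reference),
           rownames(m))
}

#' Normalize genome metrics for heatmap display
#'
#' Genome size is log10-transformed and divided by the log10 of the
#' largest genome; gene content is divided by the largest sequence
#' count.  The maximum-attaining taxon scores exactly 1 on each scale.
#'
#' @param metrics \code{data.frame} as returned by
#'   \code{\link{readTaxonMetrics}}.
#' @return the input with columns \code{gs_norm} and \code{gc_norm}
#'   appended, both in (0, 1].
#' @export
normalizeMetrics <- function(metrics) {
  gs <- metrics$genome_size_bp
  gc <- metrics$gene_count
  bad <- which(gs <= 0 | gc <= 0)
  if (length(bad))
    stop("non-positive genome metric for taxon: ",
         paste(metrics$taxon[bad], collapse = ", "))
  metrics$gs_norm <- log10(gs) / log10(max(gs))
  metrics$gc_norm <- gc / max(gc)
  metrics
}

#' Summarize a copy-number matrix
#'
#' @param x a \linkS4class{CopyNumberMatrix}.
#' @param reference reference profile for the class tallies.
#' @return list with \code{meanTotal} (mean subunit count per taxon),
#'   \code{min}/\code{max} (taxon and value), and \code{classTally}.
#' @export
summarizeCopyNumbers <- function(x, reference = ancestralProfile()) {
  m <- copyCounts(x)
  if (nrow(m) == 0L) stop("empty copy-number matrix")
  tot <- rowSums(m)
  cls <- configurationClasses(x, reference)
  list(
    meanTotal = mean(tot),
    min = list(taxon = names(which.min(tot)), value = unname(min(tot))),
    max = list(taxon = names(which.max(tot)), value = unname(max(tot))),
    classTally = table(factor(cls,
      levels = c("ancestral", "expanded", "reduced", "mixed"))))
}
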