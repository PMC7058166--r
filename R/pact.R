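## Region-wise conservation of a protein against a reference: pairwise
## global alignment, split of alignment columns into motif (PACT) vs
## background sets by reference coordinate, identity/similarity per set,
## and the PACT:background ratio compared across centriole classes.

.AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.pkgCache <- new.env(parent = emptyenv())

#' Minimum-codon-change amino-acid distance table
#'
#' For every ordered pair of the 20 standard amino acids, the minimum
#' number of nucleotide substitutions (0-3) between any two codons
#' encoding them under the standard genetic code (Fitch's mutation
#' distance).  Symmetric, zero diagonal.  A pair at distance at most
#' the chosen threshold (default 1) counts as "similar" in
#' \code{\link{conservationMeasures}}.
#'
#' @return 20x20 integer matrix with amino-acid single-letter dimnames.
#' @export
fitchMatrix <- function() {
  if (!is.null(.pkgCache$fitch)) return(.pkgCache$fitch)
  gc <- Biostrings::GENETIC_CODE
  gc <- gc[gc != "*"]
  codons <- lapply(.AA_LETTERS, function(a)
    do.call(rbind, strsplit(names(gc)[gc == a], "")))
  m <- matrix(NA_integer_, 20, 20, dimnames = list(.AA_LETTERS, .AA_LETTERS))
  for (i in seq_len(20)) for (j in i:20) {
    ci <- codons[[i]]; cj <- codons[[j]]
    d <- 3L
    for (a in seq_len(nrow(ci)))
      for (b in seq_len(nrow(cj)))
        d <- min(d, sum(ci[a, ] != cj[b, ]))
    m[i, j] <- m[j, i] <- d
  }
  .pkgCache$fitch <- m
  m
}

.checkProtein <- function(s, what) {
  if (!nzchar(s)) stop(what, " sequence is empty")
  bad <- setdiff(strsplit(s, "")[[1]], c(.AA_LETTERS, "X"))
  if (length(bad))
    stop("illegal character(s) in ", what, " sequence: ",
         paste(unique(bad), collapse = ", "))
}

#' Construct an AlignmentPair from already-aligned rows
#'
#' Entry point for ingesting externally produced pairwise alignments
#' (or gap-free equal-length sequences, which are their own alignment).
#'
#' @param ref,query equal-length gapped rows (gap character \code{"-"}).
#' @param score optional alignment score.
#' @return an \linkS4class{AlignmentPair}.
#' @export
alignmentPair <- function(ref, query, score = NA_real_) {
  rc <- strsplit(ref, "")[[1]]
  idx <- rep(NA_integer_, length(rc))
  idx[rc != "-"] <- seq_len(sum(rc != "-"))
  new("AlignmentPair", ref = ref, query = query, refIndex = idx,
      score = as.numeric(score))
}

#' Global pairwise protein alignment
#'
#' Needleman-Wunsch global alignment with affine gap penalties
#' (substitution matrix BLOSUM62, gap opening 10, gap extension 1 by
#' default; a gap of length L costs opening + L x extension), computed
#' with \code{Biostrings::pairwiseAlignment}.
#'
#' @param ref,query protein sequences (20-letter alphabet, \code{X}
#'   tolerated).
#' @param substitutionMatrix matrix name or matrix.
#' @param gapOpening,gapExtension positive penalties.
#' @return an \linkS4class{AlignmentPair} with the reference as first
#'   row.
#' @export
globalAlign <- function(ref, query, substitutionMatrix = "BLOSUM62",
                        gapOpening = 10, gapExtension = 1) {
  .checkProtein(ref, "reference")
  .checkProtein(query, "query")
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(ref),
    subject = Biostrings::AAString(query),
    type = "global", substitutionMatrix = substitutionMatrix,
    gapOpening = gapOpening, gapExtension = gapExtension)
  alignmentPair(as.character(Biostrings::alignedPattern(pa)),
                as.character(Biostrings::alignedSubject(pa)),
                score = Biostrings::score(pa))
}

#' Specify motif intervals on the reference
#'
#' @param starts,ends 1-based inclusive interval bounds on the
#'   (ungapped) reference sequence; intervals must not overlap.
#' @return \code{data.frame} with columns \code{start}, \code{end}.
#' @export
motifSpec <- function(starts, ends) {
  if (length(starts) != length(ends)) stop("starts/ends length mismatch")
  if (any(starts < 1) || any(ends < starts))
    stop("need 1 <= start <= end for every motif interval")
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  if (length(starts) > 1 && any(starts[-1] <= ends[-length(ends)]))
    stop("motif intervals overlap")
  data.frame(start = as.integer(starts), end = as.integer(ends))
}

#' Read motif intervals from YAML
#'
#' Expects a top-level \code{motifs} key (or a bare list) of
#' \code{\{start, end\}} entries.
#'
#' @param path YAML file path.
#' @return a \code{\link{motifSpec}} data.frame.
#' @export
readMotifs <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$motifs)) y <- y$motifs
  motifSpec(vapply(y, function(e) as.integer(e$start), integer(1)),
            vapply(y, function(e) as.integer(e$end), integer(1)))
}

#' Split alignment columns into motif and background sets
#'
#' A column belongs to the motif set iff its reference residue index
#' falls inside one of the intervals; columns where the reference row
#' is a gap carry no reference coordinate and go to the background.
#' The partition is exhaustive and disjoint.
#'
#' @param aln an \linkS4class{AlignmentPair}.
#' @param motifs a \code{\link{motifSpec}} data.frame.
#' @return list with components \code{motif} and \code{background},
#'   each a list of parallel character vectors \code{ref} and
#'   \code{query}.
#' @export
splitByMotifs <- function(aln, motifs) {
  rc <- strsplit(aln@ref, "")[[1]]
  qc <- strsplit(aln@query, "")[[1]]
  refLen <- sum(rc != "-")
  if (any(motifs$end > refLen))
    stop("motif interval extends beyond reference length (", refLen, ")")
  inMotif <- rep(FALSE, length(rc))
  for (i in seq_len(nrow(motifs)))
    inMotif <- inMotif | (!is.na(aln@refIndex) &
                          aln@refIndex >= motifs$start[i] &
                          aln@refIndex <= motifs$end[i])
  list(motif = list(ref = rc[inMotif], query = qc[inMotif]),
       background = list(ref = rc[!inMotif], query = qc[!inMotif]))
}

#' Identity and similarity of an aligned column set
#'
#' Columns where either row is a gap are excluded from the denominator.
#' Identity is the fraction of identical residue pairs; similarity the
#' fraction whose distance in \code{table} is at most
#' \code{threshold} (identical pairs always count as similar, so
#' similarity >= identity).  Pairs involving letters outside the table
#' (e.g. \code{X}) count as similar only when identical.
#'
#' @param columns list with character vectors \code{ref} and
#'   \code{query} (one entry per column).
#' @param table symmetric amino-acid distance table (default
#'   \code{\link{fitchMatrix}}).
#' @param threshold maximum distance that still counts as similar.
#' @return named numeric \code{c(identity = , similarity = )}.
#' @export
conservationMeasures <- function(columns, table = fitchMatrix(),
                                 threshold = 1) {
  r <- columns$ref; q <- columns$query
  if (!length(r)) stop("empty column set")
  keep <- r != "-" & q != "-"
  if (!any(keep)) stop("no columns with both residues ungapped")
  r <- r[keep]; q <- q[keep]
  ident <- r == q
  inTab <- r %in% rownames(table) & q %in% colnames(table)
  d <- rep(NA_real_, length(r))
  d[inTab] <- table[cbind(r[inTab], q[inTab])]
  simil <- ident | (!is.na(d) & d <= threshold)
  c(identity = mean(ident), similarity = mean(simil))
}

#' PACT-vs-background conservation record for one query
#'
#' Aligns the query to the reference (unless a prebuilt alignment is
#' supplied), splits columns by the motif intervals, computes identity
#' and similarity per region, and returns the motif:background ratios.
#'
#' @param ref,query protein sequences.
#' @param motifs a \code{\link{motifSpec}} data.frame.
#' @param table,threshold as in \code{\link{conservationMeasures}}.
#' @param aln optional \linkS4class{AlignmentPair} to use instead of
#'   aligning.
#' @param taxon,centrioles carried through to the output record.
#' @param ... passed to \code{\link{globalAlign}}.
#' @return one-row \code{data.frame}: \code{taxon},
#'   \code{identity_PACT}, \code{identity_nonPACT},
#'   \code{similarity_PACT}, \code{similarity_nonPACT},
#'   \code{identity_ratio}, \code{similarity_ratio}, \code{centrioles}.
#' @export
pactRatio <- function(ref, query, motifs, table = fitchMatrix(),
                      threshold = 1, aln = NULL, taxon = NA_character_,
                      centrioles = NA, ...) {
  if (is.null(aln)) aln <- globalAlign(ref, query, ...)
  sp <- splitByMotifs(aln, motifs)
  mo <- conservationMeasures(sp$motif, table, threshold)
  bg <- conservationMeasures(sp$background, table, threshold)
  if (bg["identity"] == 0 || bg["similarity"] == 0)
    stop("background conservation is zero for ", taxon,
         "; motif:background ratio undefined")
  data.frame(taxon = taxon,
             identity_PACT = unname(mo["identity"]),
             identity_nonPACT = unname(bg["identity"]),
             similarity_PACT = unname(mo["similarity"]),
             similarity_nonPACT = unname(bg["similarity"]),
             identity_ratio = unname(mo["identity"] / bg["identity"]),
             similarity_ratio = unname(mo["similarity"] / bg["similarity"]),
             centrioles = centrioles)
}

#' Conservation records for a set of orthologs against one reference
#'
#' @param sequences named character vector (or \code{AAStringSet}) of
#'   protein sequences including the reference.
#' @param refName name of the reference sequence.
#' @param motifs a \code{\link{motifSpec}} data.frame.
#' @param meta optional \code{data.frame} with columns \code{taxon} and
#'   \code{centrioles} (logical or 0/1).
#' @param preAligned if \code{TRUE}, all sequences are equal-length
#'   gapped rows already aligned to the reference.
#' @param ... passed to \code{\link{pactRatio}}.
#' @return \code{data.frame} of per-taxon records (reference excluded).
#' @export
pactTable <- function(sequences, refName, motifs, meta = NULL,
                      preAligned = FALSE, ...) {
  nm <- names(sequences)
  sequences <- as.character(sequences)
  names(sequences) <- nm
  if (!refName %in% names(sequences))
    stop("reference sequence not found: ", refName)
  ref <- sequences[[refName]]
  qnames <- setdiff(names(sequences), refName)
  cent <- setNames(rep(NA, length(qnames)), qnames)
  if (!is.null(meta)) {
    hit <- match(qnames, meta$taxon)
    cent[!is.na(hit)] <- as.logical(meta$centrioles[hit[!is.na(hit)]])
  }
  rows <- lapply(qnames, function(nm) {
    aln <- if (preAligned) alignmentPair(ref, sequences[[nm]]) else NULL
    pactRatio(ref, sequences[[nm]], motifs, aln = aln, taxon = nm,
              centrioles = cent[[nm]], ...)
  })
  do.call(rbind, rows)
}

#' Compare PACT conservation between centriole classes
#'
#' Two-tailed Mann-Whitney tests of the identity and similarity
#' motif:background ratios between centriole-bearing and
#' centriole-lacking taxa; taxa of unknown status are excluded.
#'
#' @param records \code{data.frame} as from \code{\link{pactTable}}.
#' @return list with \linkS4class{StatResult}s \code{identity} and
#'   \code{similarity} plus the per-group medians.
#' @export
compareCentrioleGroups <- function(records) {
  rec <- records[!is.na(records$centrioles), , drop = FALSE]
  g1 <- rec[rec$centrioles == TRUE, , drop = FALSE]
  g0 <- rec[rec$centrioles == FALSE, , drop = FALSE]
  if (!nrow(g1) || !nrow(g0))
    stop("both centriole classes must be non-empty")
  list(
    identity = mannWhitney(g1$identity_ratio, g0$identity_ratio),
    similarity = mannWhitney(g1$similarity_ratio, g0$similarity_ratio),
    medians = data.frame(
      group = c("centrioles", "no_centrioles"),
      identity_ratio = c(stats::median(g1$identity_ratio),
                         stats::median(g0$identity_ratio)),
      similarity_ratio = c(stats::median(g1$similarity_ratio),
                           stats::median(g0$similarity_ratio)),
      n = c(nrow(g1), nrow(g0))))
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
readProteins <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
}

#' Write protein sequences to FASTA
#'
#' @param sequences named character vector.
#' @param path output path.
#' @export
writeProteins <- function(sequences, path) {
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(unlist(sequences)), path)
}
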