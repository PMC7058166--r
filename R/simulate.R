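## Seeded generators producing inputs with the statistical structure the
## analysis assumes: random species trees, copy-number evolution with
## lineage-class rate multipliers and WGD doubling pulses, genome
## metrics, and motif-structured protein sequences.

#' Simulation configuration
#'
#' Defaults describe the study regime the generators emulate: rare
#' per-branch birth/death of subunit copies, loss acceleration on
#' streamlined (parasitic) lineages, count-doubling pulses on WGD
#' branches, and reference-length protein sequences whose motif columns
#' can be held at a different conservation level than the background.
#'
#' @param dupRate,lossRate expected duplication/loss events per branch
#'   (Poisson means); defaults 0.03 and 0.05.
#' @param parasiticLossMultiplier multiplies \code{lossRate} on
#'   parasitic lineages (1 = no streamlining effect).
#' @param wgdBranches character lineage ids whose incoming copy count
#'   is doubled (the increment is recorded as duplications).
#' @param rootProfile named per-family root copy numbers (default
#'   \code{\link{ancestralProfile}}).
#' @param seqLength reference protein length (default 300).
#' @param motifs motif intervals on the reference (default two short
#'   C-terminal motifs, \code{motifSpec(c(241, 271), c(255, 285))}).
#' @param backgroundSubProb per-site substitution probability outside
#'   the motifs (default 0.5).
#' @param motifSubProb named per-class per-site substitution
#'   probability inside the motifs,
#'   \code{c(centriole = , no_centriole = )} (default both 0.5: no
#'   group effect).
#' @return list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(dupRate = 0.03, lossRate = 0.05,
                             parasiticLossMultiplier = 1,
                             wgdBranches = character(),
                             rootProfile = ancestralProfile(),
                             seqLength = 300L,
                             motifs = motifSpec(c(241L, 271L), c(255L, 285L)),
                             backgroundSubProb = 0.5,
                             motifSubProb = c(centriole = 0.5,
                                              no_centriole = 0.5)) {
  stopifnot(dupRate >= 0, lossRate >= 0, parasiticLossMultiplier >= 0,
            backgroundSubProb >= 0, backgroundSubProb <= 1,
            all(motifSubProb >= 0), all(motifSubProb <= 1),
            seqLength >= max(motifs$end))
  structure(list(dupRate = dupRate, lossRate = lossRate,
                 parasiticLossMultiplier = parasiticLossMultiplier,
                 wgdBranches = wgdBranches, rootProfile = rootProfile,
                 seqLength = as.integer(seqLength), motifs = motifs,
                 backgroundSubProb = backgroundSubProb,
                 motifSubProb = motifSubProb),
            class = "SimulationConfig")
}

#' Simulate a random rooted binary species tree
#'
#' Uniform coalescent-style joins (\code{ape::rcoal}); deterministic
#' given the seed.
#'
#' @param nTaxa number of tips (>= 2).
#' @param seed optional integer seed (\code{set.seed} is called when
#'   given).
#' @param prefix tip-label prefix.
#' @return a \linkS4class{SpeciesTree} with all annotations unset.
#' @export
simulateSpeciesTree <- function(nTaxa, seed = NULL, prefix = "T") {
  if (nTaxa < 2L) stop("need at least 2 taxa")
  if (!is.null(seed)) set.seed(seed)
  labels <- sprintf("%s%03d", prefix, seq_len(nTaxa))
  ph <- ape::rcoal(nTaxa, tip.label = labels)
  ph$edge.length <- NULL
  speciesTree(ph)
}

#' Mark whole clades as parasitic until a lineage fraction is reached
#'
#' Random non-root clades are flagged parasitic (all their leaves, so
#' the lifestyle-propagation invariant holds) until at least
#' \code{lineageFraction} of all lineages belong to the class.
#'
#' @param tree a \linkS4class{SpeciesTree}.
#' @param lineageFraction target fraction of lineages, in [0, 1).
#' @param seed optional integer seed.
#' @return the tree with \code{parasitic} set on every node.
#' @export
markParasiticClades <- function(tree, lineageFraction, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ph <- tree@phylo
  nn <- nLineages(tree)
  root <- .rootNode(ph)
  tu <- .tipsUnder(ph)
  parLeaves <- character(0)
  tree <- propagateLifestyle(tree, parLeaves)
  for (v in sample(setdiff(seq_len(nn), root))) {
    cur <- mean(tree@nodeData$parasitic)
    if (cur >= lineageFraction) break
    cand <- union(parLeaves, ph$tip.label[tu[[v]]])
    prop <- propagateLifestyle(tree, cand)
    new <- mean(prop@nodeData$parasitic)
    ## skip clades that would overshoot the target by more than they help
    if (new > lineageFraction && (new - lineageFraction) > 2 / nn) next
    parLeaves <- cand
    tree <- prop
  }
  tree
}

#' Simulate copy-number evolution along a tree
#'
#' Walks every family from its root count toward the tips.  On each
#' branch, in order: (1) if the child lineage is a WGD branch the
#' incoming count doubles and the increment is recorded as
#' duplications; (2) duplications are drawn from
#' \code{Poisson(dupRate)}; (3) losses from \code{Poisson(lossRate)}
#' times the parasitic multiplier where the child lineage is parasitic.
#' Losses beyond the available copies are discarded and \emph{not}
#' recorded (the truth map's censoring convention), so replaying the
#' truth map always reproduces the matrix exactly.
#'
#' @param tree a \linkS4class{SpeciesTree} (parasitic flags read from
#'   its annotations).
#' @param config a \code{\link{simulationConfig}}.
#' @param seed optional integer seed.
#' @return list with \code{counts} (\linkS4class{CopyNumberMatrix}) and
#'   \code{truth} (\linkS4class{EventMap}).
#' @export
simulateGeneContent <- function(tree, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ph <- tree@phylo
  ids <- tree@nodeData$id
  parasitic <- !is.na(tree@nodeData$parasitic) & tree@nodeData$parasitic
  ntip <- length(ph$tip.label)
  ch <- .nodeChildren(ph)
  root <- .rootNode(ph)
  fams <- names(config$rootProfile)
  mat <- matrix(0L, ntip, length(fams),
                dimnames = list(ph$tip.label, fams))
  ev <- list()
  for (f in fams) {
    state <- integer(length(ids))
    state[root] <- config$rootProfile[[f]]
    for (v in rev(.postorderNodes(ph))) {     # preorder
      for (c2 in ch[[v]]) {
        cnt <- state[v]
        dup <- 0L; loss <- 0L
        if (ids[c2] %in% config$wgdBranches) {
          dup <- dup + cnt                    # doubling pulse
          cnt <- 2L * cnt
        }
        d <- stats::rpois(1L, config$dupRate)
        dup <- dup + d; cnt <- cnt + d
        lrate <- config$lossRate *
          if (parasitic[c2]) config$parasiticLossMultiplier else 1
        l <- stats::rpois(1L, lrate)
        l <- min(l, cnt)                      # censor losses at zero copies
        loss <- loss + l; cnt <- cnt - l
        state[c2] <- cnt
        if (dup > 0L || loss > 0L)
          ev[[length(ev) + 1L]] <- data.frame(
            lineage_id = ids[c2], family = f,
            n_dup = dup, n_loss = loss)
      }
    }
    mat[, f] <- state[seq_len(ntip)]
  }
  truth <- new("EventMap",
               events = if (length(ev)) do.call(rbind, ev) else
                 .emptyEvents(),
               rootCounts = vapply(config$rootProfile, as.integer,
                                   integer(1)))
  list(counts = copyNumberMatrix(mat), truth = truth)
}

#' Simulate genome metrics coupled to lifestyle
#'
#' Parasites draw smaller genomes and gene counts (log-normal around
#' 30 Mb / 5,000 genes vs 300 Mb / 15,000 for free-living taxa),
#' emulating streamlining.
#'
#' @param tree an annotated \linkS4class{SpeciesTree}.
#' @param seed optional integer seed.
#' @return \code{data.frame} in \code{\link{readTaxonMetrics}} layout.
#' @export
simulateTaxonMetrics <- function(tree, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nd <- tree@nodeData
  leaves <- nd[nd$isLeaf, ]
  par <- !is.na(leaves$parasitic) & leaves$parasitic
  n <- nrow(leaves)
  gs <- round(exp(stats::rnorm(n, mean = ifelse(par, log(3e7), log(3e8)),
                               sd = 0.8)))
  gc <- round(exp(stats::rnorm(n, mean = ifelse(par, log(5e3), log(1.5e4)),
                               sd = 0.4)))
  data.frame(taxon = leaves$id, genome_size_bp = gs, gene_count = gc,
             lifestyle = ifelse(par, "parasite", "nonparasite"),
             centrioles = NA_integer_)
}

#' Simulate reference-anchored ORC1-like protein sequences
#'
#' Draws a uniform random reference of the configured length, then one
#' sequence per taxon by substituting sites independently: at
#' \code{backgroundSubProb} outside the motif intervals and at the
#' class-specific \code{motifSubProb} inside them.  No indels, so all
#' sequences stay aligned to the reference.
#'
#' @param taxa \code{data.frame} with columns \code{taxon} and
#'   \code{centrioles} (logical).
#' @param config a \code{\link{simulationConfig}}.
#' @param seed optional integer seed.
#' @param refName name given to the reference sequence.
#' @return list: \code{sequences} (named character vector, reference
#'   first), \code{motifs}, \code{taxa}.
#' @export
simulateOrc1Sequences <- function(taxa, config, seed = NULL,
                                  refName = "Hsap") {
  if (!is.null(seed)) set.seed(seed)
  L <- config$seqLength
  refv <- sample(.AA_LETTERS, L, replace = TRUE)
  inMotif <- rep(FALSE, L)
  for (i in seq_len(nrow(config$motifs)))
    inMotif[config$motifs$start[i]:config$motifs$end[i]] <- TRUE
  seqs <- setNames(character(nrow(taxa) + 1L), c(refName, taxa$taxon))
  seqs[refName] <- paste(refv, collapse = "")
  for (k in seq_len(nrow(taxa))) {
    cls <- if (isTRUE(taxa$centrioles[k])) "centriole" else "no_centriole"
    pSub <- ifelse(inMotif, config$motifSubProb[[cls]],
                   config$backgroundSubProb)
    hit <- stats::runif(L) < pSub
    sv <- refv
    if (any(hit))
      sv[hit] <- vapply(refv[hit], function(a)
        sample(setdiff(.AA_LETTERS, a), 1L), character(1))
    seqs[taxa$taxon[k]] <- paste(sv, collapse = "")
  }
  list(sequences = seqs, motifs = config$motifs, taxa = taxa)
}

#' Simulate a complete annotated dataset
#'
#' Convenience wrapper binding the generators: species tree, parasitic
#' clades, WGD branches, gene content with truth events, genome
#' metrics, centriole classes and motif-structured sequences.
#'
#' @param nTaxa number of tips.
#' @param seed integer seed driving every draw.
#' @param parasiticLineageFraction target parasitic lineage fraction.
#' @param nWgdBranches number of internal branches receiving a WGD
#'   pulse.
#' @param centrioleFraction fraction of taxa carrying centrioles.
#' @param config a \code{\link{simulationConfig}}.
#' @return list: \code{tree}, \code{counts}, \code{truth},
#'   \code{metrics}, \code{sequences} (as from
#'   \code{\link{simulateOrc1Sequences}}), \code{config}.
#' @export
simulateDataset <- function(nTaxa, seed,
                            parasiticLineageFraction = 0.25,
                            nWgdBranches = 0L,
                            centrioleFraction = 0.5,
                            config = simulationConfig()) {
  set.seed(seed)
  tree <- simulateSpeciesTree(nTaxa)
  tree <- markParasiticClades(tree, parasiticLineageFraction)
  nd <- tree@nodeData
  if (nWgdBranches > 0L) {
    root <- .rootNode(tree@phylo)
    pool <- nd$id[nd$node != root]
    config$wgdBranches <- sample(pool, min(nWgdBranches, length(pool)))
    ann <- data.frame(node_id = config$wgdBranches, parasitic = NA,
                      wgd = "reported", centrioles = NA)
    tree <- annotateTree(tree, ann)
  }
  gcnt <- simulateGeneContent(tree, config)
  metrics <- simulateTaxonMetrics(tree)
  cent <- stats::runif(nrow(metrics)) < centrioleFraction
  metrics$centrioles <- as.integer(cent)
  tipAnn <- data.frame(node_id = metrics$taxon, parasitic = NA_integer_,
                       wgd = NA_character_, centrioles = metrics$centrioles)
  tree <- annotateTree(tree, tipAnn)
  seqTaxa <- data.frame(taxon = metrics$taxon, centrioles = cent)
  seqs <- simulateOrc1Sequences(seqTaxa, config)
  list(tree = tree, counts = gcnt$counts, truth = gcnt$truth,
       metrics = metrics, sequences = seqs, config = config)
}
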