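## Single entry point binding the stages: read the annotated tree, copy
## numbers, metrics, sequences and motif config; infer events; run the
## enrichment tests; build the cluster table and the PACT table; write
## everything plus a manifest that suffices to re-run bit-identically.

.needFile <- function(path, what) {
  if (is.null(path) || !file.exists(path))
    stop("missing ", what, " file: ", if (is.null(path)) "<unset>" else path)
  path
}

#' Run the full analysis pipeline
#'
#' @param config path to a YAML run configuration, or an equivalent
#'   named list.  Keys: \code{tree}, \code{annotations},
#'   \code{counts}, \code{metrics}, \code{fasta}, \code{motifs}
#'   (paths), optional \code{constraints}, \code{ref} (reference
#'   sequence name, default \code{"Hsap"}), \code{out_dir},
#'   \code{seed}.
#' @return invisibly, a list of the in-memory results; side effect:
#'   writes \code{events.tsv}, \code{enrichment.json},
#'   \code{cluster.tsv}, \code{pact.tsv} and \code{manifest.json}
#'   under \code{out_dir}.
#' @export
runPipeline <- function(config) {
  cfgPath <- NA_character_
  if (is.character(config)) {
    cfgPath <- .needFile(config, "configuration")
    config <- yaml::read_yaml(config)
  }
  outDir <- config$out_dir %||% "."
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(config$seed)) set.seed(config$seed)

  tree <- readSpeciesTree(.needFile(config$tree, "tree"),
                          annotations = .needFile(config$annotations,
                                                  "annotation"))
  counts <- readCopyNumbers(.needFile(config$counts, "copy-number"))
  metrics <- readTaxonMetrics(.needFile(config$metrics, "metrics"))
  seqs <- readProteins(.needFile(config$fasta, "FASTA"))
  motifs <- readMotifs(.needFile(config$motifs, "motif"))
  constraints <- if (!is.null(config$constraints))
    readConstraints(.needFile(config$constraints, "constraint")) else NULL
  refName <- config$ref %||% "Hsap"

  message("[orcEvo] inferring duplication/loss events")
  events <- inferAllEvents(tree, counts, constraints = constraints)
  utils::write.table(eventTable(events), file.path(outDir, "events.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  message("[orcEvo] branch-class enrichment tests")
  lin <- countLineages(tree)
  enr <- list(
    loss_parasitic = enrichmentTest(events, lin, "loss", "parasitic"),
    dup_wgd_margins = enrichmentTest(events, lin, "duplication", "wgd",
                                     construction = "margins"),
    dup_wgd_placement = enrichmentTest(events, lin, "duplication", "wgd",
                                       construction = "placement"))
  enrJson <- lapply(enr, function(r) list(
    test = r@test, statistic = as.list(r@statistic), p = r@p.value,
    tails = r@tails, method = r@method,
    table = unclass(r@extra$table)))
  jsonlite::write_json(enrJson, file.path(outDir, "enrichment.json"),
                       auto_unbox = TRUE, digits = NA)

  message("[orcEvo] clustering taxa by subunit configuration")
  dend <- hierarchicalCluster(countDistances(counts))
  clus <- heatmapTable(dend, counts, metrics)
  utils::write.table(clus, file.path(outDir, "cluster.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  message("[orcEvo] PACT-region conservation")
  pact <- pactTable(seqs, refName, motifs, meta = metrics)
  utils::write.table(pact, file.path(outDir, "pact.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  manifest <- list(
    package = "orcEvo",
    version = as.character(utils::packageVersion("orcEvo")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    config = config,
    config_path = cfgPath,
    config_hash = .configHash(config),
    outputs = c("events.tsv", "enrichment.json", "cluster.tsv", "pact.tsv"))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(tree = tree, events = events, enrichment = enr,
                 cluster = clus, pact = pact, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.configHash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(config[order(names(config))]), tmp)
  unname(tools::md5sum(tmp))
}
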