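.checkFile <- function(path, what) {
  if (!file.exists(path))
    stop(sprintf("%s: missing input file: %s", what, path))
  path
}

#' Read a pipeline configuration
#'
#' YAML with either \code{simulate: true} plus an optional
#' \code{generator:} block of \code{\link{simulationConfig}} overrides,
#' or explicit input paths (\code{genomes:} TSV of genome_id, fasta,
#' features; \code{hits:} TSV of source, path; \code{cutoffs:},
#' \code{dictionary:}, \code{pathway_map:}, \code{pathways:},
#' \code{orthologues:}, \code{alignments:} TSV of marker_id, path).
#' Common fields: \code{seed}, \code{bootstrap}, \code{window},
#' \code{output_dir}.
#'
#' @param path YAML file.
#' @return the configuration list.
#' @export
readPipelineConfig <- function(path) {
  yaml::read_yaml(.checkFile(path, "config"))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
}

.simCohort <- function(config) {
  gen <- do.call(simulationConfig,
                 c(config$generator,
                   if (!is.null(config$seed) &&
                       is.null(config$generator$seed))
                     list(seed = config$seed)))
  sim <- simulatePangenome(gen)
  ev <- simulateEvidence(sim$genomes, sim$truth, gen)
  list(genomes = sim$genomes, truth = sim$truth, hits = ev$hits,
       dictionary = ev$dictionary, cutoffs = ev$cutoffs,
       definitions = syntheticPathwayDefinitions(gen), gen = gen)
}

.fileCohort <- function(config) {
  genomes <- NULL
  if (!is.null(config$genomes)) {
    gtab <- utils::read.delim(.checkFile(config$genomes, "genomes"),
                              stringsAsFactors = FALSE)
    genomes <- stats::setNames(lapply(seq_len(nrow(gtab)), function(i)
      readGenome(.checkFile(gtab$fasta[i], "fasta"),
                 .checkFile(gtab$features[i], "features"),
                 genomeId = gtab$genome_id[i])), gtab$genome_id)
  }
  cutoffs <- NULL
  if (!is.null(config$cutoffs)) {
    ct <- utils::read.delim(.checkFile(config$cutoffs, "cutoffs"),
                            stringsAsFactors = FALSE)
    cutoffs <- stats::setNames(ct$trusted_cutoff, ct$accession)
  }
  hits <- NULL
  if (!is.null(config$hits)) {
    htab <- utils::read.delim(.checkFile(config$hits, "hits"),
                              stringsAsFactors = FALSE)
    hits <- lapply(split(htab, htab$source), function(rows)
      do.call(rbind, lapply(rows$path, function(p)
        readHitTable(.checkFile(p, "hit table"), rows$source[1L],
                     cutoffs = cutoffs))))
  }
  dictionary <- if (!is.null(config$dictionary))
    readFunctionDictionary(.checkFile(config$dictionary, "dictionary"),
                           if (!is.null(config$pathway_map))
                             .checkFile(config$pathway_map, "pathway map"))
  definitions <- if (!is.null(config$pathways))
    readPathwayDefinitions(.checkFile(config$pathways, "pathways"))
  list(genomes = genomes, truth = NULL, hits = hits,
       dictionary = dictionary, cutoffs = cutoffs,
       definitions = definitions, gen = NULL)
}

.cohort <- function(config) {
  if (isTRUE(config$simulate)) .simCohort(config) else .fileCohort(config)
}

.writeManifest <- function(outputDir, config, extra) {
  manifest <- c(list(package = "corepan",
                     version = as.character(utils::packageVersion("corepan")),
                     seed = config$seed), extra)
  jsonlite::write_json(manifest, file.path(outputDir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run the annotation + pathway-profiling strand
#'
#' Annotates every genome (trusted-cutoff filtering, two-pass
#' confidence reconciliation), evaluates all pathway definitions, and
#' classifies vitamin synthesis-vs-salvage strategies for every
#' \code{<x>_synthesis}/\code{<x>_salvage} definition pair.  Writes
#' \code{annotations.tsv}, \code{pathway_matrix.tsv},
#' \code{strategies.tsv} and \code{run_manifest.json} to the output
#' directory; reruns on identical inputs are byte-identical.
#'
#' @param config configuration list or YAML path
#'   (\code{\link{readPipelineConfig}}).
#' @param outputDir output directory (default
#'   \code{config$output_dir}).
#' @return invisibly: list(annotations, matrix, strategies, cohort).
#' @export
runProfile <- function(config, outputDir = config$output_dir) {
  if (is.character(config)) config <- readPipelineConfig(config)
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  co <- .stage("inputs", .cohort(config))
  if (is.null(co$hits)) stop("[inputs] profile needs evidence hit tables")
  window <- if (is.null(config$window)) 5L else as.integer(config$window)
  allHits <- do.call(rbind, unname(co$hits))
  nRaw <- nrow(allHits)
  kept <- .stage("filter", filterTrusted(allHits))
  geneGenome <- do.call(rbind, lapply(co$genomes, function(g)
    g[, c("gene_id", "genome_id")]))
  ann <- .stage("annotate", {
    lapply(co$genomes, function(g) {
      h <- kept[kept$gene_id %in% g$gene_id, , drop = FALSE]
      annotateGenome(g, h, co$dictionary, window = window)
    })
  })
  annAll <- do.call(rbind, lapply(names(ann), function(g)
    cbind(genome_id = g, ann[[g]])))
  rownames(annAll) <- NULL
  writeAnnotation(annAll, file.path(outputDir, "annotations.tsv"))
  mat <- .stage("pathways",
                profileMatrix(ann, co$definitions, co$dictionary))
  utils::write.table(data.frame(genome_id = rownames(mat), mat,
                                check.names = FALSE),
                     file.path(outputDir, "pathway_matrix.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  defIds <- vapply(co$definitions, function(d) d@pathwayId, "")
  vitamins <- sub("_synthesis$", "",
                  grep("_synthesis$", defIds, value = TRUE))
  vitamins <- vitamins[paste0(vitamins, "_salvage") %in% defIds]
  strat <- do.call(rbind, lapply(vitamins, function(v)
    data.frame(genome_id = names(ann), vitamin = v,
               strategy = vapply(names(ann), function(g)
                 classifyStrategy(g,
                   co$definitions[[paste0(v, "_synthesis")]],
                   co$definitions[[paste0(v, "_salvage")]], ann[[g]]), ""),
               stringsAsFactors = FALSE)))
  if (!is.null(strat)) rownames(strat) <- NULL
  utils::write.table(strat, file.path(outputDir, "strategies.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tierCounts <- as.list(base::table(factor(annAll$tier, confidenceTiers())))
  .writeManifest(outputDir, config,
                 list(stage = "profile", window = window,
                      hits_read = nRaw, hits_dropped = nRaw - nrow(kept),
                      tier_counts = tierCounts))
  message(sprintf("profile: %d genomes, %d/%d hits kept, %d pathways",
                  length(ann), nrow(kept), nRaw, length(co$definitions)))
  invisible(list(annotations = annAll, matrix = mat, strategies = strat,
                 cohort = co))
}

#' Run the core/pan-genome strand
#'
#' Obtains an orthologue table (precomputed TSV when
#' \code{config$orthologues} is set, otherwise RBH clustering of the
#' cohort's proteins), then writes the genus core-group list, the
#' species pairwise shared-orthologue matrix and the Venn-exclusive
#' subset counts.
#'
#' @inheritParams runProfile
#' @return invisibly: list(table, core, pairwise, venn).
#' @export
runPangenome <- function(config, outputDir = config$output_dir) {
  if (is.character(config)) config <- readPipelineConfig(config)
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  co <- .stage("inputs", .cohort(config))
  speciesMap <- if (isTRUE(config$simulate))
    .rosterOf(co$gen)$speciesMap
  else if (!is.null(config$species_map)) {
    sm <- utils::read.delim(.checkFile(config$species_map, "species map"),
                            stringsAsFactors = FALSE)
    stats::setNames(sm$species, sm$genome_id)
  } else NULL
  tab <- .stage("orthologues", {
    if (!is.null(config$orthologues))
      readOrthologueTable(.checkFile(config$orthologues, "orthologues"),
                          speciesMap = speciesMap)
    else {
      thr <- if (is.null(config$identity_threshold)) 0.7
             else config$identity_threshold
      clusterOrthologues(co$genomes, identityThreshold = thr,
                         speciesMap = speciesMap)
    }
  })
  core <- coreGenome(tab, genomeIds(tab))
  writeLines(core, file.path(outputDir, "core_groups.txt"))
  pw <- pairwiseSharedMatrix(tab)
  utils::write.table(data.frame(taxon = rownames(pw), pw,
                                check.names = FALSE),
                     file.path(outputDir, "pairwise_matrix.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  venn <- if (length(unique(speciesMap(tab))) <= 7L) {
    v <- intersectionCounts(tab)
    utils::write.table(data.frame(subset = names(v), n_groups = unname(v)),
                       file.path(outputDir, "venn_counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    v
  } else NULL
  writeOrthologueTable(tab, file.path(outputDir, "orthologue_table.tsv"))
  .writeManifest(outputDir, config,
                 list(stage = "pangenome", n_genomes = length(genomeIds(tab)),
                      n_groups = length(groupIds(tab)),
                      core_size = length(core)))
  message(sprintf("pangenome: %d groups, genus core %d",
                  length(groupIds(tab)), length(core)))
  invisible(list(table = tab, core = core, pairwise = pw, venn = venn))
}

#' Run the phylogenomics strand
#'
#' Concatenates per-marker alignments (simulated along a known tree, or
#' read from aligned FASTAs listed in \code{config$alignments}),
#' computes the configured distance (Poisson-corrected amino acid by
#' default, TN93 for nucleotides), builds the neighbor-joining tree and
#' bootstrap supports, and writes \code{tree.nwk}.
#'
#' @inheritParams runProfile
#' @return invisibly: list(tree, alignment, distance, trueTree).
#' @export
runTree <- function(config, outputDir = config$output_dir) {
  if (is.character(config)) config <- readPipelineConfig(config)
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  trueTree <- NULL
  if (isTRUE(config$simulate)) {
    gen <- do.call(simulationConfig,
                   c(config$generator,
                     if (!is.null(config$seed) &&
                         is.null(config$generator$seed))
                       list(seed = config$seed)))
    sim <- .stage("simulate", simulateMarkerAlignments(gen))
    alns <- sim$alignments
    trueTree <- sim$tree
    model <- gen$model
  } else {
    atab <- utils::read.delim(.checkFile(config$alignments, "alignments"),
                              stringsAsFactors = FALSE)
    model <- if (is.null(config$model)) "poisson_aa" else config$model
    type <- if (model == "poisson_aa") "AA" else "DNA"
    alns <- stats::setNames(lapply(atab$path, function(p)
      readAlignedFasta(.checkFile(p, "alignment"), type)), atab$marker_id)
  }
  if (length(names(alns[[1L]])) < 3L)
    stop("[tree] fewer than 3 taxa; cannot build a tree")
  cat <- .stage("concatenate", concatenateAlignments(alns))
  distFun <- if (model == "poisson_aa") poissonDistance else tamuraNeiDistance
  nReps <- if (is.null(config$bootstrap)) 100L else as.integer(config$bootstrap)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  tree <- .stage("tree", bootstrapSupports(cat, distFun, nReps = nReps,
                                           seed = seed))
  writeNewickTree(tree, file.path(outputDir, "tree.nwk"))
  .writeManifest(outputDir, config,
                 list(stage = "tree", n_taxa = length(tree$tip.label),
                      n_markers = nrow(cat@partition),
                      n_columns = Biostrings::width(cat@seqs)[1L],
                      bootstrap = nReps))
  message(sprintf("tree: %d taxa, %d markers, %d bootstrap replicates",
                  length(tree$tip.label), nrow(cat@partition), nReps))
  invisible(list(tree = tree, alignment = cat,
                 distance = distFun(cat), trueTree = trueTree))
}
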