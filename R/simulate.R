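.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
.NT4 <- c("A", "C", "G", "T")

#' Simulation configuration
#'
#' Defines the synthetic study conditions.  The defaults emulate a
#' genus-scale cohort of gut anaerobes: 5 species with 2 strains each
#' (10 genomes), a shared core, species-level accessory families,
#' strain-private families, vitamin pathways split between synthesis
#' and salvage strategies, an 18-marker single-copy panel, and
#' noise-free evidence (false-negative and false-positive rates 0).
#' Family counts and sequence lengths are kept at simulation-tractable
#' sizes; every random draw flows from \code{seed}.
#'
#' @param nSpecies number of species.
#' @param strainsPerSpecies strains per species (scalar or vector).
#' @param coreSize number of core families present in every genome
#'   (includes the marker families).
#' @param accessoryPerSpecies families shared by all strains of exactly
#'   one species.
#' @param privatePerStrain strain-private families per genome.
#' @param nVitamins number of vitamin synthesis/salvage pathway pairs.
#' @param synthesisLength genes per synthesis pathway.
#' @param fn per-source evidence false-negative rate in [0,1].
#' @param fp per-source evidence false-positive rate in [0,1].
#' @param marginMean mean of the exponential bit-score margin above the
#'   trusted cutoff for true HMM hits.
#' @param spuriousScoreSd sd of the (zero-mean) score offset around the
#'   cutoff for spurious HMM hits, so roughly half fall below it.
#' @param proteinLength mean protein length (aa).
#' @param withinFamilyDivergence per-site substitution probability
#'   between family members.
#' @param markerCount single-copy markers simulated (<= 18).
#' @param markerLength marker alignment columns.
#' @param tree optional \code{phylo} with branch lengths in
#'   substitutions/site; a seeded random tree over the roster is drawn
#'   when NULL.
#' @param model marker substitution model: \code{"poisson_aa"},
#'   \code{"jc_nt"} or \code{"tn93_nt"}.
#' @param tnFreqs,tnAlphaR,tnAlphaY TN93 base frequencies and relative
#'   purine/pyrimidine transition rates (transversion rate 1).
#' @param strategyProbs sampling weights of the per-genome vitamin
#'   strategies (synthesizer, salvager, both, neither).
#' @param seed integer seed fixing all randomness.
#' @return a \code{SimulationConfig} list.
#' @export
simulationConfig <- function(nSpecies = 5L, strainsPerSpecies = 2L,
                             coreSize = 100L, accessoryPerSpecies = 25L,
                             privatePerStrain = 10L, nVitamins = 4L,
                             synthesisLength = 4L, fn = 0, fp = 0,
                             marginMean = 15, spuriousScoreSd = 10,
                             proteinLength = 80L,
                             withinFamilyDivergence = 0.02,
                             markerCount = 18L, markerLength = 120L,
                             tree = NULL, model = c("poisson_aa", "jc_nt",
                                                    "tn93_nt"),
                             tnFreqs = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
                             tnAlphaR = 4, tnAlphaY = 2,
                             strategyProbs = c(synthesizer = 0.4,
                                               salvager = 0.3, both = 0.2,
                                               neither = 0.1),
                             seed = 1L) {
  model <- match.arg(model)
  if (any(c(fn, fp) < 0) || any(c(fn, fp) > 1))
    stop("fn and fp must be in [0, 1]")
  if (coreSize < 0) stop("coreSize must be >= 0")
  if (markerCount > 18L) stop("markerCount must be <= 18")
  if (coreSize < markerCount)
    stop("contradictory sizes: coreSize must cover the marker families")
  cfg <- list(nSpecies = as.integer(nSpecies),
              strainsPerSpecies = as.integer(strainsPerSpecies),
              coreSize = as.integer(coreSize),
              accessoryPerSpecies = as.integer(accessoryPerSpecies),
              privatePerStrain = as.integer(privatePerStrain),
              nVitamins = as.integer(nVitamins),
              synthesisLength = as.integer(synthesisLength),
              fn = fn, fp = fp, marginMean = marginMean,
              spuriousScoreSd = spuriousScoreSd,
              proteinLength = as.integer(proteinLength),
              withinFamilyDivergence = withinFamilyDivergence,
              markerCount = as.integer(markerCount),
              markerLength = as.integer(markerLength),
              tree = tree, model = model, tnFreqs = tnFreqs,
              tnAlphaR = tnAlphaR, tnAlphaY = tnAlphaY,
              strategyProbs = strategyProbs, seed = as.integer(seed))
  class(cfg) <- c("SimulationConfig", "list")
  cfg
}

.rosterOf <- function(config) {
  nsp <- config$nSpecies
  nst <- rep_len(config$strainsPerSpecies, nsp)
  species <- sprintf("sp%02d", seq_len(nsp))
  roster <- unlist(lapply(seq_len(nsp), function(i)
    sprintf("%s_st%02d", species[i], seq_len(nst[i]))))
  speciesMap <- stats::setNames(rep(species, nst), roster)
  list(roster = roster, speciesMap = speciesMap, species = species)
}

.mutateSeq <- function(rng, chars, pSub, alphabet) {
  hit <- which(.rngBinom(rng, length(chars), pSub))
  for (i in hit) {
    alt <- setdiff(alphabet, chars[i])
    chars[i] <- .rngSample(rng, alt, 1L)
  }
  chars
}

#' Simulate a multi-species pangenome with known truth
#'
#' Families are laid out as: core (all genomes; the first
#' \code{markerCount} of them are the single-copy marker families,
#' carrying the TIGRFAM marker functions), species accessory (all
#' strains of one species), strain-private (one genome), and vitamin
#' pathway families whose genome membership follows a sampled
#' synthesis/salvage strategy per genome and vitamin.  Protein
#' sequences are drawn by mutating a random per-family ancestor at
#' \code{withinFamilyDivergence}, so within-family identity is ~1 and
#' between-family identity is background.  Pathway genes are placed as
#' contiguous operon blocks on the single contig; everything else is
#' shuffled.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return list(genomes = named list of gene-record data.frames,
#'   truth = \code{\link{SyntheticTruth}}).
#' @export
simulatePangenome <- function(config = simulationConfig()) {
  rng <- .seededRNG(config$seed)
  ros <- .rosterOf(config)
  roster <- ros$roster; speciesMap <- ros$speciesMap
  markers <- markerAccessions()[seq_len(config$markerCount)]

  fam <- list()   # each: id, fn, members (genomes)
  addFam <- function(id, fn, members)
    fam[[length(fam) + 1L]] <<- list(id = id, fn = fn, members = members)
  for (i in seq_len(config$coreSize)) {
    fn <- if (i <= config$markerCount) unname(markers[i])
          else sprintf("hk_core%04d", i)
    addFam(sprintf("F_core%04d", i), fn, roster)
  }
  for (sp in ros$species) for (i in seq_len(config$accessoryPerSpecies))
    addFam(sprintf("F_acc_%s_%03d", sp, i), sprintf("acc_%s_%03d", sp, i),
           roster[speciesMap[roster] == sp])
  for (g in roster) for (i in seq_len(config$privatePerStrain))
    addFam(sprintf("F_pvt_%s_%03d", g, i), sprintf("pvt_%s_%03d", g, i), g)

  # vitamin strategies and the pathway families they imply
  vitamins <- sprintf("vit%02d", seq_len(config$nVitamins))
  strategies <- expand.grid(genome_id = roster, vitamin = vitamins,
                            stringsAsFactors = FALSE)
  strategies <- strategies[order(strategies$vitamin,
                                 strategies$genome_id), , drop = FALSE]
  strategies$strategy <- .rngSample(rng, names(config$strategyProbs),
                                    nrow(strategies), replace = TRUE,
                                    prob = config$strategyProbs)
  rownames(strategies) <- NULL
  k <- config$synthesisLength
  pwCols <- as.character(unlist(lapply(vitamins, function(v)
    paste0(v, c("_synthesis", "_salvage")))))
  pathwayStatus <- matrix(NA_character_, length(roster), length(pwCols),
                          dimnames = list(roster, pwCols))
  for (v in vitamins) {
    synFns <- sprintf("syn_%s_%02d", v, seq_len(k))
    slvFn <- sprintf("slv_%s_01", v)
    synMembers <- stats::setNames(vector("list", k), synFns)
    slvMembers <- character()
    for (g in roster) {
      st <- strategies$strategy[strategies$genome_id == g &
                                strategies$vitamin == v]
      have <- if (st %in% c("synthesizer", "both")) seq_len(k)
        else {
          nHave <- .rngSampleInt(rng, k, 1L) - 1L   # 0..k-1: never complete
          if (nHave) sort(.rngSampleInt(rng, k, nHave)) else integer()
        }
      for (i in have)
        synMembers[[i]] <- c(synMembers[[i]], g)
      if (st %in% c("salvager", "both")) slvMembers <- c(slvMembers, g)
      pathwayStatus[g, paste0(v, "_synthesis")] <-
        if (length(have) == k) "complete"
        else if (!length(have)) "absent" else "partial"
      pathwayStatus[g, paste0(v, "_salvage")] <-
        if (st %in% c("salvager", "both")) "complete" else "absent"
    }
    for (i in seq_len(k))
      if (length(synMembers[[i]]))
        addFam(sprintf("F_%s", synFns[i]), synFns[i], synMembers[[i]])
    if (length(slvMembers))
      addFam(sprintf("F_%s", slvFn), slvFn, slvMembers)
  }

  # ancestor sequences, unique per family
  for (i in seq_along(fam)) {
    L <- max(30L, .rngPois(rng, 1L, config$proteinLength))
    fam[[i]]$ancestor <- .rngSample(rng, .AA20, L, replace = TRUE)
  }

  # per-genome layout: operon blocks for pathway genes, shuffle the rest
  genomes <- list(); truthFam <- list(); truthFun <- list()
  famByGenome <- lapply(stats::setNames(roster, roster), function(g)
    which(vapply(fam, function(f) g %in% f$members, TRUE)))
  pathwayFamIdx <- which(vapply(fam, function(f)
    grepl("^F_(syn|slv)_", f$id), TRUE))
  pathwayOf <- vapply(fam, function(f)
    sub("^F_(syn|slv)_(vit[0-9]+)_.*$", "\\2_\\1", f$id), "")
  for (g in roster) {
    idx <- famByGenome[[g]]
    pw <- intersect(idx, pathwayFamIdx)
    rest <- setdiff(idx, pw)
    blocks <- split(pw, pathwayOf[pw])           # one operon block per pathway arm
    units <- c(as.list(rest), unname(blocks))
    units <- units[.rngSampleInt(rng, length(units), length(units))]
    ordered <- unlist(units)
    n <- length(ordered)
    geneIds <- sprintf("%s_g%04d", g, seq_len(n))
    seqs <- character(n)
    for (j in seq_len(n)) {
      f <- fam[[ordered[j]]]
      seqs[j] <- paste(.mutateSeq(rng, f$ancestor,
                                  config$withinFamilyDivergence, .AA20),
                       collapse = "")
    }
    strand <- .rngSample(rng, c("+", "-"), n, replace = TRUE)
    genomes[[g]] <- data.frame(gene_id = geneIds, genome_id = g,
                               contig_id = "c1",
                               position_index = seq_len(n) - 1L,
                               strand = strand, protein_seq = seqs,
                               stringsAsFactors = FALSE)
    truthFam[[g]] <- data.frame(
      group_id = vapply(fam[ordered], `[[`, "", "id"),
      genome_id = g, gene_id = geneIds, stringsAsFactors = FALSE)
    truthFun[[g]] <- data.frame(
      gene_id = geneIds, genome_id = g,
      function_id = vapply(fam[ordered], `[[`, "", "fn"),
      stringsAsFactors = FALSE)
  }
  families <- do.call(rbind, truthFam)
  families <- families[order(families$group_id, families$genome_id,
                             families$gene_id), , drop = FALSE]
  rownames(families) <- NULL
  truth <- new("SyntheticTruth", families = families,
               pathwayStatus = pathwayStatus, strategies = strategies,
               functions = do.call(rbind, truthFun), tree = list(),
               config = unclass(config))
  list(genomes = genomes, truth = truth)
}

#' Synthetic pathway definitions matching the generator's truth
#'
#' One synthesis (AND over its genes) and one salvage (single
#' transporter) definition per simulated vitamin.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return named list of \code{\link{PathwayDefinition}}s.
#' @export
syntheticPathwayDefinitions <- function(config = simulationConfig()) {
  defs <- list()
  for (v in sprintf("vit%02d", seq_len(config$nVitamins))) {
    synFns <- sprintf("syn_%s_%02d", v, seq_len(config$synthesisLength))
    defs[[paste0(v, "_synthesis")]] <- PathwayDefinition(
      paste0(v, "_synthesis"), "synthesis",
      sprintf("AND(%s)", paste(synFns, collapse = ",")))
    defs[[paste0(v, "_salvage")]] <- PathwayDefinition(
      paste0(v, "_salvage"), "salvage_transport",
      sprintf("AND(slv_%s_01)", v))
  }
  defs
}

#' Simulate evidence tables for a synthetic cohort
#'
#' Builds a synthetic function dictionary (one equivalog, KO, family and
#' domain accession per true function; marker functions reuse the real
#' TIGRFAM marker accessions so the phylogenomic extraction path works),
#' then emits per-source hits: each gene's true function fires each
#' source independently with probability 1 - \code{fn}, with HMM bit
#' scores an exponential margin above the accession's trusted cutoff;
#' spurious hits are added per gene and source with probability
#' \code{fp}, carrying a random wrong accession and a score centred on
#' the cutoff (so about half are discarded by trusted-cutoff
#' filtering).
#'
#' @param genomes named list of gene-record data.frames from
#'   \code{\link{simulatePangenome}}.
#' @param truth the matching \code{\link{SyntheticTruth}}.
#' @param config the generating \code{\link{simulationConfig}}.
#' @return list(hits = named list of per-source evidence data.frames,
#'   dictionary = \code{\link{FunctionDictionary}}, cutoffs = named
#'   trusted-cutoff vector over HMM accessions).
#' @export
simulateEvidence <- function(genomes, truth, config = simulationConfig()) {
  rng <- .seededRNG(config$seed + 101L)
  fns <- sort(unique(truth@functions$function_id))
  markers <- markerAccessions()[seq_len(config$markerCount)]
  eqAcc <- stats::setNames(sprintf("TEQ_%s", fns), fns)
  isMarker <- fns %in% unname(markers)
  eqAcc[isMarker] <- names(markers)[match(fns[isMarker], unname(markers))]
  koAcc <- stats::setNames(sprintf("K%05d", seq_along(fns)), fns)
  figAcc <- stats::setNames(sprintf("FIG%06d", seq_along(fns)), fns)
  pfAcc <- stats::setNames(sprintf("PF%05d", seq_along(fns)), fns)
  accs <- rbind(
    data.frame(accession = unname(eqAcc), source = "EQUIVALOG_HMM",
               function_id = fns, stringsAsFactors = FALSE),
    data.frame(accession = unname(koAcc), source = "KO", function_id = fns,
               stringsAsFactors = FALSE),
    data.frame(accession = unname(figAcc), source = "FAMILY",
               function_id = fns, stringsAsFactors = FALSE),
    data.frame(accession = unname(pfAcc), source = "DOMAIN_HMM",
               function_id = fns, stringsAsFactors = FALSE))
  pw <- pathwayMembershipTable(syntheticPathwayDefinitions(config))
  pw <- pw[pw$function_id %in% fns, , drop = FALSE]
  dict <- FunctionDictionary(accs, pw)
  cutAccs <- c(unname(eqAcc), unname(pfAcc))
  cutoffs <- stats::setNames(round(.rngUnif(rng, length(cutAccs), 25, 200), 1),
                             cutAccs)
  accOf <- list(EQUIVALOG_HMM = eqAcc, KO = koAcc, FAMILY = figAcc,
                DOMAIN_HMM = pfAcc)
  genes <- truth@functions
  hits <- list()
  for (src in evidenceSources()) {
    isHMM <- src %in% c("EQUIVALOG_HMM", "DOMAIN_HMM")
    keep <- .rngBinom(rng, nrow(genes), 1 - config$fn)
    acc <- unname(accOf[[src]][genes$function_id[keep]])
    score <- if (isHMM)
      unname(cutoffs[acc]) + .rngExp(rng, sum(keep), 1 / config$marginMean)
    else rep(NA_real_, sum(keep))
    h <- if (!any(keep)) .emptyHits()
    else data.frame(gene_id = genes$gene_id[keep], source = src,
                    accession = acc, bit_score = score,
                    trusted_cutoff = if (isHMM) unname(cutoffs[acc])
                                     else NA_real_,
                    stringsAsFactors = FALSE)
    spur <- .rngBinom(rng, nrow(genes), config$fp)
    if (any(spur)) {
      wrong <- vapply(genes$function_id[spur], function(f)
        unname(.rngSample(rng, accOf[[src]][names(accOf[[src]]) != f], 1L)),
        "")
      sScore <- if (isHMM)
        unname(cutoffs[wrong]) + .rngNorm(rng, sum(spur), 0,
                                          config$spuriousScoreSd)
      else rep(NA_real_, sum(spur))
      h <- rbind(h, data.frame(gene_id = genes$gene_id[spur], source = src,
                               accession = wrong, bit_score = sScore,
                               trusted_cutoff = if (isHMM)
                                 unname(cutoffs[wrong]) else NA_real_,
                               stringsAsFactors = FALSE))
    }
    h <- h[order(h$gene_id, h$accession), , drop = FALSE]
    rownames(h) <- NULL
    hits[[src]] <- h
  }
  list(hits = hits, dictionary = dict, cutoffs = cutoffs)
}

# TN93 transition-probability matrix at branch length t (expected
# substitutions/site), rates normalised to unit mean rate.
.tn93Pmatrix <- function(t, freqs, alphaR, alphaY, beta = 1) {
  gA <- freqs[["A"]]; gC <- freqs[["C"]]; gG <- freqs[["G"]]; gT <- freqs[["T"]]
  gR <- gA + gG; gY <- gC + gT
  mu <- 2 * (gA * gG * alphaR + gC * gT * alphaY + gR * gY * beta)
  a1 <- alphaR / mu; a2 <- alphaY / mu; b <- beta / mu
  e2 <- exp(-b * t)
  e3 <- exp(-(gR * a1 + gY * b) * t)
  e4 <- exp(-(gY * a2 + gR * b) * t)
  P <- matrix(0, 4, 4, dimnames = list(.NT4, .NT4))
  for (i in .NT4) for (j in .NT4) {
    pj <- freqs[[j]]
    iP <- i %in% c("A", "G"); jP <- j %in% c("A", "G")
    P[i, j] <- if (iP && jP) {
      pj + pj * (gY / gR) * e2 +
        (if (i == j) (gR - pj) / gR else -pj / gR) * e3
    } else if (!iP && !jP) {
      pj + pj * (gR / gY) * e2 +
        (if (i == j) (gY - pj) / gY else -pj / gY) * e4
    } else pj * (1 - e2)
  }
  P
}

.evolveChild <- function(rng, chars, b, model, config) {
  if (model == "poisson_aa") {
    nsub <- .rngPois(rng, length(chars), b)
    for (i in which(nsub > 0L)) for (s in seq_len(nsub[i]))
      chars[i] <- .rngSample(rng, setdiff(.AA20, chars[i]), 1L)
    chars
  } else {
    P <- if (model == "jc_nt")
      .tn93Pmatrix(b, c(A = .25, C = .25, G = .25, T = .25), 1, 1, 1)
    else .tn93Pmatrix(b, config$tnFreqs, config$tnAlphaR, config$tnAlphaY)
    vapply(chars, function(ch)
      .rngSample(rng, .NT4, 1L, prob = P[ch, ]), "")
  }
}

#' Simulate per-marker alignments along a known tree
#'
#' Sites evolve independently, with no indels, under the configured
#' model: \code{poisson_aa} draws a Poisson(branch length) number of
#' substitutions per site, each to a uniformly chosen different
#' residue; \code{jc_nt}/\code{tn93_nt} sample from the exact
#' transition-probability matrices.  Branch lengths are expected
#' substitutions per site.
#'
#' @param config a \code{\link{simulationConfig}}; \code{config$tree}
#'   supplies the true tree (taxa default to the simulated genome
#'   roster when a random tree is drawn).
#' @return list(alignments = named list of per-marker
#'   \code{XStringSet}s, tree = the true \code{phylo}).
#' @export
simulateMarkerAlignments <- function(config = simulationConfig()) {
  rng <- .seededRNG(config$seed + 202L)
  tree <- config$tree
  if (is.null(tree)) {
    roster <- .rosterOf(config)$roster
    tree <- .withRNG(rng, ape::rtree(length(roster), rooted = TRUE,
                                     tip.label = roster))
    tree$edge.length <- .rngUnif(rng, nrow(tree$edge), 0.02, 0.12)
  }
  if (any(tree$edge.length < 0)) stop("branch length < 0 in supplied tree")
  nt <- config$model != "poisson_aa"
  rootFreqs <- if (config$model == "tn93_nt") config$tnFreqs
               else if (nt) stats::setNames(rep(.25, 4), .NT4) else NULL
  nTip <- length(tree$tip.label)
  root <- nTip + 1L
  alignments <- list()
  for (m in seq_len(config$markerCount)) {
    L <- config$markerLength
    seqAt <- vector("list", nTip + tree$Nnode)
    seqAt[[root]] <- if (nt)
      .rngSample(rng, .NT4, L, replace = TRUE, prob = rootFreqs)
    else .rngSample(rng, .AA20, L, replace = TRUE)
    # preorder traversal
    for (e in seq_len(nrow(tree$edge))) {
      par <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
      seqAt[[child]] <- .evolveChild(rng, seqAt[[par]],
                                     tree$edge.length[e], config$model,
                                     config)
    }
    chs <- vapply(seq_len(nTip), function(i)
      paste(seqAt[[i]], collapse = ""), "")
    names(chs) <- tree$tip.label
    alignments[[sprintf("M%02d", m)]] <- if (nt)
      Biostrings::DNAStringSet(chs) else Biostrings::AAStringSet(chs)
  }
  list(alignments = alignments, tree = tree)
}

#' Write a synthetic cohort to disk in the package's file dialects
#'
#' Emits, under \code{dir}: per-genome FASTA + feature tables, the four
#' per-source hit tables, a trusted-cutoff TSV, the dictionary TSVs,
#' the true orthologue table, and a truth bundle (pathway status and
#' strategies TSVs).
#'
#' @param sim result of \code{\link{simulatePangenome}}.
#' @param evidence result of \code{\link{simulateEvidence}}.
#' @param dir output directory (created).
#' @return invisibly, a named list of written paths.
#' @export
writeSyntheticCohort <- function(sim, evidence, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (g in names(sim$genomes)) {
    fa <- file.path(dir, paste0(g, ".faa"))
    ft <- file.path(dir, paste0(g, ".features.tsv"))
    writeGenome(sim$genomes[[g]], fa, ft)
    paths$genomes[[g]] <- c(fasta = fa, features = ft)
  }
  for (src in names(evidence$hits)) {
    p <- file.path(dir, paste0("hits_", src, ".tsv"))
    writeHitTable(evidence$hits[[src]], p)
    paths$hits[[src]] <- p
  }
  cut <- data.frame(accession = names(evidence$cutoffs),
                    trusted_cutoff = unname(evidence$cutoffs))
  paths$cutoffs <- file.path(dir, "trusted_cutoffs.tsv")
  utils::write.table(cut, paths$cutoffs, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$dictionary <- file.path(dir, "dictionary_accessions.tsv")
  utils::write.table(evidence$dictionary@accessions, paths$dictionary,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  paths$pathwayMap <- file.path(dir, "dictionary_pathways.tsv")
  utils::write.table(evidence$dictionary@pathways, paths$pathwayMap,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  paths$orthologues <- file.path(dir, "orthologues_truth.tsv")
  writeOrthologueTable(OrthologueTable(sim$truth@families), paths$orthologues)
  paths$pathwayTruth <- file.path(dir, "truth_pathway_status.tsv")
  utils::write.table(
    data.frame(genome_id = rownames(sim$truth@pathwayStatus),
               sim$truth@pathwayStatus, check.names = FALSE),
    paths$pathwayTruth, sep = "\t", quote = FALSE, row.names = FALSE)
  paths$strategies <- file.path(dir, "truth_strategies.tsv")
  utils::write.table(sim$truth@strategies, paths$strategies, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
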