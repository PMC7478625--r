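test_that("the generator is byte-deterministic under a fixed seed", {
  cfg <- smallConfig(seed = 71L)
  s1 <- simulatePangenome(cfg)
  s2 <- simulatePangenome(cfg)
  expect_identical(s1$genomes, s2$genomes)
  expect_identical(s1$truth@families, s2$truth@families)
  e1 <- simulateEvidence(s1$genomes, s1$truth, cfg)
  e2 <- simulateEvidence(s2$genomes, s2$truth, cfg)
  expect_identical(e1$hits, e2$hits)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeSyntheticCohort(s1, e1, d1)
  writeSyntheticCohort(s2, e2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d2, f)), readLines(file.path(d1, f)))
})

test_that("a pure-core configuration gives identical gene content everywhere", {
  cfg <- simulationConfig(nSpecies = 3L, strainsPerSpecies = 2L,
                          coreSize = 100L, accessoryPerSpecies = 0L,
                          privatePerStrain = 0L, nVitamins = 0L,
                          markerCount = 18L, seed = 73L)
  sim <- simulatePangenome(cfg)
  fams <- split(sim$truth@families$group_id, sim$truth@families$genome_id)
  content <- unique(lapply(fams, sort))
  expect_length(content, 1L)
  tab <- OrthologueTable(sim$truth@families)
  expect_length(coreGenome(tab, genomeIds(tab)), 100L)
})

test_that("truth-table bookkeeping matches the emitted genomes", {
  cfg <- smallConfig(seed = 79L)
  sim <- simulatePangenome(cfg)
  byGenome <- base::table(sim$truth@families$genome_id)
  for (g in names(sim$genomes))
    expect_equal(unname(byGenome[g]), nrow(sim$genomes[[g]]),
                 ignore_attr = TRUE)
  # gene positions are a contiguous 0-based rank per contig
  for (g in names(sim$genomes))
    expect_equal(sort(sim$genomes[[g]]$position_index),
                 seq_len(nrow(sim$genomes[[g]])) - 1L)
  # truth status values are consistent with their own strategy draws
  st <- sim$truth@strategies
  ps <- sim$truth@pathwayStatus
  for (i in seq_len(nrow(st))) {
    syn <- ps[st$genome_id[i], paste0(st$vitamin[i], "_synthesis")]
    sal <- ps[st$genome_id[i], paste0(st$vitamin[i], "_salvage")]
    expect_equal(sal == "complete",
                 st$strategy[i] %in% c("salvager", "both"))
    expect_equal(syn == "complete",
                 st$strategy[i] %in% c("synthesizer", "both"))
  }
})

test_that("evidence noise behaves like its nominal rates", {
  cfg <- smallConfig(seed = 83L, fn = 1)
  sim <- simulatePangenome(cfg)
  ev <- simulateEvidence(sim$genomes, sim$truth, cfg)
  expect_true(all(vapply(ev$hits, nrow, 0L) == 0L))
  g <- sim$genomes[[1L]]
  ann <- annotateGenome(g, corepan:::.emptyHits(), ev$dictionary)
  expect_true(all(ann$tier == "NONE"))

  # empirical per-source drop rate across seeds sits inside the
  # binomial 99% interval around fn
  fn <- 0.2
  drops <- 0L; total <- 0L
  for (s in 1:10) {
    cfgN <- smallConfig(seed = 1000L + s, fn = fn)
    simN <- simulatePangenome(cfgN)
    evN <- simulateEvidence(simN$genomes, simN$truth, cfgN)
    nGenes <- nrow(simN$truth@functions)
    total <- total + 4L * nGenes
    drops <- drops + 4L * nGenes - sum(vapply(evN$hits, nrow, 0L))
  }
  ci <- stats::qbinom(c(0.005, 0.995), total, fn)
  expect_gte(drops, ci[1L])
  expect_lte(drops, ci[2L])
})

test_that("true HMM hits clear their cutoffs; spurious hits straddle them", {
  cfg <- smallConfig(seed = 87L, fp = 0.3)
  sim <- simulatePangenome(cfg)
  ev <- simulateEvidence(sim$genomes, sim$truth, cfg)
  eq <- ev$hits$EQUIVALOG_HMM
  dict <- ev$dictionary@accessions
  trueAcc <- stats::setNames(dict$accession[dict$source == "EQUIVALOG_HMM"],
                             dict$function_id[dict$source == "EQUIVALOG_HMM"])
  fnOf <- stats::setNames(sim$truth@functions$function_id,
                          sim$truth@functions$gene_id)
  isTrue <- eq$accession == unname(trueAcc[fnOf[eq$gene_id]])
  expect_true(all(eq$bit_score[isTrue] >= eq$trusted_cutoff[isTrue]))
  expect_gt(sum(!isTrue), 0L)
  expect_gt(sum(eq$bit_score[!isTrue] < eq$trusted_cutoff[!isTrue]), 0L)
})

test_that("marker evolution respects the tree and the seed", {
  star <- ape::read.tree(text = "(a:0,b:0,c:0);")
  cfg0 <- simulationConfig(markerCount = 2L, markerLength = 50L,
                           tree = star, seed = 91L)
  ms0 <- simulateMarkerAlignments(cfg0)
  for (a in ms0$alignments)
    expect_length(unique(as.character(a)), 1L)

  neg <- star; neg$edge.length <- c(-0.1, 0, 0)
  expect_error(simulateMarkerAlignments(
    simulationConfig(tree = neg, seed = 1L)), "branch length < 0")

  two <- ape::read.tree(text = "(a:0.05,b:0.05);")
  cfg2 <- simulationConfig(markerCount = 1L, markerLength = 10000L,
                           tree = two, seed = 93L)
  aln <- simulateMarkerAlignments(cfg2)$alignments[[1L]]
  d <- poissonDistance(aln)["a", "b"]
  p <- 1 - exp(-d)
  se <- sqrt(p * (1 - p) / 10000) / (1 - p)  # delta-method SE of d
  expect_lt(abs(d - 0.1), 3 * se)

  ms1 <- simulateMarkerAlignments(cfg0)
  expect_identical(lapply(ms1$alignments, as.character),
                   lapply(ms0$alignments, as.character))
})

test_that("nucleotide markers match their model's expected distances", {
  two <- ape::read.tree(text = "(a:0.08,b:0.08);")
  for (model in c("jc_nt", "tn93_nt")) {
    cfg <- simulationConfig(markerCount = 1L, markerLength = 20000L,
                            tree = two, model = model, seed = 97L)
    aln <- simulateMarkerAlignments(cfg)$alignments[[1L]]
    d <- tamuraNeiDistance(aln)["a", "b"]
    expect_lt(abs(d - 0.16), 0.02)
  }
})

test_that("pathway completeness degrades gracefully as evidence drops out", {
  meanCompleteness <- function(fn, seed) {
    cfg <- smallConfig(seed = seed, fn = fn)
    sim <- simulatePangenome(cfg)
    ev <- simulateEvidence(sim$genomes, sim$truth, cfg)
    hits <- filterTrusted(do.call(rbind, unname(ev$hits)))
    defs <- syntheticPathwayDefinitions(cfg)
    comp <- 0; nn <- 0
    for (g in names(sim$genomes)) {
      ann <- annotateGenome(sim$genomes[[g]],
                            hits[hits$gene_id %in% sim$genomes[[g]]$gene_id, ],
                            ev$dictionary)
      for (d in defs) {
        comp <- comp + callPathway(g, d, ann)$completeness
        nn <- nn + 1
      }
    }
    comp / nn
  }
  seeds <- 1:3
  m0 <- mean(vapply(seeds, function(s) meanCompleteness(0, 300 + s), 0))
  m4 <- mean(vapply(seeds, function(s) meanCompleteness(0.4, 300 + s), 0))
  m8 <- mean(vapply(seeds, function(s) meanCompleteness(0.8, 300 + s), 0))
  expect_gt(m0, m4)
  expect_gt(m4, m8)
})
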