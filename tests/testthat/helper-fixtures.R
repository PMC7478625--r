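# Shared in-code fixtures: tiny genomes, evidence frames, random
# orthologue tables and additive distance matrices.

tinyDictionary <- function() {
  FunctionDictionary(
    accessions = data.frame(
      accession = c("TIGR00001", "TIGR00002", "K00001", "K00002",
                    "FIG000001", "FIG000002", "PF00001", "PF00002"),
      source = c("EQUIVALOG_HMM", "EQUIVALOG_HMM", "KO", "KO",
                 "FAMILY", "FAMILY", "DOMAIN_HMM", "DOMAIN_HMM"),
      function_id = c("thiC", "thiD", "thiC", "thiD", "thiC", "thiD",
                      "thiC", "thiD"),
      stringsAsFactors = FALSE),
    pathways = data.frame(
      function_id = c("thiC", "thiD"),
      pathway_id = "thiamine_synthesis", stringsAsFactors = FALSE))
}

hitRow <- function(gene, source, accession, score = NA_real_,
                   cutoff = NA_real_) {
  data.frame(gene_id = gene, source = source, accession = accession,
             bit_score = score, trusted_cutoff = cutoff,
             stringsAsFactors = FALSE)
}

# assignments frame carrying function calls at a tier
assignmentsOf <- function(fns, tier = "HIGH") {
  if (!length(fns))
    return(data.frame(gene_id = character(), function_id = character(),
                      tier = character(), stringsAsFactors = FALSE))
  data.frame(gene_id = sprintf("g%03d", seq_along(fns)), function_id = fns,
             tier = tier, stringsAsFactors = FALSE)
}

# random orthologue membership table (occasionally with paralogues)
randomOrthoTable <- function(nGenomes, nGroups, paralogueProb = 0.1) {
  genomes <- sprintf("g%02d", seq_len(nGenomes))
  rows <- do.call(rbind, lapply(seq_len(nGroups), function(k) {
    p <- stats::runif(1, 0.2, 1)
    members <- genomes[stats::runif(nGenomes) < p]
    if (!length(members)) members <- sample(genomes, 1L)
    n <- ifelse(stats::runif(length(members)) < paralogueProb, 2L, 1L)
    members <- rep(members, n)
    data.frame(group_id = sprintf("OG%03d", k), genome_id = members,
               gene_id = sprintf("OG%03d_%s_%d", k, members,
                                 stats::ave(seq_along(members), members,
                                            FUN = seq_along)),
               stringsAsFactors = FALSE)
  }))
  OrthologueTable(rows, roster = genomes)
}

randomTaxa <- function(roster, nTaxa) {
  idx <- sort(c(seq_len(nTaxa), sample.int(nTaxa, length(roster) - nTaxa,
                                           replace = TRUE)))
  split(roster, sprintf("t%02d", idx))
}

# brute-force oracles over a membership data.frame
bfPresent <- function(table, genomes) {
  m <- table@membership
  vapply(sort(unique(m$group_id)), function(g)
    all(vapply(genomes, function(gm)
      any(m$group_id == g & m$genome_id == gm), TRUE)), TRUE)
}

bfCore <- function(table, genomes) names(which(bfPresent(table, genomes)))

bfTaxonPresence <- function(table, taxa, rule) {
  m <- table@membership
  groups <- sort(unique(m$group_id))
  sapply(taxa, function(gms) vapply(groups, function(g) {
    has <- vapply(gms, function(gm)
      any(m$group_id == g & m$genome_id == gm), TRUE)
    if (rule == "all_strains") all(has) else any(has)
  }, TRUE))
}

# random additive distance matrix from a random binary tree
randomAdditive <- function(nTaxa) {
  tr <- ape::rtree(nTaxa, rooted = FALSE)
  tr$tip.label <- sprintf("t%02d", seq_len(nTaxa))
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 1)
  D <- ape::cophenetic.phylo(tr)
  ord <- sort(rownames(D))
  list(tree = tr, D = D[ord, ord])
}

sameTopology <- function(t1, t2) {
  setequal(bipartitionKeys(ape::unroot(t1)), bipartitionKeys(ape::unroot(t2)))
}

# literal independent transcription of the published TN93 estimator,
# written against the formula rather than the package code
tn93Reference <- function(x, y) {
  ok <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
  x <- x[ok]; y <- y[ok]; n <- length(x)
  cnt <- function(b) (sum(x == b) + sum(y == b)) / (2 * n)
  gA <- cnt("A"); gC <- cnt("C"); gG <- cnt("G"); gT <- cnt("T")
  gR <- gA + gG; gY <- gC + gT
  P1 <- sum((x == "A" & y == "G") | (x == "G" & y == "A")) / n
  P2 <- sum((x == "C" & y == "T") | (x == "T" & y == "C")) / n
  Q <- sum(x != y) / n - P1 - P2
  k1 <- 2 * gA * gG / gR
  k2 <- 2 * gC * gT / gY
  k3 <- 2 * (gR * gY - gA * gG * gY / gR - gC * gT * gR / gY)
  -k1 * log(1 - P1 / k1 - Q / (2 * gR)) -
    k2 * log(1 - P2 / k2 - Q / (2 * gY)) -
    k3 * log(1 - Q / (2 * gR * gY))
}

smallConfig <- function(...) {
  simulationConfig(nSpecies = 3L, strainsPerSpecies = 2L, coreSize = 30L,
                   accessoryPerSpecies = 5L, privatePerStrain = 3L,
                   nVitamins = 2L, markerCount = 5L, markerLength = 80L,
                   ...)
}
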