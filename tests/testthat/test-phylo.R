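test_that("single-copy extraction honours its duplicate policy", {
  markers <- sprintf("TIGR%05d", 1:3)
  genomes <- c("gA", "gB")
  hits <- expand.grid(accession = markers, genome_id = genomes,
                      stringsAsFactors = FALSE)
  hits$gene_id <- sprintf("%s_%s", hits$genome_id, hits$accession)
  mm <- extractSingleCopy(hits, markers, genomes)
  expect_equal(dim(mm@geneMap), c(3L, 2L))
  expect_equal(mm@geneMap["TIGR00002", "gB"], "gB_TIGR00002")

  dup <- rbind(hits, hits[hits$accession == "TIGR00002" &
                          hits$genome_id == "gA", ])
  expect_message(mm2 <- extractSingleCopy(dup, markers, genomes),
                 "dropping marker TIGR00002")
  expect_equal(rownames(mm2@geneMap), c("TIGR00001", "TIGR00003"))
  expect_error(extractSingleCopy(dup, markers, genomes, policy = "fail"),
               "TIGR00002.*genome gA")
  expect_error(extractSingleCopy(dup, "TIGR00002", genomes), "all markers")
  expect_error(extractSingleCopy(hits, character()), "non-empty")
})

test_that("concatenation tiles partitions and preserves p-distances under marker permutation", {
  a1 <- Biostrings::AAStringSet(c(x = "AAAAAAAAAA", y = "AAAAACCCCC",
                                  z = "CCCCCCCCCC"))
  a2 <- Biostrings::AAStringSet(c(x = "DDDDDDDDDD", y = "DDDDDDDDDD",
                                  z = "DDDDDEEEEE"))
  cc <- concatenateAlignments(list(m1 = a1, m2 = a2))
  expect_equal(Biostrings::width(cc@seqs), rep(20L, 3L))
  expect_equal(cc@partition$start, c(1L, 11L))
  expect_equal(cc@partition$end, c(10L, 20L))
  one <- concatenateAlignments(list(m1 = a1))
  expect_equal(as.character(one@seqs), as.character(a1)[sort(names(a1))])
  flip <- concatenateAlignments(list(m1 = a1, m2 = a2),
                                markerOrder = c("m2", "m1"))
  expect_equal(poissonDistance(flip), poissonDistance(cc))
  expect_equal(flip@partition$marker_id, c("m2", "m1"))
  bad <- Biostrings::AAStringSet(c(x = "AA", y = "AA"))
  expect_error(concatenateAlignments(list(m1 = a1, m2 = bad)),
               "taxon missing.*z")
})

test_that("Poisson correction matches its closed form and flags saturation", {
  same <- Biostrings::AAStringSet(c(a = "MKLV", b = "MKLV"))
  expect_equal(poissonDistance(same)["a", "b"], 0)
  m <- rbind(a = rep("A", 10), b = c(rep("A", 9), "C"))
  expect_equal(poissonDistance(m)["a", "b"], -log(1 - 0.1),
               tolerance = 1e-12)
  expect_gte(poissonDistance(m)["a", "b"], 0.1)  # d >= p
  sat <- rbind(a = c("A", "A"), b = c("C", "C"))
  D <- poissonDistance(sat)
  expect_true(is.na(D["a", "b"]))
  expect_true(attr(D, "saturated")["a", "b"])
  gap <- rbind(a = c("A", "-"), b = c("-", "A"))
  expect_error(poissonDistance(gap), "zero comparable sites.*a / b")
})

test_that("TN93 distance agrees with an independent transcription and with ape", {
  set.seed(43)
  for (rep in 1:10) {
    n <- 600L
    x <- sample(c("A", "C", "G", "T"), n, replace = TRUE,
                prob = c(.35, .15, .2, .3))
    y <- x
    flip <- stats::runif(n) < 0.15
    y[flip] <- vapply(x[flip], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    m <- rbind(s1 = x, s2 = y)
    mine <- tamuraNeiDistance(m)["s1", "s2"]
    expect_equal(mine, tn93Reference(x, y), tolerance = 1e-12)
    apeD <- as.numeric(ape::dist.dna(ape::as.DNAbin(
      matrix(tolower(c(x, y)), 2, byrow = TRUE,
             dimnames = list(c("s1", "s2"), NULL))), model = "TN93"))
    expect_equal(mine, apeD, tolerance = 1e-9)
  }
  ident <- rbind(a = c("A", "C", "G", "T"), b = c("A", "C", "G", "T"))
  expect_equal(tamuraNeiDistance(ident)["a", "b"], 0)
})

test_that("TN93 reduces to Jukes-Cantor in the symmetric limit", {
  # equal base frequencies, all 12 substitution directions equally
  # represented: P1 = P2 = Q/4
  block <- function(from, to, n) list(rep(from, n), rep(to, n))
  n1 <- 30L   # each of the 12 ordered substitution types
  x <- character(); y <- character()
  nts <- c("A", "C", "G", "T")
  for (i in nts) for (j in nts) {
    if (i == j) next
    x <- c(x, rep(i, n1)); y <- c(y, rep(j, n1))
  }
  # pad with identical sites, equal frequencies
  x <- c(x, rep(nts, 200)); y <- c(y, rep(nts, 200))
  p <- mean(x != y)
  jc <- -3 / 4 * log(1 - 4 * p / 3)
  tn <- tamuraNeiDistance(rbind(a = x, b = y))["a", "b"]
  expect_equal(tn, jc, tolerance = 1e-9)
})

test_that("neighbor joining resolves the three- and four-taxon formulas", {
  D3 <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- neighborJoining(D3)
  expect_equal(sort(t3$tip.label), c("A", "B", "C"))
  bl <- stats::setNames(t3$edge.length, t3$tip.label[t3$edge[, 2L]])
  expect_equal(bl[c("A", "B", "C")], c(A = 1, B = 1, C = 2))

  taxa <- c("A", "B", "C", "D")
  D4 <- matrix(c(0, 3, 5, 6, 3, 0, 6, 7, 5, 6, 0, 7, 6, 7, 7, 0), 4, 4,
               dimnames = list(taxa, taxa))
  t4 <- neighborJoining(D4)
  expect_true("A|B" %in% bipartitionKeys(t4) ||
              "C|D" %in% bipartitionKeys(t4))
  internal <- t4$edge.length[t4$edge[, 2L] > length(t4$tip.label)]
  expect_equal(internal, 1)
  lens <- stats::setNames(t4$edge.length[t4$edge[, 2L] <= 4],
                          t4$tip.label[t4$edge[t4$edge[, 2L] <= 4, 2L]])
  expect_equal(lens[taxa], c(A = 1, B = 2, C = 3, D = 4))

  expect_error(neighborJoining(D3[1:2, 1:2]), ">= 3 taxa")
  Dbad <- D4; Dbad["A", "C"] <- Dbad["C", "A"] <- NA
  expect_error(neighborJoining(Dbad), "A/C")
})

test_that("NJ recovers the generating topology on random additive matrices", {
  set.seed(47)
  for (rep in 1:40) {
    ra <- randomAdditive(sample(4:8, 1))
    tr <- neighborJoining(ra$D)
    expect_true(sameTopology(tr, ra$tree))
    # agreement with an independent NJ implementation
    expect_true(sameTopology(tr, ape::nj(ra$D)))
  }
})

test_that("NJ output is invariant to taxon input order", {
  set.seed(53)
  ra <- randomAdditive(7)
  t0 <- neighborJoining(ra$D)
  for (rep in 1:5) {
    p <- sample(nrow(ra$D))
    tp <- neighborJoining(ra$D[p, p])
    expect_true(sameTopology(t0, tp))
  }
})

test_that("bootstrap supports are seeded, bounded, and saturate on congruent signal", {
  # 20 split-informative columns (a,b = A; c,d = C) + 20 constant columns
  aln <- Biostrings::AAStringSet(c(
    a = paste(c(rep("A", 20), rep("G", 20)), collapse = ""),
    b = paste(c(rep("A", 20), rep("G", 20)), collapse = ""),
    c = paste(c(rep("C", 20), rep("G", 20)), collapse = ""),
    d = paste(c(rep("C", 20), rep("G", 20)), collapse = "")))
  tr <- bootstrapSupports(aln, poissonDistance, nReps = 50, seed = 9)
  sup <- attr(tr, "supports")
  expect_length(sup, 1L)  # a 4-taxon tree has one internal edge
  expect_equal(unname(sup[1]), 100)
  tr2 <- bootstrapSupports(aln, poissonDistance, nReps = 50, seed = 9)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))
  expect_true(all(sup >= 0 & sup <= 100))
  expect_error(bootstrapSupports(aln, poissonDistance, nReps = 0), "nReps")

  cfg <- smallConfig(seed = 57L)
  ms <- simulateMarkerAlignments(cfg)
  cc <- concatenateAlignments(ms$alignments)
  b1 <- bootstrapSupports(cc, poissonDistance, nReps = 20, seed = 3)
  b2 <- bootstrapSupports(cc, poissonDistance, nReps = 20, seed = 3)
  expect_identical(attr(b1, "supports"), attr(b2, "supports"))
  expect_true(all(attr(b1, "supports") >= 0 & attr(b1, "supports") <= 100))
})

test_that("newick IO round-trips topology, lengths and supports", {
  d <- withr::local_tempdir()
  p <- file.path(d, "t.nwk")
  writeLines("(A:1,(B:2,C:3):0.5);", p)
  t3 <- readNewickTree(p)
  expect_equal(sort(t3$tip.label), c("A", "B", "C"))
  expect_equal(sort(t3$edge.length), c(0.5, 1, 2, 3))

  set.seed(59)
  for (rep in 1:10) {
    n <- sample(4:20, 1)
    tr <- ape::rtree(n)
    tr$node.label <- as.character(round(stats::runif(tr$Nnode) * 100))
    writeNewickTree(tr, p)
    back <- readNewickTree(p)
    expect_setequal(bipartitionKeys(ape::unroot(back)),
                    bipartitionKeys(ape::unroot(tr)))
    expect_equal(sort(back$edge.length), sort(tr$edge.length),
                 tolerance = 1e-9)
    expect_setequal(back$node.label, tr$node.label)
  }
  writeLines("((A:1,B:2", p)
  expect_error(readNewickTree(p), "malformed newick")
})

test_that("simulated markers yield the true topology with confident supports", {
  cfg <- simulationConfig(nSpecies = 3L, strainsPerSpecies = 2L,
                          markerCount = 8L, markerLength = 150L, seed = 61L)
  ms <- simulateMarkerAlignments(cfg)
  cc <- concatenateAlignments(ms$alignments)
  tr <- bootstrapSupports(cc, poissonDistance, nReps = 40, seed = 8)
  expect_true(sameTopology(tr, ms$tree))
  trueKeys <- bipartitionKeys(ape::unroot(ms$tree))
  sup <- attr(tr, "supports")
  expect_gt(mean(sup[names(sup) %in% trueKeys]), 60)
})
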