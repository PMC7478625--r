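test_that("genome context support scans the rank window on the same contig", {
  gene <- data.frame(gene_id = "g5", contig_id = "c1", position_index = 5L)
  nbrs <- data.frame(
    gene_id = c("g4", "g6", "g9"), contig_id = "c1",
    position_index = c(4L, 6L, 9L),
    function_id = c("thiC", "thiD", "thiC"),
    tier = c("HIGH", "MODERATE", "HIGH"), stringsAsFactors = FALSE)
  expect_true(genomeContextSupport(gene, nbrs, c("thiC", "thiD"), window = 5L))
  expect_false(genomeContextSupport(gene, nbrs, c("otherFn"), window = 5L))
  expect_false(genomeContextSupport(gene, nbrs[0, ], c("thiC"), window = 5L))
  expect_error(genomeContextSupport(gene, nbrs, c("thiC"), window = 0L),
               "window")
  # NONE-tier neighbours never lend support
  nbrs$tier <- "NONE"
  expect_false(genomeContextSupport(gene, nbrs, c("thiC", "thiD")))
})

test_that("context verdicts match an exhaustive window scan on a random contig", {
  set.seed(7)
  for (rep in 1:5) {
    n <- 30L
    nbrs <- data.frame(
      gene_id = sprintf("g%02d", 1:n), contig_id = "c1",
      position_index = sample(0:(n - 1L)),
      function_id = sample(c("a", "b", "z", NA), n, replace = TRUE),
      tier = sample(confidenceTiers(), n, replace = TRUE),
      stringsAsFactors = FALSE)
    pwFns <- c("a", "b")
    w <- sample(1:6, 1)
    for (i in 1:n) {
      got <- genomeContextSupport(nbrs[i, ], nbrs, pwFns, window = w)
      manual <- FALSE
      for (j in setdiff(1:n, i)) {
        if (abs(nbrs$position_index[j] - nbrs$position_index[i]) <= w &&
            nbrs$tier[j] != "NONE" && !is.na(nbrs$function_id[j]) &&
            nbrs$function_id[j] %in% pwFns) manual <- TRUE
      }
      expect_identical(got, manual)
    }
  }
})

test_that("the confidence scale ranks evidence as documented", {
  dict <- tinyDictionary()
  tierOf <- function(hits, context = FALSE)
    assignConfidence(hits$gene_id[1L], hits, dict, context = context)$tier
  eq <- hitRow("g", "EQUIVALOG_HMM", "TIGR00001", 120, 100)
  ko <- hitRow("g", "KO", "K00001")
  fam <- hitRow("g", "FAMILY", "FIG000001")
  dom <- hitRow("g", "DOMAIN_HMM", "PF00001", 30, 20)
  expect_equal(tierOf(eq), "HIGH")
  expect_equal(tierOf(rbind(ko, fam)), "HIGH")        # two sources agree
  expect_equal(tierOf(ko), "MODERATE")
  expect_equal(tierOf(fam, context = TRUE), "MODERATE")
  expect_equal(tierOf(fam, context = FALSE), "LOW")
  expect_equal(tierOf(dom), "LOW")                    # hole filler
  none <- assignConfidence("g", hitRow("x", "KO", "K00001"), dict)
  expect_equal(none$tier, "NONE")
  expect_true(is.na(none$function_id))
  expect_error(assignConfidence("g", hitRow("g", "KO", "K99999"), dict),
               "K99999")
})

test_that("function comes from the highest-priority source; conflicts audit", {
  dict <- tinyDictionary()
  # KO says thiC, FAMILY says thiD: KO wins, single-source support
  a <- assignConfidence("g", rbind(hitRow("g", "KO", "K00001"),
                                   hitRow("g", "FAMILY", "FIG000002")), dict)
  expect_equal(a$function_id, "thiC")
  expect_equal(a$tier, "MODERATE")
  expect_match(a$sources, "FAMILY:FIG000002")
  # equivalog overrides a disagreeing KO
  b <- assignConfidence("g", rbind(hitRow("g", "EQUIVALOG_HMM", "TIGR00002",
                                          150, 100),
                                   hitRow("g", "KO", "K00001")), dict)
  expect_equal(b$function_id, "thiD")
  expect_equal(b$tier, "HIGH")
})

test_that("adding evidence never lowers the tier; removing the equivalog drops it", {
  dict <- tinyDictionary()
  pool <- list(hitRow("g", "EQUIVALOG_HMM", "TIGR00001", 120, 100),
               hitRow("g", "KO", "K00001"),
               hitRow("g", "FAMILY", "FIG000001"),
               hitRow("g", "DOMAIN_HMM", "PF00001", 30, 20))
  set.seed(11)
  for (rep in 1:40) {
    keep <- stats::runif(4) < 0.5
    extra <- which(!keep)
    ctx <- sample(c(TRUE, FALSE), 1)
    base <- if (any(keep)) do.call(rbind, pool[keep]) else pool[[2L]][0, ]
    t0 <- assignConfidence("g", base, dict, context = ctx)$tier
    for (e in extra) {
      t1 <- assignConfidence("g", rbind(base, pool[[e]]), dict,
                             context = ctx)$tier
      expect_gte(tierRank(t1), tierRank(t0))
    }
  }
  full <- do.call(rbind, pool)
  noEq <- full[full$source != "EQUIVALOG_HMM", ]
  expect_equal(assignConfidence("g", full, dict)$tier, "HIGH")
  # KO+FAMILY still agree -> HIGH; drop FAMILY too and the tier falls
  expect_equal(assignConfidence("g", noEq[noEq$source != "FAMILY", ],
                                dict)$tier, "MODERATE")
})

test_that("two-pass genome annotation recovers truth and rescues context calls", {
  cfg <- smallConfig(seed = 21L)
  sim <- simulatePangenome(cfg)
  ev <- simulateEvidence(sim$genomes, sim$truth, cfg)
  hits <- filterTrusted(do.call(rbind, unname(ev$hits)))
  g <- sim$genomes[[1L]]
  ann <- annotateGenome(g, hits[hits$gene_id %in% g$gene_id, ],
                        ev$dictionary)
  expect_equal(nrow(ann), nrow(g))
  truth <- sim$truth@functions
  truth <- truth[match(ann$gene_id, truth$gene_id), ]
  ok <- tierRank(ann$tier) >= tierRank("MODERATE")
  expect_true(all(ok))                                   # recall 1 at zero noise
  expect_equal(ann$function_id, truth$function_id)       # precision 1

  # permuting the input hit order changes nothing
  h <- hits[hits$gene_id %in% g$gene_id, ]
  set.seed(3)
  ann2 <- annotateGenome(g, h[sample.int(nrow(h)), ], ev$dictionary)
  expect_identical(ann2, ann)

  # no evidence at all -> every gene NONE
  ann0 <- annotateGenome(g, h[0, ], ev$dictionary)
  expect_true(all(ann0$tier == "NONE"))
})

test_that("FAMILY-only calls become MODERATE inside their pathway operon", {
  dict <- tinyDictionary()
  genome <- data.frame(
    gene_id = c("g1", "g2"), genome_id = "gm", contig_id = "c1",
    position_index = 0:1, strand = "+",
    protein_seq = "M", stringsAsFactors = FALSE)
  hits <- rbind(hitRow("g1", "EQUIVALOG_HMM", "TIGR00001", 150, 100),
                hitRow("g2", "FAMILY", "FIG000002"))
  ann <- annotateGenome(genome, hits, dict)
  expect_equal(ann$tier, c("HIGH", "MODERATE"))
  expect_true(ann$context_supported[2L])
  # same FAMILY-only call in isolation stays LOW
  annIso <- annotateGenome(genome[2, ], hits[2, ], dict)
  expect_equal(annIso$tier, "LOW")
})
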