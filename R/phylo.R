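#' The default single-copy marker panel
#'
#' Eighteen ribosomal/translation-associated TIGRFAM equivalog models
#' (RpoB, InfC, NusA, RplA/B/D/M/N/P/S/T, RpsB/C/E/J/S, SmpB, Tsf)
#' used for concatenated phylogenomics.  Shipped as a config table at
#' \code{system.file("extdata/markers/tigrfam_markers.tsv",
#' package = "corepan")}.
#'
#' @return named character vector, accession -> gene symbol, in panel
#'   order.
#' @export
markerAccessions <- function() {
  path <- system.file("extdata", "markers", "tigrfam_markers.tsv",
                      package = "corepan")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(tab$symbol, tab$accession)
}

#' Extract the single-copy marker incidence matrix
#'
#' Fills a (marker x genome) matrix with the gene hitting each marker,
#' keeping only cells backed by \emph{exactly one} above-cutoff hit.
#' A marker with a zero-hit or multi-hit genome is handled per
#' \code{policy}: \code{drop_marker} removes it genus-wide (recorded in
#' the \code{dropped} slot and messaged), \code{fail} raises an error
#' naming marker and genome.
#'
#' @param hits data.frame of trusted-cutoff-filtered equivalog hits
#'   with columns \code{genome_id}, \code{accession}, \code{gene_id}.
#' @param markerIds ordered marker accessions (default the 18-marker
#'   panel).
#' @param genomeIds ordered genomes (default those seen in
#'   \code{hits}).
#' @param policy \code{"drop_marker"} or \code{"fail"}.
#' @return a \code{\link{MarkerMatrix}}.
#' @export
extractSingleCopy <- function(hits, markerIds = names(markerAccessions()),
                              genomeIds = NULL,
                              policy = c("drop_marker", "fail")) {
  policy <- match.arg(policy)
  if (!length(markerIds)) stop("marker list must be non-empty")
  if (is.null(genomeIds)) genomeIds <- sort(unique(hits$genome_id))
  geneMap <- matrix(NA_character_, length(markerIds), length(genomeIds),
                    dimnames = list(markerIds, genomeIds))
  dropped <- character()
  for (m in markerIds) {
    bad <- NULL
    for (g in genomeIds) {
      hh <- hits[hits$accession == m & hits$genome_id == g, , drop = FALSE]
      if (nrow(hh) == 1L) geneMap[m, g] <- hh$gene_id
      else if (is.null(bad)) bad <- c(genome = g, n = nrow(hh))
    }
    if (!is.null(bad)) {
      if (policy == "fail")
        stop(sprintf("marker %s has %s above-cutoff hit(s) in genome %s",
                     m, bad["n"], bad["genome"]))
      dropped <- c(dropped, stats::setNames(m, bad["genome"]))
      message(sprintf("dropping marker %s: %s hit(s) in genome %s",
                      m, bad["n"], bad["genome"]))
    }
  }
  keep <- setdiff(markerIds, dropped)
  if (!length(keep)) stop("all markers dropped; no single-copy panel left")
  new("MarkerMatrix", geneMap = geneMap[keep, , drop = FALSE],
      dropped = dropped)
}

#' Concatenate per-marker alignments
#'
#' @param alignments named list of equal-taxa \code{XStringSet}s (one
#'   per marker, rows named by genome).
#' @param markerOrder order of concatenation (default list order).
#' @return a \code{\link{ConcatenatedAlignment}} with a partition map
#'   recording each marker's column range.
#' @export
concatenateAlignments <- function(alignments, markerOrder = names(alignments)) {
  if (!length(alignments)) stop("no alignments to concatenate")
  taxa <- sort(names(alignments[[1L]]))
  for (m in markerOrder) {
    if (!m %in% names(alignments)) stop("missing alignment for marker ", m)
    if (!setequal(names(alignments[[m]]), taxa))
      stop("taxon missing from marker alignment ", m, ": ",
           paste(setdiff(taxa, names(alignments[[m]])), collapse = ", "))
  }
  chunks <- lapply(markerOrder, function(m)
    as.character(alignments[[m]])[taxa])
  widths <- vapply(chunks, function(ch) nchar(ch[[1L]]), 0L)
  seqs <- do.call(paste0, chunks)
  cls <- class(alignments[[1L]])
  xs <- if (inherits(alignments[[1L]], "DNAStringSet"))
    Biostrings::DNAStringSet(stats::setNames(seqs, taxa))
  else Biostrings::AAStringSet(stats::setNames(seqs, taxa))
  part <- data.frame(marker_id = markerOrder,
                     start = cumsum(c(1L, widths[-length(widths)])),
                     end = cumsum(widths), stringsAsFactors = FALSE)
  new("ConcatenatedAlignment", seqs = xs, partition = part)
}

.alignmentMatrix <- function(aln) {
  if (is(aln, "ConcatenatedAlignment")) aln <- aln@seqs
  if (is(aln, "XStringSet")) {
    ch <- as.character(aln)
    nm <- names(aln)
  } else if (is.matrix(aln)) return(aln)
  else stop("unsupported alignment representation")
  if (length(unique(nchar(ch))) != 1L) stop("alignment rows differ in length")
  m <- do.call(rbind, strsplit(ch, ""))
  rownames(m) <- nm
  m
}

.pairDist <- function(aln, fun) {
  m <- .alignmentMatrix(aln)
  taxa <- rownames(m)
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(taxa, taxa))
  sat <- matrix(FALSE, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    r <- fun(m[i, ], m[j, ], taxa[i], taxa[j])
    D[i, j] <- D[j, i] <- r$d
    sat[i, j] <- sat[j, i] <- r$saturated
  }
  attr(D, "saturated") <- sat
  D
}

#' Poisson-corrected amino-acid distance
#'
#' For each pair, gaps and ambiguities (anything outside the 20
#' canonical residues) are removed pairwise; with observed mismatch
#' fraction p over the compared sites, d = -ln(1 - p).  Pairs with
#' p >= 1 are flagged saturated (NA); a pair with zero comparable sites
#' is an error.
#'
#' @param aln amino-acid alignment (\code{AAStringSet},
#'   \code{\link{ConcatenatedAlignment}}, or character matrix).
#' @return symmetric numeric matrix with zero diagonal and a logical
#'   \code{"saturated"} attribute.
#' @export
poissonDistance <- function(aln) {
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  .pairDist(aln, function(x, y, nx, ny) {
    ok <- x %in% aa20 & y %in% aa20
    if (!any(ok))
      stop(sprintf("zero comparable sites for pair %s / %s", nx, ny))
    p <- mean(x[ok] != y[ok])
    if (p >= 1) list(d = NA_real_, saturated = TRUE)
    else list(d = -log(1 - p), saturated = FALSE)
  })
}

#' Tamura-Nei (1993) nucleotide distance
#'
#' Pairwise-deletion TN93 distance from the purine-transition
#' proportion P1 (A<->G), pyrimidine-transition proportion P2 (C<->T),
#' transversion proportion Q, and the empirical base frequencies of the
#' sequence pair:
#' \deqn{d = -k1 ln(1 - P1/k1 - Q/(2 gR)) - k2 ln(1 - P2/k2 - Q/(2 gY))
#'       - k3 ln(1 - Q/(2 gR gY))}
#' with \eqn{k1 = 2 gA gG / gR}, \eqn{k2 = 2 gC gT / gY},
#' \eqn{k3 = 2 (gR gY - gA gG gY/gR - gC gT gR/gY)}.  Non-positive log
#' arguments flag the pair saturated (NA).
#'
#' @param aln nucleotide alignment (\code{DNAStringSet},
#'   \code{\link{ConcatenatedAlignment}}, or character matrix).
#' @return symmetric numeric matrix with a \code{"saturated"}
#'   attribute.
#' @export
tamuraNeiDistance <- function(aln) {
  .pairDist(aln, function(x, y, nx, ny) {
    ok <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
    n <- sum(ok)
    if (!n) stop(sprintf("zero comparable sites for pair %s / %s", nx, ny))
    x <- x[ok]; y <- y[ok]
    fr <- (base::table(factor(x, c("A", "C", "G", "T"))) +
           base::table(factor(y, c("A", "C", "G", "T")))) / (2 * n)
    gA <- fr[["A"]]; gC <- fr[["C"]]; gG <- fr[["G"]]; gT <- fr[["T"]]
    gR <- gA + gG; gY <- gC + gT
    diffs <- x != y
    isPur <- function(b) b %in% c("A", "G")
    P1 <- mean(diffs & isPur(x) & isPur(y))
    P2 <- mean(diffs & !isPur(x) & !isPur(y))
    Q <- mean(diffs & (isPur(x) != isPur(y)))
    k1 <- 2 * gA * gG / gR
    k2 <- 2 * gC * gT / gY
    k3 <- 2 * (gR * gY - gA * gG * gY / gR - gC * gT * gR / gY)
    w1 <- 1 - P1 / k1 - Q / (2 * gR)
    w2 <- 1 - P2 / k2 - Q / (2 * gY)
    w3 <- 1 - Q / (2 * gR * gY)
    if (!is.finite(w1) || !is.finite(w2) || !is.finite(w3) ||
        w1 <= 0 || w2 <= 0 || w3 <= 0)
      return(list(d = NA_real_, saturated = TRUE))
    list(d = -k1 * log(w1) - k2 * log(w2) - k3 * log(w3), saturated = FALSE)
  })
}

#' Neighbor joining with deterministic tie-breaking
#'
#' Standard Saitou-Nei agglomeration on a finite distance matrix.
#' Among equal-minimal Q criteria the pair whose (lexicographically
#' smallest member label, then other label) sorts first is joined, so
#' the topology is independent of input order.  Negative limb lengths
#' are clamped to zero; the total clamped deficit is returned as the
#' \code{"clampedDeficit"} attribute.
#'
#' @param D symmetric distance matrix with taxon dimnames (>= 3 taxa,
#'   all finite).
#' @return an unrooted \code{ape::phylo} tree.
#' @export
neighborJoining <- function(D) {
  if (is.null(rownames(D))) stop("distance matrix needs taxon dimnames")
  n0 <- nrow(D)
  if (n0 < 3L) stop("neighbor joining needs >= 3 taxa")
  bad <- which(!is.finite(D) & row(D) < col(D), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-finite (saturated?) distances for pairs: ",
         paste(sprintf("%s/%s", rownames(D)[bad[, 1L]],
                       colnames(D)[bad[, 2L]]), collapse = ", "))
  labels <- rownames(D)          # clade labels: min leaf label per node
  nwk <- stats::setNames(labels, labels)    # newick fragment per node
  deficit <- 0
  clamp <- function(v) { deficit <<- deficit + sum(pmin(v, 0)); pmax(v, 0) }
  while (nrow(D) > 3L) {
    n <- nrow(D)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= qmin * 0 + 1e-12 * max(1, abs(qmin)),
                  arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    key1 <- pmin(labels[cand[, 1L]], labels[cand[, 2L]])
    key2 <- pmax(labels[cand[, 1L]], labels[cand[, 2L]])
    pick <- order(key1, key2)[1L]
    i <- cand[pick, 1L]; j <- cand[pick, 2L]
    li <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (n - 2))
    lj <- D[i, j] - li
    li <- clamp(li); lj <- clamp(lj)
    newFrag <- sprintf("(%s:%.10g,%s:%.10g)", nwk[i], li, nwk[j], lj)
    newLab <- min(labels[i], labels[j])
    dNew <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dNew[keep]),
                c(dNew[keep], 0))
    labels <- c(labels[keep], newLab)
    nwk <- c(nwk[keep], newFrag)
    dimnames(D2) <- list(labels, labels)
    D <- D2
  }
  lx <- clamp(0.5 * (D[1, 2] + D[1, 3] - D[2, 3]))
  ly <- clamp(0.5 * (D[1, 2] + D[2, 3] - D[1, 3]))
  lz <- clamp(0.5 * (D[1, 3] + D[2, 3] - D[1, 2]))
  txt <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 nwk[1L], lx, nwk[2L], ly, nwk[3L], lz)
  tree <- ape::read.tree(text = txt)
  attr(tree, "clampedDeficit") <- -deficit
  tree
}

#' Canonical internal-bipartition keys of an unrooted tree
#'
#' Each internal edge splits the taxa in two; the key is the side not
#' containing the alphabetically first taxon, sorted and joined with
#' \code{"|"}.  Trivial (single-leaf) splits are excluded.
#'
#' @param tree an \code{ape::phylo}.
#' @return character vector of keys.
#' @export
bipartitionKeys <- function(tree) {
  tips <- sort(tree$tip.label)
  first <- tips[1L]
  pp <- ape::prop.part(tree)
  keys <- vapply(pp, function(idx) {
    side <- sort(tree$tip.label[idx])
    if (first %in% side) side <- setdiff(tips, side)
    paste(side, collapse = "|")
  }, "")
  sizes <- vapply(strsplit(keys, "|", fixed = TRUE), length, 0L)
  unique(keys[sizes >= 2L & sizes <= length(tips) - 2L])
}

#' Bootstrap supports for a distance tree
#'
#' Resamples alignment columns with replacement \code{nReps} times,
#' rebuilds the NJ tree per replicate, and reports for every internal
#' edge of the point-estimate tree the percentage of replicates whose
#' tree contains the same bipartition.  All randomness flows from
#' \code{seed}.
#'
#' @param aln alignment (\code{XStringSet},
#'   \code{\link{ConcatenatedAlignment}} or character matrix).
#' @param distanceFun distance function, e.g.
#'   \code{\link{poissonDistance}}.
#' @param nReps number of bootstrap replicates (>= 1; 100 for protein
#'   concatenations, 1000 for 16S-style single genes are the
#'   conventional choices).
#' @param seed integer RNG seed.
#' @return the point-estimate \code{phylo} with supports (0-100) as
#'   internal node labels (root label empty) and a
#'   \code{"supports"} attribute keyed by bipartition.
#' @export
bootstrapSupports <- function(aln, distanceFun = poissonDistance,
                              nReps = 100L, seed = 1L) {
  if (nReps < 1L) stop("nReps must be >= 1")
  m <- .alignmentMatrix(aln)
  point <- neighborJoining(distanceFun(m))
  keys <- bipartitionKeys(point)
  hitCount <- stats::setNames(numeric(length(keys)), keys)
  rng <- .seededRNG(seed)
  for (b in seq_len(nReps)) {
    cols <- .rngSampleInt(rng, ncol(m), ncol(m), replace = TRUE)
    rep <- try(neighborJoining(distanceFun(m[, cols, drop = FALSE])),
               silent = TRUE)
    if (inherits(rep, "try-error")) next
    rk <- bipartitionKeys(rep)
    hitCount[keys %in% rk] <- hitCount[keys %in% rk] + 1
  }
  supports <- 100 * hitCount / nReps
  # attach as node labels
  tips <- sort(point$tip.label)
  pp <- ape::prop.part(point)
  lab <- vapply(seq_along(pp), function(k) {
    side <- sort(point$tip.label[pp[[k]]])
    if (tips[1L] %in% side) side <- setdiff(tips, side)
    key <- paste(side, collapse = "|")
    if (key %in% names(supports)) sprintf("%g", supports[[key]]) else ""
  }, "")
  point$node.label <- lab
  attr(point, "supports") <- supports
  point
}

#' Write / read newick trees
#'
#' Thin wrappers over \code{ape::write.tree} / \code{ape::read.tree};
#' bootstrap supports travel as internal node labels.  Round-trips
#' preserve topology, branch lengths (to printed precision) and
#' supports.
#'
#' @param tree an \code{ape::phylo}.
#' @param path file path.
#' @return \code{writeNewickTree}: invisibly, \code{path};
#'   \code{readNewickTree}: a \code{phylo}.
#' @export
writeNewickTree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname writeNewickTree
#' @export
readNewickTree <- function(path) {
  txt <- paste(readLines(path), collapse = "")
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) NULL,
                   warning = function(w) NULL)
  if (is.null(tree) || !inherits(tree, "phylo")) {
    open <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
    close <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
    stop(sprintf("malformed newick in %s (near character %d: %d '(' vs %d ')')",
                 path, nchar(txt), open, close))
  }
  tree
}

#' Read/write an aligned FASTA as an XStringSet
#'
#' @param path FASTA file.
#' @param type "AA" or "DNA".
#' @return an \code{AAStringSet} or \code{DNAStringSet}.
#' @export
readAlignedFasta <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  if (type == "AA") Biostrings::readAAStringSet(path)
  else Biostrings::readDNAStringSet(path)
}

#' @rdname readAlignedFasta
#' @param seqs an XStringSet to write.
#' @export
writeAlignedFasta <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}
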