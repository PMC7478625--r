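#' Cluster proteins across genomes into orthologue groups
#'
#' A reciprocal-best-hit (RBH) stand-in for MCL-based orthologue
#' predictors so the pipeline runs end-to-end without external tools;
#' precomputed PorthoMCL-style tables (\code{\link{readOrthologueTable}})
#' remain the first-class input path.  For each genome pair, every
#' cross-genome protein pair sharing at least one exact k-mer is
#' globally aligned; a pair is an RBH edge when each member is the
#' other's best match and the normalised identity (matches / longer
#' sequence length) reaches \code{identityThreshold}.  Groups are the
#' single-linkage components of the RBH graph; singletons become their
#' own group.  All ties break lexicographically by gene id, so output
#' is deterministic.
#'
#' @param genomes named list of gene-record data.frames (>= 2 genomes);
#'   names are genome ids.
#' @param identityThreshold fraction in (0, 1]; default 0.7.
#' @param speciesMap optional genome -> species named vector.
#' @param k k-mer width of the candidate prescreen (exact shared
#'   substring; default 8).
#' @return an \code{\link{OrthologueTable}} with groups named
#'   \code{OG000001, ...} in order of their lexicographically smallest
#'   member gene.
#' @export
clusterOrthologues <- function(genomes, identityThreshold = 0.7,
                               speciesMap = NULL, k = 8L) {
  if (length(genomes) < 2L) stop("need >= 2 genomes to cluster")
  if (identityThreshold <= 0 || identityThreshold > 1)
    stop("identityThreshold must be in (0, 1]")
  if (is.null(names(genomes)))
    names(genomes) <- vapply(genomes, function(g) g$genome_id[1L], "")
  allGenes <- do.call(rbind, lapply(names(genomes), function(gm) {
    data.frame(gene_id = genomes[[gm]]$gene_id, genome_id = gm,
               seq = genomes[[gm]]$protein_seq, stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(allGenes$gene_id))
    stop("gene ids must be unique across genomes")
  n <- nrow(allGenes)
  seqs <- Biostrings::AAStringSet(stats::setNames(allGenes$seq,
                                                  allGenes$gene_id))
  # k-mer -> gene index prescreen
  kmerIdx <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(n)) {
    s <- allGenes$seq[i]
    L <- nchar(s)
    if (L < k) km <- s
    else km <- unique(substring(s, 1:(L - k + 1L), k:L))
    for (m in km) assign(m, c(get0(m, envir = kmerIdx), i), envir = kmerIdx)
  }
  candidates <- new.env(hash = TRUE, parent = emptyenv())
  for (m in ls(kmerIdx)) {
    idx <- get(m, envir = kmerIdx)
    if (length(idx) < 2L) next
    for (a in idx) for (b in idx) {
      if (a < b && allGenes$genome_id[a] != allGenes$genome_id[b])
        assign(paste0(a, "_", b), TRUE, envir = candidates)
    }
  }
  pairKeys <- ls(candidates)
  if (length(pairKeys)) {
    ab <- do.call(rbind, strsplit(pairKeys, "_", fixed = TRUE))
    ai <- as.integer(ab[, 1L]); bi <- as.integer(ab[, 2L])
    pa <- Biostrings::pairwiseAlignment(seqs[ai], seqs[bi],
            substitutionMatrix = "BLOSUM62", gapOpening = 10,
            gapExtension = 0.5, type = "global", scoreOnly = FALSE)
    ident <- Biostrings::nmatch(pa) /
      pmax(Biostrings::width(seqs)[ai], Biostrings::width(seqs)[bi])
  } else {
    ai <- bi <- integer(); ident <- numeric()
  }
  keep <- ident >= identityThreshold
  ai <- ai[keep]; bi <- bi[keep]; ident <- ident[keep]
  # best match per gene per genome pair, lexicographic gene-id tie-break
  edges <- data.frame(a = c(ai, bi), b = c(bi, ai), ident = c(ident, ident))
  rbh <- matrix(integer(), 0L, 2L)
  if (nrow(edges)) {
    edges$pairGm <- allGenes$genome_id[edges$b]
    edges <- edges[order(edges$a, edges$pairGm, -edges$ident,
                         allGenes$gene_id[edges$b]), , drop = FALSE]
    best <- edges[!duplicated(paste(edges$a, edges$pairGm)), , drop = FALSE]
    bestKey <- paste(best$a, best$b)
    recKey <- paste(best$b, best$a)
    mutual <- best[bestKey %in% recKey, , drop = FALSE]
    mutual <- mutual[mutual$a < mutual$b, , drop = FALSE]
    rbh <- cbind(mutual$a, mutual$b)
  }
  # union-find single linkage
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  if (nrow(rbh)) for (e in seq_len(nrow(rbh))) {
    ra <- find(rbh[e, 1L]); rb <- find(rbh[e, 2L])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  comp <- vapply(seq_len(n), find, 0L)
  # name components by lexicographically smallest member gene
  minGene <- tapply(allGenes$gene_id, comp, min)
  ord <- order(minGene)
  groupName <- stats::setNames(sprintf("OG%06d", seq_along(ord)),
                               names(minGene)[ord])
  membership <- data.frame(group_id = unname(groupName[as.character(comp)]),
                           genome_id = allGenes$genome_id,
                           gene_id = allGenes$gene_id,
                           stringsAsFactors = FALSE)
  membership <- membership[order(membership$group_id, membership$genome_id,
                                 membership$gene_id), , drop = FALSE]
  rownames(membership) <- NULL
  OrthologueTable(membership, roster = names(genomes),
                  speciesMap = speciesMap)
}

#' Core genome of a genome set
#'
#' Groups with at least one member gene in \emph{every} listed genome.
#'
#' @param table an \code{\link{OrthologueTable}}.
#' @param genomeIds non-empty subset of the roster.
#' @return sorted character vector of group ids.
#' @export
coreGenome <- function(table, genomeIds) {
  if (!length(genomeIds)) stop("genomeIds must be non-empty")
  unknown <- setdiff(genomeIds, table@roster)
  if (length(unknown))
    stop("unknown genome_id: ", paste(unknown, collapse = ", "))
  pres <- presenceMatrix(table)
  rownames(pres)[rowSums(pres[, genomeIds, drop = FALSE]) == length(genomeIds)]
}

.taxaPartition <- function(table, taxa) {
  if (is.null(taxa)) {
    sm <- speciesMap(table)
    taxa <- split(names(sm), sm)
  }
  flat <- unlist(taxa, use.names = FALSE)
  if (anyDuplicated(flat)) stop("taxa overlap: a genome appears in two taxa")
  if (!setequal(flat, table@roster))
    stop("taxa must partition the genome roster")
  taxa[order(names(taxa))]
}

.taxonPresence <- function(pres, taxa, presenceRule) {
  sapply(taxa, function(gms) {
    sub <- pres[, gms, drop = FALSE]
    if (presenceRule == "all_strains") rowSums(sub) == length(gms)
    else rowSums(sub) > 0L
  })
}

#' Pairwise shared-orthologue matrix across taxa
#'
#' Entry (A, B) counts groups present in taxon A and taxon B under
#' \code{presenceRule}; a taxon "contains" a group either when all its
#' strains do (\code{all_strains}, the default and the convention for
#' species-level comparisons) or when any strain does
#' (\code{any_strain}).  The diagonal is always the taxon's core size
#' under \code{all_strains}.
#'
#' @param table an \code{\link{OrthologueTable}}.
#' @param taxa named list of genome-id vectors partitioning the roster;
#'   defaults to the species map.
#' @param presenceRule \code{"all_strains"} or \code{"any_strain"}.
#' @return symmetric integer matrix over taxa (sorted by name).
#' @export
pairwiseSharedMatrix <- function(table, taxa = NULL,
                                 presenceRule = c("all_strains", "any_strain")) {
  presenceRule <- match.arg(presenceRule)
  taxa <- .taxaPartition(table, taxa)
  pres <- presenceMatrix(table)
  tp <- .taxonPresence(pres, taxa, presenceRule)
  m <- t(tp) %*% tp
  storage.mode(m) <- "integer"
  coreP <- .taxonPresence(pres, taxa, "all_strains")
  diag(m) <- as.integer(colSums(coreP))
  m
}

#' Venn-exclusive orthologue counts across taxa
#'
#' For every non-empty subset S of taxa, counts the groups present in
#' exactly the taxa of S (Venn regions).  The counts over all subsets
#' sum to the number of groups present in at least one taxon.
#'
#' @inheritParams pairwiseSharedMatrix
#' @return named integer vector; subset names are taxon names joined
#'   with \code{"&"} in sorted taxon order.
#' @export
intersectionCounts <- function(table, taxa = NULL,
                               presenceRule = c("all_strains", "any_strain")) {
  presenceRule <- match.arg(presenceRule)
  taxa <- .taxaPartition(table, taxa)
  if (length(taxa) > 7L)
    stop("more than 7 taxa: aggregate taxa before requesting Venn regions")
  pres <- presenceMatrix(table)
  tp <- .taxonPresence(pres, taxa, presenceRule)
  if (!is.matrix(tp)) tp <- matrix(tp, nrow = nrow(pres),
                                   dimnames = list(rownames(pres), names(taxa)))
  nm <- names(taxa)
  subsets <- unlist(lapply(seq_along(nm), function(sz)
    utils::combn(nm, sz, paste, collapse = "&", simplify = FALSE)))
  counts <- stats::setNames(integer(length(subsets)), subsets)
  inAny <- rowSums(tp) > 0L
  key <- apply(tp, 1L, function(r) paste(nm[r], collapse = "&"))
  obs <- base::table(key[inAny])
  counts[names(obs)] <- as.integer(obs)
  counts
}
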