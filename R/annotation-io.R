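#' Read a genome: protein FASTA plus gene feature table
#'
#' The feature table is a TSV with columns \code{gene_id},
#' \code{contig_id}, \code{position_index} (0-based rank of the gene
#' along its contig — the package reasons about gene neighbourhoods, not
#' nucleotide coordinates) and \code{strand} (+/-).  Every FASTA entry
#' must appear in the table; records are returned sorted by
#' (contig_id, position_index).
#'
#' @param fastaPath protein FASTA file; headers are gene ids (first
#'   whitespace-delimited token).
#' @param featurePath feature table TSV.
#' @param genomeId genome identifier stored on every record; defaults to
#'   the FASTA file name without extension.
#' @return data.frame of gene records: gene_id, genome_id, contig_id,
#'   position_index, strand, protein_seq.
#' @export
readGenome <- function(fastaPath, featurePath, genomeId = NULL) {
  if (is.null(genomeId))
    genomeId <- sub("\\.[^.]*$", "", basename(fastaPath))
  aa <- Biostrings::readAAStringSet(fastaPath)
  ids <- sub("\\s.*$", "", names(aa))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate gene_id in FASTA: ", paste(unique(dup), collapse = ", "))
  feat <- utils::read.delim(featurePath, stringsAsFactors = FALSE,
                            colClasses = "character")
  need <- c("gene_id", "contig_id", "position_index", "strand")
  if (!all(need %in% names(feat)))
    stop("feature table must have columns ", paste(need, collapse = ", "))
  feat$position_index <- as.integer(feat$position_index)
  missing <- setdiff(ids, feat$gene_id)
  if (length(missing))
    stop("gene in FASTA absent from feature table: ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(feat$gene_id))
    stop("duplicate gene_id in feature table: ",
         feat$gene_id[duplicated(feat$gene_id)][1L])
  key <- paste(feat$contig_id, feat$position_index)
  if (anyDuplicated(key))
    stop("position_index not unique within contig: ", key[duplicated(key)][1L])
  feat <- feat[feat$gene_id %in% ids, , drop = FALSE]
  seqs <- as.character(aa)
  names(seqs) <- ids
  if (any(!nzchar(seqs))) stop("empty protein sequence in FASTA")
  out <- data.frame(gene_id = feat$gene_id, genome_id = genomeId,
                    contig_id = feat$contig_id,
                    position_index = feat$position_index,
                    strand = feat$strand,
                    protein_seq = unname(seqs[feat$gene_id]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$contig_id, out$position_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a genome back to protein FASTA + feature table
#'
#' Inverse of \code{\link{readGenome}}; records are written in
#' (contig_id, position_index) order so a write/read cycle is the
#' identity.
#'
#' @param genes gene-record data.frame as returned by
#'   \code{\link{readGenome}}.
#' @param fastaPath,featurePath output paths.
#' @return invisibly, the two paths.
#' @export
writeGenome <- function(genes, fastaPath, featurePath) {
  genes <- genes[order(genes$contig_id, genes$position_index), , drop = FALSE]
  aa <- Biostrings::AAStringSet(stats::setNames(genes$protein_seq, genes$gene_id))
  Biostrings::writeXStringSet(aa, fastaPath, width = 70L)
  utils::write.table(
    genes[, c("gene_id", "contig_id", "position_index", "strand")],
    featurePath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fastaPath, featurePath))
}

.emptyHits <- function() {
  data.frame(gene_id = character(), source = character(),
             accession = character(), bit_score = numeric(),
             trusted_cutoff = numeric(), stringsAsFactors = FALSE)
}

#' Read an evidence hit table
#'
#' Two dialects are understood.  For the HMM tiers
#' (\code{EQUIVALOG_HMM}, \code{DOMAIN_HMM}) the file is hmmsearch
#' per-target tabular output ("tblout": whitespace-separated, \code{#}
#' comment lines; target name in column 1, query accession in column 4
#' falling back to the query name, full-sequence bit score in column 6,
#' best-domain score in column 9).  Because tblout does not carry the
#' model's trusted cutoff, HMM tiers require a named \code{cutoffs}
#' vector (accession -> trusted cutoff, bits).  For \code{KO} and
#' \code{FAMILY} the file is a TSV with columns \code{gene_id},
#' \code{accession} (scores absent).
#'
#' @param path hit-table file.
#' @param source one of \code{\link{evidenceSources}}.
#' @param cutoffs named numeric vector of trusted cutoffs; required for
#'   HMM tiers and ignored otherwise.
#' @param score which tblout bit score to use: full-sequence
#'   (\code{"full"}, default) or best single domain (\code{"domain"}).
#' @return data.frame of evidence hits: gene_id, source, accession,
#'   bit_score, trusted_cutoff (NA for KO/FAMILY).
#' @export
readHitTable <- function(path, source, cutoffs = NULL,
                         score = c("full", "domain")) {
  score <- match.arg(score)
  if (!source %in% evidenceSources())
    stop("unknown source tag: ", source)
  lines <- readLines(path)
  isHMM <- source %in% c("EQUIVALOG_HMM", "DOMAIN_HMM")
  if (isHMM) {
    keep <- which(!grepl("^\\s*(#|$)", lines))
    if (!length(keep)) return(.emptyHits())
    rows <- lapply(keep, function(i) {
      f <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
      if (length(f) < 9L)
        stop(sprintf("malformed tblout row at line %d of %s", i, path))
      sc <- suppressWarnings(as.numeric(f[if (score == "full") 6L else 9L]))
      if (is.na(sc))
        stop(sprintf("malformed tblout row at line %d of %s: bad score", i, path))
      acc <- if (f[4L] != "-") f[4L] else f[3L]
      c(gene = f[1L], acc = acc, score = sc)
    })
    gene <- vapply(rows, `[[`, "", "gene")
    acc <- vapply(rows, `[[`, "", "acc")
    sc <- as.numeric(vapply(rows, `[[`, "", "score"))
    if (is.null(cutoffs))
      stop("HMM-tier hit tables require a named 'cutoffs' vector")
    tc <- unname(cutoffs[acc])
    if (anyNA(tc))
      stop("no trusted cutoff supplied for accession: ",
           paste(unique(acc[is.na(tc)]), collapse = ", "))
    data.frame(gene_id = gene, source = source, accession = acc,
               bit_score = sc, trusted_cutoff = tc, stringsAsFactors = FALSE)
  } else {
    keep <- which(!grepl("^\\s*(#|$)", lines))
    keep <- setdiff(keep, which(grepl("^gene_id\\t", lines)))
    if (!length(keep)) return(.emptyHits())
    rows <- strsplit(lines[keep], "\t", fixed = TRUE)
    bad <- which(vapply(rows, length, 0L) < 2L)
    if (length(bad))
      stop(sprintf("malformed row at line %d of %s (need gene_id<TAB>accession)",
                   keep[bad[1L]], path))
    data.frame(gene_id = vapply(rows, `[[`, "", 1L), source = source,
               accession = vapply(rows, `[[`, "", 2L),
               bit_score = NA_real_, trusted_cutoff = NA_real_,
               stringsAsFactors = FALSE)
  }
}

#' Write an evidence hit table in the dialect `readHitTable` consumes
#'
#' @param hits evidence-hit data.frame (single source).
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeHitTable <- function(hits, path) {
  src <- unique(hits$source)
  if (length(src) > 1L) stop("write one source per file")
  if (length(src) && src %in% c("EQUIVALOG_HMM", "DOMAIN_HMM")) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("# target_name taccn query_name query_accn evalue full_score full_bias dom_evalue dom_score", con)
    if (nrow(hits))
      writeLines(sprintf("%s - %s %s 1e-10 %.2f 0.0 1e-10 %.2f",
                         hits$gene_id, hits$accession, hits$accession,
                         hits$bit_score, hits$bit_score), con)
  } else {
    utils::write.table(hits[, c("gene_id", "accession")], path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Trusted-cutoff filtering of evidence hits
#'
#' HMM-tier hits are retained iff their bit score is at least the
#' model's trusted cutoff (inclusive, matching hmmsearch's
#' \code{--cut_tc} convention); KO/FAMILY hits pass through unchanged.
#' Surviving hits keep their input order, so the operation is
#' idempotent and never reorders.
#'
#' @param hits evidence-hit data.frame.
#' @return the filtered data.frame.
#' @export
filterTrusted <- function(hits) {
  if (!nrow(hits)) return(hits)
  isHMM <- hits$source %in% c("EQUIVALOG_HMM", "DOMAIN_HMM")
  if (any(isHMM & (is.na(hits$trusted_cutoff) | is.na(hits$bit_score))))
    stop("HMM-tier hit missing bit score or trusted cutoff")
  keep <- !isHMM | (hits$bit_score >= hits$trusted_cutoff)
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read an orthologue-group membership table
#'
#' TSV with columns \code{group_id}, \code{genome_id}, \code{gene_id}
#' (one row per member gene), as produced by PorthoMCL-style tools.
#'
#' @param path TSV file.
#' @param roster optional ordered genome roster (defaults to genomes seen).
#' @param speciesMap optional named genome -> species vector.
#' @return an \code{\link{OrthologueTable}}.
#' @export
readOrthologueTable <- function(path, roster = NULL, speciesMap = NULL) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  OrthologueTable(m, roster = roster, speciesMap = speciesMap)
}

#' Write an orthologue-group membership table
#'
#' @param table an OrthologueTable.
#' @param path output TSV.
#' @return invisibly, \code{path}.
#' @export
writeOrthologueTable <- function(table, path) {
  m <- table@membership[order(table@membership$group_id,
                              table@membership$genome_id,
                              table@membership$gene_id), , drop = FALSE]
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a function dictionary from TSVs
#'
#' @param accessionPath TSV with columns accession, source, function_id.
#' @param pathwayPath optional TSV with columns function_id, pathway_id.
#' @return a \code{\link{FunctionDictionary}}.
#' @export
readFunctionDictionary <- function(accessionPath, pathwayPath = NULL) {
  acc <- utils::read.delim(accessionPath, stringsAsFactors = FALSE)
  pw <- if (is.null(pathwayPath))
    data.frame(function_id = character(), pathway_id = character())
  else utils::read.delim(pathwayPath, stringsAsFactors = FALSE)
  FunctionDictionary(acc, pw)
}
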