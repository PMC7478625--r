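#' Genome-context support for a candidate function call
#'
#' A gene draws context support when at least one other gene within
#' \code{window} rank positions on the same contig is already assigned
#' (at any tier above NONE) to a function belonging to the same pathway
#' — i.e. the candidate call sits in an operon-like neighbourhood of its
#' own pathway.
#'
#' @param gene a single gene record (one row of a gene-record
#'   data.frame).
#' @param neighbors data.frame of gene records for the same genome with
#'   columns \code{gene_id}, \code{contig_id}, \code{position_index},
#'   \code{function_id}, \code{tier} (a first-pass annotation joined to
#'   positions).
#' @param pathwayFunctions character set of function ids belonging to
#'   the candidate function's pathway(s).
#' @param window integer >= 1, neighbourhood half-width in gene ranks
#'   (strand-agnostic).
#' @return logical.
#' @export
genomeContextSupport <- function(gene, neighbors, pathwayFunctions, window = 5L) {
  if (window < 1L) stop("window must be >= 1")
  if (!length(pathwayFunctions)) return(FALSE)
  nb <- neighbors[neighbors$contig_id == gene$contig_id &
                  neighbors$gene_id != gene$gene_id, , drop = FALSE]
  if (!nrow(nb)) return(FALSE)
  d <- abs(nb$position_index - gene$position_index)
  nb <- nb[d >= 1L & d <= window, , drop = FALSE]
  any(tierRank(nb$tier) > 0L & !is.na(nb$function_id) &
      nb$function_id %in% pathwayFunctions)
}

#' Fuse one gene's evidence into a confidence-tiered function call
#'
#' The operational scale emphasises expert curation and genome context:
#' \itemize{
#'   \item \strong{HIGH}: an equivalog-HMM hit survives the trusted
#'     cutoff, or KO and FAMILY assignments agree on the same function.
#'   \item \strong{MODERATE}: a KO assignment alone, or a FAMILY
#'     assignment alone when the call has conserved genome context.
#'   \item \strong{LOW}: a FAMILY assignment without context, or a
#'     domain-HMM hit as the only evidence (a pathway "hole filler").
#'   \item \strong{NONE}: no surviving evidence.
#' }
#' The reported function is that of the highest-priority source
#' (\code{EQUIVALOG_HMM > KO > FAMILY > DOMAIN_HMM}); disagreeing
#' sources stay listed in \code{sources} for audit.
#'
#' @param geneId the gene.
#' @param hits evidence hits for this gene, already trusted-cutoff
#'   filtered.
#' @param dictionary a \code{\link{FunctionDictionary}}; every hit
#'   accession must resolve.
#' @param context logical: does the candidate call have genome-context
#'   support?
#' @param scaleFn optional replacement confidence scale: a
#'   \code{function(sourcesSupporting, sourcesPresent, context)}
#'   returning a tier name, where \code{sourcesSupporting} are sources
#'   agreeing with the chosen function.
#' @return one-row data.frame: gene_id, function_id (NA at tier NONE),
#'   tier, sources (comma-joined \code{source:accession}),
#'   context_supported.
#' @export
assignConfidence <- function(geneId, hits, dictionary, context = FALSE,
                             scaleFn = NULL) {
  hits <- hits[hits$gene_id == geneId, , drop = FALSE]
  if (!nrow(hits))
    return(data.frame(gene_id = geneId, function_id = NA_character_,
                      tier = "NONE", sources = "", context_supported = context,
                      stringsAsFactors = FALSE))
  fn <- functionOf(dictionary, hits$accession, hits$source)
  pri <- match(hits$source, evidenceSources())
  best <- order(pri, hits$accession)[1L]
  functionId <- fn[best]
  supporting <- sort(unique(hits$source[fn == functionId]))
  present <- sort(unique(hits$source))
  tier <- if (!is.null(scaleFn)) {
    scaleFn(supporting, present, context)
  } else .defaultScale(supporting, context)
  data.frame(gene_id = geneId, function_id = functionId, tier = tier,
             sources = paste(sprintf("%s:%s", hits$source, hits$accession),
                             collapse = ","),
             context_supported = context, stringsAsFactors = FALSE)
}

# default operational confidence scale over the sources supporting the
# chosen function
.defaultScale <- function(supporting, context) {
  if ("EQUIVALOG_HMM" %in% supporting) return("HIGH")
  koFam <- intersect(c("KO", "FAMILY"), supporting)
  if (length(koFam) == 2L) return("HIGH")
  if (identical(koFam, "KO")) return("MODERATE")
  if (identical(koFam, "FAMILY")) return(if (context) "MODERATE" else "LOW")
  if ("DOMAIN_HMM" %in% supporting) return("LOW")
  "NONE"
}

#' Annotate a whole genome (two-pass, context-aware)
#'
#' Pass 1 assigns a tier to every gene without context.  Pass 2
#' recomputes the context-dependent calls (FAMILY-only evidence) using
#' only the pass-1 tiers of the neighbours, so context support can never
#' be circular and a second application is a fixed point.
#'
#' @param genome gene-record data.frame (one genome).
#' @param hits evidence hits for this genome's genes (post
#'   \code{\link{filterTrusted}}).
#' @param dictionary a \code{\link{FunctionDictionary}}.
#' @param window context window in gene ranks (default 5, the span of a
#'   typical operon).
#' @param scaleFn optional custom confidence scale, see
#'   \code{\link{assignConfidence}}.
#' @return data.frame with one row per gene, in genome order: gene_id,
#'   function_id, tier, sources, context_supported.
#' @export
annotateGenome <- function(genome, hits, dictionary, window = 5L,
                           scaleFn = NULL) {
  hits <- hits[order(hits$gene_id, match(hits$source, evidenceSources()),
                     hits$accession), , drop = FALSE]
  pass1 <- do.call(rbind, lapply(genome$gene_id, function(g)
    assignConfidence(g, hits, dictionary, context = FALSE, scaleFn = scaleFn)))
  nbrs <- cbind(genome[, c("gene_id", "contig_id", "position_index")],
                pass1[match(genome$gene_id, pass1$gene_id),
                      c("function_id", "tier")])
  out <- pass1
  for (i in seq_len(nrow(genome))) {
    fid <- pass1$function_id[i]
    if (is.na(fid)) next
    mates <- pathwayMates(dictionary, fid)
    ctx <- genomeContextSupport(genome[i, , drop = FALSE], nbrs, mates,
                                window = window)
    if (ctx)
      out[i, ] <- assignConfidence(genome$gene_id[i], hits, dictionary,
                                   context = TRUE, scaleFn = scaleFn)
  }
  rownames(out) <- NULL
  out
}

#' Write annotated-genome TSV
#'
#' @param assignments annotation data.frame from
#'   \code{\link{annotateGenome}}.
#' @param path output TSV.
#' @return invisibly, \code{path}.
#' @export
writeAnnotation <- function(assignments, path) {
  utils::write.table(assignments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
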