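#' @import methods
NULL

setOldClass("phylo")

#' Genome-by-orthologue-group membership table
#'
#' Holds one row per (group, genome, gene) membership triple, the ordered
#' genome roster, and a genome-to-species map.  This is the substrate for
#' all core/pan-genome co-occurrence arithmetic: a group is "present" in a
#' genome when it has at least one member gene there (paralogues count
#' once).
#'
#' @slot membership data.frame with columns \code{group_id},
#'   \code{genome_id}, \code{gene_id}; a gene belongs to at most one group.
#' @slot roster character, ordered genome identifiers.
#' @slot speciesMap named character, genome_id -> species label.
#' @export
setClass("OrthologueTable",
  representation(membership = "data.frame", roster = "character",
                 speciesMap = "character"))

setValidity("OrthologueTable", function(object) {
  m <- object@membership
  need <- c("group_id", "genome_id", "gene_id")
  if (!all(need %in% names(m)))
    return(sprintf("membership must have columns %s", paste(need, collapse = ", ")))
  if (anyDuplicated(object@roster))
    return("duplicated genome_id in roster")
  bad <- setdiff(unique(m$genome_id), object@roster)
  if (length(bad))
    return(sprintf("membership references genomes absent from roster: %s",
                   paste(bad, collapse = ", ")))
  if (length(object@speciesMap) &&
      !all(object@roster %in% names(object@speciesMap)))
    return("speciesMap must name every genome in the roster")
  dup <- m$gene_id[duplicated(paste(m$genome_id, m$gene_id))]
  if (length(dup))
    return(sprintf("gene assigned to more than one group: %s", dup[1L]))
  TRUE
})

#' Construct an OrthologueTable
#'
#' @param membership data.frame with columns group_id, genome_id, gene_id.
#' @param roster ordered character vector of genome ids; defaults to the
#'   genomes observed in \code{membership}, sorted.
#' @param speciesMap named character vector genome_id -> species; defaults
#'   to each genome being its own species.
#' @return an \code{OrthologueTable}.
#' @export
OrthologueTable <- function(membership, roster = NULL, speciesMap = NULL) {
  membership <- as.data.frame(membership, stringsAsFactors = FALSE)
  if (is.null(roster)) roster <- sort(unique(membership$genome_id))
  if (is.null(speciesMap)) speciesMap <- stats::setNames(roster, roster)
  new("OrthologueTable", membership = membership, roster = roster,
      speciesMap = speciesMap)
}

#' @describeIn OrthologueTable group identifiers, sorted.
#' @param x an OrthologueTable.
#' @export
groupIds <- function(x) sort(unique(x@membership$group_id))

#' @describeIn OrthologueTable the genome roster, in order.
#' @export
genomeIds <- function(x) x@roster

#' @describeIn OrthologueTable named species vector over the roster.
#' @export
speciesMap <- function(x) x@speciesMap[x@roster]

#' Presence (group x genome) logical matrix of an OrthologueTable
#'
#' @param x an OrthologueTable.
#' @return logical matrix, rows = sorted group ids, columns = roster.
#' @export
presenceMatrix <- function(x) {
  g <- groupIds(x)
  mat <- matrix(FALSE, length(g), length(x@roster),
                dimnames = list(g, x@roster))
  if (nrow(x@membership))
    mat[cbind(x@membership$group_id, x@membership$genome_id)] <- TRUE
  mat
}

setMethod("show", "OrthologueTable", function(object) {
  cat(sprintf("OrthologueTable: %d groups x %d genomes (%d species), %d member genes\n",
              length(groupIds(object)), length(object@roster),
              length(unique(object@speciesMap[object@roster])),
              nrow(object@membership)))
})

#' Accession-to-function crosswalk plus function-to-pathway memberships
#'
#' @slot accessions data.frame with columns \code{accession},
#'   \code{source}, \code{function_id}; each (source, accession) maps to
#'   exactly one function.
#' @slot pathways data.frame with columns \code{function_id},
#'   \code{pathway_id}.
#' @export
setClass("FunctionDictionary",
  representation(accessions = "data.frame", pathways = "data.frame"))

setValidity("FunctionDictionary", function(object) {
  a <- object@accessions
  if (!all(c("accession", "source", "function_id") %in% names(a)))
    return("accessions needs columns accession, source, function_id")
  if (anyDuplicated(paste(a$source, a$accession)))
    return("an accession maps to more than one function within a source")
  p <- object@pathways
  if (nrow(p) && !all(c("function_id", "pathway_id") %in% names(p)))
    return("pathways needs columns function_id, pathway_id")
  TRUE
})

#' Construct a FunctionDictionary
#'
#' @param accessions data.frame(accession, source, function_id).
#' @param pathways data.frame(function_id, pathway_id); may be empty.
#' @return a \code{FunctionDictionary}.
#' @export
FunctionDictionary <- function(accessions,
                               pathways = data.frame(function_id = character(),
                                                     pathway_id = character())) {
  new("FunctionDictionary",
      accessions = as.data.frame(accessions, stringsAsFactors = FALSE),
      pathways = as.data.frame(pathways, stringsAsFactors = FALSE))
}

#' Look up the function of an accession
#'
#' @param dict a FunctionDictionary.
#' @param accession accession string(s).
#' @param source matching source tag(s), recycled.
#' @return character function_id(s); error on an unknown accession.
#' @export
functionOf <- function(dict, accession, source) {
  key <- paste(source, accession)
  tab <- stats::setNames(dict@accessions$function_id,
                         paste(dict@accessions$source, dict@accessions$accession))
  out <- tab[key]
  if (anyNA(out))
    stop("accession not in function dictionary: ",
         paste(accession[is.na(out)], collapse = ", "))
  unname(out)
}

#' Pathways containing a function
#'
#' @param dict a FunctionDictionary.
#' @param functionId a function identifier.
#' @return character vector of pathway ids (possibly empty).
#' @export
pathwaysOf <- function(dict, functionId) {
  sort(unique(dict@pathways$pathway_id[dict@pathways$function_id %in% functionId]))
}

#' All functions sharing at least one pathway with \code{functionId}
#' (including itself when it belongs to a pathway).
#' @inheritParams pathwaysOf
#' @return character vector of function ids.
#' @export
pathwayMates <- function(dict, functionId) {
  pw <- pathwaysOf(dict, functionId)
  sort(unique(dict@pathways$function_id[dict@pathways$pathway_id %in% pw]))
}

setMethod("show", "FunctionDictionary", function(object) {
  cat(sprintf("FunctionDictionary: %d accessions -> %d functions; %d pathway memberships\n",
              nrow(object@accessions), length(unique(object@accessions$function_id)),
              nrow(object@pathways)))
})

#' Boolean requirement tree defining a pathway
#'
#' The requirement is a nested list: internal nodes
#' \code{list(op = "AND"|"OR", children = list(...))}, leaves
#' \code{list(op = "LEAF", fn = "<function_id>")}.  Built by
#' \code{\link{parsePathwayExpr}} from prefix notation such as
#' \code{"AND(thiC, thiD, OR(thiE, thiT))"}.
#'
#' @slot pathwayId pathway identifier.
#' @slot category one of \code{synthesis}, \code{salvage_transport}.
#' @slot expr the requirement tree.
#' @slot minTier minimum confidence tier for a leaf to count
#'   (default \code{"MODERATE"}).
#' @export
setClass("PathwayDefinition",
  representation(pathwayId = "character", category = "character",
                 expr = "list", minTier = "character"))

setValidity("PathwayDefinition", function(object) {
  if (!object@category %in% c("synthesis", "salvage_transport"))
    return("category must be 'synthesis' or 'salvage_transport'")
  if (!object@minTier %in% c("LOW", "MODERATE", "HIGH"))
    return("minTier must be LOW, MODERATE or HIGH")
  if (!length(object@expr)) return("empty requirement tree")
  TRUE
})

#' Construct a PathwayDefinition
#'
#' @param pathwayId pathway identifier.
#' @param category "synthesis" or "salvage_transport".
#' @param expr requirement tree (list) or a prefix-notation string.
#' @param minTier minimum tier for leaf satisfaction.
#' @return a \code{PathwayDefinition}.
#' @export
PathwayDefinition <- function(pathwayId, category, expr, minTier = "MODERATE") {
  if (is.character(expr)) expr <- parsePathwayExpr(expr)
  new("PathwayDefinition", pathwayId = pathwayId, category = category,
      expr = expr, minTier = minTier)
}

setMethod("show", "PathwayDefinition", function(object) {
  cat(sprintf("PathwayDefinition %s [%s, min %s]: %s\n", object@pathwayId,
              object@category, object@minTier, deparsePathwayExpr(object@expr)))
})

#' Concatenated multi-marker alignment
#'
#' @slot seqs an \code{XStringSet} (AA or DNA), one equal-width entry per
#'   taxon.
#' @slot partition data.frame(marker_id, start, end): 1-based column
#'   ranges tiling the alignment in marker order.
#' @export
setClass("ConcatenatedAlignment",
  representation(seqs = "XStringSet", partition = "data.frame"))

setValidity("ConcatenatedAlignment", function(object) {
  w <- Biostrings::width(object@seqs)
  if (length(w) && length(unique(w)) != 1L) return("rows differ in length")
  p <- object@partition
  if (nrow(p)) {
    if (p$start[1L] != 1L || any(p$start[-1L] != p$end[-nrow(p)] + 1L) ||
        p$end[nrow(p)] != w[1L])
      return("partition ranges must tile the alignment columns")
  }
  TRUE
})

setMethod("show", "ConcatenatedAlignment", function(object) {
  cat(sprintf("ConcatenatedAlignment: %d taxa x %d columns, %d partitions\n",
              length(object@seqs),
              if (length(object@seqs)) Biostrings::width(object@seqs)[1L] else 0L,
              nrow(object@partition)))
})

#' Single-copy marker incidence matrix
#'
#' @slot geneMap character matrix (marker x genome) of the unique gene id
#'   hitting each marker in each genome.
#' @slot dropped markers removed genus-wide by the \code{drop_marker}
#'   policy, with the offending genome recorded in names.
#' @export
setClass("MarkerMatrix",
  representation(geneMap = "matrix", dropped = "character"))

setMethod("show", "MarkerMatrix", function(object) {
  cat(sprintf("MarkerMatrix: %d markers x %d genomes (%d dropped)\n",
              nrow(object@geneMap), ncol(object@geneMap), length(object@dropped)))
})

#' Ground truth emitted by the synthetic-data generator
#'
#' @slot families data.frame(group_id, genome_id, gene_id): true
#'   orthologue families.
#' @slot pathwayStatus character matrix (genome x pathway) of
#'   complete/partial/absent.
#' @slot strategies data.frame(genome_id, vitamin, strategy).
#' @slot functions data.frame(gene_id, genome_id, function_id): true
#'   function of every gene.
#' @slot tree a \code{phylo} (or empty list when no tree was simulated).
#' @slot config the generating \code{SimulationConfig} list.
#' @export
setClass("SyntheticTruth",
  representation(families = "data.frame", pathwayStatus = "matrix",
                 strategies = "data.frame", functions = "data.frame",
                 tree = "ANY", config = "list"))

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf("SyntheticTruth: %d family memberships, %d genomes x %d pathways, %d gene functions\n",
              nrow(object@families), nrow(object@pathwayStatus),
              ncol(object@pathwayStatus), nrow(object@functions)))
})
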