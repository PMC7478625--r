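#' Parse a pathway requirement expression in prefix notation
#'
#' Grammar: \code{expr := AND(expr, ...) | OR(expr, ...) | function_id},
#' with function ids matching \code{[A-Za-z0-9_.:-]+}.  Whitespace is
#' ignored.
#'
#' @param text the expression string, e.g. \code{"AND(thiC, thiD,
#'   OR(thiE, thiT))"}.
#' @return a requirement tree (nested list of \code{op}/\code{children}
#'   nodes and \code{LEAF} nodes).
#' @export
parsePathwayExpr <- function(text) {
  toks <- regmatches(text, gregexpr("[A-Za-z0-9_.:-]+|[(),]", text))[[1L]]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  takeTok <- function() { t <- peek(); pos <<- pos + 1L; t }
  parseNode <- function() {
    t <- takeTok()
    if (is.na(t)) stop("unexpected end of pathway expression: ", text)
    if (t %in% c("AND", "OR") && identical(peek(), "(")) {
      takeTok()
      children <- list()
      repeat {
        children[[length(children) + 1L]] <- parseNode()
        s <- takeTok()
        if (identical(s, ")")) break
        if (!identical(s, ","))
          stop("expected ',' or ')' in pathway expression: ", text)
      }
      list(op = t, children = children)
    } else {
      if (t %in% c("(", ")", ","))
        stop("unexpected '", t, "' in pathway expression: ", text)
      list(op = "LEAF", fn = t)
    }
  }
  node <- parseNode()
  if (pos <= length(toks))
    stop("trailing tokens in pathway expression: ", text)
  node
}

#' Render a requirement tree back to text
#'
#' Leaves print as themselves, OR as \code{(a|b)}, AND as \code{(a&b)} —
#' the notation used for "missing" entries in pathway calls.
#'
#' @param expr a requirement tree.
#' @return character scalar.
#' @export
deparsePathwayExpr <- function(expr) {
  if (expr$op == "LEAF") return(expr$fn)
  sep <- if (expr$op == "OR") "|" else "&"
  paste0("(", paste(vapply(expr$children, deparsePathwayExpr, ""),
                    collapse = sep), ")")
}

.exprLeaves <- function(expr) {
  if (expr$op == "LEAF") return(expr$fn)
  unlist(lapply(expr$children, .exprLeaves))
}

.satisfied <- function(expr, present) {
  if (expr$op == "LEAF") return(expr$fn %in% present)
  sat <- vapply(expr$children, .satisfied, TRUE, present = present)
  if (expr$op == "AND") all(sat) else any(sat)
}

#' Evaluate a pathway requirement against tiered assignments
#'
#' A leaf is satisfied iff some gene carries that function at tier >=
#' \code{minTier}; OR nodes need any child, AND nodes need all.
#' Completeness is counted in "missing gene" units over the top-level
#' AND children (an OR subtree counts as a single child, satisfied or
#' not); a non-AND root is a single child.
#'
#' @param expr requirement tree (or prefix-notation string).
#' @param assignments annotation data.frame with columns
#'   \code{function_id}, \code{tier} (e.g. \code{\link{annotateGenome}}
#'   output, possibly concatenated over genes).
#' @param minTier minimum qualifying tier (default \code{"MODERATE"}).
#' @param dictionary optional \code{\link{FunctionDictionary}}; when
#'   given, every leaf must be a known function id.
#' @return list(satisfied, completeness, missing) where \code{missing}
#'   is a character vector of unsatisfied top-level children rendered
#'   with \code{\link{deparsePathwayExpr}}.
#' @export
evaluateRequirement <- function(expr, assignments, minTier = "MODERATE",
                                dictionary = NULL) {
  if (is.character(expr)) expr <- parsePathwayExpr(expr)
  if (!is.null(dictionary)) {
    known <- unique(c(dictionary@accessions$function_id,
                      dictionary@pathways$function_id))
    bad <- setdiff(.exprLeaves(expr), known)
    if (length(bad))
      stop("unknown function_id in pathway definition: ",
           paste(bad, collapse = ", "))
  }
  ok <- !is.na(assignments$function_id) &
    tierRank(assignments$tier) >= tierRank(minTier)
  present <- unique(assignments$function_id[ok])
  children <- if (expr$op == "AND") expr$children else list(expr)
  sat <- vapply(children, .satisfied, TRUE, present = present)
  missing <- vapply(children[!sat], deparsePathwayExpr, "")
  list(satisfied = all(sat), completeness = mean(sat), missing = missing)
}

#' Call one pathway in one genome
#'
#' @param genomeId the genome.
#' @param definition a \code{\link{PathwayDefinition}}.
#' @param assignments that genome's annotation data.frame.
#' @param dictionary optional dictionary for leaf validation.
#' @return one-row data.frame: genome_id, pathway_id, completeness,
#'   status (complete/partial/absent), missing (";"-joined).
#' @export
callPathway <- function(genomeId, definition, assignments, dictionary = NULL) {
  ev <- evaluateRequirement(definition@expr, assignments,
                            minTier = definition@minTier,
                            dictionary = dictionary)
  status <- if (ev$completeness == 1) "complete"
            else if (ev$completeness == 0) "absent" else "partial"
  data.frame(genome_id = genomeId, pathway_id = definition@pathwayId,
             completeness = ev$completeness, status = status,
             missing = paste(ev$missing, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Synthesis-versus-salvage strategy verdict for one vitamin
#'
#' @param genomeId the genome.
#' @param synthesisDef PathwayDefinition with category
#'   \code{"synthesis"}.
#' @param salvageDef PathwayDefinition with category
#'   \code{"salvage_transport"}.
#' @param assignments the genome's annotation data.frame.
#' @return one of \code{"synthesizer"}, \code{"salvager"},
#'   \code{"both"}, \code{"neither"}.
#' @export
classifyStrategy <- function(genomeId, synthesisDef, salvageDef, assignments) {
  if (synthesisDef@category != "synthesis" ||
      salvageDef@category != "salvage_transport")
    stop("definition categories are the wrong way round: expected ",
         "synthesis + salvage_transport")
  syn <- evaluateRequirement(synthesisDef@expr, assignments,
                             minTier = synthesisDef@minTier)$satisfied
  sal <- evaluateRequirement(salvageDef@expr, assignments,
                             minTier = salvageDef@minTier)$satisfied
  if (syn && sal) "both" else if (syn) "synthesizer"
  else if (sal) "salvager" else "neither"
}

#' Genome-by-pathway status matrix
#'
#' @param assignmentsByGenome named list (genome_id -> annotation
#'   data.frame).
#' @param definitions list of \code{\link{PathwayDefinition}}s.
#' @param dictionary optional dictionary for leaf validation.
#' @return character matrix of statuses, rows = genomes in list order,
#'   columns = pathways in definition order.
#' @export
profileMatrix <- function(assignmentsByGenome, definitions, dictionary = NULL) {
  pw <- unname(vapply(definitions, function(d) d@pathwayId, ""))
  out <- matrix(NA_character_, length(assignmentsByGenome), length(pw),
                dimnames = list(names(assignmentsByGenome), pw))
  for (g in names(assignmentsByGenome))
    for (j in seq_along(definitions))
      out[g, j] <- callPathway(g, definitions[[j]], assignmentsByGenome[[g]],
                               dictionary = dictionary)$status
  out
}

#' Read pathway definitions from a structured TSV
#'
#' Columns: \code{pathway_id}, \code{category}, \code{min_tier},
#' \code{expression} (prefix notation).  The package ships a fixture
#' encoding the Roseburia pathway logic (central carbon, butyrogenesis,
#' amino-acid and B-vitamin synthesis/salvage definitions) under
#' \code{system.file("extdata/pathways/roseburia_pathways.tsv",
#' package = "corepan")}.
#'
#' @param path TSV file.
#' @return named list of \code{\link{PathwayDefinition}}s.
#' @export
readPathwayDefinitions <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#")
  need <- c("pathway_id", "category", "min_tier", "expression")
  if (!all(need %in% names(tab)))
    stop("pathway definition file needs columns ",
         paste(need, collapse = ", "))
  defs <- lapply(seq_len(nrow(tab)), function(i)
    PathwayDefinition(tab$pathway_id[i], tab$category[i],
                      tab$expression[i], tab$min_tier[i]))
  stats::setNames(defs, tab$pathway_id)
}

#' Function-to-pathway map implied by a set of definitions
#'
#' @param definitions list of PathwayDefinitions.
#' @return data.frame(function_id, pathway_id) suitable for
#'   \code{\link{FunctionDictionary}}.
#' @export
pathwayMembershipTable <- function(definitions) {
  do.call(rbind, lapply(definitions, function(d)
    data.frame(function_id = unique(.exprLeaves(d@expr)),
               pathway_id = d@pathwayId, stringsAsFactors = FALSE)))
}
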