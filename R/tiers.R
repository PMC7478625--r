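#' Confidence tiers
#'
#' Ordered annotation-confidence levels used throughout the package:
#' \code{NONE < LOW < MODERATE < HIGH}.
#'
#' @return character vector of tier names in increasing order.
#' @export
confidenceTiers <- function() c("NONE", "LOW", "MODERATE", "HIGH")

#' Numeric rank of a tier (NONE = 0 ... HIGH = 3)
#'
#' @param tier character vector of tier names.
#' @return integer ranks.
#' @export
tierRank <- function(tier) {
  r <- match(tier, confidenceTiers()) - 1L
  if (anyNA(r)) stop("unknown tier: ", paste(tier[is.na(r)], collapse = ", "))
  r
}

#' Evidence source tags in decreasing priority order
#'
#' Equivalog HMMs (expert-curated, function-specific) outrank KEGG
#' Orthology assignments, which outrank protein-family (FIGfam-style)
#' assignments, which outrank domain-level HMM hits.
#'
#' @return character vector of source tags.
#' @export
evidenceSources <- function() c("EQUIVALOG_HMM", "KO", "FAMILY", "DOMAIN_HMM")
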