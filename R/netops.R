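#' Extract the subnetwork around a seed set
#'
#' Nodes are the seeds plus their direct neighbours (both parents and
#' children); edges are all parent-network edges with both endpoints in
#' that node set. Seeds absent from the network are dropped with a
#' warning; if none remain the subnetwork is empty.
#'
#' @param net a \linkS4class{ConsensusNetwork} (or any object with
#'   \code{nodeIds}/\code{edgeTable}).
#' @param seeds character vector of node ids.
#' @return a \linkS4class{Subnetwork}.
#' @export
extractSubnetwork <- function(net, seeds) {
  nodes <- nodeIds(net)
  ed <- edgeTable(net)
  known <- intersect(seeds, nodes)
  if (length(known) < length(seeds))
    warning(sprintf("%d unknown seed(s) dropped",
                    length(seeds) - length(known)), call. = FALSE)
  if (length(known) == 0L) {
    warning("no known seeds; empty subnetwork", call. = FALSE)
    return(new("Subnetwork", nodes = character(0), edges = ed[0, ],
               seeds = character(0)))
  }
  nb <- unique(c(ed$child[ed$parent %in% known],
                 ed$parent[ed$child %in% known]))
  sub <- sort(unique(c(known, nb)))
  keep <- ed[ed$parent %in% sub & ed$child %in% sub, , drop = FALSE]
  rownames(keep) <- NULL
  new("Subnetwork", nodes = sub, edges = keep, seeds = sort(known))
}

#' Over-representation of a category within a hit list
#'
#' One-sided Fisher exact test (hypergeometric upper tail) that the
#' category is enriched among the hits relative to the universe.
#'
#' @param hits,category character vectors, both subsets of universe.
#' @param universe character vector of all eligible genes.
#' @return list with \code{overlap}, \code{odds_ratio} (sample odds
#'   ratio of the 2x2 table) and \code{p_value}.
#' @export
enrichmentTest <- function(hits, category, universe) {
  if (length(universe) == 0L) stopf("empty universe")
  hits <- unique(intersect(hits, universe))
  category <- unique(intersect(category, universe))
  k <- length(intersect(hits, category))
  m <- length(category)
  n <- length(universe) - m
  q <- length(hits)
  p <- phyper(k - 1, m, n, q, lower.tail = FALSE)
  a <- k; b <- q - k; c <- m - k; d <- n - b
  or <- if (b == 0 || c == 0) Inf else (a * d) / (b * c)
  list(overlap = k, odds_ratio = or, p_value = p)
}

#' Significance of the overlap between two gene sets
#'
#' Hypergeometric upper-tail probability of observing at least the given
#' overlap between two sets drawn from a universe of the stated size.
#'
#' @param setA,setB character vectors.
#' @param universe_size total number of genes they are drawn from.
#' @return upper-tail p-value.
#' @export
overlapTest <- function(setA, setB, universe_size) {
  setA <- unique(setA); setB <- unique(setB)
  if (length(setA) > universe_size || length(setB) > universe_size)
    stopf("sets cannot exceed the universe")
  k <- length(intersect(setA, setB))
  phyper(k - 1, length(setA), universe_size - length(setA),
         length(setB), lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment helper
#'
#' Thin wrapper over \code{p.adjust(..., method = "BH")} for adjusting
#' enrichment p-values across categories.
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values.
#' @export
bhAdjust <- function(p) p.adjust(p, method = "BH")
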