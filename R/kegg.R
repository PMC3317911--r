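#' Parse KGML pathway files into a metabolite-enzyme reaction graph
#'
#' For every \code{<reaction>} element, the catalysing enzyme genes are
#' the \code{type="gene"} entries whose \code{reaction} attribute names
#' that reaction; an undirected edge is added from each enzyme to each
#' substrate and each product compound. Edges are deduplicated; reactions
#' with no enzyme mapping are skipped and counted.
#'
#' @param files character vector of KGML XML paths.
#' @return a \linkS4class{ReactionGraph}.
#' @export
parseKGML <- function(files) {
  edges <- list()
  skipped <- 0L
  for (f in files) {
    doc <- tryCatch(xml2::read_xml(f), error = function(e)
      stopf("malformed KGML file %s: %s", f, conditionMessage(e)))
    entries <- xml2::xml_find_all(doc, ".//entry[@type='gene']")
    # one entry can catalyse several reactions (space-separated attr)
    enzymeOf <- list()
    for (en in entries) {
      rxns <- strsplit(xml2::xml_attr(en, "reaction") %||% "", "\\s+")[[1L]]
      genes <- strsplit(xml2::xml_attr(en, "name") %||% "", "\\s+")[[1L]]
      genes <- genes[nzchar(genes)]
      for (rx in rxns[nzchar(rxns)])
        enzymeOf[[rx]] <- union(enzymeOf[[rx]], genes)
    }
    for (rxn in xml2::xml_find_all(doc, ".//reaction")) {
      rid <- xml2::xml_attr(rxn, "name")
      enz <- unique(unlist(enzymeOf[strsplit(rid %||% "", "\\s+")[[1L]]]))
      if (length(enz) == 0L) { skipped <- skipped + 1L; next }
      cpds <- xml2::xml_attr(
        xml2::xml_find_all(rxn, "./substrate | ./product"), "name")
      cpds <- unique(cpds[!is.na(cpds)])
      if (length(cpds) == 0L) next
      edges[[length(edges) + 1L]] <-
        expand.grid(enzyme = enz, metabolite = cpds,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    }
  }
  e <- if (length(edges)) unique(do.call(rbind, edges)) else
    data.frame(enzyme = character(0), metabolite = character(0),
               stringsAsFactors = FALSE)
  rownames(e) <- NULL
  new("ReactionGraph", edges = e, skipped = skipped)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' @describeIn parseKGML the deduplicated enzyme-metabolite edge table.
#' @param x a ReactionGraph.
#' @export
setGeneric("reactionEdges", function(x) standardGeneric("reactionEdges"))
setMethod("reactionEdges", "ReactionGraph", function(x) x@edges)

setMethod("show", "ReactionGraph", function(object) {
  e <- object@edges
  cat(sprintf(
    "ReactionGraph: %d enzyme-metabolite pairs (%d enzymes, %d metabolites, %d reactions skipped)\n",
    nrow(e), length(unique(e$enzyme)), length(unique(e$metabolite)),
    object@skipped))
})

#' All-pairs shortest distances by repeated matrix multiplication
#'
#' Computes shortest path lengths on the bipartite reaction graph using
#' boolean powers of the adjacency matrix: nodes first reached at power k
#' are at distance k; nodes never reached are at distance Inf.
#'
#' @param graph a \linkS4class{ReactionGraph}.
#' @return square numeric matrix of distances (0 on the diagonal),
#'   with attributes \code{enzymes} and \code{metabolites} naming the two
#'   node classes.
#' @export
shortestDistances <- function(graph) {
  e <- reactionEdges(graph)
  if (nrow(e) == 0L) stopf("reaction graph is empty")
  nodes <- c(sort(unique(e$enzyme)), sort(unique(e$metabolite)))
  n <- length(nodes)
  A <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  A[cbind(match(e$enzyme, nodes), match(e$metabolite, nodes))] <- TRUE
  A <- A | t(A)
  D <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(D) <- 0
  reach <- A
  d <- 1
  repeat {
    newly <- reach & !is.finite(D)
    if (!any(newly) || d > n) break
    D[newly] <- d
    # boolean matrix product: nodes reachable in one more step
    reach <- (reach %*% A) > 0
    d <- d + 1
  }
  attr(D, "enzymes") <- sort(unique(e$enzyme))
  attr(D, "metabolites") <- sort(unique(e$metabolite))
  D
}

#' Structure priors from KEGG reaction distances
#'
#' The prior that an enzyme gene's expression affects a metabolite's
#' concentration decays with their shortest distance d in the reaction
#' graph: weight = w_max * 2^-(d - 1), so a directly catalysing enzyme
#' (d = 1) gets w_max and each extra step halves the weight. Unreachable
#' pairs get no entry (the background default applies at merge time).
#'
#' @param distances matrix from \code{\link{shortestDistances}}.
#' @param w_max weight at distance 1; default 0.9.
#' @param default background weight of the returned PriorMatrix.
#' @return a \linkS4class{PriorMatrix} with enzyme -> metabolite entries.
#' @export
keggPrior <- function(distances, w_max = 0.9, default = 0.05) {
  if (w_max <= 0 || w_max > 1) stopf("w_max must lie in (0, 1]")
  enz <- attr(distances, "enzymes")
  met <- attr(distances, "metabolites")
  if (is.null(enz) || is.null(met))
    stopf("distances must come from shortestDistances()")
  sub <- distances[enz, met, drop = FALSE]
  idx <- which(is.finite(sub) & sub >= 1, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(priorMatrix(default = default))
  d <- sub[idx]
  entries <- data.frame(parent = enz[idx[, 1L]], child = met[idx[, 2L]],
                        weight = w_max * 2^(-(d - 1)),
                        stringsAsFactors = FALSE)
  priorMatrix(entries, default = default)
}
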