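#' Construct a MarkerMap
#'
#' If genetic positions are not supplied they default to 1 cM per 2 kb of
#' physical position, an order-of-magnitude yeast map density.
#'
#' @param marker character marker ids.
#' @param chrom chromosome labels.
#' @param pos_bp physical positions (1-based bp), strictly increasing
#'   within each chromosome.
#' @param cm genetic positions in cM; default \code{pos_bp / 2000}.
#' @return a \linkS4class{MarkerMap}.
#' @export
markerMap <- function(marker, chrom, pos_bp, cm = pos_bp / 2000) {
  new("MarkerMap", map = data.frame(marker = as.character(marker),
                                    chrom = as.character(chrom),
                                    pos_bp = as.numeric(pos_bp),
                                    cm = as.numeric(cm),
                                    stringsAsFactors = FALSE))
}

#' @describeIn markerMap marker ids in map order.
#' @param x a MarkerMap or GenotypeMatrix.
#' @export
setGeneric("markerIds", function(x) standardGeneric("markerIds"))
setMethod("markerIds", "MarkerMap", function(x) x@map$marker)
setMethod("markerIds", "GenotypeMatrix", function(x) x@map@map$marker)

#' @describeIn markerMap the map as a data.frame.
#' @export
setGeneric("mapTable", function(x) standardGeneric("mapTable"))
setMethod("mapTable", "MarkerMap", function(x) x@map)
setMethod("mapTable", "GenotypeMatrix", function(x) x@map@map)

#' Construct a GenotypeMatrix
#'
#' @param values segregant-by-marker matrix with entries in \{0, 1, NA\}.
#' @param map a \linkS4class{MarkerMap} matching the columns.
#' @return a \linkS4class{GenotypeMatrix}.
#' @export
genotypeMatrix <- function(values, map) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("seg%03d", seq_len(nrow(values)))
  new("GenotypeMatrix", values = values, map = map)
}

#' Accessors for cross data containers
#'
#' @param x a GenotypeMatrix or TraitMatrix.
#' @name cross-accessors
NULL

#' @rdname cross-accessors
#' @export
setGeneric("genoValues", function(x) standardGeneric("genoValues"))
setMethod("genoValues", "GenotypeMatrix", function(x) x@values)

#' @rdname cross-accessors
#' @export
setGeneric("segregantIds", function(x) standardGeneric("segregantIds"))
setMethod("segregantIds", "GenotypeMatrix", function(x) rownames(x@values))
setMethod("segregantIds", "TraitMatrix", function(x) rownames(x@values))

#' @rdname cross-accessors
#' @export
setGeneric("markerMapOf", function(x) standardGeneric("markerMapOf"))
setMethod("markerMapOf", "GenotypeMatrix", function(x) x@map)

#' Construct a TraitMatrix
#'
#' @param values segregant-by-trait numeric matrix.
#' @param meta per-trait metadata; missing columns are filled (kind
#'   defaults to "gene", location to NA, units to "au").
#' @return a \linkS4class{TraitMatrix}.
#' @export
traitMatrix <- function(values, meta = NULL) {
  if (is.null(colnames(values)))
    stopf("trait matrix must have column names")
  if (is.null(meta))
    meta <- data.frame(trait = colnames(values), stringsAsFactors = FALSE)
  if (is.null(meta$kind)) meta$kind <- "gene"
  if (is.null(meta$chrom)) meta$chrom <- NA_character_
  if (is.null(meta$pos_bp)) meta$pos_bp <- NA_real_
  if (is.null(meta$units)) meta$units <- "au"
  meta <- meta[match(colnames(values), meta$trait), , drop = FALSE]
  rownames(meta) <- NULL
  new("TraitMatrix", values = values, meta = meta)
}

#' @rdname cross-accessors
#' @export
setGeneric("traitValues", function(x) standardGeneric("traitValues"))
setMethod("traitValues", "TraitMatrix", function(x) x@values)

#' @rdname cross-accessors
#' @export
setGeneric("traitMeta", function(x) standardGeneric("traitMeta"))
setMethod("traitMeta", "TraitMatrix", function(x) x@meta)

#' @rdname cross-accessors
#' @export
setGeneric("traitIds", function(x) standardGeneric("traitIds"))
setMethod("traitIds", "TraitMatrix", function(x) colnames(x@values))

#' Construct a GroundTruthNetwork
#'
#' @param nodes data.frame(trait, kind) or character vector of trait ids
#'   (kind then defaults to "gene").
#' @param edges data.frame(parent, child, beta); NULL for none.
#' @param loci data.frame(trait, marker, a); NULL for none.
#' @param noise_sd named numeric per trait, or a single value recycled.
#' @return a \linkS4class{GroundTruthNetwork}.
#' @export
groundTruthNetwork <- function(nodes, edges = NULL, loci = NULL,
                               noise_sd = 1) {
  if (is.character(nodes))
    nodes <- data.frame(trait = nodes, kind = "gene",
                        stringsAsFactors = FALSE)
  if (is.null(edges))
    edges <- data.frame(parent = character(0), child = character(0),
                        beta = numeric(0), stringsAsFactors = FALSE)
  if (is.null(loci))
    loci <- data.frame(trait = character(0), marker = character(0),
                       a = numeric(0), stringsAsFactors = FALSE)
  if (is.null(names(noise_sd)))
    noise_sd <- setNames(rep_len(noise_sd, nrow(nodes)), nodes$trait)
  new("GroundTruthNetwork", nodes = nodes, edges = edges, loci = loci,
      noise_sd = noise_sd)
}

#' Edge and node accessors for network-like objects
#'
#' @param x a network-like object.
#' @name network-accessors
NULL

#' @rdname network-accessors
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))
setMethod("edgeTable", "GroundTruthNetwork", function(x) x@edges)
setMethod("edgeTable", "DAGModel", function(x) x@edges)
setMethod("edgeTable", "ConsensusNetwork", function(x) x@edges)
setMethod("edgeTable", "Subnetwork", function(x) x@edges)

#' @rdname network-accessors
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))
setMethod("nodeIds", "GroundTruthNetwork", function(x) x@nodes$trait)
setMethod("nodeIds", "DAGModel", function(x) x@nodes)
setMethod("nodeIds", "ConsensusNetwork", function(x) x@nodes)
setMethod("nodeIds", "Subnetwork", function(x) x@nodes)

#' @rdname network-accessors
#' @export
setGeneric("networkScore", function(x) standardGeneric("networkScore"))
setMethod("networkScore", "DAGModel", function(x) x@score)

#' @rdname network-accessors
#' @export
setGeneric("seedIds", function(x) standardGeneric("seedIds"))
setMethod("seedIds", "Subnetwork", function(x) x@seeds)

#' QTLTable accessors
#'
#' @param x a QTLTable.
#' @export
setGeneric("qtlRecords", function(x) standardGeneric("qtlRecords"))
setMethod("qtlRecords", "QTLTable", function(x) x@records)

#' @rdname qtlRecords
#' @export
setGeneric("scanParams", function(x) standardGeneric("scanParams"))
setMethod("scanParams", "QTLTable", function(x) x@params)

#' Construct a PriorMatrix
#'
#' @param entries data.frame(parent, child, weight) with weights in (0,1].
#' @param forbidden data.frame(parent, child) of disallowed edges.
#' @param default background weight for unlisted pairs.
#' @return a \linkS4class{PriorMatrix}.
#' @export
priorMatrix <- function(entries = NULL, forbidden = NULL, default = 0.05) {
  if (is.null(entries))
    entries <- data.frame(parent = character(0), child = character(0),
                          weight = numeric(0), stringsAsFactors = FALSE)
  if (is.null(forbidden)) forbidden <- emptyEdges()
  new("PriorMatrix", entries = entries, forbidden = forbidden,
      default = default)
}

#' PriorMatrix accessors
#'
#' @param x a PriorMatrix.
#' @export
setGeneric("priorEntries", function(x) standardGeneric("priorEntries"))
setMethod("priorEntries", "PriorMatrix", function(x) x@entries)

#' @rdname priorEntries
#' @export
setGeneric("priorForbidden", function(x) standardGeneric("priorForbidden"))
setMethod("priorForbidden", "PriorMatrix", function(x) x@forbidden)

#' @rdname priorEntries
#' @export
setGeneric("priorDefault", function(x) standardGeneric("priorDefault"))
setMethod("priorDefault", "PriorMatrix", function(x) x@default)

#' Look up prior weights for directed pairs
#'
#' @param x a PriorMatrix.
#' @param parent,child character vectors (recycled to common length).
#' @return numeric weights: stored value, 0 for forbidden pairs, the
#'   background default otherwise.
#' @export
priorWeight <- function(x, parent, child) {
  stopifnot(is(x, "PriorMatrix"))
  n <- max(length(parent), length(child))
  parent <- rep_len(as.character(parent), n)
  child <- rep_len(as.character(child), n)
  w <- rep_len(x@default, n)
  if (nrow(x@entries)) {
    i <- match(pairKey(parent, child), pairKey(x@entries$parent,
                                               x@entries$child))
    w[!is.na(i)] <- x@entries$weight[i[!is.na(i)]]
  }
  if (nrow(x@forbidden)) {
    bad <- pairKey(parent, child) %in% pairKey(x@forbidden$parent,
                                               x@forbidden$child)
    w[bad] <- 0
  }
  w
}

#' CausalCall accessors
#'
#' @param x a CausalCall.
#' @export
setGeneric("callModel", function(x) standardGeneric("callModel"))
setMethod("callModel", "CausalCall", function(x) x@model)

#' @rdname callModel
#' @export
setGeneric("callScores", function(x) standardGeneric("callScores"))
setMethod("callScores", "CausalCall", function(x) x@scores)

#' Construct a RunConfig
#'
#' @param lodSignificant genome-wide significant LOD (default 3.9).
#' @param lodSuggestive suggestive LOD (default 2.8).
#' @param consensusCutoff consensus edge-frequency cutoff (default 0.30).
#' @param cisWindowBp cis window in bp (default 50000).
#' @param hotspotBinBp hotspot bin width in bp (default 20000).
#' @param nRuns,nIter,baseSeed ensemble size, proposals per search, seed.
#' @param defaultWeight,wMax,wUniform,pCut prior constants.
#' @return a \linkS4class{RunConfig}.
#' @export
runConfig <- function(lodSignificant = 3.9, lodSuggestive = 2.8,
                      consensusCutoff = 0.30, cisWindowBp = 50000,
                      hotspotBinBp = 20000, nRuns = 1000L, nIter = 20000L,
                      baseSeed = 1L, defaultWeight = 0.05, wMax = 0.9,
                      wUniform = 0.5, pCut = 0.01) {
  new("RunConfig", lodSignificant = lodSignificant,
      lodSuggestive = lodSuggestive, consensusCutoff = consensusCutoff,
      cisWindowBp = cisWindowBp, hotspotBinBp = hotspotBinBp,
      nRuns = as.integer(nRuns), nIter = as.integer(nIter),
      baseSeed = as.integer(baseSeed), defaultWeight = defaultWeight,
      wMax = wMax, wUniform = wUniform, pCut = pCut)
}

setMethod("show", "GenotypeMatrix", function(object) {
  v <- object@values
  cat(sprintf("GenotypeMatrix: %d segregants x %d markers (%d chromosomes)\n",
              nrow(v), ncol(v), length(unique(object@map@map$chrom))))
})

setMethod("show", "TraitMatrix", function(object) {
  v <- object@values
  k <- table(object@meta$kind)
  cat(sprintf("TraitMatrix: %d segregants x %d traits (%s)\n",
              nrow(v), ncol(v),
              paste(sprintf("%d %s", k, names(k)), collapse = ", ")))
})

setMethod("show", "GroundTruthNetwork", function(object) {
  cat(sprintf(
    "GroundTruthNetwork: %d nodes, %d trait-trait edges, %d locus effects\n",
    nrow(object@nodes), nrow(object@edges), nrow(object@loci)))
})

setMethod("show", "QTLTable", function(object) {
  r <- object@records
  cat(sprintf("QTLTable: %d peak records over %d traits (max LOD %.2f)\n",
              nrow(r), length(unique(r$trait)),
              if (nrow(r)) max(r$lod) else 0))
})

setMethod("show", "PriorMatrix", function(object) {
  cat(sprintf(
    "PriorMatrix: %d weighted pairs, %d forbidden, background %.3g\n",
    nrow(object@entries), nrow(object@forbidden), object@default))
})

setMethod("show", "DAGModel", function(object) {
  cat(sprintf("DAGModel: %d nodes, %d edges, score %.3f\n",
              length(object@nodes), nrow(object@edges), object@score))
})

setMethod("show", "ConsensusNetwork", function(object) {
  cat(sprintf(
    "ConsensusNetwork: %d nodes, %d edges (> %.0f%% of %d runs)\n",
    length(object@nodes), nrow(object@edges), 100 * object@cutoff,
    object@nRuns))
})

setMethod("show", "Subnetwork", function(object) {
  cat(sprintf("Subnetwork: %d seeds -> %d nodes, %d edges\n",
              length(object@seeds), length(object@nodes),
              nrow(object@edges)))
})

setMethod("show", "CausalCall", function(object) {
  cat(sprintf("CausalCall: %s ~ %s @ %s -> %s%s (S = %.3f/%.3f/%.3f)\n",
              object@trait1, object@trait2, object@locus, object@model,
              if (object@tieFlag) " [tie]" else "",
              object@scores[1], object@scores[2], object@scores[3]))
})
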