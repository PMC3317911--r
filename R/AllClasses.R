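#' @import methods
#' @importFrom stats cor lm optim p.adjust pbinom phyper quantile rbinom
#'   rnorm runif sd var dhyper complete.cases setNames
#' @importFrom utils combn head read.delim write.table
NULL

setClassUnion("data.frameOrNULL", c("data.frame", "NULL"))

#' MarkerMap: genomic and genetic positions of markers
#'
#' Holds, per marker, its chromosome, physical position (bp, 1-based) and
#' genetic position (cM). Physical positions must be strictly increasing
#' within each chromosome and each marker sits on exactly one chromosome.
#'
#' @slot map data.frame with columns \code{marker}, \code{chrom},
#'   \code{pos_bp}, \code{cm}.
#' @export
setClass("MarkerMap", representation(map = "data.frame"))

setValidity("MarkerMap", function(object) {
  m <- object@map
  need <- c("marker", "chrom", "pos_bp", "cm")
  if (!all(need %in% names(m)))
    return(sprintf("map must have columns %s", paste(need, collapse = ", ")))
  if (nrow(m) == 0L) return("map is empty")
  if (anyDuplicated(m$marker)) return("duplicated marker ids")
  if (any(m$pos_bp < 0) || any(m$cm < 0))
    return("positions must be non-negative")
  for (ch in unique(m$chrom)) {
    p <- m$pos_bp[m$chrom == ch]
    if (any(diff(p) <= 0))
      return(sprintf("positions not strictly increasing on chromosome %s", ch))
  }
  TRUE
})

#' GenotypeMatrix: segregant-by-marker biallelic genotypes
#'
#' Genotypes of a haploid cross coded 0 (one parental allele) / 1 (the
#' other), rows are segregants, columns are markers matching the map.
#'
#' @slot values numeric matrix with entries in \{0, 1, NA\}.
#' @slot map a \linkS4class{MarkerMap} whose markers match the columns.
#' @export
setClass("GenotypeMatrix",
         representation(values = "matrix", map = "MarkerMap"))

setValidity("GenotypeMatrix", function(object) {
  v <- object@values
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("values must have segregant rownames and marker colnames")
  if (!identical(colnames(v), markerIds(object@map)))
    return("column names must equal the marker map ids, in order")
  bad <- v[!is.na(v)]
  if (length(bad) && !all(bad %in% c(0, 1)))
    return("genotype entries must be 0, 1 or NA")
  TRUE
})

#' TraitMatrix: segregant-by-trait quantitative phenotypes
#'
#' Gene-expression and metabolite values on the same segregants as the
#' genotypes. Per-trait metadata records the kind (gene/metabolite), the
#' genomic location for genes, and a units label.
#'
#' @slot values numeric matrix, rows segregants, columns traits.
#' @slot meta data.frame with columns \code{trait}, \code{kind},
#'   \code{chrom}, \code{pos_bp}, \code{units}.
#' @export
setClass("TraitMatrix",
         representation(values = "matrix", meta = "data.frame"))

setValidity("TraitMatrix", function(object) {
  v <- object@values
  m <- object@meta
  need <- c("trait", "kind", "chrom", "pos_bp", "units")
  if (!all(need %in% names(m)))
    return(sprintf("meta must have columns %s", paste(need, collapse = ", ")))
  if (is.null(colnames(v)) || !identical(colnames(v), m$trait))
    return("column names must equal meta$trait, in order")
  if (!all(m$kind %in% c("gene", "metabolite")))
    return("trait kind must be 'gene' or 'metabolite'")
  TRUE
})

#' GroundTruthNetwork: the generating model of a synthetic cross
#'
#' A known acyclic causal structure used by the simulator: trait nodes,
#' directed trait-trait edges with linear effects beta, marker-to-trait
#' locus effects a, and per-trait Gaussian noise standard deviations.
#'
#' @slot nodes data.frame with columns \code{trait}, \code{kind}.
#' @slot edges data.frame with columns \code{parent}, \code{child},
#'   \code{beta}.
#' @slot loci data.frame with columns \code{trait}, \code{marker}, \code{a}.
#' @slot noise_sd named numeric, one positive value per trait.
#' @export
setClass("GroundTruthNetwork",
         representation(nodes = "data.frame", edges = "data.frame",
                        loci = "data.frame", noise_sd = "numeric"))

setValidity("GroundTruthNetwork", function(object) {
  nd <- object@nodes; ed <- object@edges
  if (!all(c("trait", "kind") %in% names(nd))) return("bad nodes columns")
  if (!all(c("parent", "child", "beta") %in% names(ed)))
    return("bad edges columns")
  if (!all(c(ed$parent, ed$child) %in% nd$trait))
    return("edge endpoints must be declared nodes")
  if (!all(names(object@noise_sd) %in% nd$trait) ||
      !all(nd$trait %in% names(object@noise_sd)))
    return("noise_sd must be named by every trait")
  if (any(!is.finite(object@noise_sd)) || any(object@noise_sd < 0))
    return("noise_sd must be finite and non-negative")
  if (nrow(ed) && is.null(topoOrder(nd$trait, ed[, c("parent", "child")])))
    return("trait-trait edge set must be acyclic")
  TRUE
})

#' QTLTable: peak linkage records from a genome scan
#'
#' One record per (trait, chromosome) peak: the best marker, its LOD score,
#' genotype-class means, and (after classification) the cis/trans label.
#'
#' @slot records data.frame with columns \code{trait}, \code{marker},
#'   \code{chrom}, \code{pos_bp}, \code{lod}, \code{mu0}, \code{mu1},
#'   \code{n_used}, \code{class}.
#' @slot params list of scan parameters (thresholds, permutations).
#' @export
setClass("QTLTable", representation(records = "data.frame", params = "list"))

setValidity("QTLTable", function(object) {
  r <- object@records
  need <- c("trait", "marker", "chrom", "pos_bp", "lod", "mu0", "mu1",
            "n_used", "class")
  if (!all(need %in% names(r)))
    return(sprintf("records must have columns %s", paste(need, collapse = ", ")))
  if (nrow(r) && any(r$lod < 0)) return("lod must be >= 0")
  if (nrow(r) && anyDuplicated(r[, c("trait", "chrom")]))
    return("at most one peak record per (trait, chromosome)")
  TRUE
})

#' PriorMatrix: sparse directed structure-prior weights
#'
#' Maps (parent, child) pairs to a prior weight in (0, 1]; pairs in the
#' forbidden set have weight 0 (the edge can never be accepted); all other
#' pairs fall back to \code{default} weight.
#'
#' @slot entries data.frame with columns \code{parent}, \code{child},
#'   \code{weight}.
#' @slot forbidden data.frame with columns \code{parent}, \code{child}.
#' @slot default background weight for unlisted pairs.
#' @export
setClass("PriorMatrix",
         representation(entries = "data.frame", forbidden = "data.frame",
                        default = "numeric"))

setValidity("PriorMatrix", function(object) {
  e <- object@entries
  if (!all(c("parent", "child", "weight") %in% names(e)))
    return("entries needs parent, child, weight")
  if (nrow(e) && (any(e$weight <= 0) || any(e$weight > 1)))
    return("stored weights must lie in (0, 1]")
  if (length(object@default) != 1L || object@default <= 0 ||
      object@default > 1)
    return("default weight must be a single value in (0, 1]")
  if (nrow(e) && nrow(object@forbidden)) {
    key <- function(d) paste(d$parent, d$child, sep = "\r")
    if (any(key(e) %in% key(object@forbidden)))
      return("a pair cannot be both stored and forbidden")
  }
  TRUE
})

#' ReactionGraph: bipartite metabolite-enzyme adjacency
#'
#' Undirected bipartite graph linking metabolites to the enzyme genes
#' catalysing reactions that consume or produce them, as parsed from KGML
#' pathway files.
#'
#' @slot edges data.frame with columns \code{enzyme}, \code{metabolite}
#'   (deduplicated).
#' @slot skipped number of reactions dropped for lacking an enzyme
#'   mapping.
#' @export
setClass("ReactionGraph",
         representation(edges = "data.frame", skipped = "integer"))

setValidity("ReactionGraph", function(object) {
  e <- object@edges
  if (!all(c("enzyme", "metabolite") %in% names(e)))
    return("edges needs enzyme, metabolite columns")
  if (anyDuplicated(e)) return("duplicate edges")
  TRUE
})

#' DAGModel: one learned Bayesian-network structure
#'
#' @slot nodes character vector of trait ids.
#' @slot edges data.frame with columns \code{parent}, \code{child}.
#' @slot score total network score (sum of per-node local scores).
#' @slot localScores named numeric, one local score per node.
#' @export
setClass("DAGModel",
         representation(nodes = "character", edges = "data.frame",
                        score = "numeric", localScores = "numeric"))

setValidity("DAGModel", function(object) {
  ed <- object@edges
  if (!all(c("parent", "child") %in% names(ed))) return("bad edges columns")
  if (nrow(ed) && is.null(topoOrder(object@nodes, ed)))
    return("edge set must be acyclic")
  TRUE
})

#' ConsensusNetwork: ensemble-averaged directed network
#'
#' Directed edges retained at an ensemble frequency above the consensus
#' cutoff, each annotated with its frequency; after \code{breakCycles} the
#' structure is guaranteed acyclic.
#'
#' @slot nodes character vector of trait ids.
#' @slot edges data.frame with columns \code{parent}, \code{child},
#'   \code{frequency}.
#' @slot nRuns number of ensemble members averaged.
#' @slot cutoff the frequency cutoff applied (strict).
#' @export
setClass("ConsensusNetwork",
         representation(nodes = "character", edges = "data.frame",
                        nRuns = "integer", cutoff = "numeric"))

setValidity("ConsensusNetwork", function(object) {
  ed <- object@edges
  if (!all(c("parent", "child", "frequency") %in% names(ed)))
    return("edges needs parent, child, frequency")
  if (nrow(ed) && (any(ed$frequency <= 0) || any(ed$frequency > 1)))
    return("frequencies must lie in (0, 1]")
  TRUE
})

#' Subnetwork: seeds plus their direct neighbours
#'
#' @slot nodes character vector (seeds and their direct neighbours).
#' @slot edges data.frame with columns \code{parent}, \code{child} (and
#'   \code{frequency} when extracted from a consensus network).
#' @slot seeds the seed node ids actually found in the parent network.
#' @export
setClass("Subnetwork",
         representation(nodes = "character", edges = "data.frame",
                        seeds = "character"))

#' CausalCall: result of the genotype-anchored causality test
#'
#' @slot trait1,trait2 trait labels.
#' @slot locus anchoring marker id.
#' @slot model one of \code{"causal"}, \code{"reactive"},
#'   \code{"independent"}.
#' @slot scores named numeric of the three penalized statistics
#'   (S_causal, S_reactive, S_independent); the selected model minimises
#'   them unless \code{tieFlag}.
#' @slot tieFlag TRUE when the two best scores tie within 1e-9 (the call
#'   then falls back to "independent").
#' @export
setClass("CausalCall",
         representation(trait1 = "character", trait2 = "character",
                        locus = "character", model = "character",
                        scores = "numeric", tieFlag = "logical"))

setValidity("CausalCall", function(object) {
  if (!object@model %in% c("causal", "reactive", "independent"))
    return("unknown model label")
  if (length(object@scores) != 3L || any(!is.finite(object@scores)))
    return("scores must be three finite values")
  TRUE
})

#' RunConfig: thresholds and constants for the full pipeline
#'
#' Defaults follow the study design: genome-wide significant LOD 3.9
#' (FDR 0.05), suggestive LOD 2.8, consensus edge cutoff 0.30 (strict),
#' 50-kb cis window, 20-kb hotspot bins.
#'
#' @slot lodSignificant,lodSuggestive LOD thresholds.
#' @slot consensusCutoff consensus edge-frequency cutoff in (0, 1).
#' @slot cisWindowBp,hotspotBinBp window sizes in bp.
#' @slot nRuns,nIter,baseSeed ensemble controls.
#' @slot defaultWeight,wMax,wUniform,pCut prior constants.
#' @export
setClass("RunConfig",
         representation(lodSignificant = "numeric", lodSuggestive = "numeric",
                        consensusCutoff = "numeric", cisWindowBp = "numeric",
                        hotspotBinBp = "numeric", nRuns = "integer",
                        nIter = "integer", baseSeed = "integer",
                        defaultWeight = "numeric", wMax = "numeric",
                        wUniform = "numeric", pCut = "numeric"))

setValidity("RunConfig", function(object) {
  if (object@consensusCutoff <= 0 || object@consensusCutoff >= 1)
    return("consensusCutoff must lie in (0, 1)")
  pos <- c(object@lodSignificant, object@lodSuggestive, object@cisWindowBp,
           object@hotspotBinBp, object@defaultWeight, object@wMax,
           object@wUniform, object@pCut)
  if (any(pos <= 0)) return("thresholds and constants must be positive")
  TRUE
})
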