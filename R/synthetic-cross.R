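#' Evenly spaced marker map
#'
#' Convenience constructor for a uniformly spaced multi-chromosome map,
#' e.g. a yeast-like genome of 16 chromosomes carrying ~2,000 markers.
#'
#' @param n_chrom number of chromosomes.
#' @param markers_per_chrom markers on each chromosome.
#' @param spacing_bp physical spacing between adjacent markers (bp).
#' @param cm_per_bp genetic-map density; default 1 cM per 2 kb.
#' @return a \linkS4class{MarkerMap}.
#' @examples
#' uniformMap(2, 5, 10000)
#' @export
uniformMap <- function(n_chrom = 16, markers_per_chrom = 125,
                       spacing_bp = 6000, cm_per_bp = 1 / 2000) {
  chrom <- rep(sprintf("chr%02d", seq_len(n_chrom)), each = markers_per_chrom)
  pos <- rep(seq_len(markers_per_chrom) * spacing_bp, times = n_chrom)
  marker <- sprintf("m_%s_%04d", chrom, pos %/% 1000)
  markerMap(marker, chrom, pos, cm = pos * cm_per_bp)
}

#' Simulate haploid-cross genotypes
#'
#' Each segregant's alleles along a chromosome follow a Markov chain: the
#' first marker is Bernoulli(0.5) and the allele switches between adjacent
#' markers with the Haldane recombination fraction
#' r = (1 - exp(-2 d / 100)) / 2 computed from their genetic distance d in
#' cM. Chromosomes are independent; no missing data are generated.
#'
#' @param n_segregants number of progeny strains (>= 2).
#' @param map a \linkS4class{MarkerMap}.
#' @param seed integer seed; the same seed reproduces the same matrix.
#' @return a \linkS4class{GenotypeMatrix}.
#' @examples
#' g <- simulateGenotypes(20, uniformMap(2, 10, 10000), seed = 1)
#' dim(genoValues(g))
#' @export
simulateGenotypes <- function(n_segregants, map, seed) {
  if (!is(map, "MarkerMap") || nrow(map@map) == 0L)
    stopf("map must be a non-empty MarkerMap")
  if (n_segregants < 2) stopf("n_segregants must be >= 2")
  n <- as.integer(n_segregants)
  m <- map@map
  withSeed(seed, {
    cols <- vector("list", nrow(m))
    for (ch in unique(m$chrom)) {
      idx <- which(m$chrom == ch)
      k <- length(idx)
      first <- rbinom(n, 1L, 0.5)
      alle <- matrix(0L, n, k)
      alle[, 1L] <- first
      if (k > 1L) {
        d <- diff(m$cm[idx])
        r <- haldaneR(d)
        sw <- matrix(runif(n * (k - 1L)), n, k - 1L) <
          matrix(r, n, k - 1L, byrow = TRUE)
        # cumulative xor of switch indicators along the chromosome
        alle[, -1L] <- (first + t(apply(sw, 1L, cumsum))) %% 2L
      }
      for (j in seq_len(k)) cols[[idx[j]]] <- alle[, j]
    }
    v <- do.call(cbind, cols)
    dimnames(v) <- list(sprintf("seg%04d", seq_len(n)), m$marker)
    genotypeMatrix(v, map)
  })
}

#' Haldane map function
#'
#' Recombination fraction from genetic distance:
#' r = (1 - exp(-2 d / 100)) / 2 for d in cM.
#'
#' @param d_cm genetic distance(s) in centimorgans.
#' @return recombination fraction(s) in [0, 0.5).
#' @export
haldaneR <- function(d_cm) (1 - exp(-2 * d_cm / 100)) / 2

#' Simulate traits from a ground-truth network
#'
#' Traits are generated in topological order of the trait-trait edges as
#' linear structural equations:
#' trait = sum(beta * parent trait) + sum(a * genotype) + N(0, noise_sd).
#'
#' @param geno a \linkS4class{GenotypeMatrix}; all loci referenced by the
#'   truth must exist in its map.
#' @param truth a \linkS4class{GroundTruthNetwork} (acyclic by validity).
#' @param seed integer seed.
#' @return a \linkS4class{TraitMatrix} with metadata taken from the truth;
#'   genes driven by a locus inherit that marker's genomic position as
#'   their (cis) location.
#' @export
simulateTraits <- function(geno, truth, seed) {
  stopifnot(is(geno, "GenotypeMatrix"), is(truth, "GroundTruthNetwork"))
  mm <- mapTable(geno)
  if (!all(truth@loci$marker %in% mm$marker))
    stopf("truth references loci absent from the genotype map")
  ord <- topoOrder(truth@nodes$trait, truth@edges)
  if (is.null(ord)) stopf("ground-truth trait edges contain a cycle")
  g <- genoValues(geno)
  n <- nrow(g)
  withSeed(seed, {
    v <- matrix(0, n, length(ord), dimnames = list(rownames(g), ord))
    for (tr in ord) {
      y <- rnorm(n, 0, truth@noise_sd[[tr]])
      pe <- truth@edges[truth@edges$child == tr, , drop = FALSE]
      for (i in seq_len(nrow(pe)))
        y <- y + pe$beta[i] * v[, pe$parent[i]]
      le <- truth@loci[truth@loci$trait == tr, , drop = FALSE]
      for (i in seq_len(nrow(le)))
        y <- y + le$a[i] * g[, le$marker[i]]
      v[, tr] <- y
    }
    v <- v[, truth@nodes$trait, drop = FALSE]
    meta <- data.frame(trait = truth@nodes$trait, kind = truth@nodes$kind,
                       chrom = NA_character_, pos_bp = NA_real_,
                       units = "au", stringsAsFactors = FALSE)
    if (all(c("chrom", "pos_bp") %in% names(truth@nodes))) {
      # explicit genomic locations on the truth nodes win
      meta$chrom <- as.character(truth@nodes$chrom)
      meta$pos_bp <- as.numeric(truth@nodes$pos_bp)
    } else {
      # genes with a locus effect are cis-anchored at that marker
      loc <- truth@loci[match(meta$trait, truth@loci$trait), "marker"]
      has <- !is.na(loc) & meta$kind == "gene"
      mi <- match(loc[has], mm$marker)
      meta$chrom[has] <- mm$chrom[mi]
      meta$pos_bp[has] <- mm$pos_bp[mi]
    }
    traitMatrix(v, meta)
  })
}

#' Canned simulation scenarios
#'
#' Returns a (genotypes, traits, truth) fixture with a recoverable answer:
#' \describe{
#'   \item{chain}{L -> T1 -> T2: one locus effect (a = 1) on T1 and one
#'     trait-trait edge T1 -> T2 (beta = 1), noise sd 1.}
#'   \item{independent}{L -> T1 and L -> T2: the same locus drives both
#'     traits (a = 1 each) with no trait-trait edge.}
#'   \item{hotspot}{one marker drives 24 traits (a = 1) plus 16 undriven
#'     noise traits — a planted trans-hotspot.}
#'   \item{small_net}{a fixed 30-node DAG (24 genes, 6 metabolites,
#'     10 cis-anchored driver genes, 27 edges with |beta| = 1, noise sd 1)
#'     on a 4-chromosome map.}
#' }
#' The structure of each scenario is fixed; the seed drives genotype and
#' noise realisations only.
#'
#' @param name one of "chain", "independent", "hotspot", "small_net".
#' @param seed integer seed.
#' @param n_segregants cross size; default 120.
#' @return list with elements \code{geno}, \code{traits}, \code{truth}.
#' @examples
#' sc <- makeScenario("chain", seed = 1)
#' edgeTable(sc$truth)
#' @export
makeScenario <- function(name, seed, n_segregants = 120) {
  truthFun <- switch(name,
                     chain = scenarioChain,
                     independent = scenarioIndependent,
                     hotspot = scenarioHotspot,
                     small_net = scenarioSmallNet,
                     stopf("unknown scenario '%s'", name))
  parts <- truthFun()
  geno <- simulateGenotypes(n_segregants, parts$map, seed = seed)
  traits <- simulateTraits(geno, parts$truth, seed = childSeed(seed, 1L))
  list(geno = geno, traits = traits, truth = parts$truth)
}

scenarioChain <- function() {
  map <- uniformMap(2, 12, 20000)
  L <- markerIds(map)[6]
  truth <- groundTruthNetwork(
    nodes = data.frame(trait = c("T1", "T2"), kind = "gene",
                       stringsAsFactors = FALSE),
    edges = data.frame(parent = "T1", child = "T2", beta = 1,
                       stringsAsFactors = FALSE),
    loci = data.frame(trait = "T1", marker = L, a = 1,
                      stringsAsFactors = FALSE),
    noise_sd = c(T1 = 1, T2 = 1))
  list(map = map, truth = truth)
}

scenarioIndependent <- function() {
  map <- uniformMap(2, 12, 20000)
  L <- markerIds(map)[6]
  truth <- groundTruthNetwork(
    nodes = data.frame(trait = c("T1", "T2"), kind = "gene",
                       stringsAsFactors = FALSE),
    edges = NULL,
    loci = data.frame(trait = c("T1", "T2"), marker = L, a = 1,
                      stringsAsFactors = FALSE),
    noise_sd = c(T1 = 1, T2 = 1))
  list(map = map, truth = truth)
}

scenarioHotspot <- function() {
  map <- uniformMap(4, 15, 20000)
  L <- markerIds(map)[23]  # mid chromosome 2
  driven <- sprintf("G%02d", 1:24)
  noisy <- sprintf("N%02d", 1:16)
  traits <- c(driven, noisy)
  # driven genes physically sit on chromosomes 3-4, far from the chr2
  # hotspot locus, so their linkage there is trans
  mm <- mapTable(map)
  homes <- which(mm$chrom %in% c("chr03", "chr04"))
  at <- homes[seq(1, length(homes), length.out = length(traits))]
  truth <- groundTruthNetwork(
    nodes = data.frame(trait = traits, kind = "gene",
                       chrom = mm$chrom[at], pos_bp = mm$pos_bp[at],
                       stringsAsFactors = FALSE),
    edges = NULL,
    loci = data.frame(trait = driven, marker = L, a = 1,
                      stringsAsFactors = FALSE),
    noise_sd = setNames(rep(1, length(traits)), traits))
  list(map = map, truth = truth)
}

# Fixed 30-node ground truth: three regulatory layers ending in
# metabolite sinks, ten cis-anchored drivers on distinct chromosomes.
scenarioSmallNet <- function() {
  map <- uniformMap(4, 50, 10000)
  mk <- markerIds(map)
  genes <- sprintf("G%02d", 1:24)
  mets <- sprintf("M%02d", 1:6)
  nodes <- data.frame(trait = c(genes, mets),
                      kind = rep(c("gene", "metabolite"), c(24, 6)),
                      stringsAsFactors = FALSE)
  drivers <- genes[1:10]
  # cis anchors: driver i sits at marker 2 + 2.5 i on a rotating chromosome
  anchor <- mk[seq(5, by = 20, length.out = 10)]
  loci <- data.frame(trait = drivers, marker = anchor, a = 1,
                     stringsAsFactors = FALSE)
  e <- rbind(
    # layer 1 -> 2: drivers regulate mid-layer genes
    data.frame(parent = drivers,
               child = genes[11:20], stringsAsFactors = FALSE),
    data.frame(parent = genes[c(1, 3, 5, 7)],
               child = genes[c(12, 14, 16, 18)], stringsAsFactors = FALSE),
    # layer 2 -> 3
    data.frame(parent = genes[c(11, 13, 15, 17)],
               child = genes[21:24], stringsAsFactors = FALSE),
    # genes -> metabolite sinks
    data.frame(parent = genes[c(21, 22, 23, 24, 12, 14)],
               child = mets, stringsAsFactors = FALSE),
    # extra parents for three metabolites
    data.frame(parent = genes[c(11, 15, 19)],
               child = mets[c(2, 4, 6)], stringsAsFactors = FALSE))
  e$beta <- rep(c(1, -1), length.out = nrow(e))
  truth <- groundTruthNetwork(nodes, e, loci,
                              setNames(rep(1, 30), nodes$trait))
  list(map = map, truth = truth)
}
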