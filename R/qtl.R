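#' Single-marker LOD score
#'
#' log10 likelihood ratio of the two-mean versus one-mean Gaussian model
#' at the MLE, computed from residual sums of squares:
#' LOD = (n/2) * log10(RSS0 / RSS1), with RSS0 about the grand mean and
#' RSS1 about the genotype-class means. Pairs with missing values are
#' dropped. A constant trait or a monomorphic genotype gives 0.
#'
#' @param trait numeric vector.
#' @param genotype vector of 0/1 alleles, same length.
#' @return non-negative LOD score.
#' @examples
#' g <- rep(0:1, each = 20)
#' lodScore(g + rnorm(40, sd = 0.5), g)
#' @export
lodScore <- function(trait, genotype) {
  if (length(trait) != length(genotype))
    stopf("trait and genotype lengths differ")
  ok <- !is.na(trait) & !is.na(genotype)
  y <- trait[ok]; g <- genotype[ok]
  n <- length(y)
  if (n < 2L) return(0)
  n1 <- sum(g == 1)
  if (n1 == 0L || n1 == n) return(0)
  rss0 <- sum((y - mean(y))^2)
  if (rss0 <= 0) return(0)
  y0 <- y[g == 0]; y1 <- y[g == 1]
  rss1 <- sum((y0 - mean(y0))^2) + sum((y1 - mean(y1))^2)
  if (rss1 <= 0) return(Inf)
  max(0, (n / 2) * log10(rss0 / rss1))
}

# Vectorised LOD for all (marker, trait) pairs; missing entries handled
# pairwise. Returns a markers x traits matrix.
lodMatrixRaw <- function(G, Y) {
  Gi <- !is.na(G); Yi <- !is.na(Y)
  Gm <- G; Gm[!Gi] <- 0
  Ym <- Y; Ym[!Yi] <- 0
  Y2 <- Ym^2
  N <- crossprod(Gi, Yi)             # complete pairs
  n1 <- crossprod(Gm, Yi)            # class-1 counts
  sy <- crossprod(Gi, Ym)            # sum y
  sy1 <- crossprod(Gm, Ym)           # sum y in class 1
  syy <- crossprod(Gi, Y2)
  syy1 <- crossprod(Gm, Y2)
  n0 <- N - n1
  rss0 <- syy - sy^2 / N
  rss1 <- (syy1 - sy1^2 / pmax(n1, 1)) +
    ((syy - syy1) - (sy - sy1)^2 / pmax(n0, 1))
  lod <- (N / 2) * log10(rss0 / rss1)
  lod[n1 == 0 | n0 == 0 | rss0 <= 0] <- 0
  lod[rss1 <= 0 & rss0 > 0 & n1 > 0 & n0 > 0] <- Inf
  lod[lod < 0] <- 0
  dimnames(lod) <- list(colnames(G), colnames(Y))
  lod
}

#' LOD scores for every marker-trait pair
#'
#' @param traits a \linkS4class{TraitMatrix}.
#' @param geno a \linkS4class{GenotypeMatrix} on shared segregants.
#' @return markers x traits matrix of LOD scores.
#' @export
lodMatrix <- function(traits, geno) {
  al <- alignSegregants(traits, geno)
  lodMatrixRaw(al$G, al$Y)
}

alignSegregants <- function(traits, geno) {
  shared <- intersect(segregantIds(traits), segregantIds(geno))
  if (length(shared) == 0L)
    stopf("traits and genotypes share no segregants")
  list(Y = traitValues(traits)[shared, , drop = FALSE],
       G = genoValues(geno)[shared, , drop = FALSE])
}

#' Genome scan: per-(trait, chromosome) peak LOD records
#'
#' Computes the LOD score of every trait at every marker and records, for
#' each trait and chromosome, the peak marker with its genotype-class
#' means. The cis/trans class column is filled by \code{classifyQTL}.
#'
#' @param traits a \linkS4class{TraitMatrix}.
#' @param geno a \linkS4class{GenotypeMatrix}.
#' @return a \linkS4class{QTLTable}.
#' @examples
#' sc <- makeScenario("chain", seed = 1)
#' head(qtlRecords(genomeScan(sc$traits, sc$geno)))
#' @export
genomeScan <- function(traits, geno) {
  al <- alignSegregants(traits, geno)
  lod <- lodMatrixRaw(al$G, al$Y)
  mm <- mapTable(geno)
  recs <- vector("list", length(unique(mm$chrom)) * ncol(al$Y))
  k <- 0L
  for (ch in unique(mm$chrom)) {
    idx <- which(mm$chrom == ch)
    sub <- lod[idx, , drop = FALSE]
    best <- apply(sub, 2L, which.max)
    for (j in seq_len(ncol(sub))) {
      mi <- idx[best[j]]
      g <- al$G[, mi]; y <- al$Y[, j]
      ok <- !is.na(g) & !is.na(y)
      k <- k + 1L
      recs[[k]] <- data.frame(
        trait = colnames(al$Y)[j], marker = mm$marker[mi],
        chrom = ch, pos_bp = mm$pos_bp[mi], lod = sub[best[j], j],
        mu0 = mean(y[ok & g == 0]), mu1 = mean(y[ok & g == 1]),
        n_used = sum(ok), class = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  new("QTLTable", records = do.call(rbind, recs[seq_len(k)]),
      params = list())
}

#' Permutation threshold for genome-wide significance
#'
#' Permutes segregant labels of the trait matrix relative to the
#' genotypes and records the genome-wide (max-over-markers) LOD of every
#' trait in every permutation. In \code{type = "gwer"} mode the threshold
#' is the (1 - level) quantile of that null-max distribution. In
#' \code{type = "fdr"} mode the empirical false-discovery rate
#' FDR(t) = mean permuted exceedances / observed exceedances is scanned
#' over candidate thresholds and the smallest t with FDR(t) <= level is
#' returned.
#'
#' @param traits a \linkS4class{TraitMatrix}.
#' @param geno a \linkS4class{GenotypeMatrix}.
#' @param n_perm number of permutations (>= 100).
#' @param level genome-wide error rate (gwer) or FDR target.
#' @param seed integer seed.
#' @param type "gwer" or "fdr".
#' @return the LOD threshold (numeric scalar).
#' @export
permutationThreshold <- function(traits, geno, n_perm = 1000, level = 0.05,
                                 seed = 1, type = c("gwer", "fdr")) {
  type <- match.arg(type)
  if (n_perm < 100) stopf("n_perm must be >= 100")
  if (type == "gwer" && n_perm * level < 1)
    stopf("n_perm too small for the requested quantile")
  al <- alignSegregants(traits, geno)
  n <- nrow(al$Y)
  nullMax <- withSeed(seed, {
    out <- matrix(0, n_perm, ncol(al$Y))
    for (b in seq_len(n_perm)) {
      Yp <- al$Y[sample.int(n), , drop = FALSE]
      out[b, ] <- apply(lodMatrixRaw(al$G, Yp), 2L, max)
    }
    out
  })
  if (type == "gwer")
    return(as.numeric(quantile(nullMax, 1 - level)))
  obsMax <- apply(lodMatrixRaw(al$G, al$Y), 2L, max)
  cand <- sort(unique(obsMax), decreasing = TRUE)
  thr <- Inf
  for (t in cand) {
    r <- sum(obsMax >= t)
    v <- mean(rowSums(nullMax >= t))
    if (r > 0 && v / r <= level) thr <- t else break
  }
  if (!is.finite(thr))
    thr <- as.numeric(quantile(nullMax, 1 - level))  # nothing passes FDR
  thr
}

#' Classify one QTL record as cis or trans
#'
#' A peak is cis iff it lies on the gene's chromosome within
#' \code{window_bp} of the gene's position (closed interval, so a peak
#' exactly at the window boundary is cis). Records without a gene
#' location (e.g. metabolites) are trans, with a warning flag attribute.
#'
#' @param record one row of a QTLTable's records (list or data.frame row
#'   with \code{chrom}, \code{pos_bp}).
#' @param gene_chrom,gene_pos genomic location of the gene.
#' @param window_bp window size; default 50 kb.
#' @return "cis" or "trans".
#' @export
classifyCisTrans <- function(record, gene_chrom, gene_pos,
                             window_bp = 50000) {
  if (is.na(gene_chrom) || is.na(gene_pos)) {
    out <- "trans"
    attr(out, "missing_location") <- TRUE
    warning("gene location missing; classified trans", call. = FALSE)
    return(out)
  }
  if (identical(as.character(record$chrom), as.character(gene_chrom)) &&
      abs(record$pos_bp - gene_pos) <= window_bp) "cis" else "trans"
}

#' Fill the cis/trans class for a whole QTL table
#'
#' @param qtl a \linkS4class{QTLTable}.
#' @param traits the \linkS4class{TraitMatrix} carrying gene locations.
#' @param window_bp cis window; default 50 kb.
#' @return the QTLTable with its \code{class} column set ("cis"/"trans"
#'   for genes, NA for metabolites).
#' @export
classifyQTL <- function(qtl, traits, window_bp = 50000) {
  r <- qtlRecords(qtl)
  meta <- traitMeta(traits)
  i <- match(r$trait, meta$trait)
  cls <- rep(NA_character_, nrow(r))
  isGene <- !is.na(i) & meta$kind[i] == "gene"
  same <- isGene & !is.na(meta$chrom[i]) &
    as.character(r$chrom) == as.character(meta$chrom[i]) &
    abs(r$pos_bp - meta$pos_bp[i]) <= window_bp
  cls[isGene] <- "trans"
  cls[same] <- "cis"
  r$class <- cls
  new("QTLTable", records = r,
      params = c(qtl@params, list(cis_window_bp = window_bp)))
}

#' Detect trans-linkage hotspots
#'
#' Bins the genome into fixed non-overlapping windows and counts the
#' trans-linked traits (significant peaks not classified cis) falling in
#' each bin. Under the null each linked trait lands in a bin with
#' probability bin width / genome width; the per-bin p-value is the
#' binomial upper tail and bins with Bonferroni-adjusted p < 0.05 are
#' flagged significant.
#'
#' @param qtl a classified \linkS4class{QTLTable}.
#' @param map the \linkS4class{MarkerMap} defining the genome extent.
#' @param bin_bp bin width; default 20 kb.
#' @param lod_threshold significance threshold for peaks; default 3.9.
#' @param alpha family-wise level for the Bonferroni flag.
#' @return data.frame with one row per occupied bin: chrom, start_bp,
#'   end_bp (1-based inclusive), n_traits_linked, expected, p_value,
#'   p_adj, significant.
#' @export
detectHotspots <- function(qtl, map, bin_bp = 20000, lod_threshold = 3.9,
                           alpha = 0.05) {
  if (bin_bp <= 0) stopf("bin_bp must be positive")
  r <- qtlRecords(qtl)
  mm <- mapTable(map)
  chromLen <- tapply(mm$pos_bp, mm$chrom, max)
  nBins <- ceiling(chromLen / bin_bp)
  totalBins <- sum(nBins)
  genome <- totalBins * bin_bp
  hits <- r[r$lod >= lod_threshold & (is.na(r$class) | r$class != "cis"), ,
            drop = FALSE]
  out <- data.frame(chrom = character(0), start_bp = numeric(0),
                    end_bp = numeric(0), n_traits_linked = integer(0),
                    expected = numeric(0), p_value = numeric(0),
                    p_adj = numeric(0), significant = logical(0),
                    stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) return(out)
  bin <- floor((hits$pos_bp - 1) / bin_bp)
  key <- paste(hits$chrom, bin)
  counts <- table(key)
  nLinked <- nrow(hits)
  pHit <- bin_bp / genome
  for (k in names(counts)) {
    parts <- strsplit(k, " ")[[1L]]
    b <- as.numeric(parts[2L])
    cnt <- as.integer(counts[[k]])
    p <- pbinom(cnt - 1L, nLinked, pHit, lower.tail = FALSE)
    out <- rbind(out, data.frame(
      chrom = parts[1L], start_bp = b * bin_bp + 1,
      end_bp = (b + 1) * bin_bp, n_traits_linked = cnt,
      expected = nLinked * pHit, p_value = p,
      p_adj = min(1, p * totalBins), significant = p * totalBins < alpha,
      stringsAsFactors = FALSE))
  }
  out[order(out$p_adj), , drop = FALSE]
}

#' Export hotspots as BED intervals
#'
#' Hotspot bins are held internally as 1-based inclusive coordinates;
#' BED uses 0-based half-open intervals, so start_bp - 1 becomes the
#' BED start and end_bp is unchanged.
#'
#' @param hotspots data.frame from \code{\link{detectHotspots}}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeHotspotsBed <- function(hotspots, path) {
  lines <- sprintf("%s\t%d\t%d\tn=%d;padj=%.3g", hotspots$chrom,
                   as.integer(hotspots$start_bp) - 1L,
                   as.integer(hotspots$end_bp),
                   hotspots$n_traits_linked, hotspots$p_adj)
  writeLines(lines, path)
  invisible(path)
}
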