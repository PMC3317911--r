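#' Structure priors from genetic data
#'
#' Builds per-edge prior weights from three genetic sources, in order of
#' precedence:
#' \enumerate{
#'   \item cis/trans asymmetry: where a cis-linked gene and a trans-linked
#'     gene share a suggestive locus, the trans gene is forbidden from
#'     being a parent of the cis gene (weight 0); the reverse direction is
#'     allowed.
#'   \item causality-test reliabilities: for pairs with anchored causality
#'     calls, w(A -> B) = sum_l r_l(causal) / sum_l (all three), and
#'     w(B -> A) the reactive analogue; when independence dominates
#'     (neither ratio above 0.5) both are further shrunk by
#'     (1 - sum_l r_l(indep) / sum_l total).
#'   \item eQTL-signature complexity: remaining coincident pairs get
#'     w(A -> B) = n(B) / (n(A) + n(B)), where n(.) counts suggestive
#'     eQTLs (LOD > suggestive threshold) — the gene with the simpler
#'     signature is the likelier parent.
#' }
#' Two traits are coincident when their suggestive peaks fall in the same
#' genomic bin. All weights are clipped to [0.01, 1].
#'
#' @param qtl a classified \linkS4class{QTLTable}.
#' @param calls data.frame from \code{\link{causalBatch}} with bootstrap
#'   reliability columns; NULL to use sources (1) and (3) only.
#' @param lod_suggestive suggestive LOD threshold; default 2.8.
#' @param bin_bp coincidence bin width; default 20 kb.
#' @param default background weight for unlisted pairs.
#' @return a \linkS4class{PriorMatrix}.
#' @export
geneticPriors <- function(qtl, calls = NULL, lod_suggestive = 2.8,
                          bin_bp = 20000, default = 0.05) {
  r <- qtlRecords(qtl)
  if (!is.null(calls) && nrow(calls)) {
    bad <- setdiff(c(calls$trait1, calls$trait2), r$trait)
    if (length(bad))
      stopf("causality calls reference unknown trait(s): %s",
            paste(bad, collapse = ", "))
  }
  cp <- coincidentRecords(qtl, lod_suggestive, bin_bp)
  forb <- emptyEdges()
  coincident <- emptyEdges()
  for (i in seq_len(nrow(cp))) {
    c1 <- !is.na(cp$class1[i]) && cp$class1[i] == "cis"
    c2 <- !is.na(cp$class2[i]) && cp$class2[i] == "cis"
    # a trans-linked gene may not parent a cis-linked gene at this locus
    if (c1 && !c2)
      forb <- rbind(forb, data.frame(parent = cp$trait2[i],
                                     child = cp$trait1[i],
                                     stringsAsFactors = FALSE))
    if (c2 && !c1)
      forb <- rbind(forb, data.frame(parent = cp$trait1[i],
                                     child = cp$trait2[i],
                                     stringsAsFactors = FALSE))
    coincident <- rbind(coincident,
                        data.frame(parent = cp$trait1[i],
                                   child = cp$trait2[i],
                                   stringsAsFactors = FALSE))
  }
  forb <- unique(forb)
  sug <- qtlRecords(qtl)
  sug <- sug[sug$lod > lod_suggestive, , drop = FALSE]
  entries <- data.frame(parent = character(0), child = character(0),
                        weight = numeric(0), stringsAsFactors = FALSE)
  called <- character(0)
  if (!is.null(calls) && nrow(calls) &&
      all(c("r_causal", "r_reactive", "r_independent") %in% names(calls))) {
    a <- pmin(calls$trait1, calls$trait2)
    b <- pmax(calls$trait1, calls$trait2)
    flip <- calls$trait1 != a
    rc <- ifelse(flip, calls$r_reactive, calls$r_causal)
    rr <- ifelse(flip, calls$r_causal, calls$r_reactive)
    ri <- calls$r_independent
    for (key in unique(paste(a, b, sep = "\r"))) {
      i <- paste(a, b, sep = "\r") == key
      A <- a[which(i)[1L]]; B <- b[which(i)[1L]]
      tot <- sum(rc[i] + rr[i] + ri[i])
      if (tot <= 0) next
      wAB <- sum(rc[i]) / tot
      wBA <- sum(rr[i]) / tot
      indep <- sum(ri[i]) / tot
      if (max(wAB, wBA) <= 0.5) {          # independence-dominant pair
        wAB <- wAB * (1 - indep)
        wBA <- wBA * (1 - indep)
      }
      entries <- rbind(entries, data.frame(
        parent = c(A, B), child = c(B, A),
        weight = pmin(1, pmax(0.01, c(wAB, wBA))),
        stringsAsFactors = FALSE))
      called <- c(called, key)
    }
  }
  if (nrow(coincident)) {
    nq <- table(sug$trait)  # suggestive eQTL count per trait
    coincident <- unique(coincident)
    rest <- coincident[!pairKey(pmin(coincident$parent, coincident$child),
                                pmax(coincident$parent, coincident$child))
                       %in% called, , drop = FALSE]
    for (i in seq_len(nrow(rest))) {
      A <- rest$parent[i]; B <- rest$child[i]
      nA <- as.integer(nq[A]); nB <- as.integer(nq[B])
      entries <- rbind(entries, data.frame(
        parent = c(A, B), child = c(B, A),
        weight = pmin(1, pmax(0.01, c(nB, nA) / (nA + nB))),
        stringsAsFactors = FALSE))
    }
  }
  if (nrow(entries)) {
    # precedence within this source: first writer (reliability) wins
    entries <- entries[!duplicated(pairKey(entries$parent, entries$child)), ,
                       drop = FALSE]
    entries <- entries[!pairKey(entries$parent, entries$child) %in%
                         pairKey(forb$parent, forb$child), , drop = FALSE]
  }
  priorMatrix(entries, forb, default)
}

#' Scale-free structure priors from TF binding sites
#'
#' The prior weight of TF -> target edges is proportional to the number
#' of that TF's predicted targets whose expression correlates with the TF
#' beyond a permutation-derived cutoff. The cutoff r0 is the
#' (1 - p_cut) quantile of the per-permutation maximum absolute Pearson
#' correlation between TFs and row-permuted targets. TFs with no
#' correlated target contribute no prior entries.
#'
#' @param expr a \linkS4class{TraitMatrix} containing the TF traits.
#' @param tfbs named list: TF id -> character vector of target gene ids.
#' @param p_cut tail probability for the correlation cutoff; default 0.01.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @param w_max weight given to the TF with the most correlated targets.
#' @param default background weight of the returned PriorMatrix.
#' @return a \linkS4class{PriorMatrix} with attribute \code{r0}.
#' @export
tfPrior <- function(expr, tfbs, p_cut = 0.01, n_perm = 100, seed = 1,
                    w_max = 0.9, default = 0.05) {
  Y <- traitValues(expr)
  keep <- list()
  for (tf in names(tfbs)) {
    if (length(tfbs[[tf]]) == 0L) {
      warning(sprintf("TF %s has no targets; skipped", tf), call. = FALSE)
      next
    }
    if (!tf %in% colnames(Y)) next
    tg <- setdiff(intersect(tfbs[[tf]], colnames(Y)), tf)
    if (length(tg)) keep[[tf]] <- tg
  }
  if (length(keep) == 0L) return(priorMatrix(default = default))
  tfs <- names(keep)
  r0 <- withSeed(seed, {
    mx <- numeric(n_perm)
    n <- nrow(Y)
    for (b in seq_len(n_perm)) {
      Yp <- Y[sample.int(n), , drop = FALSE]
      mx[b] <- max(vapply(tfs, function(tf)
        max(abs(cor(Y[, tf], Yp[, keep[[tf]], drop = FALSE]))), 0))
    }
    as.numeric(quantile(mx, 1 - p_cut))
  })
  cc <- vapply(tfs, function(tf)
    sum(abs(cor(Y[, tf], Y[, keep[[tf]], drop = FALSE])) >= r0), 0L)
  if (all(cc == 0L)) {
    out <- priorMatrix(default = default)
    attr(out, "r0") <- r0
    return(out)
  }
  entries <- do.call(rbind, lapply(tfs[cc > 0L], function(tf)
    data.frame(parent = tf, child = keep[[tf]],
               weight = w_max * cc[[tf]] / max(cc),
               stringsAsFactors = FALSE)))
  out <- priorMatrix(entries, default = default)
  attr(out, "r0") <- r0
  out
}

#' Pick a representative gene for an unmodelled TF
#'
#' When a TF itself is not in the network, a gene from its responding set
#' stands in for its activity: responding genes are ranked by the number
#' of other set members they are called causal for; among the top five,
#' the gene with the highest LOD at the set's shared locus (the modal
#' peak bin of the set) is returned.
#'
#' @param responding character vector of responding gene ids.
#' @param calls data.frame from \code{\link{causalBatch}}.
#' @param qtl a \linkS4class{QTLTable} with peak records for the genes.
#' @param bin_bp bin width used to define the shared locus.
#' @return a single gene id.
#' @export
selectTfRepresentative <- function(responding, calls, qtl,
                                   bin_bp = 20000) {
  if (length(responding) == 0L) stopf("responding set is empty")
  nCausal <- vapply(responding, function(g) {
    sum((calls$model == "causal" & calls$trait1 == g &
           calls$trait2 %in% responding) |
        (calls$model == "reactive" & calls$trait2 == g &
           calls$trait1 %in% responding))
  }, 0L)
  ranked <- responding[order(-nCausal)]
  top <- head(ranked, 5L)
  r <- qtlRecords(qtl)
  r <- r[r$trait %in% responding, , drop = FALSE]
  peaks <- r[order(r$trait, -r$lod), , drop = FALSE]
  peaks <- peaks[!duplicated(peaks$trait), , drop = FALSE]  # per-gene top
  bin <- paste(peaks$chrom, floor((peaks$pos_bp - 1) / bin_bp))
  tb <- sort(table(bin), decreasing = TRUE)
  if (length(tb) == 0L || tb[1L] < 2L) {
    warning("no shared locus among responding genes; using causal rank",
            call. = FALSE)
    return(top[1L])
  }
  shared <- names(tb)[1L]
  lodAt <- vapply(top, function(g) {
    rows <- r[r$trait == g &
                paste(r$chrom, floor((r$pos_bp - 1) / bin_bp)) == shared, ,
              drop = FALSE]
    if (nrow(rows)) max(rows$lod) else 0
  }, 0)
  top[which.max(lodAt)]
}

#' Protein complexes by k-clique percolation
#'
#' Communities are maximal unions of k-cliques that can be reached from
#' one another through k-cliques sharing k - 1 nodes (clique percolation).
#'
#' @param ppi_edges two-column data.frame or matrix of undirected PPI
#'   edges.
#' @param k clique size (>= 3).
#' @return list of character vectors (one per community).
#' @examples
#' e <- t(combn(letters[1:4], 2))      # a 4-clique
#' cliqueComplexes(e, k = 3)
#' @export
cliqueComplexes <- function(ppi_edges, k = 3) {
  if (k < 3) stopf("k must be >= 3")
  ed <- as.data.frame(ppi_edges, stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(ed[, 1:2], directed = FALSE)
  g <- igraph::simplify(g)
  cl <- igraph::max_cliques(g, min = k)
  if (length(cl) == 0L) return(list())
  cl <- lapply(cl, function(x) sort(names(x)))
  m <- length(cl)
  adj <- matrix(FALSE, m, m)
  for (i in seq_len(m)) for (j in seq_len(i)) {
    if (i == j) { adj[i, j] <- TRUE; next }
    if (length(intersect(cl[[i]], cl[[j]])) >= k - 1L)
      adj[i, j] <- adj[j, i] <- TRUE
  }
  og <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(og)$membership
  out <- lapply(split(seq_len(m), comp), function(ix)
    sort(unique(unlist(cl[ix]))))
  unname(out)
}

#' Extend TFBS target sets through protein complexes
#'
#' If at least half the members of a complex carry a given TF's binding
#' site, every member of the complex is added to that TF's target set.
#'
#' @param complexes list of character vectors (each of length >= 2).
#' @param tfbs named list: TF id -> target gene ids.
#' @return the augmented tfbs list.
#' @export
complexTfbsAugment <- function(complexes, tfbs) {
  for (tf in names(tfbs)) {
    for (cx in complexes) {
      if (sum(cx %in% tfbs[[tf]]) >= length(cx) / 2)
        tfbs[[tf]] <- sort(union(tfbs[[tf]], cx))
    }
  }
  tfbs
}

#' Uniform within-complex priors
#'
#' Every ordered pair of genes inside a complex receives the same weight,
#' used for complexes whose TFs could not be integrated through the
#' scale-free TF prior.
#'
#' @param complexes list of character vectors.
#' @param w_u the uniform weight in (0, 1]; default 0.5.
#' @param default background weight of the returned PriorMatrix.
#' @return a \linkS4class{PriorMatrix}.
#' @export
complexUniformPriors <- function(complexes, w_u = 0.5, default = 0.05) {
  if (w_u <= 0 || w_u > 1) stopf("w_u must lie in (0, 1]")
  rows <- list()
  for (cx in complexes) {
    if (length(cx) < 2L) next
    pr <- expand.grid(parent = cx, child = cx, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- pr[pr$parent != pr$child, , drop = FALSE]
  }
  if (length(rows) == 0L) return(priorMatrix(default = default))
  e <- unique(do.call(rbind, rows))
  e$weight <- w_u
  priorMatrix(e, default = default)
}

#' Merge prior sources
#'
#' Per directed pair the merged weight is the maximum across sources;
#' forbidden pairs (genetic exclusions) dominate and stay 0 regardless of
#' any positive weight elsewhere.
#'
#' @param sources list of \linkS4class{PriorMatrix} objects.
#' @param default background weight of the merged matrix.
#' @return a \linkS4class{PriorMatrix}.
#' @export
mergePriors <- function(sources, default = 0.05) {
  stopifnot(length(sources) > 0L,
            all(vapply(sources, is, TRUE, "PriorMatrix")))
  forb <- unique(do.call(rbind, lapply(sources, priorForbidden)))
  ent <- do.call(rbind, lapply(sources, priorEntries))
  if (nrow(ent)) {
    key <- pairKey(ent$parent, ent$child)
    mx <- tapply(ent$weight, key, max)
    first <- !duplicated(key)
    ent <- ent[first, , drop = FALSE]
    ent$weight <- as.numeric(mx[pairKey(ent$parent, ent$child)])
    dropped <- pairKey(ent$parent, ent$child) %in%
      pairKey(forb$parent, forb$child)
    if (any(dropped))
      message(sprintf("%d prior entr%s overridden by genetic exclusions",
                      sum(dropped), if (sum(dropped) == 1) "y" else "ies"))
    ent <- ent[!dropped, , drop = FALSE]
  }
  priorMatrix(ent, forb, default)
}
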