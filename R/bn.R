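# Precomputed scoring context: centred cross-products of all candidate
# columns (traits, optionally genotype anchors), so that any local
# Gaussian score reduces to solving a tiny linear system.
scoreContext <- function(traits, geno = NULL, priors = NULL, penalty = 1) {
  X <- traitValues(traits)
  if (!is.null(geno)) {
    al <- alignSegregants(traits, geno)
    X <- cbind(al$Y, al$G)
  }
  n <- nrow(X)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  S <- crossprod(Xc)
  p <- ncol(X)
  logW <- matrix(0, p, p, dimnames = list(colnames(X), colnames(X)))
  if (!is.null(priors)) {
    w <- matrix(priorDefault(priors), p, p)
    e <- priorEntries(priors)
    if (nrow(e)) {
      i <- match(e$parent, colnames(X)); j <- match(e$child, colnames(X))
      ok <- !is.na(i) & !is.na(j)
      w[cbind(i[ok], j[ok])] <- e$weight[ok]
    }
    f <- priorForbidden(priors)
    if (nrow(f)) {
      i <- match(f$parent, colnames(X)); j <- match(f$child, colnames(X))
      ok <- !is.na(i) & !is.na(j)
      w[cbind(i[ok], j[ok])] <- 0
    }
    logW <- log(w)
  }
  nTraits <- ncol(traitValues(traits))
  list(S = S, n = n, p = p, logW = logW, penalty = penalty,
      names = colnames(X), nTraits = nTraits)
}

# Gaussian local score of child on a parent index set, from the context:
# log-likelihood at the MLE  -  (penalty/2) * k * ln n  +  sum log prior.
# The explained sum of squares S_cP S_PP^-1 S_Pc is expanded in closed
# form for up to two parents; larger sets use solve() with a ridge
# fallback for collinear designs.
localScoreCtx <- function(ctx, child, parents) {
  S <- ctx$S; n <- ctx$n
  np <- length(parents)
  rss <- S[child, child]
  if (np == 1L) {
    rss <- rss - S[parents, child]^2 / S[parents, parents]
  } else if (np == 2L) {
    a <- S[parents[1L], parents[1L]]; b <- S[parents[1L], parents[2L]]
    d <- S[parents[2L], parents[2L]]
    u <- S[parents[1L], child]; v <- S[parents[2L], child]
    det <- a * d - b * b
    if (det > 1e-12 * a * d)
      rss <- rss - (d * u * u - 2 * b * u * v + a * v * v) / det
    else {
      warning("collinear parents; ridge fallback", call. = FALSE)
      rss <- rss - (d * u * u - 2 * b * u * v + a * v * v) /
        (det + 1e-8 * a * d)
    }
  } else if (np >= 3L) {
    Spp <- S[parents, parents, drop = FALSE]
    spc <- S[parents, child]
    bb <- tryCatch(solve(Spp, spc), error = function(e) {
      warning("collinear parents; ridge fallback", call. = FALSE)
      solve(Spp + diag(1e-8 * mean(diag(Spp)), nrow(Spp)), spc)
    })
    rss <- rss - sum(spc * bb)
  }
  rss <- max(rss, .Machine$double.xmin)
  ll <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
  k <- np + 2                       # intercept/means + slopes + variance
  pri <- if (np) sum(ctx$logW[parents, child]) else 0
  ll - ctx$penalty / 2 * k * log(n) + pri
}

#' Local network score of one node given its parents
#'
#' The score of a child node is the log-likelihood of a linear-Gaussian
#' model of the child trait on its parent traits (genotype parents enter
#' as 0/1 class indicators), minus the BIC penalty (penalty/2) * k * ln n
#' with k = number of parents + 2, plus the sum of log structure-prior
#' weights of the incoming edges. A forbidden parent (prior weight 0)
#' yields -Inf. The total network score is the sum over nodes.
#'
#' @param child trait id.
#' @param parents character vector of parent ids (traits or markers).
#' @param traits a \linkS4class{TraitMatrix}.
#' @param geno optional \linkS4class{GenotypeMatrix} supplying marker
#'   parents.
#' @param priors optional \linkS4class{PriorMatrix}.
#' @param penalty multiplier on the BIC penalty; default 1.
#' @return numeric score (higher is better).
#' @export
localScore <- function(child, parents = character(0), traits, geno = NULL,
                       priors = NULL, penalty = 1) {
  if (child %in% parents) stopf("child cannot be its own parent")
  ctx <- scoreContext(traits, geno, priors, penalty)
  ci <- match(child, ctx$names)
  pi <- match(parents, ctx$names)
  if (is.na(ci) || anyNA(pi)) stopf("unknown child or parent id")
  localScoreCtx(ctx, ci, pi)
}

# does a directed path run from `from` to `to` in the children list?
hasPath <- function(children, from, to) {
  if (from == to) return(TRUE)
  seen <- logical(length(children))
  stack <- from
  while (length(stack)) {
    v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    if (v == to) return(TRUE)
    if (seen[v]) next
    seen[v] <- TRUE
    kids <- children[[v]]
    if (length(kids)) stack <- c(stack, kids[!seen[kids]])
  }
  FALSE
}

#' Greedy stochastic structure search
#'
#' Starts from the empty graph and repeatedly proposes a uniformly random
#' single-edge change — an addition for an absent ordered pair, a
#' deletion or reversal (equal odds) for a present edge — accepting a
#' proposal only when it keeps the graph acyclic, respects the parent
#' limit and forbidden edges, and improves the total score. Additions and
#' deletions must improve strictly; reversals are also accepted when
#' score-neutral, so the chain can walk across Markov-equivalent
#' orientations (whose scores tie exactly) and still reach strictly
#' better structures such as v-structures, with structure priors free to
#' break the ties. Deterministic given the seed. An optional
#' simulated-annealing temperature (default 0 = off) allows occasional
#' score-decreasing moves early in the run.
#'
#' @param traits a \linkS4class{TraitMatrix}.
#' @param priors optional \linkS4class{PriorMatrix}.
#' @param seed integer seed.
#' @param n_iter number of proposals (>= 1).
#' @param max_parents parent limit per node; default 3.
#' @param penalty BIC penalty multiplier; default 1.
#' @param temperature initial annealing temperature; 0 disables.
#' @return a \linkS4class{DAGModel}.
#' @export
bnSearch <- function(traits, priors = NULL, seed = 1, n_iter = 20000,
                     max_parents = 3, penalty = 1, temperature = 0) {
  if (n_iter < 1) stopf("n_iter must be >= 1")
  ctx <- scoreContext(traits, NULL, priors, penalty)
  p <- ctx$nTraits
  if (p < 2) stopf("need at least two traits")
  cache <- new.env(parent = emptyenv(), hash = TRUE)
  # parent sets are cached under child * 2^p + bitmask(parents), which is
  # exact in doubles up to p = 45 nodes; larger problems use string keys
  useMask <- p <= 45
  pow2 <- if (useMask) 2^(seq_len(p) - 1) else rep(0, p)
  sc <- function(child, parents, mask) {
    key <- if (useMask) as.character(child * 2^p + mask) else
      paste0(child, "|", paste(sort(parents), collapse = ","))
    v <- cache[[key]]
    if (is.null(v)) {
      v <- localScoreCtx(ctx, child, parents)
      cache[[key]] <- v
    }
    v
  }
  withSeed(seed, {
    parents <- rep(list(integer(0)), p)
    mask <- numeric(p)
    children <- rep(list(integer(0)), p)
    local <- vapply(seq_len(p), function(j) sc(j, integer(0), 0), 0)
    pairI <- sample.int(p, n_iter, replace = TRUE)
    pairJ <- sample.int(p - 1L, n_iter, replace = TRUE)
    coin <- runif(n_iter)
    anneal <- runif(n_iter)
    for (it in seq_len(n_iter)) {
      i <- pairI[it]
      j <- pairJ[it]
      if (j >= i) j <- j + 1L             # uniform ordered pair i != j
      temp <- if (temperature > 0) temperature * (1 - it / n_iter) else 0
      present <- i %in% parents[[j]]
      if (!present) {                      # propose add i -> j
        if (length(parents[[j]]) >= max_parents) next
        if (ctx$logW[i, j] == -Inf) next
        newp <- c(parents[[j]], i)
        newm <- mask[j] + pow2[i]
        news <- sc(j, newp, newm)
        delta <- news - local[j]
        if (delta > 1e-10 ||
            (temp > 0 && anneal[it] < exp(delta / temp))) {
          if (hasPath(children, j, i)) next  # would close a cycle
          parents[[j]] <- newp
          mask[j] <- newm
          children[[i]] <- c(children[[i]], j)
          local[j] <- news
        }
      } else if (coin[it] < 0.5) {         # propose delete i -> j
        newp <- parents[[j]][parents[[j]] != i]
        newm <- mask[j] - pow2[i]
        news <- sc(j, newp, newm)
        delta <- news - local[j]
        if (delta > 1e-10 ||
            (temp > 0 && anneal[it] < exp(delta / temp))) {
          parents[[j]] <- newp
          mask[j] <- newm
          children[[i]] <- children[[i]][children[[i]] != j]
          local[j] <- news
        }
      } else {                             # propose reverse i -> j
        if (length(parents[[i]]) >= max_parents) next
        if (ctx$logW[j, i] == -Inf) next
        newpj <- parents[[j]][parents[[j]] != i]
        newpi <- c(parents[[i]], j)
        newmj <- mask[j] - pow2[i]
        newmi <- mask[i] + pow2[j]
        newsj <- sc(j, newpj, newmj)
        newsi <- sc(i, newpi, newmi)
        delta <- (newsj - local[j]) + (newsi - local[i])
        # score-neutral reversals are accepted: they walk within a
        # Markov-equivalence class so that strictly improving exits
        # (e.g. into a v-structure) stay reachable
        if (delta > -1e-9 ||
            (temp > 0 && anneal[it] < exp(delta / temp))) {
          kidsI <- children[[i]][children[[i]] != j]
          children[[i]] <- kidsI
          cyc <- hasPath(children, i, j)   # other path i ~> j remains?
          children[[i]] <- c(kidsI, j)
          if (cyc) next
          parents[[j]] <- newpj
          parents[[i]] <- newpi
          mask[j] <- newmj
          mask[i] <- newmi
          children[[i]] <- kidsI
          children[[j]] <- c(children[[j]], i)
          local[j] <- newsj
          local[i] <- newsi
        }
      }
    }
    nm <- ctx$names[seq_len(p)]
    ed <- do.call(rbind, lapply(seq_len(p), function(j) {
      if (length(parents[[j]]) == 0L) return(NULL)
      data.frame(parent = nm[parents[[j]]], child = nm[j],
                 stringsAsFactors = FALSE)
    }))
    if (is.null(ed)) ed <- emptyEdges()
    new("DAGModel", nodes = nm, edges = ed, score = sum(local),
        localScores = setNames(local, nm))
  })
}

#' Ensemble of independently learned networks
#'
#' Repeats \code{\link{bnSearch}} with seeds base_seed + 1 ... base_seed
#' + n_runs; runs share no mutable state.
#'
#' @param traits a \linkS4class{TraitMatrix}.
#' @param priors optional \linkS4class{PriorMatrix}.
#' @param n_runs number of runs (>= 2).
#' @param n_iter proposals per run.
#' @param base_seed integer; run i uses seed base_seed + i.
#' @param ... further arguments to \code{\link{bnSearch}}.
#' @return list of \linkS4class{DAGModel}.
#' @export
bnEnsemble <- function(traits, priors = NULL, n_runs = 1000,
                       n_iter = 20000, base_seed = 0, ...) {
  if (n_runs < 2) stopf("n_runs must be >= 2")
  lapply(seq_len(n_runs), function(i)
    bnSearch(traits, priors, seed = base_seed + i, n_iter = n_iter, ...))
}

#' Consensus network from an ensemble
#'
#' Keeps the directed edges appearing in strictly more than
#' \code{cutoff} of the ensemble networks (default 30\%), annotated with
#' their frequency.
#'
#' @param dags non-empty list of \linkS4class{DAGModel}.
#' @param cutoff frequency cutoff in (0, 1); strict inequality.
#' @return a \linkS4class{ConsensusNetwork}.
#' @export
consensusNetwork <- function(dags, cutoff = 0.30) {
  if (length(dags) == 0L) stopf("empty ensemble")
  if (cutoff <= 0 || cutoff >= 1) stopf("cutoff must lie in (0, 1)")
  nodes <- nodeIds(dags[[1L]])
  all <- do.call(rbind, lapply(dags, edgeTable))
  if (is.null(all) || nrow(all) == 0L)
    return(new("ConsensusNetwork", nodes = nodes, edges = cbind(
      emptyEdges(), data.frame(frequency = numeric(0))),
      nRuns = length(dags), cutoff = cutoff))
  key <- pairKey(all$parent, all$child)
  freq <- table(key) / length(dags)
  first <- all[!duplicated(key), , drop = FALSE]
  first$frequency <- as.numeric(freq[pairKey(first$parent, first$child)])
  keep <- first[first$frequency > cutoff, , drop = FALSE]
  keep <- keep[order(keep$parent, keep$child), , drop = FALSE]
  rownames(keep) <- NULL
  new("ConsensusNetwork", nodes = nodes, edges = keep,
      nRuns = length(dags), cutoff = cutoff)
}

# per-edge shortest-cycle lengths: 1 + BFS distance from the edge's
# child back to its parent (Inf when the edge lies on no cycle)
edgeCycleLengths <- function(edges) {
  nodes <- sort(unique(c(edges$parent, edges$child)))
  g <- igraph::graph_from_data_frame(edges[, c("parent", "child")],
                                     directed = TRUE, vertices = nodes)
  d <- igraph::distances(g, mode = "out")
  1 + d[cbind(edges$child, edges$parent)]
}

#' Remove cycles from a consensus network
#'
#' While any directed loop remains: the shortest loop length L is found;
#' among all edges lying on a loop of length L, the most weakly
#' supported one (minimum ensemble frequency, ties broken
#' lexicographically by parent then child id) is removed. The removed
#' edge is therefore always the weakest edge of the loop it sits on.
#' Edges not on any loop are never touched, so an acyclic input passes
#' through unchanged.
#'
#' @param net a \linkS4class{ConsensusNetwork}.
#' @return an acyclic \linkS4class{ConsensusNetwork}; removed edges are
#'   reported in attribute \code{removed}.
#' @export
breakCycles <- function(net) {
  ed <- edgeTable(net)
  removed <- ed[0, , drop = FALSE]
  while (nrow(ed)) {
    len <- edgeCycleLengths(ed)
    if (all(!is.finite(len))) break
    onShortest <- which(len == min(len))
    sub <- ed[onShortest, , drop = FALSE]
    weakest <- onShortest[order(sub$frequency, sub$parent, sub$child)][1L]
    removed <- rbind(removed, ed[weakest, , drop = FALSE])
    ed <- ed[-weakest, , drop = FALSE]
  }
  rownames(ed) <- NULL
  out <- new("ConsensusNetwork", nodes = nodeIds(net), edges = ed,
             nRuns = net@nRuns, cutoff = net@cutoff)
  attr(out, "removed") <- removed
  out
}
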