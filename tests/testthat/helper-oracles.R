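# Independent oracles used across the suite. Each reimplements the
# quantity it checks by a different route (numeric optimisation,
# exhaustive enumeration, BFS, term summation) so that agreement is
# informative.

# ---- likelihood oracles -------------------------------------------------

# -2 ln L of the three anchored models by direct numeric maximisation of
# the written Gaussian likelihoods (Nelder-Mead refined by BFGS), plus
# the BIC penalty. Parameters are optimised on the log-sigma scale.
oracleModelScores <- function(t1, t2, g) {
  n <- length(t1)
  polish <- function(f, par) {
    o <- optim(par, f, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
    o <- optim(o$par, f, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
    o$value
  }
  nllClass <- function(y) {
    f <- function(p) {
      mu <- ifelse(g == 1, p[2L], p[1L])
      -2 * sum(dnorm(y, mu, exp(p[3L]), log = TRUE))
    }
    polish(f, c(mean(y), mean(y), log(sd(y))))
  }
  nllOLS <- function(y, x) {
    f <- function(p) -2 * sum(dnorm(y, p[1L] + p[2L] * x, exp(p[3L]),
                                    log = TRUE))
    polish(f, c(mean(y), 0, log(sd(y))))
  }
  # M3 joint likelihood: both class-mean structures plus the pooled
  # residual slope; 7 free parameters optimised together.
  nllM3 <- function() {
    f <- function(p) {
      mu1 <- ifelse(g == 1, p[2L], p[1L])
      mu2 <- ifelse(g == 1, p[5L], p[4L])
      -2 * sum(dnorm(t1, mu1, exp(p[3L]), log = TRUE)) -
        2 * sum(dnorm(t2, mu2 + p[6L] * (t1 - mu1), exp(p[7L]),
                      log = TRUE))
    }
    polish(f, c(mean(t1), mean(t1), log(sd(t1)),
                mean(t2), mean(t2), 0, log(sd(t2))))
  }
  c(causal = nllClass(t1) + nllOLS(t2, t1) + 6 * log(n),
    reactive = nllClass(t2) + nllOLS(t1, t2) + 6 * log(n),
    independent = nllM3() + 7 * log(n))
}

# plain-loop RSS version of the LOD formula
oracleLod <- function(y, g) {
  n <- length(y)
  rss0 <- 0
  for (v in y) rss0 <- rss0 + (v - mean(y))^2
  rss1 <- 0
  for (cl in c(0, 1)) {
    yy <- y[g == cl]
    for (v in yy) rss1 <- rss1 + (v - mean(yy))^2
  }
  if (rss0 <= 0 || rss1 <= 0) return(0)
  (n / 2) * log10(rss0 / rss1)
}

# ---- graph oracles ------------------------------------------------------

# BFS all-pairs distances on the bipartite reaction graph
oracleBfsDistances <- function(graph) {
  e <- reactionEdges(graph)
  g <- igraph::graph_from_data_frame(e, directed = FALSE)
  d <- igraph::distances(g)
  d[order(rownames(d)), order(colnames(d)), drop = FALSE]
}

# exhaustive k-clique percolation: enumerate all k-cliques with combn,
# join those sharing k-1 nodes, take connected components
oracleCliquePercolation <- function(edges, k) {
  ed <- as.data.frame(edges, stringsAsFactors = FALSE)
  nodes <- sort(unique(c(ed[[1L]], ed[[2L]])))
  adj <- matrix(FALSE, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  adj[cbind(ed[[1L]], ed[[2L]])] <- TRUE
  adj <- adj | t(adj)
  if (length(nodes) < k) return(list())
  isClique <- function(s) all(adj[s, s] | diag(length(s)))
  kc <- Filter(isClique, combn(nodes, k, simplify = FALSE))
  if (length(kc) == 0L) return(list())
  m <- length(kc)
  link <- matrix(FALSE, m, m)
  for (i in seq_len(m)) for (j in seq_len(i))
    link[i, j] <- link[j, i] <-
      length(intersect(kc[[i]], kc[[j]])) >= k - 1L
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(link, mode = "undirected"))
  unname(lapply(split(seq_len(m), comp$membership), function(ix)
    sort(unique(unlist(kc[ix])))))
}

# same-rule loop removal implemented over exhaustive simple-cycle
# enumeration (recursive DFS), independent of the BFS-distance-based
# implementation: find every simple cycle, take the minimum length L,
# pool the edges of all length-L cycles, drop the weakest
# (frequency, then lexicographic) and repeat
oracleBreakCycles <- function(edges) {
  allCycles <- function(ed) {
    nodes <- sort(unique(c(ed$parent, ed$child)))
    kids <- split(ed$child, ed$parent)
    cycles <- list()
    walk <- function(path) {
      v <- path[length(path)]
      for (w in sort(kids[[v]])) {
        if (w == path[1L]) {
          cycles[[length(cycles) + 1L]] <<- path
        } else if (!w %in% path && w > path[1L]) {
          # only enumerate cycles from their smallest node
          walk(c(path, w))
        }
      }
    }
    for (v in nodes) walk(v)
    cycles
  }
  repeat {
    cyc <- allCycles(edges)
    if (length(cyc) == 0L) return(edges)
    len <- vapply(cyc, length, 0L)
    shortest <- cyc[len == min(len)]
    rowsOf <- function(path) {
      p <- c(path, path[1L])
      vapply(seq_len(length(p) - 1L), function(s)
        which(edges$parent == p[s] & edges$child == p[s + 1L]), 0L)
    }
    pool <- sort(unique(unlist(lapply(shortest, rowsOf))))
    sub <- edges[pool, ]
    drop <- pool[order(sub$frequency, sub$parent, sub$child)][1L]
    edges <- edges[-drop, , drop = FALSE]
  }
}

# hypergeometric upper tail by term summation
oracleHyperTail <- function(k, m, n, q) {
  tot <- 0
  for (x in k:min(m, q)) tot <- tot + dhyper(x, m, n, q)
  tot
}

# ---- random structures --------------------------------------------------

randomDag <- function(nNodes, pEdge, seed) {
  withr::with_seed(seed, {
    nodes <- sprintf("n%02d", seq_len(nNodes))
    ed <- NULL
    for (i in seq_len(nNodes - 1L)) for (j in (i + 1L):nNodes)
      if (runif(1) < pEdge)
        ed <- rbind(ed, data.frame(parent = nodes[i], child = nodes[j],
                                   stringsAsFactors = FALSE))
    if (is.null(ed)) ed <- data.frame(parent = character(0),
                                      child = character(0),
                                      stringsAsFactors = FALSE)
    list(nodes = nodes, edges = ed)
  })
}

randomConsensus <- function(nNodes, nEdges, seed) {
  withr::with_seed(seed, {
    nodes <- sprintf("n%02d", seq_len(nNodes))
    pairs <- expand.grid(parent = nodes, child = nodes,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$parent != pairs$child, ]
    pick <- pairs[sample.int(nrow(pairs), min(nEdges, nrow(pairs))), ]
    pick$frequency <- round(runif(nrow(pick), 0.31, 1), 2)
    rownames(pick) <- NULL
    new("ConsensusNetwork", nodes = nodes, edges = pick,
        nRuns = 100L, cutoff = 0.3)
  })
}

isAcyclicEdges <- function(edges, nodes) {
  g <- igraph::graph_from_data_frame(edges[, c("parent", "child")],
                                     directed = TRUE, vertices = nodes)
  igraph::is_dag(g)
}

skeletonKey <- function(parent, child)
  paste(pmin(parent, child), pmax(parent, child), sep = "\r")

directedKey <- function(parent, child) paste(parent, child, sep = "\r")
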