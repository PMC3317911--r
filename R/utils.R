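# internal helpers shared across modules

# Kahn topological sort over node labels; returns NULL if the directed
# edge set (data.frame parent, child) contains a cycle.
topoOrder <- function(nodes, edges) {
  nodes <- as.character(nodes)
  if (is.null(edges) || nrow(edges) == 0L) return(nodes)
  parent <- as.character(edges$parent)
  child <- as.character(edges$child)
  indeg <- setNames(integer(length(nodes)), nodes)
  tab <- table(child)
  indeg[names(tab)] <- as.integer(tab)
  kids <- split(child, parent)
  queue <- nodes[indeg == 0L]
  out <- character(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    out <- c(out, v)
    for (w in kids[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(out) != length(nodes)) NULL else out
}

# Evaluate expr under a locally seeded RNG, leaving global state untouched.
withSeed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

# derive a distinct, bounded child seed from a base seed and an index
childSeed <- function(seed, i) {
  as.integer((as.double(seed) * 1103L + i * 7919L) %% 2147483629)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

pairKey <- function(parent, child) paste(parent, child, sep = "\r")

emptyEdges <- function() data.frame(parent = character(0),
                                    child = character(0),
                                    stringsAsFactors = FALSE)
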