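mkQtl <- function(df) {
  base <- data.frame(mu0 = 0, mu1 = 1, n_used = 100L,
                     stringsAsFactors = FALSE)
  new("QTLTable", records = cbind(df, base), params = list())
}

test_that("trans genes are forbidden as parents of coincident cis genes", {
  q <- mkQtl(data.frame(
    trait = c("A", "B"), marker = c("m1", "m2"), chrom = "chr1",
    pos_bp = c(100000, 110000), lod = c(5, 4),
    class = c("cis", "trans"), stringsAsFactors = FALSE))
  pm <- geneticPriors(q)
  expect_identical(priorWeight(pm, "B", "A"), 0)
  expect_gt(priorWeight(pm, "A", "B"), priorDefault(pm))
})

test_that("reliability sums give the documented weights", {
  q <- mkQtl(data.frame(
    trait = c("A", "B"), marker = c("m1", "m1"), chrom = "chr1",
    pos_bp = c(100000, 100000), lod = c(5, 4),
    class = c("trans", "trans"), stringsAsFactors = FALSE))
  calls <- data.frame(trait1 = "A", trait2 = "B", marker = "m1",
                      model = "causal", r_causal = 0.8, r_reactive = 0.1,
                      r_independent = 0.1, stringsAsFactors = FALSE)
  pm <- geneticPriors(q, calls)
  expect_equal(priorWeight(pm, "A", "B"), 0.8)
  expect_equal(priorWeight(pm, "B", "A"), 0.1)
  # independence-dominant: both directions shrunk by (1 - indep share)
  calls2 <- transform(calls, model = "independent", r_causal = 0.2,
                      r_reactive = 0.2, r_independent = 0.6)
  pm2 <- geneticPriors(q, calls2)
  expect_equal(priorWeight(pm2, "A", "B"), 0.2 * (1 - 0.6))
  expect_equal(priorWeight(pm2, "B", "A"), 0.2 * (1 - 0.6))
  bad <- transform(calls, trait1 = "Z")
  expect_error(geneticPriors(q, bad), "unknown trait")
})

test_that("equal eQTL counts give the symmetric complexity weight", {
  q <- mkQtl(data.frame(
    trait = c("A", "B"), marker = c("m1", "m1"), chrom = "chr1",
    pos_bp = c(100000, 100000), lod = c(5, 4),
    class = c("trans", "trans"), stringsAsFactors = FALSE))
  pm <- geneticPriors(q)
  expect_equal(priorWeight(pm, "A", "B"), 0.5)
  expect_equal(priorWeight(pm, "B", "A"), 0.5)
})

test_that("TF priors are proportional to correlated-target counts", {
  withr::with_seed(41, {
    n <- 100
    tf1 <- rnorm(n); tf2 <- rnorm(n)
    Y <- cbind(TF1 = tf1, TF2 = tf2,
               vapply(1:10, function(i) tf1 + rnorm(n, 0, 0.3),
                      numeric(n)),
               vapply(1:5, function(i) tf2 + rnorm(n, 0, 0.3),
                      numeric(n)),
               vapply(1:5, function(i) rnorm(n), numeric(n)))
    colnames(Y) <- c("TF1", "TF2", sprintf("a%02d", 1:10),
                     sprintf("b%02d", 1:5), sprintf("z%02d", 1:5))
    rownames(Y) <- sprintf("s%03d", 1:n)
  })
  expr <- traitMatrix(Y)
  tfbs <- list(TF1 = sprintf("a%02d", 1:10), TF2 = sprintf("b%02d", 1:5))
  pm <- tfPrior(expr, tfbs, n_perm = 100, seed = 2)
  w1 <- priorWeight(pm, "TF1", "a01")
  w2 <- priorWeight(pm, "TF2", "b01")
  expect_equal(w1, 0.9)            # the richer TF anchors at w_max
  expect_equal(w1 / w2, 2)         # 10 vs 5 correlated targets
  # cutoff reproduces under an independent permutation recomputation
  r0 <- attr(pm, "r0")
  oracle <- withr::with_seed(2, {
    mx <- numeric(100)
    for (b in 1:100) {
      idx <- sample.int(n)
      best <- 0
      for (tf in names(tfbs)) for (tg in tfbs[[tf]])
        best <- max(best, abs(cor(Y[, tf], Y[idx, tg])))
      mx[b] <- best
    }
    quantile(mx, 0.99)
  })
  expect_equal(r0, as.numeric(oracle), tolerance = 1e-12)
})

test_that("uncorrelated TFs contribute no prior entries", {
  withr::with_seed(43, {
    Y <- matrix(rnorm(100 * 6), 100, 6,
                dimnames = list(sprintf("s%d", 1:100),
                                c("TF", sprintf("t%d", 1:5))))
  })
  pm <- tfPrior(traitMatrix(Y), list(TF = sprintf("t%d", 1:5)),
                n_perm = 100, seed = 3)
  expect_identical(nrow(priorEntries(pm)), 0L)
  expect_warning(
    tfPrior(traitMatrix(Y), list(TF = character(0)), n_perm = 100,
            seed = 3), "no targets")
})

test_that("the TF representative follows causal rank then LOD", {
  genes <- sprintf("g%d", 1:6)
  calls <- data.frame(trait1 = "g1", trait2 = sprintf("g%d", 2:5),
                      marker = "m1", model = "causal",
                      stringsAsFactors = FALSE)
  q <- mkQtl(data.frame(trait = genes, marker = "m1", chrom = "chr1",
                        pos_bp = 50000, lod = c(4, 3, 3, 3, 3, 3),
                        class = "trans", stringsAsFactors = FALSE))
  expect_identical(selectTfRepresentative(genes, calls, q), "g1")
  # tie in causal counts: g1 and g2 each causal for two; g2 has the
  # higher LOD at the shared locus
  calls2 <- data.frame(trait1 = c("g1", "g1", "g2", "g2"),
                       trait2 = c("g3", "g4", "g5", "g6"),
                       marker = "m1", model = "causal",
                       stringsAsFactors = FALSE)
  q2 <- mkQtl(data.frame(trait = genes, marker = "m1", chrom = "chr1",
                         pos_bp = 50000, lod = c(3, 7, 2, 2, 2, 2),
                         class = "trans", stringsAsFactors = FALSE))
  expect_identical(selectTfRepresentative(genes, calls2, q2), "g2")
})

test_that("a planted driver is recovered as the representative", {
  map <- uniformMap(1, 10, 20000)
  L <- markerIds(map)[5L]
  hits <- vapply(1:50, function(s) {
    geno <- simulateGenotypes(120, map, seed = 6000 + s)
    truth <- groundTruthNetwork(
      c("D", sprintf("R%d", 1:5)),
      edges = data.frame(parent = "D", child = sprintf("R%d", 1:5),
                         beta = 1),
      loci = data.frame(trait = "D", marker = L, a = 1.5),
      noise_sd = 1)
    traits <- simulateTraits(geno, truth, seed = 7000 + s)
    q <- classifyQTL(genomeScan(traits, geno), traits)
    set <- c("D", sprintf("R%d", 1:5))
    pairs <- as.data.frame(t(combn(set, 2)), stringsAsFactors = FALSE)
    names(pairs) <- c("trait1", "trait2")
    pairs$marker <- L
    calls <- causalBatch(traits, geno, pairs, n_boot = 0)
    selectTfRepresentative(set, calls, q) == "D"
  }, TRUE)
  expect_gte(mean(hits), 0.8)
})

test_that("clique percolation matches containment and overlap rules", {
  four <- t(combn(c("a", "b", "c", "d"), 2))
  expect_identical(cliqueComplexes(four, k = 3), list(c("a", "b", "c", "d")))
  twoTri <- rbind(t(combn(c("a", "b", "c"), 2)),
                  t(combn(c("c", "d", "e"), 2)))
  out <- cliqueComplexes(twoTri, k = 3)
  expect_identical(length(out), 2L)
  expect_true(list(c("a", "b", "c")) %in% out && list(c("c", "d", "e")) %in% out)
  expect_error(cliqueComplexes(four, k = 2), "k must be")
})

test_that("clique percolation equals exhaustive enumeration on random graphs", {
  for (s in 1:15) {
    withr::with_seed(800 + s, {
      n <- sample(8:20, 1)
      nodes <- sprintf("v%02d", 1:n)
      pairs <- t(combn(nodes, 2))
      ed <- pairs[runif(nrow(pairs)) < 0.25, , drop = FALSE]
    })
    if (nrow(ed) < 3) next
    got <- cliqueComplexes(ed, k = 3)
    want <- oracleCliquePercolation(ed, 3)
    norm <- function(l) l[order(vapply(l, paste, "", collapse = ","))]
    expect_identical(norm(got), norm(want))
  }
})

test_that("complex membership extends TFBS sets at half occupancy", {
  tfbs <- list(TF = c("a", "b", "x"))
  expect_identical(
    sort(complexTfbsAugment(list(c("a", "b", "c", "d")), tfbs)$TF),
    sort(c("a", "b", "c", "d", "x")))        # 2 of 4 = half: extended
  expect_identical(
    complexTfbsAugment(list(c("a", "p", "q", "r")), tfbs)$TF,
    c("a", "b", "x"))                        # 1 of 4: unchanged
  expect_identical(
    sort(complexTfbsAugment(list(c("a", "b", "e")), tfbs)$TF),
    sort(c("a", "b", "e", "x")))             # 2 of 3: extended
})

test_that("uniform complex priors cover all ordered pairs", {
  pm <- complexUniformPriors(list(c("a", "b")), w_u = 0.5)
  expect_equal(priorWeight(pm, "a", "b"), 0.5)
  expect_equal(priorWeight(pm, "b", "a"), 0.5)
  pm3 <- complexUniformPriors(list(c("a", "b", "c")))
  expect_identical(nrow(priorEntries(pm3)), 6L)
  expect_identical(nrow(priorEntries(complexUniformPriors(list()))), 0L)
})

test_that("merging takes the maximum and lets exclusions dominate", {
  p1 <- priorMatrix(data.frame(parent = "a", child = "b", weight = 0.3))
  p2 <- priorMatrix(data.frame(parent = "a", child = "b", weight = 0.8))
  m <- mergePriors(list(p1, p2))
  expect_equal(priorWeight(m, "a", "b"), 0.8)
  expect_equal(priorWeight(m, "x", "y"), priorDefault(m))
  p3 <- priorMatrix(forbidden = data.frame(parent = "a", child = "b"))
  expect_message(m2 <- mergePriors(list(p2, p3)), "overridden")
  expect_identical(priorWeight(m2, "a", "b"), 0)
})

test_that("no trans-to-cis edge survives any merge with genetic priors", {
  q <- mkQtl(data.frame(
    trait = c("A", "B", "C"), marker = c("m1", "m2", "m3"),
    chrom = "chr1", pos_bp = c(100000, 104000, 112000),
    lod = c(6, 5, 4), class = c("cis", "trans", "trans"),
    stringsAsFactors = FALSE))
  gp <- geneticPriors(q)
  for (s in 1:10) {
    other <- withr::with_seed(s, priorMatrix(data.frame(
      parent = sample(c("A", "B", "C"), 3),
      child = sample(c("A", "B", "C"), 3), weight = runif(3))))
    ent <- priorEntries(other)
    other <- priorMatrix(ent[ent$parent != ent$child, , drop = FALSE])
    m <- suppressMessages(mergePriors(list(gp, other)))
    expect_identical(priorWeight(m, "B", "A"), 0)
    expect_identical(priorWeight(m, "C", "A"), 0)
  }
})
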