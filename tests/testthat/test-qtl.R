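test_that("lodScore handles degenerate inputs by convention", {
  g <- rep(0:1, each = 10)
  expect_identical(lodScore(rep(2, 20), g), 0)
  expect_identical(lodScore(rnorm(20), rep(1, 20)), 0)
  expect_error(lodScore(rnorm(10), rep(0:1, 10)), "length")
})

test_that("lodScore equals the independent RSS computation", {
  withr::with_seed(21, {
    for (i in 1:10) {
      g <- rbinom(120, 1, 0.5)
      y <- g + rnorm(120)
      expect_equal(lodScore(y, g), oracleLod(y, g), tolerance = 1e-8)
    }
  })
})

test_that("lodScore is affine-invariant and allele-symmetric", {
  withr::with_seed(31, {
    g <- rbinom(80, 1, 0.5)
    y <- 0.8 * g + rnorm(80)
    base <- lodScore(y, g)
    expect_equal(lodScore(3.7 * y - 11, g), base)
    expect_equal(lodScore(-y, g), base)
    expect_equal(lodScore(y, 1 - g), base)
  })
})

test_that("genome scan peaks agree with a direct lodScore loop", {
  sc <- makeScenario("chain", seed = 2)
  q <- qtlRecords(genomeScan(sc$traits, sc$geno))
  G <- genoValues(sc$geno)
  Y <- traitValues(sc$traits)
  mm <- mapTable(sc$geno)
  for (i in seq_len(nrow(q))) {
    mk <- mm$marker[mm$chrom == q$chrom[i]]
    direct <- vapply(mk, function(m) lodScore(Y[, q$trait[i]], G[, m]), 0)
    expect_equal(q$lod[i], max(direct), tolerance = 1e-10)
  }
})

test_that("a single-marker map gives exactly one record per trait", {
  map <- markerMap("m1", "chr1", 1000)
  geno <- simulateGenotypes(40, map, seed = 3)
  Y <- matrix(rnorm(40 * 3), 40, 3,
              dimnames = list(segregantIds(geno), c("a", "b", "c")))
  q <- qtlRecords(genomeScan(traitMatrix(Y), geno))
  expect_identical(nrow(q), 3L)
})

test_that("the chain peak localises at or adjacent to the true marker", {
  hit <- vapply(1:60, function(s) {
    sc <- makeScenario("chain", seed = 1000 + s)
    q <- qtlRecords(genomeScan(sc$traits, sc$geno))
    best <- q[q$trait == "T1", ]
    best <- best$marker[which.max(best$lod)]
    mk <- markerIds(sc$geno)
    abs(match(best, mk) - match("m_chr01_0120", mk)) <= 1
  }, TRUE)
  expect_gte(mean(hit), 0.95)
})

test_that("genome-wide threshold dominates the pointwise threshold", {
  map <- uniformMap(4, 10, 20000)
  geno <- simulateGenotypes(100, map, seed = 5)
  withr::with_seed(6, {
    Y <- matrix(rnorm(100 * 30), 100, 30,
                dimnames = list(segregantIds(geno), sprintf("t%d", 1:30)))
  })
  tr <- traitMatrix(Y)
  gw <- permutationThreshold(tr, geno, n_perm = 120, level = 0.05,
                             seed = 8)
  # pointwise: null LODs of a single marker under the same permutations
  pointwise <- withr::with_seed(8, {
    g1 <- genoValues(geno)[, 1L]
    quantile(replicate(120, lodScore(sample(Y[, 1L]), g1)), 0.95)
  })
  expect_gte(gw, as.numeric(pointwise) - 1e-9)
  expect_error(permutationThreshold(tr, geno, n_perm = 50, level = 0.05),
               "n_perm")
})

test_that("cis/trans classification respects window and chromosome", {
  rec <- list(chrom = "chr1", pos_bp = 100000)
  expect_identical(classifyCisTrans(rec, "chr1", 99999, 50000), "cis")
  expect_identical(classifyCisTrans(rec, "chr2", 100000, 50000), "trans")
  # closed interval: a peak exactly at the boundary is cis
  expect_identical(classifyCisTrans(rec, "chr1", 150000, 50000), "cis")
  expect_identical(classifyCisTrans(rec, "chr1", 150001, 50000), "trans")
  expect_warning(out <- classifyCisTrans(rec, NA, NA), "missing")
  expect_identical(as.character(out), "trans")
})

test_that("classifyQTL labels genes and leaves metabolites NA", {
  sc <- makeScenario("small_net", seed = 4)
  q <- classifyQTL(genomeScan(sc$traits, sc$geno), sc$traits)
  r <- qtlRecords(q)
  meta <- traitMeta(sc$traits)
  mets <- meta$trait[meta$kind == "metabolite"]
  expect_true(all(is.na(r$class[r$trait %in% mets])))
  drivers <- sc$truth@loci$trait
  # each driver's peak on its own chromosome is cis
  own <- r[r$trait %in% drivers & r$lod > 3, ]
  expect_true(any(own$class == "cis"))
})

test_that("hotspot detection flags the planted locus and only it", {
  sc <- makeScenario("hotspot", seed = 2)
  q <- classifyQTL(genomeScan(sc$traits, sc$geno), sc$traits)
  hs <- detectHotspots(q, markerMapOf(sc$geno))
  sig <- hs[hs$significant, ]
  expect_gte(nrow(sig), 1L)
  planted <- mapTable(sc$geno)
  pos <- planted$pos_bp[planted$marker == sc$truth@loci$marker[1L]]
  top <- sig[1L, ]
  expect_identical(top$chrom, "chr02")
  expect_lte(top$start_bp, pos)
  expect_gte(top$end_bp, pos)
  expect_error(detectHotspots(q, markerMapOf(sc$geno), bin_bp = 0),
               "bin_bp")
})

test_that("random significant peaks rarely produce hotspots", {
  map <- uniformMap(8, 25, 20000)
  mm <- mapTable(map)
  nSig <- vapply(1:20, function(s) {
    withr::with_seed(s, {
      idx <- sample.int(nrow(mm), 25, replace = TRUE)
      rec <- data.frame(trait = sprintf("t%d", 1:25),
                        marker = mm$marker[idx], chrom = mm$chrom[idx],
                        pos_bp = mm$pos_bp[idx], lod = 5, mu0 = 0, mu1 = 1,
                        n_used = 100L, class = "trans",
                        stringsAsFactors = FALSE)
      q <- new("QTLTable", records = rec, params = list())
      sum(detectHotspots(q, map)$significant)
    })
  }, 0L)
  expect_gte(mean(nSig == 0L), 0.95)
})

test_that("hotspot BED export shifts to 0-based half-open intervals", {
  hs <- data.frame(chrom = "chr02", start_bp = 140001, end_bp = 160000,
                   n_traits_linked = 19L, expected = 0.4,
                   p_value = 1e-30, p_adj = 1e-28, significant = TRUE,
                   stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".bed")
  writeHotspotsBed(hs, f)
  expect_identical(readLines(f), "chr02\t140000\t160000\tn=19;padj=1e-28")
})

test_that("an empty QTL table yields no hotspots", {
  map <- uniformMap(2, 5, 20000)
  q <- new("QTLTable",
           records = data.frame(trait = character(0), marker = character(0),
                                chrom = character(0), pos_bp = numeric(0),
                                lod = numeric(0), mu0 = numeric(0),
                                mu1 = numeric(0), n_used = integer(0),
                                class = character(0),
                                stringsAsFactors = FALSE),
           params = list())
  expect_identical(nrow(detectHotspots(q, map)), 0L)
})
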