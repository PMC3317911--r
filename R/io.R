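#' Read a genotype or trait matrix from TSV
#'
#' Expects a header row and a first column of segregant ids. Genotype
#' entries must be 0, 1 or NA; trait entries numeric. Parse problems are
#' reported with their row and column.
#'
#' @param path TSV file path.
#' @param kind "genotype" or "trait".
#' @param map a \linkS4class{MarkerMap} (required for genotypes).
#' @param meta optional per-trait metadata data.frame.
#' @return a \linkS4class{GenotypeMatrix} or \linkS4class{TraitMatrix}.
#' @export
readMatrix <- function(path, kind = c("genotype", "trait"), map = NULL,
                       meta = NULL) {
  kind <- match.arg(kind)
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  if (ncol(raw) < 2L) stopf("%s: expected id column plus data", path)
  ids <- raw[[1L]]
  if (anyDuplicated(ids))
    stopf("%s: duplicated segregant id '%s'", path, ids[duplicated(ids)][1L])
  m <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m),
                                 dimnames = list(ids, colnames(m))))
  bad <- which(is.na(num) & !(m %in% c("NA", "", "na")), arr.ind = TRUE)
  if (nrow(bad))
    stopf("%s: non-numeric value '%s' at row %s, column %s", path,
          m[bad[1L, 1L], bad[1L, 2L]], ids[bad[1L, 1L]],
          colnames(m)[bad[1L, 2L]])
  if (kind == "genotype") {
    dom <- which(!is.na(num) & !(num %in% c(0, 1)), arr.ind = TRUE)
    if (nrow(dom))
      stopf("%s: genotype '%s' at row %s, column %s is not 0/1", path,
            m[dom[1L, 1L], dom[1L, 2L]], ids[dom[1L, 1L]],
            colnames(m)[dom[1L, 2L]])
    if (is.null(map))
      map <- markerMap(colnames(num), "chrUnknown",
                       seq_len(ncol(num)) * 1000)
    genotypeMatrix(num, map)
  } else {
    traitMatrix(num, meta)
  }
}

#' Write a matrix container as TSV
#'
#' First column \code{segregant}, then one column per marker/trait.
#'
#' @param x a GenotypeMatrix or TraitMatrix.
#' @param path output TSV path.
#' @return invisibly, the path.
#' @export
writeMatrix <- function(x, path) {
  v <- if (is(x, "GenotypeMatrix")) genoValues(x) else traitValues(x)
  df <- data.frame(segregant = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a marker map as 4-column TSV
#'
#' Columns: marker, chrom, pos_bp, cm.
#'
#' @param path TSV path.
#' @return a \linkS4class{MarkerMap}.
#' @export
readMarkerMap <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  markerMap(d$marker, d$chrom, d$pos_bp, d$cm)
}

#' @rdname readMarkerMap
#' @param map a \linkS4class{MarkerMap}.
#' @export
writeMarkerMap <- function(map, path) {
  write.table(mapTable(map), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write a directed edge table as SIF
#'
#' @param edges data.frame with parent and child columns (and optionally
#'   frequency, ignored here).
#' @param path output path.
#' @param relation relation label; default "regulates".
#' @export
writeSIF <- function(edges, path, relation = "regulates") {
  lines <- sprintf("%s\t%s\t%s", edges$parent, relation, edges$child)
  writeLines(lines, path)
  invisible(path)
}

#' Write a consensus network as GraphML with a frequency edge attribute
#'
#' @param net a \linkS4class{ConsensusNetwork} or \linkS4class{Subnetwork}.
#' @param path output path.
#' @export
writeGraphML <- function(net, path) {
  ed <- edgeTable(net)
  g <- igraph::graph_from_data_frame(ed[, c("parent", "child")],
                                     directed = TRUE,
                                     vertices = nodeIds(net))
  if (!is.null(ed$frequency))
    igraph::E(g)$frequency <- ed$frequency
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Serialize a ground-truth network
#'
#' Writes the trait-trait edges as SIF plus a side TSV of edge effects,
#' locus effects and noise standard deviations.
#'
#' @param truth a \linkS4class{GroundTruthNetwork}.
#' @param sif_path,table_path output paths.
#' @export
writeGroundTruth <- function(truth, sif_path, table_path) {
  writeSIF(edgeTable(truth), sif_path)
  ed <- edgeTable(truth)
  side <- rbind(
    data.frame(kind = "edge", a = ed$parent, b = ed$child,
               value = ed$beta, stringsAsFactors = FALSE),
    data.frame(kind = "locus", a = truth@loci$marker, b = truth@loci$trait,
               value = truth@loci$a, stringsAsFactors = FALSE),
    data.frame(kind = "noise_sd", a = names(truth@noise_sd), b = "",
               value = unname(truth@noise_sd), stringsAsFactors = FALSE))
  write.table(side, table_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(sif_path)
}

#' Read a RunConfig from a flat key = value file
#'
#' One \code{key = value} (or \code{key<TAB>value}) pair per line;
#' unknown keys are rejected, missing keys keep their defaults. Keys
#' match the \code{\link{runConfig}} argument names. The parsed values
#' are echoed into the pipeline run log.
#'
#' @param path text file path.
#' @return a \linkS4class{RunConfig}.
#' @export
readRunConfig <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*", "", lines))
  lines <- lines[nzchar(lines)]
  args <- list()
  for (l in lines) {
    kv <- strsplit(l, "[=\t]")[[1L]]
    if (length(kv) != 2L) stopf("bad config line: '%s'", l)
    args[[trimws(kv[1L])]] <- as.numeric(trimws(kv[2L]))
  }
  bad <- setdiff(names(args), names(formals(runConfig)))
  if (length(bad)) stopf("unknown config key(s): %s",
                         paste(bad, collapse = ", "))
  do.call(runConfig, args)
}

configEcho <- function(config) {
  keys <- names(formals(runConfig))
  vapply(keys, function(k)
    sprintf("config.%s\t%s", k, format(slot(config, k))), "")
}

#' Run the full reconstruction pipeline
#'
#' scan -> causality -> priors -> ensemble -> consensus -> cycle removal
#' -> (optional) subnetwork, writing each artifact under \code{out_dir}
#' together with a log of seeds and counts. Deterministic given the
#' config seeds: rerunning writes byte-identical networks.
#'
#' @param geno a \linkS4class{GenotypeMatrix}.
#' @param traits a \linkS4class{TraitMatrix}.
#' @param out_dir output directory (created if missing).
#' @param config a \linkS4class{RunConfig}.
#' @param tfbs optional named list TF -> targets.
#' @param ppi optional two-column PPI edge data.frame.
#' @param kgml_files optional KGML paths.
#' @param subnet_seeds optional node ids for subnetwork extraction.
#' @param n_boot bootstrap resamples per causality pair.
#' @return invisibly, a list with the QTL table, calls, priors, consensus
#'   network and (if requested) subnetwork.
#' @export
runPipeline <- function(geno, traits, out_dir, config = runConfig(),
                        tfbs = NULL, ppi = NULL, kgml_files = NULL,
                        subnet_seeds = NULL, n_boot = 200) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- character(0)
  note <- function(fmt, ...) log <<- c(log, sprintf(fmt, ...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  log <- c(log, configEcho(config))

  qtl <- stage("scan", {
    q <- classifyQTL(genomeScan(traits, geno), traits,
                     window_bp = config@cisWindowBp)
    write.table(qtlRecords(q), file.path(out_dir, "qtl.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    q
  })
  note("qtl_records\t%d", nrow(qtlRecords(qtl)))

  calls <- stage("causality", {
    pairs <- coincidentPairs(qtl, config@lodSuggestive,
                             config@hotspotBinBp)
    if (nrow(pairs) == 0L) NULL else {
      cb <- causalBatch(traits, geno, pairs, n_boot = n_boot,
                        seed = config@baseSeed)
      write.table(cb, file.path(out_dir, "causal_calls.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      cb
    }
  })
  note("causality_pairs\t%d", if (is.null(calls)) 0L else nrow(calls))
  note("causality_seed\t%d", config@baseSeed)

  priors <- stage("priors", {
    src <- list(geneticPriors(qtl, calls,
                              lod_suggestive = config@lodSuggestive,
                              bin_bp = config@hotspotBinBp,
                              default = config@defaultWeight))
    if (!is.null(tfbs)) {
      if (!is.null(ppi)) {
        cx <- cliqueComplexes(ppi, k = 3)
        tfbs <- complexTfbsAugment(cx, tfbs)
        src <- c(src, list(complexUniformPriors(
          cx, config@wUniform, config@defaultWeight)))
      }
      src <- c(src, list(tfPrior(traits, tfbs, p_cut = config@pCut,
                                 seed = config@baseSeed,
                                 w_max = config@wMax,
                                 default = config@defaultWeight)))
    }
    if (!is.null(kgml_files)) {
      rg <- parseKGML(kgml_files)
      src <- c(src, list(keggPrior(shortestDistances(rg), config@wMax,
                                   config@defaultWeight)))
    }
    pm <- mergePriors(src, default = config@defaultWeight)
    ent <- rbind(priorEntries(pm),
                 cbind(priorForbidden(pm), weight = 0))
    write.table(ent, file.path(out_dir, "priors.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    pm
  })
  note("prior_entries\t%d", nrow(priorEntries(priors)))
  note("prior_forbidden\t%d", nrow(priorForbidden(priors)))

  net <- stage("network", {
    dags <- bnEnsemble(traits, priors, n_runs = config@nRuns,
                       n_iter = config@nIter, base_seed = config@baseSeed)
    cons <- breakCycles(consensusNetwork(dags, config@consensusCutoff))
    writeSIF(edgeTable(cons), file.path(out_dir, "consensus.sif"))
    writeGraphML(cons, file.path(out_dir, "consensus.graphml"))
    cons
  })
  note("ensemble_runs\t%d", config@nRuns)
  note("ensemble_seeds\t%d..%d", config@baseSeed + 1L,
       config@baseSeed + config@nRuns)
  note("consensus_edges\t%d", nrow(edgeTable(net)))

  sub <- NULL
  if (!is.null(subnet_seeds)) {
    sub <- stage("subnet", {
      s <- extractSubnetwork(net, subnet_seeds)
      writeSIF(edgeTable(s), file.path(out_dir, "subnet.sif"))
      attrs <- data.frame(node = nodeIds(s),
                          seed = nodeIds(s) %in% seedIds(s),
                          stringsAsFactors = FALSE)
      write.table(attrs, file.path(out_dir, "subnet_nodes.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      s
    })
    note("subnet_nodes\t%d", length(nodeIds(sub)))
  }
  writeLines(log, file.path(out_dir, "run_log.tsv"))
  invisible(list(qtl = qtl, calls = calls, priors = priors,
                 consensus = net, subnet = sub))
}

#' Trait pairs sharing a suggestive locus
#'
#' Enumerates unordered trait pairs whose suggestive peaks are
#' coincident (same chromosome, peak positions within \code{bin_bp} of
#' each other), anchored at the higher-LOD peak marker of the pair —
#' the input of \code{\link{causalBatch}} when building genetic priors.
#'
#' @param qtl a \linkS4class{QTLTable}.
#' @param lod_suggestive suggestive LOD threshold; default 2.8.
#' @param bin_bp coincidence distance in bp; default 20 kb.
#' @return data.frame with columns \code{trait1}, \code{trait2},
#'   \code{marker}.
#' @export
coincidentPairs <- function(qtl, lod_suggestive = 2.8, bin_bp = 20000) {
  empty <- data.frame(trait1 = character(0), trait2 = character(0),
                      marker = character(0), stringsAsFactors = FALSE)
  cp <- coincidentRecords(qtl, lod_suggestive, bin_bp)
  if (nrow(cp) == 0L) return(empty)
  anchor <- ifelse(cp$lod1 >= cp$lod2, cp$marker1, cp$marker2)
  unique(data.frame(trait1 = cp$trait1, trait2 = cp$trait2,
                    marker = anchor, stringsAsFactors = FALSE))
}

# all coincident suggestive peak-record pairs with their classes
coincidentRecords <- function(qtl, lod_suggestive = 2.8, bin_bp = 20000) {
  r <- qtlRecords(qtl)
  s <- r[r$lod > lod_suggestive, , drop = FALSE]
  out <- list()
  for (ch in unique(s$chrom)) {
    sb <- s[s$chrom == ch, , drop = FALSE]
    if (nrow(sb) < 2L) next
    sb <- sb[order(sb$pos_bp), , drop = FALSE]
    for (i in seq_len(nrow(sb) - 1L)) for (j in (i + 1L):nrow(sb)) {
      if (sb$pos_bp[j] - sb$pos_bp[i] > bin_bp) break
      if (sb$trait[i] == sb$trait[j]) next
      a <- min(sb$trait[i], sb$trait[j]); b <- max(sb$trait[i], sb$trait[j])
      ii <- if (a == sb$trait[i]) i else j
      jj <- if (ii == i) j else i
      out[[length(out) + 1L]] <- data.frame(
        trait1 = a, trait2 = b,
        marker1 = sb$marker[ii], marker2 = sb$marker[jj],
        lod1 = sb$lod[ii], lod2 = sb$lod[jj],
        class1 = sb$class[ii], class2 = sb$class[jj],
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(trait1 = character(0), trait2 = character(0),
                      marker1 = character(0), marker2 = character(0),
                      lod1 = numeric(0), lod2 = numeric(0),
                      class1 = character(0), class2 = character(0),
                      stringsAsFactors = FALSE))
  unique(do.call(rbind, out))
}
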