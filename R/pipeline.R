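# Pipeline orchestration: the staged file-based runner (simulate -> merge
# -> genes -> quant -> covary -> eval) with a checksummed manifest and
# resume, plus an in-memory end-to-end demo on a simulated community.

demoSeeds <- function(seed) {
  # independent sub-seeds per stage, kept below 2^31
  s <- as.integer(seed %% 100000L)
  list(genomes = s * 10L + 1L, expr = s * 10L + 2L, frag = s * 10L + 3L,
       reads = s * 10L + 4L)
}

# lift truth gene models onto merged scaffolds (valid when the merged
# scaffolds reproduce the genomes exactly, as on error-free simulations)
liftTruthGenes <- function(community, merged) {
  genomeC <- setNames(as.character(community@genomes),
                      names(community@genomes))
  mergedC <- setNames(as.character(scaffolds(merged)),
                      names(scaffolds(merged)))
  hit <- match(genomeC, mergedC)
  rcHit <- match(revComp(genomeC), mergedC)
  genes <- community@genes
  rows <- list()
  for (i in seq_along(genomeC)) {
    sp <- names(genomeC)[i]
    g <- genes[as.character(seqnames(genes)) == sp]
    if (!length(g)) next
    if (!is.na(hit[i])) {
      rows[[sp]] <- GRanges(names(mergedC)[hit[i]],
                            IRanges(start(g), end(g)),
                            strand = strand(g))
      mcols(rows[[sp]]) <- mcols(g)
      mcols(rows[[sp]])$species <- sp
    } else if (!is.na(rcHit[i])) {
      L <- nchar(genomeC[[i]])
      flip <- as.character(strand(g)) == "+"
      rows[[sp]] <- GRanges(names(mergedC)[rcHit[i]],
                            IRanges(L - end(g) + 1L, L - start(g) + 1L),
                            strand = ifelse(flip, "-", "+"))
      mcols(rows[[sp]]) <- mcols(g)
      mcols(rows[[sp]])$species <- sp
    } else {
      stop("merged reference does not reproduce genome ", sp,
           " exactly; cannot lift truth genes")
    }
  }
  out <- unlist(GenomicRanges::GRangesList(rows), use.names = FALSE)
  out
}

quantifySamples <- function(merged, features, reads, samples,
                            mapperParams = pipelineConfig()$mapper) {
  idx <- buildKmerIndex(merged, mapperParams$k)
  gid <- mcols(features)$gene_id
  sampleNames <- paste(samples$individual, samples$site, sep = ".")
  counts <- depth <- matrix(0, length(gid), length(sampleNames),
                            dimnames = list(gid, sampleNames))
  rnaMapped <- rnaTotal <- setNames(numeric(length(sampleNames)),
                                    sampleNames)
  for (sn in sampleNames) {
    dnaP <- reads$dna[reads$dna$sample == sn]
    rnaP <- reads$rna[reads$rna$sample == sn]
    if (nrow(dnaP)) {
      alnD <- mapReads(NULL, dnaP, index = idx,
                       maxMismatchRate = mapperParams$max_mismatch_rate,
                       maxFragmentLen = mapperParams$max_fragment_len)
      depth[, sn] <- computeDepth(alnD, features)
    }
    if (nrow(rnaP)) {
      alnR <- mapReads(NULL, rnaP, index = idx,
                       maxMismatchRate = mapperParams$max_mismatch_rate,
                       maxFragmentLen = mapperParams$max_fragment_len)
      counts[, sn] <- countReads(alnR, features)
      ok <- alnR[, .(ok = any(mapped)), by = qname]
      rnaMapped[sn] <- sum(ok$ok); rnaTotal[sn] <- nrow(rnaP)
    }
  }
  lengthsKb <- width(features) / 1000
  tpm <- apply(counts, 2L, computeTpm, lengthsKb = lengthsKb)
  perCell <- matrix(NA_real_, nrow(counts), ncol(counts),
                    dimnames = dimnames(counts))
  for (j in seq_len(ncol(counts)))
    perCell[, j] <- computePerCell(counts[, j], lengthsKb, depth[, j])
  se <- buildExpressionSE(counts, tpm, perCell, depth, features, samples)
  metadata(se)$rna_mapping_rate <- 100 * rnaMapped / pmax(1, rnaTotal)
  se
}

#' Run the end-to-end demo on a simulated community
#'
#' Simulates a multi-site community (default 2 individuals x 3 sites, 6
#' genomes), merges the per-site scaffold sets, quantifies DNA/mRNA reads
#' against the merged reference, runs the covariation benchmark and label
#' transfer, evaluates the assembly, and returns a report of the checks the
#' pipeline's contracts promise (reconstruction completeness, N-curve
#' dominance, TPM conservation, mapping-rate comparison, covariation
#' recovery and FPR, evaluation metrics).
#'
#' @param seed integer seed driving every stage.
#' @param nSpecies,genomeLength community size.
#' @param dnaDepth,rnaDepth,errorRate read simulation parameters.
#' @param nCovariantPairs,effectSize,noiseSd expression design.
#' @param mappingRateReads number of RNA pairs subsampled for the
#'   mapping-rate comparison across references.
#' @return a list report; see Details in the package vignette.
#' @export
runDemo <- function(seed = 0L, nSpecies = 6L, genomeLength = 30000L,
                    dnaDepth = 2, rnaDepth = 1, errorRate = 0,
                    nCovariantPairs = 10L, effectSize = 1.5,
                    noiseSd = 0.2, mappingRateReads = 800L) {
  ss <- demoSeeds(seed)
  cfg <- pipelineConfig()
  com <- simulateGenomes(nSpecies, c(genomeLength, genomeLength),
                         gc = 0.5, geneDensity = 1 / 4000,
                         seed = ss$genomes)
  com <- assignExpression(com, nCovariantPairs = nCovariantPairs,
                          effectSize = effectSize, noiseSd = noiseSd,
                          seed = ss$expr)
  frag <- fragmentPerSite(com, seed = ss$frag)
  merged <- mergeSites(frag$scaffolds, cfg$merge)

  # reconstruction completeness
  genomeC <- sort(unname(as.character(com@genomes)))
  mergedC <- sort(unname(as.character(scaffolds(merged))))
  exactReconstruction <- identical(genomeC, mergedC)

  # N-curve dominance (merged vs each site)
  mergedCurve <- nStatistics(width(scaffolds(merged)))
  siteCurves <- lapply(frag$scaffolds, function(s) nStatistics(width(s)))
  nstatDominance <- all(vapply(siteCurves, function(cv)
    all(mergedCurve >= cv), TRUE))

  # quantification against truth genes lifted onto the merged reference
  features <- liftTruthGenes(com, merged)
  reads <- simulateReads(com, dnaDepth = dnaDepth, rnaDepth = rnaDepth,
                         errorRate = errorRate, seed = ss$reads)
  se <- quantifySamples(merged, features, reads, com@samples, cfg$mapper)
  tpmSums <- colSums(assay(se, "tpm"))

  # truth recovery: TPM should track abundance x expression
  ab <- com@abundance[mcols(features)$species, , drop = FALSE]
  truthCommunity <- com@expression[rownames(se), , drop = FALSE] * ab
  spearTpm <- mean(vapply(seq_len(ncol(se)), function(j)
    suppressWarnings(cor(assay(se, "tpm")[, j], truthCommunity[, j],
                         method = "spearman")), 0))

  # covariation: known clusters (one per COG) vs unknown clusters
  annot <- annotationTable(com)
  W <- buildWeights(unique(com@samples$individual),
                    unique(com@samples$site))
  known <- groupKnownByCog(annot)
  knownRx <- lapply(split(annot$reactions[match(known$gene_id,
                                                annot$gene_id)],
                          known$cluster_id),
                    function(r) Filter(function(x) !is.na(x) && nzchar(x),
                                unlist(strsplit(r, ";"))))
  tpmMat <- assay(se, "tpm")
  knownProf <- clusterProfiles(tpmMat, known)
  bench <- benchmarkKnown(knownProf, knownRx, W,
                          cfg$covariation$target_fpr)

  unkGenes <- annot$gene_id[!annot$is_known]
  unkFeat <- features[match(unkGenes, mcols(features)$gene_id)]
  prots <- translateGenes(extractGeneSeqs(merged, unkFeat))
  unkClusters <- clusterUnknownProteins(prots,
                                        cfg$covariation$cluster_identity,
                                        cfg$covariation$cluster_coverage)
  unkProf <- clusterProfiles(tpmMat, unkClusters)
  knownLabels <- lapply(knownRx, identity)
  transfer <- transferFunctions(unkProf, knownProf, knownLabels, W,
                                bench@theta, membership = unkClusters)

  # recovery of designed unknown-known covariant pairs
  pairs <- com@covariantPairs
  m <- mcols(com@genes)
  isK <- setNames(m$is_known, m$gene_id)
  mixed <- pairs[xor(isK[pairs$gene1], isK[pairs$gene2]), , drop = FALSE]
  recovered <- 0L
  if (nrow(mixed)) {
    clOf <- setNames(unkClusters$cluster_id, unkClusters$gene_id)
    cogOf <- setNames(annot$cog, annot$gene_id)
    for (i in seq_len(nrow(mixed))) {
      gu <- if (isK[mixed$gene1[i]]) mixed$gene2[i] else mixed$gene1[i]
      gk <- if (isK[mixed$gene1[i]]) mixed$gene1[i] else mixed$gene2[i]
      uc <- clOf[gu]; kc <- cogOf[gk]
      if (!is.na(uc) && !is.na(kc) &&
          nrow(transfer$links[unknown == uc & known == kc])) {
        recovered <- recovered + 1L
      }
    }
  }

  # mapping-rate comparison: merged vs each single-site set
  rnaAll <- reads$rna
  nSub <- min(mappingRateReads, nrow(rnaAll))
  sub <- rnaAll[withSeed(seed + 77L, sample.int(nrow(rnaAll), nSub))]
  rateMerged <- mappingRate(merged, sub,
                            maxMismatchRate = cfg$mapper$max_mismatch_rate)
  rateSites <- vapply(frag$scaffolds, function(s)
    mappingRate(s, sub,
                maxMismatchRate = cfg$mapper$max_mismatch_rate), 0)

  speciesOf <- setNames(frag$truth$species, frag$truth$scaffold_id)
  evaluation <- evaluateAssembly(merged, com@genomes,
                                 speciesOf = speciesOf)

  list(seed = seed, community = com, merged = merged, se = se,
       exact_reconstruction = exactReconstruction,
       nstat_dominance = nstatDominance,
       merged_curve = mergedCurve, site_curves = siteCurves,
       tpm_sums = tpmSums, spearman_tpm_truth = spearTpm,
       benchmark = bench, transfer = transfer,
       n_mixed_pairs = nrow(mixed), n_mixed_recovered = recovered,
       mapping_rate_merged = rateMerged, mapping_rate_sites = rateSites,
       evaluation = evaluation)
}

#' Print a compact demo report
#' @param report result of \code{\link{runDemo}}.
#' @return invisibly, the report.
#' @export
printDemoReport <- function(report) {
  cat(sprintf("Demo (seed %d)\n", report$seed))
  cat(sprintf("  exact reconstruction of all genomes: %s\n",
              report$exact_reconstruction))
  cat(sprintf("  merged N-curve dominates all site curves: %s\n",
              report$nstat_dominance))
  cat(sprintf("  TPM conservation: max |sum - 1e6| = %.2e\n",
              max(abs(report$tpm_sums - 1e6))))
  cat(sprintf("  Spearman(TPM, truth community expression) = %.3f\n",
              report$spearman_tpm_truth))
  cat(sprintf("  covariation AUC = %.3f, theta = %.3f (FPR %.3f)\n",
              report$benchmark@auc, report$benchmark@theta,
              report$benchmark@fpr))
  cat(sprintf("  designed unknown-known pairs recovered: %d / %d\n",
              report$n_mixed_recovered, report$n_mixed_pairs))
  cat(sprintf("  RNA mapping rate: merged %.1f%% vs sites %s\n",
              report$mapping_rate_merged,
              paste(sprintf("%.1f%%", report$mapping_rate_sites),
                    collapse = ", ")))
  cat(sprintf("  nonchimeric rate %.1f%%, CI %.3f, CPM %.0f\n",
              report$evaluation@nonchimericRate, report$evaluation@ci,
              report$evaluation@cpm))
  invisible(report)
}

stageUpToDate <- function(manifest, stage, inputs, outputs) {
  st <- manifest$stages[[stage]]
  if (is.null(st)) return(FALSE)
  if (!all(file.exists(outputs))) return(FALSE)
  cur <- fileChecksums(inputs)
  stored <- unlist(st$input_md5)
  length(cur) == length(stored) && all(!is.na(cur)) &&
    all(cur == stored[names(cur)])
}

#' Run the staged file-based pipeline
#'
#' Executes simulate -> merge -> genes -> quant -> covary -> eval inside
#' \code{dir}, writing standard formats (FASTA/FASTQ/GFF3/TSV) after every
#' stage and a JSON manifest with input checksums.  A re-run resumes: a
#' stage whose outputs exist and whose inputs' checksums match the manifest
#' is skipped, so deleting one intermediate re-executes only that stage and
#' its downstream.
#'
#' @param dir working directory for the run.
#' @param config a \code{\link{pipelineConfig}}.
#' @param seed seed for the simulation stage.
#' @param demoScale passed through to the simulator (list of overrides for
#'   \code{nSpecies}, \code{genomeLength}, \code{dnaDepth},
#'   \code{rnaDepth}, \code{nCovariantPairs}).
#' @return the manifest (invisibly), with stage outputs on disk.
#' @export
runPipeline <- function(dir, config = pipelineConfig(), seed = 0L,
                        demoScale = list()) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("runPipeline needs the 'jsonlite' package for its manifest")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifestPath <- file.path(dir, "manifest.json")
  manifest <- if (file.exists(manifestPath))
    jsonlite::read_json(manifestPath) else list(stages = list())
  manifest$seed <- seed
  sc <- list(nSpecies = 6L, genomeLength = 30000L, dnaDepth = 2,
             rnaDepth = 1, nCovariantPairs = 10L)
  sc[names(demoScale)] <- demoScale
  ss <- demoSeeds(seed)
  sites <- unique(unlist(config$sites))
  record <- function(stage, inputs, outputs) {
    manifest$stages[[stage]] <<- list(
      inputs = as.list(inputs), outputs = as.list(outputs),
      input_md5 = as.list(fileChecksums(inputs)))
    jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                         pretty = TRUE)
  }
  path <- function(...) file.path(dir, ...)

  # ---- simulate ----
  siteFa <- path(sprintf("site_%s.fasta", sites))
  simOut <- c(path("genomes.fasta"), siteFa, path("annotation.tsv"),
              path("genes_truth.fasta"), path("reads_rna.tsv"),
              path("reads_dna.tsv"), path("expression_truth.tsv"))
  if (!stageUpToDate(manifest, "simulate", character(0), simOut)) {
    message("[simulate] generating community (seed ", seed, ")")
    com <- simulateGenomes(sc$nSpecies,
                           c(sc$genomeLength, sc$genomeLength),
                           gc = 0.5, geneDensity = 1 / 4000,
                           seed = ss$genomes)
    com <- assignExpression(com, nCovariantPairs = sc$nCovariantPairs,
                            individuals = names(config$sites),
                            siteOrder = config$sites[[1]],
                            seed = ss$expr)
    frag <- fragmentPerSite(com, mL = config$merge$mL, seed = ss$frag,
                            sites = sites)
    reads <- simulateReads(com, dnaDepth = sc$dnaDepth,
                           rnaDepth = sc$rnaDepth,
                           errorRate = config$simulation$error_rate,
                           seed = ss$reads)
    writeFastaRecords(com@genomes, path("genomes.fasta"))
    for (s in sites)
      writeFastaRecords(frag$scaffolds[[s]],
                        path(sprintf("site_%s.fasta", s)))
    writeAnnotationTsv(annotationTable(com), path("annotation.tsv"))
    writeFastaRecords(extractGeneSeqs(genomes(com), geneModels(com)),
                      path("genes_truth.fasta"))
    data.table::fwrite(reads$rna, path("reads_rna.tsv"), sep = "\t")
    data.table::fwrite(reads$dna, path("reads_dna.tsv"), sep = "\t")
    writeMatrixTsv(com@expression, path("expression_truth.tsv"))
    record("simulate", character(0), simOut)
  } else message("[simulate] up to date, skipping")

  # ---- merge ----
  mergeOut <- c(path("merged.fasta"), path("provenance.tsv"))
  if (!stageUpToDate(manifest, "merge", siteFa, mergeOut)) {
    message("[merge] merging ", length(sites), " site scaffold sets")
    sets <- lapply(sites, function(s)
      readFastaRecords(path(sprintf("site_%s.fasta", s))))
    names(sets) <- sites
    merged <- mergeSites(sets, config$merge)
    writeFastaRecords(scaffolds(merged), path("merged.fasta"))
    data.table::fwrite(provenance(merged), path("provenance.tsv"),
                       sep = "\t")
    record("merge", siteFa, mergeOut)
  } else message("[merge] up to date, skipping")

  # ---- genes ----
  geneOut <- path("genes.gff3")
  if (!stageUpToDate(manifest, "genes", path("merged.fasta"), geneOut)) {
    message("[genes] calling ORFs on the merged reference")
    merged <- readFastaRecords(path("merged.fasta"))
    feats <- callOrfs(merged)
    writeGff3Genes(feats, geneOut)
    record("genes", path("merged.fasta"), geneOut)
  } else message("[genes] up to date, skipping")

  # ---- quant ----
  quantIn <- c(path("merged.fasta"), geneOut, path("reads_rna.tsv"),
               path("reads_dna.tsv"))
  quantOut <- c(path("expr_counts.tsv"), path("expr_tpm.tsv"),
                path("expr_per_cell.tsv"), path("expr_depth.tsv"))
  if (!stageUpToDate(manifest, "quant", quantIn, quantOut)) {
    message("[quant] mapping and counting reads")
    merged <- readFastaRecords(path("merged.fasta"))
    feats <- readGff3Genes(geneOut)
    rna <- data.table::fread(path("reads_rna.tsv"))
    dna <- data.table::fread(path("reads_dna.tsv"))
    samples <- do.call(rbind, lapply(names(config$sites), function(ind)
      data.frame(individual = ind, site = config$sites[[ind]])))
    se <- quantifySamples(merged, feats, list(rna = rna, dna = dna),
                          samples, config$mapper)
    writeMatrixTsv(assay(se, "counts"), path("expr_counts.tsv"))
    writeMatrixTsv(assay(se, "tpm"), path("expr_tpm.tsv"))
    writeMatrixTsv(assay(se, "per_cell"), path("expr_per_cell.tsv"))
    writeMatrixTsv(assay(se, "depth"), path("expr_depth.tsv"))
    record("quant", quantIn, quantOut)
  } else message("[quant] up to date, skipping")

  # ---- covary ----
  covIn <- c(path("expr_tpm.tsv"), path("annotation.tsv"), geneOut,
             path("merged.fasta"), path("genes_truth.fasta"))
  covOut <- c(path("roc.tsv"), path("links.tsv"), path("predictions.tsv"))
  if (!stageUpToDate(manifest, "covary", covIn, covOut)) {
    message("[covary] covariation benchmark and label transfer")
    tpm <- readMatrixTsv(path("expr_tpm.tsv"))
    annot <- readAnnotationTsv(path("annotation.tsv"))
    merged <- readFastaRecords(path("merged.fasta"))
    feats <- readGff3Genes(geneOut)
    # transfer annotations from truth genes to the called catalogue by
    # sequence identity (<= 3 edits), as a database annotator would
    truthGenes <- readFastaRecords(path("genes_truth.fasta"))
    called <- extractGeneSeqs(merged, feats)
    mm <- matchSeqSets(called, truthGenes, 3L)
    annot <- annot[match(mm$b, annot$gene_id), , drop = FALSE]
    annot$gene_id <- mm$a
    annot <- annot[annot$gene_id %in% rownames(tpm), , drop = FALSE]
    W <- buildWeights(names(config$sites), config$sites[[1]])
    known <- groupKnownByCog(annot)
    knownRx <- lapply(split(annot$reactions[match(known$gene_id,
                                                  annot$gene_id)],
                            known$cluster_id), function(r)
                              Filter(function(x) !is.na(x) && nzchar(x),
                                     unlist(strsplit(r, ";"))))
    knownProf <- clusterProfiles(tpm, known)
    bench <- tryCatch(
      benchmarkKnown(knownProf, knownRx, W,
                     config$covariation$target_fpr),
      error = function(e) {
        message("[covary] benchmark skipped: ", conditionMessage(e))
        NULL
      })
    theta <- config$covariation$L_threshold_override
    if (is.na(theta))
      theta <- if (!is.null(bench)) bench@theta else Inf
    unkIds <- intersect(annot$gene_id[!annot$is_known], rownames(tpm))
    unkFeat <- feats[match(intersect(unkIds, mcols(feats)$gene_id),
                           mcols(feats)$gene_id)]
    trans <- if (length(unkFeat)) {
      prots <- translateGenes(extractGeneSeqs(merged, unkFeat))
      unkCl <- clusterUnknownProteins(
        prots, config$covariation$cluster_identity,
        config$covariation$cluster_coverage)
      unkProf <- clusterProfiles(tpm, unkCl)
      transferFunctions(unkProf, knownProf, knownRx, W, theta,
                        membership = unkCl)
    } else transferFunctions(matrix(numeric(), 0, 0), knownProf,
                             knownRx, W, theta)
    rocOut <- if (!is.null(bench)) bench@roc else
      data.frame(threshold = numeric(), fpr = numeric(),
                 sensitivity = numeric())
    data.table::fwrite(rocOut, path("roc.tsv"), sep = "\t")
    data.table::fwrite(trans$links, path("links.tsv"), sep = "\t")
    data.table::fwrite(trans$genePredictions, path("predictions.tsv"),
                       sep = "\t")
    record("covary", covIn, covOut)
  } else message("[covary] up to date, skipping")

  # ---- eval ----
  evalIn <- c(path("merged.fasta"), path("genomes.fasta"))
  evalOut <- path("eval.tsv")
  if (!stageUpToDate(manifest, "eval", evalIn, evalOut)) {
    message("[eval] assembly evaluation")
    merged <- readFastaRecords(path("merged.fasta"))
    genomesFa <- readFastaRecords(path("genomes.fasta"))
    ev <- evaluateAssembly(merged, genomesFa)
    df <- data.frame(metric = c("n50", names(ev@nstats), "ci",
                                "nonchimeric_rate", "mal", "tal", "cpm"),
                     value = c(ev@n50, unname(ev@nstats), ev@ci,
                               ev@nonchimericRate, ev@mal, ev@tal,
                               ev@cpm))
    data.table::fwrite(df, evalOut, sep = "\t")
    record("eval", evalIn, evalOut)
  } else message("[eval] up to date, skipping")

  invisible(manifest)
}
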