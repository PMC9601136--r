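# Central S4 containers.  Sequence sets are Biostrings DNAStringSet, gene
# models are GenomicRanges, expression is a SummarizedExperiment; the classes
# here add the provenance / truth / spatial structure those containers lack.

setClassUnion("data.frameOrNULL", c("data.frame", "NULL"))

#' MergedReference: a merged scaffold set with per-base provenance
#'
#' Produced by \code{\link{mergePair}} / \code{\link{mergeSites}}.  The
#' provenance table tiles every merged scaffold with intervals of the source
#' scaffolds (site, scaffold, interval, orientation), so that every base of
#' the merged reference is traceable to exactly one input base.  Scaffolds
#' dropped as contained in another scaffold are recorded in \code{dropped}.
#'
#' @slot scaffolds DNAStringSet of merged scaffolds.
#' @slot provenance data.frame with columns merged_id, segment_index,
#'   source_site, source_scaffold, merged_start, merged_end, source_start,
#'   source_end, orientation ("+" or "-"); 1-based closed intervals.
#' @slot dropped data.frame with columns scaffold_id, site, contained_in.
#' @exportClass MergedReference
setClass("MergedReference",
  representation(scaffolds = "DNAStringSet",
                 provenance = "data.frame",
                 dropped = "data.frame"))

setValidity("MergedReference", function(object) {
  pv <- object@provenance
  need <- c("merged_id", "segment_index", "source_site", "source_scaffold",
            "merged_start", "merged_end", "source_start", "source_end",
            "orientation")
  if (!all(need %in% names(pv)))
    return(sprintf("provenance lacks columns: %s",
                   paste(setdiff(need, names(pv)), collapse = ", ")))
  lens <- setNames(width(object@scaffolds), names(object@scaffolds))
  for (id in unique(pv$merged_id)) {
    seg <- pv[pv$merged_id == id, , drop = FALSE]
    seg <- seg[order(seg$merged_start), , drop = FALSE]
    if (seg$merged_start[1] != 1L) return("provenance does not start at 1")
    if (seg$merged_end[nrow(seg)] != lens[[id]])
      return(sprintf("provenance of %s does not reach scaffold end", id))
    if (nrow(seg) > 1 &&
        any(seg$merged_start[-1] != seg$merged_end[-nrow(seg)] + 1L))
      return(sprintf("provenance of %s does not tile exactly", id))
    if (any(seg$source_end - seg$source_start != seg$merged_end - seg$merged_start))
      return(sprintf("provenance of %s has inconsistent interval widths", id))
  }
  TRUE
})

#' @describeIn MergedReference scaffold sequences
#' @param x,object a MergedReference.
#' @export
setGeneric("scaffolds", function(x) standardGeneric("scaffolds"))

#' @rdname MergedReference
#' @export
setMethod("scaffolds", "MergedReference", function(x) x@scaffolds)

#' @describeIn MergedReference provenance segment table
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname MergedReference
#' @export
setMethod("provenance", "MergedReference", function(x) x@provenance)

#' @describeIn MergedReference table of contained-dropped scaffolds
#' @export
setGeneric("droppedScaffolds", function(x) standardGeneric("droppedScaffolds"))

#' @rdname MergedReference
#' @export
setMethod("droppedScaffolds", "MergedReference", function(x) x@dropped)

setMethod("show", "MergedReference", function(object) {
  cat(sprintf("MergedReference: %d scaffolds, %s bp total\n",
              length(object@scaffolds),
              format(sum(width(object@scaffolds)), big.mark = ",")))
  cat(sprintf("  provenance segments: %d from %d source scaffolds (%d sites)\n",
              nrow(object@provenance),
              length(unique(object@provenance$source_scaffold)),
              length(unique(object@provenance$source_site))))
  if (nrow(object@dropped))
    cat(sprintf("  dropped as contained: %d\n", nrow(object@dropped)))
})

#' SpatialWeights: site-adjacency weights over the sample grid
#'
#' The spatial weight matrix V consumed by \code{\link{leeL}}.  Samples are
#' the ordered (individual, site) pairs; V is block-diagonal across
#' individuals, encodes chain adjacency of the ordered sites within an
#' individual (optionally including self), and is row-standardised.
#'
#' @slot V numeric n x n weight matrix.
#' @slot samples data.frame with columns individual, site (row order matches
#'   V).
#' @exportClass SpatialWeights
setClass("SpatialWeights",
  representation(V = "matrix", samples = "data.frame"))

setValidity("SpatialWeights", function(object) {
  V <- object@V
  s <- object@samples
  if (nrow(V) != ncol(V)) return("V must be square")
  if (nrow(V) != nrow(s)) return("V dimension must match sample table")
  if (!all(c("individual", "site") %in% names(s)))
    return("samples needs columns individual, site")
  if (any(V < 0)) return("V must be nonnegative")
  rs <- rowSums(V)
  if (any(abs(rs[rs > 0] - 1) > 1e-8))
    return("nonzero rows of V must sum to 1")
  for (ind in unique(s$individual)) {
    i <- which(s$individual == ind)
    if (any(V[i, -i, drop = FALSE] != 0))
      return("V must be block-diagonal across individuals")
  }
  TRUE
})

#' @describeIn SpatialWeights the weight matrix V
#' @param x,object a SpatialWeights.
#' @export
setGeneric("weightsMatrix", function(x) standardGeneric("weightsMatrix"))

#' @rdname SpatialWeights
#' @export
setMethod("weightsMatrix", "SpatialWeights", function(x) x@V)

#' @describeIn SpatialWeights the (individual, site) sample table
#' @export
setGeneric("sampleGrid", function(x) standardGeneric("sampleGrid"))

#' @rdname SpatialWeights
#' @export
setMethod("sampleGrid", "SpatialWeights", function(x) x@samples)

setMethod("show", "SpatialWeights", function(object) {
  cat(sprintf("SpatialWeights: %d samples (%d individuals x sites: %s)\n",
              nrow(object@V), length(unique(object@samples$individual)),
              paste(unique(object@samples$site), collapse = " > ")))
})

#' SyntheticCommunity: a simulated multi-site microbial community
#'
#' Holds the genomes, gene models, annotations, sample grid, abundance and
#' expression truth of a simulated community, plus the designed covariant
#' gene pairs used to score function transfer.
#'
#' @slot genomes DNAStringSet, one genome per species.
#' @slot genes GRanges on the genomes; mcols: gene_id, frame, ko, cog,
#'   reactions (";"-separated), is_known.
#' @slot samples data.frame with columns individual, site, in site order per
#'   individual.
#' @slot abundance species x sample matrix of positive reals (empty until
#'   \code{\link{assignExpression}}).
#' @slot expression gene x sample matrix of nonnegative reals.
#' @slot covariantPairs data.frame: gene1, gene2, reaction.
#' @slot params list of generator parameters (including the seed).
#' @exportClass SyntheticCommunity
setClass("SyntheticCommunity",
  representation(genomes = "DNAStringSet",
                 genes = "GRanges",
                 samples = "data.frame",
                 abundance = "matrix",
                 expression = "matrix",
                 covariantPairs = "data.frame",
                 params = "list"))

setValidity("SyntheticCommunity", function(object) {
  g <- object@genes
  need <- c("gene_id", "frame", "ko", "cog", "reactions", "is_known")
  if (length(g) && !all(need %in% names(mcols(g))))
    return("genes mcols incomplete")
  if (length(g)) {
    if (anyDuplicated(mcols(g)$gene_id)) return("gene ids must be unique")
    glen <- setNames(width(object@genomes), names(object@genomes))
    if (any(end(g) > glen[as.character(seqnames(g))]))
      return("gene beyond genome end")
    if (any(width(g) %% 3 != 0)) return("gene widths must be multiples of 3")
    # non-overlapping within a genome
    if (any(vapply(split(IRanges::ranges(g), as.character(seqnames(g))),
                   function(r) length(reduce(r)) != length(r), TRUE)))
      return("genes overlap within a genome")
  }
  if (length(object@abundance) && any(object@abundance <= 0))
    return("abundance must be positive")
  if (length(object@expression) && any(object@expression < 0))
    return("expression must be nonnegative")
  TRUE
})

#' @describeIn SyntheticCommunity genome sequences
#' @param x,object a SyntheticCommunity.
#' @export
setGeneric("genomes", function(x) standardGeneric("genomes"))

#' @rdname SyntheticCommunity
#' @export
setMethod("genomes", "SyntheticCommunity", function(x) x@genomes)

#' @describeIn SyntheticCommunity gene models (GRanges)
#' @export
setGeneric("geneModels", function(x) standardGeneric("geneModels"))

#' @rdname SyntheticCommunity
#' @export
setMethod("geneModels", "SyntheticCommunity", function(x) x@genes)

#' @describeIn SyntheticCommunity annotation table derived from the gene
#'   mcols (gene_id, ko, cog, reactions, is_known); unknown genes have empty
#'   labels.
#' @export
setGeneric("annotationTable", function(x) standardGeneric("annotationTable"))

#' @rdname SyntheticCommunity
#' @export
setMethod("annotationTable", "SyntheticCommunity", function(x) {
  m <- mcols(x@genes)
  data.frame(gene_id = m$gene_id, ko = m$ko, cog = m$cog,
             reactions = m$reactions, is_known = m$is_known,
             stringsAsFactors = FALSE)
})

#' @describeIn SyntheticCommunity sample grid (individual, site)
#' @export
setGeneric("communitySamples", function(x) standardGeneric("communitySamples"))

#' @rdname SyntheticCommunity
#' @export
setMethod("communitySamples", "SyntheticCommunity", function(x) x@samples)

#' @describeIn SyntheticCommunity expression truth matrix (genes x samples)
#' @export
setGeneric("expressionTruth", function(x) standardGeneric("expressionTruth"))

#' @rdname SyntheticCommunity
#' @export
setMethod("expressionTruth", "SyntheticCommunity", function(x) x@expression)

#' @describeIn SyntheticCommunity abundance truth matrix (species x samples)
#' @export
setGeneric("abundanceTruth", function(x) standardGeneric("abundanceTruth"))

#' @rdname SyntheticCommunity
#' @export
setMethod("abundanceTruth", "SyntheticCommunity", function(x) x@abundance)

#' @describeIn SyntheticCommunity designed covariant gene pairs
#' @export
setGeneric("covariantPairs", function(x) standardGeneric("covariantPairs"))

#' @rdname SyntheticCommunity
#' @export
setMethod("covariantPairs", "SyntheticCommunity", function(x) x@covariantPairs)

setMethod("show", "SyntheticCommunity", function(object) {
  cat(sprintf("SyntheticCommunity: %d genomes (%s bp), %d genes\n",
              length(object@genomes),
              format(sum(width(object@genomes)), big.mark = ","),
              length(object@genes)))
  if (nrow(object@samples))
    cat(sprintf("  samples: %d individuals x %d sites\n",
                length(unique(object@samples$individual)),
                length(unique(object@samples$site))))
  if (nrow(object@covariantPairs))
    cat(sprintf("  designed covariant pairs: %d\n",
                nrow(object@covariantPairs)))
})

#' BenchmarkResult: ROC calibration of the covariation analysis
#'
#' @slot roc data.frame with columns threshold, fpr, sensitivity.
#' @slot auc area under the (FPR, sensitivity) curve.
#' @slot theta selected L threshold (smallest L with empirical FPR at or
#'   below the target).
#' @slot fpr,sensitivity achieved rates at theta.
#' @slot targetFpr the requested FPR bound.
#' @exportClass BenchmarkResult
setClass("BenchmarkResult",
  representation(roc = "data.frame", auc = "numeric", theta = "numeric",
                 fpr = "numeric", sensitivity = "numeric",
                 targetFpr = "numeric"))

setValidity("BenchmarkResult", function(object) {
  r <- object@roc
  if (!all(c("threshold", "fpr", "sensitivity") %in% names(r)))
    return("roc needs threshold, fpr, sensitivity")
  if (any(r$fpr < 0 | r$fpr > 1 | r$sensitivity < 0 | r$sensitivity > 1))
    return("roc rates must lie in [0, 1]")
  if (object@auc < 0 || object@auc > 1) return("auc must lie in [0, 1]")
  TRUE
})

setMethod("show", "BenchmarkResult", function(object) {
  cat(sprintf(paste0("Covariation benchmark: AUC = %.3f; theta = %.3f ",
                     "(FPR %.3f <= %.2f, sensitivity %.3f)\n"),
              object@auc, object@theta, object@fpr, object@targetFpr,
              object@sensitivity))
})

#' @describeIn BenchmarkResult the AUC
#' @param x,object a BenchmarkResult.
#' @export
setGeneric("rocAuc", function(x) standardGeneric("rocAuc"))

#' @rdname BenchmarkResult
#' @export
setMethod("rocAuc", "BenchmarkResult", function(x) x@auc)

#' @describeIn BenchmarkResult the selected L threshold
#' @export
setGeneric("lThreshold", function(x) standardGeneric("lThreshold"))

#' @rdname BenchmarkResult
#' @export
setMethod("lThreshold", "BenchmarkResult", function(x) x@theta)

#' @describeIn BenchmarkResult the ROC table
#' @export
setGeneric("rocTable", function(x) standardGeneric("rocTable"))

#' @rdname BenchmarkResult
#' @export
setMethod("rocTable", "BenchmarkResult", function(x) x@roc)

#' AssemblyEvaluation: contiguity and accuracy metrics for one assembly
#'
#' @slot n50 classic N50 in bp.
#' @slot nstats named numeric, N10..N100 curve.
#' @slot ci chimera index in [0,1] (NA when no scaffold aligned).
#' @slot nonchimericRate percent of assembly length attributable to a single
#'   species (NA when labels unavailable).
#' @slot mal,tal maximum / total aligned block length in bp.
#' @slot cpm composite performance metric (N50 after splitting at
#'   species-switch points, times (1 - CI), times aligned fraction).
#' @slot blocks data.frame of labelled alignment blocks.
#' @exportClass AssemblyEvaluation
setClass("AssemblyEvaluation",
  representation(n50 = "numeric", nstats = "numeric", ci = "numeric",
                 nonchimericRate = "numeric", mal = "numeric",
                 tal = "numeric", cpm = "numeric", blocks = "data.frame"))

setValidity("AssemblyEvaluation", function(object) {
  ns <- object@nstats
  if (length(ns) != 10L) return("nstats must hold N10..N100")
  if (any(diff(ns) > 0)) return("N-statistic curve must be non-increasing")
  if (!is.na(object@ci) && (object@ci < 0 || object@ci > 1))
    return("chimera index must lie in [0, 1]")
  if (!is.na(object@nonchimericRate) &&
      (object@nonchimericRate < 0 || object@nonchimericRate > 100))
    return("nonchimeric rate must lie in [0, 100]")
  if (!is.na(object@mal) && !is.na(object@tal) && object@mal > object@tal)
    return("MAL cannot exceed TAL")
  TRUE
})

setMethod("show", "AssemblyEvaluation", function(object) {
  cat(sprintf("AssemblyEvaluation: N50 = %s bp; CI = %s; nonchimeric = %s%%\n",
              format(object@n50, big.mark = ","),
              ifelse(is.na(object@ci), "NA", sprintf("%.3f", object@ci)),
              ifelse(is.na(object@nonchimericRate), "NA",
                     sprintf("%.1f", object@nonchimericRate))))
  cat(sprintf("  MAL = %s, TAL = %s, CPM = %s\n",
              format(object@mal, big.mark = ","),
              format(object@tal, big.mark = ","),
              format(round(object@cpm, 1), big.mark = ",")))
})

#' @describeIn AssemblyEvaluation the N10..N100 curve
#' @param x,object an AssemblyEvaluation.
#' @export
setGeneric("nStatCurve", function(x) standardGeneric("nStatCurve"))

#' @rdname AssemblyEvaluation
#' @export
setMethod("nStatCurve", "AssemblyEvaluation", function(x) x@nstats)

#' @describeIn AssemblyEvaluation the chimera index
#' @export
setGeneric("chimeraIndexValue", function(x) standardGeneric("chimeraIndexValue"))

#' @rdname AssemblyEvaluation
#' @export
setMethod("chimeraIndexValue", "AssemblyEvaluation", function(x) x@ci)

#' @describeIn AssemblyEvaluation the composite performance metric
#' @export
setGeneric("cpmScore", function(x) standardGeneric("cpmScore"))

#' @rdname AssemblyEvaluation
#' @export
setMethod("cpmScore", "AssemblyEvaluation", function(x) x@cpm)
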