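# Assembly evaluation: generalized N-statistics, truth alignment with
# species labels, chimera index, nonchimeric rate, MAL/TAL, a composite
# performance metric, and mapping-rate comparison.

#' Generalized N-statistics (N10..N100)
#'
#' Nx is the length of the scaffold at which the cumulative sum of
#' descending-sorted lengths first reaches x percent of the total; N100 is
#' the shortest scaffold.
#'
#' @param lengths positive scaffold lengths.
#' @return named numeric vector N10..N100.
#' @export
nStatistics <- function(lengths) {
  if (!length(lengths) || any(lengths <= 0))
    stop("nStatistics needs >= 1 positive length")
  s <- sort(lengths, decreasing = TRUE)
  cs <- cumsum(s)
  tot <- cs[length(cs)]
  xs <- seq(10, 100, by = 10)
  setNames(vapply(xs, function(x) s[which(cs >= x / 100 * tot)[1]], 0),
           paste0("N", xs))
}

#' Classic N50
#' @param lengths positive scaffold lengths.
#' @return N50 in bp.
#' @export
n50 <- function(lengths) unname(nStatistics(lengths)["N50"])

#' Align an assembly to labelled truth genomes
#'
#' Shared-k-mer seeding per (scaffold, genome, orientation) diagonal;
#' contiguous seed runs (gaps up to \code{maxGap}) become gapless blocks,
#' verified by mismatch counting.  Blocks of at least \code{minBlock} bp at
#' \code{minIdentity} percent identity are kept; overlapping blocks on a
#' scaffold are resolved best-identity-first (longer first at equal
#' identity).
#'
#' @param assembly DNAStringSet or \linkS4class{MergedReference}.
#' @param truthGenomes DNAStringSet named by species.
#' @param minBlock minimum block length in bp.
#' @param minIdentity minimum percent identity.
#' @param k anchor k-mer size.
#' @param maxGap maximum seed gap bridged within one block, in bp.
#' @return data.frame with scaffold, species, s_start, s_end (scaffold
#'   interval), g_start, g_end (genome interval), orientation, identity.
#' @export
alignToTruth <- function(assembly, truthGenomes, minBlock = 1000L,
                         minIdentity = 95, k = 21L, maxGap = 100L) {
  if (is(assembly, "MergedReference")) assembly <- scaffolds(assembly)
  aC <- setNames(as.character(assembly), names(assembly))
  gC <- setNames(as.character(truthGenomes), names(truthGenomes))
  gt <- dropAmbiguousKmers(kmerTable(gC, k))
  setkey(gt, kmer)
  out <- list()
  for (orient in c("+", "-")) {
    sC <- if (orient == "+") aC else setNames(revComp(aC), names(aC))
    st <- dropAmbiguousKmers(kmerTable(sC, k))
    if (!nrow(st)) next
    setnames(st, c("id", "pos"), c("qid", "qpos"))
    setkey(st, kmer)
    hits <- gt[st, nomatch = NULL, allow.cartesian = TRUE]
    if (!nrow(hits)) next
    setnames(hits, c("id", "pos"), c("rid", "rpos"))
    hits[, diag_ := rpos - qpos]
    setorder(hits, qid, rid, diag_, qpos)
    hits[, piece := cumsum(c(1L, diff(qpos) > maxGap)),
         by = .(qid, rid, diag_)]
    blocks <- hits[, .(q1 = min(qpos), q2 = max(qpos) + k - 1L,
                       n_seed = .N),
                   by = .(qid, rid, diag_, piece)]
    blocks <- blocks[q2 - q1 + 1L >= minBlock]
    if (!nrow(blocks)) next
    for (i in seq_len(nrow(blocks))) {
      q <- blocks$qid[i]; r <- blocks$rid[i]; d <- blocks$diag_[i]
      q1 <- blocks$q1[i]; q2 <- blocks$q2[i]
      mm <- stringMismatches(substr(sC[[q]], q1, q2),
                             substr(gC[[r]], q1 + d, q2 + d))
      ident <- 100 * (1 - mm / (q2 - q1 + 1L))
      if (ident < minIdentity) next
      L <- nchar(aC[[q]])
      s1 <- if (orient == "+") q1 else L - q2 + 1L
      s2 <- if (orient == "+") q2 else L - q1 + 1L
      out[[length(out) + 1L]] <- data.frame(
        scaffold = q, species = r, s_start = s1, s_end = s2,
        g_start = q1 + d, g_end = q2 + d, orientation = orient,
        identity = ident, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(scaffold = character(), species = character(),
                      s_start = integer(), s_end = integer(),
                      g_start = integer(), g_end = integer(),
                      orientation = character(), identity = numeric()))
  df <- do.call(rbind, out)
  # resolve overlapping blocks per scaffold, best identity first
  df <- df[order(df$scaffold, -df$identity, -(df$s_end - df$s_start),
                 df$species, df$s_start), ]
  keep <- rep(TRUE, nrow(df))
  for (sc in unique(df$scaffold)) {
    idx <- which(df$scaffold == sc)
    taken <- IRanges()
    for (j in idx) {
      iv <- IRanges(df$s_start[j], df$s_end[j])
      ov <- IRanges::findOverlaps(iv, taken, minoverlap = 50L)
      if (length(ov)) keep[j] <- FALSE else taken <- c(taken, iv)
    }
  }
  df <- df[keep, ]
  df[order(df$scaffold, df$s_start), ]
}

#' Chimera index of an aligned assembly
#'
#' Length-weighted at scaffold granularity: the summed length of scaffolds
#' whose blocks span two or more species, divided by the summed length of
#' all scaffolds with at least one block.  NA (flagged) when nothing
#' aligned.
#'
#' @param blocks data.frame from \code{\link{alignToTruth}}.
#' @param scaffoldLengths named lengths of all assembly scaffolds.
#' @param weighting "length" (default) or "count" (fraction of scaffolds).
#' @return CI in [0, 1], or NA.
#' @export
chimeraIndex <- function(blocks, scaffoldLengths, weighting = c("length",
                                                                "count")) {
  weighting <- match.arg(weighting)
  if (!nrow(blocks)) {
    warning("chimera index undefined: no aligned scaffolds")
    return(NA_real_)
  }
  sp <- tapply(blocks$species, blocks$scaffold,
               function(x) length(unique(x)))
  aligned <- names(sp)
  chim <- aligned[sp >= 2L]
  if (weighting == "length")
    sum(scaffoldLengths[chim]) / sum(scaffoldLengths[aligned])
  else length(chim) / length(aligned)
}

#' Nonchimeric rate of a merged reference
#'
#' Percentage of assembly length attributable to a single species.  With
#' simulation truth, a merged scaffold's species set comes from the species
#' of origin of its provenance segments; otherwise from alignment block
#' labels.
#'
#' @param merged a \linkS4class{MergedReference} (preferred) or
#'   DNAStringSet.
#' @param speciesOf named vector scaffold/source-scaffold -> species (truth
#'   labels), used with provenance.
#' @param blocks alternative: alignment blocks from
#'   \code{\link{alignToTruth}}.
#' @return percent in [0, 100].
#' @export
nonchimericRate <- function(merged, speciesOf = NULL, blocks = NULL) {
  if (is(merged, "MergedReference") && !is.null(speciesOf)) {
    lens <- setNames(width(merged@scaffolds), names(merged@scaffolds))
    pv <- merged@provenance
    spp <- speciesOf[pv$source_scaffold]
    if (anyNA(spp)) stop("missing species label for source scaffold(s)")
    nsp <- tapply(spp, pv$merged_id, function(x) length(unique(x)))
    single <- names(nsp)[nsp == 1L]
    return(100 * sum(lens[single]) / sum(lens))
  }
  if (!is.null(blocks)) {
    lens <- if (is(merged, "MergedReference"))
      setNames(width(merged@scaffolds), names(merged@scaffolds))
    else setNames(width(merged), names(merged))
    if (!nrow(blocks)) stop("no labels available for nonchimeric rate")
    nsp <- tapply(blocks$species, blocks$scaffold,
                  function(x) length(unique(x)))
    single <- names(nsp)[nsp == 1L]
    return(100 * sum(lens[single]) / sum(lens))
  }
  stop("no species labels available (need speciesOf or blocks)")
}

#' Composite performance metric, MAL and TAL
#'
#' MAL is the longest alignment block; TAL the summed block length.  The
#' composite metric is N50_broken x (1 - CI) x (TAL / assembly bp), where
#' N50_broken is the N50 after splitting scaffolds at species-switch
#' points, so the score is monotone in contiguity, accuracy and
#' completeness.
#'
#' @param blocks data.frame from \code{\link{alignToTruth}}.
#' @param scaffoldLengths named lengths of all assembly scaffolds.
#' @return list with cpm, mal, tal, n50_broken, ci.
#' @export
compositeMetric <- function(blocks, scaffoldLengths) {
  totalBp <- sum(scaffoldLengths)
  if (!nrow(blocks))
    return(list(cpm = 0, mal = 0, tal = 0, n50_broken = NA_real_,
                ci = NA_real_))
  mal <- max(blocks$s_end - blocks$s_start + 1L)
  tal <- sum(blocks$s_end - blocks$s_start + 1L)
  ci <- chimeraIndex(blocks, scaffoldLengths)
  brokenLens <- numeric(0)
  for (sc in names(scaffoldLengths)) {
    b <- blocks[blocks$scaffold == sc, , drop = FALSE]
    if (!nrow(b)) { brokenLens <- c(brokenLens, scaffoldLengths[[sc]]); next }
    b <- b[order(b$s_start), , drop = FALSE]
    switches <- which(b$species[-1] != b$species[-nrow(b)])
    if (!length(switches)) {
      brokenLens <- c(brokenLens, scaffoldLengths[[sc]])
    } else {
      cuts <- floor((b$s_end[switches] + b$s_start[switches + 1L]) / 2)
      bounds <- c(0, cuts, scaffoldLengths[[sc]])
      brokenLens <- c(brokenLens, diff(bounds))
    }
  }
  n50b <- n50(brokenLens[brokenLens > 0])
  list(cpm = n50b * (1 - ci) * (tal / totalBp), mal = mal, tal = tal,
       n50_broken = n50b, ci = ci)
}

#' Evaluate an assembly against labelled truth genomes
#'
#' Convenience wrapper computing the N-statistic curve, alignment blocks,
#' chimera index, nonchimeric rate, MAL, TAL and the composite metric.
#'
#' @param assembly DNAStringSet or \linkS4class{MergedReference}.
#' @param truthGenomes DNAStringSet named by species.
#' @param speciesOf optional truth labels (source scaffold -> species) for
#'   provenance-based nonchimeric attribution; alignment labels are the
#'   fallback.
#' @param ... passed to \code{\link{alignToTruth}}.
#' @return an \linkS4class{AssemblyEvaluation}.
#' @export
evaluateAssembly <- function(assembly, truthGenomes, speciesOf = NULL,
                             ...) {
  seqs <- if (is(assembly, "MergedReference")) scaffolds(assembly)
  else assembly
  lens <- setNames(width(seqs), names(seqs))
  ns <- nStatistics(lens)
  blocks <- alignToTruth(assembly, truthGenomes, ...)
  ci <- suppressWarnings(chimeraIndex(blocks, lens))
  nc <- tryCatch(
    nonchimericRate(assembly, speciesOf = speciesOf,
                    blocks = if (is.null(speciesOf)) blocks else NULL),
    error = function(e) NA_real_)
  cm <- compositeMetric(blocks, lens)
  new("AssemblyEvaluation", n50 = unname(ns["N50"]), nstats = ns,
      ci = if (is.na(ci)) NA_real_ else ci,
      nonchimericRate = nc, mal = as.numeric(cm$mal),
      tal = as.numeric(cm$tal), cpm = as.numeric(cm$cpm), blocks = blocks)
}

#' Fraction of read pairs mapping to a reference
#'
#' @param reference DNAStringSet or \linkS4class{MergedReference}.
#' @param pairs read pair table (id, seq1, seq2).
#' @param ... passed to \code{\link{mapReads}}.
#' @return percent of pairs with at least one mapped mate.
#' @export
mappingRate <- function(reference, pairs, ...) {
  aln <- mapReads(reference, pairs, ...)
  anyMapped <- aln[, .(ok = any(mapped)), by = qname]
  100 * sum(anyMapped$ok) / nrow(pairs)
}
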